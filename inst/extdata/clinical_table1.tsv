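patient_id	age_at_dx	stage_gleason	fh_first_degree	fh_second_degree
112940	68	T2aN0MX/3+4=7	sister-ovary 27 and colon 66; sister-abdominal cancer early 60s; brother-prostate 59; mother-brain 52; father-unknown cancer	
117197	68	T3bN0MX/4+3=7	mother-stomach 80, colon 95	nephew-non Hodgkins 20s; maternal uncle-unknown cancer; maternal grandmother-colon 69; paternal uncle-prostate 62; paternal uncle-mouth 88
117939	65	T2cNOMX/3+3=6	father-prostate 65; 2 siblings w polyps	paternal uncle-throat 60; paternal uncle-prostate 65; maternal grandmother-breast 30; nephew-small cell desmoplastic tumor 28
123136	59	T2cNXMX/6	mother-colon mid 40s; father-lung 59; daughter-melanoma 25	
124604	44	T2cN0MX/3+3=6	father-melanoma 72, polyps	paternal uncle-colon 50; maternal uncle-prostate cancer 62; maternal uncle-prostate cancer 55; maternal grandfather-prostate cancer 88
124853	65	T2cNOMX/3+3=6	sister-basal cell 60; mother-stomach 59	paternal aunt-breast; paternal cousins daughter-ovarian 50s
125671	54	T2cN0MX/3+3=6	sister-uterine 54; sister-non Hodgkins 37; father-prostate 72; mother-kidney 76	paternal cousin-breast 36; paternal cousin-colon 58; maternal uncle-unknown cancer 30
126002	59	T3aN0MX/3+4=7 and 4+3=7 and 6 (multiple areas)		maternal aunt-unknown cancer 89; maternal cousin-colon 65; maternal cousin-brain 50s; maternal 1st cousin-leukemia 7, breast/skin 40s; paternal 1st cousin-brain 59
129413	57	T1c/3+4=7	father-prostate 70, kidney 80, liver 80; sister-precancerous uterine 47	paternal grandfather-prostate 85; paternal great-grandfather-stomach; paternal uncle-prostate 66
129547	62	T2cN0MX/3+4=7	sister-ovary 57, cervix 57	paternal cousin-inflammatory breast 45; maternal uncle-prostate 78; maternal uncle-prostate 78; maternal half uncle-pancreas 56; maternal half uncle-prostate 78; 2 maternal cousins-unknown cancer
129748	41	T3bN1M0/4+4=8	father-prostate 67	paternal grandfather-polyps; paternal great aunt-breast 30s
131534	52	T2cNO/3+4=7	mother-breast 68, melanoma 65; father-prostate 70	maternal aunt-colon 45; maternal aunt-polyps 40; maternal cousin-glioblastoma 26; paternal grandmother-lung
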
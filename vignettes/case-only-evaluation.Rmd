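---
title: "Case-only germline evaluation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-only germline evaluation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostvar)
library(dplyr)
```

## The problem

Familial prostate cancer risk is genetically heterogeneous: beyond a few
high-penetrance genes, risk is thought to accumulate from rare variants of
low-to-moderate effect, often in DNA damage response (DDR) and androgen
signaling genes. A common clinical reality is the *case-only* presentation -
a single affected proband with no genotyped relatives - which rules out
segregation analysis. prostvar implements a workflow for that setting:
restrict exome-derived germline variants to a hypothesis-driven candidate
gene panel, prioritize by a consensus of in-silico pathogenicity predictors,
annotate against population allele frequencies, summarize the cohort with a
DDR focus, and quantify a cellular DNA-damage phenotype (γH2AX foci) in
patient versus control lymphocytes.

The package ships a fully encoded 12-patient study (clinical table,
58 selected-variant rows with printed consensus scores and matched
European non-Finnish ExAC allele counts, and a 17-gene DDR list) as
plain-text, checksum-verified fixtures, plus a seeded synthetic-data
generator, so every stage runs with no downloads.

## Candidate gene panel

`build_panel()` merges heterogeneous source lists (curated DDR genes,
androgen-receptor interactors, tumor-sequencing recurrences, literature
mining, glycosylation disorders, ...) by plain set union after three
normalization steps:

1. **Alias resolution** against a packaged static snapshot
   (`load_fixture("aliases")`), case-insensitively. A live nomenclature
   service would not be reproducible as a fixed artifact; the snapshot
   covers the packaged study's symbol space (e.g. FANCN→PALB2,
   ARIP4→RAD54L2, MMS2→UBE2V2). Unmapped symbols are reported in an audit
   table, never silently dropped.
2. **Rank truncation**: "Top N" literature-mining sources are cut to their
   published ordering before merging; overlaps between such lists are
   resolved by plain union, since no tie-breaking rule is published.
3. **Locus-type exclusion**: phenotype-only loci (risk loci with no
   identified causative gene), non-coding transcripts and pseudogenes are
   removed with a logged reason.

Category tags (DDR, AR-related, hormone metabolism, ...) are assigned per
source, with per-gene overrides. The accounting invariant - normalized +
unmapped + excluded = deduplicated raw input, per source - is tested.

## Variant prioritization

`select_variants()` composes four row-wise predicates and a scorer; because
each stage is a row predicate, the composition equals the intersection of
predicates, which the tests verify against a brute-force row scan on 10^4
random variants.

* **Quality**: depth > 3 reads and quality score > 25, both strict.
* **Consequence**: synonymous and non-coding/unclassifiable ("other") calls
  are removed; splice-region records are retained.
* **Panel restriction** to the candidate genes.
* **Rarity**: matched-subpopulation allele frequency < 1% (`maf_cutoff =
  0.01`). Variants absent from the population table pass. Non-rare variants
  survive only when their gene is on a configurable whitelist - the
  carve-out for genes clearly relevant to hereditary cancer. For the
  packaged study the whitelist is `fixture_whitelist()`, the six genes whose
  printed variants exceed 1% (BRCA1, PALB2, FANCA, BLM, RAD51D, DOLK): the
  study's own retention decisions are the only machine-readable record of
  its carve-out. The rarity filter uses the matched subpopulation because
  that is the only frequency the tables carry per variant; this
  approximates "frequency in the general population".

### Consensus damage scoring

Five SNV predictors are converted to neutral / non-neutral calls:
PolyPhen-2 *probably/possibly damaging*, MutationAssessor *high/medium*,
SIFT *damaging* and PROVEAN *deleterious* are non-neutral; MutationTaster
*disease_causing(_automatic)* is non-neutral only when its probability
reaches 0.99. The cutoff is applied as ≥ 0.99 (the source rule states the
value without strictness); it is configurable (`mt_cutoff`).

A missense SNV is selected when at least 3 of the 5 predictors are
non-neutral. The count is always out of the fixed panel of five - an
unavailable predictor counts as not non-neutral - matching the printed
"n of 5" score semantics; a missense variant with *no* available predictor
is flagged unscorable instead. Two overrides:

* **Truncating** consequences (stop-gain, frameshift, start-loss) are
  selected automatically - the printed maximal-score ("5†") convention.
  Start-loss is included because the study prints it with that score.
* A **missense variant located in a splice site** is selected regardless of
  its consensus count (the study's "**" footnote).

Pure splice variants are selected as such. In-frame indels are evaluated
with PROVEAN and MutationTaster, plus SIFT-Indel when the indel length is
divisible by 3; they are selected when **at least one** applicable predictor
is non-neutral. The one-vs-all choice is not published (indels print no
score); `indel_rule = "all"` gives the stricter reading. Monotonicity -
upgrading any neutral call can never un-select a variant - is a tested
property.

The fixtures encode each printed score; `fixture_variant_table()`
reconstructs predictor columns from them (first *k* predictors in the fixed
order non-neutral), and the suite checks that scoring reproduces every
printed score and that the full pipeline re-selects all 58 rows. The one
irregularity: the AKR1C1 p.S221N change spans two adjacent nucleotide rows
in the printed table; the unscored second row inherits its companion's
score, and per-patient gene counts deduplicate by gene anyway.

## Population-frequency annotation

`annotate_frequency()` assigns a presence status per variant:
`present` (matched allele count > 0, with `frequency = ac/an`),
`absent_in_matched_subpop` (a zero matched count, or the allele seen only in
other ancestries - the printed "(0)"), `absent_everywhere` (no database
record - the printed "(−)"), or `excluded_by_database` for alleles a
database omits by policy (e.g. severe pediatric disease); those count as
previously reported, not novel. `tally_rare()` deduplicates by variant key
and counts variants below an allele-count threshold (default 20, the
"fewer than 20 individuals" criterion, operationalized as matched allele
count - the only printed quantity) and never-reported variants. On the
packaged study this yields 10 never-reported variants; the corresponding
printed "thirty alterations below 20 individuals" is *not* asserted
anywhere, because no single counting convention recovers it from printed
counts alone (the "(0)" rows' full-database counts are not printed) - the
package reports its tally (21 under the matched-count convention) without
claiming equality.

## Cohort reporting

* `parse_gleason()` accepts "a+b=c", "a+b", bare totals, and multi-area
  strings (maximum total across areas). `parse_stage_t()` extracts the TNM
  T category and tolerates the letter-O-for-digit-0 typography of printed
  tables ("T2cNOMX"). Unparseable entries are flagged and leave percentage
  denominators with a warning.
* Percentages are reported to the nearest integer, matching the cohort
  descriptors' printed rounding (58%, 25%, 33%).
* `recurrent_variant_incidence()` compares the observed carrier fraction
  with the Hardy-Weinberg expectation `1 − (1 − p)²` at the matched allele
  frequency. For BRCA1 p.Q356R this gives an observed 4/12 ≈ 33% versus an
  expected ≈ 12%; the source text quotes 9% without stating a method, and
  HWE on the printed frequency does not give 9%, so the package reports the
  HWE value and flags the discrepancy rather than asserting the printed
  number.
* DDR prevalence counts distinct affected genes per patient over the
  17-symbol packaged list; membership uses normalized symbols so alias
  forms collapse correctly.

## Functional assay statistics

Per-cell γH2AX foci counts are summarized to per-subject means before any
testing - subjects, not cells, are the independent units (a well yields
many images of the same biology). Choices, all configurable:

* **Group comparison**: Wilcoxon rank-sum, two-sided (exact where
  possible). The source analysis does not name its test; a rank test is
  robust at n = 9 vs 10 and consistent with the rank-based AUC. Welch's t
  is the alternative.
* **Cutoffs**: "statistically optimal" is operationalized as Youden's
  J = sensitivity + specificity − 1, maximized over midpoints between
  adjacent sorted unique scores; ties in J break toward the lower cutoff.
  The reported high/low classification counts are, by construction,
  consistent with applying the reported cutoff - a tested invariant.
* **Combination**: the combined two-treatment classifier is a linear rule in
  the aphidicolin × etoposide plane; the default is the sum of
  per-treatment z-standardized means (so combined scores have zero mean),
  with `max` and `either-above-cutoff` exposed, since the published rule is
  under-specified.
* **ROC/AUC**: the empirical AUC via the rank (Mann-Whitney) formulation
  with half credit for ties; the suite verifies equality with a brute-force
  all-pairs count and with an external reference implementation, plus the
  label-flip complement and monotone-transform invariances.

The study's printed assay numbers (p = 0.746 / 0.0337 / 0.007,
AUC = 0.8778, 7/9 vs 1/10 classification) depend on raw foci values that
are not published; they are therefore not asserted. Instead the package
demonstrates, by simulation at the stated design, that the statistics
recover the qualitative pattern (next section).

## The synthetic-data generator

`sim_config()` fixes every knob; generators are pure functions of the
configuration (same seed ⇒ identical output). Defaults encode the study
conditions: 12 patients with 3-7 candidate variants each; a 9-case /
10-control assay under vehicle, aphidicolin and etoposide.

* **Variants**: consequences in configurable proportions; QC fields
  straddle the depth/quality thresholds for 10% of rows; predictor calls
  are Bernoulli draws at concordance `c` = 0.9 for truly damaging variants
  and a 0.1 false-call rate for benign ones. The consensus rule's operating
  characteristic is the closed form `P(Binomial(5, c) ≥ 3)`
  (`consensus_sensitivity()`), verified by enumeration over all 2⁵ call
  patterns, and the end-to-end recovery test checks measured selection
  sensitivity against it within a binomial confidence band on 10⁴
  variants.
* **Population table**: a point mass of never-reported variants (17%,
  mirroring the packaged study's 10/58), a small subpopulation-absent
  fraction, and Beta-distributed allele frequencies with binomial allele
  counts for the rest.
* **Foci**: per-cell counts are negative binomial - foci counts are
  overdispersed across cells, so Poisson would understate cell-level
  variance (dispersion `size = 5` by default, configurable). A per-subject
  lognormal random effect (`sdlog = 0.4`) makes subjects the carriers of
  between-group variance; without it, subject means at many cells per
  subject would be nearly noiseless and any effect would be detected
  trivially. Drug treatments multiply everyone's mean (2× aphidicolin,
  2.5× etoposide); the case multiplier (default 2×) applies **only under
  drug treatment**, so the baseline is indistinguishable between groups by
  construction - the study's design.

What the generator does *not* emulate: linkage between variants, real gene
lengths and mutation spectra, predictor-predictor correlation (calls are
conditionally independent given the damage state), ancestry structure in
allele frequencies, and dose-response in the assay. Passing recovery tests
therefore show the *statistics* behave as designed under the assumed model,
not that the model captures every feature of real cohorts.

## Numerical choices and degenerate inputs

* QC thresholds are strict (`depth > 3`, `qual > 25`); records missing QC
  fields are dropped with a warning, not an error.
* MutationTaster cutoff applied as ≥ 0.99.
* Youden ties break to the lower cutoff; constant scores give a flagged
  degenerate cutoff. AUC ties get half credit.
* An empty variant table (or one emptied by filtering) produces an empty
  report and a warning, not an error; patients with no selected variants
  get explicit zero gene counts when a roster is supplied.
* Fixtures are MD5-verified at load; a checksum mismatch is an error.

## Problem sizes used by the test suite

The suite exercises the oracle equivalences at 10⁴ random variants, the
consensus-recovery check at ~10⁴ missense variants, and the assay
calibration at 500 simulated cohorts of 19 subjects × 3 treatments × 20
cells (null calibration: uniform p-values at multiplier 1; pattern
recovery: baseline non-significant and treated discriminative at
multiplier 3). These sizes give stable Monte-Carlo behavior at desk scale;
all are plain function arguments and can be raised.

## Known limitations

* The 826-gene panel of the original study is not reproducible from
  machine-readable sources, and its "84 extracted SNVs" depend on raw
  exomes that were never deposited; the panel builder is validated on its
  published 17-gene DDR sub-list and on synthetic sources instead.
* Predictor outputs are consumed as inputs; the package never re-runs
  PolyPhen-2/SIFT/PROVEAN/MutationAssessor/MutationTaster.
* HGVS strings are carried as annotations and validated only syntactically;
  there is no re-annotation against transcripts and no genome-build
  lift-over.
* The whitelist semantics, indel rule, combination rule and test choice are
  documented interpretations of under-specified published procedures; all
  are configurable arguments with the package's defaults stated above.
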
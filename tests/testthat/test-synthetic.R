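test_that("generators are pure functions of the configuration seed", {
  cfg <- sim_config(seed = 101L)
  a <- synth_variant_table(cfg)
  b <- synth_variant_table(cfg)
  expect_identical(a, b)
  expect_identical(synth_foci(cfg), synth_foci(cfg))
  expect_identical(synth_population_table(cfg, a$variants),
                   synth_population_table(cfg, a$variants))
  # a different seed changes the draws
  expect_false(identical(a, synth_variant_table(sim_config(seed = 102L))))
})

test_that("perfect predictor concordance scores every damaging missense 5/5", {
  cfg <- sim_config(seed = 7L, n_patients = 40L,
                    predictor_concordance = 1, predictor_false_rate = 0,
                    consequence_probs = c(missense = 1),
                    damaging_fraction = 1, qc_fail_fraction = 0)
  sv <- synth_variant_table(cfg)
  scored <- score_variants(sv$variants)
  expect_true(all(scored$n_non_neutral == 5L))
  expect_true(all(scored$selected))
})

test_that("at concordance 0.5 consensus counts follow Binomial(5, 0.5)", {
  cfg <- sim_config(seed = 31L, n_patients = 1500L,
                    variants_per_patient = c(7L, 7L),
                    predictor_concordance = 0.5, predictor_false_rate = 0.5,
                    consequence_probs = c(missense = 1),
                    qc_fail_fraction = 0)
  sv <- synth_variant_table(cfg)
  scored <- score_variants(sv$variants)
  obs <- tabulate(scored$n_non_neutral + 1L, nbins = 6L)
  expected <- dbinom(0:5, 5, 0.5) * nrow(scored)
  chisq <- sum((obs - expected)^2 / expected)
  expect_lt(chisq, qchisq(0.999, df = 5))
})

test_that("population generator hits its absent-everywhere fraction", {
  cfg <- sim_config(seed = 47L, n_patients = 1500L,
                    variants_per_patient = c(7L, 7L),
                    maf_absent_fraction = 0.17)
  sv <- synth_variant_table(cfg)
  sp <- synth_population_table(cfg, sv$variants)
  ann <- annotate_frequency(sv$variants, sp$popfreq)
  tall <- tally_rare(ann)
  frac <- tall$n_never_reported / tall$n_variants
  se <- sqrt(0.17 * 0.83 / tall$n_variants)
  expect_lt(abs(frac - 0.17), 4 * se)
  # generator truth agrees with the annotation status
  truth_absent <- sum(sp$truth$presence == "absent_everywhere")
  expect_equal(tall$n_never_reported, truth_absent)
})

test_that("zero-frequency population rows give zero allele counts", {
  cfg <- sim_config(seed = 3L, maf_beta = c(1e-6, 1),
                    maf_absent_fraction = 0, maf_subpop_absent_fraction = 0)
  sv <- synth_variant_table(cfg)
  sp <- synth_population_table(cfg, sv$variants)
  expect_true(all(sp$popfreq$allele_count == 0))
})

test_that("foci generator matches its configured moments and design", {
  cfg <- sim_config(seed = 11L, cells_per_sample = 4000L, subject_sdlog = 0,
                    case_multiplier = 2)
  foci <- synth_foci(cfg)
  expect_equal(nrow(foci), (9 + 10) * 3 * 4000)
  base <- foci$foci_count[foci$treatment == "vehicle" &
                            foci$group == "control"]
  # mean ~ baseline_mean; variance ~ mu + mu^2/size (negative binomial)
  expect_equal(mean(base), 4, tolerance = 0.05)
  expect_equal(var(base), 4 + 16 / 5, tolerance = 0.1)
  # case multiplier applies under treatment only
  s <- summarize_foci(foci)
  m <- tapply(s$mean_foci, list(s$group, s$treatment), mean)
  expect_equal(m["case", "vehicle"] / m["control", "vehicle"], 1,
               tolerance = 0.05)
  expect_equal(m["case", "etoposide"] / m["control", "etoposide"], 2,
               tolerance = 0.1)
})

test_that("the consensus operating characteristic closed form is correct", {
  # brute-force enumeration over all 2^5 call patterns
  for (c0 in c(0.3, 0.7, 0.9)) {
    pats <- expand.grid(rep(list(c(0, 1)), 5))
    p_pat <- apply(pats, 1, function(r) prod(ifelse(r == 1, c0, 1 - c0)))
    want <- sum(p_pat[rowSums(pats) >= 3])
    expect_equal(consensus_sensitivity(c0), want)
  }
})

test_that("simulate_all writes a round-trippable bundle", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 5L)
  simulate_all(cfg, dir)
  v <- read_variant_table(file.path(dir, "variants.tsv"))
  p <- read_population_table(file.path(dir, "popfreq.tsv"))
  f <- read_foci_table(file.path(dir, "foci.tsv"))
  sv <- synth_variant_table(cfg)
  expect_equal(nrow(v), nrow(sv$variants))
  expect_equal(as.data.frame(f), as.data.frame(synth_foci(cfg)))
  expect_true(all(p$allele_count <= p$allele_number))
})
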
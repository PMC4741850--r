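make_summary <- function(case_scores, control_scores,
                         treatment = "etoposide") {
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_along(c(case_scores, control_scores))),
    group = rep(c("case", "control"),
                c(length(case_scores), length(control_scores))),
    treatment = treatment,
    mean_foci = c(case_scores, control_scores))
}

test_that("per-cell counts are summarized to per-subject means", {
  long <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 4), group = "case",
    treatment = "vehicle", cell = rep(1:4, 2),
    foci_count = c(1, 2, 3, 4, 10, 10, 10, 10))
  s <- summarize_foci(long)
  expect_equal(s$mean_foci, c(2.5, 10))
  expect_equal(s$n_cells, c(4L, 4L))
  # summary-form input passes through
  expect_equal(summarize_foci(s), s)
})

test_that("rank test on a small design equals exact permutation enumeration", {
  d <- make_summary(c(8.1, 9.4, 12.0), c(3.2, 4.4, 5.1))
  got <- group_compare(d, "etoposide")
  expect_equal(got$p_value, oracle_ranksum_p(c(8.1, 9.4, 12.0),
                                             c(3.2, 4.4, 5.1)))
  # identical group distributions: p near 1
  same <- make_summary(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 0.5))
  expect_gt(group_compare(same, "etoposide")$p_value, 0.5)
  expect_error(group_compare(d, "aphidicolin"), "both groups")
})

test_that("Youden cutoff equals an exhaustive midpoint scan", {
  set.seed(5)
  for (i in 1:20) {
    sc <- round(c(rnorm(9, 8, 3), rnorm(10, 5, 3)), 2)
    d <- make_summary(sc[1:9], sc[10:19])
    got <- optimal_cutoff(d, mean_foci, group)
    want <- oracle_cutoff(sc, d$group)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$j, want$j)
    # reported classification counts are consistent with applying the cutoff
    expect_equal(got$n_cases_high, sum(sc[1:9] > got$cutoff))
    expect_equal(got$n_controls_high, sum(sc[10:19] > got$cutoff))
  }
})

test_that("perfect separation gives J = 1; constant scores are degenerate", {
  d <- make_summary(c(10, 11, 12), c(1, 2, 3))
  got <- optimal_cutoff(d, mean_foci, group)
  expect_equal(got$j, 1)
  expect_equal(got$n_cases_high, 3L)
  expect_equal(got$n_controls_high, 0L)
  flat <- make_summary(c(5, 5), c(5, 5))
  expect_warning(deg <- optimal_cutoff(flat, mean_foci, group), "degenerate")
  expect_true(deg$degenerate)
})

test_that("a cohort built around a known cutoff is recovered as 7/9 vs 1/10", {
  # cases: 7 above 10 foci, 2 well below; controls: 1 above, 9 in 6-9.5
  cases <- c(10.8, 11.2, 11.9, 12.5, 13.1, 14.0, 15.3, 4.1, 5.2)
  controls <- c(12.2, 6.2, 6.8, 7.1, 7.5, 8.0, 8.4, 8.8, 9.1, 9.5)
  d <- make_summary(cases, controls)
  got <- optimal_cutoff(d, mean_foci, group)
  expect_equal(got$n_cases_high, 7L)
  expect_equal(got$n_controls_high, 1L)
})

test_that("combined z-scores have zero mean and reduce to one treatment", {
  d2 <- dplyr::bind_rows(
    make_summary(c(8, 9, 12, 7), c(3, 4, 5, 6), "aphidicolin"),
    make_summary(c(7, 8, 11, 6), c(2, 5, 4, 3), "etoposide"))
  comb <- combine_treatments(d2)
  expect_equal(mean(comb$combined_score), 0, tolerance = 1e-12)
  one <- combine_treatments(d2, treatments = "etoposide")
  z <- scale(d2$mean_foci[d2$treatment == "etoposide"])
  expect_equal(sort(one$combined_score), sort(as.numeric(z)))
  # subjects missing a treatment are excluded with a warning
  expect_warning(
    short <- combine_treatments(d2[-1, ]),
    "missing a treatment")
  expect_equal(nrow(short), 7L)
})

test_that("AUC equals the all-pairs oracle, with half credit for ties", {
  set.seed(9)
  for (i in 1:15) {
    sc <- round(c(rnorm(9, 7, 2), rnorm(10, 5, 2)), 1)  # rounding makes ties
    d <- make_summary(sc[1:9], sc[10:19])
    got <- roc_auc(d, mean_foci, group)
    expect_equal(got$auc, oracle_auc(sc, d$group))
  }
})

test_that("AUC agrees with an external reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- c(rnorm(9, 7, 2), rnorm(10, 5, 2))
  d <- make_summary(sc[1:9], sc[10:19])
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = d$group, predictor = d$mean_foci, levels = c("control", "case"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(d, mean_foci, group)$auc, ref)
})

test_that("ROC invariances: label flip complements, monotone transforms fix AUC", {
  set.seed(17)
  sc <- c(rnorm(9, 7, 2), rnorm(10, 5, 2))
  d <- make_summary(sc[1:9], sc[10:19])
  a <- roc_auc(d, mean_foci, group)$auc
  flipped <- roc_auc(d, mean_foci, group, positive = "control")$auc
  expect_equal(a + flipped, 1)
  d2 <- dplyr::mutate(d, mean_foci = exp(mean_foci / 3))
  expect_equal(roc_auc(d2, mean_foci, group)$auc, a)
  # perfectly separated scores give AUC 1
  sep <- make_summary(c(10, 11), c(1, 2))
  expect_equal(roc_auc(sep, mean_foci, group)$auc, 1)
  expect_error(roc_auc(sep[1:2, ], mean_foci, group), "both classes")
})

test_that("ROC curve is monotone and tidy/glance expose it", {
  d <- make_summary(c(8, 9, 12, 7), c(3, 9, 5, 6))
  r <- roc_auc(d, mean_foci, group)
  pts <- tidy(r)
  expect_true(all(diff(pts$sensitivity) <= 0))
  expect_true(all(diff(pts$specificity) >= 0))
  g <- glance(r)
  expect_equal(g$auc, r$auc)
  expect_s3_class(autoplot(r), "ggplot")
})
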
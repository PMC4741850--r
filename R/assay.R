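#' Read a gamma-H2AX foci table
#'
#' Long per-cell format (`subject_id, group, treatment, cell, foci_count`) or
#' per-subject summary format (`subject_id, group, treatment, mean_foci`).
#'
#' @param path TSV path.
#' @return Foci tibble.
#' @export
read_foci_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject_id = "c", group = "c", treatment = "c", .default = "d"),
    progress = FALSE)
}

#' Summarize per-cell foci counts to per-subject means
#'
#' Subjects, not cells, are the independent units: all testing operates on
#' the mean foci/cell per subject and treatment. Input already in summary
#' form passes through unchanged.
#'
#' @param foci Foci tibble (long per-cell or summary form).
#' @return Tibble `subject_id, group, treatment, mean_foci, n_cells`.
#' @export
summarize_foci <- function(foci) {
  if ("mean_foci" %in% names(foci)) {
    return(as_tibble(foci))
  }
  stopifnot("foci_count" %in% names(foci))
  foci %>%
    group_by(.data$subject_id, .data$group, .data$treatment) %>%
    summarise(mean_foci = mean(.data$foci_count), n_cells = n(),
              .groups = "drop")
}

#' Case/control comparison of foci induction under one treatment
#'
#' Two-sample test on per-subject mean foci/cell. The default is the
#' Wilcoxon rank-sum (Mann-Whitney) test, two-sided, exact where possible;
#' Welch's t is available as an alternative.
#'
#' @param foci Foci tibble.
#' @param treatment Treatment label to test (e.g. `"etoposide"`).
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @param case_label,control_label Group labels.
#' @return One-row tibble: `treatment, statistic, p_value, n_case,
#'   n_control, method`.
#' @export
group_compare <- function(foci, treatment, test = c("wilcoxon", "welch"),
                          case_label = "case", control_label = "control") {
  test <- match.arg(test)
  s <- summarize_foci(foci)
  s <- s[s$treatment == treatment, , drop = FALSE]
  x <- s$mean_foci[s$group == case_label]
  y <- s$mean_foci[s$group == control_label]
  if (length(x) == 0L || length(y) == 0L) {
    abort(sprintf("both groups must be present for treatment '%s'", treatment))
  }
  fit <- if (test == "wilcoxon") {
    suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  } else {
    t.test(x, y, alternative = "two.sided")
  }
  tibble(treatment = treatment, statistic = unname(fit$statistic),
         p_value = fit$p.value, n_case = length(x), n_control = length(y),
         method = test)
}

#' Youden-optimal cutoff for a case/control score
#'
#' Scans the midpoints between adjacent sorted unique scores and returns the
#' cutoff maximizing Youden's J = sensitivity + specificity - 1, where a
#' subject is called "high" when its score exceeds the cutoff. Ties in J are
#' broken toward the lower cutoff. If all scores are identical the cutoff is
#' degenerate and flagged.
#'
#' @param data Tibble with one row per subject.
#' @param score Column (unquoted) holding the score.
#' @param group Column (unquoted) holding the case/control label.
#' @param positive Label treated as case (default `"case"`).
#' @return A `prostvar_cutoff` one-row tibble: `cutoff, j, sensitivity,
#'   specificity, n_cases_high, n_controls_high, n_cases, n_controls,
#'   degenerate`.
#' @export
optimal_cutoff <- function(data, score, group, positive = "case") {
  sc <- dplyr::pull(data, {{ score }})
  gr <- dplyr::pull(data, {{ group }})
  is_case <- gr == positive
  if (!any(is_case) || all(is_case)) {
    abort("both case and control labels must be represented")
  }
  u <- sort(unique(sc))
  degenerate <- length(u) < 2L
  cand <- if (degenerate) u[1] else (u[-length(u)] + u[-1]) / 2
  n1 <- sum(is_case); n0 <- sum(!is_case)
  sens <- vapply(cand, function(ct) sum(sc[is_case] > ct) / n1, numeric(1))
  spec <- vapply(cand, function(ct) sum(sc[!is_case] <= ct) / n0, numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # candidates ascend, so first max = lowest cutoff
  ct <- cand[best]
  out <- tibble(cutoff = ct, j = j[best], sensitivity = sens[best],
                specificity = spec[best],
                n_cases_high = sum(sc[is_case] > ct),
                n_controls_high = sum(sc[!is_case] > ct),
                n_cases = n1, n_controls = n0, degenerate = degenerate)
  if (degenerate) warn("all scores identical: cutoff is degenerate")
  class(out) <- c("prostvar_cutoff", class(out))
  out
}

#' Combine per-treatment foci scores into one score per subject
#'
#' The default combination is the sum of per-treatment z-standardized mean
#' foci/cell (standardized across all subjects within each treatment), the
#' linear rule used for the combined case/control classification.
#' Alternatives: `"max"` (maximum of the standardized scores) and `"either"`
#' (indicator that the subject exceeds the per-treatment Youden cutoff under
#' at least one treatment). Subjects missing any named treatment are excluded
#' with a warning.
#'
#' @param foci Foci tibble.
#' @param treatments Character vector of treatments to combine.
#' @param method `"zsum"` (default), `"max"` or `"either"`.
#' @param positive Case label (used by `"either"`).
#' @return Tibble `subject_id, group, combined_score`.
#' @export
combine_treatments <- function(foci, treatments = c("aphidicolin",
                                                    "etoposide"),
                               method = c("zsum", "max", "either"),
                               positive = "case") {
  method <- match.arg(method)
  s <- summarize_foci(foci)
  s <- s[s$treatment %in% treatments, , drop = FALSE]
  complete <- s %>%
    count(.data$subject_id) %>%
    filter(.data$n == length(treatments)) %>%
    pull(.data$subject_id)
  dropped <- setdiff(unique(s$subject_id), complete)
  if (length(dropped)) {
    warn(sprintf("subject(s) missing a treatment, excluded: %s",
                 paste(dropped, collapse = ", ")))
  }
  s <- s[s$subject_id %in% complete, , drop = FALSE]
  if (method == "either") {
    flags <- lapply(treatments, function(tr) {
      d <- s[s$treatment == tr, , drop = FALSE]
      ct <- optimal_cutoff(d, .data$mean_foci, .data$group,
                           positive = positive)$cutoff
      tibble(subject_id = d$subject_id, group = d$group,
             high = d$mean_foci > ct)
    })
    out <- bind_rows(flags) %>%
      group_by(.data$subject_id, .data$group) %>%
      summarise(combined_score = as.numeric(any(.data$high)),
                .groups = "drop")
    return(arrange(out, .data$subject_id))
  }
  z <- s %>%
    group_by(.data$treatment) %>%
    mutate(z = as.numeric(scale(.data$mean_foci))) %>%
    ungroup()
  out <- z %>%
    group_by(.data$subject_id, .data$group) %>%
    summarise(combined_score = if (method == "zsum") sum(.data$z) else
      max(.data$z), .groups = "drop")
  arrange(out, .data$subject_id)
}

#' Empirical ROC curve and AUC
#'
#' AUC via the rank (Mann-Whitney) formulation with half credit for ties:
#' `AUC = (R1 - n1(n1+1)/2) / (n1 n0)` where `R1` is the sum of mid-ranks of
#' case scores. Operating points are computed at every unique score
#' threshold (a subject is positive when its score exceeds the threshold).
#'
#' @param data Tibble with one row per subject.
#' @param score Column (unquoted) holding the score.
#' @param group Column (unquoted) holding the label.
#' @param positive Label treated as case.
#' @return A `prostvar_roc` object: list with `auc`, `points` (tibble
#'   `threshold, sensitivity, specificity`), `n_case`, `n_control`.
#' @export
roc_auc <- function(data, score, group, positive = "case") {
  sc <- dplyr::pull(data, {{ score }})
  gr <- dplyr::pull(data, {{ group }})
  is_case <- gr == positive
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  r <- rank(sc)  # mid-ranks: ties get half credit
  auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(-Inf, sort(unique(sc)))
  pts <- tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) sum(sc[is_case] > t) / n1,
                         numeric(1)),
    specificity = vapply(thr, function(t) sum(sc[!is_case] <= t) / n0,
                         numeric(1)))
  structure(list(auc = auc, points = pts, n_case = n1, n_control = n0),
            class = "prostvar_roc")
}

#' @export
print.prostvar_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d cases vs %d controls)\n",
              x$auc, x$n_case, x$n_control))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ROC result into its operating points
#' @param x A `prostvar_roc` object.
#' @param ... Unused.
#' @return Tibble `threshold, sensitivity, specificity`.
#' @method tidy prostvar_roc
#' @export
tidy.prostvar_roc <- function(x, ...) x$points

#' One-row AUC summary of an ROC result
#' @param x A `prostvar_roc` object.
#' @param ... Unused.
#' @return Tibble `auc, n_case, n_control`.
#' @method glance prostvar_roc
#' @export
glance.prostvar_roc <- function(x, ...) {
  tibble(auc = x$auc, n_case = x$n_case, n_control = x$n_control)
}

#' Tidy a cutoff result
#' @param x A `prostvar_cutoff` object.
#' @param ... Unused.
#' @return The underlying one-row tibble.
#' @method tidy prostvar_cutoff
#' @export
tidy.prostvar_cutoff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "prostvar_cutoff")
  out
}

#' Plot an ROC curve
#' @param object A `prostvar_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prostvar_roc
#' @export
autoplot.prostvar_roc <- function(object, ...) {
  pts <- arrange(object$points, .data$sensitivity)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.4f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-subject foci by group and treatment
#'
#' Jittered per-subject mean foci/cell with optional Youden cutoff lines per
#' treatment.
#'
#' @param foci Foci tibble.
#' @param cutoffs Optional tibble `treatment, cutoff` (e.g. built from
#'   [optimal_cutoff()] per treatment) drawn as dashed lines.
#' @return A ggplot.
#' @export
plot_foci <- function(foci, cutoffs = NULL) {
  s <- summarize_foci(foci)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$group, y = .data$mean_foci,
                                       colour = .data$group,
                                       shape = .data$group)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::facet_wrap(~treatment, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Mean γH2AX foci per cell") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(cutoffs)) {
    p <- p + ggplot2::geom_hline(data = cutoffs,
                                 ggplot2::aes(yintercept = .data$cutoff),
                                 linetype = "dashed", colour = "grey30")
  }
  p
}
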
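#' Pipeline configuration
#'
#' Thresholds and options for a full run, defaulting to the study's stated
#' values: depth > 3 reads, quality > 25, rarity < 1%, MutationTaster cutoff
#' 0.99, rare-count threshold 20, matched subpopulation "European
#' non-Finnish".
#'
#' @param min_reads,min_qual QC thresholds (strict).
#' @param maf_cutoff Rarity cutoff (fraction).
#' @param mt_cutoff MutationTaster probability cutoff.
#' @param rare_count_threshold Allele-count threshold for the rare tally.
#' @param subpop Matched subpopulation label.
#' @param whitelist Genes exempt from the rarity cutoff.
#' @param min_predictors Consensus threshold.
#' @param indel_rule `"any"` or `"all"`.
#' @param assay_test `"wilcoxon"` or `"welch"`.
#' @param assay_treatments Treatments combined for classification.
#' @param assay_combine `"zsum"`, `"max"` or `"either"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_reads = 3, min_qual = 25, maf_cutoff = 0.01,
                            mt_cutoff = 0.99, rare_count_threshold = 20,
                            subpop = "European non-Finnish",
                            whitelist = NULL, min_predictors = 3,
                            indel_rule = "any", assay_test = "wilcoxon",
                            assay_treatments = c("aphidicolin", "etoposide"),
                            assay_combine = "zsum") {
  cfg <- as.list(environment())
  stopifnot(cfg$min_reads > 0, cfg$min_qual > 0, cfg$maf_cutoff > 0,
            cfg$mt_cutoff > 0, cfg$rare_count_threshold > 0)
  structure(cfg, class = "pipeline_config")
}

#' Run the full evaluation pipeline
#'
#' Composes the stages: variant selection ([select_variants()]),
#' population-frequency tallies ([tally_rare()]), clinical and cohort
#' summaries ([clinical_summary()], [genes_per_patient()],
#' [ddr_prevalence()]), and, when foci data are supplied, the functional
#' assay statistics (per-treatment [group_compare()], [optimal_cutoff()]
#' and combined-score [roc_auc()]). Per-stage in/out record counts are
#' collected in the report's `log`.
#'
#' @param variants Annotated variant tibble (input schema).
#' @param clinical Clinical tibble.
#' @param panel Panel tibble / symbol vector, or `NULL`.
#' @param popfreq Population tibble, or `NULL`.
#' @param ddr_genes DDR gene symbols for prevalence reporting.
#' @param foci Optional foci tibble.
#' @param config A [pipeline_config()].
#' @param db_excluded_keys Optional database-excluded variant keys.
#' @return A `pipeline_report` list: `selected`, `tally`, `clinical`,
#'   `genes_per_patient`, `ddr`, `assay` (or `NULL`), `log`, `config`.
#' @export
run_pipeline <- function(variants, clinical, panel = NULL, popfreq = NULL,
                         ddr_genes = character(), foci = NULL,
                         config = pipeline_config(),
                         db_excluded_keys = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  n_in <- nrow(variants)
  selected <- select_variants(
    variants, panel = panel, popfreq = popfreq,
    maf_cutoff = config$maf_cutoff, whitelist = config$whitelist,
    subpop = config$subpop, db_excluded_keys = db_excluded_keys,
    min_reads = config$min_reads, min_qual = config$min_qual,
    min_predictors = config$min_predictors, mt_cutoff = config$mt_cutoff,
    indel_rule = config$indel_rule)
  if (n_in > 0 && nrow(selected) == 0) {
    warn("no variants selected")
  }
  tally <- if (!is.null(popfreq)) {
    tally_rare(selected, count_threshold = config$rare_count_threshold)
  } else NULL
  patients <- as.character(clinical$patient_id)
  clin <- clinical_summary(clinical)
  gpp <- genes_per_patient(selected, patients = patients)
  ddr <- if (length(ddr_genes)) {
    ddr_prevalence(selected, ddr_genes, patients = patients)
  } else NULL
  assay <- if (!is.null(foci)) {
    treatments <- unique(summarize_foci(foci)$treatment)
    comparisons <- bind_rows(lapply(
      treatments, function(tr) group_compare(foci, tr,
                                             test = config$assay_test)))
    cutoffs <- bind_rows(lapply(config$assay_treatments, function(tr) {
      d <- summarize_foci(foci)
      d <- d[d$treatment == tr, , drop = FALSE]
      mutate(tidy(optimal_cutoff(d, .data$mean_foci, .data$group)),
             treatment = tr, .before = 1)
    }))
    combined <- combine_treatments(foci,
                                   treatments = config$assay_treatments,
                                   method = config$assay_combine)
    roc <- roc_auc(combined, .data$combined_score, .data$group)
    combined_cutoff <- optimal_cutoff(combined, .data$combined_score,
                                      .data$group)
    list(comparisons = comparisons, cutoffs = cutoffs, combined = combined,
         combined_cutoff = combined_cutoff, roc = roc)
  } else NULL
  log <- tibble(
    stage = c("input", "selected"),
    n = c(n_in, nrow(selected)))
  structure(list(selected = selected, tally = tally, clinical = clin,
                 genes_per_patient = gpp, ddr = ddr, assay = assay,
                 log = log, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Case-only evaluation report\n")
  cat(sprintf("  patients: %d | selected variant rows: %d\n",
              x$clinical$n_patients, nrow(x$selected)))
  cat(sprintf("  mean age %.1f (range %d-%d); Gleason >=7: %d%%; T3: %d%%\n",
              x$clinical$mean_age, x$clinical$age_min, x$clinical$age_max,
              x$clinical$pct_gleason_ge7, x$clinical$pct_stage_t3))
  if (!is.null(x$tally)) {
    cat(sprintf("  unique variants: %d | below rare-count threshold: %d | never reported: %d\n",
                x$tally$n_variants, x$tally$n_below_threshold,
                x$tally$n_never_reported))
  }
  if (nrow(x$genes_per_patient)) {
    cat(sprintf("  genes per patient: %d-%d\n",
                min(x$genes_per_patient$n_genes),
                max(x$genes_per_patient$n_genes)))
  }
  if (!is.null(x$ddr)) {
    cat(sprintf("  DDR: %d/%d patients with >=1 gene, %d/%d with >=2\n",
                x$ddr$n_ge1, x$ddr$n_patients, x$ddr$n_ge2, x$ddr$n_patients))
  }
  if (!is.null(x$assay)) {
    cat(sprintf("  assay: combined AUC = %.4f\n", x$assay$roc$auc))
  }
  invisible(x)
}

#' Reproduce the packaged study from fixtures
#'
#' Runs the full pipeline on the packaged tables only (no downloads, no
#' randomness) and returns the headline quantities: clinical summary,
#' genes-per-patient span, DDR prevalence, rare/novel variant tallies and
#' the recurrent-variant incidence for BRCA1 p.Q356R.
#'
#' @return A list: `report` (the `pipeline_report`), `recurrent` (the
#'   BRCA1 p.Q356R incidence tibble), `summary` (named list of headline
#'   numbers).
#' @export
reproduce_study <- function() {
  variants <- fixture_variant_table()
  clinical <- load_fixture("clinical")
  popfreq <- fixture_population_table()
  ddr <- fixture_ddr_genes()
  config <- pipeline_config(whitelist = fixture_whitelist())
  report <- run_pipeline(variants, clinical,
                         panel = unique(variants$gene), popfreq = popfreq,
                         ddr_genes = ddr, config = config,
                         db_excluded_keys = fixture_db_excluded_keys())
  recurrent <- recurrent_variant_incidence(
    report$selected, chrom = "17", pos = 41246481, ref = "T", alt = "C",
    popfreq = popfreq, n_patients = nrow(clinical))
  summary <- list(
    mean_age = report$clinical$mean_age,
    age_min = report$clinical$age_min,
    age_max = report$clinical$age_max,
    pct_gleason_ge7 = report$clinical$pct_gleason_ge7,
    pct_stage_t3 = report$clinical$pct_stage_t3,
    genes_per_patient_min = min(report$genes_per_patient$n_genes),
    genes_per_patient_max = max(report$genes_per_patient$n_genes),
    ddr_n_ge1 = report$ddr$n_ge1,
    ddr_n_ge2 = report$ddr$n_ge2,
    n_never_reported = report$tally$n_never_reported,
    n_below_rare_threshold = report$tally$n_below_threshold,
    brca1_q356r_observed_pct = recurrent$observed_pct,
    brca1_q356r_expected_pct = recurrent$expected_pct)
  list(report = report, recurrent = recurrent, summary = summary)
}
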
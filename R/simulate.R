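#' Simulation configuration
#'
#' One object holds every knob of the synthetic-data generators. Defaults
#' encode the study design the package reproduces: 12 sequenced patients,
#' a gamma-H2AX assay with 9 cases versus 10 controls under three treatments
#' (vehicle, aphidicolin, etoposide), 3-7 candidate-list variants per
#' patient, a 1% rarity cutoff regime with a point mass of never-reported
#' variants, five SNV predictors whose per-predictor concordance with the
#' true damage state drives the 3-of-5 consensus rule, and negative-binomial
#' per-cell foci counts whose case multiplier applies under drug treatment
#' only (baseline indistinguishable by design).
#'
#' @param seed Integer seed fixing all draws.
#' @param n_patients Number of sequenced patients.
#' @param n_genes Candidate panel size for simulation.
#' @param ddr_fraction Fraction of panel genes tagged DDR.
#' @param variants_per_patient Integer range (min, max) sampled uniformly.
#' @param damaging_fraction Fraction of generated variants that are truly
#'   damaging.
#' @param consequence_probs Named numeric vector of consequence proportions
#'   (must cover missense/stop_gain/frameshift/inframe_indel/splice/
#'   synonymous).
#' @param qc_fail_fraction Fraction of rows generated with depth/quality
#'   straddling (failing) the QC thresholds.
#' @param predictor_concordance Probability a truly damaging variant draws a
#'   non-neutral call, per predictor.
#' @param predictor_false_rate Probability a benign variant draws a
#'   non-neutral call, per predictor.
#' @param maf_absent_fraction Fraction of variants absent from the population
#'   database everywhere.
#' @param maf_subpop_absent_fraction Fraction absent in the matched
#'   subpopulation but present elsewhere.
#' @param maf_beta Shape parameters of the Beta allele-frequency model for
#'   present variants.
#' @param allele_number Subpopulation allele number (2N chromosomes).
#' @param n_cases,n_controls Assay arm sizes.
#' @param treatments Treatment labels; the first is the untreated baseline.
#' @param baseline_mean Baseline mean foci/cell.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param treatment_effect Named multiplier per treatment applied to all
#'   subjects (drug-induced foci induction).
#' @param case_multiplier Extra multiplier applied to cases under drug
#'   treatments only.
#' @param subject_sdlog SD of the per-subject lognormal random effect.
#' @param cells_per_sample Cells imaged per subject and treatment.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 12L,
                       n_genes = 200L,
                       ddr_fraction = 0.15,
                       variants_per_patient = c(3L, 7L),
                       damaging_fraction = 0.5,
                       consequence_probs = c(missense = 0.70,
                                             stop_gain = 0.07,
                                             frameshift = 0.07,
                                             inframe_indel = 0.06,
                                             splice = 0.05,
                                             synonymous = 0.05),
                       qc_fail_fraction = 0.1,
                       predictor_concordance = 0.9,
                       predictor_false_rate = 0.1,
                       maf_absent_fraction = 0.17,
                       maf_subpop_absent_fraction = 0.08,
                       maf_beta = c(0.5, 150),
                       allele_number = 66000L,
                       n_cases = 9L,
                       n_controls = 10L,
                       treatments = c("vehicle", "aphidicolin", "etoposide"),
                       baseline_mean = 4,
                       dispersion = 5,
                       treatment_effect = c(vehicle = 1, aphidicolin = 2,
                                            etoposide = 2.5),
                       case_multiplier = 2,
                       subject_sdlog = 0.4,
                       cells_per_sample = 80L) {
  cfg <- as.list(environment())
  stopifnot(cfg$predictor_concordance >= 0, cfg$predictor_concordance <= 1,
            cfg$predictor_false_rate >= 0, cfg$predictor_false_rate <= 1,
            cfg$maf_absent_fraction + cfg$maf_subpop_absent_fraction <= 1,
            length(cfg$variants_per_patient) == 2L)
  structure(cfg, class = "sim_config")
}

# draw a predictor-call block for n variants with per-predictor non-neutral
# probability p (vector of length n)
draw_predictor_calls <- function(n, p_nn) {
  nn <- matrix(runif(n * 5) < p_nn, nrow = n)
  colnames(nn) <- SNV_PREDICTORS
  tibble(
    polyphen2 = ifelse(nn[, "polyphen2"], "probably_damaging", "benign"),
    sift = ifelse(nn[, "sift"], "damaging", "tolerated"),
    provean = ifelse(nn[, "provean"], "deleterious", "neutral"),
    mutation_assessor = ifelse(nn[, "mutation_assessor"], "high", "neutral"),
    mt_call = ifelse(nn[, "mutation_taster"], "disease_causing",
                     "polymorphism"),
    mt_prob = ifelse(nn[, "mutation_taster"], 0.999, 0.5))
}

random_base <- function(n, exclude = NULL) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    sample(setdiff(bases, exclude[i]), 1L)
  }, character(1))
}

#' Generate a synthetic annotated variant table with ground truth
#'
#' Emits per-patient variant rows in the canonical input schema
#' ([read_variant_table()]): random GRCh37-style coordinates, consequences in
#' configured proportions, QC fields straddling the depth/quality thresholds
#' for a configured fraction of rows, and predictor call sets drawn at the
#' configured concordance (damaging variants) or false-call rate (benign
#' variants). Indel rows use anchored ref/alt representation.
#'
#' @param cfg A [sim_config()].
#' @return List: `variants` (input-schema tibble), `truth` (tibble with the
#'   variant key, `damaging`, `qc_pass`, consequence), `genes` (tibble
#'   `symbol`, `category`).
#' @export
synth_variant_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    genes <- tibble(
      symbol = sprintf("GENE%04d", seq_len(cfg$n_genes)),
      category = ifelse(seq_len(cfg$n_genes) <=
                          round(cfg$ddr_fraction * cfg$n_genes),
                        "DDR", "other"))
    n_per <- sample(cfg$variants_per_patient[1]:cfg$variants_per_patient[2],
                    cfg$n_patients, replace = TRUE)
    n <- sum(n_per)
    patient_id <- rep(sprintf("P%03d", seq_len(cfg$n_patients)), n_per)
    cons <- sample(names(cfg$consequence_probs), n, replace = TRUE,
                   prob = cfg$consequence_probs)
    chrom <- as.character(sample(1:22, n, replace = TRUE))
    pos <- sample.int(2.4e8, n)
    ref <- random_base(n)
    alt <- random_base(n, exclude = ref)
    # anchored indel representation
    is_fs <- cons == "frameshift"
    is_if <- cons == "inframe_indel"
    if (any(is_fs)) {
      ins <- paste0(ref[is_fs], strrep("A", sample(c(1L, 2L, 4L),
                                                   sum(is_fs),
                                                   replace = TRUE)))
      alt[is_fs] <- ins
    }
    if (any(is_if)) {
      alt[is_if] <- paste0(ref[is_if], strrep("TAG", sample(1:2, sum(is_if),
                                                            replace = TRUE)))
    }
    damaging <- runif(n) < cfg$damaging_fraction
    qc_fail <- runif(n) < cfg$qc_fail_fraction
    depth <- ifelse(qc_fail, sample(1:3, n, replace = TRUE),
                    sample(4:120, n, replace = TRUE))
    qual <- ifelse(qc_fail, runif(n, 5, 25), runif(n, 26, 99))
    p_nn <- ifelse(damaging, cfg$predictor_concordance,
                   cfg$predictor_false_rate)
    calls <- draw_predictor_calls(n, p_nn)
    sift_indel <- rep(NA_character_, n)
    len3 <- abs(nchar(ref) - nchar(alt)) %% 3L == 0L
    si_rows <- is_if & len3
    sift_indel[si_rows] <- ifelse(runif(sum(si_rows)) < p_nn[si_rows],
                                  "damaging", "neutral")
    variants <- tibble(
      patient_id = patient_id, chrom = chrom, pos = pos, ref = ref,
      alt = alt, gene = sample(genes$symbol, n, replace = TRUE),
      hgvs_p = NA_character_, consequence = cons, depth = depth,
      qual = round(qual, 1), in_splice_site = FALSE) %>%
      dplyr::bind_cols(calls) %>%
      mutate(sift_indel = sift_indel)
    truth <- tibble(patient_id = patient_id, chrom = chrom, pos = pos,
                    ref = ref, alt = alt, consequence = cons,
                    damaging = damaging, qc_pass = !qc_fail)
    list(variants = variants, truth = truth, genes = genes)
  })
}

#' Generate a synthetic population allele-frequency table
#'
#' For each supplied variant key: with probability `maf_absent_fraction` the
#' variant gets no row at all (never reported); with probability
#' `maf_subpop_absent_fraction` it gets a matched-subpopulation row with
#' count zero plus a nonzero row in another subpopulation; otherwise its
#' allele frequency is drawn from the Beta model and the matched allele
#' count from `Binomial(allele_number, maf)`.
#'
#' @param cfg A [sim_config()].
#' @param variants Tibble of variant keys (`chrom, pos, ref, alt`); rows are
#'   deduplicated by key.
#' @param subpop Matched subpopulation label.
#' @return List: `popfreq` (population tibble), `truth` (tibble of key plus
#'   `presence` in absent_everywhere / absent_in_matched_subpop / present).
#' @export
synth_population_table <- function(cfg, variants,
                                   subpop = "European non-Finnish") {
  stopifnot(inherits(cfg, "sim_config"))
  keys <- variants[!duplicated(variant_key(variants)),
                   c("chrom", "pos", "ref", "alt")]
  withr::with_seed(cfg$seed + 1L, {
    n <- nrow(keys)
    u <- runif(n)
    presence <- ifelse(
      u < cfg$maf_absent_fraction, "absent_everywhere",
      ifelse(u < cfg$maf_absent_fraction + cfg$maf_subpop_absent_fraction,
             "absent_in_matched_subpop", "present"))
    maf <- rbeta(n, cfg$maf_beta[1], cfg$maf_beta[2])
    ac <- rbinom(n, cfg$allele_number, maf)
    rows <- list()
    pres <- presence == "present"
    if (any(pres)) {
      rows[[1]] <- dplyr::bind_cols(
        keys[pres, ],
        tibble(subpop = subpop, allele_count = ac[pres],
               allele_number = cfg$allele_number))
    }
    sub0 <- presence == "absent_in_matched_subpop"
    if (any(sub0)) {
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        keys[sub0, ],
        tibble(subpop = subpop, allele_count = 0,
               allele_number = cfg$allele_number))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        keys[sub0, ],
        tibble(subpop = "other",
               allele_count = pmax(1, rbinom(sum(sub0), cfg$allele_number,
                                             maf[sub0])),
               allele_number = cfg$allele_number))
    }
    popfreq <- bind_rows(rows) %||%
      tibble(chrom = character(), pos = numeric(), ref = character(),
             alt = character(), subpop = character(),
             allele_count = numeric(), allele_number = numeric())
    list(popfreq = popfreq,
         truth = dplyr::bind_cols(keys, tibble(presence = presence)))
  })
}

#' Generate synthetic per-cell gamma-H2AX foci counts
#'
#' Per-cell counts are negative binomial (overdispersed across cells), with
#' a per-subject lognormal random effect so subjects carry between-group
#' variance, a per-treatment induction multiplier applied to everyone, and
#' the case multiplier applied only under drug treatments - the baseline
#' (first treatment) is indistinguishable between groups by construction.
#'
#' @param cfg A [sim_config()].
#' @return Long foci tibble `subject_id, group, treatment, cell,
#'   foci_count`.
#' @export
synth_foci <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 2L, {
    subjects <- tibble(
      subject_id = c(sprintf("case%02d", seq_len(cfg$n_cases)),
                     sprintf("ctrl%02d", seq_len(cfg$n_controls))),
      group = rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls)),
      subj_effect = exp(rnorm(cfg$n_cases + cfg$n_controls, 0,
                              cfg$subject_sdlog)))
    baseline <- cfg$treatments[1]
    grid <- tidyr::expand_grid(subjects, treatment = cfg$treatments)
    grid <- grid %>%
      mutate(mu = cfg$baseline_mean * .data$subj_effect *
               cfg$treatment_effect[.data$treatment] *
               ifelse(.data$group == "case" & .data$treatment != baseline,
                      cfg$case_multiplier, 1))
    cells <- grid[rep(seq_len(nrow(grid)), each = cfg$cells_per_sample), ]
    cells$cell <- rep(seq_len(cfg$cells_per_sample), nrow(grid))
    cells$foci_count <- rnbinom(nrow(cells), size = cfg$dispersion,
                                mu = cells$mu)
    select(cells, "subject_id", "group", "treatment", "cell", "foci_count")
  })
}

#' Operating characteristic of the consensus rule
#'
#' With per-predictor concordance `c`, a damaging missense variant is
#' selected when at least `k` of the `n` predictors call it non-neutral, so
#' the selection sensitivity is `P(Binomial(n, c) >= k)` in closed form.
#' The same formula with the false-call rate gives 1 - specificity.
#'
#' @param concordance Per-predictor non-neutral probability.
#' @param k Consensus threshold (default 3).
#' @param n Number of predictors (default 5).
#' @return Probability of selection.
#' @export
consensus_sensitivity <- function(concordance, k = 3, n = 5) {
  pbinom(k - 1, n, concordance, lower.tail = FALSE)
}

#' Write all synthetic inputs to a directory
#'
#' Emits `variants.tsv`, `popfreq.tsv`, `foci.tsv` and the ground-truth
#' tables (`truth_variants.tsv`, `truth_popfreq.tsv`) for a configuration.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
simulate_all <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sv <- synth_variant_table(cfg)
  sp <- synth_population_table(cfg, sv$variants)
  foci <- synth_foci(cfg)
  readr::write_tsv(sv$variants, file.path(dir, "variants.tsv"))
  readr::write_tsv(sv$truth, file.path(dir, "truth_variants.tsv"))
  readr::write_tsv(sv$genes, file.path(dir, "genes.tsv"))
  readr::write_tsv(sp$popfreq, file.path(dir, "popfreq.tsv"))
  readr::write_tsv(sp$truth, file.path(dir, "truth_popfreq.tsv"))
  readr::write_tsv(foci, file.path(dir, "foci.tsv"))
  invisible(dir)
}
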
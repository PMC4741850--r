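#' Read a clinical characteristics table
#'
#' Expected columns: `patient_id`, `age_at_dx`, `stage_gleason` (the combined
#' "stage/Gleason" string as printed in pathology summaries, e.g.
#' `"T2aN0MX/3+4=7"`), plus free-text family-history columns.
#'
#' @param path TSV path.
#' @return Clinical tibble.
#' @export
read_clinical_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    patient_id = "c", age_at_dx = "d", .default = "c"), progress = FALSE)
}

#' Parse Gleason strings to a total score
#'
#' Handles `"a+b=c"` (total taken from `c`), `"a+b"` (summed), bare totals
#' (`"6"`), and multi-area strings joined by "and" or commas, for which the
#' maximum total across areas is returned. Unparseable strings give `NA` with
#' a warning.
#'
#' @param gleason_raw Character vector of Gleason strings.
#' @return Integer vector of total scores.
#' @export
parse_gleason <- function(gleason_raw) {
  one <- function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return(NA_integer_)
    # strip parentheticals like "(multiple areas)"
    x <- gsub("\\([^)]*\\)", "", x)
    parts <- strsplit(x, "\\band\\b|,", perl = TRUE)[[1]]
    totals <- integer()
    for (p in parts) {
      p <- trimws(p)
      if (!nzchar(p)) next
      m <- regmatches(p, regexec("^(\\d+)\\s*\\+\\s*(\\d+)(?:\\s*=\\s*(\\d+))?$", p))[[1]]
      if (length(m)) {
        tot <- if (nzchar(m[4])) as.integer(m[4]) else
          as.integer(m[2]) + as.integer(m[3])
        totals <- c(totals, tot)
      } else if (grepl("^\\d+$", p)) {
        totals <- c(totals, as.integer(p))
      }
    }
    if (length(totals) == 0L) NA_integer_ else max(totals)
  }
  out <- vapply(as.character(gleason_raw), one, integer(1), USE.NAMES = FALSE)
  if (anyNA(out) && any(!is.na(gleason_raw))) {
    bad <- !is.na(gleason_raw) & is.na(out)
    if (any(bad)) {
      warn(sprintf("unparseable Gleason string(s): %s",
                   paste(unique(gleason_raw[bad]), collapse = "; ")))
    }
  }
  out
}

#' Extract the TNM T category from a stage string
#'
#' Tolerates the letter-O-for-digit-0 typography seen in printed tables
#' (`"T2cNOMX"` reads as N0). Returns e.g. `"T2a"`, `"T3b"`, `"T1c"`; `NA`
#' when no T category is found.
#'
#' @param stage_raw Character vector of TNM stage strings.
#' @return Character vector of T categories.
#' @export
parse_stage_t <- function(stage_raw) {
  stringr::str_extract(as.character(stage_raw), "T\\d[a-c]?")
}

split_stage_gleason <- function(stage_gleason) {
  pieces <- stringr::str_split_fixed(stage_gleason, "/", 2)
  tibble(stage_raw = pieces[, 1],
         gleason_raw = ifelse(nzchar(pieces[, 2]), pieces[, 2], NA_character_))
}

#' Cohort clinical summary
#'
#' Computes the cohort descriptors used for reporting: mean age at diagnosis
#' (1 decimal), age range, percentage with Gleason total >= 7 (over
#' parseable profiles; percentages rounded to the nearest integer) and
#' percentage with locally advanced (T3) stage.
#'
#' @param clinical Clinical tibble with `patient_id`, `age_at_dx` and either
#'   a combined `stage_gleason` column or separate `stage_raw` /
#'   `gleason_raw` columns.
#' @return One-row tibble: `n_patients`, `mean_age`, `age_min`, `age_max`,
#'   `n_gleason_ge7`, `pct_gleason_ge7`, `n_stage_t3`, `pct_stage_t3`.
#' @export
clinical_summary <- function(clinical) {
  stopifnot(nrow(clinical) >= 1L)
  if (!all(c("stage_raw", "gleason_raw") %in% names(clinical))) {
    clinical <- dplyr::bind_cols(clinical,
                                 split_stage_gleason(clinical$stage_gleason))
  }
  gleason <- parse_gleason(clinical$gleason_raw)
  tcat <- parse_stage_t(clinical$stage_raw)
  n <- nrow(clinical)
  n_g <- sum(!is.na(gleason))
  tibble(
    n_patients = n,
    mean_age = round(mean(clinical$age_at_dx), 1),
    age_min = min(clinical$age_at_dx),
    age_max = max(clinical$age_at_dx),
    n_gleason_ge7 = sum(gleason >= 7, na.rm = TRUE),
    pct_gleason_ge7 = round(100 * sum(gleason >= 7, na.rm = TRUE) / n_g),
    n_stage_t3 = sum(startsWith(tcat, "T3"), na.rm = TRUE),
    pct_stage_t3 = round(100 * sum(startsWith(tcat, "T3"), na.rm = TRUE) / n))
}

#' Distinct affected genes per patient
#'
#' Two variants in the same gene count once.
#'
#' @param selected Selected-variant tibble (`patient_id`, `gene`).
#' @param patients Optional character vector giving the full patient roster
#'   (patients with no selected variants get a zero count).
#' @return Tibble `patient_id`, `n_genes`.
#' @export
genes_per_patient <- function(selected, patients = NULL) {
  counts <- selected %>%
    distinct(.data$patient_id, .data$gene) %>%
    count(.data$patient_id, name = "n_genes")
  if (!is.null(patients)) {
    counts <- tibble(patient_id = as.character(patients)) %>%
      left_join(counts, by = "patient_id") %>%
      mutate(n_genes = tidyr::replace_na(.data$n_genes, 0L))
  }
  arrange(counts, .data$patient_id)
}

#' DDR-category prevalence
#'
#' Counts, per patient, distinct selected genes belonging to the DNA damage
#' response category, and tallies how many patients carry at least one and at
#' least two such genes.
#'
#' @param selected Selected-variant tibble (`patient_id`, `gene`).
#' @param ddr_genes Character vector of DDR gene symbols (normalized).
#' @param patients Optional full patient roster.
#' @return List with `per_patient` (tibble `patient_id`, `n_ddr_genes`),
#'   `n_ge1`, `n_ge2`, `n_patients`.
#' @export
ddr_prevalence <- function(selected, ddr_genes, patients = NULL) {
  patients <- patients %||% sort(unique(selected$patient_id))
  per <- selected %>%
    filter(.data$gene %in% ddr_genes) %>%
    distinct(.data$patient_id, .data$gene) %>%
    count(.data$patient_id, name = "n_ddr_genes")
  per <- tibble(patient_id = as.character(patients)) %>%
    left_join(per, by = "patient_id") %>%
    mutate(n_ddr_genes = tidyr::replace_na(.data$n_ddr_genes, 0L)) %>%
    arrange(.data$patient_id)
  list(per_patient = per,
       n_ge1 = sum(per$n_ddr_genes >= 1L),
       n_ge2 = sum(per$n_ddr_genes >= 2L),
       n_patients = length(patients))
}

#' Observed vs expected carrier incidence for a recurrent variant
#'
#' The observed carrier fraction is the number of patients carrying the
#' variant over the cohort size. The expected fraction is the
#' Hardy-Weinberg carrier probability `1 - (1 - p)^2`, with `p` the matched
#' subpopulation allele frequency; if the variant is absent from the
#' population table the expectation is undefined (`NA`).
#'
#' @param selected Selected-variant tibble (`patient_id`, `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param chrom,pos,ref,alt The variant key.
#' @param popfreq Population tibble; `subpop` the matched subpopulation.
#' @param n_patients Cohort size (defaults to the number of distinct
#'   patients in `selected`).
#' @param subpop Matched subpopulation label.
#' @return One-row tibble: `n_carriers`, `n_patients`, `observed_fraction`,
#'   `observed_pct`, `allele_freq`, `expected_fraction`, `expected_pct`
#'   (percentages rounded to the nearest integer).
#' @export
recurrent_variant_incidence <- function(selected, chrom, pos, ref, alt,
                                        popfreq = NULL, n_patients = NULL,
                                        subpop = "European non-Finnish") {
  key <- paste(chrom, pos, ref, alt, sep = ":")
  hit <- variant_key(selected) == key
  carriers <- unique(selected$patient_id[hit])
  n_patients <- n_patients %||% dplyr::n_distinct(selected$patient_id)
  obs <- length(carriers) / n_patients
  p <- NA_real_
  if (!is.null(popfreq)) {
    ann <- annotate_frequency(tibble(chrom = as.character(chrom), pos = pos,
                                     ref = ref, alt = alt),
                              popfreq, subpop = subpop)
    if (ann$status == "present") p <- ann$frequency
    if (ann$status %in% c("absent_everywhere", "absent_in_matched_subpop")) {
      p <- if (ann$status == "absent_in_matched_subpop") 0 else NA_real_
    }
  }
  expected <- if (is.na(p)) NA_real_ else 1 - (1 - p)^2
  tibble(n_carriers = length(carriers), n_patients = n_patients,
         observed_fraction = obs, observed_pct = round(100 * obs),
         allele_freq = p, expected_fraction = expected,
         expected_pct = if (is.na(expected)) NA_real_ else
           round(100 * expected))
}
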
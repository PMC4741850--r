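#' Read / write an annotated variant table
#'
#' The canonical interchange schema is one row per variant call:
#' `patient_id, chrom, pos, ref, alt, gene, hgvs_p, consequence, depth, qual,
#' in_splice_site, polyphen2, sift, provean, mutation_assessor, mt_call,
#' mt_prob, sift_indel`. Coordinates are 1-based GRCh37; indels are anchored
#' (ref and alt share their first base). Predictor columns hold each tool's
#' categorical call (`NA` = call unavailable); `mt_prob` is the
#' MutationTaster probability in \[0, 1\].
#'
#' @param path TSV path.
#' @return A tibble in the schema above.
#' @export
read_variant_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    patient_id = "c", chrom = "c", pos = "d", ref = "c", alt = "c",
    gene = "c", hgvs_p = "c", consequence = "c", depth = "d", qual = "d",
    in_splice_site = "l", polyphen2 = "c", sift = "c", provean = "c",
    mutation_assessor = "c", mt_call = "c", mt_prob = "d", sift_indel = "c"),
    progress = FALSE)
}

#' @rdname read_variant_table
#' @param variants Variant tibble.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}

#' Sequencing quality filter
#'
#' Retains calls with more than `min_reads` supporting reads and a quality
#' score above `min_qual` (both strict inequalities). Rows with missing QC
#' fields are dropped with a warning.
#'
#' @param variants Variant tibble (needs `depth` and `qual`).
#' @param min_reads Read-depth threshold (default 3; "more than 3 reads").
#' @param min_qual Quality threshold (default 25).
#' @return Filtered tibble.
#' @export
qc_filter <- function(variants, min_reads = 3, min_qual = 25) {
  miss <- is.na(variants$depth) | is.na(variants$qual)
  if (any(miss)) {
    warn(sprintf("%d variant(s) dropped for missing depth/qual", sum(miss)))
  }
  keep <- !miss & variants$depth > min_reads & variants$qual > min_qual
  variants[keep, , drop = FALSE]
}

# consequence classes removed by the coding-effect filter; "other" covers
# non-coding / unclassifiable annotations
NONCODING_CONSEQUENCES <- c("synonymous", "other")

#' Coding-consequence filter
#'
#' Removes synonymous and non-coding ("other") calls; splice-region records
#' are retained.
#'
#' @param variants Variant tibble (needs `consequence`).
#' @return Filtered tibble.
#' @export
consequence_filter <- function(variants) {
  variants[!variants$consequence %in% NONCODING_CONSEQUENCES, , drop = FALSE]
}

# valid categorical vocabularies per predictor
PREDICTOR_LEVELS <- list(
  polyphen2 = c("probably_damaging", "possibly_damaging", "benign"),
  sift = c("damaging", "tolerated"),
  provean = c("deleterious", "neutral"),
  mutation_assessor = c("high", "medium", "low", "neutral"),
  mutation_taster = c("disease_causing", "disease_causing_automatic",
                      "polymorphism", "polymorphism_automatic"),
  sift_indel = c("damaging", "neutral")
)

#' Convert one predictor call to neutral / non-neutral
#'
#' Conversion rules: PolyPhen-2 probably/possibly damaging and
#' MutationAssessor high/medium are non-neutral; SIFT damaging and PROVEAN
#' deleterious are non-neutral (tolerated / neutral are neutral);
#' MutationTaster disease_causing(_automatic) is non-neutral only when its
#' probability reaches `mt_cutoff` (default 0.99), polymorphism calls are
#' neutral. SIFT-Indel damaging is non-neutral. A missing call is
#' `"unavailable"`.
#'
#' @param predictor One of `"polyphen2"`, `"sift"`, `"provean"`,
#'   `"mutation_assessor"`, `"mutation_taster"`, `"sift_indel"`.
#' @param call The tool's categorical call (character), `NA` if absent.
#' @param prob MutationTaster probability (used only for that predictor).
#' @param mt_cutoff MutationTaster probability cutoff, applied as `>=`.
#' @return `"non_neutral"`, `"neutral"` or `"unavailable"` (vectorized over
#'   `call`/`prob`).
#' @export
classify_call <- function(predictor, call, prob = NULL, mt_cutoff = 0.99) {
  predictor <- match.arg(predictor, names(PREDICTOR_LEVELS))
  call <- as.character(call)
  out <- rep("unavailable", length(call))
  known <- !is.na(call)
  bad <- known & !call %in% PREDICTOR_LEVELS[[predictor]]
  if (any(bad)) {
    abort(sprintf("unknown %s category: %s", predictor,
                  paste(unique(call[bad]), collapse = ", ")))
  }
  nn <- switch(predictor,
    polyphen2 = call %in% c("probably_damaging", "possibly_damaging"),
    sift = call == "damaging",
    provean = call == "deleterious",
    mutation_assessor = call %in% c("high", "medium"),
    sift_indel = call == "damaging",
    mutation_taster = {
      if (is.null(prob)) prob <- rep(NA_real_, length(call))
      call %in% c("disease_causing", "disease_causing_automatic") &
        !is.na(prob) & prob >= mt_cutoff
    })
  out[known] <- ifelse(nn[known], "non_neutral", "neutral")
  out
}

#' Consensus damage scoring
#'
#' Adds consensus-scoring columns to a variant tibble:
#' \describe{
#'   \item{truncating consequences}{stop-gain, frameshift and start-loss
#'     variants are automatically selected (`selection_reason =
#'     "truncating"`), the convention behind the printed maximal score.}
#'   \item{splice variants}{pure splice-site variants are selected
#'     (`"splice"`).}
#'   \item{missense SNVs}{`n_non_neutral` counts non-neutral calls over the
#'     fixed panel of five SNV predictors (an unavailable predictor counts as
#'     not non-neutral, so scores are always out of five); selected when
#'     `n_non_neutral >= min_predictors` (`"consensus"`). A missense variant
#'     located in a splice site is selected regardless
#'     (`"splice_site_missense"`). A missense variant with no available
#'     predictor is flagged `unscorable` and not selected.}
#'   \item{in-frame indels}{evaluated with PROVEAN and MutationTaster, plus
#'     SIFT-Indel when the indel length is divisible by 3; selected when at
#'     least one applicable predictor is non-neutral (`indel_rule = "any"`,
#'     the default) or when all available ones are (`"all"`).}
#' }
#'
#' @param variants Variant tibble (see [read_variant_table()] for schema).
#' @param min_predictors Consensus threshold for missense SNVs (default 3 of
#'   5).
#' @param mt_cutoff MutationTaster probability cutoff (default 0.99).
#' @param indel_rule `"any"` (default) or `"all"`.
#' @return `variants` plus columns `n_available`, `n_non_neutral`,
#'   `auto_truncating`, `unscorable`, `selected`, `selection_reason`.
#' @export
score_variants <- function(variants, min_predictors = 3, mt_cutoff = 0.99,
                           indel_rule = c("any", "all")) {
  indel_rule <- match.arg(indel_rule)
  n <- nrow(variants)
  if (n == 0L) {
    return(mutate(variants, n_available = integer(), n_non_neutral = integer(),
                  auto_truncating = logical(), unscorable = logical(),
                  selected = logical(), selection_reason = character()))
  }
  calls <- cbind(
    polyphen2 = classify_call("polyphen2", variants$polyphen2),
    sift = classify_call("sift", variants$sift),
    provean = classify_call("provean", variants$provean),
    mutation_assessor = classify_call("mutation_assessor",
                                      variants$mutation_assessor),
    mutation_taster = classify_call("mutation_taster", variants$mt_call,
                                    variants$mt_prob, mt_cutoff = mt_cutoff))
  si <- classify_call("sift_indel", variants$sift_indel)

  nn <- calls == "non_neutral"
  avail <- calls != "unavailable"
  cons <- variants$consequence
  splice_site <- variants$in_splice_site %||% rep(FALSE, n)
  splice_site[is.na(splice_site)] <- FALSE

  n_non_neutral <- integer(n)
  n_available <- integer(n)
  auto_truncating <- cons %in% c("stop_gain", "frameshift", "start_loss")
  unscorable <- rep(FALSE, n)
  selected <- rep(FALSE, n)
  reason <- rep("not_selected", n)

  selected[auto_truncating] <- TRUE
  reason[auto_truncating] <- "truncating"

  is_splice <- cons == "splice" & !auto_truncating
  selected[is_splice] <- TRUE
  reason[is_splice] <- "splice"

  is_mis <- cons == "missense" & !auto_truncating
  n_non_neutral[is_mis] <- rowSums(nn[is_mis, , drop = FALSE])
  n_available[is_mis] <- rowSums(avail[is_mis, , drop = FALSE])
  unscorable[is_mis] <- n_available[is_mis] == 0L
  mis_consensus <- is_mis & n_non_neutral >= min_predictors
  selected[mis_consensus] <- TRUE
  reason[mis_consensus] <- "consensus"
  mis_splice <- is_mis & !mis_consensus & splice_site
  selected[mis_splice] <- TRUE
  reason[mis_splice] <- "splice_site_missense"

  is_ind <- cons == "inframe_indel" & !auto_truncating
  if (any(is_ind)) {
    indel_len <- abs(nchar(variants$ref) - nchar(variants$alt))
    use_si <- is_ind & indel_len %% 3L == 0L & indel_len > 0L
    ind_nn <- nn[, "provean"] + nn[, "mutation_taster"] +
      ifelse(use_si, si == "non_neutral", 0L)
    ind_avail <- avail[, "provean"] + avail[, "mutation_taster"] +
      ifelse(use_si, si != "unavailable", 0L)
    n_non_neutral[is_ind] <- ind_nn[is_ind]
    n_available[is_ind] <- ind_avail[is_ind]
    unscorable[is_ind] <- ind_avail[is_ind] == 0L
    ind_sel <- if (indel_rule == "any") {
      is_ind & ind_nn >= 1L
    } else {
      is_ind & ind_avail > 0L & ind_nn == ind_avail
    }
    selected[ind_sel] <- TRUE
    reason[ind_sel] <- "indel_predictor"
  }

  mutate(variants,
         n_available = n_available, n_non_neutral = n_non_neutral,
         auto_truncating = auto_truncating, unscorable = unscorable,
         selected = selected, selection_reason = reason)
}

#' Select candidate variants
#'
#' The full prioritization pipeline, applied as a composition of row-wise
#' predicates: quality filter, coding-consequence filter, restriction to the
#' candidate gene panel, population-rarity filter, then consensus damage
#' scoring ([score_variants()]); only rows the scorer selects are kept.
#'
#' The rarity filter keeps variants whose matched-subpopulation allele
#' frequency is below `maf_cutoff`; variants absent from (or excluded by) the
#' population table pass. Variants at or above the cutoff are kept only when
#' their gene is on the `whitelist` (the carve-out for non-rare variants in
#' genes relevant to cancer risk).
#'
#' @param variants Variant tibble.
#' @param panel Panel tibble (or character vector of symbols), or `NULL` to
#'   skip panel restriction.
#' @param popfreq Population table (see [read_population_table()]), or `NULL`
#'   to skip the rarity filter.
#' @param maf_cutoff Rarity cutoff as an allele-frequency fraction (default
#'   0.01, i.e. 1%).
#' @param whitelist Character vector of gene symbols exempt from the rarity
#'   cutoff.
#' @param subpop Matched subpopulation label for frequency lookup.
#' @param db_excluded_keys Optional tibble of variant keys the population
#'   database excludes by policy (see [annotate_frequency()]).
#' @inheritParams score_variants
#' @inheritParams qc_filter
#' @return Tibble of selected variants, sorted by patient then coordinate,
#'   with frequency-annotation and consensus-score columns.
#' @export
select_variants <- function(variants, panel = NULL, popfreq = NULL,
                            maf_cutoff = 0.01, whitelist = NULL,
                            subpop = "European non-Finnish",
                            db_excluded_keys = NULL,
                            min_reads = 3, min_qual = 25,
                            min_predictors = 3, mt_cutoff = 0.99,
                            indel_rule = "any") {
  out <- variants %>%
    qc_filter(min_reads = min_reads, min_qual = min_qual) %>%
    consequence_filter()
  if (!is.null(panel)) {
    symbols <- if (is.data.frame(panel)) panel$symbol else as.character(panel)
    out <- out[out$gene %in% symbols, , drop = FALSE]
  }
  if (!is.null(popfreq)) {
    out <- annotate_frequency(out, popfreq, subpop = subpop,
                              db_excluded_keys = db_excluded_keys)
    rare <- is.na(out$frequency) | out$frequency < maf_cutoff
    out <- out[rare | out$gene %in% (whitelist %||% character()), ,
               drop = FALSE]
  }
  out <- score_variants(out, min_predictors = min_predictors,
                        mt_cutoff = mt_cutoff, indel_rule = indel_rule)
  out <- out[out$selected, , drop = FALSE]
  arrange(out, .data$patient_id, .data$chrom, .data$pos)
}
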
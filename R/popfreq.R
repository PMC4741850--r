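#' Read / write a population allele-frequency table
#'
#' ExAC-style long format: one row per variant per subpopulation, columns
#' `chrom, pos, ref, alt, subpop, allele_count, allele_number`.
#'
#' @param path TSV path.
#' @return Population tibble.
#' @export
read_population_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "d", ref = "c", alt = "c", subpop = "c",
    allele_count = "d", allele_number = "d"), progress = FALSE)
  validate_population_table(tbl)
  tbl
}

#' @rdname read_population_table
#' @param popfreq Population tibble.
#' @export
write_population_table <- function(popfreq, path) {
  readr::write_tsv(popfreq, path)
  invisible(path)
}

validate_population_table <- function(popfreq) {
  ok <- !is.na(popfreq$allele_count) & !is.na(popfreq$allele_number) &
    popfreq$allele_count >= 0 &
    popfreq$allele_count <= popfreq$allele_number
  if (!all(ok)) abort("population table: allele_count must lie in [0, allele_number]")
  invisible(popfreq)
}

variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Annotate variants with population frequency and presence status
#'
#' Each variant gets a three-way presence status against the matched
#' subpopulation:
#' \describe{
#'   \item{`present`}{the matched subpopulation carries the allele
#'     (`allele_count > 0`); `frequency = allele_count / allele_number`.}
#'   \item{`absent_in_matched_subpop`}{the database knows the variant but the
#'     matched subpopulation count is zero (the table legend's "(0)").}
#'   \item{`absent_everywhere`}{no database record at all (the legend's
#'     "(-)"): a never-reported variant.}
#' }
#' Variants listed in `db_excluded_keys` (excluded from the database by
#' policy, e.g. alleles tied to severe pediatric disease) get status
#' `excluded_by_database`; they count as previously reported, not novel.
#'
#' @param variants Variant tibble with `chrom, pos, ref, alt`.
#' @param popfreq Population tibble (see [read_population_table()]).
#' @param subpop Matched subpopulation label (default
#'   `"European non-Finnish"`).
#' @param db_excluded_keys Optional tibble with `chrom, pos, ref, alt` of
#'   database-excluded variants.
#' @return `variants` plus columns `status`, `matched_ac`, `matched_an`,
#'   `frequency`.
#' @export
annotate_frequency <- function(variants, popfreq,
                               subpop = "European non-Finnish",
                               db_excluded_keys = NULL) {
  validate_population_table(popfreq)
  if (!subpop %in% popfreq$subpop && nrow(popfreq) > 0) {
    warn(sprintf("subpopulation '%s' has no rows in the population table",
                 subpop))
  }
  if (any(is.na(variants$chrom) | is.na(variants$pos) |
          is.na(variants$ref) | is.na(variants$alt))) {
    abort("malformed variant key: chrom/pos/ref/alt must be complete")
  }
  key <- variant_key(variants)
  pkey <- variant_key(popfreq)

  matched <- popfreq[popfreq$subpop == subpop, , drop = FALSE]
  m <- match(key, variant_key(matched))
  matched_ac <- matched$allele_count[m]
  matched_an <- matched$allele_number[m]

  # allele counts summed over all other subpopulations, for the
  # "absent here, seen elsewhere" call
  other <- popfreq[popfreq$subpop != subpop, , drop = FALSE]
  other_ac <- vapply(key, function(k) {
    sum(other$allele_count[variant_key(other) == k])
  }, numeric(1), USE.NAMES = FALSE)

  known <- key %in% pkey
  status <- rep("absent_everywhere", length(key))
  status[known & (other_ac > 0 | (!is.na(matched_ac) & matched_ac == 0))] <-
    "absent_in_matched_subpop"
  status[!is.na(matched_ac) & matched_ac > 0] <- "present"

  if (!is.null(db_excluded_keys) && nrow(db_excluded_keys) > 0) {
    status[key %in% variant_key(db_excluded_keys)] <- "excluded_by_database"
  }

  frequency <- ifelse(status == "present", matched_ac / matched_an, NA_real_)
  matched_ac[status %in% c("absent_everywhere", "excluded_by_database")] <-
    NA_real_
  matched_an[status %in% c("absent_everywhere", "excluded_by_database")] <-
    NA_real_

  mutate(variants, status = status, matched_ac = matched_ac,
         matched_an = matched_an, frequency = frequency)
}

#' Tally rare and never-reported variants
#'
#' Deduplicates by variant key and counts (a) unique variants whose matched
#' allele count is below `count_threshold` among those present or absent only
#' in the matched subpopulation (a subpopulation-absent variant has matched
#' count 0), and (b) unique variants never reported in the database
#' (`absent_everywhere`). Database-excluded variants count in neither tally:
#' they are previously reported but carry no usable count.
#'
#' @param annotated Variant tibble annotated by [annotate_frequency()].
#' @param count_threshold Allele-count threshold (default 20, "fewer than 20
#'   individuals").
#' @return One-row tibble: `n_below_threshold`, `n_never_reported`,
#'   `n_variants` (unique keys).
#' @export
tally_rare <- function(annotated, count_threshold = 20) {
  uniq <- annotated[!duplicated(variant_key(annotated)), , drop = FALSE]
  ac <- ifelse(uniq$status == "absent_in_matched_subpop", 0, uniq$matched_ac)
  in_db <- uniq$status %in% c("present", "absent_in_matched_subpop")
  tibble(
    n_below_threshold = sum(in_db & !is.na(ac) & ac < count_threshold),
    n_never_reported = sum(uniq$status == "absent_everywhere"),
    n_variants = nrow(uniq))
}
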
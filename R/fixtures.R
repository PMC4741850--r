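# Packaged study tables, encoded as plain-text TSVs under inst/extdata and
# checksum-verified at load. The variant table carries, per row, the printed
# consensus score (NA for variants scored by the truncating/splice/indel
# conventions), the splice-site-missense flag, the database-exclusion flag,
# and the matched-subpopulation allele count/number (NA/NA = never reported).

FIXTURE_FILES <- c(
  clinical = "clinical_table1.tsv",
  variants = "variants_table3.tsv",
  ddr_genes = "ddr_genes.tsv",
  aliases = "alias_snapshot.tsv")

FIXTURE_MD5 <- c(
  clinical = "9cf044b9c830c4b64e89ced8273b1661",
  variants = "d5c7010052d8ec8b47e8b6476d7e9d76",
  ddr_genes = "5a4101d5f7d2d009dc305496438c3a9b",
  aliases = "ad7379f9dda061c1550568a988c1ecf9")

fixture_path <- function(name) {
  system.file("extdata", FIXTURE_FILES[[name]], package = "prostvar",
              mustWork = TRUE)
}

#' Load a packaged study fixture
#'
#' Available fixtures:
#' \describe{
#'   \item{`"clinical"`}{12 patient profiles (age at diagnosis, combined
#'     stage/Gleason string, family history).}
#'   \item{`"variants"`}{the 58 selected-variant rows with printed consensus
#'     scores, footnote flags and matched-subpopulation allele counts.}
#'   \item{`"ddr_genes"`}{the 17 DNA damage response gene symbols used for
#'     category prevalence.}
#'   \item{`"aliases"`}{the static gene-symbol alias snapshot.}
#' }
#' Files are verified against packaged MD5 checksums before parsing; a
#' mismatch signals fixture corruption.
#'
#' @param name One of `"clinical"`, `"variants"`, `"ddr_genes"`,
#'   `"aliases"`.
#' @return A tibble.
#' @export
load_fixture <- function(name) {
  if (!name %in% names(FIXTURE_FILES)) {
    abort(sprintf("unknown fixture '%s' (available: %s)", name,
                  paste(names(FIXTURE_FILES), collapse = ", ")))
  }
  path <- fixture_path(name)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(FIXTURE_MD5[[name]]))) {
    abort(sprintf("fixture '%s' failed checksum verification", name))
  }
  switch(name,
    clinical = read_clinical_table(path),
    variants = readr::read_tsv(path, col_types = readr::cols(
      patient_id = "c", chrom = "c", pos = "d", ref = "c", alt = "c",
      gene = "c", hgvs_p = "c", consequence = "c", score = "i",
      in_splice_site = "l", db_excluded = "l", allele_count = "d",
      allele_number = "d"), progress = FALSE),
    ddr_genes = readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                                progress = FALSE),
    aliases = read_alias_table(path))
}

#' Re-encode the packaged variant table in the pipeline input schema
#'
#' Expands each fixture row into the canonical annotated-variant schema
#' ([read_variant_table()]): QC fields are set to passing values (the
#' packaged variants passed upstream QC), and predictor call columns are
#' reconstructed from the printed consensus score by setting the first
#' `score` predictors (in the fixed panel order PolyPhen-2, SIFT, PROVEAN,
#' MutationAssessor, MutationTaster) non-neutral and the rest neutral.
#' In-frame indels (printed without a score) get a deleterious PROVEAN call;
#' truncating and splice variants need no predictor input. The second
#' nucleotide row of the two-row AKR1C1 p.S221N change inherits the printed
#' score of its companion row.
#'
#' @return Variant tibble in the pipeline input schema.
#' @export
fixture_variant_table <- function() {
  fx <- load_fixture("variants")
  # two-row MNV: fill the unscored companion row from its scored partner
  fx <- fx %>%
    group_by(.data$patient_id, .data$gene, .data$hgvs_p) %>%
    mutate(score_fill = if (all(is.na(.data$score))) NA_integer_ else
      as.integer(max(.data$score, na.rm = TRUE)),
      score = ifelse(is.na(.data$score) & .data$consequence == "missense" &
                       n() > 1, .data$score_fill, .data$score)) %>%
    ungroup() %>%
    select(-"score_fill")
  k <- ifelse(is.na(fx$score), 0L, fx$score)
  nn <- function(j) k >= j  # predictor j non-neutral iff score reaches j
  is_indel <- fx$consequence == "inframe_indel"
  tibble(
    patient_id = fx$patient_id, chrom = fx$chrom, pos = fx$pos,
    ref = fx$ref, alt = fx$alt, gene = fx$gene, hgvs_p = fx$hgvs_p,
    consequence = fx$consequence, depth = 50, qual = 90,
    in_splice_site = fx$in_splice_site,
    polyphen2 = ifelse(fx$consequence == "missense",
                       ifelse(nn(1), "probably_damaging", "benign"),
                       NA_character_),
    sift = ifelse(fx$consequence == "missense",
                  ifelse(nn(2), "damaging", "tolerated"), NA_character_),
    provean = ifelse(fx$consequence == "missense",
                     ifelse(nn(3), "deleterious", "neutral"),
                     ifelse(is_indel, "deleterious", NA_character_)),
    mutation_assessor = ifelse(fx$consequence == "missense",
                               ifelse(nn(4), "high", "neutral"),
                               NA_character_),
    mt_call = ifelse(fx$consequence == "missense",
                     ifelse(nn(5), "disease_causing", "polymorphism"),
                     NA_character_),
    mt_prob = ifelse(fx$consequence == "missense",
                     ifelse(nn(5), 0.999, 0.5), NA_real_),
    sift_indel = NA_character_)
}

#' Population table derived from the packaged variant fixture
#'
#' Matched-subpopulation rows for every fixture variant with a printed
#' allele count; never-reported and database-excluded variants get no row.
#'
#' @return Population tibble (`subpop = "European non-Finnish"`).
#' @export
fixture_population_table <- function() {
  fx <- load_fixture("variants")
  fx <- fx[!is.na(fx$allele_count), , drop = FALSE]
  fx <- fx[!duplicated(variant_key(fx)), , drop = FALSE]
  tibble(chrom = fx$chrom, pos = fx$pos, ref = fx$ref, alt = fx$alt,
         subpop = "European non-Finnish", allele_count = fx$allele_count,
         allele_number = fx$allele_number)
}

#' Variant keys the population database excludes by policy
#'
#' @return Tibble of `chrom, pos, ref, alt` for fixture variants flagged as
#'   excluded from the database (severe-pediatric-disease policy).
#' @export
fixture_db_excluded_keys <- function() {
  fx <- load_fixture("variants")
  fx[fx$db_excluded, c("chrom", "pos", "ref", "alt")]
}

#' DDR gene symbols from the packaged list
#'
#' @return Character vector of 17 normalized symbols.
#' @export
fixture_ddr_genes <- function() {
  load_fixture("ddr_genes")$symbol
}

#' Non-rare carve-out whitelist for the packaged study
#'
#' The genes whose packaged variants exceed the 1% rarity cutoff in the
#' matched subpopulation but were retained as relevant to cancer risk:
#' BRCA1, PALB2, FANCA, BLM, RAD51D and DOLK (whose start-loss variant
#' carries the maximal truncating score).
#'
#' @return Character vector of gene symbols.
#' @export
fixture_whitelist <- function() {
  c("BRCA1", "PALB2", "FANCA", "BLM", "RAD51D", "DOLK")
}
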
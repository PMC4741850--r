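base_row <- function(...) {
  row <- tibble::tibble(
    patient_id = "P1", chrom = "1", pos = 100, ref = "A", alt = "G",
    gene = "BRCA1", hgvs_p = "p.Q356R", consequence = "missense",
    depth = 50, qual = 90, in_splice_site = FALSE,
    polyphen2 = NA_character_, sift = NA_character_,
    provean = NA_character_, mutation_assessor = NA_character_,
    mt_call = NA_character_, mt_prob = NA_real_,
    sift_indel = NA_character_)
  dplyr::mutate(row, ...)
}

test_that("quality filter applies strict depth/quality thresholds", {
  tbl <- dplyr::bind_rows(
    base_row(depth = 4, qual = 26),   # just above both: retained
    base_row(depth = 3, qual = 40),   # "more than 3 reads" is strict
    base_row(depth = 10, qual = 25),  # quality boundary is strict
    base_row(depth = 2, qual = 20))
  expect_equal(nrow(qc_filter(tbl)), 1L)
  expect_warning(qc_filter(base_row(depth = NA)), "missing")
  # 100 random records against a brute-force row scan
  rnd <- random_variant_table(100, seed = 7)
  expect_equal(qc_filter(rnd), rnd[rnd$depth > 3 & rnd$qual > 25, ])
})

test_that("consequence filter drops synonymous/non-coding, keeps splice", {
  tbl <- dplyr::bind_rows(
    base_row(consequence = "synonymous"),
    base_row(consequence = "other"),
    base_row(consequence = "splice", hgvs_p = "Splice acceptor (-1)"),
    base_row(consequence = "missense"))
  out <- consequence_filter(tbl)
  expect_setequal(out$consequence, c("splice", "missense"))
  expect_equal(nrow(consequence_filter(tbl[0, ])), 0L)
})

test_that("predictor call conversion follows the published rules", {
  expect_equal(classify_call("polyphen2", "possibly_damaging"), "non_neutral")
  expect_equal(classify_call("polyphen2", "benign"), "neutral")
  expect_equal(classify_call("mutation_assessor", "medium"), "non_neutral")
  expect_equal(classify_call("mutation_assessor", "low"), "neutral")
  expect_equal(classify_call("sift", "tolerated"), "neutral")
  expect_equal(classify_call("provean", "deleterious"), "non_neutral")
  # MutationTaster needs a disease_causing call AND probability >= 0.99
  expect_equal(classify_call("mutation_taster", "disease_causing", 0.98),
               "neutral")
  expect_equal(classify_call("mutation_taster", "disease_causing", 0.99),
               "non_neutral")
  expect_equal(classify_call("mutation_taster", "polymorphism", 0.999),
               "neutral")
  expect_equal(classify_call("sift", NA), "unavailable")
  expect_error(classify_call("sift", "bogus"), "bogus")
})

test_that("consensus scoring reproduces the printed score conventions", {
  scored <- score_variants(dplyr::bind_rows(
    # 4 of 5 non-neutral missense: selected by consensus
    base_row(polyphen2 = "probably_damaging", sift = "damaging",
             provean = "deleterious", mutation_assessor = "high",
             mt_call = "polymorphism", mt_prob = 0.5),
    # 2 of 5 but in a splice site: selected regardless
    base_row(gene = "CRISP3", polyphen2 = "probably_damaging",
             sift = "damaging", provean = "neutral",
             mutation_assessor = "low", mt_call = "polymorphism",
             mt_prob = 0.5, in_splice_site = TRUE),
    # frameshift: auto-truncating
    base_row(gene = "PALB2", hgvs_p = "p.E1002Tfs*4",
             consequence = "frameshift", ref = "TTTTC", alt = "T"),
    # start loss is treated as truncating
    base_row(gene = "DOLK", hgvs_p = "p.M1?", consequence = "start_loss"),
    # missense with no predictor available: unscorable, not selected
    base_row(gene = "ZZZ9"),
    # 2 of 5, no splice site: not selected
    base_row(polyphen2 = "probably_damaging", sift = "damaging",
             provean = "neutral", mutation_assessor = "low",
             mt_call = "polymorphism", mt_prob = 0.5)))
  expect_equal(scored$selection_reason,
               c("consensus", "splice_site_missense", "truncating",
                 "truncating", "not_selected", "not_selected"))
  expect_equal(scored$n_non_neutral[1], 4L)
  expect_true(all(scored$auto_truncating[3:4]))
  expect_true(scored$unscorable[5])
  expect_equal(scored$selected,
               c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("in-frame indels use PROVEAN/MutationTaster plus SIFT-Indel for 3N", {
  ind <- function(...) base_row(consequence = "inframe_indel",
                                ref = "ATAG", alt = "A", ...)
  scored <- score_variants(dplyr::bind_rows(
    ind(provean = "deleterious"),
    ind(mt_call = "disease_causing", mt_prob = 0.999),
    ind(provean = "neutral", mt_call = "polymorphism", mt_prob = 0.5,
        sift_indel = "damaging"),
    ind(provean = "neutral", mt_call = "polymorphism", mt_prob = 0.5,
        sift_indel = "neutral"),
    # non-3N indel: damaging SIFT-Indel call must not count
    ind(ref = "AT", alt = "A", provean = "neutral", sift_indel = "damaging")))
  expect_equal(scored$selected, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(scored$selection_reason[1:3] == "indel_predictor"))
  # the stricter "all available predictors" rule is available
  strict <- score_variants(ind(provean = "deleterious",
                               mt_call = "polymorphism", mt_prob = 0.5),
                           indel_rule = "all")
  expect_false(strict$selected)
})

test_that("upgrading any neutral call never un-selects a variant", {
  rnd <- random_variant_table(300, seed = 11)
  scored <- score_variants(rnd)
  upgrade <- rnd
  upgrade$polyphen2[!is.na(upgrade$polyphen2)] <- "probably_damaging"
  upgrade$provean[!is.na(upgrade$provean)] <- "deleterious"
  rescored <- score_variants(upgrade)
  expect_true(all(rescored$n_non_neutral >= scored$n_non_neutral))
  expect_true(all(rescored$selected >= scored$selected))
})

test_that("the composed pipeline equals a brute-force sequential row scan", {
  rnd <- random_variant_table(500, seed = 3)
  pop <- random_population_table(rnd, seed = 3)
  panel_genes <- sprintf("G%03d", 1:30)  # drop some genes
  whitelist <- c("G001", "G002")
  got <- select_variants(rnd, panel = panel_genes, popfreq = pop,
                         maf_cutoff = 0.01, whitelist = whitelist)
  want <- rnd[oracle_pipeline(rnd, panel_genes, pop, 0.01, whitelist), ]
  key <- function(x) paste(x$patient_id, x$chrom, x$pos, x$ref, x$alt)
  expect_setequal(key(got), key(want))
  # output ordering: patient then coordinate
  expect_equal(order(got$patient_id, got$chrom, got$pos), seq_len(nrow(got)))
})

test_that("a common variant is excluded unless its gene is whitelisted", {
  v <- base_row(polyphen2 = "probably_damaging", sift = "damaging",
                provean = "deleterious", mutation_assessor = "high")
  pop <- tibble::tibble(chrom = "1", pos = 100, ref = "A", alt = "G",
                        subpop = "European non-Finnish",
                        allele_count = 3300, allele_number = 66000)  # 5%
  expect_equal(nrow(select_variants(v, popfreq = pop)), 0L)
  expect_equal(nrow(select_variants(v, popfreq = pop, whitelist = "BRCA1")),
               1L)
  # variants absent from the table pass the rarity filter
  expect_equal(nrow(select_variants(v, popfreq = pop[0, ])), 1L)
})

test_that("variant tables round-trip through the TSV reader/writer", {
  rnd <- random_variant_table(40, seed = 19)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(rnd, path)
  back <- read_variant_table(path)
  expect_equal(as.data.frame(back), as.data.frame(rnd))
})
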
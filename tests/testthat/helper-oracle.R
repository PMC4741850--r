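# Independent helpers for oracle-based tests: plain base-R row scans and
# closed forms, deliberately written without reusing package internals.

# random annotated variant table in the pipeline input schema
random_variant_table <- function(n, seed) {
  set.seed(seed)
  cons <- sample(c("missense", "stop_gain", "frameshift", "inframe_indel",
                   "splice", "start_loss", "synonymous", "other"),
                 n, replace = TRUE)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- ifelse(cons == "inframe_indel",
                paste0(ref, strrep("TA", sample(1:3, n, replace = TRUE))),
                sample(c("A", "C", "G", "T"), n, replace = TRUE))
  same <- alt == ref
  alt[same] <- chartr("ACGT", "CGTA", alt[same])
  cat5 <- function(hit, miss) {
    x <- ifelse(runif(n) < 0.5, hit, miss)
    x[runif(n) < 0.15] <- NA
    x
  }
  tibble::tibble(
    patient_id = sample(sprintf("P%02d", 1:8), n, replace = TRUE),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(1e8, n), ref = ref, alt = alt,
    gene = sample(sprintf("G%03d", 1:40), n, replace = TRUE),
    hgvs_p = NA_character_, consequence = cons,
    depth = sample(1:10, n, replace = TRUE),
    qual = sample(20:30, n, replace = TRUE),
    in_splice_site = runif(n) < 0.1,
    polyphen2 = cat5("probably_damaging", "benign"),
    sift = cat5("damaging", "tolerated"),
    provean = cat5("deleterious", "neutral"),
    mutation_assessor = cat5("medium", "low"),
    mt_call = cat5("disease_causing", "polymorphism"),
    mt_prob = round(runif(n, 0.9, 1), 3),
    sift_indel = cat5("damaging", "neutral"))
}

# random population table covering a subset of the variants
random_population_table <- function(variants, seed,
                                    subpop = "European non-Finnish") {
  set.seed(seed + 1000)
  keys <- unique(variants[c("chrom", "pos", "ref", "alt")])
  n <- nrow(keys)
  fate <- sample(c("none", "zero", "present"), n, replace = TRUE,
                 prob = c(0.3, 0.2, 0.5))
  an <- 50000
  ac <- ifelse(fate == "present", rbinom(n, an, rbeta(n, 0.4, 30)), 0)
  keep <- fate != "none"
  out <- keys[keep, ]
  out$subpop <- subpop
  out$allele_count <- ac[keep]
  out$allele_number <- an
  tibble::as_tibble(out)
}

# row-wise oracle: is one predictor call non-neutral?
oracle_nn <- function(pred, call, prob = NA) {
  if (is.na(call)) return(FALSE)
  switch(pred,
    polyphen2 = call %in% c("probably_damaging", "possibly_damaging"),
    sift = call == "damaging",
    provean = call == "deleterious",
    mutation_assessor = call %in% c("high", "medium"),
    mutation_taster = call %in% c("disease_causing",
                                  "disease_causing_automatic") &&
      !is.na(prob) && prob >= 0.99,
    sift_indel = call == "damaging")
}

# row-wise oracle for the damage-selection decision of one variant
oracle_selected <- function(row) {
  cons <- row$consequence
  if (cons %in% c("stop_gain", "frameshift", "start_loss")) return(TRUE)
  if (cons == "splice") return(TRUE)
  if (cons == "missense") {
    k <- oracle_nn("polyphen2", row$polyphen2) +
      oracle_nn("sift", row$sift) +
      oracle_nn("provean", row$provean) +
      oracle_nn("mutation_assessor", row$mutation_assessor) +
      oracle_nn("mutation_taster", row$mt_call, row$mt_prob)
    if (k >= 3) return(TRUE)
    return(isTRUE(row$in_splice_site))
  }
  if (cons == "inframe_indel") {
    k <- oracle_nn("provean", row$provean) +
      oracle_nn("mutation_taster", row$mt_call, row$mt_prob)
    if (abs(nchar(row$ref) - nchar(row$alt)) %% 3 == 0) {
      k <- k + oracle_nn("sift_indel", row$sift_indel)
    }
    return(k >= 1)
  }
  FALSE
}

# full-pipeline oracle: sequential row scan over the four filters + scoring
oracle_pipeline <- function(variants, panel_genes, popfreq, maf_cutoff,
                            whitelist, subpop = "European non-Finnish") {
  keep <- logical(nrow(variants))
  pkeys <- paste(popfreq$chrom, popfreq$pos, popfreq$ref, popfreq$alt,
                 popfreq$subpop, sep = ":")
  for (i in seq_len(nrow(variants))) {
    row <- as.list(variants[i, ])
    if (!(row$depth > 3 && row$qual > 25)) next
    if (row$consequence %in% c("synonymous", "other")) next
    if (!row$gene %in% panel_genes) next
    k <- paste(row$chrom, row$pos, row$ref, row$alt, subpop, sep = ":")
    hit <- match(k, pkeys)
    if (!is.na(hit) && popfreq$allele_count[hit] > 0) {
      freq <- popfreq$allele_count[hit] / popfreq$allele_number[hit]
      if (freq >= maf_cutoff && !row$gene %in% whitelist) next
    }
    keep[i] <- oracle_selected(row)
  }
  keep
}

# all-pairs AUC oracle with half credit for ties
oracle_auc <- function(scores, labels, positive = "case") {
  cs <- scores[labels == positive]
  ns <- scores[labels != positive]
  tot <- 0
  for (a in cs) for (b in ns) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cs) * length(ns))
}

# exhaustive Youden scan oracle over all midpoints
oracle_cutoff <- function(scores, labels, positive = "case") {
  u <- sort(unique(scores))
  cand <- (u[-length(u)] + u[-1]) / 2
  best <- -Inf; best_ct <- NA
  for (ct in cand) {
    sens <- mean(scores[labels == positive] > ct)
    spec <- mean(scores[labels != positive] <= ct)
    if (sens + spec - 1 > best) {
      best <- sens + spec - 1
      best_ct <- ct
    }
  }
  list(cutoff = best_ct, j = best)
}

# exact two-sided permutation p-value for the rank-sum statistic
oracle_ranksum_p <- function(x, y) {
  all <- c(x, y)
  n <- length(all)
  r <- rank(all)
  obs <- sum(r[seq_along(x)])
  combs <- utils::combn(n, length(x))
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- length(x) * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}
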
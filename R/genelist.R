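#' Read a gene-symbol alias snapshot
#'
#' The panel builder resolves raw symbols against a static alias snapshot: a
#' three-column table mapping every raw symbol (official symbols map to
#' themselves) to its official symbol and HGNC-style locus type. A packaged
#' snapshot covering the genes used by the packaged study tables is available
#' via [load_fixture()]`("aliases")`.
#'
#' @param path Path to a TSV with columns `raw`, `official`, `locus_type`.
#' @return A tibble with columns `raw`, `official`, `locus_type`.
#' @export
read_alias_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  stopifnot(all(c("raw", "official", "locus_type") %in% names(tbl)))
  as_tibble(tbl)
}

#' Normalize raw gene symbols to official symbols
#'
#' Symbols are looked up case-insensitively in the alias table; duplicates
#' (after normalization) are collapsed. Symbols without a mapping are not
#' dropped silently: they are returned separately so a curator can inspect
#' them.
#'
#' @param raw_list Character vector of raw gene symbols.
#' @param aliases Alias tibble from [read_alias_table()], or `NULL` to treat
#'   every symbol as already official (identity mapping).
#' @return A list with elements `normalized` (official symbols, deduplicated,
#'   input order preserved) and `unmapped` (raw symbols with no mapping).
#' @export
normalize_symbols <- function(raw_list, aliases = NULL) {
  if (length(raw_list) == 0L) {
    abort("empty symbol list: source is misconfigured")
  }
  raw_list <- as.character(raw_list)
  if (is.null(aliases)) {
    return(list(normalized = unique(raw_list), unmapped = character()))
  }
  idx <- match(toupper(raw_list), toupper(aliases$raw))
  unmapped <- raw_list[is.na(idx)]
  normalized <- unique(aliases$official[idx[!is.na(idx)]])
  list(normalized = normalized, unmapped = unique(unmapped))
}

# locus types excluded from the panel (phenotype-only loci have no causative
# gene; non-coding transcripts and pseudogenes are outside a protein-damage
# screen)
EXCLUDED_LOCUS_TYPES <- c("phenotype-only", "non-coding RNA", "pseudogene")

#' Drop panel entries with excluded locus types
#'
#' Removes entries whose locus type is phenotype-only, non-coding RNA or
#' pseudogene. Removals are recorded in the `"excluded"` attribute of the
#' result (a tibble of symbol + reason), never silently.
#'
#' @param entries A tibble with a `symbol` column of official symbols.
#' @param aliases Alias tibble providing `locus_type` per official symbol.
#' @return `entries` without excluded rows; attribute `"excluded"` holds the
#'   removal log.
#' @export
apply_exclusions <- function(entries, aliases) {
  lt <- aliases$locus_type[match(toupper(entries$symbol),
                                 toupper(aliases$official))]
  drop <- !is.na(lt) & lt %in% EXCLUDED_LOCUS_TYPES
  excluded <- tibble(symbol = entries$symbol[drop],
                     reason = paste("locus type:", lt[drop]))
  out <- entries[!drop, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Describe one candidate-gene source
#'
#' @param source_id Short unique label for the source.
#' @param symbols Ordered character vector of raw gene symbols.
#' @param description Free-text description.
#' @param rank_limit Optional integer: keep only the top `rank_limit`
#'   symbols of the published ordering before merging ("Top 50" style
#'   sources).
#' @param categories Character vector of category tags applied to every gene
#'   contributed by this source (e.g. `"DDR"`).
#' @return A `gene_source` list.
#' @export
gene_source <- function(source_id, symbols, description = "",
                        rank_limit = NULL, categories = character()) {
  stopifnot(is.character(source_id), length(source_id) == 1L)
  structure(list(source_id = source_id, symbols = as.character(symbols),
                 description = description, rank_limit = rank_limit,
                 categories = as.character(categories)),
            class = "gene_source")
}

#' Build the candidate gene panel from multiple sources
#'
#' Each source is truncated to its `rank_limit` (if any), deduplicated,
#' normalized against the alias snapshot, and filtered by locus type; the
#' panel is the union of the survivors. Every entry carries the full set of
#' contributing sources and the union of their category tags. Output is
#' sorted by symbol, so rebuilding from identical inputs is deterministic.
#'
#' Unmapped symbols are not fatal: they are reported in the audit attached as
#' attribute `"audit"`, a tibble with columns `source_id`, `raw_symbol`,
#' `status` (`"unmapped"` or `"excluded"`) and `reason`. The accounting
#' invariant holds per source: normalized + unmapped + excluded = deduplicated
#' raw input.
#'
#' @param sources List of [gene_source()] objects (at least one).
#' @param aliases Alias tibble, or `NULL` for identity mapping (no
#'   exclusions possible without locus types).
#' @param category_overrides Optional tibble (`symbol`, `category`) adding
#'   per-gene category tags on top of the source-level tags.
#' @return Tibble with columns `symbol`, `sources` (semicolon-joined),
#'   `categories` (semicolon-joined); attribute `"audit"` as described.
#' @export
build_panel <- function(sources, aliases = NULL, category_overrides = NULL) {
  if (inherits(sources, "gene_source")) sources <- list(sources)
  stopifnot(length(sources) >= 1L)
  ids <- vapply(sources, function(s) s$source_id, character(1))
  if (anyDuplicated(ids)) abort("duplicate source_id in panel build")

  audit <- list()
  contrib <- list()
  for (s in sources) {
    syms <- s$symbols
    if (!is.null(s$rank_limit)) syms <- utils::head(syms, s$rank_limit)
    syms <- unique(syms)
    norm <- normalize_symbols(syms, aliases)
    if (length(norm$unmapped)) {
      audit[[length(audit) + 1L]] <- tibble(
        source_id = s$source_id, raw_symbol = norm$unmapped,
        status = "unmapped", reason = "no alias-table entry")
    }
    entries <- tibble(symbol = norm$normalized)
    if (!is.null(aliases)) {
      entries <- apply_exclusions(entries, aliases)
      exc <- attr(entries, "excluded")
      if (nrow(exc)) {
        audit[[length(audit) + 1L]] <- tibble(
          source_id = s$source_id, raw_symbol = exc$symbol,
          status = "excluded", reason = exc$reason)
      }
    }
    if (nrow(entries)) {
      contrib[[length(contrib) + 1L]] <- tibble(
        symbol = entries$symbol, source_id = s$source_id,
        category = list(s$categories))
    }
  }
  contrib <- bind_rows(contrib)
  if (is.null(contrib) || nrow(contrib) == 0L) {
    out <- tibble(symbol = character(), sources = character(),
                  categories = character())
  } else {
    out <- contrib %>%
      group_by(.data$symbol) %>%
      summarise(
        sources = paste(sort(unique(.data$source_id)), collapse = ";"),
        categories = paste(sort(unique(unlist(.data$category))),
                           collapse = ";"),
        .groups = "drop") %>%
      arrange(.data$symbol)
  }
  if (!is.null(category_overrides) && nrow(out)) {
    ov <- category_overrides %>%
      group_by(.data$symbol) %>%
      summarise(extra = paste(sort(unique(.data$category)), collapse = ";"),
                .groups = "drop")
    out <- out %>%
      left_join(ov, by = "symbol") %>%
      mutate(categories = ifelse(
        is.na(.data$extra), .data$categories,
        vapply(strsplit(paste(.data$categories, .data$extra, sep = ";"), ";"),
               function(x) paste(sort(unique(x[nzchar(x)])), collapse = ";"),
               character(1)))) %>%
      select(-"extra")
  }
  attr(out, "audit") <- bind_rows(audit) %||%
    tibble(source_id = character(), raw_symbol = character(),
           status = character(), reason = character())
  if (length(audit) == 0L) {
    attr(out, "audit") <- tibble(source_id = character(),
                                 raw_symbol = character(),
                                 status = character(), reason = character())
  }
  out
}

#' Write / read a gene panel TSV
#'
#' @param panel Panel tibble from [build_panel()].
#' @param path Output path.
#' @return `path`, invisibly (writer); panel tibble (reader).
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(panel, path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}
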
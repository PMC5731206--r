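#' A named collection of gene symbols
#'
#' Symbols are normalised (whitespace trimmed, case-folded) and
#' de-duplicated.  No alias or ortholog resolution is attempted — raw
#' symbol joins are a known source of undercounting when comparing lists
#' across studies, and that behaviour is deliberate.
#'
#' @param name Collection name (unique within a comparison).
#' @param symbols Character vector of gene symbols.
#' @param note Free-text provenance note.
#' @return A `gene_list_collection` list with `name`, `symbols`
#'   (normalised, unique) and `note`.
#' @export
gene_list_collection <- function(name, symbols, note = "") {
  if (!nzchar(name)) stop("collection needs a non-empty name")
  sym <- unique(normalize_symbols(symbols))
  sym <- sym[!is.na(sym) & nzchar(sym)]
  structure(list(name = name, symbols = sym, note = note),
            class = "gene_list_collection")
}

#' @export
print.gene_list_collection <- function(x, ...) {
  cat(sprintf("gene_list_collection '%s': %d symbols\n",
              x$name, length(x$symbols)))
  invisible(x)
}

#' Align an external gene list with the ablation contrasts
#'
#' For every symbol of an external Sertoli-cell gene list (e.g. from a
#' RiboTag or FACS study), reports whether it matches a transcript in the
#' ablation contrasts (case-insensitive symbol join) and, if so, whether
#' that transcript (a) shows a DTX residual at or below the criteria's
#' ceiling (the "70% or greater decrease" condition alone) and (b) passes
#' the full Sertoli-specificity criteria.  Symbols mapping to several
#' transcripts count as passing if any transcript passes, so full-criteria
#' passes are always a subset of residual-only passes.
#'
#' @param external A [gene_list_collection()].
#' @param bus_contrast,dtx_contrast The two ablation `group_contrast`
#'   tables, carrying gene symbols and q-values.
#' @param criteria A `stringency_criteria`.
#' @return A data.frame with one row per external symbol: `symbol`,
#'   `matched`, `passes_residual`, `passes_full`; plus attributes
#'   `n_matched`, `n_residual`, `n_full`.
#' @export
align_by_symbol <- function(external, bus_contrast, dtx_contrast, criteria) {
  stopifnot(inherits(external, "gene_list_collection"))
  if (!length(external$symbols)) stop("external gene list is empty")
  calls <- classify_sertoli_specific(bus_contrast, dtx_contrast, criteria)
  key <- normalize_symbols(calls$gene_symbol)
  n_nosym <- sum(is.na(key))
  if (n_nosym > 0)
    message(n_nosym, " transcript(s) without gene symbol skipped in join")
  residual_ok <- !is.na(calls$dtx_residual) &
    calls$dtx_residual <= criteria$max_dtx_residual
  full_ok <- calls$category == "sertoli_specific"
  out <- data.frame(symbol = external$symbols, stringsAsFactors = FALSE)
  out$matched <- out$symbol %in% key[!is.na(key)]
  out$passes_residual <- vapply(out$symbol, function(s)
    any(residual_ok[!is.na(key) & key == s]), logical(1))
  out$passes_full <- vapply(out$symbol, function(s)
    any(full_ok[!is.na(key) & key == s]), logical(1))
  attr(out, "n_matched") <- sum(out$matched)
  attr(out, "n_residual") <- sum(out$passes_residual)
  attr(out, "n_full") <- sum(out$passes_full)
  out
}

#' Intersect gene-list collections
#'
#' Symbols present in every collection; commutative and associative under
#' reordering of the inputs.
#'
#' @param collections A list of [gene_list_collection()] objects (length
#'   >= 1).
#' @return A `gene_list_collection` named by joining the input names with
#'   an intersection sign.
#' @export
intersect_collections <- function(collections) {
  if (!length(collections)) stop("need at least one collection")
  stopifnot(all(vapply(collections, inherits, logical(1),
                       "gene_list_collection")))
  sym <- Reduce(intersect, lapply(collections, `[[`, "symbols"))
  gene_list_collection(
    paste(vapply(collections, `[[`, character(1), "name"),
          collapse = " ∩ "),
    sym,
    note = sprintf("intersection of %d collections", length(collections)))
}
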
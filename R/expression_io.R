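#' Construct an expression matrix with grouped samples
#'
#' The central container of the package: a transcripts-by-samples matrix of
#' non-negative, FPKM-scale (or normalised-per-testis) abundances together
#' with a per-sample design (group label and replicate index) and optional
#' per-transcript gene symbols.  Many transcripts in ablation-derived lists
#' are unannotated gene models, so missing symbols (`NA`) are allowed;
#' symbol-keyed operations skip such rows and report how many were skipped.
#'
#' @param values Numeric matrix, transcripts in rows (rownames are the
#'   transcript ids) and samples in columns.  All values must be finite and
#'   `>= 0`; abundances are treated as opaque non-negative reals.
#' @param groups Character vector of group labels, one per sample column.
#' @param replicates Optional integer vector of replicate indices per sample;
#'   defaults to 1..k within each group in column order.
#' @param gene_symbol Optional character vector of gene symbols per
#'   transcript (`NA` where unannotated).
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `samples` (data.frame with `sample_id`, `group`, `replicate`) and
#'   `gene_symbol`.
#' @export
expression_matrix <- function(values, groups, replicates = NULL,
                              gene_symbol = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    stop("'values' must carry transcript ids as rownames")
  if (length(groups) != ncol(values))
    stop("'groups' must have one entry per sample column")
  if (is.null(colnames(values)))
    colnames(values) <- make.unique(paste(groups, "s", sep = "_"))
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_along(groups), groups, FUN = seq_along)
  }
  x <- structure(
    list(values = values,
         samples = data.frame(sample_id = colnames(values),
                              group = as.character(groups),
                              replicate = as.integer(replicates),
                              stringsAsFactors = FALSE),
         gene_symbol = if (is.null(gene_symbol))
           rep(NA_character_, nrow(values)) else as.character(gene_symbol)),
    class = "expr_matrix")
  validate_expression_matrix(x)
}

#' Validate an expression matrix
#'
#' Checks the container invariants: unique transcript ids, finite
#' non-negative values, every sample labelled with exactly one group and at
#' least one replicate per group.
#'
#' @param x An `expr_matrix`.
#' @return `x`, invisibly usable, after passing all checks (errors otherwise).
#' @export
validate_expression_matrix <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  ids <- rownames(x$values)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate transcript id(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(x$values) | x$values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative or non-finite value at row '%s', column '%s'",
                 ids[bad[1, 1]], colnames(x$values)[bad[1, 2]]))
  if (any(is.na(x$samples$group) | x$samples$group == ""))
    stop("sample without a group label: ",
         x$samples$sample_id[is.na(x$samples$group) | x$samples$group == ""][1])
  if (length(x$gene_symbol) != nrow(x$values))
    stop("gene_symbol length must match the number of transcripts")
  x
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d transcripts x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$group)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Group labels of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of distinct group labels in sample order.
#' @export
expr_groups <- function(x) unique(x$samples$group)

#' Table dialect for expression matrices
#'
#' Column-name descriptor for the tab-separated expression format.  The
#' working table formats of upstream pipelines vary, so the reader is
#' configurable: only the transcript-id column is mandatory.
#'
#' @param id_col Name of the transcript-id column.
#' @param symbol_col Name of the gene-symbol column, or `NULL` if absent.
#' @return A list usable as the `dialect` argument of
#'   [read_expression_table()].
#' @export
expression_dialect <- function(id_col = "transcript_id",
                               symbol_col = "gene_symbol") {
  list(id_col = id_col, symbol_col = symbol_col)
}

#' Read an expression table with its sidecar design
#'
#' Reads a tab-separated, UTF-8, one-header-line table of abundances plus a
#' sidecar design table (`sample_id`, `group`, `replicate`) mapping sample
#' columns to treatment groups.  Row order is preserved; no rows are ever
#' silently dropped.
#'
#' @param path Path to the expression TSV.
#' @param design Path to the design TSV, or a data.frame with columns
#'   `sample_id`, `group` and optionally `replicate`.
#' @param dialect An [expression_dialect()].
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, design,
                                  dialect = expression_dialect()) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!dialect$id_col %in% names(tab))
    stop("missing transcript-id column '", dialect$id_col, "' in ", path)
  if (is.character(design)) design <- read_design(design)
  if (!all(c("sample_id", "group") %in% names(design)))
    stop("design must have columns 'sample_id' and 'group'")
  ids <- as.character(tab[[dialect$id_col]])
  sym <- NULL
  meta_cols <- dialect$id_col
  if (!is.null(dialect$symbol_col) && dialect$symbol_col %in% names(tab)) {
    sym <- as.character(tab[[dialect$symbol_col]])
    sym[sym == ""] <- NA_character_
    meta_cols <- c(meta_cols, dialect$symbol_col)
  }
  sample_cols <- setdiff(names(tab), meta_cols)
  missing_design <- setdiff(sample_cols, design$sample_id)
  if (length(missing_design))
    stop("sample without group in design: ",
         paste(missing_design, collapse = ", "))
  design <- design[match(sample_cols, design$sample_id), , drop = FALSE]
  vals <- as.matrix(tab[, sample_cols, drop = FALSE])
  rownames(vals) <- ids
  expression_matrix(vals, groups = design$group,
                    replicates = if ("replicate" %in% names(design))
                      design$replicate else NULL,
                    gene_symbol = sym)
}

#' Read a sample design table
#' @param path Path to a TSV with columns `sample_id`, `group`,
#'   optionally `replicate`.
#' @return A data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(d)))
    stop("design file must have columns 'sample_id' and 'group'")
  d
}

#' Write an expression matrix and its design to TSV
#'
#' Inverse of [read_expression_table()]; a write-then-read round trip
#' reproduces values to floating-point precision and metadata exactly.
#'
#' @param x An `expr_matrix`.
#' @param path Output path for the expression TSV.
#' @param design_path Output path for the sidecar design TSV.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, design_path) {
  validate_expression_matrix(x)
  tab <- data.frame(transcript_id = rownames(x$values),
                    gene_symbol = x$gene_symbol,
                    stringsAsFactors = FALSE, check.names = FALSE)
  tab <- cbind(tab, as.data.frame(x$values, check.names = FALSE))
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Table dialect for pairwise-contrast tables
#'
#' Descriptor for ingesting differential-expression output in the tabular
#' dialect of Cuffdiff-style tools (gene id, symbol, two group means, p, q).
#' Fold change is always recomputed from the two means, never trusted from
#' the file.
#'
#' @param id_col,symbol_col,mean_ref_col,mean_alt_col,p_col,q_col Column
#'   names in the file.
#' @return A list usable as the `dialect` argument of
#'   [read_contrast_table()].
#' @export
contrast_dialect <- function(id_col = "gene_id", symbol_col = "gene",
                             mean_ref_col = "value_1",
                             mean_alt_col = "value_2",
                             p_col = "p_value", q_col = "q_value") {
  list(id_col = id_col, symbol_col = symbol_col,
       mean_ref_col = mean_ref_col, mean_alt_col = mean_alt_col,
       p_col = p_col, q_col = q_col)
}

#' Read a precomputed pairwise-contrast table
#'
#' Parses one two-group contrast per row into the package's contrast
#' format.  `log2fc` is flagged undefined (`NA`) whenever either group mean
#' is zero; no pseudocounts are introduced.  Adjusted values smaller than
#' their p-values are tolerated (a foreign adjustment method may produce
#' them) but reported with a message.
#'
#' @param path Path to the contrast TSV.
#' @param dialect A [contrast_dialect()].
#' @return A `group_contrast` data.frame (see [compute_group_contrast()]).
#' @export
read_contrast_table <- function(path, dialect = contrast_dialect()) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c(dialect$id_col, dialect$mean_ref_col, dialect$mean_alt_col,
            dialect$p_col, dialect$q_col)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing column(s) in contrast table: ", paste(miss, collapse = ", "))
  mean_ref <- as.numeric(tab[[dialect$mean_ref_col]])
  mean_alt <- as.numeric(tab[[dialect$mean_alt_col]])
  p <- as.numeric(tab[[dialect$p_col]])
  q <- as.numeric(tab[[dialect$q_col]])
  n_qlp <- sum(q < p, na.rm = TRUE)
  if (n_qlp > 0)
    message(n_qlp, " row(s) with q < p (foreign adjustment method); kept as-is")
  sym <- if (!is.null(dialect$symbol_col) && dialect$symbol_col %in% names(tab))
    as.character(tab[[dialect$symbol_col]]) else NA_character_
  new_group_contrast(
    transcript_id = as.character(tab[[dialect$id_col]]),
    gene_symbol = sym,
    mean_ref = mean_ref, mean_alt = mean_alt,
    p_value = p, q_value = q,
    ref_group = "ref", alt_group = "alt")
}

#' Read a morphometry table
#'
#' One row per genotype with the quantities that define the Sertoli-cell
#' mRNA enrichment factor: Sertoli cells per testis and testis volume.
#'
#' @param path Path to a TSV with columns `genotype`,
#'   `sertoli_cells_per_testis`, `testis_volume`.
#' @return A validated data.frame.
#' @export
read_morphometry <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genotype", "sertoli_cells_per_testis", "testis_volume")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("morphometry table missing column(s): ", paste(miss, collapse = ", "))
  if (any(m$sertoli_cells_per_testis <= 0) || any(m$testis_volume <= 0))
    stop("morphometry counts and volumes must be strictly positive")
  if (anyDuplicated(m$genotype))
    stop("duplicated genotype in morphometry table")
  m
}

#' Read a plain gene list
#'
#' One symbol per line; blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln[nzchar(ln) & !startsWith(ln, "#")]
}

#' Biotype categories recognised by the package
#' @export
BIOTYPES <- c("protein_coding", "non_coding", "pseudogene", "other")

#' Read a biotype annotation table
#'
#' Maps transcript ids (or symbols) to one of the closed set of biotypes
#' `protein_coding`, `non_coding`, `pseudogene`, `other`.  Unknown labels
#' collapse to `other`.
#'
#' @param path Path to a TSV with columns `transcript_id` and `biotype`.
#' @return A data.frame with `transcript_id` and normalised `biotype`.
#' @export
read_biotype_annotation <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "biotype") %in% names(a)))
    stop("annotation must have columns 'transcript_id' and 'biotype'")
  a$biotype <- ifelse(a$biotype %in% BIOTYPES, a$biotype, "other")
  a
}

#' Normalise expression to an external spike-in standard
#'
#' Rescales each sample by its spike-in signal (e.g. luciferase mRNA added
#' per testis at extraction), yielding a relative value of transcript
#' expression per testis.  Within-sample relative ordering is unchanged.
#'
#' @param x An `expr_matrix` of raw values.
#' @param spike_signal Positive numeric vector, one spike signal per sample
#'   (optionally named by sample id).
#' @param scale Global scale constant applied after division (default 1, so
#'   the operation is idempotent for an all-ones spike signal).
#' @return An `expr_matrix` with `value[t, s] = raw[t, s] / spike_signal[s]
#'   * scale`.
#' @export
normalize_to_spike_in <- function(x, spike_signal, scale = 1) {
  validate_expression_matrix(x)
  if (length(spike_signal) != ncol(x$values))
    stop("'spike_signal' must have one value per sample")
  if (!is.null(names(spike_signal)))
    spike_signal <- spike_signal[x$samples$sample_id]
  bad <- which(!is.finite(spike_signal) | spike_signal <= 0)
  if (length(bad))
    stop("zero, negative or missing spike signal for sample: ",
         paste(x$samples$sample_id[bad], collapse = ", "))
  out <- x
  out$values <- sweep(x$values, 2, as.numeric(spike_signal), "/") * scale
  validate_expression_matrix(out)
}
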
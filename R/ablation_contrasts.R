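# Internal constructor shared by compute_group_contrast() and
# read_contrast_table().  Fold change is mean_alt/mean_ref, defined iff
# mean_ref > 0; log2fc additionally requires mean_alt > 0.  Incomputable
# ratios stay NA (flagged, never imputed with pseudocounts).
new_group_contrast <- function(transcript_id, gene_symbol, mean_ref, mean_alt,
                               p_value, q_value, ref_group, alt_group) {
  fc <- ifelse(mean_ref > 0, mean_alt / mean_ref, NA_real_)
  l2 <- ifelse(mean_ref > 0 & mean_alt > 0, log2(mean_alt / mean_ref),
               NA_real_)
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE))
    stop("p-value outside [0, 1]")
  out <- data.frame(transcript_id = transcript_id,
                    gene_symbol = gene_symbol,
                    mean_ref = mean_ref, mean_alt = mean_alt,
                    fold_change = fc, log2fc = l2,
                    p_value = p_value, q_value = q_value,
                    stringsAsFactors = FALSE)
  attr(out, "ref_group") <- ref_group
  attr(out, "alt_group") <- alt_group
  class(out) <- c("group_contrast", "data.frame")
  out
}

#' Per-transcript two-group contrast
#'
#' Computes, for every transcript, the two group means, the fold change
#' (`alt/ref`), the log2 fold change, and a p-value from either Welch's
#' unequal-variance two-sample t-test (the default, since replicate numbers
#' per treatment group need not be equal) or a one-way ANOVA.  Benjamini-
#' Hochberg q-values are filled across all transcripts of the contrast (one
#' adjustment family per contrast).
#'
#' Transcripts with all-zero values in both groups are retained with
#' undefined fold change and `p = 1`, so transcript universes stay aligned
#' between contrasts.  When both groups have zero within-group variance the
#' t-statistic is degenerate: such transcripts get `p = 1` if the means are
#' equal and `p = 0` if they differ (a noiseless difference).
#'
#' @param x An `expr_matrix`.
#' @param ref_group,alt_group Group labels of the reference (denominator)
#'   and alternative (numerator) conditions.
#' @param test `"welch_t"` (default), `"pooled_t"`, or `"one_way_anova"`.
#' @param adjust If `TRUE` (default) fill `q_value` by [adjust_fdr_bh()];
#'   otherwise `q_value` is `NA`.
#' @return A `group_contrast` data.frame with one row per transcript, in
#'   input row order, and columns `transcript_id`, `gene_symbol`,
#'   `mean_ref`, `mean_alt`, `fold_change`, `log2fc`, `p_value`, `q_value`.
#' @export
compute_group_contrast <- function(x, ref_group, alt_group,
                                   test = c("welch_t", "pooled_t",
                                            "one_way_anova"),
                                   adjust = TRUE) {
  validate_expression_matrix(x)
  test <- match.arg(test)
  grp <- x$samples$group
  if (!ref_group %in% grp) stop("unknown group label: ", ref_group)
  if (!alt_group %in% grp) stop("unknown group label: ", alt_group)
  ref <- x$values[, grp == ref_group, drop = FALSE]
  alt <- x$values[, grp == alt_group, drop = FALSE]
  if (ncol(ref) < 2 || ncol(alt) < 2)
    stop("both groups need >= 2 replicates for a variance-based test")
  mean_ref <- rowMeans(ref)
  mean_alt <- rowMeans(alt)
  p <- vapply(seq_len(nrow(x$values)), function(i) {
    a <- ref[i, ]; b <- alt[i, ]
    if (all(a == 0) && all(b == 0)) return(1)
    va <- stats::var(a); vb <- stats::var(b)
    if (va == 0 && vb == 0)
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    if (test == "one_way_anova") {
      y <- c(a, b)
      g <- factor(rep(c("r", "a"), c(length(a), length(b))))
      stats::anova(stats::lm(y ~ g))[["Pr(>F)"]][1]
    } else {
      stats::t.test(a, b, var.equal = (test == "pooled_t"))$p.value
    }
  }, numeric(1))
  out <- new_group_contrast(rownames(x$values), x$gene_symbol,
                            mean_ref, mean_alt, p, NA_real_,
                            ref_group, alt_group)
  if (adjust) out$q_value <- adjust_fdr_bh(out$p_value)
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted (q) values by the BH step-up procedure, monotone non-decreasing
#' in p-rank and capped at 1, returned in input order.  Undefined p-values
#' are excluded from the family and returned as `NA`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
adjust_fdr_bh <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-value outside [0, 1]")
  q <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Ablation scatter coordinates
#'
#' Joins the germ-cell-ablation contrast (busulfan vs control) and the
#' Sertoli-cell-ablation contrast (busulfan+DTX vs busulfan) into per-
#' transcript scatter coordinates: `x` is the busulfan log2 fold change,
#' `y` the DTX log2 fold change.  When the DTX-group mean is zero while the
#' busulfan mean is positive the log ratio cannot be calculated; such
#' points carry `undefined_y = TRUE` rather than a substituted value (the
#' "red arrow" points of an MA-style ablation scatter).
#'
#' @param bus_contrast `group_contrast` for busulfan vs control.
#' @param dtx_contrast `group_contrast` for busulfan+DTX vs busulfan.
#' @return A data.frame with `transcript_id`, `x`, `y`, `undefined_y`.
#'   Transcripts present in only one contrast are excluded with a message.
#' @export
scatter_coordinates <- function(bus_contrast, dtx_contrast) {
  common <- intersect(bus_contrast$transcript_id, dtx_contrast$transcript_id)
  n_drop <- length(union(bus_contrast$transcript_id,
                         dtx_contrast$transcript_id)) - length(common)
  if (n_drop > 0)
    message(n_drop, " transcript(s) present in only one contrast; excluded")
  b <- bus_contrast[match(common, bus_contrast$transcript_id), ]
  d <- dtx_contrast[match(common, dtx_contrast$transcript_id), ]
  data.frame(transcript_id = common,
             x = b$log2fc,
             y = d$log2fc,
             undefined_y = d$mean_alt == 0 & d$mean_ref > 0,
             stringsAsFactors = FALSE)
}

#' Somatic-enrichment estimate from a marker panel
#'
#' After germ-cell ablation, within-sample-normalised abundances of somatic
#' transcripts rise purely because somatic cells make up a larger share of
#' the remaining tissue.  This estimates that apparent enrichment as the
#' average busulfan-vs-control fold change over a user-supplied panel of
#' known somatic marker genes.
#'
#' @param bus_contrast `group_contrast` for busulfan vs control, carrying
#'   gene symbols.
#' @param marker_panel Character vector of somatic marker gene symbols.
#' @param average `"arithmetic"` (default) or `"geometric"` mean.
#' @return A list with `mean_fc`, `min_fc`, `max_fc` and `n_used` (the
#'   number of panel members matched with a defined fold change).
#' @export
estimate_enrichment_from_markers <- function(bus_contrast, marker_panel,
                                             average = c("arithmetic",
                                                         "geometric")) {
  average <- match.arg(average)
  key <- normalize_symbols(bus_contrast$gene_symbol)
  hit <- key %in% normalize_symbols(marker_panel)
  fc <- bus_contrast$fold_change[hit]
  fc <- fc[!is.na(fc)]
  if (!length(fc))
    stop("no marker-panel member matched with a defined fold change")
  m <- if (average == "arithmetic") mean(fc) else exp(mean(log(fc)))
  list(mean_fc = m, min_fc = min(fc), max_fc = max(fc), n_used = length(fc))
}

#' Write a contrast table to TSV
#' @param contrast A `group_contrast`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contrast_table <- function(contrast, path) {
  utils::write.table(format(as.data.frame(contrast), digits = 17,
                            trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# case-fold and trim gene symbols for joining; NA stays NA
normalize_symbols <- function(sym) toupper(trimws(sym))
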
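#' Stringency criteria for cell-specificity calling
#'
#' Bundles the thresholds of the ablation classifier.  A transcript is
#' called Sertoli-cell-specific when its abundance rises more than
#' `min_busulfan_fc`-fold after germ-cell ablation (strict inequality:
#' "more than n-fold") and falls after Sertoli-cell ablation to at most
#' `max_dtx_residual` of its busulfan-alone level (inclusive: "an n%
#' decrease"), with the required significance evidence.  Germ-cell
#' specificity requires a significant reduction after busulfan leaving less
#' than `germ_max_residual` of the control level (strict: ">90% reduction").
#'
#' @param min_busulfan_fc Fold-change floor for the busulfan increase
#'   (> 1).
#' @param max_dtx_residual Ceiling on the fraction of the busulfan-alone
#'   level remaining after DTX, in (0, 1).
#' @param require_significant_dtx Must the DTX reduction be significant at
#'   `fdr`?  Default `TRUE`.
#' @param significance_mode `"busulfan_or_dtx"` (default): a significant
#'   effect in either ablation contrast suffices as supporting evidence;
#'   `"dtx_only"`: only the DTX contrast counts.
#' @param alpha Per-test significance level (default 0.05).
#' @param fdr Benjamini-Hochberg FDR level applied to q-values (default
#'   0.05).
#' @param germ_max_residual Ceiling (exclusive) on the fraction of control
#'   level remaining after busulfan for a germ-cell call, in (0, 1).
#' @return A `stringency_criteria` list.
#' @export
stringency_criteria <- function(min_busulfan_fc = 2,
                                max_dtx_residual = 0.30,
                                require_significant_dtx = TRUE,
                                significance_mode = c("busulfan_or_dtx",
                                                      "dtx_only"),
                                alpha = 0.05, fdr = 0.05,
                                germ_max_residual = 0.10) {
  significance_mode <- match.arg(significance_mode)
  if (min_busulfan_fc <= 1)
    stop("'min_busulfan_fc' must be > 1")
  if (max_dtx_residual <= 0 || max_dtx_residual >= 1)
    stop("'max_dtx_residual' must lie in (0, 1)")
  if (germ_max_residual <= 0 || germ_max_residual >= 1)
    stop("'germ_max_residual' must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1 || fdr <= 0 || fdr >= 1)
    stop("'alpha' and 'fdr' must lie in (0, 1)")
  structure(list(min_busulfan_fc = min_busulfan_fc,
                 max_dtx_residual = max_dtx_residual,
                 require_significant_dtx = require_significant_dtx,
                 significance_mode = significance_mode,
                 alpha = alpha, fdr = fdr,
                 germ_max_residual = germ_max_residual),
            class = "stringency_criteria")
}

#' Preset stringency criteria
#'
#' `"relaxed"`: more than 2-fold increase after busulfan and at least a 70%
#' decrease after DTX (residual <= 0.30) — chosen to capture most known
#' Sertoli-cell genes.  `"strict"`: more than 5-fold increase and at least a
#' 90% decrease (residual <= 0.10).  Both use a >90% busulfan reduction for
#' germ-cell calls and alpha = fdr = 0.05.
#'
#' @param preset `"relaxed"` or `"strict"`.
#' @param ... Overrides passed to [stringency_criteria()].
#' @return A `stringency_criteria` list.
#' @export
make_criteria <- function(preset = c("relaxed", "strict"), ...) {
  preset <- match.arg(preset)
  base <- if (preset == "relaxed")
    list(min_busulfan_fc = 2, max_dtx_residual = 0.30)
  else
    list(min_busulfan_fc = 5, max_dtx_residual = 0.10)
  args <- utils::modifyList(base, list(...))
  do.call(stringency_criteria, args)
}

#' Call Sertoli-cell-specific transcripts
#'
#' Applies the stringency criteria to the two ablation contrasts.  The DTX
#' residual fraction is the (busulfan+DTX)/busulfan mean ratio, i.e. the
#' fold change of the DTX contrast.  Transcripts whose busulfan fold change
#' is undefined (control mean zero) cannot show the required increase and
#' stay unclassified.
#'
#' @param bus_contrast `group_contrast` busulfan vs control, q-values
#'   populated.
#' @param dtx_contrast `group_contrast` busulfan+DTX vs busulfan, q-values
#'   populated.
#' @param criteria A `stringency_criteria`.
#' @return A data.frame of specificity calls: `transcript_id`,
#'   `gene_symbol`, `category` (`"sertoli_specific"` or `"unclassified"`),
#'   `busulfan_fc`, `dtx_residual`, `q_bus`, `q_dtx`, and
#'   `significance_evidence` naming the contrasts significant at `fdr`.
#' @export
classify_sertoli_specific <- function(bus_contrast, dtx_contrast, criteria) {
  stopifnot(inherits(criteria, "stringency_criteria"))
  if (all(is.na(bus_contrast$q_value)) && nrow(bus_contrast) > 0)
    stop("q-values must be populated on the busulfan contrast")
  common <- intersect(bus_contrast$transcript_id, dtx_contrast$transcript_id)
  b <- bus_contrast[match(common, bus_contrast$transcript_id), ]
  d <- dtx_contrast[match(common, dtx_contrast$transcript_id), ]
  bus_fc <- b$fold_change
  residual <- d$fold_change             # (bus+DTX)/bus
  sig_bus <- !is.na(b$q_value) & b$q_value <= criteria$fdr
  sig_dtx_down <- !is.na(d$q_value) & d$q_value <= criteria$fdr &
    d$mean_alt < d$mean_ref
  evidence <- ifelse(sig_bus & sig_dtx_down, "busulfan+dtx",
                     ifelse(sig_bus, "busulfan",
                            ifelse(sig_dtx_down, "dtx", "none")))
  support <- if (criteria$significance_mode == "busulfan_or_dtx")
    sig_bus | sig_dtx_down else sig_dtx_down
  ok <- !is.na(bus_fc) & bus_fc > criteria$min_busulfan_fc &
    !is.na(residual) & residual <= criteria$max_dtx_residual &
    support
  if (criteria$require_significant_dtx) ok <- ok & sig_dtx_down
  data.frame(transcript_id = common,
             gene_symbol = b$gene_symbol,
             category = ifelse(ok, "sertoli_specific", "unclassified"),
             busulfan_fc = bus_fc,
             dtx_residual = residual,
             q_bus = b$q_value, q_dtx = d$q_value,
             significance_evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Call germ-cell-specific transcripts
#'
#' A transcript is germ-cell-specific when germ-cell ablation removes more
#' than `1 - germ_max_residual` of its control-level expression (default
#' >90% reduction) with a significant busulfan contrast at `fdr`.
#'
#' @param bus_contrast `group_contrast` busulfan vs control, q-values
#'   populated.
#' @param criteria A `stringency_criteria`.
#' @return A data.frame of calls: `transcript_id`, `gene_symbol`,
#'   `category` (`"germ_specific"` or `"unclassified"`),
#'   `busulfan_residual`, `q_bus`.
#' @export
classify_germ_specific <- function(bus_contrast, criteria) {
  stopifnot(inherits(criteria, "stringency_criteria"))
  if (all(is.na(bus_contrast$q_value)) && nrow(bus_contrast) > 0)
    stop("q-values must be populated on the busulfan contrast")
  residual <- bus_contrast$fold_change  # busulfan/control
  sig <- !is.na(bus_contrast$q_value) &
    bus_contrast$q_value <= criteria$fdr
  ok <- !is.na(residual) & residual < criteria$germ_max_residual & sig
  data.frame(transcript_id = bus_contrast$transcript_id,
             gene_symbol = bus_contrast$gene_symbol,
             category = ifelse(ok, "germ_specific", "unclassified"),
             busulfan_residual = residual,
             q_bus = bus_contrast$q_value,
             stringsAsFactors = FALSE)
}

#' Summarise specificity calls by biotype
#'
#' Counts called transcripts per biotype category; called transcripts with
#' no annotation entry fall into `other`.
#'
#' @param calls A call data.frame from [classify_sertoli_specific()] or
#'   [classify_germ_specific()].
#' @param annotation A biotype annotation data.frame
#'   ([read_biotype_annotation()]).
#' @param category Which call category to count (default: everything that
#'   is not `"unclassified"`).
#' @return Named integer vector over `protein_coding`, `non_coding`,
#'   `pseudogene`, `other`, summing to the number of called transcripts.
#' @export
summarize_biotypes <- function(calls, annotation, category = NULL) {
  called <- if (is.null(category)) calls$category != "unclassified"
  else calls$category == category
  ids <- calls$transcript_id[called]
  bt <- annotation$biotype[match(ids, annotation$transcript_id)]
  bt[is.na(bt) | !(bt %in% BIOTYPES)] <- "other"
  counts <- table(factor(bt, levels = BIOTYPES))
  stats::setNames(as.integer(counts), BIOTYPES)
}
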
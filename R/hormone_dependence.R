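#' Sertoli-cell mRNA enrichment factor for one genotype
#'
#' Knockout genotypes with fewer germ cells carry proportionally more
#' Sertoli-cell mRNA per unit of total testicular mRNA.  The enrichment
#' factor quantifies this as the ratio of Sertoli-cell densities:
#' `(cells_X / volume_X) / (cells_control / volume_control)`.  Dividing raw
#' signal by this factor expresses abundance per Sertoli cell relative to
#' control.
#'
#' @param morphometry Morphometry data.frame ([read_morphometry()]).
#' @param genotype Genotype label to evaluate.
#' @param control Label of the control genotype (default `"control"`).
#' @return A positive scalar; exactly 1 for the control genotype.
#' @export
compute_enrichment_factor <- function(morphometry, genotype,
                                      control = "control") {
  for (g in c(genotype, control)) {
    if (!g %in% morphometry$genotype)
      stop("genotype missing from morphometry table: ", g)
  }
  row_g <- morphometry[morphometry$genotype == genotype, ]
  row_c <- morphometry[morphometry$genotype == control, ]
  if (any(c(row_g$sertoli_cells_per_testis, row_g$testis_volume,
            row_c$sertoli_cells_per_testis, row_c$testis_volume) <= 0))
    stop("morphometry counts and volumes must be strictly positive")
  (row_g$sertoli_cells_per_testis / row_g$testis_volume) /
    (row_c$sertoli_cells_per_testis / row_c$testis_volume)
}

#' Enrichment factors for every genotype in a morphometry table
#' @inheritParams compute_enrichment_factor
#' @return Named numeric vector of factors, one per genotype.
#' @export
enrichment_factors <- function(morphometry, control = "control") {
  stats::setNames(
    vapply(morphometry$genotype, compute_enrichment_factor,
           numeric(1), morphometry = morphometry, control = control),
    morphometry$genotype)
}

#' Normalise expression to Sertoli-cell number
#'
#' Divides every sample by the enrichment factor of its genotype (the
#' sample's group label), undoing the compositional enrichment of
#' Sertoli-cell mRNA so that genotype means are comparable per Sertoli
#' cell.  Control samples (factor 1) are unchanged.
#'
#' @param x An `expr_matrix` whose group labels are genotypes.
#' @param factors Named numeric vector of enrichment factors (names are
#'   genotypes), e.g. from [enrichment_factors()].
#' @return An `expr_matrix` of normalised values.
#' @export
normalize_to_sertoli_number <- function(x, factors) {
  validate_expression_matrix(x)
  grp <- x$samples$group
  unmapped <- setdiff(unique(grp), names(factors))
  if (length(unmapped))
    stop("no enrichment factor for genotype: ",
         paste(unmapped, collapse = ", "))
  out <- x
  out$values <- sweep(x$values, 2, as.numeric(factors[grp]), "/")
  validate_expression_matrix(out)
}

#' The 2x2 knockout factorial design
#'
#' Maps genotype labels to the two binary factors of the factorial: loss of
#' the FSH receptor (`fshr_ko`) and Sertoli-cell-specific loss of the
#' androgen receptor (`ar_ko`).
#'
#' @param genotypes Character vector of the four genotype labels, in the
#'   order control, FSHR knockout, Sertoli-cell AR knockout, double
#'   knockout.
#' @return A data.frame with columns `genotype`, `fshr_ko`, `ar_ko`.
#' @export
factorial_design <- function(genotypes = c("control", "FSHRKO", "SCARKO",
                                           "FSHRKO_SCARKO")) {
  if (length(genotypes) != 4 || anyDuplicated(genotypes))
    stop("the factorial design needs four distinct genotypes")
  data.frame(genotype = genotypes,
             fshr_ko = c(0L, 1L, 0L, 1L),
             ar_ko = c(0L, 0L, 1L, 1L),
             stringsAsFactors = FALSE)
}

#' Per-transcript two-factor ANOVA with interaction
#'
#' Fits, for each transcript, the 2x2 factorial model
#' `value ~ fshr_ko * ar_ko` on normalised abundances and extracts the
#' main-effect and interaction p-values.  Benjamini-Hochberg q-values are
#' computed across transcripts within each effect family (FSHR, AR,
#' interaction).  A significant interaction (`q_interaction <= fdr`) means
#' the double-knockout effect departs from the sum of the single-knockout
#' effects; for those transcripts main-effect p-values are replaced by
#' Tukey honest-significant-difference post-hoc comparisons of the single
#' knockouts against control, and compact letter displays over the four
#' genotype cells are reported.  Otherwise main-effect p-values are taken
#' directly from the ANOVA.
#'
#' The model is fitted on the normalised linear scale by default (the
#' enrichment normalisation acts on signal, not log signal).  Because
#' additivity is scale-dependent, `log2 = TRUE` fits `log2(value)` instead,
#' on which multiplicative hormone effects are additive.
#'
#' @param x An `expr_matrix` of normalised values whose groups are the four
#'   genotypes.
#' @param design A [factorial_design()].
#' @param fdr FDR level for the interaction gate and regulation calls.
#' @param log2 Fit on the log2 scale?  Default `FALSE`.  Requires strictly
#'   positive values.
#' @param alpha Per-comparison level for post-hoc letters (default 0.05).
#' @return A data.frame (one row per transcript, input order): normalised
#'   genotype means (`mean_<genotype>`), `p_fshr`, `p_ar` (post-hoc values
#'   where the interaction is significant, ANOVA values otherwise; the raw
#'   ANOVA main-effect p-values are always kept in `p_fshr_anova`,
#'   `p_ar_anova`), `p_interaction`,
#'   `q_fshr`, `q_ar`, `q_interaction`, `effect_mode` (`"additive"` or
#'   `"interaction"`), `posthoc_letters` (non-empty only when the
#'   interaction is significant), and per-factor regulation calls
#'   `reg_fshr`, `reg_ar` in `{down, up, unchanged}` (direction from the
#'   single-knockout mean vs control; `unchanged` iff the factor's q
#'   exceeds `fdr`).
#' @export
per_transcript_two_factor_anova <- function(x, design = factorial_design(),
                                            fdr = 0.05, log2 = FALSE,
                                            alpha = 0.05) {
  validate_expression_matrix(x)
  grp <- x$samples$group
  missing_cells <- setdiff(design$genotype, unique(grp))
  if (length(missing_cells))
    stop("design cell(s) with no samples: ",
         paste(missing_cells, collapse = ", "))
  if (any(table(grp[grp %in% design$genotype]) < 2))
    stop("every design cell needs >= 2 replicates")
  keep <- grp %in% design$genotype
  vals <- x$values[, keep, drop = FALSE]
  grp <- grp[keep]
  counts <- table(grp)
  if (length(unique(counts)) > 1)
    warning("unbalanced design; factorial sums of squares are ",
            "order-dependent")
  f <- factor(design$fshr_ko[match(grp, design$genotype)])
  a <- factor(design$ar_ko[match(grp, design$genotype)])
  geno <- factor(grp, levels = design$genotype)
  if (log2) {
    if (any(vals <= 0))
      stop("log2 = TRUE requires strictly positive values")
    vals <- base::log2(vals)
  }
  n <- nrow(vals)
  p_f <- p_a <- p_i <- rep(NA_real_, n)
  gm <- matrix(NA_real_, n, 4,
               dimnames = list(rownames(vals),
                               paste0("mean_", design$genotype)))
  n_degenerate <- 0L
  for (i in seq_len(n)) {
    y <- vals[i, ]
    gm[i, ] <- vapply(design$genotype, function(g) mean(y[grp == g]),
                      numeric(1))
    # perfect fits trigger anova()'s unreliable-F warning; those
    # transcripts are detected below and their p-values left undefined
    tab <- suppressWarnings(stats::anova(stats::lm(y ~ f * a)))
    ms_resid <- tab["Residuals", "Mean Sq"]
    # residual variance indistinguishable from zero at double precision
    # (relative to the total variation) makes F meaningless
    ss_tot <- sum(tab[, "Sum Sq"])
    if (!is.finite(ms_resid) || ms_resid <= ss_tot * 1e-12) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    p_f[i] <- tab["f", "Pr(>F)"]
    p_a[i] <- tab["a", "Pr(>F)"]
    p_i[i] <- tab["f:a", "Pr(>F)"]
  }
  if (n_degenerate > 0)
    message(n_degenerate,
            " transcript(s) with zero residual variance; p undefined")
  p_f_anova <- p_f
  p_a_anova <- p_a
  q_i <- adjust_fdr_bh(p_i)
  interacting <- !is.na(q_i) & q_i <= fdr
  letters <- rep("", n)
  # post-hoc pass: Tukey HSD over the four genotype cells
  for (i in which(interacting)) {
    y <- vals[i, ]
    tuk <- stats::TukeyHSD(stats::aov(y ~ geno))$geno
    pmat <- tukey_p_matrix(tuk, design$genotype)
    ctrl <- design$genotype[design$fshr_ko == 0 & design$ar_ko == 0]
    fshr_g <- design$genotype[design$fshr_ko == 1 & design$ar_ko == 0]
    ar_g <- design$genotype[design$fshr_ko == 0 & design$ar_ko == 1]
    p_f[i] <- pmat[ctrl, fshr_g]
    p_a[i] <- pmat[ctrl, ar_g]
    letters[i] <- compact_letters(pmat, alpha = alpha)
  }
  q_f <- adjust_fdr_bh(p_f)
  q_a <- adjust_fdr_bh(p_a)
  ctrl_mean <- gm[, 1]
  direction <- function(q, single_mean) {
    ifelse(is.na(q) | q > fdr, "unchanged",
           ifelse(single_mean < ctrl_mean, "down", "up"))
  }
  out <- data.frame(transcript_id = rownames(vals),
                    gm,
                    p_fshr = p_f, p_ar = p_a, p_interaction = p_i,
                    p_fshr_anova = p_f_anova, p_ar_anova = p_a_anova,
                    q_fshr = q_f, q_ar = q_a, q_interaction = q_i,
                    effect_mode = ifelse(interacting, "interaction",
                                         "additive"),
                    posthoc_letters = letters,
                    reg_fshr = direction(q_f, gm[, 2]),
                    reg_ar = direction(q_a, gm[, 3]),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (log2) gm_note <- "log2" else gm_note <- "linear"
  attr(out, "scale") <- gm_note
  attr(out, "design") <- design
  rownames(out) <- NULL
  out
}

# Symmetric matrix of Tukey pairwise adjusted p-values over genotype cells.
tukey_p_matrix <- function(tuk, genotypes) {
  pmat <- matrix(NA_real_, 4, 4, dimnames = list(genotypes, genotypes))
  diag(pmat) <- 1
  for (nm in rownames(tuk)) {
    pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
    pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- tuk[nm, "p adj"]
  }
  pmat
}

# Compact letter display for <= 4 groups: maximal cliques of the
# "not significantly different" graph, lettered in group order.
compact_letters <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  k <- length(g)
  ns <- pmat > alpha          # TRUE = not significantly different
  subsets <- list()
  for (m in seq_len(2^k) - 1L) {
    members <- which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0)
    if (!length(members)) next
    if (all(ns[members, members])) subsets <- c(subsets, list(members))
  }
  maximal <- Filter(function(s) {
    !any(vapply(subsets, function(t)
      length(t) > length(s) && all(s %in% t), logical(1)))
  }, subsets)
  maximal <- maximal[order(vapply(maximal, min, integer(1)))]
  labs <- character(k)
  for (j in seq_along(maximal))
    for (i in maximal[[j]])
      labs[i] <- paste0(labs[i], letters[j])
  paste(paste0(g, ":", labs), collapse = " ")
}

#' Summarise hormone-dependent regulation
#'
#' Tabulates the per-transcript ANOVA records: how many transcripts are
#' significantly down- or up-regulated by each knockout, how many show
#' additive vs interacting (synergistic or sub-additive) double-knockout
#' effects, and which interaction-significant transcripts collapse by more
#' than `1 - deep_decrease` in the double knockout relative to control.
#'
#' @param records Output of [per_transcript_two_factor_anova()].
#' @param deep_decrease Residual-fraction cutoff for the deep-decrease
#'   list (default 0.10, i.e. >90% decrease).
#' @return A list: `n_tested`, `fshr` and `ar` (each with `down`, `up`,
#'   `unchanged` counts), `additive`, `interaction`, and
#'   `deep_decrease_double_ko` (transcript ids).
#' @export
classify_regulation <- function(records, deep_decrease = 0.10) {
  design <- attr(records, "design")
  if (is.null(design)) design <- factorial_design()
  mean_cols <- paste0("mean_", design$genotype)
  ctrl <- records[[mean_cols[1]]]
  dbl <- records[[mean_cols[4]]]
  if (identical(attr(records, "scale"), "log2")) {
    ratio <- 2^(dbl - ctrl)
  } else {
    ratio <- ifelse(ctrl > 0, dbl / ctrl, NA_real_)
  }
  interacting <- records$effect_mode == "interaction"
  deep <- records$transcript_id[interacting & !is.na(ratio) &
                                  ratio <= deep_decrease]
  count3 <- function(v) {
    c(down = sum(v == "down"), up = sum(v == "up"),
      unchanged = sum(v == "unchanged"))
  }
  list(n_tested = nrow(records),
       fshr = count3(records$reg_fshr),
       ar = count3(records$reg_ar),
       additive = sum(!interacting),
       interaction = sum(interacting),
       deep_decrease_double_ko = deep)
}
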
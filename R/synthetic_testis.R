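#' Cell types of the synthetic testis mixture
#' @export
CELL_TYPES <- c("germ", "sertoli", "leydig", "other_somatic")

#' Generate a ground-truthed synthetic testis transcriptome
#'
#' Builds per-transcript expression profiles over the four testicular
#' compartments (germ cells, Sertoli cells, Leydig cells, other somatic
#' cells) together with per-condition composition fractions and
#' per-transcript knockout effect multipliers.  Bulk data simulated from
#' this truth reproduce the compositional-renormalisation artifact of
#' within-sample-normalised abundances: ablating a compartment inflates
#' the apparent abundance of everything else by `1 / (1 - f_removed)`.
#'
#' Each cell-type profile is scaled to the same per-cell total output
#' (`total`), so mixture samples conserve total abundance exactly and the
#' renormalisation identity holds exactly at zero noise.  The default germ
#' composition fraction is `1 - 1/6.49 ≈ 0.846`, so that germ-cell
#' ablation yields an apparent ~6.5-fold somatic enrichment, the scale
#' observed with marker panels in busulfan-treated testes.
#'
#' Transcript classes: a configured share of transcripts is exclusive to
#' each compartment; the remainder (`"shared"`) is expressed in all four
#' with per-compartment lognormal level multipliers.  An optional
#' confounder class (`"sertoli_dependent"`) is expressed in the
#' other-somatic compartment but collapses to `sertoli_dependence_residual`
#' of its level when the Sertoli cells are ablated — the misclassification
#' risk of ablation-based specificity calling.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param prop_exclusive Named proportions of compartment-exclusive
#'   transcripts (`germ`, `sertoli`, `leydig`, `other_somatic`); together
#'   with `prop_sertoli_dependent` they must sum to <= 1.
#' @param prop_sertoli_dependent Proportion of the confounder class
#'   (default 0).
#' @param f_germ Germ-cell composition fraction of the control testis.
#' @param somatic_split Named split of the somatic fraction over
#'   `sertoli`, `leydig`, `other_somatic` (sums to 1).
#' @param base_meanlog,base_sdlog Lognormal parameters of per-cell
#'   expression levels.
#' @param shared_sdlog Spread of per-compartment level multipliers for
#'   shared transcripts; modest by default so shared transcripts are
#'   broadly expressed rather than compartment-dominated.
#' @param germ_removal,sertoli_removal Ablation completeness in (0, 1]
#'   (default 1: complete removal).
#' @param sertoli_dependence_residual Fraction of expression the
#'   confounder class retains after Sertoli ablation.
#' @param fshr_effect,ar_effect,interaction_multiplier Positive multipliers
#'   (scalar or length `n_transcripts`) applied to Sertoli-cell expression
#'   under FSHR knockout, Sertoli-cell AR knockout, and (beyond the product
#'   of both) the double knockout; 1 = no effect.
#' @param cv Lognormal coefficient of variation of replicate noise
#'   (0 = noiseless).
#' @param total Per-cell total output; also each simulated sample's total
#'   abundance before noise (FPKM-like scaling).
#' @param seed Integer seed; identical seeds give bit-identical truth.
#' @return A `synthetic_truth` list: `expression` (transcripts x cell
#'   types), `class`, `compositions` (per condition), `effects`,
#'   `cv`, `total`, `seed`, `config`.
#' @export
generate_truth <- function(n_transcripts = 1000,
                           prop_exclusive = c(germ = 0.30, sertoli = 0.15,
                                              leydig = 0.10,
                                              other_somatic = 0.10),
                           prop_sertoli_dependent = 0,
                           f_germ = 1 - 1 / 6.49,
                           somatic_split = c(sertoli = 0.50, leydig = 0.25,
                                             other_somatic = 0.25),
                           base_meanlog = log(100), base_sdlog = 1,
                           shared_sdlog = 0.4,
                           germ_removal = 1, sertoli_removal = 1,
                           sertoli_dependence_residual = 0.05,
                           fshr_effect = 1, ar_effect = 1,
                           interaction_multiplier = 1,
                           cv = 0.2, total = 1e6, seed = 1) {
  if (n_transcripts < 1) stop("'n_transcripts' must be >= 1")
  prop_exclusive <- prop_exclusive[CELL_TYPES]
  names(prop_exclusive) <- CELL_TYPES
  prop_exclusive[is.na(prop_exclusive)] <- 0
  if (any(prop_exclusive < 0) || prop_sertoli_dependent < 0 ||
      sum(prop_exclusive) + prop_sertoli_dependent > 1)
    stop("class proportions must be non-negative and sum to <= 1")
  if (f_germ <= 0 || f_germ >= 1) stop("'f_germ' must lie in (0, 1)")
  if (abs(sum(somatic_split) - 1) > 1e-8)
    stop("'somatic_split' must sum to 1")
  set.seed(seed)
  n_class <- floor(n_transcripts *
                     c(prop_exclusive,
                       sertoli_dependent = prop_sertoli_dependent))
  cls <- c(rep(names(n_class), n_class),
           rep("shared", n_transcripts - sum(n_class)))
  ids <- sprintf("tx%05d", seq_len(n_transcripts))
  e <- matrix(0, n_transcripts, length(CELL_TYPES),
              dimnames = list(ids, CELL_TYPES))
  base <- stats::rlnorm(n_transcripts, base_meanlog, base_sdlog)
  for (ct in CELL_TYPES)
    e[cls == ct, ct] <- base[cls == ct]
  e[cls == "sertoli_dependent", "other_somatic"] <-
    base[cls == "sertoli_dependent"]
  shared <- cls == "shared"
  if (any(shared)) {
    mult <- matrix(stats::rlnorm(sum(shared) * length(CELL_TYPES),
                                 0, shared_sdlog),
                   sum(shared), length(CELL_TYPES))
    e[shared, ] <- base[shared] * mult
  }
  # equal per-cell total output across compartments: mixtures conserve
  # total abundance and the renormalisation identity is exact
  for (ct in CELL_TYPES) {
    s <- sum(e[, ct])
    if (s > 0) e[, ct] <- e[, ct] / s * total
  }
  f_ctrl <- c(germ = f_germ, (1 - f_germ) * somatic_split)[CELL_TYPES]
  ablate <- function(f, remove) {
    f <- f * remove
    f / sum(f)
  }
  comps <- list(
    control = f_ctrl,
    busulfan = ablate(f_ctrl, c(1 - germ_removal, 1, 1, 1)),
    busulfan_dtx = ablate(f_ctrl, c(1 - germ_removal, 1 - sertoli_removal,
                                    1, 1)))
  rep_len_n <- function(v) rep_len(v, n_transcripts)
  effects <- data.frame(fshr_effect = rep_len_n(fshr_effect),
                        ar_effect = rep_len_n(ar_effect),
                        interaction_multiplier =
                          rep_len_n(interaction_multiplier))
  if (any(unlist(effects) <= 0))
    stop("knockout effect multipliers must be > 0")
  structure(list(expression = e, class = cls, compositions = comps,
                 effects = effects, cv = cv, total = total, seed = seed,
                 config = list(
                   prop_exclusive = prop_exclusive,
                   prop_sertoli_dependent = prop_sertoli_dependent,
                   f_germ = f_germ, somatic_split = somatic_split,
                   germ_removal = germ_removal,
                   sertoli_removal = sertoli_removal,
                   sertoli_dependence_residual =
                     sertoli_dependence_residual)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d transcripts (seed %d, cv %.2f)\n",
              nrow(x$expression), x$seed, x$cv))
  print(table(x$class))
  invisible(x)
}

# multiplicative lognormal noise with unit mean at the given CV
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate the sequential-ablation study
#'
#' Draws replicate bulk expression for the three conditions of the
#' ablation design: control, busulfan (germ cells removed) and
#' busulfan+DTX (germ and Sertoli cells removed).  The expected abundance
#' of transcript `t` in condition `k` is the composition-weighted mixture
#' `sum_c f_c(k) * e[t, c]`; replicate values add multiplicative lognormal
#' noise at the truth's CV.  Because compositions are renormalised after
#' ablation, purely somatic transcripts show an apparent
#' `1 / (1 - f_germ)`-fold increase after busulfan at zero noise.
#'
#' @param truth A [generate_truth()] object.
#' @param n_replicates Replicates per condition.
#' @param seed Integer seed for the replicate noise.
#' @return An `expr_matrix` with groups `control`, `busulfan`,
#'   `busulfan_dtx` (gene symbols mirror transcript ids).
#' @export
simulate_ablation_study <- function(truth, n_replicates = 5, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  conds <- names(truth$compositions)
  expected <- sapply(truth$compositions, function(f)
    as.numeric(truth$expression %*% f))
  # confounder class: loses expression when the Sertoli cells go,
  # although it lives in the other-somatic compartment
  dep <- truth$class == "sertoli_dependent"
  if (any(dep))
    expected[dep, "busulfan_dtx"] <- expected[dep, "busulfan_dtx"] *
      truth$config$sertoli_dependence_residual
  n_t <- nrow(truth$expression)
  vals <- matrix(NA_real_, n_t, length(conds) * n_replicates,
                 dimnames = list(rownames(truth$expression), NULL))
  groups <- rep(conds, each = n_replicates)
  for (j in seq_len(ncol(vals)))
    vals[, j] <- expected[, groups[j]] * lognormal_noise(n_t, truth$cv)
  colnames(vals) <- paste0(groups, "_", rep(seq_len(n_replicates),
                                            times = length(conds)))
  expression_matrix(vals, groups = groups,
                    gene_symbol = rownames(truth$expression))
}

#' Somatic marker panel from a synthetic truth
#'
#' Picks compartment-exclusive somatic transcripts (Sertoli, Leydig, other
#' somatic) as a known-marker panel for enrichment estimation, spread
#' evenly across the available markers.
#'
#' @param truth A `synthetic_truth`.
#' @param n Panel size (default 25).
#' @return Character vector of transcript ids (= gene symbols).
#' @export
somatic_marker_panel <- function(truth, n = 25) {
  pool <- rownames(truth$expression)[
    truth$class %in% c("sertoli", "leydig", "other_somatic")]
  if (length(pool) < n)
    stop("only ", length(pool), " somatic-exclusive transcripts available")
  pool[round(seq(1, length(pool), length.out = n))]
}

#' Synthetic morphometry preset for the knockout genotypes
#'
#' A synthetic per-genotype table of Sertoli cells per testis (millions)
#' and testis volume (mm^3), constructed so that the knockout genotypes
#' show the expected pattern: reduced Sertoli number under FSHR knockout,
#' normal Sertoli number but smaller testes under Sertoli-cell AR
#' knockout, and both in the double knockout.  The implied enrichment
#' factors are 1, 1.4, 1.67 and 2.8.
#'
#' @return A morphometry data.frame.
#' @export
default_morphometry <- function() {
  data.frame(genotype = c("control", "FSHRKO", "SCARKO", "FSHRKO_SCARKO"),
             sertoli_cells_per_testis = c(4.0, 2.8, 4.0, 2.8),
             testis_volume = c(100, 50, 60, 25),
             stringsAsFactors = FALSE)
}

#' Simulate the 2x2 knockout array study
#'
#' Draws replicate bulk expression for the four genotypes of the factorial
#' design.  The Sertoli-cell component of transcript `t` is multiplied by
#' `fshr_effect` in the FSHR knockout, `ar_effect` in the AR knockout, and
#' `fshr_effect * ar_effect * interaction_multiplier` in the double
#' knockout; all other compartments keep their control levels.  The whole
#' Sertoli component is additionally scaled by the genotype's morphometric
#' enrichment factor, so the raw data exhibit the compositional enrichment
#' artifact that [normalize_to_sertoli_number()] must undo.
#'
#' @param truth A `synthetic_truth`.
#' @param morphometry Per-genotype morphometry (default
#'   [default_morphometry()]); all four genotypes of `design` must be
#'   present.
#' @param design A [factorial_design()].
#' @param n_replicates Replicates per genotype (default 4).
#' @param seed Integer seed for the replicate noise.
#' @return An `expr_matrix` whose groups are the four genotypes.
#' @export
simulate_knockout_study <- function(truth, morphometry = default_morphometry(),
                                    design = factorial_design(),
                                    n_replicates = 4, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  missing_g <- setdiff(design$genotype, morphometry$genotype)
  if (length(missing_g))
    stop("genotype missing from morphometry: ",
         paste(missing_g, collapse = ", "))
  set.seed(seed)
  ef <- enrichment_factors(morphometry, control = design$genotype[1])
  f <- truth$compositions$control
  e <- truth$expression
  non_sertoli <- as.numeric(e[, setdiff(CELL_TYPES, "sertoli"),
                              drop = FALSE] %*%
                              f[setdiff(CELL_TYPES, "sertoli")])
  n_t <- nrow(e)
  expected <- sapply(design$genotype, function(g) {
    i <- match(g, design$genotype)
    mult <- truth$effects$fshr_effect^design$fshr_ko[i] *
      truth$effects$ar_effect^design$ar_ko[i] *
      truth$effects$interaction_multiplier^(design$fshr_ko[i] *
                                              design$ar_ko[i])
    ef[[g]] * f[["sertoli"]] * mult * e[, "sertoli"] + non_sertoli
  })
  groups <- rep(design$genotype, each = n_replicates)
  vals <- matrix(NA_real_, n_t, length(groups),
                 dimnames = list(rownames(e), NULL))
  for (j in seq_along(groups))
    vals[, j] <- expected[, groups[j]] * lognormal_noise(n_t, truth$cv)
  colnames(vals) <- paste0(groups, "_",
                           rep(seq_len(n_replicates), times = 4))
  expression_matrix(vals, groups = groups,
                    gene_symbol = rownames(e))
}

#' Score calls against the synthetic truth
#'
#' Exhaustive confusion counts of a call set against the generator's
#' ground truth: true positives are transcripts of the matching exclusive
#' class (`sertoli` for `sertoli_specific` calls, `germ` for
#' `germ_specific`).
#'
#' @param calls A call data.frame with `transcript_id` and `category`.
#' @param truth A `synthetic_truth` over the same transcript universe.
#' @param positive `"sertoli_specific"` or `"germ_specific"`.
#' @return A list with `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_calls <- function(calls, truth,
                           positive = c("sertoli_specific",
                                        "germ_specific")) {
  positive <- match.arg(positive)
  ids <- rownames(truth$expression)
  if (!setequal(calls$transcript_id, ids))
    stop("calls and truth do not share a transcript universe")
  truth_class <- if (positive == "sertoli_specific") "sertoli" else "germ"
  is_pos <- truth$class[match(calls$transcript_id, ids)] == truth_class
  called <- calls$category == positive
  tp <- sum(called & is_pos); fp <- sum(called & !is_pos)
  fn <- sum(!called & is_pos); tn <- sum(!called & !is_pos)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}
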
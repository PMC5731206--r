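# Independent reference oracles, computed from first-principles definitions
# (never by calling the implementation path they check).

# Benjamini-Hochberg step-up definition: q_i = min_{j >= rank(i)} p_(j)*m/j,
# capped at 1, mapped back to input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Welch two-sample t-test, two-sided, by the textbook formula
# (statistic + Welch-Satterthwaite degrees of freedom).
welch_t_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 /
    (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Balanced 2x2 factorial ANOVA by hand-computed sums of squares.
# f, a: 0/1 factor codings; returns F and p for (f, a, f:a).
anova2x2_oracle <- function(y, f, a) {
  cells <- paste(f, a)
  gm <- mean(y)
  cell_mean <- stats::ave(y, cells)
  mf <- tapply(y, f, mean)
  ma <- tapply(y, a, mean)
  nf <- table(f)
  na_ <- table(a)
  ss_f <- sum(nf * (mf - gm)^2)
  ss_a <- sum(na_ * (ma - gm)^2)
  ss_cells <- sum((cell_mean - gm)^2)
  ss_i <- ss_cells - ss_f - ss_a
  ss_e <- sum((y - cell_mean)^2)
  dfe <- length(y) - 4
  fstat <- c(ss_f, ss_a, ss_i) / (ss_e / dfe)
  list(F = fstat, p = stats::pf(fstat, 1, dfe, lower.tail = FALSE))
}

# Exhaustive row-by-row filter applying the Sertoli stringency conditions
# with scalar logic; returns the ids called sertoli_specific.
brute_force_sertoli <- function(bus, dtx, cr) {
  ids <- intersect(bus$transcript_id, dtx$transcript_id)
  out <- character(0)
  for (id in ids) {
    b <- bus[bus$transcript_id == id, ]
    d <- dtx[dtx$transcript_id == id, ]
    fc <- if (b$mean_ref > 0) b$mean_alt / b$mean_ref else NA_real_
    res <- if (d$mean_ref > 0) d$mean_alt / d$mean_ref else NA_real_
    sig_b <- !is.na(b$q_value) && b$q_value <= cr$fdr
    sig_d <- !is.na(d$q_value) && d$q_value <= cr$fdr &&
      d$mean_alt < d$mean_ref
    support <- if (cr$significance_mode == "busulfan_or_dtx")
      sig_b || sig_d else sig_d
    ok <- !is.na(fc) && fc > cr$min_busulfan_fc &&
      !is.na(res) && res <= cr$max_dtx_residual && support
    if (cr$require_significant_dtx) ok <- ok && sig_d
    if (isTRUE(ok)) out <- c(out, id)
  }
  out
}

# Same, for the germ-cell criterion (significant > (1 - germ_max_residual)
# reduction after busulfan).
brute_force_germ <- function(bus, cr) {
  out <- character(0)
  for (i in seq_len(nrow(bus))) {
    b <- bus[i, ]
    res <- if (b$mean_ref > 0) b$mean_alt / b$mean_ref else NA_real_
    sig <- !is.na(b$q_value) && b$q_value <= cr$fdr
    if (!is.na(res) && res < cr$germ_max_residual && sig)
      out <- c(out, b$transcript_id)
  }
  out
}
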
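test_that("enrichment factors follow the density-ratio formula", {
  morph <- data.frame(
    genotype = c("control", "same", "halved_quartered"),
    sertoli_cells_per_testis = c(4, 4, 2),
    testis_volume = c(100, 100, 25))
  expect_equal(compute_enrichment_factor(morph, "control"), 1)
  expect_equal(compute_enrichment_factor(morph, "same"), 1)
  # Sertoli count halved, volume quartered: density doubles
  expect_equal(compute_enrichment_factor(morph, "halved_quartered"), 2)
  expect_error(compute_enrichment_factor(morph, "absent"), "missing")

  # random morphometry against the direct arithmetic oracle
  set.seed(101)
  m <- data.frame(genotype = c("control", "x"),
                  sertoli_cells_per_testis = runif(2, 1, 10),
                  testis_volume = runif(2, 10, 100))
  oracle <- (m$sertoli_cells_per_testis[2] / m$testis_volume[2]) /
    (m$sertoli_cells_per_testis[1] / m$testis_volume[1])
  expect_equal(compute_enrichment_factor(m, "x"), oracle,
               tolerance = 1e-12)
})

test_that("Sertoli-number normalisation divides by the genotype factor", {
  tr <- generate_truth(n_transcripts = 50, cv = 0.1, seed = 111)
  km <- simulate_knockout_study(tr, n_replicates = 3, seed = 112)
  ef <- enrichment_factors(default_morphometry())
  norm <- normalize_to_sertoli_number(km, ef)
  expect_equal(norm$values[, km$samples$group == "control"],
               km$values[, km$samples$group == "control"])
  sel <- km$samples$group == "FSHRKO"
  expect_equal(norm$values[, sel], km$values[, sel] / ef[["FSHRKO"]])
  expect_error(normalize_to_sertoli_number(km, ef[-2]), "FSHRKO")

  # all-ones factors leave everything unchanged
  ones <- setNames(rep(1, 4), names(ef))
  expect_identical(normalize_to_sertoli_number(km, ones)$values, km$values)
})

test_that("normalisation recovers per-cell expression across genotypes", {
  # a Sertoli-exclusive transcript with constant per-cell expression but
  # genotype-specific Sertoli density: normalised means must coincide
  tr <- generate_truth(n_transcripts = 40,
                       prop_exclusive = c(germ = 0, sertoli = 1,
                                          leydig = 0, other_somatic = 0),
                       cv = 0, seed = 121)
  km <- simulate_knockout_study(tr, n_replicates = 2, seed = 122)
  ef <- enrichment_factors(default_morphometry())
  norm <- normalize_to_sertoli_number(km, ef)
  for (g in c("FSHRKO", "SCARKO", "FSHRKO_SCARKO")) {
    expect_equal(rowMeans(norm$values[, norm$samples$group == g]),
                 rowMeans(norm$values[, norm$samples$group == "control"]),
                 tolerance = 1e-10)
  }
})

test_that("the factorial ANOVA matches the closed-form oracle", {
  set.seed(131)
  design <- factorial_design()
  for (i in 1:100) {
    n_rep <- sample(3:5, 1)
    groups <- rep(design$genotype, each = n_rep)
    y <- rlnorm(length(groups), 3, 0.4)
    vals <- matrix(y, 1, dimnames = list("t", NULL))
    x <- expression_matrix(vals, groups = groups)
    rec <- per_transcript_two_factor_anova(x, design, fdr = 0.05)
    f <- design$fshr_ko[match(groups, design$genotype)]
    a <- design$ar_ko[match(groups, design$genotype)]
    oracle <- anova2x2_oracle(y, f, a)
    expect_equal(c(rec$p_fshr_anova, rec$p_ar_anova, rec$p_interaction),
                 oracle$p, tolerance = 1e-8)
  }
})

test_that("degenerate inputs are handled explicitly", {
  design <- factorial_design()
  groups <- rep(design$genotype, each = 4)
  # equal cell means with nonzero within-cell spread: F = 0, p = 1
  y_flat <- rep(c(-1.5, -0.5, 0.5, 1.5) + 10, times = 4)
  x <- expression_matrix(matrix(y_flat, 1, dimnames = list("t", NULL)),
                         groups = groups)
  rec <- per_transcript_two_factor_anova(x, design)
  expect_equal(c(rec$p_fshr, rec$p_ar, rec$p_interaction), rep(1, 3))

  # zero residual variance: p undefined and reported
  x0 <- expression_matrix(
    matrix(rep(c(8, 4, 6, 2), each = 4), 1, dimnames = list("t", NULL)),
    groups = groups)
  expect_message(rec0 <- per_transcript_two_factor_anova(x0, design),
                 "zero residual variance")
  expect_true(is.na(rec0$p_interaction))

  # purely additive effects on the log scale leave no interaction signal
  mu <- log2(c(control = 8, FSHRKO = 4, SCARKO = 4, FSHRKO_SCARKO = 2))
  y_add <- 2^(mu[groups] + rep(c(-0.2, -0.1, 0.1, 0.2), times = 4))
  xa <- expression_matrix(matrix(y_add, 1, dimnames = list("t", NULL)),
                          groups = groups)
  ra <- per_transcript_two_factor_anova(xa, design, log2 = TRUE)
  expect_equal(ra$p_interaction, 1)

  # missing design cell is a hard error
  xm <- expression_matrix(
    matrix(rnorm(12, 10), 1, dimnames = list("t", NULL)),
    groups = rep(c("control", "FSHRKO", "SCARKO"), each = 4))
  expect_error(per_transcript_two_factor_anova(xm, design),
               "FSHRKO_SCARKO")
})

test_that("interaction gates Tukey post-hoc letters and p-values", {
  set.seed(141)
  design <- factorial_design()
  groups <- rep(design$genotype, each = 4)
  mu <- c(control = 10, FSHRKO = 7, SCARKO = 7, FSHRKO_SCARKO = 0.5)
  y <- mu[groups] * rlnorm(16, 0, 0.05)
  vals <- rbind(inter = y, flat = rlnorm(16, 2, 0.05))
  x <- expression_matrix(vals, groups = groups)
  rec <- per_transcript_two_factor_anova(x, design, fdr = 0.05)
  inter <- rec[rec$transcript_id == "inter", ]
  flat <- rec[rec$transcript_id == "flat", ]
  expect_equal(inter$effect_mode, "interaction")
  expect_match(inter$posthoc_letters, "FSHRKO_SCARKO:")
  expect_equal(flat$posthoc_letters, "")
  # post-hoc main-effect p equals the Tukey control-vs-single-KO p
  f_fac <- factor(groups, levels = design$genotype)
  tuk <- TukeyHSD(aov(y ~ f_fac))$f_fac
  expect_equal(inter$p_fshr, tuk["FSHRKO-control", "p adj"],
               tolerance = 1e-10)
  expect_equal(inter$p_ar, tuk["SCARKO-control", "p adj"],
               tolerance = 1e-10)
})

test_that("regulation direction matches the sign of the mean difference", {
  set.seed(151)
  n <- 60
  fe <- sample(c(0.4, 1, 2.5), n, replace = TRUE)
  ae <- sample(c(0.4, 1, 2.5), n, replace = TRUE)
  tr <- generate_truth(n_transcripts = n,
                       prop_exclusive = c(germ = 0, sertoli = 1,
                                          leydig = 0, other_somatic = 0),
                       fshr_effect = fe, ar_effect = ae,
                       interaction_multiplier = 1, cv = 0.15, seed = 152)
  km <- simulate_knockout_study(tr, n_replicates = 4, seed = 153)
  norm <- normalize_to_sertoli_number(km,
                                      enrichment_factors(default_morphometry()))
  rec <- per_transcript_two_factor_anova(norm, fdr = 0.05, log2 = TRUE)
  sig <- rec$reg_fshr != "unchanged"
  expect_true(all((rec$mean_FSHRKO < rec$mean_control)[sig] ==
                    (rec$reg_fshr == "down")[sig]))
  expect_true(all(rec$reg_fshr[is.na(rec$q_fshr) |
                                 rec$q_fshr > 0.05] == "unchanged"))

  summ <- classify_regulation(rec)
  expect_equal(summ$n_tested, n)
  expect_equal(unname(summ$fshr["down"]),
               sum(rec$reg_fshr == "down"))
  expect_equal(summ$additive + summ$interaction, n)
  # additive by definition when the interaction q exceeds the FDR
  expect_true(all(rec$effect_mode[rec$q_interaction > 0.05] == "additive"))
})

test_that("deep double-knockout decreases are listed among interactions", {
  set.seed(161)
  n <- 30
  inter_mult <- c(rep(0.1, 10), rep(1, 20))   # deep synergistic collapse
  tr <- generate_truth(n_transcripts = n,
                       prop_exclusive = c(germ = 0, sertoli = 1,
                                          leydig = 0, other_somatic = 0),
                       fshr_effect = 0.6, ar_effect = 0.6,
                       interaction_multiplier = inter_mult,
                       cv = 0.1, seed = 162)
  km <- simulate_knockout_study(tr, n_replicates = 4, seed = 163)
  norm <- normalize_to_sertoli_number(km,
                                      enrichment_factors(default_morphometry()))
  rec <- per_transcript_two_factor_anova(norm, fdr = 0.05, log2 = TRUE)
  summ <- classify_regulation(rec, deep_decrease = 0.10)
  deep_true <- rec$transcript_id[1:10]
  # double-KO mean is 0.6 * 0.6 * 0.1 = 3.6% of control: deep decrease
  expect_true(all(summ$deep_decrease_double_ko %in% deep_true))
  expect_gte(length(summ$deep_decrease_double_ko), 8)
})
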
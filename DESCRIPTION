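Package: testismix
Title: Cell-Type-Specific Transcript Calling and Hormone Dependence in
    Testis Ablation Studies
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies cell-type-specific transcripts in bulk testis
    expression data from sequential cell-ablation designs (germ-cell
    ablation by busulfan, Sertoli-cell ablation by diphtheria toxin in a
    germ-free background), applying fold-change stringency criteria with
    Benjamini-Hochberg false-discovery-rate control.  Downstream, array
    data from factorial hormone-receptor knockouts (FSHR and
    Sertoli-cell androgen receptor) are normalised to Sertoli-cell
    density and analysed per transcript by two-factor ANOVA with
    interaction and Tukey post-hoc testing to classify FSH- and
    androgen-dependent regulation.  A ground-truthed synthetic
    testis-mixture generator emulates the compositional-renormalisation
    enrichment artifact of within-sample-normalised abundances, so that
    every pipeline stage can be benchmarked against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
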
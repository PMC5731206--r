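# Small programmatic fixtures shared across test files.

# A tiny 3-transcript, 2-group expression TSV (+ sidecar design) on disk;
# returns the two paths.
write_tiny_expression_fixture <- function(
    dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tab <- data.frame(transcript_id = c("Amh", "Sox9", "Ddx4"),
                    gene_symbol = c("Amh", "Sox9", "Ddx4"),
                    c1 = c(10, 5, 100), c2 = c(12, 6, 110),
                    t1 = c(60, 30, 1), t2 = c(66, 33, 2),
                    check.names = FALSE)
  path <- file.path(dir, "expr.tsv")
  design_path <- file.path(dir, "design.tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = c("c1", "c2", "t1", "t2"),
               group = c("control", "control", "treated", "treated"),
               replicate = c(1L, 2L, 1L, 2L)),
    design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(expr = path, design = design_path)
}

# An expr_matrix built directly from a matrix of group means with a given
# number of identical replicates per group (noise-free).
matrix_from_means <- function(means, n_rep = 3) {
  groups <- rep(colnames(means), each = n_rep)
  vals <- means[, groups, drop = FALSE]
  colnames(vals) <- paste0(groups, "_", rep(seq_len(n_rep),
                                            times = ncol(means)))
  expression_matrix(vals, groups = groups,
                    gene_symbol = rownames(means))
}

# A contrast table fabricated from explicit fields (q defaults to p).
fake_contrast <- function(id, mean_ref, mean_alt, q = NULL, p = NULL,
                          symbol = id) {
  if (is.null(p)) p <- rep(0.001, length(id))
  if (is.null(q)) q <- p
  testismix:::new_group_contrast(id, symbol, mean_ref, mean_alt, p, q,
                                 "ref", "alt")
}
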
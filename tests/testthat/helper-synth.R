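# Small generator configurations shared across tests.

two_pop_config <- function(seed = 1L, n_cells = 150, n_genes = 600,
                           fold = 3, doublet_rate = 0, n_samples = 1L,
                           props = c(0.5, 0.5)) {
  pops <- list(
    population_spec("A", marker_log_fold = fold, n_private_markers = 15,
                    proportion_by_region = c(CN = props[1], Pu = props[1]),
                    block = 1L),
    population_spec("B", marker_log_fold = fold, n_private_markers = 15,
                    proportion_by_region = c(CN = props[2], Pu = props[2]),
                    block = 2L))
  samples <- data.frame(sample_id = sprintf("T%02d", seq_len(n_samples)),
                        region = rep(c("CN", "Pu"),
                                     length.out = n_samples),
                        n_cells = n_cells, stringsAsFactors = FALSE)
  generator_config(n_genes = n_genes, populations = pops, samples = samples,
                   mean_library_size = 8000, doublet_rate = doublet_rate,
                   seed = seed)
}

# hand-built normalized matrix for tests that need exact profiles
fake_norm <- function(mat, gene_names = colnames(mat),
                      cell_ids = rownames(mat), meta = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("c%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("g%03d", seq_len(ncol(mat)))
  if (is.null(meta))
    meta <- data.frame(sample_id = rep("s1", nrow(mat)),
                       region = rep("CN", nrow(mat)),
                       row.names = rownames(mat))
  structure(list(mat = Matrix::Matrix(mat, sparse = TRUE),
                 target_sum = 1e4,
                 gene_flags = gene_category_flags(colnames(mat)),
                 cell_meta = meta),
            class = "norm_matrix")
}
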
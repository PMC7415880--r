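# Shared fixtures, built in code at test time.

# tiny CITE-seq-like dataset, cached per session
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_citeseq(sim_spec(n_cells = 120L, n_genes = 20L,
                                          n_proteins = 3L, n_types = 3L,
                                          marker_pairs = 3L, seed = 42L))
    cache
  }
})

# a small trained model (few epochs, tiny network) shared across tests
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- tiny_sim()
      plab <- probabilize_proteins(sim$proteins)
      net <- network_config(n_hidden_layers = 1L, n_hidden_units = 32L,
                            n_latent = 6L)
      m <- scvae_model(ncol(sim$counts$values), n_proteins = 3L,
                       network = net, seed = 5L)
      cache <<- fit_scvae(m, sim$counts, labels = plab,
                          training = training_config(gamma = 20,
                                                     max_epochs = 200,
                                                     batch_size = 32,
                                                     patience = Inf,
                                                     seed = 5L))
    }
    cache
  }
})

# write a 3 x 2 (cells x genes) Matrix Market fixture in the genes-as-rows
# on-disk dialect; returns the directory and the expected dense matrix
write_toy_mtx <- function(dir, genes_as_rows = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dense <- matrix(c(1L, 0L, 3L, 0L, 5L, 2L), nrow = 3,
                  dimnames = list(c("bc1", "bc2", "bc3"), c("gA", "gB")))
  m <- Matrix::Matrix(if (genes_as_rows) t(dense) else dense, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(dense), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(dense), file.path(dir, "features.tsv"))
  dense
}
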
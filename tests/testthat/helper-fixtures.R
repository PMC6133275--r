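# Small in-code fixtures shared across the suite.

# stack from a list of value matrices (full mask unless given)
make_stack <- function(mats, mask = NULL, names = NULL) {
  g <- vs_grid(nrow(mats[[1]]), ncol(mats[[1]]))
  if (is.null(mask)) mask <- matrix(TRUE, g$nrows, g$ncols)
  vs_stack(lapply(mats, function(m) vs_layer(g, m, mask)), names = names)
}

# layer from a value matrix
make_layer <- function(m, mask = NULL) {
  g <- vs_grid(nrow(m), ncol(m))
  if (is.null(mask)) mask <- matrix(TRUE, g$nrows, g$ncols)
  vs_layer(g, m, mask)
}

# occupancy map from a logical matrix
make_occupancy <- function(occ, mask = NULL, species_id = "sp") {
  g <- vs_grid(nrow(occ), ncol(occ))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(occ), ncol(occ))
  structure(list(grid = g, mask = mask, occupied = occ & mask,
                 species_id = species_id, seed_cell = which(occ)[1],
                 realization_seed = 0L, n_iterations_run = 0L,
                 warning = FALSE),
            class = "vs_occupancy")
}

# a small correlated synthetic stack used by several files
small_env <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- env_gen_spec(4L, vs_grid(40, 40),
                           target_corr = {
                             C <- matrix(0.5, 4, 4); diag(C) <- 1; C
                           },
                           spatial_range = 5, mask_style = "rectangle",
                           seed = 7L)
      cache <<- generate_synthetic_env(spec)
    }
    cache
  }
})

# vs_pca object with a prescribed eigenvalue spectrum (for axis-selection
# semantics; loadings are irrelevant there)
fake_pca <- function(eigenvalues) {
  V <- length(eigenvalues)
  structure(
    list(means = rep(0, V), sds = rep(1, V),
         eigenvalues = eigenvalues,
         eigenvectors = diag(V),
         proportion = eigenvalues / sum(eigenvalues),
         cumulative = cumsum(eigenvalues) / sum(eigenvalues),
         layer_names = paste0("b", seq_len(V)),
         n_cells = 100L),
    class = "vs_pca")
}
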
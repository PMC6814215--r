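# Shared fixtures, built in code at test time.

make_grid <- function(nr = 4, nc = 5, mask = NULL, weights = NULL) {
  grid_spec(nr, nc, valid_mask = mask, cell_area_weights = weights)
}

# layer from a vector filled column-major over the full grid
make_layer <- function(values, grid = NULL, name = "x", units = "") {
  if (is.null(grid)) {
    grid <- make_grid(nrow(as.matrix(values)), ncol(as.matrix(values)))
  }
  raster_layer(grid, matrix(values, grid$n_rows, grid$n_cols), name, units)
}

# constant fuzzy layer (defaults to a single cell)
make_fz <- function(value, grid = make_grid(1, 1), name = "f") {
  fuzzy_layer(grid, matrix(value, grid$n_rows, grid$n_cols), name)
}

rand_fuzzy <- function(grid, name = "f") {
  fuzzy_layer(grid, matrix(runif(grid$n_rows * grid$n_cols),
                           grid$n_rows, grid$n_cols), name)
}

rand_stack <- function(grid, n_members, name = "s") {
  vals <- array(runif(n_members * grid$n_rows * grid$n_cols),
                c(n_members, grid$n_rows, grid$n_cols))
  ensemble_stack(grid, sprintf("m%02d", seq_len(n_members)), vals, name,
                 units = "fuzzy truth")
}

# one small bundle shared across test files (generated once per test run)
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_bundle(
        synthetic_config(n_rows = 30, n_cols = 30, n_members = 5, seed = 11))
    }
    cache
  }
})

default_tree_path <- function() {
  system.file("extdata", "biomass_loss_risk_tree.json", package = "fuzzyrisk")
}
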
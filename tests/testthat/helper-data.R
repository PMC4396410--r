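# shared small dataset: gridded cells with a known log-linear richness link
make_model_data <- function(n_cells = 200, beta = 0.6, seed = 1) {
  set.seed(seed)
  nr <- ceiling(sqrt(n_cells))
  d <- tidyr::expand_grid(row = 1:nr, col = 1:nr)[1:n_cells, ] |>
    dplyr::mutate(
      cell_id = sprintf("r%d_c%d", row, col),
      centroid_x = col, centroid_y = row,
      env1 = rnorm(n_cells), env2 = rnorm(n_cells), env3 = rnorm(n_cells),
      richness = rpois(n_cells, exp(1.5 + beta * env1)) + 1L,
      pd = pmin(1, 0.05 + 0.1 * richness + rnorm(n_cells, 0, 0.02)),
      y_gauss = 2 + env1 + rnorm(n_cells)
    )
  d
}
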
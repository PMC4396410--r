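test_that("simulate_tree builds reproducible pure-birth trees", {
  expect_error(simulate_tree(1), "n_taxa")

  t2 <- simulate_tree(2, seed = 4)
  expect_s3_class(t2, "phylo")
  expect_length(t2$tip.label, 2)
  expect_equal(nrow(t2$edge), 2)
  expect_equal(t2$Nnode, 1)

  a <- ape::write.tree(simulate_tree(89, seed = 11))
  b <- ape::write.tree(simulate_tree(89, seed = 11))
  expect_identical(a, b)

  t89 <- simulate_tree(89, seed = 11)
  expect_length(t89$tip.label, 89)
  expect_gt(sum(t89$edge.length), 0)
  expect_true(all(t89$edge.length > 0))
  expect_identical(t89$tip.label, paste0("t", 1:89))
})

test_that("simulate_environment produces gradient-plus-noise surfaces", {
  cfg <- sim_config(
    n_taxa = 10, grid_dims = c(4, 6),
    env_fields = list(
      list(name = "e1", gradient_direction = 0, noise_sd = 0),
      list(name = "e2", gradient_direction = pi / 2, noise_sd = 0.1)
    ),
    seed = 5
  )
  env <- simulate_environment(cfg)
  expect_equal(nrow(env), 24)
  expect_true(all(c("e1", "e2") %in% names(env)))

  # zero-noise gradient along +x is strictly monotone in column index
  by_col <- env |> dplyr::distinct(.data$col, .data$e1) |>
    dplyr::arrange(.data$col)
  expect_true(all(diff(by_col$e1) > 0))

  expect_identical(simulate_environment(cfg), simulate_environment(cfg))
})

test_that("neutral occurrences show no env trend when the effect is off", {
  cfg <- sim_config(n_taxa = 40, grid_dims = c(20, 25), richness_effect = 0,
                    seed = 21)
  tree <- simulate_tree(40, seed = 21)
  env <- simulate_environment(cfg)
  occ <- simulate_occurrences(tree, env, cfg)
  mat <- build_matrix(occ, grid_spec(cfg$cell_size, 0, 0))
  r <- richness(mat)
  env1 <- env$precipitation[match(names(r), env$cell_id)]
  rho <- suppressWarnings(cor(r, env1, method = "spearman"))
  expect_lt(abs(rho), 0.12)
})

test_that("assembly_strength = 0 collapses every mode to neutral", {
  base <- list(n_taxa = 15, grid_dims = c(4, 5), assembly_strength = 0,
               seed = 33)
  occs <- lapply(c("neutral", "clustered", "overdispersed"), function(m) {
    cfg <- do.call(sim_config, c(base, list(assembly_mode = m)))
    tree <- simulate_tree(15, seed = 33)
    simulate_occurrences(tree, simulate_environment(cfg), cfg)
  })
  expect_identical(occs[[1]], occs[[2]])
  expect_identical(occs[[1]], occs[[3]])
})

test_that("clustered assembly draws phylogenetically close communities", {
  tree <- simulate_tree(60, seed = 8)
  coph <- stats::cophenetic(tree)
  mean_pair_dist <- function(occ) {
    occ |>
      dplyr::distinct(.data$cell_id, .data$taxon) |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::filter(dplyr::n() >= 3) |>
      dplyr::summarise(d = mean(coph[.data$taxon, .data$taxon])) |>
      dplyr::pull(.data$d) |>
      mean()
  }
  runs <- sapply(c("neutral", "clustered"), function(m) {
    cfg <- sim_config(n_taxa = 60, grid_dims = c(8, 10), assembly_mode = m,
                      assembly_strength = 20, seed = 8)
    mean_pair_dist(simulate_occurrences(tree, simulate_environment(cfg), cfg))
  })
  expect_lt(runs["clustered"], 0.8 * runs["neutral"])
})

test_that("strong clustering confines cells to clades far above chance", {
  n <- 40
  tree <- simulate_tree(n, seed = 14)
  clades <- ape::prop.part(tree)
  clade_sets <- lapply(clades, function(i) tree$tip.label[i])

  # fraction of >=3-taxon cells whose taxa all sit inside one proper clade;
  # the uniformly drawn clade is often smaller than the cell's richness, so
  # perfect confinement is not expected even at extreme strength — the
  # audit is against the neutral rate
  confined_frac <- function(mode) {
    cfg <- sim_config(n_taxa = n, grid_dims = c(6, 8), assembly_mode = mode,
                      assembly_strength = 1000, richness_baseline = 5,
                      seed = 14)
    occ <- simulate_occurrences(tree, simulate_environment(cfg), cfg)
    cells <- split(occ$taxon, occ$cell_id)
    confined <- vapply(cells, function(tx) {
      tx <- unique(tx)
      if (length(tx) < 3) return(NA)
      any(vapply(clade_sets,
                 function(s) all(tx %in% s) && length(s) < n, logical(1)))
    }, logical(1))
    mean(confined, na.rm = TRUE)
  }
  f_neutral <- confined_frac("neutral")
  f_clustered <- confined_frac("clustered")
  expect_gt(f_clustered, f_neutral + 0.2)
  expect_gt(f_clustered, 0.3)
})

test_that("the worked fixture matches its hand computation", {
  fx <- worked_fixture()
  expect_equal(sum(fx$tree$edge.length), 6)
  expect_equal(nrow(fx$tree$edge), 6)
  expect_equal(unname(richness(fx$matrix)), c(2L, 4L, 1L))
})
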
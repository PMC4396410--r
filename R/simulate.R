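#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator. The defaults emulate
#' the data regime of a continental genus-level herbarium compilation: 89
#' taxa, a 40 x 50 grid of 50 km cells (~2,000 occupied cells), a log-linear
#' effect of the first environmental field on expected per-cell richness
#' (baseline ~7 taxa per cell, giving roughly 17k unique occurrences), and
#' overdispersed duplicate sampling so redundancy varies across cells.
#'
#' @param n_taxa number of tips in the simulated tree (`>= 2`).
#' @param grid_dims integer pair `(rows, cols)`.
#' @param cell_size cell side length in projection units.
#' @param env_fields list of fields, each `list(name, gradient_direction
#'   (radians), noise_sd)`; every field is a planar gradient rescaled to
#'   `[0, 1]` plus Gaussian noise.
#' @param richness_baseline expected richness in an average cell (the
#'   log-link intercept is `log(richness_baseline)`).
#' @param richness_effect log-linear effect of the first (standardized)
#'   field on expected richness.
#' @param assembly_mode `"neutral"`, `"clustered"` (taxa biased toward one
#'   clade per cell) or `"overdispersed"` (biased toward phylogenetically
#'   distant tips).
#' @param assembly_strength non-negative bias strength; 0 reduces every mode
#'   to neutral.
#' @param sampling_effort_dispersion mean number of extra duplicate records
#'   per (cell, taxon), drawn negative-binomially (size 1), `> 0`.
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 89,
                       grid_dims = c(40, 50),
                       cell_size = 50000,
                       env_fields = list(
                         list(name = "precipitation",
                              gradient_direction = 0, noise_sd = 0.15),
                         list(name = "temperature",
                              gradient_direction = pi / 2, noise_sd = 0.15),
                         list(name = "radiation",
                              gradient_direction = pi / 4, noise_sd = 0.15)
                       ),
                       richness_baseline = 7,
                       richness_effect = 0.7,
                       assembly_mode = c("neutral", "clustered",
                                         "overdispersed"),
                       assembly_strength = 1,
                       sampling_effort_dispersion = 2,
                       seed = 1L) {
  assembly_mode <- match.arg(assembly_mode)
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  if (any(grid_dims < 1)) stop("grid_dims must be positive", call. = FALSE)
  if (assembly_strength < 0)
    stop("assembly_strength must be >= 0", call. = FALSE)
  if (sampling_effort_dispersion <= 0)
    stop("sampling_effort_dispersion must be > 0", call. = FALSE)
  structure(
    list(n_taxa = as.integer(n_taxa), grid_dims = as.integer(grid_dims),
         cell_size = cell_size, env_fields = env_fields,
         richness_baseline = richness_baseline,
         richness_effect = richness_effect,
         assembly_mode = assembly_mode,
         assembly_strength = assembly_strength,
         sampling_effort_dispersion = sampling_effort_dispersion,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a pure-birth phylogeny
#'
#' A unit-rate pure-birth (Yule) tree with tips labelled `t1..tN`. PD uses
#' branch lengths only, so no molecular clock or calibration is implied.
#'
#' @param n_taxa number of tips (`>= 2`).
#' @param seed integer seed; identical seeds give byte-identical trees.
#' @return An ape `phylo`.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  tree
}

#' Simulate smooth environmental surfaces over the grid
#'
#' Each field is a planar gradient in its stated direction, rescaled to
#' `[0, 1]` across the grid, plus i.i.d. Gaussian noise — a minimal stand-in
#' for interpolated climate layers (precipitation / temperature / radiation
#' analogues).
#'
#' @param config a [sim_config()].
#' @return A tibble with one row per grid cell: `cell_id, row, col,
#'   centroid_x, centroid_y`, then one column per field.
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  nr <- config$grid_dims[1]
  nc <- config$grid_dims[2]
  cells <- tidyr::expand_grid(row = seq_len(nr) - 1L, col = seq_len(nc) - 1L)
  cells <- dplyr::mutate(
    cells,
    cell_id = cell_label(.data$row, .data$col),
    centroid_x = (.data$col + 0.5) * config$cell_size,
    centroid_y = (.data$row + 0.5) * config$cell_size
  ) |>
    dplyr::select("cell_id", "row", "col", "centroid_x", "centroid_y")

  for (f in config$env_fields) {
    g <- cos(f$gradient_direction) * cells$centroid_x +
      sin(f$gradient_direction) * cells$centroid_y
    if (diff(range(g)) > 0) g <- (g - min(g)) / diff(range(g))
    cells[[f$name]] <- g + rnorm(nrow(cells), 0, f$noise_sd)
  }
  cells
}

#' Simulate occurrence records over the grid
#'
#' Per-cell expected richness follows the log-linear link
#' `exp(log(richness_baseline) + richness_effect * z)`, where `z` is the
#' first environmental field standardized over cells. The realized richness
#' is Poisson (truncated at `n_taxa`). Taxa are then drawn without
#' replacement: uniformly (neutral), biased toward one randomly chosen
#' clade per cell (clustered), or biased toward tips with large mean
#' phylogenetic distance (overdispersed); with `assembly_strength = 0` all
#' modes coincide exactly. Finally each (cell, taxon) pair receives
#' `1 + NegBin(size = 1, mu = sampling_effort_dispersion)` records at
#' uniform positions within the cell, so duplicate sampling — and hence
#' redundancy — varies across cells.
#'
#' @param tree a `phylo` whose tips are the taxon pool.
#' @param env environment table from [simulate_environment()] over the same
#'   grid as `config`.
#' @param config a [sim_config()].
#' @return A tibble of records `taxon, x, y, cell_id`.
#' @export
simulate_occurrences <- function(tree, env, config) {
  stopifnot(inherits(config, "sim_config"))
  n_taxa <- length(tree$tip.label)
  if (n_taxa < 2) stop("tree must have >= 2 tips", call. = FALSE)
  if (nrow(env) != prod(config$grid_dims))
    stop("environment table does not match config grid", call. = FALSE)
  env1 <- env[[config$env_fields[[1]]$name]]
  if (is.null(env1)) stop("first env field missing from table", call. = FALSE)

  set.seed(config$seed + 2L)
  z <- as.numeric(scale(env1))
  lambda <- exp(log(config$richness_baseline) + config$richness_effect * z)
  R <- pmin(rpois(nrow(env), lambda), n_taxa)

  mode <- config$assembly_mode
  strength <- config$assembly_strength
  # subtree tip sets per internal node, for the clustered mode
  n_node <- tree$Nnode
  subtrees <- lapply(seq_len(n_node) + n_taxa, function(nd) {
    unlist(phangorn_free_descendants(tree, nd))
  })
  # mean cophenetic distance per tip, for the overdispersed mode
  dbar <- rowMeans(stats::cophenetic(tree))
  dbar_z <- if (sd(dbar) > 0) (dbar - mean(dbar)) / sd(dbar) else dbar * 0

  recs <- vector("list", nrow(env))
  for (i in seq_len(nrow(env))) {
    if (R[i] == 0) next
    # the random clade pick consumes RNG in every mode so that
    # assembly_strength = 0 yields identical streams across modes
    node_pick <- sample.int(n_node, 1)
    w <- rep(1, n_taxa)
    if (mode == "clustered") {
      w[subtrees[[node_pick]]] <- 1 + strength * n_taxa
    } else if (mode == "overdispersed") {
      w <- exp(strength * dbar_z)
    }
    taxa <- sample.int(n_taxa, R[i], prob = w)
    extra <- rnbinom(R[i], size = 1, mu = config$sampling_effort_dispersion)
    n_rec <- 1L + extra
    idx <- rep(taxa, n_rec)
    x0 <- (env$col[i]) * config$cell_size
    y0 <- (env$row[i]) * config$cell_size
    recs[[i]] <- tibble::tibble(
      taxon = tree$tip.label[idx],
      x = x0 + runif(length(idx)) * config$cell_size,
      y = y0 + runif(length(idx)) * config$cell_size,
      cell_id = env$cell_id[i]
    )
  }
  dplyr::bind_rows(recs)
}

# tips descending from an internal node (1-based tip indices); small local
# walker to avoid a heavier dependency for one call
phangorn_free_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  children <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    nd <- stack[[1]]
    stack <- stack[-1]
    kids <- children[[as.character(nd)]]
    tips <- kids[kids <= n_tip]
    out <- c(out, tips)
    stack <- c(stack, kids[kids > n_tip])
  }
  out
}

#' Hand-checkable worked fixture
#'
#' A fixed 4-tip tree with unit branch lengths and topology `((A,B),(C,D))`
#' — 6 branches, total length 6 — and a 3-cell presence matrix:
#' cell 1 = \{A, B\}, cell 2 = \{A, B, C, D\}, cell 3 = \{C\}. The PD
#' proportions are 3/6, 6/6 and 2/6: small enough to verify by hand.
#'
#' @return A list with elements `tree` (phylo) and `matrix`
#'   (`presence_matrix`).
#' @export
worked_fixture <- function() {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  counts <- matrix(0L, 3, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  counts[1, c("A", "B")] <- 1L
  counts[2, ] <- 1L
  counts[3, "C"] <- 1L
  cells <- tibble::tibble(
    cell_id = c("r0_c0", "r0_c1", "r0_c2"),
    row = 0L, col = 0:2,
    centroid_x = (0:2) + 0.5, centroid_y = 0.5
  )
  list(tree = tree, matrix = presence_matrix(counts, cells, grid_spec(1, 0, 0)))
}
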
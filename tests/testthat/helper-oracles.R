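# Independent oracles and small generators shared across tests.

# Brute-force Faith's PD: mark every edge on each tip's walk to the root by
# scanning the raw edge table, then sum. Kept deliberately naive and
# separate from the package's indexed implementation.
pd_oracle <- function(taxa, tree) {
  marked <- rep(FALSE, nrow(tree$edge))
  for (lab in unique(taxa)) {
    node <- match(lab, tree$tip.label)
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      marked[e] <- TRUE
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[marked]) / sum(tree$edge.length)
}

# Brute-force Moran's I as an explicit double sum.
moran_oracle <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  S0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + W[i, j] * z[i] * z[j]
      S0 <- S0 + W[i, j]
    }
  }
  (n / S0) * num / sum(z^2)
}

# Random tree with random branch lengths (not the package's simulator).
random_tree <- function(n_tips) {
  tree <- ape::rtree(n_tips)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.1, 2)
  tree
}

# Random binary matrix with no empty rows/columns, wrapped as a
# presence_matrix on a dummy grid. Empty rows/columns are repaired by
# switching on one random entry (cheaper than rejection sampling, which
# stalls for short-wide matrices at low fill).
random_presence <- function(n_cells, n_taxa, p = 0.3) {
  m <- matrix(stats::rbinom(n_cells * n_taxa, 1, p), n_cells, n_taxa)
  for (i in which(rowSums(m) == 0)) m[i, sample.int(n_taxa, 1)] <- 1L
  for (j in which(colSums(m) == 0)) m[sample.int(n_cells, 1), j] <- 1L
  as_presence(m)
}

as_presence <- function(m) {
  colnames(m) <- paste0("t", seq_len(ncol(m)))
  cells <- tibble::tibble(
    cell_id = sprintf("r0_c%d", seq_len(nrow(m)) - 1),
    row = 0L, col = seq_len(nrow(m)) - 1L,
    centroid_x = seq_len(nrow(m)) - 0.5, centroid_y = 0.5
  )
  presence_matrix(m, cells, grid_spec(1, 0, 0))
}

# Rook-adjacency weights on an nr x nc torus (for the checkerboard case).
torus_rook_weights <- function(nr, nc) {
  n <- nr * nc
  W <- matrix(0, n, n)
  id <- function(r, c) (r %% nr) * nc + (c %% nc) + 1
  for (r in 0:(nr - 1)) {
    for (c in 0:(nc - 1)) {
      i <- id(r, c)
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        W[i, id(r + d[1], c + d[2])] <- 1
      }
    }
  }
  W
}

# Wrap an arbitrary weights matrix as a spatial_weights object.
as_weights <- function(W, radius = 1) {
  ids <- sprintf("c%d", seq_len(nrow(W)))
  dimnames(W) <- list(ids, ids)
  structure(list(cell_id = ids, W = W, excluded_isolates = character(0),
                 radius = radius, cache = new.env(parent = emptyenv())),
            class = "spatial_weights")
}

# Key identifying a binary matrix configuration (for uniformity tests).
matrix_key <- function(x) paste(as.integer(presence(x)), collapse = "")
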
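#' @keywords internal
#' Validate a phylogeny and index each tip's path to the root.
#'
#' Returns the edge lengths, the total tree length, and for every tip the
#' 1-based edge indices on its root-to-tip path. A root edge in the Newick
#' (a branch hanging below the root) is ignored with a warning: Faith's PD
#' sums branches up to, but not beyond, the root node.
#' @noRd
tree_index <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo'", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths", call. = FALSE)
  # the tree is read as rooted at its root node; basal multifurcations
  # (including star trees) are allowed, so ape::is.rooted is not consulted
  if (!is.null(tree$root.edge) && tree$root.edge > 0)
    warning("root edge present in tree; ignored for PD", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("tip labels must be unique", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)

  n_tip <- length(tree$tip.label)
  # parent edge index of every node (tips and internals), 0 if root
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  parent_node <- integer(max(tree$edge))
  parent_node[tree$edge[, 2]] <- tree$edge[, 1]

  paths <- vector("list", n_tip)
  for (t in seq_len(n_tip)) {
    node <- t
    p <- integer(0)
    while (parent_edge[node] != 0L) {
      p <- c(p, parent_edge[node])
      node <- parent_node[node]
    }
    paths[[t]] <- p
  }
  list(tips = tree$tip.label, paths = paths,
       edge_length = tree$edge.length,
       total_length = sum(tree$edge.length))
}

#' Faith's phylogenetic diversity of a set of tips
#'
#' Sums the branch lengths on the union of root-to-tip paths for the given
#' tips and expresses the sum as a proportion of the total tree length, so a
#' cell containing every tip scores exactly 1.
#'
#' @param taxa character vector of tip labels present in a cell (non-empty).
#' @param tree rooted `phylo` with branch lengths.
#' @return A single number in `(0, 1]`.
#' @export
faith_pd <- function(taxa, tree) {
  if (length(taxa) == 0) stop("empty taxon set", call. = FALSE)
  ti <- tree_index(tree)
  hit <- match(unique(taxa), ti$tips)
  if (anyNA(hit))
    stop("unknown tip label(s): ",
         paste(unique(taxa)[is.na(hit)], collapse = ", "), call. = FALSE)
  edges <- unique(unlist(ti$paths[hit]))
  sum(ti$edge_length[edges]) / ti$total_length
}

# Per-cell PD proportions for a whole presence matrix via the C++ engine.
# Taxa absent from the tree must already have been excluded.
pd_cells <- function(x, tree) {
  ti <- tree_index(tree)
  pres <- presence(x)
  hit <- match(colnames(pres), ti$tips)
  if (anyNA(hit))
    stop("matrix taxa missing from tree: ",
         paste(colnames(pres)[is.na(hit)], collapse = ", "), call. = FALSE)
  tip_edges <- lapply(ti$paths[hit], function(p) as.integer(p - 1L))
  raw <- cpp_pd_cells(matrix(as.integer(pres), nrow(pres), ncol(pres)),
                      tip_edges, ti$edge_length)
  stats::setNames(raw / ti$total_length, rownames(pres))
}

# Drop matrix taxa that do not resolve to a tree tip (warn with names);
# returns the reduced matrix for PD work. Cells left empty are dropped too.
match_tree_taxa <- function(x, tree) {
  missing <- setdiff(colnames(x$counts), tree$tip.label)
  if (length(missing) == 0) return(x)
  warning("excluding ", length(missing),
          " matrix taxa absent from the tree: ",
          paste(missing, collapse = ", "), call. = FALSE)
  keep <- setdiff(colnames(x$counts), missing)
  counts <- x$counts[, keep, drop = FALSE]
  occupied <- rowSums(counts) > 0
  if (!all(occupied))
    warning(sum(!occupied), " cells empty after taxon exclusion; dropped",
            call. = FALSE)
  presence_matrix(counts[occupied, , drop = FALSE],
                  x$cells[occupied, , drop = FALSE], x$grid)
}

#' Margalef richness
#'
#' Sampling-corrected richness `(R - 1) / ln(N)` for a cell with `R` taxa in
#' `N` records. Cells with a single record (`N = 1`) are assigned 0 — they
#' necessarily have `R = 1`, and the zero numerator makes this the natural
#' degenerate value rather than 0/0.
#'
#' @param R integer vector of per-cell richness (`>= 1`).
#' @param N integer vector of per-cell record counts (`>= R`).
#' @return Numeric vector of Margalef values.
#' @export
margalef <- function(R, N) {
  if (any(R < 1) || any(N < 1)) stop("R and N must be >= 1", call. = FALSE)
  if (any(N < R))
    stop("N < R: more taxa than records is impossible", call. = FALSE)
  ifelse(N == 1, 0, (R - 1) / log(N))
}

#' Relative phylogenetic diversity
#'
#' PD standardized by richness, `pd / R`.
#'
#' @param pd numeric vector of PD proportions.
#' @param R integer vector of richness values (`>= 1`).
#' @return Numeric vector.
#' @export
pd_rel <- function(pd, R) {
  if (any(R < 1)) stop("richness must be >= 1", call. = FALSE)
  pd / R
}

#' Per-cell richness
#' @param x a `presence_matrix`.
#' @return named integer vector of presence row sums.
#' @export
richness <- function(x) {
  stopifnot(inherits(x, "presence_matrix"))
  rowSums(presence(x))
}

#' Per-cell diversity table
#'
#' Computes the full per-cell metric set: richness, record count,
#' redundancy, Margalef richness, Faith's PD (proportion of total tree
#' length) and relative PD. Taxa present in the matrix but absent from the
#' tree are excluded from PD (with a warning) but still count toward
#' richness, records and Margalef.
#'
#' @param x a `presence_matrix`.
#' @param tree rooted `phylo` with branch lengths whose tips cover the
#'   matrix taxa (extra tips are fine).
#' @return A tibble `cell_id, row, col, centroid_x, centroid_y, richness,
#'   n_records, redundancy, margalef, pd, pd_rel` of class
#'   `diversity_table`.
#' @export
diversity_table <- function(x, tree) {
  stopifnot(inherits(x, "presence_matrix"))
  red <- redundancy(x)
  xt <- match_tree_taxa(x, tree)
  pd <- pd_cells(xt, tree)

  out <- x$cells |>
    dplyr::left_join(red, by = "cell_id") |>
    dplyr::mutate(
      margalef = margalef(.data$richness, .data$n_records),
      pd = unname(pd[.data$cell_id]),
      pd_rel = .data$pd / .data$richness
    )
  class(out) <- c("diversity_table", class(out))
  out
}

#' Compare two PD tables cell by cell
#'
#' Differences are `pd_b - pd_a` per shared cell, the operation used to
#' check how sensitive per-cell PD is to an updated phylogeny.
#'
#' @param table_a,table_b diversity tables (or any tibbles with `cell_id`
#'   and `pd`) over the same cell set.
#' @return A list with `differences` (tibble `cell_id, pd_a, pd_b, diff`)
#'   and `summary` (tibble `min, max, mean`).
#' @export
compare_pd <- function(table_a, table_b) {
  if (!setequal(table_a$cell_id, table_b$cell_id))
    stop("cell sets differ between tables", call. = FALSE)
  d <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(table_a), "cell_id", pd_a = "pd"),
    dplyr::select(tibble::as_tibble(table_b), "cell_id", pd_b = "pd"),
    by = "cell_id"
  ) |>
    dplyr::mutate(diff = .data$pd_b - .data$pd_a)
  list(
    differences = d,
    summary = tibble::tibble(min = min(d$diff), max = max(d$diff),
                             mean = mean(d$diff))
  )
}
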
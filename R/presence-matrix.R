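#' Presence matrix of grid cells by taxa
#'
#' The central container of the pipeline: an integer matrix of record counts
#' with grid cells as rows and taxa as columns, plus a cell table carrying
#' grid indices and centroid coordinates. Presence is `counts >= 1`; the row
#' sums of presence are per-cell richness, the column sums are taxon range
#' sizes, and the total number of `TRUE` entries (the fill) is the number of
#' unique occurrences.
#'
#' @param counts integer matrix, cells x taxa, non-negative; rownames are
#'   cell ids and colnames taxon names.
#' @param cells tibble with one row per matrix row: `cell_id`, `row`, `col`,
#'   `centroid_x`, `centroid_y`.
#' @param grid the [grid_spec()] the cells were derived from, or `NULL`.
#' @return An object of class `presence_matrix`.
#' @seealso [build_matrix()], [tidy.presence_matrix()]
#' @export
presence_matrix <- function(counts, cells, grid = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(cells), !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(counts) == 0))
    stop("every retained cell must hold at least one record", call. = FALSE)
  if (any(colSums(counts) == 0))
    stop("every retained taxon must occur in at least one cell", call. = FALSE)
  rownames(counts) <- cells$cell_id
  structure(
    list(counts = counts, cells = tibble::as_tibble(cells), grid = grid),
    class = "presence_matrix"
  )
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf(
    "<presence_matrix> %d cells x %d taxa, fill %d (unique occurrences), %d records\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts >= 1), sum(x$counts)
  ))
  invisible(x)
}

#' @export
dim.presence_matrix <- function(x) dim(x$counts)

#' Binary presence indicator of a presence matrix
#' @param x a `presence_matrix`.
#' @return logical matrix, cells x taxa.
#' @export
presence <- function(x) {
  stopifnot(inherits(x, "presence_matrix"))
  x$counts >= 1L
}

#' Per-cell record totals
#' @param x a `presence_matrix`.
#' @return named integer vector, records per cell.
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "presence_matrix"))
  rowSums(x$counts)
}

#' Taxon range sizes (cells occupied per taxon)
#' @param x a `presence_matrix`.
#' @return named integer vector.
#' @export
range_size <- function(x) colSums(presence(x))

#' Long-format view of a presence matrix
#'
#' @param x a `presence_matrix`.
#' @param ... unused.
#' @return A tibble `cell_id, taxon, count` with one row per occupied
#'   (cell, taxon) pair; `nrow()` equals the matrix fill.
#' @export
tidy.presence_matrix <- function(x, ...) {
  idx <- which(x$counts >= 1L, arr.ind = TRUE)
  tibble::tibble(
    cell_id = rownames(x$counts)[idx[, 1]],
    taxon = colnames(x$counts)[idx[, 2]],
    count = as.integer(x$counts[idx])
  ) |>
    dplyr::arrange(.data$cell_id, .data$taxon)
}

#' @export
glance.presence_matrix <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$counts),
    n_taxa = ncol(x$counts),
    fill = sum(x$counts >= 1L),
    n_records = as.integer(sum(x$counts))
  )
}

# Replace counts (binary) while keeping cell/taxon bookkeeping; internal,
# used by the null shuffle.
set_presence <- function(x, pres) {
  stopifnot(all(dim(pres) == dim(x$counts)))
  counts <- matrix(as.integer(pres), nrow(pres), ncol(pres),
                   dimnames = dimnames(x$counts))
  x$counts <- counts
  x
}
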
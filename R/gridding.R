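#' Equal-area square grid specification
#'
#' Cells are half-open squares `[edge, edge + cell_size)` in both axes, so
#' every point maps to exactly one cell. The default origin is the minimum
#' corner of the data extent (set when records are gridded).
#'
#' @param cell_size side length of a cell in the projection's length units
#'   (e.g. 50000 for 50 km cells on metre-based equal-area coordinates).
#' @param origin_x,origin_y coordinates of the grid origin corner; `NA` means
#'   "infer from the data minimum".
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(cell_size, origin_x = NA_real_, origin_y = NA_real_) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a single positive number", call. = FALSE)
  structure(
    list(cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> cell_size %g, origin (%s, %s)\n", x$cell_size,
              format(x$origin_x), format(x$origin_y)))
  invisible(x)
}

#' Clean occurrence records
#'
#' Drops rows with missing or non-finite coordinates, trims and canonicalizes
#' taxon names through a synonymy map, and optionally clips to a bounding
#' box. Counts of dropped rows are attached as the `"dropped"` attribute and
#' reported via `message()`.
#'
#' @param records data frame with columns `taxon`, `x`, `y` (extra columns
#'   are kept).
#' @param synonymy named character vector or two-column data frame
#'   (`from`, `to`) mapping names onto accepted names. Chains (a -> b -> c)
#'   are resolved to their terminal name; cycles are an error.
#' @param bbox optional numeric vector `c(x0, y0, x1, y1)`; records strictly
#'   outside are dropped.
#' @return A tibble of retained records with normalized taxon names.
#' @export
clean_records <- function(records, synonymy = NULL, bbox = NULL) {
  records <- tibble::as_tibble(records)
  if (!all(c("taxon", "x", "y") %in% names(records)))
    stop("records need columns taxon, x, y", call. = FALSE)
  n0 <- nrow(records)

  ok_coord <- is.finite(suppressWarnings(as.numeric(records$x))) &
    is.finite(suppressWarnings(as.numeric(records$y)))
  dropped_coord <- sum(!ok_coord)
  out <- records[ok_coord, , drop = FALSE]
  out$x <- as.numeric(out$x)
  out$y <- as.numeric(out$y)

  out$taxon <- trimws(as.character(out$taxon))
  ok_name <- !is.na(out$taxon) & nzchar(out$taxon)
  dropped_name <- sum(!ok_name)
  out <- out[ok_name, , drop = FALSE]

  if (!is.null(synonymy)) {
    map <- resolve_synonymy(synonymy)
    hit <- out$taxon %in% names(map)
    out$taxon[hit] <- unname(map[out$taxon[hit]])
  }

  dropped_bbox <- 0L
  if (!is.null(bbox)) {
    stopifnot(length(bbox) == 4)
    inside <- out$x >= bbox[1] & out$y >= bbox[2] &
      out$x <= bbox[3] & out$y <= bbox[4]
    dropped_bbox <- sum(!inside)
    out <- out[inside, , drop = FALSE]
  }

  dropped <- c(`missing coordinates` = dropped_coord,
               `missing taxon name` = dropped_name,
               `outside bbox` = dropped_bbox)
  if (any(dropped > 0))
    message(sprintf("clean_records: dropped %d of %d rows (%s)",
                    sum(dropped), n0,
                    paste(names(dropped)[dropped > 0],
                          dropped[dropped > 0], collapse = ", ")))
  attr(out, "dropped") <- dropped
  out
}

# Normalize a synonymy map: accept named vector or from/to data frame,
# follow chains to their terminal accepted name, error on cycles.
resolve_synonymy <- function(synonymy) {
  if (is.data.frame(synonymy)) {
    stopifnot(all(c("from", "to") %in% names(synonymy)))
    map <- stats::setNames(trimws(as.character(synonymy$to)),
                           trimws(as.character(synonymy$from)))
  } else {
    map <- stats::setNames(trimws(as.character(synonymy)),
                           trimws(names(synonymy)))
  }
  map <- map[names(map) != map]
  resolved <- map
  for (nm in names(map)) {
    seen <- nm
    cur <- map[[nm]]
    while (cur %in% names(map)) {
      if (cur %in% seen)
        stop("synonymy cycle involving '", nm, "'", call. = FALSE)
      seen <- c(seen, cur)
      cur <- map[[cur]]
    }
    resolved[[nm]] <- cur
  }
  resolved
}

#' Map projected coordinates to grid cell indices
#'
#' Uses the half-open convention: `col = floor((x - origin_x) / cell_size)`,
#' `row = floor((y - origin_y) / cell_size)`, zero-based from the origin.
#' Points exactly on an upper edge belong to the next cell; indices may be
#' negative for points below/left of the origin.
#'
#' @param x,y numeric vectors of projected coordinates.
#' @param grid a [grid_spec()] with a concrete origin.
#' @return A tibble with integer columns `row` and `col`.
#' @export
assign_cell <- function(x, y, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite coordinate passed to assign_cell", call. = FALSE)
  if (!is.finite(grid$origin_x) || !is.finite(grid$origin_y))
    stop("grid origin must be set before assigning cells", call. = FALSE)
  tibble::tibble(
    row = as.integer(floor((y - grid$origin_y) / grid$cell_size)),
    col = as.integer(floor((x - grid$origin_x) / grid$cell_size))
  )
}

cell_label <- function(row, col) sprintf("r%d_c%d", row, col)

#' Aggregate cleaned records into a presence matrix
#'
#' One matrix row per cell containing at least one record; counts accumulate
#' duplicate records of the same taxon in the same cell, and the fill (number
#' of occupied entries) equals the number of distinct (cell, taxon) pairs —
#' the "unique occurrences" of the gridded dataset.
#'
#' @param records cleaned occurrence tibble (`taxon`, `x`, `y`).
#' @param grid a [grid_spec()]; an unset origin is replaced by the data
#'   minimum corner.
#' @return A [presence_matrix()].
#' @export
build_matrix <- function(records, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(records) == 0) stop("no records to grid", call. = FALSE)
  if (!is.finite(grid$origin_x)) grid$origin_x <- min(records$x)
  if (!is.finite(grid$origin_y)) grid$origin_y <- min(records$y)

  idx <- assign_cell(records$x, records$y, grid)
  long <- tibble::tibble(row = idx$row, col = idx$col,
                         taxon = records$taxon) |>
    dplyr::count(.data$row, .data$col, .data$taxon, name = "count")

  cells <- long |>
    dplyr::distinct(.data$row, .data$col) |>
    dplyr::arrange(.data$row, .data$col) |>
    dplyr::mutate(
      cell_id = cell_label(.data$row, .data$col),
      centroid_x = grid$origin_x + (.data$col + 0.5) * grid$cell_size,
      centroid_y = grid$origin_y + (.data$row + 0.5) * grid$cell_size
    ) |>
    dplyr::select("cell_id", "row", "col", "centroid_x", "centroid_y")

  taxa <- sort(unique(long$taxon))
  counts <- matrix(0L, nrow(cells), length(taxa),
                   dimnames = list(cells$cell_id, taxa))
  counts[cbind(match(cell_label(long$row, long$col), cells$cell_id),
               match(long$taxon, taxa))] <- long$count
  presence_matrix(counts, cells, grid)
}

#' Per-cell sampling redundancy
#'
#' Redundancy is `1 - richness / n_records` per cell: a sampling-quality
#' score in `[0, 1)`. Values near 0 flag possible under-sampling (nearly
#' every record is a different taxon); values near 1 indicate many duplicate
#' records per taxon, i.e. well-sampled cells.
#'
#' @param x a `presence_matrix`.
#' @return A tibble `cell_id, richness, n_records, redundancy`.
#' @export
redundancy <- function(x) {
  stopifnot(inherits(x, "presence_matrix"))
  r <- rowSums(presence(x))
  n <- rowSums(x$counts)
  tibble::tibble(cell_id = x$cells$cell_id,
                 richness = as.integer(unname(r)),
                 n_records = as.integer(unname(n)),
                 redundancy = unname(1 - r / n))
}

#' Read an occurrence table from delimited text
#'
#' Expects a header with at least `taxon,x,y`; extra columns are kept.
#'
#' @param path file path (csv or tsv inferred from extension).
#' @return A tibble of raw records.
#' @export
read_occurrences <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  out <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("taxon", "x", "y") %in% names(out)))
    stop("occurrence file needs columns taxon, x, y", call. = FALSE)
  out
}
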
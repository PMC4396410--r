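#' Validate pipeline inputs
#'
#' Checks that the configured input files exist and parse, that the
#' occurrence table has the required columns, how many occurrence taxa
#' resolve to tree tips, and what fraction of occupied grid cells have an
#' environment row. Zero taxon overlap is fatal; partial overlap is
#' reported and handled downstream by the PD exclusion rule.
#'
#' @param config a pipeline config list (see [run_pipeline()]) with
#'   `occurrences`, `tree` and `environment` paths set.
#' @return A list report: `n_records`, `taxa_matched`, `taxa_unmatched`,
#'   `env_coverage`.
#' @export
validate_inputs <- function(config) {
  for (p in c("occurrences", "tree", "environment")) {
    if (is.null(config[[p]]))
      stop("config lacks input path '", p, "'", call. = FALSE)
    if (!file.exists(config[[p]]))
      stop("input file not found: ", config[[p]], call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(config$tree),
                   error = function(e)
                     stop("malformed Newick in ", config$tree, ": ",
                          conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed Newick in ", config$tree, call. = FALSE)
  occ <- read_occurrences(config$occurrences)
  env <- readr::read_csv(config$environment, show_col_types = FALSE,
                         progress = FALSE)

  taxa <- unique(trimws(occ$taxon))
  matched <- intersect(taxa, tree$tip.label)
  if (length(matched) == 0)
    stop("no occurrence taxon matches a tree tip", call. = FALSE)

  cleaned <- suppressMessages(clean_records(occ))
  grid <- pipeline_grid(config)
  mat <- build_matrix(cleaned, grid)
  coverage <- if ("cell_id" %in% names(env))
    mean(mat$cells$cell_id %in% env$cell_id) else NA_real_

  report <- list(n_records = nrow(occ),
                 taxa_matched = length(matched),
                 taxa_unmatched = length(setdiff(taxa, tree$tip.label)),
                 env_coverage = coverage)
  message(sprintf("validate: %d records; %d taxa matched, %d unmatched; env coverage %.2f",
                  report$n_records, report$taxa_matched,
                  report$taxa_unmatched, report$env_coverage))
  report
}

pipeline_grid <- function(config) {
  origin <- config$origin %||% c(0, 0)
  grid_spec(config$cell_size %||% 50000, origin[1], origin[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full spatial-phylogenetics pipeline
#'
#' Orchestrates simulate (optional) -> grid -> diversity -> randomize ->
#' models from a single flat config, writing every stage output as
#' delimited text plus a JSON run manifest. A single seed fans out to the
#' per-stage seeds, so one integer reproduces every output byte for byte.
#'
#' Config keys (all optional unless noted): `out_dir` (required), `seed`
#' (default 1), `simulate` (list of [sim_config()] overrides; if absent,
#' `occurrences`/`tree`/`environment` file paths must be given),
#' `cell_size` (default 50000), `origin` (grid origin, default `c(0, 0)`),
#' `n_rand` (999), `tail_alpha` (0.025), `radius` (default 1.5 cell sizes,
#' the eight-neighbor band), `indicator_radii` (default 3 and 6 cell
#' sizes), `responses` (default richness, margalef, pd + both indicators),
#' `variables` (default: every environment column).
#'
#' @param config named list as above.
#' @return The manifest (invisibly), also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config needs out_dir", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- list()

  # -- simulate ------------------------------------------------------------
  if (is.null(config$occurrences)) {
    cfg <- do.call(sim_config, c(config$simulate %||% list(),
                                 list(seed = seed)))
    tree <- simulate_tree(cfg$n_taxa, seed = seed)
    env <- simulate_environment(cfg)
    occ <- simulate_occurrences(tree, env, cfg)
    config$cell_size <- cfg$cell_size
    config$occurrences <- file.path(out_dir, "occurrences.csv")
    config$tree <- file.path(out_dir, "tree.nwk")
    config$environment <- file.path(out_dir, "environment.csv")
    readr::write_csv(occ[c("taxon", "x", "y")], config$occurrences)
    ape::write.tree(tree, config$tree)
    readr::write_csv(env, config$environment)
    stages <- c(stages, list(list(stage = "simulate",
                                  n_records = nrow(occ),
                                  n_taxa = cfg$n_taxa)))
  }

  validation <- validate_inputs(config)

  # -- grid ----------------------------------------------------------------
  occ <- read_occurrences(config$occurrences)
  cleaned <- clean_records(occ, synonymy = config$synonymy,
                           bbox = config$bbox)
  grid <- pipeline_grid(config)
  mat <- build_matrix(cleaned, grid)
  red <- redundancy(mat)
  cells_out <- dplyr::left_join(mat$cells, red, by = "cell_id")
  readr::write_csv(cells_out, file.path(out_dir, "cells.csv"))
  readr::write_csv(tidy(mat), file.path(out_dir, "matrix_long.csv"))
  stages <- c(stages, list(list(
    stage = "grid", n_records_in = nrow(occ), n_records_kept = nrow(cleaned),
    dropped = as.list(attr(cleaned, "dropped")),
    n_cells = nrow(mat$counts), n_taxa = ncol(mat$counts),
    fill = sum(mat$counts >= 1)
  )))

  # -- diversity -----------------------------------------------------------
  tree <- ape::read.tree(config$tree)
  div <- diversity_table(mat, tree)
  readr::write_csv(tibble::as_tibble(div), file.path(out_dir, "diversity.csv"))
  stages <- c(stages, list(list(stage = "diversity", n_cells = nrow(div))))

  # -- randomize -----------------------------------------------------------
  n_rand <- config$n_rand %||% 999L
  tail_alpha <- config$tail_alpha %||% 0.025
  rand <- randomization_test(mat, tree, n_rand = n_rand,
                             tail_alpha = tail_alpha, seed = seed + 1L)
  readr::write_csv(
    tibble::as_tibble(rand)[c("cell_id", "observed_pd", "p_high", "p_low",
                              "code")],
    file.path(out_dir, "randomization.csv")
  )
  jsonlite::write_json(
    list(seed = seed + 1L, n_rand = n_rand, tail_alpha = tail_alpha,
         backend = attr(rand, "backend"), burn_in = attr(rand, "burn_in"),
         thin = attr(rand, "thin")),
    file.path(out_dir, "randomization_config.json"), auto_unbox = TRUE
  )
  stages <- c(stages, list(list(stage = "randomize",
                                n_high = sum(rand$code == "high"),
                                n_low = sum(rand$code == "low"),
                                n_ns = sum(rand$code == "ns"))))

  # -- models --------------------------------------------------------------
  env <- readr::read_csv(config$environment, show_col_types = FALSE,
                         progress = FALSE)
  env_vars <- config$variables %||%
    setdiff(names(env), c("cell_id", "row", "col", "centroid_x",
                          "centroid_y"))
  joined <- tibble::as_tibble(div) |>
    dplyr::left_join(dplyr::select(env, "cell_id",
                                   dplyr::all_of(env_vars)),
                     by = "cell_id") |>
    dplyr::mutate(
      pd_high = as.integer(significance_indicator(rand, "high")[.data$cell_id]),
      pd_low = as.integer(significance_indicator(rand, "low")[.data$cell_id])
    )
  n_env_missing <- sum(!stats::complete.cases(joined[env_vars]))
  readr::write_csv(joined, file.path(out_dir, "cells_joined.csv"))

  cell_size <- config$cell_size %||% 50000
  radius <- config$radius %||% (1.5 * cell_size)
  indicator_radii <- config$indicator_radii %||% (c(3, 6) * cell_size)
  w <- neighbor_weights(joined, radius)

  responses <- config$responses %||% c("richness", "margalef", "pd",
                                       "pd_high", "pd_low")
  model_files <- character(0)
  for (resp in setdiff(responses, c("pd_high", "pd_low"))) {
    rep_tab <- model_battery(joined, resp, env_vars, w)
    f <- file.path(out_dir, paste0("models_", resp, ".csv"))
    readr::write_csv(rep_tab, f)
    model_files <- c(model_files, f)
  }
  for (resp in intersect(responses, c("pd_high", "pd_low"))) {
    if (sum(joined[[resp]], na.rm = TRUE) < 5) {
      message("skipping ", resp,
              " models: fewer than 5 significant cells")
      next
    }
    for (r in indicator_radii) {
      wi <- neighbor_weights(joined, r)
      rep_tab <- model_battery(joined, resp, env_vars, wi, sar = FALSE)
      f <- file.path(out_dir,
                     paste0("models_", resp, "_r", round(r / 1000), "km.csv"))
      readr::write_csv(rep_tab, f)
      model_files <- c(model_files, f)
    }
  }
  stages <- c(stages, list(list(
    stage = "models", n_variables = length(env_vars),
    n_cells_missing_env = n_env_missing,
    n_isolates_excluded = length(w$excluded_isolates),
    files = basename(model_files)
  )))

  # -- manifest ------------------------------------------------------------
  outputs <- list.files(out_dir, pattern = "\\.(csv|nwk|json)$",
                        full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package = "pdgrid",
    version = as.character(utils::packageVersion("pdgrid")),
    seed = seed,
    inputs = list(occurrences = unname(tools::md5sum(config$occurrences)),
                  tree = unname(tools::md5sum(config$tree)),
                  environment = unname(tools::md5sum(config$environment))),
    validation = validation,
    stages = stages,
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
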
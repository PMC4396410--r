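#' Model specification for a diversity-environment GLM
#'
#' @param response name of the response column (e.g. `"richness"`,
#'   `"margalef"`, `"pd"`, `"pd_high"`, `"pd_low"`).
#' @param terms character vector of one or two predictor names.
#' @param kind `"single"`, `"additive"` (`v1 + v2`) or `"interaction"`
#'   (`v1 * v2`, hierarchical: main effects included).
#' @param family a [stats::family] object; `NULL` picks the default for the
#'   response: poisson(log) for richness, Gamma(log) for Margalef and PD,
#'   binomial(logit) for 0/1 indicators, gaussian otherwise.
#' @return A `model_spec`.
#' @export
model_spec <- function(response, terms,
                       kind = c("single", "additive", "interaction"),
                       family = NULL) {
  kind <- match.arg(kind)
  if (kind == "single" && length(terms) != 1)
    stop("single models take exactly one term", call. = FALSE)
  if (kind != "single" && length(terms) != 2)
    stop("additive/interaction models take two terms", call. = FALSE)
  if (is.null(family)) family <- default_family(response)
  structure(list(response = response, terms = terms, kind = kind,
                 family = family),
            class = "model_spec")
}

default_family <- function(response) {
  switch(response,
         richness = poisson(link = "log"),
         margalef = Gamma(link = "log"),
         pd = Gamma(link = "log"),
         pd_rel = Gamma(link = "log"),
         pd_high = binomial(link = "logit"),
         pd_low = binomial(link = "logit"),
         pd_high_indicator = binomial(link = "logit"),
         pd_low_indicator = binomial(link = "logit"),
         gaussian())
}

spec_formula <- function(spec) {
  rhs <- switch(spec$kind,
                single = spec$terms[1],
                additive = paste(spec$terms, collapse = " + "),
                interaction = paste(spec$terms, collapse = " * "))
  stats::as.formula(paste(spec$response, "~", rhs))
}

spec_label <- function(spec) {
  sep <- switch(spec$kind, single = "", additive = " + ", interaction = " x ")
  paste(spec$terms, collapse = sep)
}

# the coefficient whose sign is reported as the model's "slope": the
# interaction coefficient for "x" models, the second main effect for "+"
# models, the single term otherwise (a documented convention)
slope_term <- function(spec) {
  switch(spec$kind,
         single = spec$terms[1],
         additive = spec$terms[2],
         interaction = paste(spec$terms, collapse = ":"))
}

#' Fit one diversity-environment GLM
#'
#' Predictors are z-scored over the rows used in the fit (numerical
#' stability; AIC and deviance are unaffected). Cells with any missing
#' modeled variable are excluded, and for gamma families rows with
#' non-positive response (e.g. Margalef 0 in single-record cells) are
#' excluded too; both counts are recorded on the result.
#'
#' @param spec a [model_spec()].
#' @param data per-cell table holding the response and predictor columns.
#' @return A `model_fit`: the underlying `glm`, `aic`, `de_pct`
#'   (`100 * (1 - residual deviance / null deviance)`), a coefficient table
#'   with Wald z and p, `slope_sign`, and the exclusion counts.
#' @export
fit_glm <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  data <- tibble::as_tibble(data)
  cols <- c(spec$response, spec$terms)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n_missing <- nrow(data) - nrow(d)

  n_nonpos <- 0L
  if (spec$family$family == "Gamma") {
    pos <- d[[spec$response]] > 0
    n_nonpos <- sum(!pos)
    d <- d[pos, , drop = FALSE]
  }
  if (spec$family$family == "binomial" &&
      !all(d[[spec$response]] %in% c(0, 1)))
    stop("binomial response must be 0/1", call. = FALSE)
  for (v in spec$terms) d[[v]] <- as.numeric(scale(d[[v]]))

  p <- length(attr(stats::terms(spec_formula(spec)), "term.labels")) + 1
  if (nrow(d) < p + 5)
    stop("too few complete cells to fit model", call. = FALSE)

  fit <- suppressWarnings(glm(spec_formula(spec), family = spec$family,
                              data = d))
  if (!fit$converged) {
    if (spec$family$family == "binomial") {
      # typically complete separation; flag but report the fit
      warning("binomial GLM for ", spec_label(spec),
              " did not converge (possible complete separation)",
              call. = FALSE)
    } else {
      stop("GLM did not converge for ", spec_label(spec), call. = FALSE)
    }
  }

  sm <- summary(fit)$coefficients
  est <- unname(sm[, 1])
  se <- unname(sm[, 2])
  coefs <- tibble::tibble(term = rownames(sm), estimate = est,
                          std.error = se,
                          statistic = est / se,
                          p.value = 2 * pnorm(abs(est / se),
                                              lower.tail = FALSE))
  st <- slope_term(spec)
  slope_est <- coefs$estimate[match(st, coefs$term)]

  structure(
    list(spec = spec, fit = fit, label = spec_label(spec),
         aic = AIC(fit),
         de_pct = 100 * (1 - fit$deviance / fit$null.deviance),
         coefficients = coefs,
         wald_z = coefs$statistic[match(st, coefs$term)],
         wald_p = coefs$p.value[match(st, coefs$term)],
         slope_sign = if (is.na(slope_est)) NA_character_ else
           if (slope_est >= 0) "+" else "-",
         n = nrow(d), n_missing_env = n_missing,
         n_nonpositive = n_nonpos),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s ~ %s [%s, %s]: AIC %.2f, DE%% %.2f, slope %s\n",
              x$spec$response, x$label, x$spec$kind, x$spec$family$family,
              x$aic, x$de_pct, x$slope_sign))
  invisible(x)
}

#' @export
tidy.model_fit <- function(x, ...) x$coefficients

#' @export
glance.model_fit <- function(x, ...) {
  tibble::tibble(AIC = x$aic, de_pct = x$de_pct, nobs = x$n,
                 family = x$spec$family$family)
}

#' Build and fit the single / additive / interaction model set
#'
#' Fits every single-variable GLM first, ranks them by AIC, and expands the
#' `top_n` (default 5) best single predictors into all unordered pairs, each
#' fitted once additively and once with an interaction. With 11 variables
#' this yields 11 + 10 + 10 = 31 fitted models. Fewer than `top_n`
#' variables fall back to all available pairs (with a message).
#'
#' @param data per-cell table with the response and predictors.
#' @param response response column name.
#' @param variables character vector of predictor names (`>= 1`).
#' @param family optional family override for every model.
#' @param top_n number of best single predictors expanded into pairs.
#' @return A tibble of class `model_set`, one row per model, AIC-ranked:
#'   `model, kind, aic, delta_aic, de_pct, wald_z, wald_p, slope, n, fit`
#'   (list column of `model_fit`).
#' @export
build_model_set <- function(data, response, variables, family = NULL,
                            top_n = 5) {
  if (length(variables) < 1) stop("need at least one variable", call. = FALSE)
  singles <- purrr::map(variables, function(v) {
    fit_glm(model_spec(response, v, "single", family), data)
  })
  single_aic <- purrr::map_dbl(singles, "aic")
  n_top <- min(top_n, length(variables))
  if (length(variables) < top_n && length(variables) >= 2)
    message("fewer than ", top_n, " variables; pairing all ", n_top)
  top <- variables[order(single_aic)][seq_len(n_top)]

  fits <- singles
  if (n_top >= 2) {
    prs <- utils::combn(top, 2, simplify = FALSE)
    for (pr in prs) {
      fits <- c(fits,
                list(fit_glm(model_spec(response, pr, "additive", family),
                             data)),
                list(fit_glm(model_spec(response, pr, "interaction", family),
                             data)))
    }
  }

  out <- tibble::tibble(
    model = purrr::map_chr(fits, "label"),
    kind = purrr::map_chr(fits, function(f) f$spec$kind),
    aic = purrr::map_dbl(fits, "aic"),
    de_pct = purrr::map_dbl(fits, "de_pct"),
    wald_z = purrr::map_dbl(fits, "wald_z"),
    wald_p = purrr::map_dbl(fits, "wald_p"),
    slope = purrr::map_chr(fits, "slope_sign"),
    n = purrr::map_int(fits, "n"),
    fit = fits
  ) |>
    dplyr::arrange(.data$aic) |>
    dplyr::mutate(delta_aic = .data$aic - min(.data$aic), .after = "aic")
  attr(out, "response") <- response
  class(out) <- c("model_set", class(out))
  out
}

#' Models within an AIC window of the best
#'
#' Returns the fits whose AIC lies within `window` units of the set's
#' minimum (inclusive); such models are treated as equally informative.
#'
#' @param fits a `model_set` (or any tibble with `delta_aic`).
#' @param window AIC window, default 3.
#' @return The qualifying rows.
#' @export
equivalence_class <- function(fits, window = 3) {
  if (nrow(fits) < 1) stop("empty model set", call. = FALSE)
  fits[fits$delta_aic <= window, , drop = FALSE]
}

#' Assemble the model report table
#'
#' One row per fitted model with the GLM columns (delta AIC, deviance
#' explained, Wald significance, slope sign), Moran's I of the matching
#' ordinary linear model's residuals, and the spatial error model's delta
#' AIC and z where fitted — the shape of a diversity-vs-environment results
#' table. Sorted by SAR delta AIC when SAR fits are present, else by GLM
#' delta AIC.
#'
#' @param fits a `model_set`.
#' @param moran_results optional tibble `model, moran_i, moran_p` (see
#'   [moran_for_models()]).
#' @param sar_fits optional tibble `model, sar_aic, sar_z` (see
#'   [sar_for_models()]).
#' @return A tibble, one row per model.
#' @export
summarize_models <- function(fits, moran_results = NULL, sar_fits = NULL) {
  out <- tibble::as_tibble(fits[c("model", "kind", "aic", "delta_aic",
                                  "de_pct", "wald_z", "wald_p", "slope",
                                  "n")])
  names(out)[names(out) == "aic"] <- "glm_aic"
  names(out)[names(out) == "delta_aic"] <- "glm_delta_aic"
  if (!is.null(moran_results))
    out <- dplyr::left_join(out, moran_results, by = "model")
  if (!is.null(sar_fits)) {
    sar_fits$sar_delta_aic <- sar_fits$sar_aic - min(sar_fits$sar_aic)
    out <- dplyr::left_join(out, sar_fits, by = "model") |>
      dplyr::arrange(.data$sar_delta_aic)
  } else {
    out <- dplyr::arrange(out, .data$glm_delta_aic)
  }
  out
}

#' Moran's I of LM residuals for every model in a set
#'
#' Refits each model's terms as an ordinary linear model (identity,
#' gaussian) on the weights' non-isolate cells and computes Moran's I of
#' the residuals — the spatial-autocorrelation diagnostic attached to each
#' GLM row of the report.
#'
#' @param fits a `model_set`.
#' @param data per-cell table with `cell_id`, the response and predictors.
#' @param weights a [neighbor_weights()] object.
#' @return A tibble `model, moran_i, moran_p`.
#' @export
moran_for_models <- function(fits, data, weights) {
  data <- as.data.frame(data)
  purrr::map_dfr(fits$fit, function(f) {
    d <- data[match(weights$cell_id, data$cell_id), , drop = FALSE]
    cols <- c("cell_id", f$spec$response, f$spec$terms)
    d <- d[cols]
    cc <- stats::complete.cases(d)
    sw <- subset_weights(weights, weights$cell_id[cc])
    d <- d[match(sw$cell_id, d$cell_id), , drop = FALSE]
    lmfit <- lm(spec_formula(f$spec), data = d)
    mi <- tryCatch(
      morans_i(stats::setNames(residuals(lmfit), d$cell_id), sw),
      error = function(e) {
        message("Moran's I undefined for ", f$label, ": ",
                conditionMessage(e))
        tibble::tibble(I = NA_real_, p = NA_real_)
      }
    )
    tibble::tibble(model = f$label, moran_i = mi$I, moran_p = mi$p)
  })
}

#' Spatial error fits for every model in a set
#'
#' Fits the gaussian spatial error model with each model's terms over the
#' weights' non-isolate cells; reports AIC and the z statistic of the
#' model's slope coefficient (same convention as the GLM slope).
#'
#' @inheritParams moran_for_models
#' @return A tibble `model, sar_aic, sar_z, sar_lambda`.
#' @export
sar_for_models <- function(fits, data, weights) {
  purrr::map_dfr(fits$fit, function(f) {
    sf <- fit_sar_err(spec_formula(f$spec), data, weights)
    st <- slope_term(f$spec)
    z <- sf$coefficients$statistic[match(st, sf$coefficients$term)]
    tibble::tibble(model = f$label, sar_aic = sf$aic, sar_z = z,
                   sar_lambda = sf$lambda)
  })
}

# restrict a spatial_weights object to a subset of cells, re-dropping
# cells isolated within the subset
subset_weights <- function(weights, ids) {
  keep <- weights$cell_id %in% ids
  W <- weights$W[keep, keep, drop = FALSE]
  deg <- rowSums(W)
  W <- W[deg > 0, deg > 0, drop = FALSE]
  structure(
    list(cell_id = rownames(W), W = W,
         excluded_isolates = c(weights$excluded_isolates,
                               setdiff(weights$cell_id[keep], rownames(W))),
         radius = weights$radius),
    class = "spatial_weights"
  )
}

#' Full model battery for one response
#'
#' Convenience wrapper: [build_model_set()] then [moran_for_models()] and —
#' unless the response is a 0/1 significance indicator, for which a linear
#' spatial model is not appropriate — [sar_for_models()], assembled with
#' [summarize_models()].
#'
#' @param data per-cell table with `cell_id`, response and predictors.
#' @param response response column name.
#' @param variables predictor names.
#' @param weights a [neighbor_weights()] object (or `NULL` to skip the
#'   spatial columns).
#' @param family optional family override.
#' @param sar fit the spatial error models (default: not for binomial
#'   indicator responses).
#' @return The report tibble of [summarize_models()].
#' @export
model_battery <- function(data, response, variables, weights = NULL,
                          family = NULL, sar = NULL) {
  fits <- build_model_set(data, response, variables, family)
  if (is.null(sar))
    sar <- default_family(response)$family != "binomial"
  mor <- if (!is.null(weights)) moran_for_models(fits, data, weights)
  sf <- if (!is.null(weights) && sar) sar_for_models(fits, data, weights)
  summarize_models(fits, mor, sf)
}
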
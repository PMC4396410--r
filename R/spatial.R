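#' Distance-band binary spatial weights
#'
#' Cells i and j are neighbors iff `0 < d(i, j) <= radius` on centroid
#' distance; every neighbor relation gets weight 1. For square cells a
#' radius of 1.5 cell sides captures exactly the eight adjoining cells
#' (e.g. 75 km for 50 km cells). Cells with no neighbor within the radius
#' (isolates) are listed and excluded from any analysis using the weights.
#'
#' @param cells tibble with `cell_id`, `centroid_x`, `centroid_y` (a
#'   diversity table works directly).
#' @param radius neighborhood radius in the same length units.
#' @return A `spatial_weights` object: `cell_id` (non-isolates, in input
#'   order), binary symmetric matrix `W`, `excluded_isolates`, `radius`.
#' @export
neighbor_weights <- function(cells, radius) {
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  xy <- cbind(cells$centroid_x, cells$centroid_y)
  d <- as.matrix(stats::dist(xy))
  W <- (d > 0 & d <= radius) * 1
  deg <- rowSums(W)
  isolates <- cells$cell_id[deg == 0]
  keep <- deg > 0
  W <- W[keep, keep, drop = FALSE]
  ids <- cells$cell_id[keep]
  dimnames(W) <- list(ids, ids)
  structure(
    list(cell_id = ids, W = W, excluded_isolates = isolates,
         radius = radius, cache = new.env(parent = emptyenv())),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf(
    "<spatial_weights> %d cells, radius %g, %d links, %d isolates excluded\n",
    length(x$cell_id), x$radius, sum(x$W) / 2, length(x$excluded_isolates)
  ))
  invisible(x)
}

#' Global Moran's I
#'
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2` with `S0 = sum_ij w_ij`; expectation `-1/(n-1)` under no
#' autocorrelation. The p-value uses the normal approximation under the
#' randomization assumption; set `n_perm` for a permutation p-value as
#' well. Values toward 1 mean neighbors share similar values, toward -1
#' that neighbors take opposite values.
#'
#' @param values numeric vector, one per weights cell (aligned to
#'   `weights$cell_id`, or named by cell id).
#' @param weights a [neighbor_weights()] object.
#' @param n_perm optional number of permutations for a permutation p-value.
#' @return A one-row tibble of class `moran_result`: `I, expected, sd,
#'   p, n` (plus `p_perm` when requested).
#' @export
morans_i <- function(values, weights, n_perm = 0) {
  stopifnot(inherits(weights, "spatial_weights"))
  W <- weights$W
  if (!is.null(names(values))) values <- values[weights$cell_id]
  if (length(values) != nrow(W))
    stop("values do not align with weights", call. = FALSE)
  n <- length(values)
  if (n < 3) stop("need at least 3 non-isolate cells", call. = FALSE)
  z <- values - mean(values)
  m2 <- sum(z^2)
  if (m2 == 0) stop("constant input: Moran's I undefined", call. = FALSE)

  S0 <- sum(W)
  I <- (n / S0) * as.numeric(z %*% W %*% z) / m2

  ex <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / m2^2
  v <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
          b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - ex^2
  p <- 2 * pnorm(abs((I - ex) / sqrt(v)), lower.tail = FALSE)

  out <- tibble::tibble(I = I, expected = ex, sd = sqrt(v), p = p, n = n)
  if (n_perm > 0) {
    perm <- replicate(n_perm, {
      zp <- sample(z)
      (n / S0) * as.numeric(zp %*% W %*% zp) / sum(zp^2)
    })
    out$p_perm <- (1 + sum(abs(perm - ex) >= abs(I - ex))) / (n_perm + 1)
  }
  class(out) <- c("moran_result", class(out))
  out
}

#' Maximum-likelihood spatial error regression
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`, `eps ~ N(0, sigma^2 I)`
#' by profile maximum likelihood. The binary weights are row-standardized
#' internally; the log-determinant `ln|I - lambda W|` is evaluated from the
#' precomputed eigenvalues of the (symmetrized) standardized weights, and
#' the concentrated likelihood is maximized over `lambda` within the
#' stationarity bounds `(1/e_min, 1)`.
#'
#' @param formula model formula (gaussian, identity link).
#' @param data per-cell data frame containing `cell_id` and the model
#'   variables; rows are matched to the weights' non-isolate cells and
#'   reduced to complete cases.
#' @param weights a [neighbor_weights()] object.
#' @param lambda_fixed optional value at which to hold `lambda` (0 gives
#'   the OLS fit with its spatial-likelihood bookkeeping).
#' @return A `sar_fit`: `lambda`, `coefficients` tibble (estimate, se, z,
#'   p), `sigma2`, `loglik`, `aic` (`2k - 2 loglik`, `k = p + 2` for
#'   `lambda` and `sigma^2`), `n`, `residuals` (generalized, i.e. the
#'   whitened errors), `cell_id`.
#' @export
fit_sar_err <- function(formula, data, weights, lambda_fixed = NULL) {
  stopifnot(inherits(weights, "spatial_weights"))
  data <- as.data.frame(data)
  rows <- match(weights$cell_id, data$cell_id)
  if (anyNA(rows))
    stop("weights cells missing from data", call. = FALSE)
  data <- data[rows, , drop = FALSE]
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  cc <- stats::complete.cases(mf)
  if (!all(cc)) {
    # keep weights consistent: refit the W sub-block on complete cases
    keep <- which(cc)
    W <- weights$W[keep, keep, drop = FALSE]
    deg <- rowSums(W)
    keep2 <- deg > 0
    W <- W[keep2, keep2, drop = FALSE]
    mf <- mf[keep[keep2], , drop = FALSE]
    ids <- weights$cell_id[keep][keep2]
  } else {
    W <- weights$W
    mf <- mf
    ids <- weights$cell_id
  }
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  if (qr(X)$rank < ncol(X)) stop("singular design matrix", call. = FALSE)

  deg <- rowSums(W)
  Ws <- W / deg
  # eigenvalues of D^{-1/2} W D^{-1/2} equal those of the row-standardized W;
  # cached on the weights object when no rows were dropped, since repeated
  # model fits over the same weights dominate the battery's cost otherwise
  full <- nrow(W) == nrow(weights$W)
  ev <- if (full && !is.null(weights$cache)) get0("ev", weights$cache) else NULL
  if (is.null(ev)) {
    Dm <- 1 / sqrt(deg)
    M <- W * tcrossprod(Dm)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (full && !is.null(weights$cache)) assign("ev", ev, weights$cache)
  }

  conc <- function(lambda) {
    Sy <- y - lambda * (Ws %*% y)
    SX <- X - lambda * (Ws %*% X)
    fit <- stats::lm.fit(SX, Sy)
    s2 <- sum(fit$residuals^2) / n
    ll <- -(n / 2) * (log(2 * pi * s2) + 1) + sum(log(1 - lambda * ev))
    list(ll = ll, beta = fit$coefficients, sigma2 = s2,
         resid = fit$residuals, SX = SX)
  }

  lo <- 1 / min(ev) + 1e-6
  hi <- 1 / max(ev) - 1e-6
  if (is.null(lambda_fixed)) {
    opt <- optimize(function(l) conc(l)$ll, c(lo, hi), maximum = TRUE,
                    tol = 1e-8)
    lambda <- opt$maximum
    if (lambda < lo + 1e-4 || lambda > hi - 1e-4)
      warning("lambda estimate at stationarity boundary", call. = FALSE)
  } else {
    lambda <- lambda_fixed
  }
  at <- conc(lambda)
  covb <- at$sigma2 * solve(crossprod(at$SX))
  se <- sqrt(diag(covb))
  z <- at$beta / se
  coefs <- tibble::tibble(
    term = colnames(X), estimate = unname(at$beta), std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * pnorm(abs(unname(z)), lower.tail = FALSE)
  )
  k <- ncol(X) + 2
  structure(
    list(lambda = lambda, coefficients = coefs, sigma2 = at$sigma2,
         loglik = at$ll, aic = 2 * k - 2 * at$ll, n = n, k = k,
         residuals = as.numeric(at$resid), cell_id = ids,
         formula = formula),
    class = "sar_fit"
  )
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("<sar_fit> lambda %.4f, sigma2 %.4g, loglik %.2f, AIC %.2f, n %d\n",
              x$lambda, x$sigma2, x$loglik, x$aic, x$n))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.sar_fit <- function(x, ...) x$coefficients

#' @export
glance.sar_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, sigma2 = x$sigma2, logLik = x$loglik,
                 AIC = x$aic, nobs = x$n)
}
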
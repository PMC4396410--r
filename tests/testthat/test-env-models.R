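
test_that("poisson GLM on a binary covariate matches the closed form", {
  set.seed(3)
  d <- tibble::tibble(
    g = rep(0:1, each = 100),
    richness = c(rpois(100, 4), rpois(100, 9))
  )
  m0 <- mean(d$richness[d$g == 0])
  m1 <- mean(d$richness[d$g == 1])
  f <- glm(richness ~ g, poisson(), d)
  expect_equal(unname(coef(f)), c(log(m0), log(m1 / m0)), tolerance = 1e-8)

  # the package's wrapper agrees with stats::glm on the same design
  spec <- model_spec("richness", "g", "single", poisson())
  d$g <- as.numeric(scale(d$g))
  fit <- fit_glm(spec, d)
  ref <- glm(richness ~ g, poisson(), d)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-10)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-10)
})

test_that("gaussian GLM equals OLS and intercept-only explains nothing", {
  d <- make_model_data(120)
  fit <- fit_glm(model_spec("y_gauss", "env1", family = gaussian()), d)
  ds <- dplyr::mutate(d, env1 = as.numeric(scale(env1)))
  ols <- lm(y_gauss ~ env1, ds)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-10)

  f0 <- glm(y_gauss ~ 1, gaussian(), d)
  expect_equal(100 * (1 - f0$deviance / f0$null.deviance), 0)
})

test_that("fit_glm reports DE%, Wald z and the slope convention", {
  d <- make_model_data(200)
  fit <- fit_glm(model_spec("richness", "env1"), d)
  expect_equal(fit$spec$family$family, "poisson")
  expect_true(fit$de_pct > 0 && fit$de_pct <= 100)
  expect_equal(fit$slope_sign, "+")
  expect_equal(fit$wald_z,
               fit$coefficients$statistic[fit$coefficients$term == "env1"])

  # additive: slope is the second main effect; interaction: the product term
  add <- fit_glm(model_spec("richness", c("env1", "env2"), "additive"), d)
  expect_equal(add$slope_sign,
               if (add$coefficients$estimate[3] >= 0) "+" else "-")
  int <- fit_glm(model_spec("richness", c("env1", "env2"), "interaction"), d)
  expect_true("env1:env2" %in% int$coefficients$term)
})

test_that("gamma responses exclude non-positive cells with a count", {
  d <- make_model_data(150)
  d$margalef <- d$richness / log(d$richness * 3)  # strictly positive
  d$margalef[1:5] <- 0
  fit <- fit_glm(model_spec("margalef", "env1"), d)
  expect_equal(fit$n_nonpositive, 5L)
  expect_equal(fit$n, 145L)
})

test_that("build_model_set yields the single/pair combinatorics", {
  d <- make_model_data(260)
  # add noise variables up to 11
  set.seed(8)
  for (v in paste0("nv", 1:8)) d[[v]] <- rnorm(nrow(d))
  vars11 <- c("env1", "env2", "env3", paste0("nv", 1:8))
  ms <- build_model_set(d, "richness", vars11)
  expect_equal(nrow(ms), 31)   # 11 singles + 10 additive + 10 interaction
  expect_equal(sum(ms$kind == "single"), 11)
  expect_equal(sum(ms$kind == "additive"), 10)
  expect_equal(sum(ms$kind == "interaction"), 10)
  expect_equal(ms$delta_aic[1], 0)
  expect_true(!is.unsorted(ms$aic))

  # informative variable makes the top-5 cut and wins
  expect_true(grepl("env1", ms$model[1]))

  ms2 <- suppressMessages(build_model_set(d, "richness", c("env1", "env2")))
  expect_equal(nrow(ms2), 4)   # 2 singles + 1 additive + 1 interaction
  ms1 <- build_model_set(d, "richness", "env1")
  expect_equal(nrow(ms1), 1)
})

test_that("equivalence_class applies the inclusive AIC window", {
  fits <- tibble::tibble(model = c("a", "b", "c"),
                         delta_aic = c(0, 2, 5))
  expect_equal(equivalence_class(fits)$model, c("a", "b"))
  expect_equal(equivalence_class(fits[1, ])$model, "a")
  fits$delta_aic <- c(0, 3, 5)
  expect_equal(equivalence_class(fits)$model, c("a", "b"))
})

test_that("poisson recovery: fitted slope covers the simulated effect", {
  hits <- vapply(1:20, function(r) {
    d <- make_model_data(300, beta = 0.5, seed = 400 + r)
    # a clean log-linear response (richness in the helper is shifted by 1)
    d$richness <- rpois(nrow(d), exp(1.5 + 0.5 * d$env1))
    fit <- fit_glm(model_spec("richness", "env1"), d)
    est <- fit$coefficients$estimate[2]
    se <- fit$coefficients$std.error[2]
    # predictors are z-scored inside fit_glm; rescale the true effect
    truth <- 0.5 * sd(d$env1)
    abs(est - truth) <= 3 * se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the report table assembles GLM, Moran and SAR columns", {
  d <- make_model_data(144)
  w <- neighbor_weights(d, 1.5)
  rep_tab <- model_battery(d, "richness", c("env1", "env2", "env3"), w) |>
    suppressMessages()
  expect_equal(nrow(rep_tab), 9)  # 3 singles + 3 additive + 3 interaction
  expect_true(all(c("glm_aic", "glm_delta_aic", "de_pct", "wald_p", "slope",
                    "moran_i", "moran_p", "sar_aic", "sar_delta_aic",
                    "sar_z") %in% names(rep_tab)))
  expect_equal(min(rep_tab$glm_delta_aic), 0)
  expect_equal(min(rep_tab$sar_delta_aic), 0)
  expect_true(!is.unsorted(rep_tab$sar_delta_aic))
  expect_true(all(rep_tab$slope %in% c("+", "-")))

  # indicator battery: binomial family, no SAR columns
  set.seed(5)
  d$pd_high <- rbinom(nrow(d), 1, plogis(-2 + d$env1))
  rep_hi <- suppressMessages(
    model_battery(d, "pd_high", c("env1", "env2"), w))
  expect_false("sar_aic" %in% names(rep_hi))
  expect_equal(nrow(rep_hi), 4)
})

test_that("missing environment cells are excluded and counted", {
  d <- make_model_data(150)
  d$env1[1:7] <- NA
  fit <- fit_glm(model_spec("richness", "env1"), d)
  expect_equal(fit$n_missing_env, 7L)
  expect_equal(fit$n, 143L)
})
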
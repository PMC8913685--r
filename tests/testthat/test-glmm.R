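test_that("the gamma GLMM fit is coherent and recovers the small truth", {
  sf <- small_fit()
  fit <- sf$fit
  # parameter bookkeeping: fixed effects (incl. intercept) + 3 random-effect
  # parameters + gamma shape
  expect_equal(fit$n_params, length(fit$beta) + 3L + 1L)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik, tolerance = 1e-8)
  # random-effect covariance is symmetric PSD
  expect_equal(fit$re_cov, t(fit$re_cov))
  expect_true(all(eigen(fit$re_cov, symmetric = TRUE)$values > -1e-10))
  # truth recovery on the frozen simulation scale
  nw <- small_network()
  tb <- c("(Intercept)" = nw$truth$intercept, truth_beta(nw$truth))
  cover <- abs(fit$beta[names(tb)] - tb) <= 3 * fit$se[names(tb)]
  expect_gte(mean(cover), 0.9)
  expect_equal(fit$gamma_shape, nw$truth$gamma_shape, tolerance = 0.35)
})

test_that("the Laplace likelihood matches dense quadrature on a tiny instance", {
  set.seed(21)
  n_tree <- 2L; n_obs <- 10L
  tree <- factor(rep(c("a", "b"), each = n_obs))
  x <- rnorm(n_tree * n_obs)
  z <- rnorm(n_tree * n_obs)
  Sigma <- matrix(c(0.09, 0.012, 0.012, 0.04), 2)
  b <- MASS::mvrnorm(n_tree, c(0, 0), Sigma)
  eta <- 2 + 0.3 * x + b[as.integer(tree), 1] + b[as.integer(tree), 2] * z
  y <- rgamma(n_tree * n_obs, shape = 10, rate = 10 / exp(eta))
  design <- list(y = y, X = matrix(x, dimnames = list(NULL, "x")),
                 tree = tree, ba_z = z,
                 col_info = data.frame(name = "x", kind = "main",
                                       block = "cli", groups = "cli"),
                 scaler = NULL, spec = NULL)
  fit <- suppressWarnings(fit_glmm(design, on_nonconvergence = "warning"))
  ll_quad <- marginal_loglik_quadrature(
    y = y, X = matrix(x), intercept = fit$beta[["(Intercept)"]],
    beta = fit$beta[["x"]], tree = tree, slope_z = z,
    Sigma = fit$re_cov, shape = fit$gamma_shape, n_nodes = 50L)
  expect_equal(fit$loglik, ll_quad, tolerance = 1e-3)
})

test_that("the model ladder orders, tests and labels nested models", {
  sf <- small_fit()
  cmp <- suppressWarnings(compare_models(sf$design))
  expect_equal(nrow(cmp), 8L)
  expect_equal(cmp$delta_aic, cmp$aic - min(cmp$aic))
  expect_true(any(cmp$delta_aic == 0))
  null_row <- cmp[cmp$model == "Null model", ]
  expect_true(is.na(null_row$chisq))
  full_row <- cmp[cmp$model == "Full model", ]
  expect_equal(full_row$df,
               full_row$n_params - null_row$n_params)
  expect_true(full_row$p < 0.05)  # strong true effects in the fixture
  # chi-square equals twice the log-likelihood gain, by definition
  expect_equal(full_row$chisq, 2 * (full_row$loglik - null_row$loglik),
               tolerance = 1e-8)
})

test_that("a model compared with itself gives chisq 0 on df 0", {
  sf <- small_fit()
  res <- suppressWarnings(lrt_block(sf$design, drop = character(0)))
  expect_equal(res$chisq, 0, tolerance = 1e-6)
  expect_equal(res$df, 0L)
})

test_that("dropping a block removes exactly its columns from the fit", {
  sf <- small_fit()
  res <- suppressWarnings(lrt_block(sf$design, drop = "cli"))
  n_cli <- sum(sf$design$col_info$groups == "cli")
  expect_equal(res$df, n_cli)
  expect_error(lrt_block(sf$design, drop = "cli", groups = c("ai", "geo")),
               "not nested")
})

test_that("population-level prediction at the training mean is exp(intercept)", {
  nw <- small_network()
  # data-driven scaler and a linear basis: a row at the training mean of
  # every variable maps to an all-zero design row
  des <- build_design(nw$bai, nw$seasonal, nw$sites, nw$truth$spec)
  fit <- suppressWarnings(fit_glmm(des))
  vs <- des$scaler$var
  newdata <- as.data.frame(as.list(setNames(vs$mean, vs$name)))
  # invert the variable-level transforms (log for ai/pp)
  newdata$ai <- exp(newdata$ai)
  for (v in grep("^pp_", names(newdata), value = TRUE))
    newdata[[v]] <- exp(newdata[[v]]) - nw$truth$spec$pp_offset
  pred <- predict_bai(fit, newdata, ba_fixed = newdata$ba_prev)
  expect_equal(pred, exp(fit$beta[["(Intercept)"]]), tolerance = 1e-8)
})

test_that("perturbing one coefficient moves log-predictions by delta * x", {
  sf <- small_fit()
  nw <- small_network()
  newdata <- data.frame(ai = c(25, 40), lat = c(40, 55), alt = c(100, 1200),
                        tmax_WIN = c(3, 1), tmax_SUM = c(22, 17),
                        tmin_WIN = c(-2, -5), tmin_SUM = c(12, 9),
                        pp_WIN = c(200, 300), pp_SUM = c(250, 400),
                        ba_prev = 20000)
  p0 <- predict_bai(sf$fit, newdata)
  m2 <- sf$fit
  delta <- 0.1
  m2$beta[["pp_SUM"]] <- m2$beta[["pp_SUM"]] + delta
  p1 <- predict_bai(m2, newdata)
  dm <- baigrowth:::.design_matrix(newdata, sf$fit$spec, scaler = sf$fit$scaler)
  expect_equal(log(p1) - log(p0), delta * dm$X[, "pp_SUM"], tolerance = 1e-10)
})

test_that("BLUP-level predictions track observed growth more closely", {
  nw <- small_network()
  sf <- small_fit()
  wide_rows <- nw$sim$bai
  newdata <- data.frame(
    ai = nw$sites$ai[match(wide_rows$site_id, nw$sites$site_id)],
    lat = nw$sites$lat[match(wide_rows$site_id, nw$sites$site_id)],
    alt = nw$sites$alt[match(wide_rows$site_id, nw$sites$site_id)],
    ba_prev = wide_rows$ba_prev)
  wide <- baigrowth:::.seasonal_wide(nw$seasonal, sf$fit$spec$seasons,
                                     sf$fit$spec$climate_vars)
  i <- match(paste(wide_rows$site_id, wide_rows$year),
             paste(wide$site_id, wide$year))
  for (v in setdiff(names(wide), c("site_id", "year"))) newdata[[v]] <- wide[[v]][i]
  tree <- paste(wide_rows$site_id, wide_rows$tree_code, sep = "/")
  p_pop <- predict_bai(sf$fit, newdata)
  p_blup <- predict_bai(sf$fit, newdata, population_level = FALSE, tree = tree)
  expect_true(all(p_pop > 0) && all(p_blup > 0))
  rmse <- function(p) sqrt(mean((log(wide_rows$bai) - log(p))^2))
  expect_lt(rmse(p_blup), rmse(p_pop))
  expect_error(predict_bai(sf$fit, newdata, population_level = FALSE,
                           tree = rep("nope", nrow(newdata))), "unknown tree")
})

test_that("predictions are positive and monotone in a positive-coefficient input", {
  sf <- small_fit()
  stopifnot(sf$fit$beta[["pp_SUM"]] > 0)  # truth 0.1, well identified
  newdata <- data.frame(ai = 30, lat = 48, alt = 500,
                        tmax_WIN = 2, tmax_SUM = 20, tmin_WIN = -3,
                        tmin_SUM = 11, pp_WIN = 250,
                        pp_SUM = seq(50, 600, by = 50), ba_prev = 15000)
  p <- predict_bai(sf$fit, newdata)
  expect_true(all(p > 0))
  expect_true(all(diff(p) > 0))
})
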
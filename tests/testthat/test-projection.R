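test_that("grid prediction equals a per-pixel prediction loop", {
  nw <- small_network()
  sf <- small_fit()
  seas <- nw$seasonal[nw$seasonal$year %in% 2005:2010, ]
  grid <- predict_grid(sf$fit, seas, nw$sites, ba_fixed = 20000)
  expect_true(all(grid$bai > 0))
  wide <- baigrowth:::.seasonal_wide(seas, sf$fit$spec$seasons,
                                     sf$fit$spec$climate_vars)
  for (j in sample(nrow(grid), 10)) {
    row <- grid[j, ]
    w <- wide[wide$site_id == row$site_id & wide$year == row$year, ]
    meta <- nw$sites[nw$sites$site_id == row$site_id, ]
    nd <- cbind(meta[c("ai", "lat", "alt")],
                w[setdiff(names(w), c("site_id", "year"))])
    expect_equal(row$bai, predict_bai(sf$fit, nd, ba_fixed = 20000),
                 tolerance = 1e-10)
  }
  # identical climate and geography give identical predictions
  sites2 <- nw$sites[c(1, 1), ]
  sites2$site_id <- c("P1", "P2")
  seas2 <- seas[seas$site_id == nw$sites$site_id[1], ]
  seas2 <- rbind(transform(seas2, site_id = "P1"),
                 transform(seas2, site_id = "P2"))
  g2 <- predict_grid(sf$fit, seas2, sites2, ba_fixed = 20000)
  expect_equal(g2$bai[g2$site_id == "P1"], g2$bai[g2$site_id == "P2"])
})

test_that("period means are inclusive-endpoint arithmetic means", {
  g <- expand.grid(site_id = c("P1", "P2"), year = 1950:2016)
  g$bai <- 7
  class(g) <- c("prediction_grid", "data.frame")
  pm <- period_mean(g, c(1955, 1985))
  expect_equal(pm$mean_bai, c(7, 7))
  expect_equal(attr(pm, "n_years"), 31L)
  # brute-force oracle on an arbitrary series
  g$bai <- seq_len(nrow(g))
  pm2 <- period_mean(g, c(1986, 2016))
  for (p in c("P1", "P2")) {
    sel <- g$site_id == p & g$year >= 1986 & g$year <= 2016
    expect_equal(pm2$mean_bai[pm2$site_id == p], sum(g$bai[sel]) / 31)
  }
  expect_error(period_mean(g[g$year > 1960, ], c(1955, 1985)),
               "not fully covered")
})

test_that("percent change matches its definition and swap identity", {
  expect_equal(percent_change(100, 80), -20)
  expect_equal(percent_change(50, 75), 50)
  expect_equal(percent_change(123.4, 123.4), 0)
  expect_error(percent_change(0, 10), "> 0")
  set.seed(3)
  a <- runif(50, 10, 100); b <- runif(50, 10, 100)
  pc <- percent_change(a, b)
  expect_equal(percent_change(b, a), -100 * pc / (100 + pc), tolerance = 1e-9)
})

test_that("the applicability domain equals a brute-force range check", {
  nw <- small_network()
  train <- nw$seasonal
  set.seed(4)
  fut <- train[train$year == 2010, ]
  fut$tmax_mean <- fut$tmax_mean + rnorm(nrow(fut), 0, 3)
  fut$pp_sum <- pmax(0, fut$pp_sum + rnorm(nrow(fut), 0, 150))
  mask <- applicability_domain(train, fut)
  # independent per-cell double loop
  for (pix in mask$pixels$site_id) {
    rows <- fut[fut$site_id == pix, ]
    outside <- FALSE
    for (v in c("tmax_mean", "tmin_mean", "pp_sum")) for (k in seq_len(nrow(rows))) {
      tr <- train[train$season == rows$season[k], v]
      if (rows[[v]][k] > max(tr) || rows[[v]][k] < min(tr)) outside <- TRUE
    }
    expect_equal(!outside, mask$pixels$inside[mask$pixels$site_id == pix])
  }
  # identity: the training set is inside its own domain
  m0 <- applicability_domain(train, train)
  expect_true(all(m0$pixels$inside))
  expect_equal(nrow(m0$violations), 0L)
  expect_error(applicability_domain(train[0, ], fut), "empty")
})

test_that("a constructed exceedance is flagged with variable, season, side", {
  nw <- small_network()
  train <- nw$seasonal
  fut <- train[train$year == 2012 & train$site_id %in% nw$sites$site_id[1:3], ]
  hi <- max(train$tmax_mean[train$season == "SUM"])
  k <- which(fut$season == "SUM")[1]
  fut$tmax_mean[k] <- hi + 0.1
  mask <- applicability_domain(train, fut)
  bad_pix <- fut$site_id[k]
  expect_false(mask$pixels$inside[mask$pixels$site_id == bad_pix])
  v <- mask$violations
  expect_equal(nrow(v), 1L)
  expect_equal(v$variable, "tmax_mean")
  expect_equal(v$season, "SUM")
  expect_equal(v$direction, "above")
})

test_that("enlarging the training set never moves a pixel outside", {
  nw <- small_network()
  train_small <- nw$seasonal[nw$seasonal$year <= 2005, ]
  train_big <- nw$seasonal
  fut <- nw$seasonal[nw$seasonal$year >= 2014, ]
  fut$tmax_mean <- fut$tmax_mean + 1.5
  m_small <- applicability_domain(train_small, fut)
  m_big <- applicability_domain(train_big, fut)
  i <- match(m_small$pixels$site_id, m_big$pixels$site_id)
  expect_true(all(m_big$pixels$inside[i] >= m_small$pixels$inside))
})

test_that("scenario projection yields six maps and is exact at zero delta", {
  nw <- small_network()
  sf <- small_fit()
  baseline <- nw$seasonal[nw$seasonal$year >= 1991 & nw$seasonal$year <= 2016, ]
  ens0 <- generate_scenario_ensemble(nw$sites, magnitude = 0, seed = 11)
  proj <- run_scenarios(sf$fit, baseline, nw$sites, ens0, nw$seasonal,
                        baseline_window = c(1991L, 2016L), ba_fixed = 20000)
  expect_length(proj, 6L)
  for (el in proj) {
    expect_equal(el$change$pct_change, rep(0, nrow(el$change)))
    expect_true(all(el$ad$pixels$inside))
  }
  # a missing combination is an error
  ens_partial <- ens0
  ens_partial[["SSP5-8.5"]][["2060-2090"]] <- NULL
  expect_error(run_scenarios(sf$fit, baseline, nw$sites, ens_partial,
                             nw$seasonal, baseline_window = c(1991L, 2016L)),
               "missing delta set")
})

test_that("uniform warming moves growth in the direction of the local slope", {
  nw <- small_network()
  sf <- small_fit()
  baseline <- nw$seasonal[nw$seasonal$year >= 1991, ]
  # shift only summer tmax, whose fitted total effect is negative in the
  # fixture truth; prediction change must be negative at every pixel
  delta <- data.frame(expand.grid(site_id = nw$sites$site_id,
                                  season = c("pSUM", "pAUT", "WIN",
                                             "SPR", "SUM", "AUT"),
                                  stringsAsFactors = FALSE),
                      dtmax = 0, dtmin = 0, dpp = 0)
  delta$dtmax[delta$season == "SUM"] <- 2
  shifted <- apply_delta(baseline, delta)
  g0 <- predict_grid(sf$fit, baseline, nw$sites, ba_fixed = 20000)
  g1 <- predict_grid(sf$fit, shifted, nw$sites, ba_fixed = 20000)
  stopifnot(sf$fit$beta[["tmax_SUM"]] < 0)
  expect_true(all(g1$bai < g0$bai))
})
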
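make_monthly <- function(years, site = "S1", tmax = 10, tmin = 2, prcp = 50) {
  g <- expand.grid(month = 1:12, year = years)
  data.frame(site_id = site, year = g$year, month = g$month,
             tmax = tmax, tmin = tmin, prcp = prcp)
}

test_that("seasonal aggregation averages temperature and sums precipitation", {
  m <- make_monthly(1999:2001)
  m$tmax[m$year == 2000 & m$month %in% 1:2] <- c(2, 3)
  m$tmax[m$year == 1999 & m$month == 12] <- 1
  m$prcp[m$year == 2000 & m$month %in% 6:8] <- c(10, 20, 30)
  s <- aggregate_seasons(m)
  win <- s[s$year == 2000 & s$season == "WIN", ]
  expect_equal(win$tmax_mean, 2)  # mean of Dec(1), Jan(2), Feb(3)
  expect_equal(s$pp_sum[s$year == 2000 & s$season == "SUM"], 60)
  # previous-year seasons are re-keyed to the ring year
  expect_equal(s$pp_sum[s$year == 2001 & s$season == "pSUM"], 60)
})

test_that("incomplete seasons are omitted, not filled", {
  s <- aggregate_seasons(make_monthly(2000))
  # one isolated year: WIN lacks Dec 1999 -> only SPR/SUM/AUT for 2000,
  # plus pSUM/pAUT re-keyed to 2001
  expect_setequal(paste(s$year, s$season),
                  c("2000 SPR", "2000 SUM", "2000 AUT",
                    "2001 pSUM", "2001 pAUT"))
  expect_equal(nrow(s), 5L)
})

test_that("De Martonne index matches direct evaluation and its domain", {
  expect_equal(de_martonne(500, 10), 25)
  expect_equal(de_martonne(0, 5), 0)
  expect_equal(de_martonne(1200, 8.6), 1200 / 18.6)
  expect_equal(as.character(classify_aridity(de_martonne(1200, 8.6))),
               "extremely humid")
  expect_error(de_martonne(500, -10), "domain|index")
  expect_error(de_martonne(-1, 5), "negative")
})

test_that("De Martonne index is increasing in P and decreasing in T", {
  p <- seq(0, 2000, by = 100)
  expect_true(all(diff(de_martonne(p, 7)) > 0))
  tt <- seq(-5, 25, by = 0.5)
  expect_true(all(diff(de_martonne(800, tt)) < 0))
})

test_that("aridity classes tile [0, Inf) with lower-inclusive boundaries", {
  expect_equal(as.character(classify_aridity(15)), "semi-arid")
  expect_equal(as.character(classify_aridity(0)), "arid")
  # each boundary belongs to the upper class
  bnd <- c(10, 20, 24, 28, 35, 55)
  expect_equal(as.character(classify_aridity(bnd)),
               c("semi-arid", "Mediterranean", "semi-humid", "humid",
                 "very humid", "extremely humid"))
  # totality and uniqueness on random values
  set.seed(1)
  x <- c(runif(500, 0, 80), bnd, bnd - 1e-9)
  cl <- classify_aridity(x)
  expect_false(anyNA(cl))
  expect_error(classify_aridity(-0.1), "negative")
})

test_that("site aridity is the mean of annual indices", {
  m <- make_monthly(1990:1999, tmax = 14, tmin = 6, prcp = 50)
  # T = 10, P = 600 every year -> AI = 30 each year and on average
  ai <- site_mean_ai(m, window = c(1990, 1999))
  expect_equal(ai$ai, 30)
  # two years with AI 20 and 40 average to 30
  m2 <- rbind(make_monthly(2000, tmax = 14, tmin = 6, prcp = 400 / 12),
              make_monthly(2001, tmax = 14, tmin = 6, prcp = 800 / 12))
  ai2 <- site_mean_ai(m2, window = c(2000, 2001))
  expect_equal(ai2$ai, 30, tolerance = 1e-9)
  expect_error(site_mean_ai(m, window = c(1900, 1901)), "window")
})

test_that("site aridity equals a brute-force year loop on generated climate", {
  nw <- small_network()
  got <- site_mean_ai(nw$climate, window = c(1995, 2016))
  for (sid in nw$sites$site_id[1:3]) {
    vals <- sapply(1995:2016, function(y) {
      mm <- nw$climate[nw$climate$site_id == sid & nw$climate$year == y, ]
      de_martonne(sum(mm$prcp), mean((mm$tmax + mm$tmin) / 2))
    })
    expect_equal(got$ai[got$site_id == sid], mean(vals), tolerance = 1e-10)
  }
})

test_that("ensemble mean delta averages members per cell", {
  base <- data.frame(site_id = rep(c("P1", "P2"), each = 6),
                     season = rep(c("pSUM", "pAUT", "WIN", "SPR", "SUM", "AUT"), 2))
  mk <- function(v) data.frame(base, dtmax = v, dtmin = v / 2)
  mkp <- function(v) data.frame(base, dpp = v)
  em <- ensemble_mean_delta(list(mk(1), mk(3)), list(mkp(-2), mkp(4), mkp(1)))
  expect_equal(unique(em$dtmax), 2)
  expect_equal(unique(em$dtmin), 1)
  expect_equal(unique(em$dpp), 1)
  # a single member is its own mean
  em1 <- ensemble_mean_delta(list(mk(1.5)), list(mkp(7)))
  expect_equal(unique(em1$dtmax), 1.5)
  expect_equal(unique(em1$dpp), 7)
  # mismatched location sets are rejected
  bad <- mk(1); bad$site_id[1] <- "P9"
  expect_error(ensemble_mean_delta(list(mk(1), bad), list(mkp(0))),
               "mismatched")
})

test_that("generated ensembles average to the per-cell loop mean", {
  sites <- generate_sites(5, seed = 9)
  ens <- generate_scenario_ensemble(sites, scenarios = "SSP5-8.5",
                                    future_windows = list(c(2040L, 2070L)),
                                    seed = 9)
  memb <- ens[["SSP5-8.5"]][["2040-2070"]]
  expect_length(memb$temp_members, 21L)
  expect_length(memb$precip_members, 26L)
  em <- ensemble_mean_delta(memb$temp_members, memb$precip_members)
  # brute-force mean over members for a handful of cells
  ref <- memb$temp_members[[1]][order(memb$temp_members[[1]]$site_id,
                                      memb$temp_members[[1]]$season), ]
  for (j in c(1, 10, 25)) {
    cell <- ref[j, c("site_id", "season")]
    vals <- vapply(memb$temp_members, function(m)
      m$dtmax[m$site_id == cell$site_id & m$season == cell$season],
      numeric(1))
    expect_equal(em$dtmax[em$site_id == cell$site_id & em$season == cell$season],
                 mean(vals), tolerance = 1e-12)
  }
})

test_that("delta application shifts, floors precipitation and is identity at zero", {
  nw <- small_network()
  base <- nw$seasonal[nw$seasonal$year %in% 2010:2012, ]
  zero <- data.frame(expand.grid(site_id = unique(base$site_id),
                                 season = levels(base$season),
                                 stringsAsFactors = FALSE),
                     dtmax = 0, dtmin = 0, dpp = 0)
  expect_equal(apply_delta(base, zero), base)
  plus2 <- zero; plus2$dtmax <- 2
  shifted <- apply_delta(base, plus2)
  expect_equal(shifted$tmax_mean, base$tmax_mean + 2)
  expect_equal(shifted$pp_sum, base$pp_sum)
  # precipitation floored at zero
  drown <- zero; drown$dpp <- -1e6
  expect_true(all(apply_delta(base, drown)$pp_sum == 0))
  expect_error(apply_delta(base, zero[zero$site_id != base$site_id[1], ]),
               "misalignment")
})
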
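window_fixture <- function(n_sites, n_countries, years_per_site,
                           span = 1990:2005) {
  site_years <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
    data.frame(site_id = sprintf("s%03d", i),
               year = sort(sample(span, years_per_site)))
  }))
  site_country <- stats::setNames(
    paste0("c", rep(seq_len(n_countries), length.out = n_sites)),
    sprintf("s%03d", seq_len(n_sites)))
  list(site_years = site_years, site_country = site_country)
}

test_that("window eligibility applies exact integer thresholds", {
  set.seed(109)
  # 300 qualifying sites from 9 countries -> window retained
  fx <- window_fixture(300, 9, 8, span = 1990:1999)
  bw <- build_windows(fx$site_years, fx$site_country,
                      start = 1990, end = 1999)
  expect_equal(nrow(bw$windows), 1L)
  expect_equal(bw$windows$n_sites, 300L)
  expect_equal(bw$total_segments, 300L)
  # 249 sites -> dropped (strict "at least 250")
  fx2 <- window_fixture(249, 9, 8, span = 1990:1999)
  bw2 <- build_windows(fx2$site_years, fx2$site_country,
                       start = 1990, end = 1999)
  expect_equal(nrow(bw2$windows), 0L)
  expect_equal(bw2$all_windows$n_sites, 249L)
  # 7 countries -> dropped even with many sites
  fx3 <- window_fixture(300, 7, 8, span = 1990:1999)
  bw3 <- build_windows(fx3$site_years, fx3$site_country,
                       start = 1990, end = 1999)
  expect_equal(nrow(bw3$windows), 0L)
})

test_that("a site needs >= 6 sampling years inside the window", {
  site_years <- rbind(
    data.frame(site_id = "rich", year = 1990:1997),   # 8 years inside
    data.frame(site_id = "poor", year = c(1990:1994)) # 5 years inside
  )
  sc <- c(rich = "c1", poor = "c2")
  bw <- build_windows(site_years, sc, min_sites = 1, min_countries = 1,
                      start = 1990, end = 1999)
  expect_equal(bw$windows$n_sites[1], 1L)   # only "rich" qualifies
})

test_that("window labels use the centre convention", {
  set.seed(113)
  fx <- window_fixture(10, 3, 8, span = 1990:1999)
  bw <- build_windows(fx$site_years, fx$site_country, min_sites = 5,
                      min_countries = 2, start = 1990, end = 1999)
  expect_equal(bw$windows$label, 1994L)       # 1990-1999 centres on 1994
  bws <- build_windows(fx$site_years, fx$site_country, min_sites = 5,
                       min_countries = 2, start = 1990, end = 1999,
                       label = "start")
  expect_equal(bws$windows$label, 1990L)
})

test_that("segment bookkeeping is exact over multiple windows", {
  set.seed(127)
  fx <- window_fixture(40, 4, 12, span = 1990:2004)
  bw <- build_windows(fx$site_years, fx$site_country, min_sites = 10,
                      min_countries = 2)
  expect_equal(bw$total_segments,
               sum(bw$windows$n_sites))
  expect_equal(nrow(bw$windows), sum(bw$all_windows$eligible))
})

test_that("weighted proportion positive matches the hand calculation", {
  # studies: A has one certainly-positive site, B one certainly-negative,
  # C two sites, one of each sign -> weighted proportion 1.5/3 = 0.5
  st <- data.frame(
    site_id = c("a1", "b1", "c1", "c2"),
    post_mean = c(5, -5, 5, -5), post_sd = rep(1e-6, 4),
    study_id = c("A", "B", "C", "C"), stringsAsFactors = FALSE)
  pp <- proportion_positive(st, n_draws = 500, seed = 1)
  expect_equal(pp$proportion, 0.5, tolerance = 1e-9)
  expect_equal(pp$expected, 0.5, tolerance = 1e-9)
  # all certainly positive: proportion 1, zero-width intervals
  st2 <- st; st2$post_mean <- abs(st2$post_mean)
  pp2 <- proportion_positive(st2, n_draws = 500, seed = 1)
  expect_equal(pp2$proportion, 1)
  expect_equal(unname(pp2$intervals["95%", "upper"] -
                        pp2$intervals["95%", "lower"]), 0)
  # draw-based estimate vs exact Gaussian orthant probabilities
  set.seed(131)
  st3 <- data.frame(
    site_id = paste0("s", 1:5),
    post_mean = stats::rnorm(5, 0.1, 0.3),
    post_sd = stats::runif(5, 0.1, 0.4),
    study_id = c("A", "A", "B", "C", "C"), stringsAsFactors = FALSE)
  pp3 <- proportion_positive(st3, n_draws = 40000, seed = 2)
  expect_equal(pp3$proportion, pp3$expected, tolerance = 0.01)
})

test_that("trajectory regression recovers linear change in window means", {
  # exactly linear window means with tiny se
  wr <- data.frame(label = 1994:2005,
                   mean = 0.5 - 0.03 * (0:11), se = 1e-5)
  tc <- trajectory_change(wr)
  expect_equal(tc$slope, -0.03, tolerance = 1e-6)
  expect_lt(tc$intervals["95%", "upper"], 0)
  # constant means -> slope ~ 0
  set.seed(137)
  wr2 <- data.frame(label = 1994:2005, mean = 0.2 +
                      stats::rnorm(12, 0, 0.001), se = 0.02)
  tc2 <- trajectory_change(wr2)
  expect_lt(abs(tc2$slope), 0.005)
  expect_error(trajectory_change(wr2[1:2, ]))
})

test_that("window meta matches the overall meta when the window covers
           the whole series", {
  set.seed(139)
  metrics <- do.call(rbind, lapply(1:20, function(i) {
    yrs <- sort(sample(1995:2004, 8))
    data.frame(site_id = sprintf("s%02d", i), metric = "richness",
               year = yrs, value = sim_ar1(yrs, 0.1, 0.3, 0.4, 20),
               stringsAsFactors = FALSE)
  }))
  site_info <- data.frame(
    site_id = sprintf("s%02d", 1:20),
    study_id = paste0("st", rep(1:5, each = 4)),
    country = paste0("c", rep(1:4, each = 5)), stringsAsFactors = FALSE)
  window <- data.frame(start = 1995, end = 2004, label = 1999)
  wm <- window_meta(metrics, window, unique(metrics$site_id), site_info,
                    min_years = 8L)
  # site trends refit on the full extent equal the full-series fits
  full <- fit_all_trends(metrics, min_obs = 8L)
  merged <- merge(wm$site_trends, full, by = "site_id")
  expect_equal(merged$slope.x, merged$slope.y, tolerance = 1e-9)
  overall <- fit_meta(merge(full, site_info, by = "site_id"))
  expect_equal(wm$meta$mean, overall$mean, tolerance = 1e-9)
})
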
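small_cfg <- function(...) {
  sim_config(n_sites = 12, n_studies = 5, n_countries = 3,
             species_pool = 40, mean_richness = 12, ...)
}

test_that("identical (config, seed) give identical output", {
  a <- generate_dataset(small_cfg(), seed = 5)
  b <- generate_dataset(small_cfg(), seed = 5)
  expect_identical(a$community, b$community)
  expect_identical(a$traits$affinities, b$traits$affinities)
  expect_identical(a$truth, b$truth)
  c <- generate_dataset(small_cfg(), seed = 6)
  expect_false(identical(a$community, c$community))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_studies = 10, n_sites = 5))
  expect_error(sim_config(rho = 1.2))
  expect_error(sim_config(sd_study_pct = -1))
  expect_error(sim_config(nonsense_field = 1), "unknown config")
})

test_that("sampling-year counts respect the configured bounds", {
  sim <- generate_dataset(sim_config(n_sites = 80, n_studies = 10,
                                     n_countries = 4, species_pool = 30,
                                     mean_richness = 8), seed = 9)
  ny <- sim$site_metadata$n_sampling_years
  expect_true(all(ny >= 8 & ny <= 32))
  yrs <- as.integer(format(sim$community$date, "%Y"))
  expect_true(all(yrs >= 1968 & yrs <= 2020))
})

test_that("zero noise and zero trend give exactly flat fitted slopes", {
  cfg <- small_cfg(trend_mean_pct = 0, sd_study_pct = 0,
                   sd_country_pct = 0, sd_site_pct = 0, sigma_year = 0,
                   obs_model = "deterministic",
                   nonnative_premium_pct = 0)
  sim <- generate_dataset(cfg, seed = 3)
  tm <- taxonomic_metric_series(sim$community)
  ab <- tm[tm$metric == "abundance", ]
  for (s in unique(ab$site_id)) {
    d <- ab[ab$site_id == s, ]
    f <- fit_site_trend(d$year, log10(d$value))
    expect_equal(f$slope, 0, tolerance = 1e-8)
  }
})

test_that("the known abundance trend is recovered from counts", {
  cfg <- sim_config(n_sites = 30, n_studies = 6, n_countries = 3,
                    species_pool = 50, mean_richness = 25,
                    trend_mean_pct = 2, sd_study_pct = 0,
                    sd_country_pct = 0, sd_site_pct = 0,
                    sigma_year = 0.02, nb_size = 50,
                    nonnative_premium_pct = 0)
  sim <- generate_dataset(cfg, seed = 21)
  tm <- taxonomic_metric_series(sim$community)
  tr <- fit_all_trends(tm[tm$metric == "abundance", ])
  # every site's true log10 trend is log10(1.02)
  expect_lt(abs(mean(tr$slope) - log10(1.02)), 5e-4)
})

test_that("trait tables carry 10 traits with 53 modalities", {
  layout <- trait_layout()
  expect_length(layout, 10L)
  expect_equal(sum(layout), 53L)
  sim <- generate_dataset(small_cfg(), seed = 5)
  expect_equal(ncol(sim$traits$affinities), 53L)
  expect_setequal(unique(unname(sim$traits$trait_of)), names(layout))
  # zero missingness -> full coverage
  cfg0 <- small_cfg(trait_missingness = c(species = 0, genus = 0,
                                          family = 0))
  tt0 <- generate_trait_table(species_pool_taxonomy(cfg0), cfg0, seed = 2)
  expect_equal(trait_coverage(tt0)$overall, 1)
  # a fully masked genus resolves at the family-median step
  cfg1 <- small_cfg(trait_missingness = c(species = 0, genus = 0,
                                          family = 0))
  tax <- species_pool_taxonomy(cfg1)
  db <- generate_trait_table(tax, cfg1, seed = 2)
  g1 <- tax$taxon_id[tax$level == "species" & tax$genus == "gen001"]
  masked <- db$affinities
  masked[c(g1, "gen001"), ] <- NA
  db_masked <- fw_traits(masked, db$trait_of)
  res <- fill_trait_gaps(g1, db_masked, tax)
  expect_true(all(res$traits$provenance[g1, ] == "family_median"))
})

test_that("covariate generator closes the loop on climate trends", {
  yrs <- list(1990:2019)
  cfg <- small_cfg(tmax_trend = 0.037, tmax_trend_sd = 0,
                   tmax_noise = 0, ppt_trend_sd = 0, ppt_noise = 0)
  cov <- generate_covariates("s1", yrs, cfg, seed = 4)
  cl <- cov$climate
  ct <- climate_trend(cl$year, cl$tmax)
  expect_equal(ct$slope, 0.037, tolerance = 1e-9)
  # seeded reproducibility
  cov2 <- generate_covariates("s1", yrs, cfg, seed = 4)
  expect_identical(cov$climate, cov2$climate)
  # dam scores are non-negative and percentages bounded
  expect_true(all(cov$static$dam_score >= 0))
  expect_true(all(cov$static$pct_urban <= 100))
})

test_that("simulated datasets round-trip through the CSV writers", {
  sim <- generate_dataset(small_cfg(), seed = 13)
  dir <- withr::local_tempdir()
  paths <- write_dataset(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- suppressMessages(read_community_table(paths["community"]))
  expect_equal(nrow(back), nrow(sim$community))
  meta <- read_site_metadata(paths["site_metadata"])
  expect_equal(nrow(meta), 12L)
})

test_that("non-native taxa trend faster than the community", {
  cfg <- sim_config(n_sites = 25, n_studies = 5, n_countries = 3,
                    species_pool = 60, mean_richness = 30,
                    trend_mean_pct = 0.5, sd_study_pct = 0,
                    sd_country_pct = 0, sd_site_pct = 0,
                    sigma_year = 0.02, nb_size = 50,
                    nonnative_fraction = 0.2, nonnative_premium_pct = 4)
  sim <- generate_dataset(cfg, seed = 31)
  res <- stats::setNames(sim$site_metadata$taxonomic_resolution,
                         sim$site_metadata$site_id)
  nn <- subset_community(sim$community, "non_native",
                         lookup = sim$nonnative_lookup,
                         site_resolution = res)
  nat <- subset_community(sim$community, "native",
                          lookup = sim$nonnative_lookup,
                          site_resolution = res)
  slope_of <- function(comm) {
    tm <- taxonomic_metric_series(comm)
    tr <- fit_all_trends(tm[tm$metric == "abundance", ])
    mean(tr$slope)
  }
  expect_gt(slope_of(nn), slope_of(nat) + log10(1.02))
})
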
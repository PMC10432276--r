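# Small in-code fixtures shared across test files.

toy_community <- function() {
  as_fw_community(data.frame(
    site_id = "s1", study_id = "st1", country = "AA",
    date = as.Date(c("2000-05-10", "2000-05-10", "2000-05-10")),
    taxon_id = c("Baetis", "Perla", "Lymnaea"),
    taxon_level = "species",
    abundance = c(3, 1, 6), stringsAsFactors = FALSE))
}

toy_taxonomy <- function() {
  data.frame(
    taxon_id = c("Baetis", "Perla", "Lymnaea", "Hydropsyche", "Chironomus"),
    genus = c("Baetis", "Perla", "Lymnaea", "Hydropsyche", "Chironomus"),
    family = c("Baetidae", "Perlidae", "Lymnaeidae", "Hydropsychidae",
               "Chironomidae"),
    order = c("Ephemeroptera", "Plecoptera", "Gastropoda", "Trichoptera",
              "Diptera"),
    class = c("Insecta", "Insecta", "Gastropoda", "Insecta", "Insecta"),
    stringsAsFactors = FALSE)
}

# a site sampled every year in `years`, `n_taxa` taxa, fixed date
site_events <- function(site = "s1", years, month = 5, day = 15,
                        n_taxa = 3, country = "AA", study = "st1") {
  do.call(rbind, lapply(years, function(y) {
    data.frame(site_id = site, study_id = study, country = country,
               date = as.Date(sprintf("%d-%02d-%02d", y, month, day)),
               taxon_id = paste0("t", seq_len(n_taxa)),
               taxon_level = "species",
               abundance = seq_len(n_taxa) * 2,
               stringsAsFactors = FALSE)
  }))
}

random_fuzzy_traits <- function(n_taxa, layout = c(a = 3L, b = 2L, c = 4L),
                                seed = 1) {
  set.seed(seed)
  mods <- unlist(lapply(names(layout), function(tr)
    paste0(tr, "_m", seq_len(layout[[tr]]))))
  trait_of <- stats::setNames(rep(names(layout), layout), mods)
  raw <- matrix(stats::runif(n_taxa * length(mods)), n_taxa,
                dimnames = list(sprintf("tx%02d", seq_len(n_taxa)), mods))
  normalize_fuzzy(raw, trait_of)
}

# simulate one Gaussian AR(1) series over irregular years
sim_ar1 <- function(years, slope, rho, sigma, intercept = 0) {
  n <- length(years)
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sigma / sqrt(1 - rho^2))
  for (t in 2:n) {
    dt <- years[t] - years[t - 1]
    r <- rho^dt
    e[t] <- r * e[t - 1] + stats::rnorm(1, 0, sigma * sqrt(1 - r^2))
  }
  intercept + slope * (years - mean(years)) + e
}

# direct simulation of the driver-model world: standardized covariates,
# study/country random intercepts, known coefficients, known trend se
sim_driver_data <- function(n_sites = 300, n_studies = 20, n_countries = 6,
                            beta = stats::setNames(rep(0, 11),
                                                   freshtrend:::DRIVER_COVARIATES),
                            tau_study = 0.1, tau_country = 0.05,
                            se_range = c(0.05, 0.15), seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n_sites * length(beta)), n_sites,
              dimnames = list(NULL, names(beta)))
  study <- paste0("st", rep(seq_len(n_studies), length.out = n_sites))
  country <- paste0("c", rep(seq_len(n_countries), length.out = n_sites))
  u <- stats::rnorm(n_studies, 0, tau_study)
  v <- stats::rnorm(n_countries, 0, tau_country)
  se <- stats::runif(n_sites, se_range[1], se_range[2])
  y <- as.numeric(X %*% beta) + u[as.integer(factor(study))] +
    v[as.integer(factor(country))] + stats::rnorm(n_sites, 0, se)
  trends <- data.frame(site_id = paste0("s", seq_len(n_sites)),
                       slope = y, se = se, study_id = study,
                       country = country, stringsAsFactors = FALSE)
  covs <- data.frame(site_id = trends$site_id, X,
                     stringsAsFactors = FALSE)
  list(trends = trends, covariates = covs)
}

# two-stage pipeline on a lean simulated dataset: site trends on the
# log10 scale, then the hierarchical meta-analysis
two_stage_meta <- function(cfg, seed) {
  sim <- simulate_trend_dataset(cfg, seed = seed)
  m <- sim$metrics
  m$value <- log10(m$value)
  tr <- do.call(rbind, lapply(split(m, m$site_id), function(d) {
    f <- fit_site_trend(d$year, d$value)
    if (is.na(f$slope)) return(NULL)
    data.frame(site_id = d$site_id[1], slope = f$slope, se = f$se,
               stringsAsFactors = FALSE)
  }))
  tr <- merge(tr, sim$site_info, by = "site_id")
  list(meta = fit_meta(tr), trends = tr, truth = sim$truth)
}
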
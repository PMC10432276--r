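# Synthetic community generator with known ground truth. The stated world:
# site-level log-linear abundance trends nested in studies and countries,
# AR(1) year effects, negative-binomial counts, irregular sampling years
# (8-32 per site, mean about 14.9, within a 1968-2020 span), fuzzy-coded
# traits with taxonomically structured missingness, a non-native species
# subset with faster trends, and covariate effects on trends.

#' Simulation configuration
#'
#' Defaults encode the conditions of the emulated monitoring world:
#' a 1968-2020 span; 8-32 sampling years per site averaging about 14.9;
#' a mean abundance trend of +0.5% per year with between-study,
#' between-country and residual site spread of 0.8, 0.4 and 1.0 %/yr; an
#' AR(1) year effect (rho = 0.3, sd 0.1 on the natural-log scale);
#' negative-binomial counts (size 5); a +3.4 %/yr trend premium for
#' non-native taxa (5% of the species pool); a climate with +0.037 degC/yr
#' warming and +0.49 mm/yr precipitation gain; and trait missingness that
#' exercises the full gap-filling cascade.
#'
#' @param ... overrides of the defaults listed above
#' @return list of class `fw_simconfig`
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_countries = 10L, n_studies = 40L, n_sites = 500L,
    year_start = 1968L, year_end = 2020L,
    min_years = 8L, max_years = 32L, mean_extra_years = 6.9,
    species_pool = 200L, species_per_genus = 4L, genera_per_family = 5L,
    mean_richness = 30,
    trend_mean_pct = 0.5, sd_study_pct = 0.8, sd_country_pct = 0.4,
    sd_site_pct = 1.0, trend_change_pct_per_yr = 0,
    rho = 0.3, sigma_year = 0.1, nb_size = 5, obs_model = "nb",
    nonnative_fraction = 0.05, nonnative_premium_pct = 3.4,
    covariate_effects = c(tmax_slope = 0, ppt_mean = 0, dam_score = 0,
                          pct_urban = 0, pct_cropland = 0),
    trait_missingness = c(species = 0.5, genus = 0.2, family = 0.05),
    tmax_mean = 12, tmax_mean_sd = 3, tmax_trend = 0.037,
    tmax_trend_sd = 0.01, tmax_noise = 0.5,
    ppt_mean = 800, ppt_mean_sd = 200, ppt_trend = 0.49,
    ppt_trend_sd = 1, ppt_noise = 50
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop("unknown config field(s): ",
                             paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$n_studies <= cfg$n_sites,
            cfg$n_countries <= cfg$n_studies,
            abs(cfg$rho) < 1,
            cfg$sd_study_pct >= 0, cfg$sd_country_pct >= 0,
            cfg$sd_site_pct >= 0, cfg$sigma_year >= 0)
  structure(cfg, class = c("fw_simconfig", "list"))
}

pct_to_log10 <- function(pct) log10(1 + pct / 100)

draw_sampling_years <- function(n, cfg) {
  extra <- stats::rnbinom(n, size = 3, mu = cfg$mean_extra_years)
  pmin(cfg$min_years + extra, cfg$max_years)
}

ar1_series <- function(n, rho, sigma) {
  if (n == 0L) return(numeric(0))
  e <- stats::rnorm(n, 0, sigma)
  x <- numeric(n)
  x[1] <- e[1] / sqrt(max(1 - rho^2, 1e-12))
  for (t in seq_len(n - 1L)) x[t + 1L] <- rho * x[t] + e[t + 1L]
  x
}

species_pool_taxonomy <- function(cfg) {
  sp <- cfg$species_pool
  genus_id <- ceiling(seq_len(sp) / cfg$species_per_genus)
  family_id <- ceiling(genus_id / cfg$genera_per_family)
  orders <- c("Ephemeroptera", "Plecoptera", "Trichoptera", "Diptera",
              "Coleoptera", "Odonata", "Gastropoda", "Amphipoda",
              "Tricladida", "Oligochaeta")
  classes <- c(rep("Insecta", 6), "Gastropoda", "Malacostraca",
               "Turbellaria", "Clitellata")
  fam_order <- orders[(seq_len(max(family_id)) - 1L) %% length(orders) + 1L]
  fam_class <- classes[(seq_len(max(family_id)) - 1L) %% length(orders) + 1L]
  species <- sprintf("sp%03d", seq_len(sp))
  genera <- sprintf("gen%03d", genus_id)
  families <- sprintf("fam%03d", family_id)
  tax_sp <- data.frame(taxon_id = species, genus = genera,
                       family = families, order = fam_order[family_id],
                       class = fam_class[family_id],
                       level = "species", stringsAsFactors = FALSE)
  gtab <- unique(data.frame(taxon_id = genera, genus = genera,
                            family = families,
                            order = fam_order[family_id],
                            class = fam_class[family_id],
                            level = "genus", stringsAsFactors = FALSE))
  ftab <- unique(data.frame(taxon_id = families, genus = "",
                            family = families,
                            order = fam_order[family_id],
                            class = fam_class[family_id],
                            level = "family", stringsAsFactors = FALSE))
  rbind(tax_sp, gtab, ftab)
}

#' Trait modality layout used by the generator
#'
#' Ten biological traits with 53 modalities in total (body size carries
#' seven size classes), mirroring the fuzzy-coded trait systems used for
#' European freshwater invertebrates.
#' @return named integer vector trait -> number of modalities
#' @export
trait_layout <- function() {
  c(body_size = 7L, feeding_type = 8L, respiration = 5L,
    resistance_form = 5L, dispersal = 4L, aquatic_stage = 4L,
    life_cycle_duration = 2L, reproduction = 8L, wing_form = 4L,
    drift_propensity = 6L)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), alpha, 1)
  x / sum(x)
}

#' Generate a fuzzy-coded trait database with structured missingness
#'
#' Species of a genus share a Dirichlet centre per trait, so genus and
#' family medians are informative; genus-level database entries are
#' included. Missingness is injected per taxonomic level at the configured
#' rates so the full gap-filling cascade is exercised.
#'
#' @param taxonomy taxonomy as from the generator (species + genus rows)
#' @param cfg `fw_simconfig`
#' @param seed RNG seed
#' @return `fw_traits` database
#' @export
generate_trait_table <- function(taxonomy, cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  layout <- trait_layout()
  mods <- unlist(lapply(names(layout), function(tr) {
    paste0(tr, "_m", seq_len(layout[[tr]]))
  }))
  trait_of <- stats::setNames(rep(names(layout), layout), mods)
  sp <- taxonomy[taxonomy$level == "species", , drop = FALSE]
  gn <- taxonomy[taxonomy$level == "genus", , drop = FALSE]
  taxa <- c(sp$taxon_id, gn$taxon_id)
  aff <- matrix(NA_real_, length(taxa), length(mods),
                dimnames = list(taxa, mods))
  genus_centre <- list()
  for (g in unique(sp$genus)) {
    genus_centre[[g]] <- lapply(names(layout), function(tr) {
      rdirichlet1(rep(0.8, layout[[tr]])) * 8 + 0.4
    })
  }
  fill_row <- function(genus) {
    ctr <- genus_centre[[genus]]
    unlist(lapply(seq_along(ctr), function(k) rdirichlet1(ctr[[k]])))
  }
  for (i in seq_len(nrow(sp))) aff[sp$taxon_id[i], ] <- fill_row(sp$genus[i])
  for (i in seq_len(nrow(gn))) aff[gn$taxon_id[i], ] <- fill_row(gn$genus[i])
  # inject missingness per trait at the configured per-level rates
  miss <- cfg$trait_missingness
  for (tr in names(layout)) {
    cols <- names(trait_of)[trait_of == tr]
    drop_sp <- sp$taxon_id[stats::runif(nrow(sp)) < miss[["species"]]]
    drop_gn <- gn$taxon_id[stats::runif(nrow(gn)) < miss[["genus"]]]
    aff[c(drop_sp, drop_gn), cols] <- NA_real_
  }
  fw_traits(aff, trait_of)
}

#' Generate site covariates and annual climate series
#'
#' Static stream characteristics (stream order, flow accumulation,
#' elevation, slope, upstream % urban and % cropland, dam distances and
#' the derived dam impact score) plus per-site annual series of maximum
#' monthly temperature and cumulative precipitation with configurable
#' means and trends.
#'
#' @param site_ids character vector
#' @param years_by_site named list of sampled years per site (climate is
#'   generated over each site's span)
#' @param cfg `fw_simconfig`
#' @param seed RNG seed
#' @return list with `static` (data.frame keyed by site_id; includes the
#'   true per-site climate trends) and `climate` (data.frame site_id,
#'   year, tmax, ppt)
#' @export
generate_covariates <- function(site_ids, years_by_site,
                                cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  n <- length(site_ids)
  dam_dists <- lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, 1.2)
    if (k == 0L) numeric(0) else stats::runif(k, 1, 60)
  })
  static <- data.frame(
    site_id = site_ids,
    stream_order = sample(1:7, n, replace = TRUE,
                          prob = c(0.15, 0.25, 0.25, 0.15, 0.1, 0.07, 0.03)),
    flow_accumulation = stats::rlnorm(n, 4, 1.5),
    elevation = stats::runif(n, 5, 1500),
    slope = stats::rlnorm(n, -3, 1),
    pct_urban = pmin(stats::rlnorm(n, 1, 1), 100),
    pct_cropland = pmin(stats::rlnorm(n, 2.5, 0.8), 100),
    dam_score = vapply(dam_dists, dam_impact_score, numeric(1)),
    tmax_mean_true = stats::rnorm(n, cfg$tmax_mean, cfg$tmax_mean_sd),
    tmax_slope_true = stats::rnorm(n, cfg$tmax_trend, cfg$tmax_trend_sd),
    ppt_mean_true = stats::rnorm(n, cfg$ppt_mean, cfg$ppt_mean_sd),
    ppt_slope_true = stats::rnorm(n, cfg$ppt_trend, cfg$ppt_trend_sd),
    stringsAsFactors = FALSE)
  clim <- list()
  for (i in seq_len(n)) {
    yrs <- seq(min(years_by_site[[i]]), max(years_by_site[[i]]))
    cy <- yrs - mean(yrs)
    clim[[i]] <- data.frame(
      site_id = site_ids[i], year = yrs,
      tmax = static$tmax_mean_true[i] + static$tmax_slope_true[i] * cy +
        stats::rnorm(length(yrs), 0, cfg$tmax_noise),
      ppt = static$ppt_mean_true[i] + static$ppt_slope_true[i] * cy +
        stats::rnorm(length(yrs), 0, cfg$ppt_noise),
      stringsAsFactors = FALSE)
  }
  list(static = static, climate = do.call(rbind, clim))
}

#' Generate a full synthetic dataset with known truth
#'
#' Draws a hierarchy of countries, studies and sites; per-site log-linear
#' abundance trends composed of the global mean, study and country random
#' effects, covariate effects (on standardized covariates) and site noise;
#' AR(1) year effects shared by all taxa of a site; and per-taxon annual
#' counts (negative binomial around the log-linear expectation, or exact
#' expectations when `obs_model = "deterministic"`). Non-native taxa
#' receive the configured trend premium. Identical `(config, seed)` give
#' identical output.
#'
#' @param cfg `fw_simconfig`
#' @param seed RNG seed
#' @return list with `community` (`fw_community`), `traits` (`fw_traits`
#'   database), `taxonomy`, `site_metadata`, `covariates` (static +
#'   climate), `nonnative_lookup` and `truth` (per-site true trends and
#'   effects; recorded before observation noise)
#' @export
generate_dataset <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  n_sites <- cfg$n_sites
  countries <- sprintf("C%02d", seq_len(cfg$n_countries))
  studies <- sprintf("S%03d", seq_len(cfg$n_studies))
  study_country <- countries[c(seq_len(cfg$n_countries),
                               sample(cfg$n_countries,
                                      cfg$n_studies - cfg$n_countries,
                                      replace = TRUE))]
  site_study <- studies[c(seq_len(cfg$n_studies),
                          sample(cfg$n_studies, n_sites - cfg$n_studies,
                                 replace = TRUE))]
  site_ids <- sprintf("site%04d", seq_len(n_sites))
  site_country <- study_country[match(site_study, studies)]

  # sampling years per site
  n_years <- draw_sampling_years(n_sites, cfg)
  span <- cfg$year_end - cfg$year_start + 1L
  years_by_site <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    dur <- min(span, n_years[i] +
                 stats::rnbinom(1, size = 3, mu = 4.3))
    start <- cfg$year_start +
      sample.int(span - dur + 1L, 1L) - 1L
    inner <- if (dur > 2L && n_years[i] > 2L)
      sort(sample(seq(start + 1L, start + dur - 2L), n_years[i] - 2L))
    else integer(0)
    years_by_site[[i]] <- unique(c(start, inner, start + dur - 1L))
  }

  cov <- generate_covariates(site_ids, years_by_site, cfg,
                             seed = seed + 1L)
  eff <- cfg$covariate_effects
  Xeff <- matrix(0, n_sites, length(eff),
                 dimnames = list(NULL, names(eff)))
  for (nm in names(eff)) {
    src <- switch(nm, tmax_slope = cov$static$tmax_slope_true,
                  tmax_mean = cov$static$tmax_mean_true,
                  ppt_slope = cov$static$ppt_slope_true,
                  ppt_mean = cov$static$ppt_mean_true,
                  cov$static[[nm]])
    s <- stats::sd(src)
    Xeff[, nm] <- if (s > 0) (src - mean(src)) / s else 0
  }

  u_study <- stats::rnorm(cfg$n_studies, 0,
                          pct_to_log10(cfg$sd_study_pct))
  v_country <- stats::rnorm(cfg$n_countries, 0,
                            pct_to_log10(cfg$sd_country_pct))
  b_mean <- pct_to_log10(cfg$trend_mean_pct)
  eff_log10 <- vapply(eff, pct_to_log10, numeric(1))
  b_site <- b_mean + u_study[match(site_study, studies)] +
    v_country[match(site_country, countries)] +
    as.numeric(Xeff %*% eff_log10) +
    stats::rnorm(n_sites, 0, pct_to_log10(cfg$sd_site_pct))

  taxonomy <- species_pool_taxonomy(cfg)
  sp_tab <- taxonomy[taxonomy$level == "species", , drop = FALSE]
  traits <- generate_trait_table(taxonomy, cfg, seed = seed + 2L)
  # country-level non-native status for a fixed subset of the pool
  nn_species <- sp_tab$taxon_id[
    seq_len(max(1L, round(cfg$nonnative_fraction * nrow(sp_tab))))]
  nonnative_lookup <- do.call(rbind, lapply(countries, function(cn) {
    data.frame(species = nn_species, country = cn, status = "non_native",
               stringsAsFactors = FALSE)
  }))
  premium <- pct_to_log10(cfg$nonnative_premium_pct)

  resolution <- sample(c("species", "mixed", "family"), n_sites,
                       replace = TRUE, prob = c(0.42, 0.30, 0.28))
  modal_month <- sample(3:10, n_sites, replace = TRUE)

  rows <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    yrs <- years_by_site[[i]]
    S <- max(5L, min(nrow(sp_tab),
                     stats::rpois(1, cfg$mean_richness)))
    pool_idx <- sample(nrow(sp_tab), S)
    pool <- sp_tab$taxon_id[pool_idx]
    base <- stats::rnorm(S, log(8), 1)
    gam <- ar1_series(length(yrs), cfg$rho, cfg$sigma_year)
    is_nn <- pool %in% nn_species
    b_taxon <- log(10) * (b_site[i] + premium * is_nn)
    dates <- as.Date(sprintf("%d-%02d-%02d", yrs, modal_month[i],
                             pmin(28L, 10L + (seq_along(yrs) %% 10L))))
    site_rows <- vector("list", length(yrs))
    for (t in seq_along(yrs)) {
      mu <- exp(base + b_taxon * (yrs[t] - yrs[1]) + gam[t])
      counts <- if (cfg$obs_model == "nb") {
        stats::rnbinom(S, mu = mu, size = cfg$nb_size)
      } else mu
      keep <- counts > 0
      if (!any(keep)) next
      site_rows[[t]] <- data.frame(
        site_id = site_ids[i], study_id = site_study[i],
        country = site_country[i], date = dates[t],
        taxon_id = pool[keep],
        taxon_level = "species",
        abundance = counts[keep], stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, site_rows)
  }
  community <- do.call(rbind, rows)
  # family-resolution sites report family-level taxa
  fam_sites <- site_ids[resolution == "family"]
  if (length(fam_sites) > 0L) {
    idx <- community$site_id %in% fam_sites
    fam <- sp_tab$family[match(community$taxon_id[idx], sp_tab$taxon_id)]
    agg <- stats::aggregate(
      abundance ~ site_id + study_id + country + date + taxon_id,
      data = transform(community[idx, , drop = FALSE], taxon_id = fam),
      FUN = sum)
    agg$taxon_level <- "family"
    community <- rbind(community[!idx, , drop = FALSE],
                       agg[, names(community)])
  }
  community <- as_fw_community(community)

  site_metadata <- data.frame(
    site_id = site_ids, study_id = site_study, country = site_country,
    taxonomic_resolution = resolution,
    n_sampling_years = vapply(years_by_site, length, integer(1)),
    effort_consistent = TRUE,
    cov$static[, setdiff(names(cov$static), "site_id")],
    stringsAsFactors = FALSE)

  truth <- data.frame(
    site_id = site_ids, study_id = site_study, country = site_country,
    trend_log10 = b_site, trend_pct = (10^b_site - 1) * 100,
    stringsAsFactors = FALSE)
  attr(truth, "study_effects") <- stats::setNames(u_study, studies)
  attr(truth, "country_effects") <- stats::setNames(v_country, countries)
  attr(truth, "covariate_effects_pct") <- eff
  attr(truth, "rho") <- cfg$rho
  attr(truth, "nonnative_premium_pct") <- cfg$nonnative_premium_pct

  list(community = community, traits = traits, taxonomy = taxonomy,
       site_metadata = site_metadata, covariates = cov,
       nonnative_lookup = nonnative_lookup, truth = truth)
}

#' Directly simulate site-level metric series with known trends
#'
#' Lean generator for estimator and meta-analysis studies: per-site
#' Gaussian AR(1) series around a log10-linear trend drawn from the same
#' study/country hierarchy as [generate_dataset()], without the community
#' layer. Much faster than generating counts, and the truth is exact.
#'
#' @param cfg `fw_simconfig` (uses the hierarchy, trend, rho and span
#'   fields; `sigma_year` is the observation sd on the log10 scale)
#' @param seed RNG seed
#' @return list with `metrics` (tidy site_id/metric/year/value, metric
#'   `"abundance"` on the log10 scale is exposed as raw abundance),
#'   `site_info` (site_id, study_id, country) and `truth`
#' @export
simulate_trend_dataset <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  n_sites <- cfg$n_sites
  countries <- sprintf("C%02d", seq_len(cfg$n_countries))
  studies <- sprintf("S%03d", seq_len(cfg$n_studies))
  study_country <- countries[c(seq_len(cfg$n_countries),
                               sample(cfg$n_countries,
                                      cfg$n_studies - cfg$n_countries,
                                      replace = TRUE))]
  site_study <- studies[c(seq_len(cfg$n_studies),
                          sample(cfg$n_studies, n_sites - cfg$n_studies,
                                 replace = TRUE))]
  site_ids <- sprintf("site%04d", seq_len(n_sites))
  site_country <- study_country[match(site_study, studies)]
  u_study <- stats::rnorm(cfg$n_studies, 0, pct_to_log10(cfg$sd_study_pct))
  v_country <- stats::rnorm(cfg$n_countries, 0,
                            pct_to_log10(cfg$sd_country_pct))
  b_site <- pct_to_log10(cfg$trend_mean_pct) +
    u_study[match(site_study, studies)] +
    v_country[match(site_country, countries)] +
    stats::rnorm(n_sites, 0, pct_to_log10(cfg$sd_site_pct))
  n_years <- draw_sampling_years(n_sites, cfg)
  span <- cfg$year_end - cfg$year_start + 1L
  # optional linear change of the local trend over calendar time (for
  # deceleration scenarios): b(y) = b_site + c * (y - mid-span)
  cc <- pct_to_log10(cfg$trend_change_pct_per_yr)
  y_mid <- (cfg$year_start + cfg$year_end) / 2
  out <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    yrs <- sort(sample(seq(cfg$year_start, cfg$year_end),
                       min(n_years[i], span)))
    g <- ar1_series(length(yrs), cfg$rho, cfg$sigma_year)
    if (cc == 0) {
      trend_part <- b_site[i] * (yrs - yrs[1])
    } else {
      # integrate b(y) dy between consecutive sampled years
      dy <- diff(yrs)
      mids <- (yrs[-1] + yrs[-length(yrs)]) / 2
      trend_part <- c(0, cumsum((b_site[i] + cc * (mids - y_mid)) * dy))
    }
    vals <- 2 + trend_part + g
    out[[i]] <- data.frame(site_id = site_ids[i], metric = "abundance",
                           year = yrs, value = 10^vals,
                           stringsAsFactors = FALSE)
  }
  list(metrics = do.call(rbind, out),
       site_info = data.frame(site_id = site_ids, study_id = site_study,
                              country = site_country,
                              stringsAsFactors = FALSE),
       truth = data.frame(site_id = site_ids, trend_log10 = b_site,
                          trend_pct = (10^b_site - 1) * 100,
                          stringsAsFactors = FALSE))
}

#' Write a simulated dataset to CSV files
#'
#' Writes the same formats the readers consume: community, traits, site
#' metadata, static covariates, climate series and non-native lookup.
#'
#' @param sim output of [generate_dataset()]
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    community = file.path(dir, "community.csv"),
    traits = file.path(dir, "traits.csv"),
    taxonomy = file.path(dir, "taxonomy.csv"),
    site_metadata = file.path(dir, "site_metadata.csv"),
    covariates = file.path(dir, "covariates.csv"),
    climate = file.path(dir, "climate.csv"),
    nonnative = file.path(dir, "nonnative_lookup.csv"),
    truth = file.path(dir, "truth.csv"))
  write_community_table(sim$community, paths["community"])
  write_trait_table(sim$traits, paths["traits"])
  utils::write.csv(sim$taxonomy, paths["taxonomy"], row.names = FALSE)
  utils::write.csv(sim$site_metadata, paths["site_metadata"],
                   row.names = FALSE)
  utils::write.csv(sim$covariates$static, paths["covariates"],
                   row.names = FALSE)
  utils::write.csv(sim$covariates$climate, paths["climate"],
                   row.names = FALSE)
  utils::write.csv(sim$nonnative_lookup, paths["nonnative"],
                   row.names = FALSE)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
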
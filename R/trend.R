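# Site-level trend estimation. Each metric series is modelled as
#   y_t = a + b * cYear_t (+ c * cDOY_t) + e_t,
# where the errors follow a continuous-time AR(1): cor(e_s, e_t) =
# rho^|s - t| with the time index in integer years since the first sample,
# so gaps decay correlation naturally. The exact Gaussian likelihood is
# profiled over rho. With a Normal(0, 10) prior on the slope the Gaussian
# posterior is stored alongside the point estimate.

#' Default metric transformation ledger
#'
#' Maps each analysed metric to the transform applied before Gaussian
#' trend fitting: evenness, functional richness and (subset) abundance are
#' log10-transformed; functional divergence is squared; functional
#' turnover is bounded in (0, 1) and fitted with a beta likelihood on the
#' logit scale; all remaining metrics are fitted untransformed. Zeros
#' under log10 are replaced by half the series' minimum positive value
#' (configurable via `zero_rule`).
#'
#' @return named character vector metric -> transform tag
#' @export
default_transform_ledger <- function() {
  c(abundance = "log10",
    richness = "identity",
    shannon = "identity",
    evenness = "log10",
    rarefied_richness = "identity",
    turnover = "identity",
    FRic = "log10",
    FEve = "identity",
    FDiv = "square",
    RaoQ = "identity",
    redundancy = "identity",
    functional_turnover = "logit_beta",
    # community subsets share the transform of their parent metric
    abundance_EPT = "log10", abundance_insects = "log10",
    abundance_native = "log10", abundance_non_native = "log10",
    richness_EPT = "identity", richness_insects = "identity",
    richness_native = "identity", richness_non_native = "identity")
}

#' Apply a ledger transform to a metric series
#'
#' @param values numeric vector
#' @param transform one of `"identity"`, `"log10"`, `"square"`,
#'   `"logit_beta"` (beta-fitted series are passed through and squeezed at
#'   fit time)
#' @param zero_rule for log10: `"half_min_positive"` replaces zeros by
#'   half the smallest positive value (flagged via attribute
#'   `zeros_adjusted`); `"error"` refuses zeros
#' @return transformed numeric vector
#' @export
apply_transform <- function(values, transform,
                            zero_rule = c("half_min_positive", "error")) {
  zero_rule <- match.arg(zero_rule)
  switch(transform,
    identity = values,
    square = values^2,
    logit_beta = values,
    log10 = {
      if (any(values < 0, na.rm = TRUE)) {
        stop("negative values cannot be log10-transformed")
      }
      nz <- sum(values == 0, na.rm = TRUE)
      if (nz > 0L) {
        if (zero_rule == "error") stop("zero values under log10 transform")
        mp <- min(values[values > 0], na.rm = TRUE)
        values[values == 0] <- mp / 2
        out <- log10(values)
        attr(out, "zeros_adjusted") <- nz
        return(out)
      }
      log10(values)
    },
    stop("unknown transform: ", transform)
  )
}

ar1_loglik <- function(rho, y, X, tidx, reml = FALSE) {
  n <- length(y)
  R <- rho^abs(outer(tidx, tidx, "-"))
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  yw <- backsolve(ch, y, transpose = TRUE)
  Xw <- backsolve(ch, X, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  logdetR <- 2 * sum(log(diag(ch)))
  p <- ncol(X)
  if (reml) {
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + logdetR +
              2 * sum(log(abs(diag(qr.R(qr(Xw)))))) + (n - p))
  } else {
    s2 <- rss / n
    -0.5 * (n * log(2 * pi * s2) + logdetR + n)
  }
}

ar1_gls <- function(y, X, tidx, rho_max = 0.98) {
  # an (effectively) exact linear fit leaves rho unidentified: report 0
  rss0 <- sum(stats::lm.fit(X, y)$residuals^2)
  if (rss0 <= 1e-20 * max(sum(y^2), 1)) {
    rho <- 0
  } else {
    # profile the exact AR(1) likelihood over rho (coarse grid, then
    # local refinement), then GLS at the optimum
    grid <- seq(-rho_max, rho_max, length.out = 21)
    f <- function(r) ar1_loglik(r, y, X, tidx)
    ll <- vapply(grid, f, numeric(1))
    i <- which.max(ll)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
    rho <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  }
  n <- length(y)
  p <- ncol(X)
  R <- rho^abs(outer(tidx, tidx, "-"))
  ch <- chol(R)
  yw <- backsolve(ch, y, transpose = TRUE)
  Xw <- backsolve(ch, X, transpose = TRUE)
  qx <- qr(Xw)
  beta <- qr.coef(qx, yw)
  rss <- sum(qr.resid(qx, yw)^2)
  s2 <- rss / (n - p)                      # REML-flavoured variance for se
  XtX_inv <- chol2inv(qr.R(qx))
  list(coef = beta, vcov = s2 * XtX_inv, rho = rho, sigma2 = s2,
       loglik = ar1_loglik(rho, y, X, tidx))
}

ar1_mixture <- function(y, X, tidx, rho_grid = seq(-0.9, 0.9, by = 0.05)) {
  # Gaussian-approximated posterior for the slope, integrating over the
  # AR(1) parameter: conditional on rho the slope posterior is a
  # location-scale t_(n-p) around the GLS estimate (Jeffreys prior on the
  # residual variance); rho is integrated over a grid with weights
  # proportional to the REML likelihood. Propagating rho uncertainty this
  # way restores near-nominal interval coverage, which a plug-in rho-hat
  # se does not achieve at these series lengths.
  n <- length(y); p <- ncol(X)
  df <- n - p
  rss0 <- sum(stats::lm.fit(X, y)$residuals^2)
  if (rss0 <= 1e-20 * max(sum(y^2), 1)) {
    fit <- stats::lm.fit(X, y)
    return(list(coef = fit$coefficients, post_mean = fit$coefficients[2],
                post_sd = 0, rho = 0, components = NULL))
  }
  K <- length(rho_grid)
  m <- v <- ll <- numeric(K)
  icoef <- numeric(K)
  for (k in seq_len(K)) {
    R <- rho_grid[k]^abs(outer(tidx, tidx, "-"))
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) { ll[k] <- -Inf; next }
    yw <- backsolve(ch, y, transpose = TRUE)
    Xw <- backsolve(ch, X, transpose = TRUE)
    qx <- qr(Xw)
    b <- qr.coef(qx, yw)
    rss <- sum(qr.resid(qx, yw)^2)
    vv <- rss / df * chol2inv(qr.R(qx))
    m[k] <- b[2]; icoef[k] <- b[1]; v[k] <- vv[2, 2]
    s2 <- rss / df
    ll[k] <- -0.5 * (df * log(s2) + 2 * sum(log(diag(ch))) +
                       2 * sum(log(abs(diag(qr.R(qx))))))
  }
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  post_mean <- sum(w * m)
  tvar <- v * df / (df - 2)            # t_(df) component variance
  post_var <- sum(w * (tvar + m^2)) - post_mean^2
  k_map <- which.max(ll)
  list(coef = c(icoef[k_map], m[k_map]), post_mean = post_mean,
       post_sd = sqrt(post_var), rho = rho_grid[k_map],
       components = list(w = w, m = m, v = v, df = df))
}

squeeze01 <- function(y) {
  # Smithson-Verkuilen squeeze for beta likelihoods on [0, 1] data
  n <- length(y)
  (y * (n - 1) + 0.5) / n
}

beta_trend <- function(y, cyear) {
  if (any(y <= 0 | y >= 1)) y <- squeeze01(y)
  nll <- function(par) {
    mu <- stats::plogis(par[1] + par[2] * cyear)
    phi <- exp(par[3])
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  start <- c(stats::qlogis(mean(y)), 0, log(5))
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE)
  vc <- tryCatch(solve(opt$hessian), error = function(e)
    matrix(NA_real_, 3, 3))
  list(coef = opt$par[1:2], se = sqrt(pmax(diag(vc)[1:2], 0)),
       mu_first = stats::plogis(opt$par[1] + opt$par[2] * cyear[1]))
}

#' Fit a site-level trend with AR(1) errors
#'
#' Estimates the linear trend of one metric series. Year is centred; the
#' AR(1) time index is integer years since the first sample, so the error
#' correlation between observations Delta-t years apart is rho^Delta-t
#' even across gaps. Day of year is included as an additional centred
#' predictor when the spread of sampling dates exceeds `doy_window` days.
#' For the `logit_beta` transform the series is fitted by a beta
#' likelihood with a logit link (no AR term). The stored posterior is the
#' Gaussian combination of the likelihood with a Normal(0, `prior_sd`)
#' slope prior.
#'
#' @param years integer sampling years
#' @param values metric values (already transformed per the ledger, except
#'   `logit_beta` which is handled internally)
#' @param transform transform tag (affects only the beta route and the
#'   back-transformation bookkeeping)
#' @param doy optional day-of-year per observation
#' @param doy_window include DOY as predictor when `max(doy) - min(doy)`
#'   exceeds this many days (default 30)
#' @param min_obs minimum observations required (default 8)
#' @param prior_sd slope prior standard deviation (default 10)
#' @return object of class `fw_trend`: slope, se, rho, n_years, post_mean,
#'   post_sd, baseline (fitted value at the first sampled year on the
#'   transformed scale), transform
#' @export
fit_site_trend <- function(years, values, transform = "identity",
                           doy = NULL, doy_window = 30, min_obs = 8L,
                           prior_sd = 10) {
  ok <- is.finite(values)
  n_dropped <- sum(!ok)
  years <- years[ok]; values <- values[ok]
  if (!is.null(doy)) doy <- doy[ok]
  if (length(values) < min_obs) {
    return(structure(list(slope = NA_real_, se = NA_real_, rho = NA_real_,
                          n_years = length(values), post_mean = NA_real_,
                          post_sd = NA_real_, baseline = NA_real_,
                          transform = transform, n_dropped = n_dropped),
                     class = "fw_trend"))
  }
  ord <- order(years)
  years <- years[ord]; values <- values[ord]
  if (!is.null(doy)) doy <- doy[ord]
  cyear <- years - mean(years)
  if (transform == "logit_beta") {
    bt <- beta_trend(values, cyear)
    slope <- bt$coef[2]; se <- bt$se[2]; rho <- NA_real_
    baseline <- bt$mu_first
  } else {
    X <- cbind(1, cyear)
    use_doy <- !is.null(doy) && (max(doy) - min(doy)) > doy_window
    if (use_doy) X <- cbind(X, doy - mean(doy))
    tidx <- years - years[1]
    fit <- ar1_mixture(values, X, tidx)
    slope <- unname(fit$post_mean); se <- unname(fit$post_sd)
    rho <- fit$rho
    baseline <- unname(fit$coef[1] + fit$coef[2] * cyear[1])
  }
  prec <- 1 / se^2 + 1 / prior_sd^2
  post_sd <- sqrt(1 / prec)
  post_mean <- (slope / se^2) / prec
  structure(list(slope = slope, se = se, rho = rho,
                 n_years = length(values), post_mean = post_mean,
                 post_sd = post_sd, baseline = baseline,
                 transform = transform, n_dropped = n_dropped),
            class = "fw_trend")
}

#' @export
print.fw_trend <- function(x, ...) {
  cat(sprintf("trend: slope %.4g (se %.3g), rho %.2f, n = %d [%s]\n",
              x$slope, x$se, if (is.na(x$rho)) 0 else x$rho, x$n_years,
              x$transform))
  invisible(x)
}

#' Back-transform a trend to percent change per year
#'
#' log10 scale: (10^slope - 1) * 100. Identity scale: 100 * slope /
#' baseline, with baseline the fitted value at the series' first sampled
#' year. Square scale (fitted on y^2): by the delta method the relative
#' change of y is slope / (2 * baseline_y^2), where `baseline` is the
#' fitted y^2 at the first year. Logit-beta: slope * (1 - baseline_mu) *
#' 100 (derivative of the inverse logit at the baseline mean, relative to
#' that mean).
#'
#' @param slope trend on the transformed scale
#' @param transform transform tag
#' @param baseline fitted value at the first sampled year on the
#'   transformed scale (or the fitted mean for `logit_beta`)
#' @return percent change per year; NA when a required baseline is
#'   non-positive
#' @export
percent_change_per_year <- function(slope, transform, baseline = NA_real_) {
  switch(transform,
    log10 = (10^slope - 1) * 100,
    identity = {
      if (is.na(baseline) || baseline <= 0) NA_real_
      else 100 * slope / baseline
    },
    square = {
      if (is.na(baseline) || baseline <= 0) NA_real_
      else 100 * slope / (2 * baseline)
    },
    logit_beta = {
      if (is.na(baseline) || baseline <= 0 || baseline >= 1) NA_real_
      else 100 * slope * (1 - baseline)
    },
    stop("unknown transform: ", transform)
  )
}

#' Trend of an annual covariate series
#'
#' Same estimator contract as [fit_site_trend()] without the day-of-year
#' term; used for per-site climate trends. A constant series returns
#' slope 0.
#'
#' @param years integer years
#' @param values covariate values (>= 3 required)
#' @return list with `slope` and `se`
#' @export
climate_trend <- function(years, values) {
  ok <- is.finite(values)
  years <- years[ok]; values <- values[ok]
  if (length(values) < 3L) stop("climate_trend needs >= 3 years")
  if (stats::sd(values) == 0) return(list(slope = 0, se = 0))
  fit <- fit_site_trend(years, values, min_obs = 3L)
  list(slope = fit$slope, se = fit$se)
}

#' Fit trends for every site and metric in a tidy metric table
#'
#' @param metrics data.frame `site_id`, `metric`, `year`, `value` (as
#'   produced by [taxonomic_metric_series()] and
#'   [functional_metric_series()])
#' @param ledger named transform vector (default
#'   [default_transform_ledger()]); metrics absent from the ledger are
#'   fitted untransformed
#' @param doy optional data.frame `site_id`, `year`, `doy`
#' @param min_obs minimum observations per series (default 8)
#' @return data.frame with one row per site x metric: slope, se, rho,
#'   n_years, post_mean, post_sd, transform, percent_per_year
#' @export
fit_all_trends <- function(metrics, ledger = default_transform_ledger(),
                           doy = NULL, min_obs = 8L) {
  out <- list()
  key <- unique(metrics[, c("site_id", "metric")])
  for (i in seq_len(nrow(key))) {
    s <- key$site_id[i]; m <- key$metric[i]
    rows <- metrics[metrics$site_id == s & metrics$metric == m, ,
                    drop = FALSE]
    tr <- if (m %in% names(ledger)) unname(ledger[m]) else "identity"
    vals <- tryCatch(apply_transform(rows$value, tr),
                     error = function(e) rep(NA_real_, nrow(rows)))
    dv <- NULL
    if (!is.null(doy)) {
      dm <- merge(rows["year"], doy[doy$site_id == s, c("year", "doy")],
                  by = "year", all.x = TRUE)
      dv <- dm$doy[match(rows$year, dm$year)]
      if (anyNA(dv)) dv <- NULL
    }
    fit <- fit_site_trend(rows$year, as.numeric(vals), transform = tr,
                          doy = dv, min_obs = min_obs)
    if (is.na(fit$slope)) next
    out[[length(out) + 1L]] <- data.frame(
      site_id = s, metric = m, slope = fit$slope, se = fit$se,
      rho = fit$rho, n_years = fit$n_years, post_mean = fit$post_mean,
      post_sd = fit$post_sd, transform = tr,
      percent_per_year = percent_change_per_year(fit$slope, tr,
                                                 fit$baseline),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
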
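# Hierarchical pooling of site-level trends:
#   estimate_i ~ N(mu + u_study(i) + v_country(i), s_i^2 [+ sigma^2])
# with known sampling variances s_i^2 (weighted) or a free residual
# variance only (unweighted). The deterministic backend profiles the REML
# likelihood over the variance components; an optional Gibbs backend
# mirrors a Bayesian fit with a Normal(0, 3) intercept prior.

cell_matrix <- function(f) {
  # indicator (cell-means) matrix; unlike model.matrix() this accepts a
  # single-level factor
  f <- factor(f)
  m <- vapply(levels(f), function(l) as.numeric(f == l),
              numeric(length(f)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(f))
  m
}

# Woodbury helpers: V = D + Z G Z' with q = ncol(Z) small.
lmm_core <- function(y, X, Z, g, d) {
  n <- length(y)
  Dinv <- 1 / d
  ZtDZ <- crossprod(Z * Dinv, Z)
  M <- ZtDZ + diag(1 / g, ncol(Z))
  chM <- chol(M)
  # V^-1 a = D^-1 a - D^-1 Z M^-1 Z' D^-1 a
  Vinv <- function(a) {
    a <- as.matrix(a)
    da <- a * Dinv
    da - Dinv * (Z %*% backsolve(chM, backsolve(chM, crossprod(Z, da),
                                                transpose = TRUE)))
  }
  # log|V| = log|M| + log|G| + log|D| (matrix determinant lemma)
  logdetV <- 2 * sum(log(diag(chM))) +
    sum(log(rep(g, length.out = ncol(Z)))) + sum(log(d))
  XtVinvX <- crossprod(X, Vinv(X))
  XtVinvy <- crossprod(X, Vinv(y))
  chXX <- chol(XtVinvX)
  beta <- backsolve(chXX, backsolve(chXX, XtVinvy, transpose = TRUE))
  r <- y - X %*% beta
  quad <- sum(r * Vinv(r))
  reml <- -0.5 * (logdetV + 2 * sum(log(diag(chXX))) + quad)
  list(beta = as.numeric(beta), vcov = chol2inv(chXX), reml = reml,
       quad = quad)
}

fit_lmm_reml <- function(y, X, Zs, Zc, s2 = NULL) {
  n <- length(y)
  # a grouping with a single level is unidentifiable (confounded with the
  # intercept): drop it and report zero variance
  use_s <- ncol(Zs) >= 2L
  use_c <- ncol(Zc) >= 2L
  qs <- if (use_s) ncol(Zs) else 0L
  qc <- if (use_c) ncol(Zc) else 0L
  Z <- cbind(if (use_s) Zs, if (use_c) Zc)
  if (is.null(Z)) Z <- matrix(0, n, 1)   # inert block, variance pinned
  weighted <- !is.null(s2)
  np <- (qs > 0) + (qc > 0) + 1L
  expand <- function(par) {
    k <- 1L
    tau2s <- 0; tau2c <- 0
    if (qs > 0) { tau2s <- exp(par[k]); k <- k + 1L }
    if (qc > 0) { tau2c <- exp(par[k]); k <- k + 1L }
    list(tau2s = tau2s, tau2c = tau2c, sig2 = exp(par[k]))
  }
  make_gd <- function(p) {
    g <- c(rep(p$tau2s, qs), rep(p$tau2c, qc))
    if (length(g) == 0L) g <- 1e-12
    d <- if (weighted) s2 + p$sig2 else rep(p$sig2, n)
    list(g = g, d = d)
  }
  obj <- function(par) {
    gd <- make_gd(expand(par))
    res <- tryCatch(lmm_core(y, X, Z, gd$g, gd$d),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$reml)) return(1e10)
    -res$reml
  }
  v0 <- stats::var(y)
  start <- log(c(rep(v0 / 4 + 1e-8, np - 1L),
                 if (weighted) v0 / 100 + 1e-10 else v0 / 2 + 1e-8))
  opt <- stats::optim(start, obj, method = if (np > 1) "Nelder-Mead"
                      else "BFGS",
                      control = list(maxit = 2000, reltol = 1e-10))
  p <- expand(opt$par)
  gd <- make_gd(p)
  res <- lmm_core(y, X, Z, gd$g, gd$d)
  list(beta = res$beta, vcov = res$vcov, tau2_study = p$tau2s,
       tau2_country = p$tau2c, sigma2 = p$sig2, reml = res$reml)
}

ci_levels <- c(0.80, 0.90, 0.95)

gaussian_intervals <- function(mean, sd) {
  out <- t(vapply(ci_levels, function(l) {
    z <- stats::qnorm(1 - (1 - l) / 2)
    c(lower = mean - z * sd, upper = mean + z * sd)
  }, numeric(2)))
  rownames(out) <- paste0(ci_levels * 100, "%")
  out
}

draw_intervals <- function(draws) {
  out <- t(vapply(ci_levels, function(l) {
    q <- stats::quantile(draws, c((1 - l) / 2, 1 - (1 - l) / 2),
                         names = FALSE)
    c(lower = q[1], upper = q[2])
  }, numeric(2)))
  rownames(out) <- paste0(ci_levels * 100, "%")
  out
}

gibbs_meta <- function(y, study, country, s2 = NULL, iter = 5000,
                       burn = floor(iter / 2), prior_intercept_sd = 3,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  su <- factor(study); co <- factor(country)
  qs <- nlevels(su); qc <- nlevels(co)
  weighted <- !is.null(s2)
  u <- rep(0, qs); v <- rep(0, qc)
  mu <- mean(y); tau2s <- tau2c <- stats::var(y) / 4 + 1e-6
  sig2 <- if (weighted) stats::var(y) / 100 + 1e-8 else stats::var(y) / 2
  d <- if (weighted) s2 + sig2 else rep(sig2, n)
  a0 <- 0.5; b0 <- 0.5 * stats::var(y)   # weakly-informative IG(a0, b0)
  keep <- matrix(NA_real_, iter - burn, 3 + 0)
  mu_draws <- numeric(iter - burn)
  tau_draws <- matrix(NA_real_, iter - burn, 2)
  for (it in seq_len(iter)) {
    # mu | rest, prior N(0, prior_intercept_sd^2)
    r <- y - u[su] - v[co]
    prec <- sum(1 / d) + 1 / prior_intercept_sd^2
    mu <- stats::rnorm(1, sum(r / d) / prec, sqrt(1 / prec))
    # u_j | rest
    r <- y - mu - v[co]
    for (j in seq_len(qs)) {
      idx <- which(as.integer(su) == j)
      prec <- sum(1 / d[idx]) + 1 / tau2s
      u[j] <- stats::rnorm(1, sum(r[idx] / d[idx]) / prec, sqrt(1 / prec))
    }
    r <- y - mu - u[su]
    for (j in seq_len(qc)) {
      idx <- which(as.integer(co) == j)
      prec <- sum(1 / d[idx]) + 1 / tau2c
      v[j] <- stats::rnorm(1, sum(r[idx] / d[idx]) / prec, sqrt(1 / prec))
    }
    tau2s <- 1 / stats::rgamma(1, a0 + qs / 2, b0 + sum(u^2) / 2)
    tau2c <- 1 / stats::rgamma(1, a0 + qc / 2, b0 + sum(v^2) / 2)
    res <- y - mu - u[su] - v[co]
    sig2 <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(res^2) / 2)
    d <- if (weighted) s2 + sig2 else rep(sig2, n)
    if (it > burn) {
      mu_draws[it - burn] <- mu
      tau_draws[it - burn, ] <- c(tau2s, tau2c)
    }
  }
  list(mu_draws = mu_draws, tau2_study = mean(tau_draws[, 1]),
       tau2_country = mean(tau_draws[, 2]), sigma2 = sig2)
}

#' Pool site-level trends in a hierarchical meta-analysis
#'
#' Random-effects meta-analysis of site-level trend estimates with crossed
#' study and country random intercepts. When `weighted = TRUE` the known
#' sampling variances (`se^2`) enter the residual variance (measurement
#' error weighting, plus a small free residual component); when
#' `weighted = FALSE` the standard errors are ignored and a single
#' residual variance is estimated. The default deterministic backend
#' profiles the REML likelihood and summarizes the intercept's Gaussian
#' sampling distribution; the `gibbs` backend draws from the posterior
#' with a Normal(0, 3) intercept prior.
#'
#' @param trends data.frame with columns `slope` (or the column named by
#'   `estimate_col`), `se`, `study_id`, `country`
#' @param weighted use the site-level standard errors (default TRUE)
#' @param backend `"reml"` (deterministic, default) or `"gibbs"`
#' @param estimate_col column holding the estimates (default `"slope"`)
#' @param transform optional transform tag for a percent-per-year
#'   conversion of the pooled mean (only `"log10"` has a closed form
#'   without a baseline)
#' @param iter,seed Gibbs settings (4 chains' worth of draws in one run;
#'   50% burn-in)
#' @return object of class `fw_meta`: mean, se, intervals (80/90/95%),
#'   p_direction, tau2_study, tau2_country, sigma2, n_sites, weighted,
#'   backend, draws (gibbs only), percent_per_year (when transform given)
#' @export
fit_meta <- function(trends, weighted = TRUE,
                     backend = c("reml", "gibbs"), estimate_col = "slope",
                     transform = NULL, iter = 5000, seed = NULL) {
  backend <- match.arg(backend)
  y <- trends[[estimate_col]]
  stopifnot(!is.null(y))
  study <- factor(trends$study_id)
  country <- factor(trends$country)
  s2 <- if (weighted) trends$se^2 else NULL
  if (weighted && (is.null(trends$se) || anyNA(trends$se))) {
    stop("weighted meta-analysis needs a complete se column")
  }
  if (weighted) {
    # a site whose series is fit exactly (e.g. constant integer richness)
    # reports se = 0 — an artifact of the Gaussian model, not infinite
    # precision. Floor such variances at the smallest regularly-estimated
    # one so the site stays influential but bounded.
    zero <- s2 <= 1e-12 * max(stats::var(y), .Machine$double.xmin)
    if (any(zero)) {
      s2[zero] <- if (all(zero)) stats::var(y) / length(y)
        else min(s2[!zero])
      message(sum(zero), " site(s) with (near-)zero se floored at the ",
              "smallest positive sampling variance")
    }
  }
  n <- length(y)
  if (nlevels(study) < 2L) {
    warning("single study: random-effect variances unidentifiable; ",
            "degrading to a fixed-effect mean")
    w <- if (weighted) 1 / s2 else rep(1, n)
    m <- sum(w * y) / sum(w)
    se <- if (weighted) sqrt(1 / sum(w)) else stats::sd(y) / sqrt(n)
    out <- list(mean = m, se = se, intervals = gaussian_intervals(m, se),
                p_direction = 1 - stats::pnorm(0, m, se),
                tau2_study = 0, tau2_country = 0, sigma2 = NA_real_,
                n_sites = n, weighted = weighted, backend = "fixed",
                draws = NULL)
    class(out) <- "fw_meta"
    return(out)
  }
  X <- matrix(1, n, 1)
  Zs <- cell_matrix(study)
  Zc <- cell_matrix(country)
  if (backend == "reml") {
    fit <- fit_lmm_reml(y, X, Zs, Zc, s2 = s2)
    m <- fit$beta[1]; se <- sqrt(fit$vcov[1, 1])
    out <- list(mean = m, se = se, intervals = gaussian_intervals(m, se),
                p_direction = 1 - stats::pnorm(0, m, se),
                tau2_study = fit$tau2_study,
                tau2_country = fit$tau2_country, sigma2 = fit$sigma2,
                n_sites = n, weighted = weighted, backend = "reml",
                draws = NULL)
  } else {
    g <- gibbs_meta(y, study, country, s2 = s2, iter = iter, seed = seed)
    m <- mean(g$mu_draws); se <- stats::sd(g$mu_draws)
    out <- list(mean = m, se = se, intervals = draw_intervals(g$mu_draws),
                p_direction = mean(g$mu_draws > 0),
                tau2_study = g$tau2_study, tau2_country = g$tau2_country,
                sigma2 = g$sigma2, n_sites = n, weighted = weighted,
                backend = "gibbs", draws = g$mu_draws)
  }
  if (!is.null(transform) && transform == "log10") {
    out$percent_per_year <- (10^out$mean - 1) * 100
    out$percent_intervals <- (10^out$intervals - 1) * 100
  }
  class(out) <- "fw_meta"
  out
}

#' @export
print.fw_meta <- function(x, ...) {
  cat(sprintf("meta-analysis (%s, %s): mean %.4g (se %.3g), P(>0) = %.3f\n",
              x$backend, if (x$weighted) "weighted" else "unweighted",
              x$mean, x$se, x$p_direction))
  cat(sprintf("  tau2(study) %.3g, tau2(country) %.3g, n = %d\n",
              x$tau2_study, x$tau2_country, x$n_sites))
  invisible(x)
}

#' Probability of direction
#'
#' Posterior mass of the mean trend above zero. Accepts an `fw_meta`
#' (uses draws when present, else the Gaussian approximation), a numeric
#' vector of draws, or `mean`/`sd` of a Gaussian.
#'
#' @param x `fw_meta`, numeric draws, or a Gaussian mean
#' @param sd Gaussian sd (when `x` is a scalar mean)
#' @return P(mean > 0)
#' @export
probability_of_direction <- function(x, sd = NULL) {
  if (inherits(x, "fw_meta")) {
    if (!is.null(x$draws)) return(mean(x$draws > 0))
    return(1 - stats::pnorm(0, x$mean, x$se))
  }
  if (is.numeric(x) && length(x) > 1L) return(mean(x > 0))
  stopifnot(!is.null(sd))
  1 - stats::pnorm(0, x, sd)
}

#' Country jackknife of the meta-analysis
#'
#' Refits the meta-analysis once per country, leaving that country out.
#'
#' @param trends as in [fit_meta()]; needs >= 3 countries
#' @param ... passed to [fit_meta()]
#' @return list with `fits` (one `fw_meta` per left-out country) and
#'   `summary` data.frame (country, mean, se, p_direction) plus the range
#'   of leave-one-out means
#' @export
jackknife_by_country <- function(trends, ...) {
  countries <- unique(trends$country)
  if (length(countries) < 3L) stop("country jackknife needs >= 3 countries")
  fits <- lapply(countries, function(cn) {
    fit_meta(trends[trends$country != cn, , drop = FALSE], ...)
  })
  names(fits) <- countries
  summ <- data.frame(
    country = countries,
    mean = vapply(fits, `[[`, numeric(1), "mean"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    p_direction = vapply(fits, `[[`, numeric(1), "p_direction"),
    stringsAsFactors = FALSE)
  list(fits = fits, summary = summ, range = range(summ$mean))
}

#' Meta-analysis with an additional fixed factor
#'
#' Reruns the meta-analysis with a categorical site attribute (sampling
#' season or taxonomic resolution) as a fixed factor, sharing the study
#' and country random effects: the fixed-effect design is the cell-means
#' parameterization, so each level gets its own mean trend. Levels with
#' fewer than two sites are dropped with a message.
#'
#' @param trends as in [fit_meta()]
#' @param factor_values character/factor vector aligned with `trends`
#'   rows
#' @param weighted use the site-level standard errors
#' @param estimate_col column holding the estimates
#' @return data.frame per retained level: level, mean, se, lower/upper 95%,
#'   p_direction, n_sites
#' @export
sensitivity_fixed_factor <- function(trends, factor_values, weighted = TRUE,
                                     estimate_col = "slope") {
  f <- factor(factor_values)
  keep_levels <- names(which(table(f) >= 2L))
  drop_levels <- setdiff(levels(f), keep_levels)
  if (length(drop_levels) > 0L) {
    message("dropping level(s) with < 2 sites: ",
            paste(drop_levels, collapse = ", "))
  }
  sel <- f %in% keep_levels
  trends <- trends[sel, , drop = FALSE]
  f <- droplevels(f[sel])
  y <- trends[[estimate_col]]
  # cell-means design built by hand: model.matrix() rejects single-level
  # factors, but a one-level factor is a legitimate degenerate case here
  X <- vapply(levels(f), function(l) as.numeric(f == l),
              numeric(length(f)))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Zs <- cell_matrix(trends$study_id)
  Zc <- cell_matrix(trends$country)
  fit <- fit_lmm_reml(y, X, Zs, Zc,
                      s2 = if (weighted) trends$se^2 else NULL)
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(0.975)
  data.frame(level = levels(f), mean = fit$beta, se = se,
             lower95 = fit$beta - z * se, upper95 = fit$beta + z * se,
             p_direction = 1 - stats::pnorm(0, fit$beta, se),
             n_sites = as.integer(table(f)), stringsAsFactors = FALSE)
}
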
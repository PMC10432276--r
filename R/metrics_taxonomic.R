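# Per-sample taxonomic diversity metrics. A "sample" is a named numeric
# vector of abundances (one entry per taxon) for one site in one year.

#' Taxon richness and total abundance
#'
#' @param sample named numeric vector of abundances
#' @return list with `richness` (number of taxa with abundance > 0) and
#'   `abundance` (summed individuals). An empty or all-zero sample yields
#'   zeros with attribute `empty = TRUE`.
#' @export
richness_abundance <- function(sample) {
  sample <- sample[!is.na(sample)]
  out <- list(richness = sum(sample > 0), abundance = sum(sample))
  if (length(sample) == 0L || all(sample == 0)) attr(out, "empty") <- TRUE
  out
}

#' Shannon diversity and evenness
#'
#' H = -sum p_i log p_i (natural log); evenness J = H / log S for S > 1.
#' For a single-taxon sample H = 0 and J is undefined (returned as NA):
#' evenness has no meaning without at least two taxa.
#'
#' @param sample named numeric vector of abundances
#' @return list with `H` (nats) and `J` in \[0, 1\] or NA
#' @export
shannon <- function(sample) {
  x <- sample[!is.na(sample) & sample > 0]
  if (length(x) == 0L) stop("shannon() needs at least one positive abundance")
  p <- x / sum(x)
  H <- -sum(p * log(p))
  S <- length(x)
  list(H = H, J = if (S > 1L) H / log(S) else NA_real_)
}

#' Individual-based rarefied richness
#'
#' Expected number of taxa in a random subsample of `n_ref` individuals
#' drawn without replacement (hypergeometric expectation):
#' E\[S\] = sum_i (1 - choose(N - N_i, n_ref) / choose(N, n_ref)).
#' `n_ref` is conventionally the lowest number of individuals in any
#' sampling year of the series, computed upstream.
#'
#' @param sample named numeric vector of (integer) abundances
#' @param n_ref subsample size; must not exceed total individuals
#' @return expected richness (numeric)
#' @export
rarefied_richness <- function(sample, n_ref) {
  x <- round(sample[!is.na(sample) & sample > 0])
  N <- sum(x)
  if (n_ref > N) stop("n_ref (", n_ref, ") exceeds total individuals (", N, ")")
  if (n_ref < 0) stop("n_ref must be non-negative")
  # lchoose for numerical stability at large N
  sum(1 - exp(lchoose(N - x, n_ref) - lchoose(N, n_ref)))
}

#' Temporal turnover between two communities
#'
#' Ratio of taxa gained or lost to the pooled number of taxa present in
#' the two samples: (gains + losses) / richness(union).
#'
#' @param a,b named abundance vectors (names are taxa; presence =
#'   abundance > 0)
#' @return turnover in \[0, 1\]
#' @export
turnover_pair <- function(a, b) {
  ta <- names(a)[!is.na(a) & a > 0]
  tb <- names(b)[!is.na(b) & b > 0]
  pool <- union(ta, tb)
  if (length(pool) == 0L) return(NA_real_)
  gains <- length(setdiff(tb, ta))
  losses <- length(setdiff(ta, tb))
  (gains + losses) / length(pool)
}

#' Temporal turnover along an annual series
#'
#' Turnover is computed between consecutive *sampled* years (gaps allowed,
#' because series are irregular) and attributed to the later year of each
#' pair.
#'
#' @param series named list year -> abundance vector, or a matrix with
#'   years as rows and taxa as columns
#' @return data.frame with columns `year` and `turnover`
#' @export
temporal_turnover <- function(series) {
  if (is.matrix(series)) {
    yrs <- as.integer(rownames(series))
    series <- lapply(seq_len(nrow(series)), function(i) series[i, ])
    names(series) <- yrs
  }
  yrs <- sort(as.integer(names(series)))
  if (length(yrs) < 2L) {
    return(data.frame(year = integer(0), turnover = numeric(0)))
  }
  vals <- vapply(seq_len(length(yrs) - 1L), function(i) {
    turnover_pair(series[[as.character(yrs[i])]],
                  series[[as.character(yrs[i + 1L])]])
  }, numeric(1))
  data.frame(year = yrs[-1L], turnover = vals)
}

# ---- series-level driver -------------------------------------------------

#' Compute taxonomic metric series for every site
#'
#' Produces the tidy per-site, per-year metric table used downstream:
#' total abundance, taxon richness, Shannon diversity and evenness,
#' individual-based rarefied richness (reference size = the series'
#' minimum annual total), and temporal turnover (attributed to the later
#' year of each consecutive sampled-year pair).
#'
#' @param community a `fw_community` with one sampling event per site-year
#' @return data.frame with columns `site_id`, `metric`, `year`, `value`
#' @export
taxonomic_metric_series <- function(community) {
  out <- list()
  for (s in unique(community$site_id)) {
    rows <- community[community$site_id == s, , drop = FALSE]
    yrs <- sort(unique(as.integer(format(rows$date, "%Y"))))
    samples <- lapply(yrs, function(y) {
      r <- rows[as.integer(format(rows$date, "%Y")) == y, , drop = FALSE]
      tapply(r$abundance, r$taxon_id, sum)
    })
    names(samples) <- yrs
    totals <- vapply(samples, sum, numeric(1))
    n_ref <- floor(min(totals))
    rec <- function(metric, year, value) {
      data.frame(site_id = s, metric = metric, year = year, value = value,
                 stringsAsFactors = FALSE)
    }
    for (i in seq_along(yrs)) {
      sm <- samples[[i]]
      ra <- richness_abundance(sm)
      out[[length(out) + 1L]] <- rec("abundance", yrs[i], ra$abundance)
      out[[length(out) + 1L]] <- rec("richness", yrs[i], ra$richness)
      if (ra$richness > 0) {
        sh <- shannon(sm)
        out[[length(out) + 1L]] <- rec("shannon", yrs[i], sh$H)
        out[[length(out) + 1L]] <- rec("evenness", yrs[i], sh$J)
        if (n_ref >= 1 && n_ref <= sum(round(sm))) {
          out[[length(out) + 1L]] <-
            rec("rarefied_richness", yrs[i], rarefied_richness(sm, n_ref))
        }
      }
    }
    to <- temporal_turnover(samples)
    if (nrow(to) > 0L) {
      out[[length(out) + 1L]] <- rec("turnover", to$year, to$turnover)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
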
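# Distance-based functional diversity: trait distances, principal
# coordinates, convex-hull richness (FRic), minimum-spanning-tree evenness
# (FEve), divergence (FDiv), Rao's quadratic entropy, redundancy, and
# functional turnover of community-weighted means.

#' Pairwise trait distances between taxa
#'
#' Two metrics are offered. `gower_fuzzy`: within each trait the distance
#' is half the Manhattan distance between affinity profiles (in \[0, 1\]
#' since profiles sum to 1), then averaged over traits. `euclidean_scaled`:
#' the plain Euclidean distance across all modalities, rescaled by its
#' maximum so all distances lie in \[0, 1\] (the convention used for the
#' redundancy calculation). Taxa with any missing trait are excluded and
#' listed in the `excluded` attribute.
#'
#' @param traits `fw_traits`
#' @param metric `"gower_fuzzy"` or `"euclidean_scaled"`
#' @return `dist` object over covered taxa
#' @export
trait_distance <- function(traits, metric = c("gower_fuzzy",
                                              "euclidean_scaled")) {
  metric <- match.arg(metric)
  aff <- traits$affinities
  ok <- rowSums(is.na(aff)) == 0L
  excluded <- rownames(aff)[!ok]
  aff <- aff[ok, , drop = FALSE]
  if (nrow(aff) < 2L) stop("need at least two taxa with complete traits")
  if (metric == "gower_fuzzy") {
    trait_names <- unique(unname(traits$trait_of))
    acc <- 0
    for (tr in trait_names) {
      cols <- colnames(aff)[traits$trait_of[colnames(aff)] == tr]
      acc <- acc + 0.5 * stats::dist(aff[, cols, drop = FALSE],
                                     method = "manhattan")
    }
    d <- acc / length(trait_names)
  } else {
    d <- stats::dist(aff)
    mx <- max(d)
    if (mx > 0) d <- d / mx
  }
  attr(d, "excluded") <- excluded
  attr(d, "metric") <- metric
  d
}

#' Principal coordinates analysis of a trait distance matrix
#'
#' Double-centred eigendecomposition of the squared distances. When
#' negative eigenvalues exceed the tolerance, the configured correction is
#' applied: `sqrt` (square-root transform of the distances, the default),
#' `cailliez` (additive constant) or `none` (negative axes discarded). The
#' first `axes` positive axes are retained.
#'
#' @param d `dist` object
#' @param axes maximum number of axes to keep (default 6)
#' @param correction `"sqrt"`, `"cailliez"` or `"none"`
#' @param tol negative-eigenvalue tolerance relative to the largest
#'   eigenvalue
#' @return object of class `fw_traitspace`: list with `coords` (taxa x
#'   axes), `eig` (all eigenvalues of the analysed matrix), `correction`
#'   (tag actually applied), `taxa`
#' @export
trait_space <- function(d, axes = 6L, correction = c("sqrt", "cailliez",
                                                     "none"),
                        tol = 1e-8) {
  correction <- match.arg(correction)
  taxa <- attr(d, "Labels")
  n <- attr(d, "Size")
  if (n < 2L) stop("degenerate trait space: fewer than 2 taxa")
  k <- n - 1L
  cm <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  applied <- "none"
  if (min(cm$eig) < -tol * max(abs(cm$eig)) && correction != "none") {
    cm <- suppressWarnings(
      if (correction == "sqrt") stats::cmdscale(sqrt(d), k = k, eig = TRUE)
      else stats::cmdscale(d, k = k, eig = TRUE, add = TRUE))
    applied <- correction
  }
  pos <- which(cm$eig > tol * max(abs(cm$eig)))
  keep <- utils::head(pos, axes)
  coords <- cm$points[, keep, drop = FALSE]
  rownames(coords) <- taxa
  structure(list(coords = coords, eig = cm$eig, correction = applied,
                 taxa = taxa), class = "fw_traitspace")
}

#' @export
print.fw_traitspace <- function(x, ...) {
  cat(sprintf("trait space: %d taxa, %d axes (correction: %s)\n",
              length(x$taxa), ncol(x$coords), x$correction))
  invisible(x)
}

present_taxa <- function(community, taxa) {
  community <- community[!is.na(community) & community > 0]
  intersect(names(community), taxa)
}

#' Functional richness (convex hull volume)
#'
#' Volume of the convex hull of the community's taxa in ordination space.
#' When fewer than `axes + 1` taxa are present, the dimensionality falls
#' back to S - 1 axes (flagged via the `axes_used` attribute) rather than
#' returning a missing value. Collinear configurations give 0 with a
#' degenerate flag.
#'
#' @param space `fw_traitspace`
#' @param community named abundance vector
#' @param standardize divide by the hull volume of the full taxon pool in
#'   the same number of axes (default FALSE)
#' @return hull volume (numeric) with attributes `axes_used` and
#'   `degenerate`
#' @export
functional_richness <- function(space, community, standardize = FALSE) {
  pres <- present_taxa(community, rownames(space$coords))
  S <- length(pres)
  if (S < 2L) {
    return(structure(NA_real_, axes_used = 0L, degenerate = TRUE))
  }
  m <- min(ncol(space$coords), S - 1L)
  coords <- space$coords[pres, seq_len(m), drop = FALSE]
  h <- convhull_volume(coords)
  out <- h$volume
  if (standardize) {
    pool <- convhull_volume(space$coords[, seq_len(m), drop = FALSE])
    out <- if (pool$volume > 0) out / pool$volume else NA_real_
  }
  structure(out, axes_used = m, degenerate = h$degenerate)
}

#' Functional evenness (minimum spanning tree regularity)
#'
#' FEve of Villeger et al.: branch lengths of the minimum spanning tree of
#' the community's taxa in trait space are divided by the summed relative
#' abundances of their two endpoints (EW), normalized (PEW), and compared
#' with the perfectly even value 1/(S-1):
#' FEve = (sum min(PEW, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1)).
#'
#' @param space `fw_traitspace`
#' @param community named abundance vector; needs >= 3 present taxa
#' @return FEve in \[0, 1\] or NA
#' @export
functional_evenness <- function(space, community) {
  pres <- present_taxa(community, rownames(space$coords))
  S <- length(pres)
  if (S < 3L) return(NA_real_)
  w <- community[pres] / sum(community[pres])
  d <- stats::dist(space$coords[pres, , drop = FALSE])
  mst <- vegan::spantree(d)
  # spantree: link i connects node i+1 to node mst$kid[i]
  from <- 2:S
  to <- mst$kid
  ew <- mst$dist / (w[from] + w[to])
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Functional divergence
#'
#' FDiv of Villeger et al.: abundance-weighted deviation of taxa from the
#' mean distance to the centre of gravity of the convex-hull vertices,
#' bounded in \[0, 1\].
#'
#' @param space `fw_traitspace`
#' @param community named abundance vector; needs >= 3 present taxa and a
#'   non-degenerate hull
#' @return FDiv in \[0, 1\] or NA
#' @export
functional_divergence <- function(space, community) {
  pres <- present_taxa(community, rownames(space$coords))
  S <- length(pres)
  if (S < 3L) return(NA_real_)
  m <- min(ncol(space$coords), S - 1L)
  coords <- space$coords[pres, seq_len(m), drop = FALSE]
  h <- convhull_volume(coords)
  if (h$degenerate) return(NA_real_)
  gc <- colMeans(coords[h$vertices, , drop = FALSE])
  dG <- sqrt(rowSums((coords - matrix(gc, S, m, byrow = TRUE))^2))
  dbar <- mean(dG)
  w <- community[pres] / sum(community[pres])
  delta_d <- sum(w * (dG - dbar))
  delta_ad <- sum(w * abs(dG - dbar))
  (delta_d + dbar) / (delta_ad + dbar)
}

#' Rao's quadratic entropy, Simpson diversity and functional redundancy
#'
#' Q = sum_ij d_ij p_i p_j (expected trait distance between two random
#' individuals); D = 1 - sum p_i^2 (Gini-Simpson); community uniqueness
#' U = Q / D and redundancy = 1 - U. With distances in \[0, 1\], Q <= D,
#' so U and redundancy lie in \[0, 1\]. For a monoculture D falls below
#' the tolerance and U and redundancy are undefined.
#'
#' @param d `dist` or square matrix of trait distances in \[0, 1\]
#' @param community named abundance vector
#' @param tol tolerance below which D is treated as zero (default 1e-8)
#' @return list with `Q`, `D`, `U`, `redundancy`
#' @export
rao_simpson_redundancy <- function(d, community, tol = 1e-8) {
  dm <- as.matrix(d)
  pres <- present_taxa(community, rownames(dm))
  if (length(pres) == 0L) stop("no community taxa present in distance matrix")
  p <- community[pres] / sum(community[pres])
  dm <- dm[pres, pres, drop = FALSE]
  Q <- as.numeric(t(p) %*% dm %*% p)
  D <- 1 - sum(p^2)
  if (D <= tol) {
    return(list(Q = Q, D = D, U = NA_real_, redundancy = NA_real_))
  }
  U <- Q / D
  list(Q = Q, D = D, U = U, redundancy = 1 - U)
}

#' Functional turnover of community-weighted means
#'
#' Applies the taxonomic gains/losses turnover ratio to trait modalities:
#' a modality is treated as present in a year when its community-weighted
#' mean affinity exceeds `threshold` (default 0: exact zeros only count as
#' absent). Turnover between consecutive sampled years is attributed to
#' the later year.
#'
#' @param cwm_series matrix of CWM vectors, years as rows (rownames) and
#'   modalities as columns
#' @param threshold presence threshold on CWM affinity (default 0)
#' @return data.frame with columns `year` and `turnover` (empty if a
#'   single year)
#' @export
functional_turnover <- function(cwm_series, threshold = 0) {
  yrs <- sort(as.integer(rownames(cwm_series)))
  if (length(yrs) < 2L) {
    return(data.frame(year = integer(0), turnover = numeric(0)))
  }
  pres <- lapply(as.character(yrs), function(y) {
    v <- cwm_series[y, ]
    stats::setNames(as.numeric(v > threshold & !is.na(v)), colnames(cwm_series))
  })
  vals <- vapply(seq_len(length(yrs) - 1L), function(i) {
    turnover_pair(pres[[i]], pres[[i + 1L]])
  }, numeric(1))
  data.frame(year = yrs[-1L], turnover = vals)
}

fd_hull_metrics <- function(space, community, standardize = FALSE,
                            pool_volume = NA_real_) {
  # FRic and FDiv from a single hull computation (the hull dominates the
  # cost of the per-year loop)
  pres <- present_taxa(community, rownames(space$coords))
  S <- length(pres)
  if (S < 2L) return(list(FRic = NA_real_, FDiv = NA_real_))
  m <- min(ncol(space$coords), S - 1L)
  coords <- space$coords[pres, seq_len(m), drop = FALSE]
  h <- convhull_volume(coords)
  fric <- h$volume
  if (standardize) {
    fric <- if (is.finite(pool_volume) && pool_volume > 0)
      fric / pool_volume else NA_real_
  }
  fdiv <- NA_real_
  if (S >= 3L && !h$degenerate) {
    gc <- colMeans(coords[h$vertices, , drop = FALSE])
    dG <- sqrt(rowSums((coords - matrix(gc, S, m, byrow = TRUE))^2))
    dbar <- mean(dG)
    w <- community[pres] / sum(community[pres])
    fdiv <- (sum(w * (dG - dbar)) + dbar) /
      (sum(w * abs(dG - dbar)) + dbar)
  }
  list(FRic = fric, FDiv = fdiv)
}

#' Compute functional metric series for every site
#'
#' Builds a per-site trait space from the site's taxon pool and computes,
#' per year: FRic, FEve, FDiv, Rao's Q and functional redundancy, plus the
#' functional turnover of community-weighted means. Redundancy uses
#' scaled Euclidean distances (bounded in \[0, 1\]); hull- and MST-based
#' metrics use the ordination of `distance_metric` distances.
#'
#' @param community a `fw_community` with one sampling event per site-year
#' @param traits `fw_traits` (filled and coverage-filtered)
#' @param axes number of ordination axes (default 6)
#' @param distance_metric distance for FRic/FEve/FDiv ordination (default
#'   `"gower_fuzzy"`)
#' @param standardize_fric standardize hull volumes by the site pool hull
#' @return tidy data.frame `site_id`, `metric`, `year`, `value`
#' @export
functional_metric_series <- function(community, traits, axes = 6L,
                                     distance_metric = "gower_fuzzy",
                                     standardize_fric = FALSE) {
  out <- list()
  aff_ok <- rownames(traits$affinities)[
    rowSums(is.na(traits$affinities)) == 0L]
  for (s in unique(community$site_id)) {
    rows <- community[community$site_id == s, , drop = FALSE]
    pool <- intersect(unique(rows$taxon_id), aff_ok)
    if (length(pool) < 3L) next
    sub <- fw_traits(traits$affinities[pool, , drop = FALSE],
                     traits$trait_of)
    d_ord <- trait_distance(sub, distance_metric)
    d_eu <- trait_distance(sub, "euclidean_scaled")
    space <- trait_space(d_ord, axes = axes)
    yrs <- sort(unique(as.integer(format(rows$date, "%Y"))))
    cwm <- matrix(NA_real_, length(yrs), ncol(sub$affinities),
                  dimnames = list(yrs, colnames(sub$affinities)))
    rec <- function(metric, year, value) {
      data.frame(site_id = s, metric = metric, year = year, value = value,
                 stringsAsFactors = FALSE)
    }
    pool_vol <- if (standardize_fric) {
      convhull_volume(space$coords)$volume
    } else NA_real_
    for (y in yrs) {
      r <- rows[as.integer(format(rows$date, "%Y")) == y, , drop = FALSE]
      sample <- tapply(r$abundance, r$taxon_id, sum)
      hm <- fd_hull_metrics(space, sample, standardize_fric, pool_vol)
      out[[length(out) + 1L]] <- rec("FRic", y, hm$FRic)
      out[[length(out) + 1L]] <- rec("FEve", y,
                                     functional_evenness(space, sample))
      out[[length(out) + 1L]] <- rec("FDiv", y, hm$FDiv)
      rr <- rao_simpson_redundancy(d_eu, sample)
      out[[length(out) + 1L]] <- rec("RaoQ", y, rr$Q)
      out[[length(out) + 1L]] <- rec("redundancy", y, rr$redundancy)
      cw <- community_weighted_means(sample, sub)
      cwm[as.character(y), ] <- cw
    }
    ft <- functional_turnover(cwm)
    if (nrow(ft) > 0L) {
      out[[length(out) + 1L]] <- rec("functional_turnover", ft$year,
                                     ft$turnover)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
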
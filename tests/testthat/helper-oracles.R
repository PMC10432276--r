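# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition with naive loops/enumeration, staying
# independent of the package's implementation paths.

oracle_shannon <- function(x) {
  x <- unname(x[x > 0])
  p <- x / sum(x)
  H <- 0
  for (i in seq_along(p)) H <- H - p[i] * log(p[i])
  H
}

# exact rarefaction by enumerating every subset of n_ref individuals
oracle_rarefaction_enum <- function(counts, n_ref) {
  individuals <- rep(seq_along(counts), counts)
  subsets <- utils::combn(length(individuals), n_ref)
  mean(apply(subsets, 2, function(ix) length(unique(individuals[ix]))))
}

oracle_rao <- function(dmat, p) {
  p <- unname(p)
  Q <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) Q <- Q + dmat[i, j] * p[i] * p[j]
  }
  Q
}

oracle_gower_fuzzy <- function(aff, trait_of) {
  n <- nrow(aff)
  traits <- unique(unname(trait_of[colnames(aff)]))
  d <- matrix(0, n, n, dimnames = list(rownames(aff), rownames(aff)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (tr in traits) {
        cols <- colnames(aff)[trait_of[colnames(aff)] == tr]
        acc <- acc + 0.5 * sum(abs(aff[i, cols] - aff[j, cols]))
      }
      d[i, j] <- acc / length(traits)
    }
  }
  d
}

oracle_cwm <- function(sample, aff) {
  taxa <- intersect(names(sample), rownames(aff))
  p <- sample[taxa] / sum(sample[taxa])
  out <- numeric(ncol(aff))
  for (m in seq_len(ncol(aff))) {
    for (i in seq_along(taxa)) out[m] <- out[m] + p[i] * aff[taxa[i], m]
  }
  stats::setNames(out, colnames(aff))
}

# minimum spanning tree by exhaustive search over all spanning trees
# (feasible for n <= 6); returns the edge list of the minimum tree
oracle_mst <- function(dmat) {
  n <- nrow(dmat)
  edges <- t(utils::combn(n, 2))
  best <- NULL; best_w <- Inf
  for (pick in utils::combn(nrow(edges), n - 1, simplify = FALSE)) {
    e <- edges[pick, , drop = FALSE]
    # connectivity via union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (k in seq_len(nrow(e))) {
      a <- find(e[k, 1]); b <- find(e[k, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (!ok) next
    w <- sum(dmat[e])
    if (w < best_w) { best_w <- w; best <- e }
  }
  list(edges = best, weight = best_w)
}

oracle_feve <- function(coords, abund) {
  dmat <- as.matrix(stats::dist(coords))
  S <- nrow(coords)
  w <- abund / sum(abund)
  mst <- oracle_mst(dmat)
  ew <- numeric(nrow(mst$edges))
  for (k in seq_len(nrow(mst$edges))) {
    i <- mst$edges[k, 1]; j <- mst$edges[k, 2]
    ew[k] <- dmat[i, j] / (w[i] + w[j])
  }
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

# Monte-Carlo hull volume for a simplex (membership via barycentric
# coordinates, independent of the hull algorithm)
oracle_simplex_volume_mc <- function(simplex, n_mc = 2e5, seed = 1) {
  set.seed(seed)
  d <- ncol(simplex)
  lo <- apply(simplex, 2, min); hi <- apply(simplex, 2, max)
  q <- matrix(stats::runif(n_mc * d), n_mc, d)
  q <- sweep(sweep(q, 2, hi - lo, "*"), 2, lo, "+")
  A <- t(simplex[-1, , drop = FALSE]) - simplex[1, ]
  lam <- t(solve(A, t(q) - simplex[1, ]))
  inside <- rowSums(lam < 0) == 0 & rowSums(lam) <= 1
  mean(inside) * prod(hi - lo)
}

shoelace_area <- function(pts) {
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  nxt <- c(2:nrow(hp), 1)
  abs(sum(hp[, 1] * hp[nxt, 2] - hp[nxt, 1] * hp[, 2])) / 2
}

# classical one-grouping random-effects meta-analysis (REML, known
# sampling variances), written independently of the package machinery
oracle_re_meta <- function(y, s2) {
  reml <- function(tau2) {
    w <- 1 / (s2 + tau2)
    mu <- sum(w * y) / sum(w)
    -0.5 * (sum(log(s2 + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  opt <- stats::optimize(reml, c(0, stats::var(y) * 10 + 1), maximum = TRUE)
  tau2 <- opt$maximum
  w <- 1 / (s2 + tau2)
  list(mu = sum(w * y) / sum(w), se = sqrt(1 / sum(w)), tau2 = tau2)
}
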
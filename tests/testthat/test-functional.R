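test_that("trait distances match brute-force definitions", {
  # identical profiles -> 0; opposite single-trait profiles -> 1
  trait_of <- c(z_m1 = "z", z_m2 = "z")
  aff <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0))
  colnames(aff) <- names(trait_of)
  tt <- fw_traits(aff, trait_of)
  d <- as.matrix(trait_distance(tt, "gower_fuzzy"))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 1)
  # random profiles vs double loop
  tt2 <- random_fuzzy_traits(8, seed = 21)
  d2 <- as.matrix(trait_distance(tt2, "gower_fuzzy"))
  expect_equal(d2, oracle_gower_fuzzy(tt2$affinities, tt2$trait_of),
               tolerance = 1e-9)
  # scaled Euclidean is bounded in [0, 1] with max exactly 1
  de <- trait_distance(tt2, "euclidean_scaled")
  expect_equal(max(de), 1)
  expect_gte(min(de), 0)
  # taxa with missing traits are excluded and reported
  aff3 <- tt2$affinities
  aff3[1, 1:3] <- NA
  d3 <- trait_distance(fw_traits(aff3, tt2$trait_of))
  expect_equal(attr(d3, "excluded"), rownames(aff3)[1])
})

test_that("principal coordinates reproduce Euclidean configurations", {
  set.seed(31)
  pts <- matrix(stats::rnorm(10), 5, 2,
                dimnames = list(paste0("t", 1:5), NULL))
  d <- stats::dist(pts)
  sp <- trait_space(d, axes = 6)
  expect_equal(as.matrix(stats::dist(sp$coords)), as.matrix(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sp$correction, "none")
  # permutation of taxa leaves eigenvalues unchanged
  perm <- sample(5)
  sp2 <- trait_space(stats::dist(pts[perm, ]), axes = 6)
  expect_equal(sort(sp2$eig), sort(sp$eig), tolerance = 1e-9)
})

test_that("non-Euclidean distances trigger the configured correction", {
  # a violated triangle inequality cannot embed without correction
  m <- matrix(c(0, 1, 1, 10,
                1, 0, 1, 1,
                1, 1, 0, 1,
                10, 1, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d <- stats::as.dist(m)
  sp <- trait_space(d, correction = "sqrt")
  expect_equal(sp$correction, "sqrt")
  expect_true(all(sp$eig[seq_len(ncol(sp$coords))] >= 0))
  sp2 <- trait_space(d, correction = "cailliez")
  expect_equal(sp2$correction, "cailliez")
})

test_that("FRic behaves like a hull volume over present taxa", {
  coords <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1),
                  d = c(0.2, 0.2), e = c(2, 2))
  space <- structure(list(coords = coords, eig = c(1, 1),
                          correction = "none", taxa = rownames(coords)),
                     class = "fw_traitspace")
  comm <- c(a = 1, b = 1, c = 1)
  expect_equal(as.numeric(functional_richness(space, comm)), 0.5)
  # adding an interior taxon leaves the volume unchanged
  expect_equal(
    as.numeric(functional_richness(space, c(comm, d = 5))), 0.5)
  # monotone under union
  fa <- as.numeric(functional_richness(space, comm))
  fb <- as.numeric(functional_richness(space, c(a = 1, b = 1, e = 1)))
  fu <- as.numeric(functional_richness(space,
                                       c(a = 1, b = 1, c = 1, e = 1)))
  expect_gte(fu, max(fa, fb) - 1e-12)
  # fewer taxa than axes+1: falls back to S-1 axes
  sp6 <- structure(list(coords = cbind(coords, coords, coords),
                        eig = rep(1, 6), correction = "none",
                        taxa = rownames(coords)),
                   class = "fw_traitspace")
  fr <- functional_richness(sp6, c(a = 1, b = 1, c = 1))
  expect_equal(attr(fr, "axes_used"), 2L)
})

test_that("FEve matches the brute-force MST formula", {
  # equidistant points on a line with equal abundances -> 1
  space <- structure(list(coords = cbind(0:4, 0), eig = c(1, 0),
                          correction = "none",
                          taxa = paste0("t", 1:5)),
                     class = "fw_traitspace")
  rownames(space$coords) <- space$taxa
  even <- stats::setNames(rep(2, 5), space$taxa)
  expect_equal(functional_evenness(space, even), 1, tolerance = 1e-12)
  # clumped abundances reduce FEve
  clump <- stats::setNames(c(100, 1, 1, 1, 100), space$taxa)
  expect_lt(functional_evenness(space, clump), 1)
  # random configurations vs exhaustive spanning-tree oracle (n <= 6)
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    coords <- matrix(stats::rnorm(2 * n), n, 2,
                     dimnames = list(paste0("s", 1:n), NULL))
    ab <- stats::setNames(stats::runif(n, 1, 10), rownames(coords))
    sp <- structure(list(coords = coords, eig = c(1, 1),
                         correction = "none", taxa = rownames(coords)),
                    class = "fw_traitspace")
    expect_equal(functional_evenness(sp, ab), oracle_feve(coords, ab),
                 tolerance = 1e-9)
  }
  # fewer than 3 taxa -> missing
  expect_true(is.na(functional_evenness(space, even[1:2])))
})

test_that("FDiv follows the hull-centroid formula and its limits", {
  # symmetric square, equal abundances: all taxa equidistant -> FDiv
  # collapses to dbar/(0 + dbar) = 1
  coords <- rbind(a = c(0, 0), b = c(1, 0), c = c(1, 1), d = c(0, 1))
  sp <- structure(list(coords = coords, eig = c(1, 1),
                       correction = "none", taxa = rownames(coords)),
                  class = "fw_traitspace")
  eq <- stats::setNames(rep(1, 4), rownames(coords))
  expect_equal(functional_divergence(sp, eq), 1, tolerance = 1e-12)
  # hand-computed asymmetric fixture
  coords2 <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1), m = c(0.25, 0.25))
  sp2 <- structure(list(coords = coords2, eig = c(1, 1),
                        correction = "none", taxa = rownames(coords2)),
                   class = "fw_traitspace")
  ab <- c(a = 1, b = 1, c = 1, m = 1)
  gc <- colMeans(coords2[1:3, ])                  # hull vertices a, b, c
  dG <- sqrt(rowSums((coords2 - matrix(gc, 4, 2, byrow = TRUE))^2))
  dbar <- mean(dG)
  w <- rep(0.25, 4)
  hand <- (sum(w * (dG - dbar)) + dbar) / (sum(w * abs(dG - dbar)) + dbar)
  expect_equal(functional_divergence(sp2, ab), hand, tolerance = 1e-12)
  # abundance concentrated on extreme vertices pushes FDiv towards 1
  skew <- c(a = 100, b = 100, c = 100, m = 1)
  expect_gt(functional_divergence(sp2, skew),
            functional_divergence(sp2, c(a = 1, b = 1, c = 1, m = 100)))
  # label permutation invariance
  perm <- sample(4)
  sp3 <- structure(list(coords = coords2[perm, ], eig = c(1, 1),
                        correction = "none",
                        taxa = rownames(coords2)[perm]),
                   class = "fw_traitspace")
  expect_equal(functional_divergence(sp3, ab),
               functional_divergence(sp2, ab), tolerance = 1e-12)
})

test_that("Rao's Q, Simpson and redundancy satisfy their identities", {
  # two maximally distinct equal-abundance species
  dm <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  r <- rao_simpson_redundancy(dm, c(a = 1, b = 1))
  expect_equal(r$Q, 0.5)
  expect_equal(r$D, 0.5)
  expect_equal(r$redundancy, 0)
  # functionally identical species -> redundancy 1
  dm0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  r0 <- rao_simpson_redundancy(dm0, c(a = 1, b = 2, c = 3))
  expect_equal(r0$Q, 0)
  expect_equal(r0$redundancy, 1)
  # monoculture: D below tolerance -> undefined
  rm <- rao_simpson_redundancy(dm, c(a = 5, b = 0))
  expect_true(is.na(rm$redundancy))
  # random communities: oracle agreement and Q <= D (d in [0,1])
  set.seed(43)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    tt <- random_fuzzy_traits(n, seed = rep)
    d <- as.matrix(trait_distance(tt, "euclidean_scaled"))
    ab <- stats::setNames(stats::runif(n, 0, 5) + 0.1,
                          rownames(tt$affinities))
    p <- ab / sum(ab)
    r <- rao_simpson_redundancy(d, ab)
    expect_equal(r$Q, oracle_rao(d, p), tolerance = 1e-9)
    expect_lte(r$Q, r$D + 1e-12)
    expect_gte(r$redundancy, -1e-12)
    expect_lte(r$redundancy, 1 + 1e-12)
    # uniform abundance rescaling changes nothing
    r2 <- rao_simpson_redundancy(d, ab * 7)
    expect_equal(r2$Q, r$Q, tolerance = 1e-12)
  }
  # equal abundances and constant distance d0: Q = (1 - 1/S) d0
  S <- 5
  dmc <- matrix(0.4, S, S); diag(dmc) <- 0
  dimnames(dmc) <- list(paste0("t", 1:S), paste0("t", 1:S))
  rc <- rao_simpson_redundancy(dmc, stats::setNames(rep(1, S),
                                                    paste0("t", 1:S)))
  expect_equal(rc$Q, (1 - 1 / S) * 0.4, tolerance = 1e-12)
})

test_that("functional turnover of CWMs mirrors taxonomic turnover", {
  cwm <- rbind(`2000` = c(m1 = 0.5, m2 = 0.5, m3 = 0),
               `2001` = c(m1 = 0.5, m2 = 0.5, m3 = 0),
               `2003` = c(m1 = 0, m2 = 0, m3 = 1))
  ft <- functional_turnover(cwm)
  expect_equal(ft$year, c(2001, 2003))
  expect_equal(ft$turnover, c(0, 1))
  # single year -> empty
  expect_equal(nrow(functional_turnover(cwm[1, , drop = FALSE])), 0L)
  # hand-computed 3-year fixture with partial overlap
  cwm2 <- rbind(`2000` = c(m1 = 0.4, m2 = 0.6, m3 = 0),
                `2001` = c(m1 = 0, m2 = 0.3, m3 = 0.7))
  # gains {m3}, losses {m1}, pool {m1, m2, m3} -> 2/3
  expect_equal(functional_turnover(cwm2)$turnover, 2 / 3)
})

test_that("functional_metric_series runs end to end on a toy dataset", {
  set.seed(47)
  comm <- as_fw_community(site_events(years = 2000:2008, n_taxa = 8))
  comm$abundance <- stats::rpois(nrow(comm), 10) + 1
  tt <- random_fuzzy_traits(8, seed = 5)
  rownames(tt$affinities) <- paste0("t", 1:8)
  fm <- functional_metric_series(comm, tt, axes = 4)
  expect_setequal(unique(fm$metric),
                  c("FRic", "FEve", "FDiv", "RaoQ", "redundancy",
                    "functional_turnover"))
  red <- fm$value[fm$metric == "redundancy"]
  expect_true(all(red >= 0 & red <= 1))
})
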
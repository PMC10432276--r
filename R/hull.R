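# d-dimensional convex hull volume via an incremental beneath-beyond
# algorithm with simplicial facets. Written for the small point sets that
# arise in trait-space work (tens to a few hundred taxa, <= 6 axes).

facet_plane <- function(V) {
  # V: d x d matrix of facet vertex coordinates (rows). Returns unit
  # normal and offset b with normal %*% x = b on the facet plane.
  d <- ncol(V)
  if (d == 1L) return(list(normal = 1, b = V[1, 1]))
  E <- V[-1, , drop = FALSE] - matrix(V[1, ], d - 1L, d, byrow = TRUE)
  qrE <- qr(t(E))
  Q <- qr.Q(qrE, complete = TRUE)
  normal <- Q[, d]
  list(normal = normal, b = sum(normal * V[1, ]))
}

#' Convex hull volume of a point set
#'
#' Computes the volume (area for d = 2, length for d = 1) of the convex
#' hull of `points` in d dimensions, together with the hull's vertex set.
#' Points whose affine span has lower dimension than d yield volume 0 with
#' a degenerate flag.
#'
#' @param points numeric matrix, n points (rows) x d coordinates
#' @param tol relative tolerance for visibility / rank decisions
#' @return list with `volume`, `vertices` (row indices of hull vertices)
#'   and `degenerate` (logical)
#' @export
convhull_volume <- function(points, tol = 1e-10) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- ncol(points)
  scale <- max(1, max(abs(points)))
  eps <- tol * scale
  if (d == 1L) {
    i <- which.min(points[, 1]); j <- which.max(points[, 1])
    vol <- points[j, 1] - points[i, 1]
    return(list(volume = vol, vertices = unique(c(i, j)),
                degenerate = vol <= eps))
  }
  if (n < d + 1L) return(list(volume = 0, vertices = seq_len(n),
                              degenerate = TRUE))

  # greedy initial simplex: start from the lexicographic minimum, then add
  # the point farthest from the current affine hull
  ord <- do.call(order, lapply(seq_len(d), function(k) points[, k]))
  simplex <- ord[1L]
  for (k in seq_len(d)) {
    base <- points[simplex[1L], ]
    if (length(simplex) == 1L) {
      dist2 <- rowSums((points - matrix(base, n, d, byrow = TRUE))^2)
    } else {
      E <- points[simplex[-1L], , drop = FALSE] -
        matrix(base, length(simplex) - 1L, d, byrow = TRUE)
      qrE <- qr(t(E))
      R <- points - matrix(base, n, d, byrow = TRUE)
      proj <- t(qr.fitted(qrE, t(R)))
      dist2 <- rowSums((R - proj)^2)
    }
    dist2[simplex] <- -Inf
    cand <- which.max(dist2)
    if (dist2[cand] <= eps^2) {
      return(list(volume = 0, vertices = simplex, degenerate = TRUE))
    }
    simplex <- c(simplex, cand)
  }
  centre <- colMeans(points[simplex, , drop = FALSE])

  make_facet <- function(verts) {
    verts <- sort.int(verts)      # sorted so ridges come out pre-sorted
    pl <- facet_plane(points[verts, , drop = FALSE])
    s <- sum(pl$normal * centre) - pl$b
    if (s > 0) { pl$normal <- -pl$normal; pl$b <- -pl$b }
    list(verts = verts, normal = pl$normal, b = pl$b)
  }
  facets <- lapply(seq_len(d + 1L), function(i) make_facet(simplex[-i]))

  for (p in setdiff(seq_len(n), simplex)) {
    x <- points[p, ]
    vis <- vapply(facets, function(f) sum(f$normal * x) - f$b > eps,
                  logical(1))
    if (!any(vis)) next
    # horizon ridges: (d-1)-subsets appearing in exactly one visible facet
    vf <- facets[vis]
    ridge_mat <- matrix(0L, length(vf) * d, d - 1L)
    k <- 0L
    for (f in vf) {
      for (i in seq_len(d)) {
        k <- k + 1L
        ridge_mat[k, ] <- f$verts[-i]     # already sorted
      }
    }
    keys <- do.call(paste, c(as.data.frame(ridge_mat), sep = ","))
    once <- !(keys %in% keys[duplicated(keys)])
    horizon <- ridge_mat[once, , drop = FALSE]
    facets <- facets[!vis]
    for (i in seq_len(nrow(horizon))) {
      facets[[length(facets) + 1L]] <- make_facet(c(horizon[i, ], p))
    }
  }

  vol <- 0
  for (f in facets) {
    V <- points[f$verts, , drop = FALSE] -
      matrix(centre, d, d, byrow = TRUE)
    vol <- vol + abs(det(V))
  }
  vol <- vol / factorial(d)
  verts <- sort(unique(unlist(lapply(facets, `[[`, "verts"))))
  list(volume = vol, vertices = verts, degenerate = FALSE)
}
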
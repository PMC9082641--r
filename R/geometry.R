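# Planar geometry primitives for the synthetic region generator.
#
# Coordinates are projected kilometres; all distances are Euclidean. Voronoi
# cells clipped to a rectangle are convex, which the rest of the package
# relies on: territory membership reduces to nearest-generator, areas to the
# shoelace formula, and uniform sampling to fan triangulation.

# Clip a convex polygon (n x 2 matrix, vertices in order) by the half-plane
# {x : a . x <= b} (Sutherland-Hodgman, single edge).
clip_halfplane <- function(xy, a, b) {
  d <- drop(xy %*% a) - b
  keep <- d <= 0
  if (all(keep)) return(xy)
  if (!any(keep)) return(xy[0, , drop = FALSE])
  n <- nrow(xy)
  nxt <- c(seq_len(n)[-1], 1L)
  out <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    j <- nxt[i]
    if (keep[i]) {
      k <- k + 1L
      out[[k]] <- xy[i, ]
    }
    if (xor(keep[i], keep[j])) {
      t <- d[i] / (d[i] - d[j])
      k <- k + 1L
      out[[k]] <- xy[i, ] + t * (xy[j, ] - xy[i, ])
    }
  }
  do.call(rbind, out[seq_len(k)])
}

# Voronoi partition of generator points within a bounding rectangle.
# Returns a list of convex polygons (matrices), one per generator, in input
# order. O(n^2) half-plane clipping with a distance prune: a generator
# farther than twice the current cell's circumradius cannot cut the cell.
voronoi_partition <- function(pts, bbox) {
  n <- nrow(pts)
  rect <- matrix(c(bbox[1], bbox[3],
                   bbox[2], bbox[3],
                   bbox[2], bbox[4],
                   bbox[1], bbox[4]), ncol = 2, byrow = TRUE)
  lapply(seq_len(n), function(i) {
    p <- pts[i, ]
    poly <- rect
    d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    for (j in ord) {
      rmax2 <- max((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2)
      if (d2[j] > 4 * rmax2) break
      q <- pts[j, ]
      a <- q - p
      poly <- clip_halfplane(poly, a, sum(a * (p + q)) / 2)
      if (nrow(poly) < 3) break
    }
    poly
  })
}

# Shoelace area of a simple polygon (absolute value).
polygon_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(n)[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Area centroid of a simple polygon.
polygon_centroid <- function(xy) {
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(n)[-1], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Draw n points uniformly inside a convex polygon by fan triangulation:
# pick a triangle with probability proportional to its area, then a uniform
# point within it via the square-root warp.
sample_in_polygon <- function(poly, n) {
  m <- nrow(poly)
  stopifnot(m >= 3)
  v1 <- poly[1, ]
  k <- m - 2L
  areas <- numeric(k)
  for (t in seq_len(k)) {
    b <- poly[t + 1L, ] - v1
    c <- poly[t + 2L, ] - v1
    areas[t] <- abs(b[1] * c[2] - b[2] * c[1]) / 2
  }
  idx <- if (k == 1L) rep(1L, n) else
    sample.int(k, n, replace = TRUE, prob = areas)
  r1 <- sqrt(stats::runif(n))
  r2 <- stats::runif(n)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    b <- poly[idx[i] + 1L, ]
    c <- poly[idx[i] + 2L, ]
    out[i, ] <- (1 - r1[i]) * v1 + r1[i] * (1 - r2[i]) * b + r1[i] * r2[i] * c
  }
  out
}

# Euclidean distance between two points, or row-wise between matrices.
euclid <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- matrix(a, ncol = 2)
    b <- matrix(b, ncol = 2)
    sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
  } else {
    sqrt(sum((a - b)^2))
  }
}

# Full distance matrix between two point sets (na x 2, nb x 2) -> na x nb.
cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 2)
  b <- matrix(b, ncol = 2)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx^2 + dy^2)
}
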
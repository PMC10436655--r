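# Planar geometry primitives used throughout the package.
#
# Conventions: a *ring* is an n x 2 numeric matrix of vertices in order,
# not closed (first row is not repeated at the end). A *multipolygon* is a
# list of rings (pieces are interior-disjoint; holes are not supported —
# every geometry the package produces is a union of convex pieces). All
# coordinates are planar meters.

ring_matrix <- function(x, y) cbind(x = as.numeric(x), y = as.numeric(y))

#' Signed area of a ring (shoelace formula)
#' @param ring n x 2 vertex matrix, not closed.
#' @return Signed area; positive for counter-clockwise orientation.
#' @keywords internal
#' @noRd
ring_signed_area <- function(ring) {
  n <- nrow(ring)
  if (is.null(n) || n < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

ring_area <- function(ring) abs(ring_signed_area(ring))

mp_area <- function(mp) {
  if (length(mp) == 0) return(0)
  sum(vapply(mp, ring_area, numeric(1)))
}

ring_centroid <- function(ring) {
  n <- nrow(ring)
  if (n == 1L) return(as.numeric(ring[1, ]))
  if (n == 2L) return(colMeans(ring))
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(n, seq_len(n - 1L))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(ring))
  c(sum((x[j] + x) * cr) / (6 * a), sum((y[j] + y) * cr) / (6 * a))
}

mp_centroid <- function(mp) {
  areas <- vapply(mp, ring_area, numeric(1))
  cents <- t(vapply(mp, ring_centroid, numeric(2)))
  if (sum(areas) <= 0) return(colMeans(cents))
  c(sum(cents[, 1] * areas), sum(cents[, 2] * areas)) / sum(areas)
}

mp_bbox <- function(mp) {
  xy <- do.call(rbind, mp)
  c(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
    xmax = max(xy[, 1]), ymax = max(xy[, 2]))
}

bbox_ring <- function(bb) {
  ring_matrix(c(bb[1], bb[3], bb[3], bb[1]), c(bb[2], bb[2], bb[4], bb[4]))
}

#' Even-odd point-in-ring test, vectorised over points
#'
#' Points exactly on the boundary may land on either side; callers that
#' need a deterministic boundary rule resolve ties at a higher level.
#' @keywords internal
#' @noRd
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  x <- ring[, 1]; y <- ring[, 2]
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py))
    if (any(crosses)) {
      xs <- (x[j] - x[i]) * (py[crosses] - y[i]) / (y[j] - y[i]) + x[i]
      flip <- px[crosses] < xs
      inside[crosses] <- xor(inside[crosses], flip)
    }
    j <- i
  }
  inside
}

points_in_mp <- function(px, py, mp) {
  inside <- logical(length(px))
  bb <- mp_bbox(mp)
  cand <- px >= bb[1] & px <= bb[3] & py >= bb[2] & py <= bb[4]
  if (!any(cand)) return(inside)
  for (ring in mp) {
    todo <- cand & !inside
    if (!any(todo)) break
    inside[todo] <- points_in_ring(px[todo], py[todo], ring)
  }
  inside
}

# Clip a ring by the half-plane a*x + b*y + c <= 0 (one Sutherland-Hodgman
# step). Returns a possibly empty vertex matrix.
clip_halfplane <- function(ring, a, b, cc) {
  n <- nrow(ring)
  if (is.null(n) || n == 0L) return(ring_matrix(numeric(0), numeric(0)))
  d <- a * ring[, 1] + b * ring[, 2] + cc
  if (all(d <= 0)) return(ring)
  if (all(d > 0)) return(ring_matrix(numeric(0), numeric(0)))
  outx <- numeric(2L * n); outy <- numeric(2L * n); k <- 0L
  jp <- n
  for (i in seq_len(n)) {
    di <- d[i]; dj <- d[jp]
    if (dj <= 0) {
      if (di <= 0) {                      # in -> in
        k <- k + 1L; outx[k] <- ring[i, 1]; outy[k] <- ring[i, 2]
      } else {                            # in -> out: add crossing
        t <- dj / (dj - di)
        k <- k + 1L
        outx[k] <- ring[jp, 1] + t * (ring[i, 1] - ring[jp, 1])
        outy[k] <- ring[jp, 2] + t * (ring[i, 2] - ring[jp, 2])
      }
    } else {
      if (di <= 0) {                      # out -> in: crossing then vertex
        t <- dj / (dj - di)
        k <- k + 1L
        outx[k] <- ring[jp, 1] + t * (ring[i, 1] - ring[jp, 1])
        outy[k] <- ring[jp, 2] + t * (ring[i, 2] - ring[jp, 2])
        k <- k + 1L; outx[k] <- ring[i, 1]; outy[k] <- ring[i, 2]
      }
    }
    jp <- i
  }
  ring_matrix(outx[seq_len(k)], outy[seq_len(k)])
}

# Ensure counter-clockwise orientation.
ring_ccw <- function(ring) {
  if (ring_signed_area(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

#' Intersection of an arbitrary simple ring with a convex ring
#'
#' Sutherland-Hodgman clipping: the subject may be any simple polygon, the
#' clip ring must be convex. Returns a ring (possibly empty).
#' @keywords internal
#' @noRd
clip_ring_convex <- function(subject, clip) {
  clip <- ring_ccw(clip)
  n <- nrow(clip)
  out <- subject
  j <- n
  for (i in seq_len(n)) {
    # half-plane to the left of edge clip[j] -> clip[i]
    ex <- clip[i, 1] - clip[j, 1]; ey <- clip[i, 2] - clip[j, 2]
    # left of edge: ex*(y - yj) - ey*(x - xj) >= 0  =>  ey*x - ex*y + (ex*yj - ey*xj) <= 0
    a <- ey; b <- -ex; cc <- ex * clip[j, 2] - ey * clip[j, 1]
    out <- clip_halfplane(out, a, b, cc)
    if (nrow(out) == 0L) return(out)
    j <- i
  }
  out
}

is_convex_ring <- function(ring, tol = 1e-9) {
  n <- nrow(ring)
  if (n < 4) return(TRUE)
  x <- ring[, 1]; y <- ring[, 2]
  i1 <- seq_len(n); i2 <- c(2:n, 1L); i3 <- c(3:n, 1L, 2L)
  cr <- (x[i2] - x[i1]) * (y[i3] - y[i2]) - (y[i2] - y[i1]) * (x[i3] - x[i2])
  scale <- max(abs(cr), 1)
  all(cr >= -tol * scale) || all(cr <= tol * scale)
}

# Intersection area of two multipolygons. Exact when at least one side's
# pieces are all convex (clipping); otherwise estimated on a fine grid.
mp_intersection_area <- function(a, b, grid_n = 200L) {
  conv_b <- all(vapply(b, is_convex_ring, logical(1)))
  conv_a <- all(vapply(a, is_convex_ring, logical(1)))
  if (conv_b || conv_a) {
    if (!conv_b && conv_a) { tmp <- a; a <- b; b <- tmp }
    tot <- 0
    for (ra in a) for (rb in b) {
      piece <- clip_ring_convex(ra, rb)
      if (nrow(piece) >= 3) tot <- tot + ring_area(piece)
    }
    return(tot)
  }
  bba <- mp_bbox(a); bbb <- mp_bbox(b)
  bb <- c(max(bba[1], bbb[1]), max(bba[2], bbb[2]),
          min(bba[3], bbb[3]), min(bba[4], bbb[4]))
  if (bb[1] >= bb[3] || bb[2] >= bb[4]) return(0)
  gx <- seq(bb[1], bb[3], length.out = grid_n)
  gy <- seq(bb[2], bb[4], length.out = grid_n)
  px <- rep(gx, times = grid_n); py <- rep(gy, each = grid_n)
  frac <- mean(points_in_mp(px, py, a) & points_in_mp(px, py, b))
  frac * (bb[3] - bb[1]) * (bb[4] - bb[2])
}

# Minimum distance from points to the boundary segments of a ring,
# vectorised over segments for each point.
point_ring_boundary_dist <- function(px, py, ring) {
  n <- nrow(ring)
  x1 <- ring[, 1]; y1 <- ring[, 2]
  x2 <- ring[c(2:n, 1L), 1]; y2 <- ring[c(2:n, 1L), 2]
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- .Machine$double.eps
  out <- numeric(length(px))
  for (k in seq_along(px)) {
    t <- pmin(1, pmax(0, ((px[k] - x1) * dx + (py[k] - y1) * dy) / len2))
    out[k] <- sqrt(min((x1 + t * dx - px[k])^2 + (y1 + t * dy - py[k])^2))
  }
  out
}

mp_boundary_dist <- function(px, py, mp) {
  d <- rep(Inf, length(px))
  for (ring in mp) d <- pmin(d, point_ring_boundary_dist(px, py, ring))
  d
}

#' Voronoi cells of a seed set, clipped to a bounding rectangle
#'
#' Each cell is computed by successive half-plane clipping against the
#' perpendicular bisectors with every other seed, starting from the
#' bounding rectangle. Seeds sorted by distance are applied first and a
#' radius cutoff skips bisectors that cannot intersect the current cell,
#' so the expected cost is near-linear per cell.
#'
#' @param x,y Seed coordinates.
#' @param bbox Numeric c(xmin, ymin, xmax, ymax) enclosing all seeds.
#' @return List of convex rings, one per seed, partitioning the rectangle.
#' @keywords internal
#' @noRd
voronoi_cells <- function(x, y, bbox) {
  n <- length(x)
  base <- bbox_ring(bbox)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- base
    d2 <- (x - x[i])^2 + (y - y[i])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    for (j in ord) {
      # cutoff: bisector with a seed farther than twice the current cell
      # radius cannot cut the cell
      r2 <- max((cell[, 1] - x[i])^2 + (cell[, 2] - y[i])^2)
      if (d2[j] > 4 * r2) break
      a <- 2 * (x[j] - x[i]); b <- 2 * (y[j] - y[i])
      cc <- x[i]^2 + y[i]^2 - x[j]^2 - y[j]^2
      cell <- clip_halfplane(cell, a, b, cc)
      if (nrow(cell) == 0L) break
    }
    cells[[i]] <- cell
  }
  cells
}
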
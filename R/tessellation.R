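#' Estimate neighborhood boundaries from labeled seed points
#'
#' Builds the Thiessen (Voronoi) tessellation of the seed points and trims
#' it to the study area. Each neighborhood polygon is the locus of points
#' nearer to its seed than to any other seed, intersected with the study
#' area; the seed's name propagates to the polygon. This converts named
#' point labels (e.g. crowd-sourced "suburb" nodes placed at neighborhood
#' centers) into areal units suitable for small-area analysis where no
#' sub-administrative boundaries exist.
#'
#' Cells of the Voronoi diagram are computed inside a bounding envelope
#' padded by twice the study-area diameter, so unbounded cells are closed
#' before intersection. Seeds that fall outside the study area may yield
#' an empty polygon after trimming; these are dropped with a warning and
#' recorded in the `dropped` attribute.
#'
#' @param seeds A `labeled_points` data.frame (name, x, y).
#' @param study_area A `polygon_set` of study-area polygons (e.g.
#'   administrative sections). Pieces must be simple polygons.
#' @param coincident_tol Seeds closer than this (meters) are an error.
#' @return A `polygon_set` with one unit per retained seed and columns
#'   `population`, `case_count`, `rate_per_10k` initialised to `NA`, plus
#'   attributes `seed_xy` (retained seed coordinates) and `dropped`
#'   (names of seeds whose trimmed polygon was empty).
#' @export
build_thiessen <- function(seeds, study_area, coincident_tol = 1e-9) {
  if (nrow(seeds) < 1) stop("at least one seed is required")
  if (nrow(seeds) >= 2) {
    d <- as.matrix(stats::dist(cbind(seeds$x, seeds$y)))
    d[upper.tri(d, diag = TRUE)] <- Inf
    hit <- which(d < coincident_tol, arr.ind = TRUE)
    if (nrow(hit) > 0)
      stop(sprintf("coincident seeds: '%s' and '%s'",
                   seeds$name[hit[1, 2]], seeds$name[hit[1, 1]]))
  }
  bb <- set_bbox(study_area)
  diam <- sqrt((bb[3] - bb[1])^2 + (bb[4] - bb[2])^2)
  pad <- 2 * diam
  env <- c(min(bb[1], min(seeds$x)) - pad, min(bb[2], min(seeds$y)) - pad,
           max(bb[3], max(seeds$x)) + pad, max(bb[4], max(seeds$y)) + pad)
  cells <- if (nrow(seeds) == 1L) list(bbox_ring(env)) else
    voronoi_cells(seeds$x, seeds$y, env)

  area_tol <- 1e-12 * (diam^2)
  geoms <- vector("list", nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    pieces <- list()
    for (sec in study_area$geometry) {
      for (ring in sec) {
        piece <- clip_ring_convex(ring, cells[[i]])
        if (nrow(piece) >= 3 && ring_area(piece) > area_tol)
          pieces[[length(pieces) + 1L]] <- piece
      }
    }
    geoms[[i]] <- pieces
  }
  keep <- vapply(geoms, function(g) length(g) > 0, logical(1))
  if (any(!keep)) {
    warning(sprintf("dropped %d seed(s) with empty trimmed polygon: %s",
                    sum(!keep), paste(seeds$name[!keep], collapse = ", ")))
  }
  out <- polygon_set(seeds$name[keep], geoms[keep],
                     population = NA_real_, case_count = NA_integer_,
                     rate_per_10k = NA_real_)
  attr(out, "seed_xy") <- cbind(x = seeds$x[keep], y = seeds$y[keep])
  attr(out, "dropped") <- seeds$name[!keep]
  out
}

#' Validate a neighborhood partition against its study area
#'
#' Report-only diagnostics: the relative mismatch between the summed
#' polygon areas and the study-area area, total pairwise overlap area,
#' empty polygons, and a periphery-distortion metric — the ratio of each
#' polygon's area to the median polygon area, flagged beyond a threshold.
#' Thiessen estimates distort most near the study-area periphery, where
#' seed density falls off, so flagged units concentrate there.
#'
#' @param nbhds A `polygon_set` of neighborhoods.
#' @param study_area The study-area `polygon_set`.
#' @param distortion_threshold Flag units whose area ratio to the median
#'   exceeds this factor (default 3).
#' @return A list of class `partition_report`: `area_mismatch` (relative),
#'   `overlap_area`, `empty_units`, and a data.frame `distortion` with
#'   per-unit area ratios, flags and distance of the unit centroid from
#'   the study-area centroid.
#' @export
validate_partition <- function(nbhds, study_area, distortion_threshold = 3) {
  areas <- vapply(nbhds$geometry, mp_area, numeric(1))
  target <- set_area(study_area)
  mismatch <- abs(sum(areas) - target) / max(target, .Machine$double.eps)

  overlap <- 0
  bbs <- t(vapply(nbhds$geometry, mp_bbox, numeric(4)))
  n <- nrow(nbhds)
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq((i + 1), n)) {
      if (bbs[i, 1] > bbs[j, 3] || bbs[j, 1] > bbs[i, 3] ||
          bbs[i, 2] > bbs[j, 4] || bbs[j, 2] > bbs[i, 4]) next
      overlap <- overlap + mp_intersection_area(nbhds$geometry[[i]],
                                                nbhds$geometry[[j]])
    }
  }
  # pieces of a valid partition share boundaries; treat sliver-level
  # intersection as zero
  if (overlap < 1e-9 * target) overlap <- 0

  med <- stats::median(areas[areas > 0])
  ratio <- areas / med
  cents <- t(vapply(nbhds$geometry, mp_centroid, numeric(2)))
  acent <- c(
    stats::weighted.mean(vapply(study_area$geometry, function(g) mp_centroid(g)[1], numeric(1)),
                         vapply(study_area$geometry, mp_area, numeric(1))),
    stats::weighted.mean(vapply(study_area$geometry, function(g) mp_centroid(g)[2], numeric(1)),
                         vapply(study_area$geometry, mp_area, numeric(1))))
  structure(list(
    area_mismatch = mismatch,
    overlap_area = overlap,
    empty_units = nbhds$name[areas <= 0],
    distortion = data.frame(
      name = nbhds$name, area = areas, area_ratio = ratio,
      flagged = ratio > distortion_threshold | ratio < 1 / distortion_threshold,
      center_dist = sqrt((cents[, 1] - acent[1])^2 + (cents[, 2] - acent[2])^2),
      stringsAsFactors = FALSE)
  ), class = "partition_report")
}

#' @export
print.partition_report <- function(x, ...) {
  cat(sprintf("partition report: area mismatch %.3g (relative), overlap %.3g\n",
              x$area_mismatch, x$overlap_area))
  cat(sprintf("empty units: %d; distortion-flagged: %d of %d\n",
              length(x$empty_units), sum(x$distortion$flagged),
              nrow(x$distortion)))
  invisible(x)
}

#' Nearest-seed assignment of probe points
#'
#' Brute-force assignment of points to the nearest seed, with ties broken
#' toward the lexicographically smaller name. This is the defining
#' property of the Thiessen tessellation and serves as its independent
#' check.
#'
#' @param px,py Probe coordinates.
#' @param seeds A `labeled_points` data.frame.
#' @return Character vector of seed names.
#' @export
nearest_seed <- function(px, py, seeds) {
  ord <- order(seeds$name)
  sx <- seeds$x[ord]; sy <- seeds$y[ord]; nm <- seeds$name[ord]
  out <- character(length(px))
  for (k in seq_along(px)) {
    d2 <- (sx - px[k])^2 + (sy - py[k])^2
    out[k] <- nm[which.min(d2)]  # first minimum = smallest name on ties
  }
  out
}
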
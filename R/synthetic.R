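# Synthetic study generator.
#
# Emulates the structure of an urban injury-surveillance study in a city
# with low mapping penetration: a study area of administrative sections, a
# set of named neighborhood seed points densest near the city center, a
# heterogeneous gridded population, and a hospital line list of geocoded
# firearm-injury cases with day-level dates and block missingness. The
# defaults mirror the study design this package reproduces: 16 sections,
# 106 neighborhood seeds, a total population of ~3.57 million, an expected
# 248 firearm cases over a 406-day window of which 133 days (in 2-4 week
# blocks) carry no records.

#' Study-design truth for the synthetic generator
#'
#' Collects the design constants of a synthetic study: area and seed
#' counts, population, baseline case rate, embedded risk clusters, study
#' period and missing-data blocks. Missing blocks are contiguous runs of
#' 14 to 28 days drawn at construction time until the requested number of
#' missing days is reached.
#'
#' @param n_sections Number of study-area sections.
#' @param n_seeds Number of neighborhood seed points.
#' @param total_population Total persons in the study area.
#' @param baseline_rate Expected cases per person over the whole study
#'   period (default tuned so the expected case total is 248).
#' @param embedded_clusters List of clusters, each a list with `center`
#'   (xy), `radius` (m), `relative_risk` (>= 1) and optional `date_window`
#'   (length-2 Date vector inside the study period).
#' @param study_start,study_end Study period (inclusive).
#' @param missing_days Total days without records (0 for none).
#' @param missing_block_range Min/max length (days) of a missing block.
#' @param extent Study rectangle `c(xmin, ymin, xmax, ymax)` in meters.
#' @param rng_seed Integer seed; the truth object is deterministic in it.
#' @return An object of class `study_truth`.
#' @export
study_truth <- function(n_sections = 16L, n_seeds = 106L,
                        total_population = 3565000,
                        baseline_rate = 248 / 3565000,
                        embedded_clusters = list(),
                        study_start = as.Date("2019-11-22"),
                        study_end = as.Date("2020-12-31"),
                        missing_days = 133L,
                        missing_block_range = c(14L, 28L),
                        extent = c(0, 0, 15000, 15000),
                        rng_seed = 1L) {
  if (total_population <= 0) stop("total_population must be positive")
  n_days <- as.integer(study_end - study_start) + 1L
  if (n_days < 1) stop("study_end must not precede study_start")
  if (missing_days >= n_days) stop("missing_days must leave at least one day")
  for (cl in embedded_clusters) {
    if (is.null(cl$relative_risk) || cl$relative_risk < 1)
      stop("embedded cluster relative_risk must be >= 1")
    if (!is.null(cl$date_window)) {
      dw <- as.Date(cl$date_window)
      if (dw[1] < study_start || dw[2] > study_end || dw[1] > dw[2])
        stop("cluster date_window must lie within the study period")
    }
  }
  blocks <- list()
  if (missing_days > 0) {
    rng <- local_rng(rng_seed, "missing-blocks")
    taken <- rep(FALSE, n_days)
    remaining <- as.integer(missing_days)
    guard <- 0L
    while (remaining > 0 && guard < 10000L) {
      guard <- guard + 1L
      len <- min(remaining,
                 rng_int(rng, missing_block_range[1], missing_block_range[2]))
      if (remaining - len > 0 && remaining - len < missing_block_range[1])
        len <- remaining  # avoid leaving an impossible stub
      start <- rng_int(rng, 1L, n_days - len + 1L)
      idx <- start:(start + len - 1L)
      if (any(taken[idx])) next
      taken[idx] <- TRUE
      blocks[[length(blocks) + 1L]] <-
        c(study_start + start - 1L, study_start + start + len - 2L)
      remaining <- remaining - len
    }
    if (remaining > 0) stop("could not place missing blocks; reduce missing_days")
    blocks <- blocks[order(vapply(blocks, function(b) as.integer(b[1]), integer(1)))]
  }
  structure(list(
    n_sections = as.integer(n_sections), n_seeds = as.integer(n_seeds),
    total_population = total_population, baseline_rate = baseline_rate,
    embedded_clusters = embedded_clusters,
    study_start = study_start, study_end = study_end,
    missing_blocks = blocks, extent = extent,
    rng_seed = as.integer(rng_seed)
  ), class = "study_truth")
}

#' @export
print.study_truth <- function(x, ...) {
  n_days <- as.integer(x$study_end - x$study_start) + 1L
  miss <- sum(vapply(x$missing_blocks,
                     function(b) as.integer(b[2] - b[1]) + 1L, integer(1)))
  cat(sprintf("<study_truth: %d sections, %d seeds, pop %.3g, %d days (%d missing), %d embedded cluster(s)>\n",
              x$n_sections, x$n_seeds, x$total_population, n_days, miss,
              length(x$embedded_clusters)))
  invisible(x)
}

#' Days of the study period available for case dates
#' @param truth A `study_truth`.
#' @return Date vector of non-missing days.
#' @export
available_days <- function(truth) {
  days <- seq(truth$study_start, truth$study_end, by = "day")
  if (length(truth$missing_blocks) == 0) return(days)
  miss <- rep(FALSE, length(days))
  for (b in truth$missing_blocks)
    miss[days >= b[1] & days <= b[2]] <- TRUE
  days[!miss]
}

# isolated RNG stream: a seed derived from (rng_seed, tag) keeps the
# generator's sub-streams independent and below 2^31
local_rng <- function(rng_seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  seed <- (as.integer(rng_seed) * 7919L + h) %% 2147483647L
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    st
  }
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
  })
  expr
}

rng_int <- function(rng, lo, hi) {
  with_rng(rng, as.integer(lo) + if (hi > lo)
    sample.int(as.integer(hi - lo + 1L), 1L) - 1L else 0L)
}

#' Generate a synthetic study area
#'
#' Partitions a rectangle into `n_sections` interior-disjoint polygons —
#' a Voronoi partition of uniformly placed section seeds (or the rectangle
#' itself for one section). Section polygons are convex and their areas
#' sum to the extent area.
#'
#' @param n_sections Number of sections (>= 1).
#' @param extent Rectangle `c(xmin, ymin, xmax, ymax)`.
#' @param rng_seed Integer seed; output is deterministic in it.
#' @return A `polygon_set` with names `section_01`, ...
#' @export
generate_study_area <- function(n_sections, extent, rng_seed = 1L) {
  if (n_sections < 1) stop("n_sections must be >= 1")
  if (extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("extent is degenerate")
  nm <- sprintf("section_%02d", seq_len(n_sections))
  if (n_sections == 1L)
    return(polygon_set(nm, list(list(bbox_ring(extent)))))
  rng <- local_rng(rng_seed, "study-area")
  pts <- with_rng(rng, cbind(
    stats::runif(n_sections, extent[1], extent[3]),
    stats::runif(n_sections, extent[2], extent[4])))
  cells <- voronoi_cells(pts[, 1], pts[, 2], extent)
  polygon_set(nm, lapply(cells, list))
}

#' Generate named neighborhood seed points
#'
#' Rejection-samples `n_seeds` uniquely named points inside the study
#' area. With `center_bias > 0` acceptance decays exponentially with
#' distance from the area centroid, emulating label density that thins
#' toward the urban periphery; `center_bias = 0` gives spatially uniform
#' points.
#'
#' @param area Study-area `polygon_set`.
#' @param n_seeds Number of points (>= 1).
#' @param center_bias Nonnegative decay strength (unitless; distance is
#'   scaled by half the area diagonal).
#' @param rng_seed Integer seed.
#' @param min_separation Minimum pairwise distance between seeds, as a
#'   fraction of the area diagonal (guards the tessellation against
#'   near-coincident seeds).
#' @return A `labeled_points` data.frame with names `nbhd_001`, ...
#' @export
generate_suburb_seeds <- function(area, n_seeds, center_bias = 1.5,
                                  rng_seed = 1L, min_separation = 1e-4) {
  if (nrow(area) == 0 || set_area(area) <= 0) stop("study area is empty")
  if (n_seeds < 1) stop("n_seeds must be >= 1")
  bb <- set_bbox(area)
  diag_len <- sqrt((bb[3] - bb[1])^2 + (bb[4] - bb[2])^2)
  dscale <- diag_len / 2
  sep2 <- (min_separation * diag_len)^2
  cents <- t(vapply(area$geometry, mp_centroid, numeric(2)))
  w <- vapply(area$geometry, mp_area, numeric(1))
  ctr <- c(stats::weighted.mean(cents[, 1], w), stats::weighted.mean(cents[, 2], w))
  rng <- local_rng(rng_seed, "suburb-seeds")
  xs <- numeric(0); ys <- numeric(0)
  guard <- 0L
  while (length(xs) < n_seeds && guard < 200000L) {
    guard <- guard + 1L
    p <- with_rng(rng, stats::runif(3))
    px <- bb[1] + p[1] * (bb[3] - bb[1])
    py <- bb[2] + p[2] * (bb[4] - bb[2])
    if (center_bias > 0) {
      d <- sqrt((px - ctr[1])^2 + (py - ctr[2])^2)
      if (p[3] > exp(-center_bias * d / dscale)) next
    }
    inside <- any(vapply(area$geometry, function(mp)
      points_in_mp(px, py, mp), logical(1)))
    if (!inside) next
    if (length(xs) > 0 && min((xs - px)^2 + (ys - py)^2) < sep2) next
    xs <- c(xs, px); ys <- c(ys, py)
  }
  if (length(xs) < n_seeds)
    stop("rejection sampling failed to place all seeds; lower center_bias or min_separation")
  labeled_points(sprintf("nbhd_%03d", seq_len(n_seeds)), xs, ys)
}

#' Generate a heterogeneous gridded population
#'
#' Lays a regular grid of `cell_size` meter cells over the study-area
#' bounding box; cells whose centers fall inside the area receive
#' log-normal weights (urban-style heterogeneity), normalised and rounded
#' by largest remainder so the grid total equals `total_population`
#' exactly. Cells with centers outside the area are zero.
#'
#' @param area Study-area `polygon_set`.
#' @param cell_size Cell edge, meters (> 0).
#' @param total_population Total persons (>= 0).
#' @param rng_seed Integer seed.
#' @param sigma Log-normal sigma of cell weights (default 1).
#' @return A `pop_grid` object.
#' @export
generate_population_grid <- function(area, cell_size = 100,
                                     total_population, rng_seed = 1L,
                                     sigma = 1) {
  if (cell_size <= 0) stop("cell_size must be positive")
  if (total_population < 0) stop("total_population must be nonnegative")
  bb <- set_bbox(area)
  nx <- max(1L, ceiling((bb[3] - bb[1]) / cell_size))
  ny <- max(1L, ceiling((bb[4] - bb[2]) / cell_size))
  g <- pop_grid(origin = c(bb[1], bb[2]), cell_size = cell_size,
                values = matrix(0, nrow = ny, ncol = nx))
  ctr <- grid_centers(g)
  inside <- rep(FALSE, nrow(ctr))
  for (mp in area$geometry)
    inside <- inside | points_in_mp(ctr$x, ctr$y, mp)
  if (total_population == 0 || !any(inside)) return(g)
  rng <- local_rng(rng_seed, "population-grid")
  wts <- with_rng(rng, stats::rlnorm(sum(inside), 0, sigma))
  alloc <- wts / sum(wts) * total_population
  fl <- floor(alloc)
  rem <- as.integer(round(total_population - sum(fl)))
  if (rem > 0) {
    extra <- order(alloc - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  vals <- numeric(nrow(ctr)); vals[inside] <- fl
  g$values[cbind(ctr$row, ctr$col)] <- vals
  g
}

#' Generate a synthetic case line list
#'
#' Draws firearm-injury cases from a discrete Poisson process over grid
#' cells and study days: the case total is Poisson with mean
#' `baseline_rate * total_population`, scaled up by any embedded excess
#' risk; each case picks a cell with probability proportional to
#' population times the relative risk of any embedded cluster covering
#' the cell (during its date window), is jittered uniformly within the
#' cell, and receives a date uniform over non-missing days (reweighted
#' inside cluster windows). No case is dated inside a missing block.
#'
#' @param truth A `study_truth`.
#' @param grid A `pop_grid` (its total defines the population at risk).
#' @param rng_seed Integer seed.
#' @param nonfirearm_mean Expected count of additional non-firearm cases
#'   (drawn population-proportionally, uniform over available days);
#'   default 0.
#' @return A data.frame of class `case_records` with columns
#'   `case_id, x, y, date, is_firearm`.
#' @export
generate_cases <- function(truth, grid, rng_seed = 1L, nonfirearm_mean = 0) {
  days <- available_days(truth)
  if (length(days) == 0) stop("all study days are missing; cannot date cases")
  ctr <- grid_centers(grid)
  pop <- grid$values[cbind(ctr$row, ctr$col)]
  pos <- pop > 0
  if (!any(pos)) stop("population grid is empty")
  ctr <- ctr[pos, , drop = FALSE]; pop <- pop[pos]
  n_cells <- length(pop)
  d_avail <- length(days)

  # per-cluster masks: cells covered, days in window
  k <- length(truth$embedded_clusters)
  cell_mask <- matrix(FALSE, n_cells, max(1L, k))
  day_mask <- matrix(FALSE, d_avail, max(1L, k))
  rrs <- rep(1, max(1L, k))
  if (k > 0) {
    for (j in seq_len(k)) {
      cl <- truth$embedded_clusters[[j]]
      cell_mask[, j] <- (ctr$x - cl$center[1])^2 + (ctr$y - cl$center[2])^2 <=
        cl$radius^2
      day_mask[, j] <- if (is.null(cl$date_window)) TRUE else
        days >= as.Date(cl$date_window)[1] & days <= as.Date(cl$date_window)[2]
      rrs[j] <- cl$relative_risk
    }
  }
  # day-factor per cell: f_i(t) = prod over clusters covering cell i of
  # RR^[t in window]; cells share one of few patterns
  pat <- if (k > 0) apply(cell_mask, 1, function(m) paste(which(m), collapse = ","))
         else rep("", n_cells)
  upat <- unique(pat)
  day_w <- matrix(1, d_avail, length(upat))
  for (u in seq_along(upat)) {
    if (upat[u] == "") next
    for (j in as.integer(strsplit(upat[u], ",")[[1]]))
      day_w[, u] <- day_w[, u] * ifelse(day_mask[, j], rrs[j], 1)
  }
  pat_id <- match(pat, upat)
  day_sum <- colSums(day_w)                       # per pattern
  cell_w <- pop * day_sum[pat_id] / d_avail       # marginal cell weight
  lambda <- truth$baseline_rate * sum(cell_w)     # = rate * P * excess factor

  rng <- local_rng(rng_seed, "cases")
  out <- with_rng(rng, {
    n <- stats::rpois(1, lambda)
    if (n == 0) {
      data.frame(case_id = character(0), x = numeric(0), y = numeric(0),
                 date = as.Date(character(0)), is_firearm = logical(0),
                 stringsAsFactors = FALSE)
    } else {
      cell <- sample.int(n_cells, n, replace = TRUE, prob = cell_w)
      jx <- stats::runif(n, -0.5, 0.5) * grid$cell_size
      jy <- stats::runif(n, -0.5, 0.5) * grid$cell_size
      u <- stats::runif(n)
      cdfs <- apply(day_w, 2, function(wc) cumsum(wc) / sum(wc))
      di <- integer(n)
      for (i in seq_len(n))
        di[i] <- findInterval(u[i], cdfs[, pat_id[cell[i]]],
                              left.open = TRUE) + 1L
      data.frame(case_id = sprintf("case_%05d", seq_len(n)),
                 x = ctr$x[cell] + jx, y = ctr$y[cell] + jy,
                 date = days[di], is_firearm = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  if (nonfirearm_mean > 0) {
    extra <- with_rng(rng, {
      m <- stats::rpois(1, nonfirearm_mean)
      if (m == 0) NULL else {
        cell <- sample.int(n_cells, m, replace = TRUE, prob = pop)
        data.frame(case_id = sprintf("ctrl_%05d", seq_len(m)),
                   x = ctr$x[cell] + stats::runif(m, -0.5, 0.5) * grid$cell_size,
                   y = ctr$y[cell] + stats::runif(m, -0.5, 0.5) * grid$cell_size,
                   date = days[sample.int(d_avail, m, replace = TRUE)],
                   is_firearm = FALSE, stringsAsFactors = FALSE)
      }
    })
    if (!is.null(extra)) out <- rbind(out, extra)
  }
  class(out) <- c("case_records", "data.frame")
  out
}

#' Generate the full synthetic study
#'
#' Convenience wrapper chaining area, seeds, grid and cases from one
#' `study_truth`.
#'
#' @param truth A `study_truth`.
#' @param cell_size Grid cell edge, meters.
#' @param center_bias Seed density decay (see [generate_suburb_seeds()]).
#' @param sigma Population heterogeneity (see [generate_population_grid()]).
#' @param nonfirearm_mean Passed to [generate_cases()].
#' @return List with `area`, `seeds`, `grid`, `cases`, `truth`.
#' @export
generate_study <- function(truth, cell_size = 100, center_bias = 1.5,
                           sigma = 1, nonfirearm_mean = 0) {
  area <- generate_study_area(truth$n_sections, truth$extent, truth$rng_seed)
  seeds <- generate_suburb_seeds(area, truth$n_seeds, center_bias,
                                 truth$rng_seed)
  grid <- generate_population_grid(area, cell_size, truth$total_population,
                                   truth$rng_seed, sigma)
  cases <- generate_cases(truth, grid, truth$rng_seed, nonfirearm_mean)
  list(area = area, seeds = seeds, grid = grid, cases = cases, truth = truth)
}
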
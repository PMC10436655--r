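# Attach population and cases to neighborhoods; rates; exploratory KDE.

# Deterministic one-of assignment of points to units: units are visited
# in lexicographic name order and a point, once assigned, is never
# re-tested, so boundary points land in exactly one unit (the
# lexicographically smallest containing name).
assign_points_to_units <- function(px, py, nbhds) {
  n <- length(px)
  assigned <- rep(NA_integer_, n)
  ord <- order(nbhds$name)
  bbs <- t(vapply(nbhds$geometry, mp_bbox, numeric(4)))
  for (i in ord) {
    todo <- which(is.na(assigned) &
                    px >= bbs[i, 1] & px <= bbs[i, 3] &
                    py >= bbs[i, 2] & py <= bbs[i, 4])
    if (length(todo) == 0) next
    hit <- points_in_mp(px[todo], py[todo], nbhds$geometry[[i]])
    assigned[todo[hit]] <- i
  }
  assigned
}

#' Zonal population sums over neighborhoods
#'
#' Sums grid cell values whose cell centers fall inside each neighborhood
#' polygon (cell-center containment, the common zonal-extraction default:
#' conservation is exact because every center contributes to at most one
#' unit). Cell centers on a shared boundary are assigned to the
#' lexicographically smallest containing unit name.
#'
#' @param grid A `pop_grid`.
#' @param nbhds A `polygon_set`.
#' @return `nbhds` with its `population` column filled; attribute
#'   `unassigned_population` holds the total over cell centers inside no
#'   unit. Warns if the grid lies entirely outside the units.
#' @export
zonal_population <- function(grid, nbhds) {
  ctr <- grid_centers(grid)
  vals <- grid$values[cbind(ctr$row, ctr$col)]
  keep <- vals > 0
  assigned <- assign_points_to_units(ctr$x[keep], ctr$y[keep], nbhds)
  pops <- rep(0, nrow(nbhds))
  tab <- tapply(vals[keep], assigned, sum)
  pops[as.integer(names(tab))] <- tab
  if (sum(vals) > 0 && sum(pops) == 0)
    warning("population grid lies entirely outside the neighborhoods; populations are zero")
  nbhds$population <- pops
  attr(nbhds, "unassigned_population") <- sum(vals[keep][is.na(assigned)])
  nbhds
}

#' Assign cases to neighborhoods by spatial join
#'
#' Counts each in-area case in exactly one neighborhood (boundary points
#' go to the lexicographically smallest containing name); cases outside
#' every neighborhood are returned in the `excluded` attribute, mirroring
#' the exclusion of patients residing outside the study area. Records
#' with non-finite coordinates or missing dates are rejected per record
#' with a reason.
#'
#' @param cases A data.frame with columns `case_id, x, y, date,
#'   is_firearm`.
#' @param nbhds A `polygon_set`.
#' @param firearm_only If TRUE (default) only `is_firearm` cases count.
#' @return `nbhds` with `case_count` filled; attributes `excluded`
#'   (data.frame of in-filter cases outside the area) and `rejected`
#'   (malformed records with a `reason` column).
#' @export
assign_cases <- function(cases, nbhds, firearm_only = TRUE) {
  cases <- as.data.frame(cases)
  bad_xy <- !is.finite(cases$x) | !is.finite(cases$y)
  bad_date <- is.na(cases$date)
  rejected <- cases[bad_xy | bad_date, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- ifelse(bad_xy[bad_xy | bad_date],
                              "non-finite coordinates", "missing date")
    warning(sprintf("rejected %d malformed case record(s)", nrow(rejected)))
  }
  ok <- cases[!(bad_xy | bad_date), , drop = FALSE]
  if (firearm_only) ok <- ok[as.logical(ok$is_firearm), , drop = FALSE]
  assigned <- if (nrow(ok) > 0)
    assign_points_to_units(ok$x, ok$y, nbhds) else integer(0)
  counts <- integer(nrow(nbhds))
  tab <- table(assigned)
  counts[as.integer(names(tab))] <- as.integer(tab)
  nbhds$case_count <- counts
  attr(nbhds, "excluded") <- ok[is.na(assigned), , drop = FALSE]
  attr(nbhds, "rejected") <- rejected
  attr(nbhds, "case_assignment") <- assigned
  nbhds
}

#' Population-adjusted rates per 10,000 persons
#'
#' `rate = 10000 * case_count / population`. Units with zero population
#' and zero cases get rate 0; zero population with cases is flagged
#' invalid (rate `NA`, with a warning).
#'
#' @param nbhds A `polygon_set` with `population` and `case_count` filled.
#' @return `nbhds` with `rate_per_10k` filled.
#' @export
compute_rates <- function(nbhds) {
  if (any(is.na(nbhds$population)) || any(is.na(nbhds$case_count)))
    stop("populations and case counts must be filled before computing rates")
  if (any(nbhds$population < 0) || any(nbhds$case_count < 0))
    stop("populations and case counts must be nonnegative")
  rate <- ifelse(nbhds$population > 0,
                 10000 * nbhds$case_count / nbhds$population, 0)
  bad <- nbhds$population == 0 & nbhds$case_count > 0
  if (any(bad)) {
    warning(sprintf("%d unit(s) have cases but zero population; rate set to NA",
                    sum(bad)))
    rate[bad] <- NA_real_
  }
  nbhds$rate_per_10k <- rate
  nbhds
}

#' Exploratory kernel density surface of case locations
#'
#' Axis-aligned Gaussian product-kernel density on a square lattice over
#' a bounding box, scaled so the surface integrates to the number of
#' input points. Automatic per-axis bandwidth uses the normal-reference
#' rule. The surface is exploratory output only; no downstream statistic
#' consumes it.
#'
#' @param x,y Case coordinates (>= 2 points for automatic bandwidth).
#' @param bandwidth `"auto"` or a length-1/2 numeric: Gaussian kernel
#'   standard deviation in meters per axis.
#' @param grid_n Lattice size per axis.
#' @param bbox Optional `c(xmin, ymin, xmax, ymax)`; defaults to the
#'   point range padded by three bandwidths.
#' @return List of class `density_surface`: `x`, `y` (lattice axes), `z`
#'   (density, persons per square meter scale such that
#'   `sum(z) * cell_area ~ length(x)`), `bandwidth` (per-axis sd).
#' @export
kde_surface <- function(x, y, bandwidth = "auto", grid_n = 128L,
                        bbox = NULL) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (identical(bandwidth, "auto")) {
    if (length(x) < 2) stop("automatic bandwidth needs at least 2 points")
    hx <- MASS::bandwidth.nrd(x); hy <- MASS::bandwidth.nrd(y)
    if (hx <= 0 || hy <= 0)
      stop("points are degenerate along an axis; supply an explicit bandwidth")
    bw <- c(hx, hy) / 4   # bandwidth.nrd is 4x the kernel sd
  } else {
    bw <- rep(as.numeric(bandwidth), length.out = 2)
    if (any(bw <= 0)) stop("bandwidth must be positive")
  }
  if (is.null(bbox)) {
    bbox <- c(min(x) - 3 * bw[1], min(y) - 3 * bw[2],
              max(x) + 3 * bw[1], max(y) + 3 * bw[2])
  }
  k <- MASS::kde2d(x, y, h = 4 * bw, n = grid_n,
                   lims = c(bbox[1], bbox[3], bbox[2], bbox[4]))
  structure(list(x = k$x, y = k$y, z = k$z * length(x), bandwidth = bw),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf("<density_surface: %d x %d lattice, bandwidth (%.4g, %.4g) m>\n",
              length(x$x), length(x$y), x$bandwidth[1], x$bandwidth[2]))
  invisible(x)
}

#' Communal-section style summary table
#'
#' Case counts, population and rate per 10,000 aggregated over any
#' polygon set (e.g. the administrative sections, for the exploratory
#' table at section level).
#'
#' @param units A `polygon_set`.
#' @param grid A `pop_grid`.
#' @param cases Case data.frame.
#' @param firearm_only Passed to [assign_cases()].
#' @return A data.frame `name, population, case_count, rate_per_10k`.
#' @export
section_summary <- function(units, grid, cases, firearm_only = TRUE) {
  u <- zonal_population(grid, units)
  u <- assign_cases(cases, u, firearm_only = firearm_only)
  u <- compute_rates(u)
  as.data.frame(u[, c("name", "population", "case_count", "rate_per_10k")])
}
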
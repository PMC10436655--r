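#' Polygon set container
#'
#' A light-weight areal-unit container: a data.frame with a `name` column
#' and a `geometry` list-column whose elements are multipolygons (lists of
#' n x 2 vertex matrices, planar meters). Neighborhood sets add
#' `population`, `case_count` and `rate_per_10k` columns as the pipeline
#' fills them in.
#'
#' @param name Character vector of unique unit names.
#' @param geometry List of multipolygons (each a list of vertex matrices).
#' @param ... Further per-unit columns (e.g. population).
#' @return An object of class `polygon_set` (a data.frame).
#' @export
polygon_set <- function(name, geometry, ...) {
  stopifnot(length(name) == length(geometry))
  if (anyDuplicated(name)) stop("unit names must be unique")
  geometry <- lapply(geometry, function(g) {
    if (is.matrix(g)) list(g) else g
  })
  out <- data.frame(name = as.character(name), stringsAsFactors = FALSE, ...)
  out$geometry <- geometry
  class(out) <- c("polygon_set", "data.frame")
  out
}

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set: %d units, total area %.6g>\n",
              nrow(x), sum(vapply(x$geometry, mp_area, numeric(1)))))
  cols <- setdiff(names(x), "geometry")
  print.data.frame(utils::head(x[, cols, drop = FALSE], 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more units\n")
  invisible(x)
}

#' Total area and bounding box of a polygon set
#' @param x A `polygon_set`.
#' @return `set_area`: total area (sum over units). `set_bbox`: numeric
#'   `c(xmin, ymin, xmax, ymax)`.
#' @export
set_area <- function(x) sum(vapply(x$geometry, mp_area, numeric(1)))

#' @rdname set_area
#' @export
set_bbox <- function(x) {
  bbs <- t(vapply(x$geometry, mp_bbox, numeric(4)))
  c(xmin = min(bbs[, 1]), ymin = min(bbs[, 2]),
    xmax = max(bbs[, 3]), ymax = max(bbs[, 4]))
}

#' Area-weighted centroids of each unit
#' @param x A `polygon_set`.
#' @return A data.frame with columns `name`, `x`, `y`.
#' @export
set_centroids <- function(x) {
  ce <- t(vapply(x$geometry, mp_centroid, numeric(2)))
  data.frame(name = x$name, x = ce[, 1], y = ce[, 2],
             stringsAsFactors = FALSE)
}

#' Labeled seed points
#'
#' @param name Unique names, one per point.
#' @param x,y Planar coordinates (meters); must be finite.
#' @return A data.frame of class `labeled_points`.
#' @export
labeled_points <- function(name, x, y) {
  if (anyDuplicated(name)) stop("point names must be unique")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("point coordinates must be finite")
  out <- data.frame(name = as.character(name), x = as.numeric(x),
                    y = as.numeric(y), stringsAsFactors = FALSE)
  class(out) <- c("labeled_points", "data.frame")
  out
}
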
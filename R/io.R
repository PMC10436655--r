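# Readers and writers: GeoJSON for points and polygon sets, ESRI ASCII
# grid for the population raster, CSV line lists and reports, JSON
# summaries. Coordinates are planar meters throughout; GeoJSON files
# carry a `metadata` member noting the planar CRS, the tool version and
# the seed used to produce them (formats that admit no comments, like the
# ASCII grid, are written bare).

io_metadata <- function(rng_seed = NULL) {
  m <- list(tool = "voroscan",
            version = as.character(utils::packageVersion("voroscan")),
            crs = "planar meters (no geographic CRS)")
  if (!is.null(rng_seed)) m$rng_seed <- as.integer(rng_seed)
  m
}

#' Write / read labeled points as GeoJSON
#'
#' @param points A `labeled_points` data.frame.
#' @param path Output file.
#' @param rng_seed Optional seed recorded in the file metadata.
#' @return `read_geojson_points` returns a `labeled_points`.
#' @export
write_geojson_points <- function(points, path, rng_seed = NULL) {
  feats <- lapply(seq_len(nrow(points)), function(i) list(
    type = "Feature",
    properties = list(name = points$name[i]),
    geometry = list(type = "Point",
                    coordinates = c(round(points$x[i], 6),
                                    round(points$y[i], 6)))))
  obj <- list(type = "FeatureCollection", metadata = io_metadata(rng_seed),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_geojson_points
#' @export
read_geojson_points <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$features)) stop(sprintf("'%s': not a GeoJSON FeatureCollection", path))
  rows <- lapply(seq_along(obj$features), function(i) {
    f <- obj$features[[i]]
    if (is.null(f$geometry) || !identical(f$geometry$type, "Point"))
      stop(sprintf("'%s': feature %d is not a Point", path, i))
    data.frame(name = as.character(f$properties$name %||% sprintf("point_%03d", i)),
               x = as.numeric(f$geometry$coordinates[[1]]),
               y = as.numeric(f$geometry$coordinates[[2]]),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  labeled_points(d$name, d$x, d$y)
}

mp_to_geojson_coords <- function(mp) {
  lapply(mp, function(ring) {
    ring <- rbind(ring, ring[1, , drop = FALSE])  # close the ring
    list(lapply(seq_len(nrow(ring)),
                function(i) c(round(ring[i, 1], 6), round(ring[i, 2], 6))))
  })
}

#' Write / read a polygon set as GeoJSON
#'
#' Each unit becomes a MultiPolygon feature; `name` and any of
#' `population`, `case_count`, `rate_per_10k` present are written as
#' feature properties.
#'
#' @param x A `polygon_set`.
#' @param path Output file.
#' @param rng_seed Optional seed recorded in metadata.
#' @export
write_geojson_polygons <- function(x, path, rng_seed = NULL) {
  extra <- intersect(c("population", "case_count", "rate_per_10k"),
                     names(x))
  feats <- lapply(seq_len(nrow(x)), function(i) {
    props <- list(name = x$name[i])
    for (cn in extra) props[[cn]] <- unname(x[[cn]][i])
    list(type = "Feature", properties = props,
         geometry = list(type = "MultiPolygon",
                         coordinates = mp_to_geojson_coords(x$geometry[[i]])))
  })
  obj <- list(type = "FeatureCollection", metadata = io_metadata(rng_seed),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_geojson_polygons
#' @export
read_geojson_polygons <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$features)) stop(sprintf("'%s': not a GeoJSON FeatureCollection", path))
  name <- character(0); geoms <- list()
  extra <- list(population = numeric(0), case_count = numeric(0),
                rate_per_10k = numeric(0))
  seen_extra <- c(population = FALSE, case_count = FALSE,
                  rate_per_10k = FALSE)
  parse_poly <- function(coords) {
    # a GeoJSON Polygon: list of rings; keep outer rings only
    lapply(coords, function(ring) {
      m <- do.call(rbind, lapply(ring, function(pt)
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
      if (nrow(m) >= 2 &&
          isTRUE(all.equal(m[1, ], m[nrow(m), ], tolerance = 1e-12)))
        m <- m[-nrow(m), , drop = FALSE]
      colnames(m) <- c("x", "y")
      m
    })[1]
  }
  for (i in seq_along(obj$features)) {
    f <- obj$features[[i]]
    g <- f$geometry
    if (is.null(g)) stop(sprintf("'%s': feature %d has no geometry", path, i))
    mp <- switch(g$type,
      Polygon = parse_poly(g$coordinates),
      MultiPolygon = unlist(lapply(g$coordinates, parse_poly),
                            recursive = FALSE),
      stop(sprintf("'%s': feature %d has unsupported type '%s'",
                   path, i, g$type)))
    name <- c(name, as.character(f$properties$name %||% sprintf("unit_%03d", i)))
    geoms[[length(geoms) + 1L]] <- mp
    for (cn in names(extra)) {
      v <- f$properties[[cn]]
      if (!is.null(v)) seen_extra[cn] <- TRUE
      extra[[cn]] <- c(extra[[cn]], if (is.null(v)) NA_real_ else as.numeric(v))
    }
  }
  out <- polygon_set(name, geoms)
  for (cn in names(extra)) if (seen_extra[cn]) out[[cn]] <- extra[[cn]]
  out
}

#' Write / read a population grid as ESRI ASCII grid
#'
#' Plain-text raster interchange: a 6-line header (`ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value`) followed by rows of cell
#' values, northernmost row first.
#'
#' @param grid A `pop_grid`.
#' @param path Output file (conventionally `.asc`).
#' @export
write_asc_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(grid$values)),
    sprintf("nrows %d", nrow(grid$values)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    "NODATA_value -9999"), con)
  utils::write.table(grid$values, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_asc_grid
#' @export
read_asc_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, character(1), 1))
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys))
    stop(sprintf("'%s': malformed ASCII grid header", path))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  if (nrow(m) != vals["nrows"] || ncol(m) != vals["ncols"])
    stop(sprintf("'%s': grid body does not match header dimensions", path))
  m[m == -9999] <- 0
  pop_grid(origin = c(vals["xllcorner"], vals["yllcorner"]),
           cell_size = vals["cellsize"], values = m)
}

#' Write / read a case line list CSV
#'
#' Columns `case_id, x, y, date, is_firearm`; dates ISO-8601. The writer
#' prepends a `#` comment line with the tool version and seed. The reader
#' rejects malformed rows (bad date or non-numeric coordinates) with a
#' warning naming the row numbers; rejected rows are returned in the
#' `rejected` attribute.
#'
#' @param cases Case data.frame.
#' @param path CSV path.
#' @param rng_seed Optional seed recorded in the header comment.
#' @export
write_cases_csv <- function(cases, path, rng_seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- io_metadata(rng_seed)
  writeLines(sprintf("# %s %s%s", meta$tool, meta$version,
                     if (is.null(rng_seed)) "" else
                       sprintf(" seed=%d", as.integer(rng_seed))), con)
  df <- as.data.frame(cases)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cases_csv
#' @export
read_cases_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("case_id", "x", "y", "date", "is_firearm")
  if (!all(need %in% names(d)))
    stop(sprintf("'%s': missing columns: %s", path,
                 paste(setdiff(need, names(d)), collapse = ", ")))
  x <- suppressWarnings(as.numeric(d$x))
  y <- suppressWarnings(as.numeric(d$y))
  date <- as.Date(d$date, format = "%Y-%m-%d")
  fire <- d$is_firearm %in% c("TRUE", "true", "1")
  bad <- !is.finite(x) | !is.finite(y) | is.na(date)
  if (any(bad))
    warning(sprintf("'%s': rejected malformed row(s): %s", path,
                    paste(which(bad), collapse = ", ")))
  out <- data.frame(case_id = d$case_id[!bad], x = x[!bad], y = y[!bad],
                    date = date[!bad], is_firearm = fire[!bad],
                    stringsAsFactors = FALSE)
  attr(out, "rejected") <- cbind(d[bad, , drop = FALSE],
                                 row = which(bad))
  class(out) <- c("case_records", "data.frame")
  out
}

#' Write a JSON summary
#' @param x A list of scalar summaries.
#' @param path Output path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
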
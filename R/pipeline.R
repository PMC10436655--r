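#' Run the full small-area analysis pipeline
#'
#' Chains the stages: simulate (optional) -> tessellate -> aggregate ->
#' global/local Moran -> spatial scan -> space-time scan -> reports.
#' Every stage's outputs are written under `output_dir` together with a
#' `manifest.json` recording inputs, seed and package version; a rerun
#' with the same config and seed writes identical manifests.
#'
#' @param config A named list or a path to a YAML file. Recognised
#'   fields: `rng_seed`; `output_dir`; either `simulate` (a list of
#'   [study_truth()] arguments, plus optional `cell_size`, `center_bias`,
#'   `sigma`) or `inputs` (paths `seeds`, `sections`, `grid`, `cases`,
#'   plus `study_start`, `study_end`); `lisa` (list: `reps`, `alpha`);
#'   `scan` (list of [scan_config()] arguments plus logical
#'   `exclude_missing_days_from_baseline`); logical switches
#'   `run_spacetime`, `run_kde`.
#' @return Invisibly, a list with the stage objects (`area`, `seeds`,
#'   `grid`, `cases`, `nbhds`, `weights`, `moran`, `lisa`,
#'   `scan_spatial`, `scan_spacetime`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$rng_seed %||% 1L)
  out_dir <- config$output_dir %||% stop("config error: 'output_dir' is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "voroscan",
                   version = as.character(utils::packageVersion("voroscan")),
                   rng_seed = seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message(sprintf("[%s] done", stage))
  }

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    truth_args <- sim[setdiff(names(sim), c("cell_size", "center_bias",
                                            "sigma", "nonfirearm_mean"))]
    truth_args$rng_seed <- seed
    if (!is.null(truth_args$study_start))
      truth_args$study_start <- as.Date(truth_args$study_start)
    if (!is.null(truth_args$study_end))
      truth_args$study_end <- as.Date(truth_args$study_end)
    truth <- do.call(study_truth, truth_args)
    study <- generate_study(truth,
                            cell_size = sim$cell_size %||% 100,
                            center_bias = sim$center_bias %||% 1.5,
                            sigma = sim$sigma %||% 1,
                            nonfirearm_mean = sim$nonfirearm_mean %||% 0)
    area <- study$area; seeds <- study$seeds
    grid <- study$grid; cases <- study$cases
    study_start <- truth$study_start; study_end <- truth$study_end
    avail <- available_days(truth)
    write_geojson_polygons(area, file.path(out_dir, "sections.geojson"), seed)
    write_geojson_points(seeds, file.path(out_dir, "seeds.geojson"), seed)
    write_asc_grid(grid, file.path(out_dir, "popgrid.asc"))
    write_cases_csv(cases, file.path(out_dir, "cases.csv"), seed)
    note("simulate", n_sections = truth$n_sections, n_seeds = truth$n_seeds,
         total_population = truth$total_population,
         n_cases = nrow(cases))
  } else {
    inp <- config$inputs %||% stop("config error: either 'simulate' or 'inputs' is required")
    for (f in c("seeds", "sections", "grid", "cases"))
      if (is.null(inp[[f]]))
        stop(sprintf("config error: missing input path '%s'", f))
      else if (!file.exists(inp[[f]]))
        stop(sprintf("config error: input '%s' not found at '%s'", f, inp[[f]]))
    seeds <- read_geojson_points(inp$seeds)
    area <- read_geojson_polygons(inp$sections)
    grid <- read_asc_grid(inp$grid)
    cases <- read_cases_csv(inp$cases)
    study_start <- as.Date(inp$study_start %||% min(cases$date))
    study_end <- as.Date(inp$study_end %||% max(cases$date))
    avail <- sort(unique(cases$date))
    note("load", seeds = inp$seeds, sections = inp$sections,
         grid = inp$grid, cases = inp$cases)
  }

  nbhds <- build_thiessen(seeds, area)
  report <- validate_partition(nbhds, area)
  note("tessellate", n_neighborhoods = nrow(nbhds),
       area_mismatch = report$area_mismatch,
       dropped = as.list(attr(nbhds, "dropped")))

  nbhds <- zonal_population(grid, nbhds)
  nbhds <- assign_cases(cases, nbhds, firearm_only = TRUE)
  nbhds <- compute_rates(nbhds)
  excluded <- attr(nbhds, "excluded")
  write_geojson_polygons(nbhds, file.path(out_dir, "neighborhoods.geojson"),
                         seed)
  sec_summary <- section_summary(area, grid, cases)
  utils::write.csv(sec_summary, file.path(out_dir, "section_summary.csv"),
                   row.names = FALSE)
  note("aggregate", total_population = sum(nbhds$population),
       cases_included = sum(nbhds$case_count),
       cases_excluded = nrow(excluded))

  lisa_cfg <- config$lisa %||% list()
  W <- queen_weights(nbhds, style = "W")
  moran <- global_morans_i(nbhds$rate_per_10k, W,
                           reps = lisa_cfg$reps %||% 999L, rng_seed = seed)
  lisa <- local_morans_i(nbhds$rate_per_10k, W,
                         reps = lisa_cfg$reps %||% 999L,
                         alpha = lisa_cfg$alpha %||% 0.10, rng_seed = seed)
  utils::write.csv(
    data.frame(name = lisa$name, rate_per_10k = lisa$value,
               local_I = lisa$local_i, p_raw = lisa$p_raw,
               p_fdr_units = lisa$p_fdr_units,
               p_fdr_links = lisa$p_fdr_links,
               quadrant_unadjusted = lisa$quadrant_unadjusted,
               quadrant_fdr_units = lisa$quadrant_fdr_units,
               quadrant_fdr_links = lisa$quadrant_fdr_links),
    file.path(out_dir, "lisa.csv"), row.names = FALSE)
  utils::write.csv(weights_edge_list(W), file.path(out_dir, "weights.csv"),
                   row.names = FALSE)
  write_json_summary(list(
    I = moran$I, expectation = moran$expectation, variance = moran$variance,
    z = moran$z, p = moran$p, permutation_p = moran$permutation_p,
    reps = moran$reps, rng_seed = seed),
    file.path(out_dir, "moran.json"))
  note("moran", I = moran$I, p = moran$p)

  scan_cfg_args <- config$scan %||% list()
  exclude_missing <- isTRUE(scan_cfg_args$exclude_missing_days_from_baseline)
  scan_cfg_args$exclude_missing_days_from_baseline <- NULL
  cfg <- do.call(scan_config, scan_cfg_args)
  units <- as_unit_table(nbhds)
  sc <- spatial_scan(units, cfg, rng_seed = seed)
  utils::write.csv(cluster_table(sc),
                   file.path(out_dir, "clusters_spatial.csv"),
                   row.names = FALSE)
  write_cluster_footprints(sc, nbhds,
                           file.path(out_dir, "clusters_spatial.geojson"),
                           seed)
  note("scan", n_clusters = length(sc$clusters),
       top_llr = if (length(sc$clusters)) sc$clusters[[1]]$LLR else 0)

  sc_st <- NULL
  if (isTRUE(config$run_spacetime %||% TRUE)) {
    dmat <- case_day_matrix(cases, nbhds, study_start, study_end)
    baseline <- NULL
    if (exclude_missing) {
      alldays <- seq(study_start, study_end, by = "day")
      baseline <- as.numeric(alldays %in% avail)
    }
    sc_st <- spacetime_scan(units, dmat, cfg, study_start,
                            baseline_days = baseline, rng_seed = seed)
    utils::write.csv(cluster_table(sc_st),
                     file.path(out_dir, "clusters_spacetime.csv"),
                     row.names = FALSE)
    note("scan-st", n_clusters = length(sc_st$clusters))
  }

  if (isTRUE(config$run_kde %||% FALSE)) {
    fire <- cases[as.logical(cases$is_firearm), , drop = FALSE]
    surf <- kde_surface(fire$x, fire$y, grid_n = 128L,
                        bbox = set_bbox(area))
    kde_grid <- pop_grid(origin = c(min(surf$x), min(surf$y)),
                         cell_size = diff(surf$x[1:2]),
                         values = t(surf$z)[rev(seq_along(surf$y)), ,
                                            drop = FALSE])
    write_asc_grid(kde_grid, file.path(out_dir, "kde.asc"))
    note("kde", bandwidth_x = surf$bandwidth[1],
         bandwidth_y = surf$bandwidth[2])
  }

  write_json_summary(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(area = area, seeds = seeds, grid = grid, cases = cases,
                 nbhds = nbhds, weights = W, moran = moran, lisa = lisa,
                 scan_spatial = sc, scan_spacetime = sc_st,
                 manifest = manifest))
}

#' Write reported cluster footprints as GeoJSON
#'
#' Dissolve-free footprints: each reported cluster becomes one
#' MultiPolygon feature collecting its member neighborhoods' pieces, with
#' rank, counts, RR and p as properties.
#'
#' @param scan A `scan_result`.
#' @param nbhds The `polygon_set` the scan units came from.
#' @param path Output GeoJSON path.
#' @param rng_seed Optional seed for metadata.
#' @export
write_cluster_footprints <- function(scan, nbhds, path, rng_seed = NULL) {
  if (length(scan$clusters) == 0) {
    jsonlite::write_json(list(type = "FeatureCollection",
                              metadata = io_metadata(rng_seed),
                              features = list()),
                         path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  feats <- lapply(scan$clusters, function(cl) {
    geom <- unlist(nbhds$geometry[match(cl$member_units, nbhds$name)],
                   recursive = FALSE)
    props <- list(cluster = cl$cluster_rank, center = cl$window_center,
                  population = cl$population, cases = cl$c,
                  expected = cl$E, RR = cl$RR, LLR = cl$LLR, p = cl$p)
    if (!is.null(cl$date_range)) {
      props$date_start <- format(cl$date_range[1], "%Y-%m-%d")
      props$date_end <- format(cl$date_range[2], "%Y-%m-%d")
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "MultiPolygon",
                         coordinates = mp_to_geojson_coords(geom)))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            metadata = io_metadata(rng_seed),
                            features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
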
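# Synthetic study generator.

test_that("study area partitions the extent and is deterministic", {
  one <- generate_study_area(1, c(0, 0, 2, 1))
  expect_equal(nrow(one), 1)
  expect_equal(set_area(one), 2)

  a <- generate_study_area(16, c(0, 0, 1, 1), rng_seed = 7)
  expect_equal(nrow(a), 16)
  expect_equal(set_area(a), 1, tolerance = 1e-9)

  # same seed => byte-identical GeoJSON
  f1 <- tempfile(fileext = ".geojson"); f2 <- tempfile(fileext = ".geojson")
  write_geojson_polygons(generate_study_area(16, c(0, 0, 1, 1), 7), f1)
  write_geojson_polygons(generate_study_area(16, c(0, 0, 1, 1), 7), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_error(generate_study_area(0, c(0, 0, 1, 1)), "n_sections")
  expect_error(generate_study_area(2, c(0, 0, 0, 1)), "degenerate")
})

test_that("suburb seeds are named, inside the area, center-biased when asked", {
  area <- generate_study_area(4, c(0, 0, 1000, 1000), 3)
  s <- generate_suburb_seeds(area, 106, center_bias = 1.5, rng_seed = 5)
  expect_equal(nrow(s), 106)
  expect_false(anyDuplicated(s$name) > 0)
  inside <- rep(FALSE, 106)
  for (mp in area$geometry)
    inside <- inside | voroscan:::points_in_mp(s$x, s$y, mp)
  expect_true(all(inside))

  one <- generate_suburb_seeds(area, 1, rng_seed = 2)
  expect_equal(nrow(one), 1)

  # center_bias = 0: quadrat counts consistent with uniformity
  # (chi-square over a 4x4 quadrat grid, pooled over reps)
  counts <- matrix(0, 16, 1)
  for (r in 1:20) {
    u <- generate_suburb_seeds(area, 100, center_bias = 0, rng_seed = r,
                               min_separation = 0)
    qx <- pmin(floor(u$x / 250) + 1, 4); qy <- pmin(floor(u$y / 250) + 1, 4)
    counts <- counts + tabulate((qy - 1) * 4 + qx, 16)
  }
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)

  # center bias concentrates points near the centroid
  b <- generate_suburb_seeds(area, 200, center_bias = 3, rng_seed = 8)
  u <- generate_suburb_seeds(area, 200, center_bias = 0, rng_seed = 8,
                             min_separation = 0)
  dc <- function(d) sqrt((d$x - 500)^2 + (d$y - 500)^2)
  expect_lt(mean(dc(b)), mean(dc(u)))

  expect_error(generate_suburb_seeds(polygon_set(character(0), list()), 5),
               "empty")
})

test_that("population grid conserves the total and zeroes outside cells", {
  area <- generate_study_area(3, c(0, 0, 500, 500), 2)
  g <- generate_population_grid(area, 50, 35000, rng_seed = 4)
  expect_equal(grid_total(g), 35000)    # largest-remainder rounding: exact
  expect_true(all(g$values >= 0))

  g0 <- generate_population_grid(area, 50, 0, rng_seed = 4)
  expect_true(all(g0$values == 0))

  # determinism
  g2 <- generate_population_grid(area, 50, 35000, rng_seed = 4)
  expect_identical(g$values, g2$values)

  # cells with centers outside the union are zero: use an L-shaped area
  # (one section of a 2x2 grid removed)
  gl <- grid_units(2)[1:3, ]
  class(gl) <- c("polygon_set", "data.frame")
  gg <- generate_population_grid(gl, 0.5, 1000, rng_seed = 1)
  ctr <- grid_centers(gg)
  inside <- rep(FALSE, nrow(ctr))
  for (mp in gl$geometry) inside <- inside | voroscan:::points_in_mp(ctr$x, ctr$y, mp)
  expect_true(all(gg$values[cbind(ctr$row, ctr$col)][!inside] == 0))
})

test_that("case totals follow the Poisson oracle and avoid missing blocks", {
  st <- small_study(seed = 21, pop = 3565000, expected_cases = 248,
                    n_seeds = 10, missing_days = 133)
  cases <- st$cases
  expect_true(all(cases$is_firearm))
  # Poisson oracle: within 3 sd of the mean for a seeded run
  expect_lt(abs(nrow(cases) - 248), 3 * sqrt(248))
  # no case dated in a missing block; about 67% of days available
  avail <- available_days(st$truth)
  expect_true(all(cases$date %in% avail))
  expect_equal(length(avail), 406 - 133)
  expect_equal(length(avail) / 406, 0.67, tolerance = 0.01)
})

test_that("a relative_risk = 1 cluster leaves the draw unchanged", {
  area <- generate_study_area(4, c(0, 0, 1000, 1000), 3)
  g <- generate_population_grid(area, 100, 50000, rng_seed = 2)
  t0 <- study_truth(n_sections = 4, n_seeds = 5, total_population = 50000,
                    baseline_rate = 100 / 50000, missing_days = 0,
                    extent = c(0, 0, 1000, 1000), rng_seed = 9)
  t1 <- study_truth(n_sections = 4, n_seeds = 5, total_population = 50000,
                    baseline_rate = 100 / 50000, missing_days = 0,
                    embedded_clusters = list(list(center = c(500, 500),
                                                  radius = 200,
                                                  relative_risk = 1)),
                    extent = c(0, 0, 1000, 1000), rng_seed = 9)
  c0 <- generate_cases(t0, g, rng_seed = 13)
  c1 <- generate_cases(t1, g, rng_seed = 13)
  expect_equal(c0, c1)
})

test_that("an embedded high-risk cluster raises local case density", {
  cl <- list(list(center = c(1000, 1000), radius = 600, relative_risk = 8))
  st <- small_study(seed = 5, clusters = cl, expected_cases = 200)
  cases <- st$cases
  d <- sqrt((cases$x - 1000)^2 + (cases$y - 1000)^2)
  inside_frac <- mean(d <= 600)
  # population share of the disc is well under 20%; with RR 8 the case
  # share must be several times that
  expect_gt(inside_frac, 0.25)
})

test_that("truth validation rejects bad designs", {
  expect_error(study_truth(total_population = 0), "total_population")
  expect_error(study_truth(embedded_clusters = list(
    list(center = c(0, 0), radius = 1, relative_risk = 0.5))), "relative_risk")
  expect_error(study_truth(embedded_clusters = list(
    list(center = c(0, 0), radius = 1, relative_risk = 2,
         date_window = c("2019-01-01", "2019-02-01")))), "date_window")
  expect_error(study_truth(missing_days = 406), "missing_days")
  # all-days-missing case generation error surfaces via available_days
  tr <- study_truth(missing_days = 0)
  tr$missing_blocks <- list(c(tr$study_start, tr$study_end))
  area <- generate_study_area(2, c(0, 0, 100, 100), 1)
  g <- generate_population_grid(area, 10, 100, 1)
  expect_error(generate_cases(tr, g), "missing")
})

test_that("null per-neighborhood counts are Poisson-dispersed", {
  # no embedded clusters: across seeded replicates the per-unit counts
  # should have variance ~= mean (dispersion index near 1)
  area <- generate_study_area(4, c(0, 0, 2000, 2000), 2)
  seeds <- generate_suburb_seeds(area, 12, 1, rng_seed = 2)
  nb <- build_thiessen(seeds, area)
  g <- generate_population_grid(area, 100, 80000, rng_seed = 2)
  nb <- zonal_population(g, nb)
  truth <- study_truth(n_sections = 4, n_seeds = 12,
                       total_population = 80000,
                       baseline_rate = 150 / 80000, missing_days = 0,
                       extent = c(0, 0, 2000, 2000), rng_seed = 2)
  reps <- 200
  counts <- matrix(0L, reps, nrow(nb))
  for (r in seq_len(reps)) {
    cs <- generate_cases(truth, g, rng_seed = 1000 + r)
    counts[r, ] <- assign_cases(cs, nb)$case_count
  }
  disp <- apply(counts, 2, var) / pmax(colMeans(counts), 1e-9)
  expect_gt(mean(disp), 0.7)
  expect_lt(mean(disp), 1.3)
})
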
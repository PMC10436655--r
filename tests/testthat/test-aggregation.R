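# Zonal population, case assignment, rates, KDE.

test_that("zonal sums count exactly the cell centers inside each unit", {
  # uniform grid of 1 person per cell over a 10x10 lattice; a rectangle
  # covering k cell centers must sum to k
  g <- pop_grid(c(0, 0), 1, matrix(1, 10, 10))
  units <- polygon_set(c("box", "rest"),
                       list(list(ring_sq(0, 0, 3, 4)),
                            list(ring_sq(3, 0, 10, 10),
                                 ring_sq(0, 4, 3, 10))))
  z <- zonal_population(g, units)
  expect_equal(z$population[z$name == "box"], 12)   # 3 x 4 cell centers
  expect_equal(sum(z$population), 100)              # conservation
})

test_that("zonal conservation holds on the synthetic study", {
  st <- small_study(seed = 41, n_seeds = 20)
  nb <- zonal_population(st$grid, build_thiessen(st$seeds, st$area))
  ctr <- grid_centers(st$grid)
  vals <- st$grid$values[cbind(ctr$row, ctr$col)]
  inside <- rep(FALSE, nrow(ctr))
  for (mp in st$area$geometry)
    inside <- inside | voroscan:::points_in_mp(ctr$x, ctr$y, mp)
  expect_equal(sum(nb$population) + attr(nb, "unassigned_population"),
               sum(vals[vals > 0]))
  # everything generated inside the area must be assigned
  expect_equal(sum(nb$population), grid_total(st$grid))
})

test_that("out-of-frame grid warns and yields zero populations", {
  g <- pop_grid(c(100, 100), 1, matrix(1, 5, 5))
  units <- unit_square()
  expect_warning(z <- zonal_population(g, units), "outside")
  expect_equal(z$population, 0)
})

test_that("case assignment counts each case once and excludes outsiders", {
  units <- grid_units(2)   # 2x2 unit squares covering [0,2]^2
  cases <- data.frame(
    case_id = sprintf("c%d", 1:6),
    x = c(0.5, 1.5, 0.5, 1.0, 5.0, 0.2),   # 1.0 is on the shared boundary
    y = c(0.5, 0.5, 1.5, 0.5, 5.0, NA),
    date = as.Date("2020-01-01") + 0:5,
    is_firearm = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_warning(nb <- assign_cases(cases, units), "malformed")
  # 4 in-area, 1 outside, 1 rejected (NA coordinate)
  expect_equal(sum(nb$case_count), 4)
  expect_equal(nrow(attr(nb, "excluded")), 1)
  expect_equal(nrow(attr(nb, "rejected")), 1)
  # conservation audit: counted + excluded = cases passing the filter
  expect_equal(sum(nb$case_count) + nrow(attr(nb, "excluded")), 5)

  # boundary point assigned to exactly one unit
  b <- assign_cases(data.frame(case_id = "b", x = 1, y = 0.5,
                               date = as.Date("2020-06-01"),
                               is_firearm = TRUE), units)
  expect_equal(sum(b$case_count), 1)

  # firearm filter
  mix <- data.frame(case_id = c("f", "n"), x = c(0.5, 0.5), y = c(0.5, 0.5),
                    date = as.Date("2020-01-01"), is_firearm = c(TRUE, FALSE))
  expect_equal(sum(assign_cases(mix, units)$case_count), 1)
  expect_equal(sum(assign_cases(mix, units, firearm_only = FALSE)$case_count), 2)

  # zero cases
  z <- assign_cases(cases[0, ], units)
  expect_equal(z$case_count, rep(0L, 4))
})

test_that("case counts are conserved under tessellation refinement", {
  st <- small_study(seed = 51, n_seeds = 12)
  nb1 <- build_thiessen(st$seeds, st$area)
  fine <- labeled_points(c(st$seeds$name, "zx1", "zx2"),
                         c(st$seeds$x, 1200, 2700), c(st$seeds$y, 900, 3100))
  nb2 <- build_thiessen(fine, st$area)
  c1 <- sum(assign_cases(st$cases, nb1)$case_count)
  c2 <- sum(assign_cases(st$cases, nb2)$case_count)
  expect_equal(c1, c2)
})

test_that("rates follow the 10k formula and flag impossible rows", {
  nb <- grid_units(2)
  nb$population <- c(10000, 16040, 11358, 0)
  nb$case_count <- c(3L, 19L, 0L, 0L)
  r <- compute_rates(nb)
  expect_equal(r$rate_per_10k[1], 3.0)
  expect_equal(r$rate_per_10k[2], 11.845, tolerance = 5e-4)
  expect_equal(r$rate_per_10k[3], 0)
  expect_equal(r$rate_per_10k[4], 0)
  # rate * population / 10000 recovers the integer count
  expect_equal(r$rate_per_10k[1:3] * r$population[1:3] / 10000,
               as.numeric(r$case_count[1:3]))

  nb$population[4] <- 0; nb$case_count[4] <- 2L
  expect_warning(r2 <- compute_rates(nb), "zero population")
  expect_true(is.na(r2$rate_per_10k[4]))
  nb$population[4] <- -1
  expect_error(compute_rates(nb), "nonnegative")
})

test_that("KDE surface is located, normalised and guards degenerate input", {
  s1 <- kde_surface(500, 700, bandwidth = 50, grid_n = 64)
  peak <- which(s1$z == max(s1$z), arr.ind = TRUE)
  expect_equal(s1$x[peak[1]], 500, tolerance = 10)
  expect_equal(s1$y[peak[2]], 700, tolerance = 10)

  set.seed(2)
  pts <- rbind(cbind(rnorm(300, 0, 30), rnorm(300, 0, 30)),
               cbind(rnorm(300, 1000, 30), rnorm(300, 1000, 30)))
  s2 <- kde_surface(pts[, 1], pts[, 2], bandwidth = 40, grid_n = 128,
                    bbox = c(-300, -300, 1300, 1300))
  cell <- diff(s2$x[1:2]) * diff(s2$y[1:2])
  expect_equal(sum(s2$z) * cell, 600, tolerance = 0.02 * 600)
  # a local maximum at each blob center: the density peak within each
  # half of the lattice sits within a few cells of the blob center
  cell_w <- diff(s2$x[1:2])
  for (blob in list(list(cx = 0, cy = 0, mx = s2$x < 500, my = s2$y < 500),
                    list(cx = 1000, cy = 1000, mx = s2$x >= 500,
                         my = s2$y >= 500))) {
    sub <- s2$z[blob$mx, blob$my]
    pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    expect_lt(abs(s2$x[blob$mx][pk[1]] - blob$cx), 3 * cell_w)
    expect_lt(abs(s2$y[blob$my][pk[2]] - blob$cy), 3 * cell_w)
  }

  expect_error(kde_surface(rep(1, 5), rep(2, 5)), "bandwidth")
})
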
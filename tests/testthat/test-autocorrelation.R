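# Spatial weights, Moran's I, LISA, FDR tiers.

test_that("queen contiguity recovers known grid structure", {
  w2 <- queen_weights(grid_units(2), style = "W")
  # 2x2: every pair is queen-adjacent (shared edge or corner)
  expect_true(all(lengths(w2$neighbours) == 3))
  for (i in 1:4) expect_equal(sum(w2$weights[[i]]), 1)

  w3 <- queen_weights(grid_units(3), style = "B")
  deg <- lengths(w3$neighbours)
  nm <- grid_units(3)$name
  expect_equal(deg[nm == "g11"], 3)   # corner
  expect_equal(deg[nm == "g22"], 8)   # center
  expect_equal(deg[nm == "g12"], 5)   # edge
  expect_equal(w3$L, sum(deg))
  # symmetry
  for (i in seq_len(w3$n)) for (j in w3$neighbours[[i]])
    expect_true(i %in% w3$neighbours[[j]])
})

test_that("tessellation adjacency is symmetric with L = twice the edge count", {
  st <- small_study(seed = 61, n_seeds = 30)
  nb <- build_thiessen(st$seeds, st$area)
  W <- queen_weights(nb, style = "B")
  edges <- 0
  for (i in seq_len(W$n)) for (j in W$neighbours[[i]]) {
    expect_true(i %in% W$neighbours[[j]])
    if (j > i) edges <- edges + 1
  }
  expect_equal(W$L, 2 * edges)
})

test_that("checkerboard on a rook 2x2 grid gives I = -1", {
  W <- weights_from_neighbours(list(c(2, 3), c(1, 4), c(1, 4), c(2, 3)), "W")
  m <- global_morans_i(c(1, 0, 0, 1), W)
  expect_equal(m$I, -1)
  expect_equal(m$expectation, -1 / 3)
})

test_that("global Moran matches a brute-force double sum and guards input", {
  st <- small_study(seed = 71, n_seeds = 24)
  nb <- build_thiessen(st$seeds, st$area)
  W <- queen_weights(nb, "W")
  set.seed(5); x <- rgamma(24, 2)
  m <- global_morans_i(x, W)
  expect_equal(m$I, moran_brute(x, W), tolerance = 1e-12)
  expect_error(global_morans_i(rep(3, 24), W), "constant")
  expect_error(global_morans_i(c(Inf, x[-1]), W), "finite")
})

test_that("permutation p approximates the exhaustive permutation rank (n = 6)", {
  W <- weights_from_neighbours(
    list(2, c(1, 3), c(2, 4), c(3, 5), c(4, 6), 5), "W")   # path graph
  x <- c(5, 4, 3, 1, 2, 0)
  m <- global_morans_i(x, W, reps = 4000, rng_seed = 3)
  # exhaustive oracle over all 720 permutations
  z <- x - mean(x)
  perms <- do.call(rbind, combinat_perms(6))
  wm <- voroscan:::weights_matrix(W)
  Is <- apply(perms, 1, function(p) voroscan:::moran_stat(z[p], wm, W$S0))
  p_exact <- mean(Is >= m$I - 1e-12)
  expect_lt(abs(m$permutation_p - p_exact), 0.02)
})

test_that("analytic Moran p has nominal type-I error under shuffling", {
  st <- small_study(seed = 81, n_seeds = 25)
  nb <- build_thiessen(st$seeds, st$area)
  W <- queen_weights(nb, "W")
  set.seed(7)
  base <- rgamma(25, 2)
  rej <- 0L
  for (r in 1:200) {
    m <- global_morans_i(sample(base), W)
    if (m$p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 200, 0.03 - 1e-9)
  expect_lte(rej / 200, 0.08 + 1e-9)
})

test_that("local Moran satisfies the sum identity and the zero case", {
  st <- small_study(seed = 91, n_seeds = 20)
  nb <- build_thiessen(st$seeds, st$area)
  W <- queen_weights(nb, "W")
  set.seed(11); x <- rnorm(20, 10, 3)
  g <- global_morans_i(x, W)
  l <- local_morans_i(x, W, reps = 99, rng_seed = 4)
  expect_equal(sum(l$local_i), 20 * g$I, tolerance = 1e-9)
  # a unit sitting exactly at the mean has I_i = 0
  x2 <- x
  x2[5] <- sum(x2[-5]) / 19           # so x2[5] == mean(x2)
  l2 <- local_morans_i(x2, W, reps = 99, rng_seed = 4)
  expect_equal(l2$local_i[5], 0)
})

test_that("a planted high-rate blob classifies as high-high with low-high ring", {
  # 5x5 grid of squares; the 2x2 block in the middle has high rates
  units <- grid_units(5)
  W <- queen_weights(units, "W")
  rate <- rep(1, 25)
  hot <- units$name %in% c("g33", "g34", "g43", "g44")
  rate[hot] <- 20
  set.seed(3)
  rate <- rate + runif(25, 0, 0.01)   # break exact ties
  l <- local_morans_i(rate, W, reps = 999, alpha = 0.10, rng_seed = 8)
  expect_true(all(l$quadrant_unadjusted[hot] == "high-high"))
  ring <- l$name %in% c("g22", "g23", "g24", "g25", "g32", "g42", "g52",
                        "g35", "g45", "g55", "g25", "g53", "g54", "g55")
  sig_ring <- l$quadrant_unadjusted[ring & !hot]
  expect_true(any(sig_ring == "low-high"))
  expect_false(any(sig_ring %in% c("high-high", "high-low")))
})

test_that("BH tiers match hand computation and are ordered in conservatism", {
  W <- weights_from_neighbours(list(c(2, 3), c(1, 4), c(1, 4), c(2, 3)), "W")
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_pvalues(p, "unadjusted"), p)
  expect_equal(adjust_pvalues(p, "fdr_units", W), rep(0.04, 4))
  # m = L = 8 directed links in the rook 2x2 graph
  expect_equal(W$L, 8)
  expect_equal(adjust_pvalues(p, "fdr_links", W),
               p.adjust(p, "BH", n = 8))
  # links regime never less conservative than units when L >= n
  expect_true(all(adjust_pvalues(p, "fdr_links", W) >=
                    adjust_pvalues(p, "fdr_units", W)))
  # m = 1 leaves a single p unchanged
  W1 <- weights_from_neighbours(list(2, 1), "B")
  expect_equal(adjust_pvalues(0.03, "fdr_units", W1), 0.03)
  expect_error(adjust_pvalues(c(0.5, 1.2), "unadjusted"), "\\[0, 1\\]")
})

test_that("stricter regimes flag subsets of looser regimes", {
  st <- small_study(seed = 101, n_seeds = 40,
                    clusters = list(list(center = c(2000, 2000),
                                         radius = 800, relative_risk = 6)))
  nb <- build_thiessen(st$seeds, st$area)
  nb <- zonal_population(st$grid, nb)
  nb <- assign_cases(st$cases, nb)
  nb <- compute_rates(nb)
  W <- queen_weights(nb, "W")
  l <- local_morans_i(nb$rate_per_10k, W, reps = 999, alpha = 0.10,
                      rng_seed = 5)
  sig_raw <- l$name[l$quadrant_unadjusted != "not-significant"]
  sig_units <- l$name[l$quadrant_fdr_units != "not-significant"]
  sig_links <- l$name[l$quadrant_fdr_links != "not-significant"]
  expect_true(all(sig_units %in% sig_raw))
  expect_true(all(sig_links %in% sig_units))
})
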
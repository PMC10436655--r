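# Discrete-Poisson scan statistic: building blocks and the spatial scan.

test_that("expected counts are population-proportional and sum to C", {
  expect_equal(expected_counts(100, 7), 7)
  expect_equal(expected_counts(c(1, 1), 10), c(5, 5))
  # population-inversion worked example: the published reference row
  E <- expected_counts(c(16040, 3565473 - 16040), 248)
  expect_equal(E[1], 1.116, tolerance = 1e-3)
  expect_equal(sum(E), 248)
  expect_error(expected_counts(c(0, 0), 5), "positive")
})

test_that("the LLR is one-sided and matches direct evaluation", {
  expect_equal(poisson_llr(5, 5, 100), 0)          # c = E
  expect_equal(poisson_llr(3, 5, 100), 0)          # c < E: high-only
  # published cluster-1 values: c=101, C=248, E from the inverted P
  E1 <- 248 * 593211 / 3565473
  expect_equal(poisson_llr(101, E1, 248), 40.28, tolerance = 5e-3)
  # 0 log 0 convention
  expect_equal(poisson_llr(0, 1, 10), 0)
  expect_error(poisson_llr(5, 0, 10), "between 0 and C")
  expect_error(poisson_llr(5, 10, 10), "between 0 and C")
})

test_that("relative risk reproduces published rows and handles edges", {
  expect_equal(relative_risk(5, 5, 100), 1)
  E_ner <- 248 * 16040 / 3565473
  expect_equal(relative_risk(19, E_ner, 248), 18.36, tolerance = 5e-4)
  E1 <- 248 * 593211 / 3565473
  expect_equal(relative_risk(101, E1, 248), 3.44, tolerance = 1e-3)
  expect_true(is.infinite(relative_risk(10, 5, 10)))
})

test_that("candidate windows respect the population bound", {
  one <- candidate_windows(data.frame(name = "a", x = 0, y = 0), 100)
  expect_equal(length(one$members), 1)

  # three collinear equidistant equal-population units
  cen <- data.frame(name = c("a", "b", "c"), x = c(0, 1, 2), y = 0)
  w50 <- candidate_windows(cen, c(1, 1, 1), 0.5)
  expect_true(all(lengths(w50$members) == 1))      # any pair exceeds 50%
  expect_equal(length(w50$members), 3)
  w70 <- candidate_windows(cen, c(1, 1, 1), 0.7)
  expect_equal(sort(unique(lengths(w70$members))), c(1, 2))

  # bound: never more than n^2 windows
  set.seed(12)
  cen2 <- data.frame(name = sprintf("u%02d", 1:15), x = runif(15),
                     y = runif(15))
  ws <- candidate_windows(cen2, rep(1, 15), 0.5)
  expect_lte(length(ws$members), 225)
  # deduplication: no two member sets identical
  keys <- vapply(ws$members, function(m) paste(sort(m), collapse = ","), "")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("Monte Carlo p follows the rank formula", {
  expect_equal(monte_carlo_p(10, rep(1, 999)), 0.001)   # above all -> floor
  expect_equal(monte_carlo_p(0, rep(1, 999)), 1)        # below all
  expect_equal(monte_carlo_p(5, c(4, 5, 6, 7, 3, 2, 1, 0, 8)), 0.5)  # ties count
  expect_error(monte_carlo_p(1, c(1, 2), R = 5), "replicates")
})

test_that("scan max LLR equals exhaustive window enumeration (n <= 6)", {
  # oracle: enumerate every distance-nested subset directly from the
  # definition, no shared code with the scan internals
  brute_max <- function(units, frac) {
    C <- sum(units$case_count)
    P <- sum(units$population)
    best <- 0
    for (i in seq_len(nrow(units))) {
      d <- sqrt((units$x - units$x[i])^2 + (units$y - units$y[i])^2)
      ord <- order(d, units$name)
      for (s in seq_len(nrow(units))) {
        mem <- ord[seq_len(s)]
        pw <- sum(units$population[mem])
        if (s > 1 && pw > frac * P) break
        cw <- sum(units$case_count[mem])
        Ew <- C * pw / P
        if (Ew <= 0 || Ew >= C || cw <= Ew) next
        llr <- cw * log(cw / Ew) +
          (C - cw) * log((C - cw) / (C - Ew))
        best <- max(best, llr)
      }
    }
    best
  }
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    units <- data.frame(name = sprintf("u%d", 1:n),
                        x = runif(n), y = runif(n),
                        population = sample(50:200, n),
                        case_count = rpois(n, 4))
    if (sum(units$case_count) == 0) next
    sc <- spatial_scan(units, scan_config(replications = 9,
                                          report_all = TRUE), rng_seed = 1)
    got <- if (length(sc$clusters)) sc$clusters[[1]]$LLR else 0
    expect_equal(got, brute_max(units, 0.5), tolerance = 1e-10)
  }
})

test_that("the scan is deterministic per seed and invariant to relabeling", {
  set.seed(44)
  n <- 12
  units <- data.frame(name = sprintf("u%02d", 1:n), x = runif(n),
                      y = runif(n), population = sample(500:900, n),
                      case_count = rpois(n, 6))
  cfg <- scan_config(replications = 99, report_all = TRUE)
  s1 <- spatial_scan(units, cfg, rng_seed = 7)
  s2 <- spatial_scan(units, cfg, rng_seed = 7)
  expect_equal(cluster_table(s1), cluster_table(s2))
  expect_equal(s1$replicate_llrs, s2$replicate_llrs)

  # shuffling unit order leaves the max LLR unchanged
  perm <- sample(n)
  s3 <- spatial_scan(units[perm, ], cfg, rng_seed = 7)
  expect_equal(s1$clusters[[1]]$LLR, s3$clusters[[1]]$LLR)
  expect_setequal(s1$clusters[[1]]$member_units,
                  s3$clusters[[1]]$member_units)

  # adding an empty-population unit changes nothing substantive
  units0 <- rbind(units, data.frame(name = "zz_empty", x = 0.5, y = 0.5,
                                    population = 0, case_count = 0L))
  s4 <- spatial_scan(units0, cfg, rng_seed = 7)
  expect_equal(s4$clusters[[1]]$LLR, s1$clusters[[1]]$LLR)
})

test_that("secondary clusters never share units under the default criterion", {
  set.seed(55)
  n <- 20
  units <- data.frame(name = sprintf("u%02d", 1:n), x = runif(n),
                      y = runif(n), population = rep(100, n),
                      case_count = rpois(n, 5))
  sc <- spatial_scan(units, scan_config(replications = 9,
                                        report_all = TRUE), rng_seed = 2)
  seen <- character(0)
  for (cl in sc$clusters) {
    expect_false(any(cl$member_units %in% seen))
    seen <- c(seen, cl$member_units)
  }
})

test_that("zero cases yield an empty result with a warning", {
  units <- data.frame(name = c("a", "b"), x = 0:1, y = 0,
                      population = c(10, 10), case_count = c(0L, 0L))
  expect_warning(sc <- spatial_scan(units, scan_config(replications = 9)),
                 "no cases")
  expect_equal(length(sc$clusters), 0)
})
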
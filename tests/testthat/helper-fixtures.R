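# Shared fixtures, all built in code.

unit_square <- function() polygon_set("area", list(list(ring_sq(0, 0, 1, 1))))

ring_sq <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# k x k grid of unit squares as a polygon_set (known queen adjacency)
grid_units <- function(k) {
  nm <- character(0); geo <- list()
  for (r in seq_len(k)) for (cc in seq_len(k)) {
    nm <- c(nm, sprintf("g%d%d", r, cc))
    geo[[length(geo) + 1L]] <- list(ring_sq(cc - 1, r - 1, cc, r))
  }
  polygon_set(nm, geo)
}

# small synthetic study used by several tests (cheap; seeded)
small_study <- function(seed = 11L, n_seeds = 30L, n_sections = 6L,
                        pop = 60000, expected_cases = 120,
                        extent = c(0, 0, 4000, 4000),
                        clusters = list(), missing_days = 0L) {
  truth <- study_truth(
    n_sections = n_sections, n_seeds = n_seeds, total_population = pop,
    baseline_rate = expected_cases / pop, embedded_clusters = clusters,
    study_start = as.Date("2019-11-22"), study_end = as.Date("2020-12-31"),
    missing_days = missing_days, extent = extent, rng_seed = seed)
  generate_study(truth, cell_size = 100)
}

# brute-force Moran's I from the definition (independent of the package's
# matrix-based path)
moran_brute <- function(x, W) {
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(W$n)) {
    nbs <- W$neighbours[[i]]
    if (length(nbs)) num <- num + sum(W$weights[[i]] * z[i] * z[nbs])
  }
  (W$n / W$S0) * num / sum(z^2)
}

# all permutations of 1..n (tiny n only)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) for (k in 0:(n - 1)) {
    out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}
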
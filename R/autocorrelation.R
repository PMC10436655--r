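# Spatial weights, global and local Moran's I, and tiered FDR adjustment.

#' Queen-contiguity spatial weights
#'
#' Two units are neighbors if their polygons share any boundary point
#' (edge or corner). Contiguity is detected by vertex-to-boundary
#' proximity within a snap tolerance scaled to the study extent, which is
#' robust to the floating-point jitter left by clipping. Islands (units
#' with no neighbor) are permitted but reported; an all-island set is an
#' error.
#'
#' @param nbhds A `polygon_set`.
#' @param style `"W"` row-standardized (each row of weights sums to 1) or
#'   `"B"` binary.
#' @param snap Contiguity tolerance as a fraction of the bounding-box
#'   diagonal.
#' @return An object of class `spatial_weights`: `n`, `neighbours` (list
#'   of integer vectors), `weights` (list, aligned), `style`, `S0` (sum of
#'   weights), `L` (count of nonzero directed links), `names`.
#' @export
queen_weights <- function(nbhds, style = c("W", "B"), snap = 1e-6) {
  style <- match.arg(style)
  n <- nrow(nbhds)
  if (n < 2) stop("at least two polygons are required")
  bb <- set_bbox(nbhds)
  tol <- snap * sqrt((bb[3] - bb[1])^2 + (bb[4] - bb[2])^2)
  bbs <- t(vapply(nbhds$geometry, mp_bbox, numeric(4)))
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (bbs[i, 1] > bbs[j, 3] + tol || bbs[j, 1] > bbs[i, 3] + tol ||
          bbs[i, 2] > bbs[j, 4] + tol || bbs[j, 2] > bbs[i, 4] + tol) next
      if (mp_touch(nbhds$geometry[[i]], nbhds$geometry[[j]], tol)) {
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  deg <- lengths(nb)
  if (all(deg == 0)) stop("all units are islands; no contiguity structure")
  if (any(deg == 0))
    message(sprintf("note: %d island unit(s): %s", sum(deg == 0),
                    paste(nbhds$name[deg == 0], collapse = ", ")))
  wts <- lapply(seq_len(n), function(i) {
    if (deg[i] == 0) numeric(0)
    else if (style == "W") rep(1 / deg[i], deg[i])
    else rep(1, deg[i])
  })
  structure(list(n = n, neighbours = nb, weights = wts, style = style,
                 S0 = sum(unlist(wts)), L = sum(deg),
                 names = nbhds$name), class = "spatial_weights")
}

# any vertex of one boundary within tol of the other's boundary
mp_touch <- function(a, b, tol) {
  va <- do.call(rbind, a); vb <- do.call(rbind, b)
  for (ring in b)
    if (any(point_ring_boundary_dist(va[, 1], va[, 2], ring) <= tol))
      return(TRUE)
  for (ring in a)
    if (any(point_ring_boundary_dist(vb[, 1], vb[, 2], ring) <= tol))
      return(TRUE)
  FALSE
}

#' Build spatial weights from an explicit neighbour list
#'
#' Constructor for known adjacency structures (grids, test fixtures).
#' @param neighbours List of integer vectors (symmetric adjacency).
#' @param style `"W"` or `"B"`.
#' @param names Optional unit names.
#' @return A `spatial_weights` object.
#' @export
weights_from_neighbours <- function(neighbours, style = c("W", "B"),
                                    names = NULL) {
  style <- match.arg(style)
  n <- length(neighbours)
  for (i in seq_len(n)) for (j in neighbours[[i]])
    if (!(i %in% neighbours[[j]])) stop("adjacency must be symmetric")
  deg <- lengths(neighbours)
  wts <- lapply(seq_len(n), function(i) {
    if (deg[i] == 0) numeric(0)
    else if (style == "W") rep(1 / deg[i], deg[i]) else rep(1, deg[i])
  })
  structure(list(n = n, neighbours = neighbours, weights = wts,
                 style = style, S0 = sum(unlist(wts)), L = sum(deg),
                 names = names %||% as.character(seq_len(n))),
            class = "spatial_weights")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights: %d units, style %s, %d directed links, S0 = %.4g>\n",
              x$n, x$style, x$L, x$S0))
  invisible(x)
}

weights_matrix <- function(W) {
  m <- matrix(0, W$n, W$n)
  for (i in seq_len(W$n))
    if (length(W$neighbours[[i]])) m[i, W$neighbours[[i]]] <- W$weights[[i]]
  m
}

#' Export spatial weights as an edge list
#' @param W A `spatial_weights`.
#' @return data.frame `from, to, weight` over nonzero directed links.
#' @export
weights_edge_list <- function(W) {
  from <- rep(W$names, lengths(W$neighbours))
  to <- W$names[unlist(W$neighbours)]
  data.frame(from = from, to = to, weight = unlist(W$weights),
             stringsAsFactors = FALSE)
}

moran_stat <- function(z, wm, S0) {
  n <- length(z)
  (n / S0) * sum(wm * tcrossprod(z)) / sum(z^2)
}

#' Global Moran's I with analytic and permutation inference
#'
#' I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2 on the mean-deviations
#' z. The analytic p-value is one-sided (greater) under the randomization
#' assumption; an optional conditional-permutation pseudo p uses `reps`
#' random permutations of the values.
#'
#' @param values Per-unit values (e.g. rates per 10,000); finite, with
#'   nonzero variance.
#' @param W A `spatial_weights`.
#' @param reps Number of permutations for the pseudo p (0 to skip).
#' @param rng_seed Integer seed for the permutations.
#' @return List of class `moran_result`: `I`, `expectation`, `variance`,
#'   `z`, `p`, and `permutation_p`/`reps` when requested.
#' @export
global_morans_i <- function(values, W, reps = 0L, rng_seed = 1L) {
  x <- as.numeric(values)
  n <- length(x)
  if (n != W$n) stop("values length must match the weights")
  if (any(!is.finite(x))) stop("values must be finite")
  if (stats::var(x) == 0) stop("values are constant; Moran's I is undefined")
  z <- x - mean(x)
  wm <- weights_matrix(W)
  S0 <- W$S0
  I <- moran_stat(z, wm, S0)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((wm + t(wm))^2)
  S2 <- sum((rowSums(wm) + colSums(wm))^2)
  b2 <- n * sum(z^4) / (sum(z^2)^2)
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zscore <- (I - EI) / sqrt(VI)
  out <- list(I = I, expectation = EI, variance = VI, z = zscore,
              p = stats::pnorm(zscore, lower.tail = FALSE))
  if (reps > 0) {
    rng <- local_rng(rng_seed, "moran-perm")
    perm <- with_rng(rng, vapply(seq_len(reps), function(r) {
      moran_stat(z[sample.int(n)], wm, S0)
    }, numeric(1)))
    out$permutation_p <- (1 + sum(perm >= I)) / (reps + 1)
    out$reps <- as.integer(reps)
  }
  class(out) <- "moran_result"
  out
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f, z = %.3f, p = %.4g%s)\n",
              x$I, x$expectation, x$z, x$p,
              if (!is.null(x$permutation_p))
                sprintf(", permutation p = %.4g [R=%d]", x$permutation_p, x$reps)
              else ""))
  invisible(x)
}

#' Local Moran's I (LISA) with conditional permutation inference
#'
#' I_i = (z_i / m2) * sum_j w_ij z_j with m2 = sum(z^2)/n, so that with
#' row-standardized weights sum_i I_i = n * I (the global statistic).
#' Pseudo p-values hold unit i fixed and permute the remaining values
#' onto its neighbors; significance is read off the adjusted p under each
#' multiple-testing regime, and a cluster quadrant (high-high, low-low,
#' low-high, high-low) is assigned only to significant units.
#'
#' @param values Per-unit values.
#' @param W A `spatial_weights` (row-standardized recommended).
#' @param reps Conditional permutations per unit (default 999).
#' @param alpha Significance level for quadrant assignment (default 0.10).
#' @param rng_seed Integer seed.
#' @return data.frame of class `lisa_result`: `name, value, z, lag,
#'   local_i, p_raw, p_fdr_units, p_fdr_links`, and a quadrant column per
#'   regime (`quadrant_unadjusted, quadrant_fdr_units,
#'   quadrant_fdr_links`).
#' @export
local_morans_i <- function(values, W, reps = 999L, alpha = 0.10,
                           rng_seed = 1L) {
  x <- as.numeric(values)
  n <- length(x)
  if (n != W$n) stop("values length must match the weights")
  if (any(!is.finite(x))) stop("values must be finite")
  if (stats::var(x) == 0) stop("values are constant; local Moran is undefined")
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  lag <- vapply(seq_len(n), function(i) {
    if (length(W$neighbours[[i]]) == 0) return(0)
    sum(W$weights[[i]] * z[W$neighbours[[i]]])
  }, numeric(1))
  Ii <- z / m2 * lag

  rng <- local_rng(rng_seed, "lisa-perm")
  p_raw <- with_rng(rng, vapply(seq_len(n), function(i) {
    k <- length(W$neighbours[[i]])
    if (k == 0) return(1)
    pool <- z[-i]
    idx <- vapply(seq_len(reps), function(r)
      sample.int(length(pool), k), integer(k))
    draws <- matrix(pool[idx], nrow = k)
    perm <- (z[i] / m2) * as.numeric(crossprod(draws, W$weights[[i]]))
    if (Ii[i] >= 0) (1 + sum(perm >= Ii[i])) / (reps + 1)
    else (1 + sum(perm <= Ii[i])) / (reps + 1)
  }, numeric(1)))

  p_units <- adjust_pvalues(p_raw, "fdr_units", W)
  p_links <- adjust_pvalues(p_raw, "fdr_links", W)
  quad <- ifelse(z >= 0,
                 ifelse(lag >= 0, "high-high", "high-low"),
                 ifelse(lag >= 0, "low-high", "low-low"))
  classify <- function(p) ifelse(p < alpha, quad, "not-significant")
  out <- data.frame(
    name = W$names, value = x, z = z, lag = lag, local_i = Ii,
    p_raw = p_raw, p_fdr_units = p_units, p_fdr_links = p_links,
    quadrant_unadjusted = classify(p_raw),
    quadrant_fdr_units = classify(p_units),
    quadrant_fdr_links = classify(p_links),
    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "reps") <- as.integer(reps)
  class(out) <- c("lisa_result", "data.frame")
  out
}

#' Tiered multiple-testing adjustment for LISA p-values
#'
#' Three regimes in increasing conservatism: `unadjusted` returns the raw
#' p-values; `fdr_units` applies Benjamini-Hochberg with m equal to the
#' number of units; `fdr_links` applies Benjamini-Hochberg with m equal
#' to the number of nonzero directed links of the weights matrix.
#'
#' @param p Vector of p-values in [0, 1].
#' @param regime One of `"unadjusted"`, `"fdr_units"`, `"fdr_links"`.
#' @param W A `spatial_weights`; required for `fdr_links`.
#' @return Adjusted p-values (capped at 1).
#' @export
adjust_pvalues <- function(p, regime = c("unadjusted", "fdr_units",
                                         "fdr_links"), W = NULL) {
  regime <- match.arg(regime)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  switch(regime,
    unadjusted = p,
    fdr_units = stats::p.adjust(p, method = "BH"),
    fdr_links = {
      if (is.null(W)) stop("fdr_links requires the spatial weights")
      stats::p.adjust(p, method = "BH", n = max(W$L, length(p)))
    })
}
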
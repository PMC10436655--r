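# Kulldorff discrete-Poisson scan statistic: purely spatial and
# space-time, with Monte Carlo inference conditional on the observed case
# total, high-rates-only scanning, population-bounded circular windows
# and non-overlapping secondary cluster reporting.

#' Scan configuration
#'
#' @param max_population_fraction Largest window population as a fraction
#'   of the total at-risk population (default 0.5).
#' @param max_temporal_fraction Longest cylinder interval as a fraction of
#'   the study period (default 0.5; space-time scan only).
#' @param replications Monte Carlo replications R (default 999, >= 9).
#' @param significance_threshold Report clusters with Monte Carlo p below
#'   this level (default 0.001).
#' @param allow_purely_temporal Permit cylinders covering every unit
#'   (default FALSE).
#' @param secondary `"no_shared_units"`: a secondary cluster shares no
#'   unit with any higher-ranked reported cluster; `"no_centers_in_previous"`
#'   (weaker, used when replicating published tables whose cluster
#'   member lists overlap): only the window center must be new.
#' @param report_all Report the most likely cluster and secondaries
#'   regardless of significance (useful for power studies).
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(max_population_fraction = 0.5,
                        max_temporal_fraction = 0.5,
                        replications = 999L,
                        significance_threshold = 0.001,
                        allow_purely_temporal = FALSE,
                        secondary = c("no_shared_units",
                                      "no_centers_in_previous"),
                        report_all = FALSE) {
  if (max_population_fraction <= 0 || max_population_fraction > 1)
    stop("max_population_fraction must lie in (0, 1]")
  if (max_temporal_fraction <= 0 || max_temporal_fraction > 1)
    stop("max_temporal_fraction must lie in (0, 1]")
  if (replications < 9) stop("replications must be >= 9")
  structure(list(
    model = "poisson", scan_direction = "high_only",
    max_population_fraction = max_population_fraction,
    max_temporal_fraction = max_temporal_fraction,
    time_aggregation = "day",
    replications = as.integer(replications),
    significance_threshold = significance_threshold,
    allow_purely_temporal = allow_purely_temporal,
    secondary = match.arg(secondary),
    report_all = report_all), class = "scan_config")
}

#' Population-proportional expected counts
#'
#' Under the discrete Poisson model the expectation in unit i is
#' `E_i = C * p_i / P`; the expectations sum to C exactly.
#'
#' @param pops Per-unit populations (sum > 0).
#' @param C Total observed cases.
#' @return Numeric vector of expectations.
#' @export
expected_counts <- function(pops, C) {
  P <- sum(pops)
  if (P <= 0) stop("total population must be positive")
  C * pops / P
}

#' Poisson log-likelihood ratio, high rates only
#'
#' `LLR = c log(c/E) + (C-c) log((C-c)/(C-E))` when `c > E`, else 0
#' (one-sided scanning for elevated rates); `0 log 0` is taken as 0.
#' Vectorised over `c` and `E`.
#'
#' @param c Observed cases in the window (0 <= c <= C).
#' @param E Expected cases in the window (0 < E < C).
#' @param C Total cases.
#' @return Log-likelihood ratio(s), >= 0.
#' @export
poisson_llr <- function(c, E, C) {
  if (any(E <= 0) || any(E >= C)) stop("E must lie strictly between 0 and C")
  if (any(c < 0) || any(c > C)) stop("c must lie in [0, C]")
  t1 <- ifelse(c > 0, c * log(c / E), 0)
  t2 <- ifelse(C - c > 0, (C - c) * log((C - c) / (C - E)), 0)
  ifelse(c > E, t1 + t2, 0)
}

#' Scan relative risk
#'
#' `RR = (c/E) / ((C-c)/(C-E))`: the estimated risk inside the window
#' relative to outside. A window holding every case (`c = C`) has
#' infinite RR and is reported as `Inf`.
#'
#' @inheritParams poisson_llr
#' @return Relative risk(s).
#' @export
relative_risk <- function(c, E, C) {
  if (any(E <= 0) || any(E >= C)) stop("E must lie strictly between 0 and C")
  if (any(c < 0) || any(c > C)) stop("c must lie in [0, C]")
  ifelse(c >= C, Inf, (c / E) / ((C - c) / (C - E)))
}

#' Circular candidate windows
#'
#' For every unit taken as a center, the nested windows formed by adding
#' units in order of centroid distance, stopping before the cumulative
#' population exceeds `max_population_fraction` of the total. The
#' singleton window is always included. Distance ties are broken by unit
#' name; identical member sets are de-duplicated.
#'
#' @param centroids data.frame with `name, x, y`.
#' @param pops Per-unit populations.
#' @param max_population_fraction Population bound in (0, 1].
#' @return List of class `scan_windows`: `members` (list of integer
#'   vectors, in order of addition), `center` (integer), `radius`
#'   (distance to the farthest member centroid), plus the nesting tables
#'   used by the scan internals.
#' @export
candidate_windows <- function(centroids, pops,
                              max_population_fraction = 0.5) {
  n <- nrow(centroids)
  if (n < 1) stop("at least one unit is required")
  P <- sum(pops)
  lim <- max_population_fraction * P
  members <- list(); center <- integer(0); radius <- numeric(0)
  seen <- new.env(hash = TRUE)
  order_tab <- matrix(0L, n, n)   # per-center distance ordering
  size_tab <- integer(n)          # windows kept per center
  widx_tab <- matrix(0L, n, n)    # deduped window id per (center, size)
  for (i in seq_len(n)) {
    d2 <- (centroids$x - centroids$x[i])^2 + (centroids$y - centroids$y[i])^2
    ord <- order(d2, centroids$name)
    cum <- cumsum(pops[ord])
    m <- max(1L, sum(cum <= lim))        # singleton always allowed
    order_tab[i, ] <- ord
    size_tab[i] <- m
    for (s in seq_len(m)) {
      mem <- sort(ord[seq_len(s)])
      key <- paste(mem, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      members[[length(members) + 1L]] <- ord[seq_len(s)]
      center <- c(center, i)
      radius <- c(radius, sqrt(d2[ord[s]]))
      widx_tab[i, s] <- length(members)
    }
  }
  structure(list(members = members, center = center, radius = radius,
                 order_tab = order_tab, size_tab = size_tab,
                 widx_tab = widx_tab, names = centroids$name, pops = pops),
            class = "scan_windows")
}

# LLR that treats degenerate windows (E ~ 0 or E ~ C, i.e. the whole
# region) as carrying no evidence rather than erroring: used internally
# where cumulative windows can reach the full region.
llr_safe <- function(c, E, C) {
  m <- max(length(c), length(E))
  c <- rep_len(as.numeric(c), m)
  E <- rep_len(as.numeric(E), m)
  out <- numeric(m)
  ok <- which(c > E & E > 0 & E < C * (1 - 1e-12))
  if (length(ok)) {
    cc <- c[ok]; EE <- E[ok]
    v <- cc * log(cc / EE)            # c > E > 0, so c log c is finite
    rem <- C - cc
    pos <- rem > 0                    # (C-c) log(...) term, 0 log 0 = 0
    v[pos] <- v[pos] + rem[pos] * log(rem[pos] / (C - EE[pos]))
    out[ok] <- v
  }
  out
}

# Max LLR over all nested windows for each column of a unit x R case
# matrix; one column per Monte Carlo replicate. Column-wise cumulative
# sums via a lower-triangular product (fast for many replicates).
scan_max_llr <- function(win, case_mat, C, E_tot) {
  n <- nrow(case_mat)
  R <- ncol(case_mat)
  best <- numeric(R)
  tri_cache <- list()
  for (i in seq_len(n)) {
    m <- win$size_tab[i]
    ord <- win$order_tab[i, seq_len(m)]
    key <- as.character(m)
    tri <- tri_cache[[key]]
    if (is.null(tri)) {
      tri <- matrix(0, m, m); tri[lower.tri(tri, diag = TRUE)] <- 1
      tri_cache[[key]] <- tri
    }
    cc <- tri %*% case_mat[ord, , drop = FALSE]
    E <- cumsum(E_tot[ord])
    llr <- matrix(llr_safe(as.vector(cc), rep(E, R), C), nrow = m)
    best <- pmax(best, if (m == 1L) as.vector(llr) else
      do.call(pmax, lapply(seq_len(m), function(r) llr[r, ])))
  }
  best
}

#' Monte Carlo p-value for a scan statistic
#'
#' `p = rank / (R + 1)` with `rank = 1 + #{replicate max-LLRs >= observed}`,
#' conditioning on the observed case total. Values at the floor
#' `1/(R+1)` print as `"< threshold"` in the cluster tables.
#'
#' @param observed_llr Observed log-likelihood ratio.
#' @param replicate_llrs Max LLRs of the Monte Carlo replicates.
#' @param R Number of replications (= `length(replicate_llrs)`).
#' @return Monte Carlo p-value in `{1/(R+1), ..., 1}`.
#' @export
monte_carlo_p <- function(observed_llr, replicate_llrs, R = length(replicate_llrs)) {
  if (length(replicate_llrs) != R) stop("R must equal the number of replicates")
  (1 + sum(replicate_llrs >= observed_llr)) / (R + 1)
}

#' Purely spatial discrete-Poisson scan
#'
#' Finds the circular window maximising the Poisson log-likelihood ratio
#' for elevated rates, with Monte Carlo inference by multinomial
#' redistribution of the observed case total over units with
#' population-proportional probabilities. Secondary clusters are reported
#' in decreasing LLR among windows passing the overlap criterion; ties in
#' LLR break toward smaller window population, then the lexicographically
#' smaller center name.
#'
#' @param units data.frame with columns `name, x, y, population,
#'   case_count` (use [as_unit_table()] on a `polygon_set`).
#' @param config A [scan_config()].
#' @param rng_seed Integer seed for the Monte Carlo replicates.
#' @return An object of class `scan_result`; see [cluster_table()].
#' @export
spatial_scan <- function(units, config = scan_config(), rng_seed = 1L) {
  units <- as.data.frame(units)
  if (any(is.na(units$population)) || any(is.na(units$case_count)))
    stop("populations and case counts must be filled")
  C <- sum(units$case_count)
  if (C == 0) {
    warning("no cases; scan returns an empty result")
    return(empty_scan_result(config, C, sum(units$population)))
  }
  E_tot <- expected_counts(units$population, C)
  win <- candidate_windows(units[, c("name", "x", "y")], units$population,
                           config$max_population_fraction)
  cases <- units$case_count

  # observed per-window quantities, one cumulative pass per center
  nw <- length(win$members)
  obs_llr <- numeric(nw)
  obs_c <- numeric(nw); obs_E <- numeric(nw); obs_pop <- numeric(nw)
  for (i in seq_len(nrow(units))) {
    m <- win$size_tab[i]
    keep <- win$widx_tab[i, seq_len(m)]
    sel <- keep > 0L
    if (!any(sel)) next
    ord <- win$order_tab[i, seq_len(m)]
    idx <- keep[sel]
    obs_c[idx] <- cumsum(cases[ord])[sel]
    obs_E[idx] <- cumsum(E_tot[ord])[sel]
    obs_pop[idx] <- cumsum(units$population[ord])[sel]
  }
  obs_llr <- llr_safe(obs_c, obs_E, C)

  R <- config$replications
  rng <- local_rng(rng_seed, "scan-mc")
  rep_mat <- with_rng(rng,
    stats::rmultinom(R, size = C, prob = E_tot / C))
  rep_max <- scan_max_llr(win, rep_mat, C, E_tot)

  build_scan_result(win, units, obs_llr, obs_c, obs_E, obs_pop, C,
                    rep_max, config)
}

# shared cluster-report assembly for spatial and space-time scans;
# date_ranges is an optional per-window list of Date pairs
build_scan_result <- function(win, units, obs_llr, obs_c, obs_E, obs_pop,
                              C, rep_max, config, date_ranges = NULL) {
  R <- length(rep_max)
  ord <- order(-obs_llr, obs_pop, win$names[win$center])
  used_units <- logical(nrow(units))
  clusters <- list()
  for (w in ord) {
    if (obs_llr[w] <= 0) break
    mem <- win$members[[w]]
    if (config$secondary == "no_shared_units") {
      if (any(used_units[mem])) next
    } else {
      # weaker criterion: only the window center must not lie inside a
      # previously reported cluster (published member lists may overlap)
      if (used_units[win$center[w]]) next
    }
    p <- monte_carlo_p(obs_llr[w], rep_max, R)
    # the Monte Carlo floor 1/(R+1) prints as "< threshold", so the
    # report rule is p <= threshold; windows below in LLR order can only
    # have equal-or-larger p
    if (!config$report_all && p > config$significance_threshold + 1e-12) break
    used_units[mem] <- TRUE
    clusters[[length(clusters) + 1L]] <- list(
      cluster_rank = length(clusters) + 1L,
      member_idx = mem, member_units = units$name[mem],
      window_center = win$names[win$center[w]],
      window_radius = win$radius[w],
      date_range = if (is.null(date_ranges)) NULL else date_ranges[[w]],
      c = obs_c[w], E = obs_E[w],
      RR = relative_risk(obs_c[w], obs_E[w], C),
      LLR = obs_llr[w], p = p,
      population = obs_pop[w])
    if (length(clusters) >= nrow(units)) break
  }
  structure(list(clusters = clusters, C = C,
                 P = sum(units$population), units = units,
                 replicate_llrs = rep_max, config = config),
            class = "scan_result")
}

empty_scan_result <- function(config, C, P) {
  structure(list(clusters = list(), C = C, P = P, units = NULL,
                 replicate_llrs = numeric(0), config = config),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result: %d reported cluster(s), C = %d, P = %.6g, R = %d>\n",
              length(x$clusters), x$C, x$P, length(x$replicate_llrs)))
  for (cl in x$clusters) {
    cat(sprintf("  #%d center %s: %d unit(s), pop %.6g, c = %g, E = %.3f, RR = %.2f, LLR = %.2f, p %s\n",
                cl$cluster_rank, cl$window_center, length(cl$member_idx),
                cl$population, cl$c, cl$E, cl$RR, cl$LLR,
                format_mc_p(cl$p, length(x$replicate_llrs),
                            x$config$significance_threshold)))
    if (!is.null(cl$date_range))
      cat(sprintf("     dates %s to %s\n",
                  format(cl$date_range[1], "%d/%m/%Y"),
                  format(cl$date_range[2], "%d/%m/%Y")))
  }
  invisible(x)
}

format_mc_p <- function(p, R, threshold) {
  if (R > 0 && abs(p - 1 / (R + 1)) < 1e-12 && 1 / (R + 1) <= threshold)
    sprintf("< %g", threshold)
  else sprintf("= %g", p)
}

#' Per-unit cluster report table
#'
#' One row per (cluster, member unit), mirroring the published scan
#' output tables: unit population, unit case count, unit relative risk,
#' then the cluster totals, relative risk and Monte Carlo p. Units are
#' ordered within a cluster by decreasing unit relative risk. P-values at
#' the Monte Carlo floor are printed `"< threshold"`.
#'
#' @param x A `scan_result`.
#' @return data.frame with columns `cluster, neighborhood,
#'   [date_start, date_end,] neighborhood_population,
#'   neighborhood_case_count, neighborhood_RR, cluster_population,
#'   cluster_case_count, cluster_RR, p_value`.
#' @export
cluster_table <- function(x) {
  rows <- list()
  R <- length(x$replicate_llrs)
  for (cl in x$clusters) {
    mem <- cl$member_idx
    u <- x$units[mem, , drop = FALSE]
    E_u <- expected_counts(x$units$population, x$C)[mem]
    rr_u <- relative_risk(u$case_count, E_u, x$C)
    o <- order(-rr_u, u$name)
    df <- data.frame(
      cluster = cl$cluster_rank,
      neighborhood = u$name[o],
      neighborhood_population = u$population[o],
      neighborhood_case_count = u$case_count[o],
      neighborhood_RR = rr_u[o],
      cluster_population = cl$population,
      cluster_case_count = cl$c,
      cluster_RR = cl$RR,
      p_value = format_mc_p(cl$p, R, x$config$significance_threshold),
      stringsAsFactors = FALSE)
    if (!is.null(cl$date_range)) {
      df$date_start <- format(cl$date_range[1], "%d/%m/%Y")
      df$date_end <- format(cl$date_range[2], "%d/%m/%Y")
      df <- df[, c("cluster", "neighborhood", "date_start", "date_end",
                   setdiff(names(df), c("cluster", "neighborhood",
                                        "date_start", "date_end")))]
    }
    rows[[length(rows) + 1L]] <- df
  }
  if (length(rows) == 0) return(data.frame())
  do.call(rbind, rows)
}

#' Unit table from a neighborhood polygon set
#'
#' Extracts the columns the scan statistics need — name, centroid
#' coordinates, population and case count — from a `polygon_set`.
#'
#' @param nbhds A `polygon_set` with population/case_count filled.
#' @return data.frame `name, x, y, population, case_count`.
#' @export
as_unit_table <- function(nbhds) {
  ce <- set_centroids(nbhds)
  data.frame(name = nbhds$name, x = ce$x, y = ce$y,
             population = nbhds$population, case_count = nbhds$case_count,
             stringsAsFactors = FALSE)
}
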
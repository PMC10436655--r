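# Space-time discrete-Poisson scan: cylindrical windows (a circular
# spatial window crossed with a contiguous day interval), same LLR / RR /
# Monte Carlo machinery as the purely spatial scan.

#' Space-time discrete-Poisson scan
#'
#' Scans cylinders: every circular spatial window of
#' [candidate_windows()] crossed with every contiguous day interval no
#' longer than `max_temporal_fraction` of the study period. The expected
#' count of a cylinder is `C * (window population / P) * (interval weight)`,
#' where the interval weight is the fraction of the temporal baseline it
#' covers — uniform over days by default, or proportional to the supplied
#' per-day baseline (e.g. to exclude days without records). A cylinder
#' covering the full period reduces to the purely spatial window;
#' cylinders covering every unit are rejected unless
#' `allow_purely_temporal`. Because the scan is one-sided for high rates,
#' the maximising interval starts and ends on days with cases, so only
#' case-day endpoints are enumerated.
#'
#' @param units data.frame `name, x, y, population, case_count`.
#' @param daily_counts Integer matrix, units x days; row sums must match
#'   `units$case_count`.
#' @param config A [scan_config()].
#' @param study_start Date of day 1 (column 1 of `daily_counts`).
#' @param baseline_days Optional nonnegative weights, one per day, for
#'   the temporal baseline (default uniform). Use 0/1 to exclude
#'   missing-record days from the baseline.
#' @param rng_seed Integer seed for the Monte Carlo replicates.
#' @return A `scan_result` whose clusters carry a `date_range`.
#' @export
spacetime_scan <- function(units, daily_counts, config = scan_config(),
                           study_start, baseline_days = NULL,
                           rng_seed = 1L) {
  units <- as.data.frame(units)
  n <- nrow(units)
  TT <- ncol(daily_counts)
  if (nrow(daily_counts) != n) stop("daily_counts must have one row per unit")
  if (!isTRUE(all.equal(as.numeric(rowSums(daily_counts)),
                        as.numeric(units$case_count))))
    stop("inconsistent totals: daily_counts row sums differ from unit case counts")
  C <- sum(daily_counts)
  if (C == 0) {
    warning("no cases; scan returns an empty result")
    return(empty_scan_result(config, C, sum(units$population)))
  }
  u <- if (is.null(baseline_days)) rep(1, TT) else as.numeric(baseline_days)
  if (length(u) != TT || any(u < 0) || sum(u) <= 0)
    stop("baseline_days must be nonnegative weights, one per day")
  u <- u / sum(u)
  cumu <- c(0, cumsum(u))
  Lmax <- max(1L, floor(config$max_temporal_fraction * TT))

  win <- candidate_windows(units[, c("name", "x", "y")], units$population,
                           config$max_population_fraction)
  q <- vapply(win$members, function(mem) sum(units$population[mem]),
              numeric(1)) / sum(units$population)

  scan_obs <- st_scan_counts(win, daily_counts, C, q, cumu, Lmax, TT,
                             config$allow_purely_temporal, n,
                             keep_detail = TRUE)

  R <- config$replications
  rng <- local_rng(rng_seed, "scan-st-mc")
  pop_prob <- units$population / sum(units$population)
  rep_max <- with_rng(rng, vapply(seq_len(R), function(r) {
    uc <- as.vector(stats::rmultinom(1, C, pop_prob))
    dc <- matrix(0L, n, TT)
    for (i in which(uc > 0)) {
      dd <- sample.int(TT, uc[i], replace = TRUE, prob = u)
      tb <- tabulate(dd, nbins = TT)
      dc[i, ] <- tb
    }
    st_scan_counts(win, dc, C, q, cumu, Lmax, TT,
                   config$allow_purely_temporal, n,
                   keep_detail = FALSE)$max_llr
  }, numeric(1)))

  dr <- lapply(seq_along(win$members), function(w) {
    iv <- scan_obs$interval[[w]]
    if (is.null(iv)) NULL else c(study_start + iv[1] - 1L,
                                 study_start + iv[2] - 1L)
  })
  build_scan_result(win, units, scan_obs$llr, scan_obs$c, scan_obs$E,
                    q * sum(units$population), C, rep_max, config,
                    date_ranges = dr)
}

# Core cylinder evaluation: for each deduplicated spatial window, the best
# day interval (case-day endpoints, length <= Lmax, plus the full period
# when allowed) and its LLR/c/E. keep_detail = FALSE returns only the
# overall max LLR.
st_scan_counts <- function(win, daily_counts, C, q, cumu, Lmax, TT,
                           allow_purely_temporal, n_units,
                           keep_detail = TRUE) {
  nw <- length(win$members)
  out_llr <- numeric(nw); out_c <- numeric(nw); out_E <- numeric(nw)
  out_iv <- vector("list", nw)
  best <- 0
  # process windows with many cases first so the upper-bound prune bites
  unit_tot <- rowSums(daily_counts)
  win_tot <- vapply(win$members, function(mem) sum(unit_tot[mem]),
                    numeric(1))
  du <- diff(cumu)
  umin <- min(du[du > 0])   # smallest positive single-day baseline weight
  for (w in order(-win_tot)) {
    mem <- win$members[[w]]
    if (!allow_purely_temporal && length(mem) == n_units) next
    cw <- win_tot[w]
    if (cw == 0) next
    # upper bound: all of the window's cases in the cheapest single day;
    # any real cylinder has c <= cw and E >= E1, so LLR <= llr(cw, E1)
    E1 <- C * q[w] * max(umin, .Machine$double.eps)
    ub <- llr_safe(cw, min(E1, C * (1 - 1e-9)), C)
    if (ub <= 0) next
    if (!keep_detail && ub <= best) next
    dc <- if (length(mem) == 1L) daily_counts[mem, ] else
      colSums(daily_counts[mem, , drop = FALSE])
    cd <- which(dc > 0)
    cumc <- c(0, cumsum(dc))
    k <- length(cd)
    # for each starting case day, the last case day within Lmax
    eb <- findInterval(cd + Lmax - 1L, cd)
    nper <- eb - seq_len(k) + 1L
    si <- rep.int(seq_len(k), nper)
    cs <- cd[si]
    ce <- cd[sequence(nper, from = seq_len(k))]
    if (Lmax >= TT) {
      # full-period cylinder (purely spatial reduction) as an extra candidate
      cs <- c(cs, 1L); ce <- c(ce, TT)
    }
    if (length(cs) == 0) next
    cvec <- cumc[ce + 1L] - cumc[cs]
    Evec <- C * q[w] * (cumu[ce + 1L] - cumu[cs])
    llr <- llr_safe(cvec, Evec, C)
    j <- which.max(llr)
    # deterministic tie-break: among equal LLR prefer the shorter interval,
    # then the earlier start
    lens <- ce - cs + 1L
    tied <- which(llr >= llr[j] - 1e-12)
    j <- tied[order(lens[tied], cs[tied])][1]
    if (keep_detail) {
      out_llr[w] <- llr[j]; out_c[w] <- cvec[j]; out_E[w] <- Evec[j]
      out_iv[[w]] <- c(cs[j], ce[j])
    }
    if (llr[j] > best) best <- llr[j]
  }
  list(llr = out_llr, c = out_c, E = out_E, interval = out_iv,
       max_llr = best)
}

#' Unit-by-day case count matrix from a case line list
#'
#' @param cases Case data.frame (`x, y, date, is_firearm`).
#' @param nbhds A `polygon_set` (assignment as in [assign_cases()]).
#' @param study_start,study_end Study period; dates outside it are an
#'   error.
#' @param firearm_only Count only firearm cases (default TRUE).
#' @return Integer matrix units x days; attribute `excluded` lists
#'   out-of-area cases.
#' @export
case_day_matrix <- function(cases, nbhds, study_start, study_end,
                            firearm_only = TRUE) {
  nb <- assign_cases(cases, nbhds, firearm_only = firearm_only)
  ok <- as.data.frame(cases)
  if (firearm_only) ok <- ok[as.logical(ok$is_firearm), , drop = FALSE]
  ok <- ok[is.finite(ok$x) & is.finite(ok$y) & !is.na(ok$date), , drop = FALSE]
  assigned <- attr(nb, "case_assignment")
  TT <- as.integer(study_end - study_start) + 1L
  if (any(ok$date < study_start | ok$date > study_end, na.rm = TRUE))
    stop("case dates fall outside the study period")
  m <- matrix(0L, nrow(nbhds), TT)
  keep <- !is.na(assigned)
  di <- as.integer(ok$date[keep] - study_start) + 1L
  ui <- assigned[keep]
  for (i in seq_along(di)) m[ui[i], di[i]] <- m[ui[i], di[i]] + 1L
  attr(m, "excluded") <- attr(nb, "excluded")
  m
}
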
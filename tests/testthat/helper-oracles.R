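# Independent oracles used across the suite. These re-derive expected values
# by brute force (scans, loops, hand formulas) and never call the package
# code paths they check.

# Brute-force product-limit estimator: risk set by direct counting at each
# distinct event time (ties between events and censorings count the events
# first, i.e. censored-at-t subjects are still at risk at t).
oracle_km_survival <- function(time, event, eval_times) {
  ev_times <- sort(unique(time[event]))
  s <- 1
  surv_at <- function(t0) {
    s <- 1
    for (tj in ev_times[ev_times <= t0]) {
      n_j <- sum(time >= tj)
      d_j <- sum(time == tj & event)
      s <- s * (1 - d_j / n_j)
    }
    s
  }
  vapply(eval_times, surv_at, numeric(1))
}

# Dq by bisection on the linearly interpolated cumulative curve: largest
# dose whose interpolated coverage is >= q.
oracle_dose_at_volume <- function(dvh, q, tol = 1e-9) {
  vfun <- stats::approxfun(dvh$dose_gy, dvh$volume_fraction)
  lo <- 0
  hi <- max(dvh$dose_gy)
  if (vfun(hi) >= q) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (vfun(mid) >= q) lo <- mid else hi <- mid
  }
  lo
}

# Mean dose as the area under the cumulative curve (integration by parts),
# by fine trapezoidal quadrature.
oracle_mean_dose <- function(dvh, n_grid = 200000) {
  g <- seq(0, max(dvh$dose_gy), length.out = n_grid)
  v <- stats::approx(dvh$dose_gy, dvh$volume_fraction, xout = g)$y
  sum((v[-1] + v[-n_grid]) / 2 * diff(g))
}

# Random valid differential DVH (for EUD loop oracles).
random_ddvh <- function(n_bins = 25, max_dose = 60) {
  d <- sort(stats::runif(n_bins, 0.1, max_dose))
  w <- stats::runif(n_bins)
  differential_dvh(d, w / sum(w))
}

# Random generated PTV DVH with shape ratios drawn from the generator's
# default ranges.
random_ptv_dvh <- function(rx = 50) {
  d95 <- stats::runif(1, 0.98, 1.02)
  d99 <- min(stats::runif(1, 0.95, 1.00), d95)
  dmax <- stats::runif(1, 1.10, 1.25)
  generate_ptv_dvh(rx, dvh_shape_params(d99, d95, dmax,
                                        stats::runif(1, 1, 3)))
}

# Shared large synthetic cohort (expensive; built once per test run).
.shared <- new.env(parent = emptyenv())
big_cohort <- function() {
  if (is.null(.shared$big)) {
    spec <- cohort_spec(n_tumors = 10000, seed = 424242L)
    co <- generate_cohort(spec)
    .shared$big <- add_followup(co, simulate_outcomes(co, spec))
    .shared$big_spec <- spec
  }
  .shared$big
}
big_cohort_spec <- function() {
  big_cohort()
  .shared$big_spec
}

scheme_of <- function(cohort, i) {
  fractionation_scheme(cohort$total_dose_gy[i], cohort$n_fractions[i])
}
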
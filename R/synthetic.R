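# Derived per-stream seeds: one root seed, a fixed stream id per random
# quantity, each drawn as its own vectorized stream. Adding tumors then
# extends every stream without reshuffling earlier draws.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(stream) * 101L
}

#' @keywords internal
#' @noRd
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  expr
}

#' Default SBRT fractionation mix
#'
#' Scheme frequencies of the emulated cohort: 50 Gy/5 fx (60%), 54/3 (26%),
#' 60/5 (9%), 48/4 (2%), 40/5 (3%).
#'
#' @return Data frame with columns `total_dose_gy`, `n_fractions`, `prob`.
#' @export
default_scheme_mix <- function() {
  data.frame(
    total_dose_gy = c(50, 54, 60, 48, 40),
    n_fractions = c(5L, 3L, 5L, 4L, 5L),
    prob = c(0.60, 0.26, 0.09, 0.02, 0.03)
  )
}

#' Synthetic cohort specification
#'
#' All knobs of the virtual SBRT cohort. Defaults emulate a 109-tumor lung
#' SBRT population: the fractionation mix of [default_scheme_mix()], target
#' volumes lognormal with median 22.4 cc truncated to 5.8-163.4 cc, 6-39
#' month censoring window, and recurrence outcomes drawn from the D99-based
#' TCP model.
#'
#' @param n_tumors Cohort size.
#' @param scheme_mix Data frame (`total_dose_gy`, `n_fractions`, `prob`);
#'   probabilities must sum to 1.
#' @param volume_median_cc,volume_sdlog Lognormal target-volume parameters
#'   (median in cc and SD on the log scale).
#' @param volume_bounds_cc Truncation bounds in cc; must straddle the median.
#' @param followup_window_months Censoring-time window (months).
#' @param event_window_months Window for recurrence event times (months);
#'   recurrence-by-2-years is Bernoulli(1 - TCP) and the event time uniform
#'   on this window.
#' @param generating_metric PTV dose metric whose TCP drives the outcomes.
#' @param tcp_params,ntcp_params Model parameter sets.
#' @param d99_ratio_range,d95_ratio_range,dmax_ratio_range Per-tumor DVH
#'   shape ratios (multiples of prescription dose), drawn uniformly.
#' @param steepness_range_gy Per-tumor DVH shoulder width range, Gy.
#' @param seed Root seed; every draw is derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tumors = 109,
                        scheme_mix = default_scheme_mix(),
                        volume_median_cc = 22.4,
                        volume_sdlog = 0.65,
                        volume_bounds_cc = c(5.8, 163.4),
                        followup_window_months = c(6, 39),
                        event_window_months = c(3, 24),
                        generating_metric = "D99",
                        tcp_params = sbedtcp::tcp_params(),
                        ntcp_params = sbedtcp::ntcp_params(),
                        d99_ratio_range = c(0.95, 1.00),
                        d95_ratio_range = c(0.98, 1.02),
                        dmax_ratio_range = c(1.10, 1.25),
                        steepness_range_gy = c(1, 3),
                        seed = 1L) {
  stopifnot(is.data.frame(scheme_mix),
            all(c("total_dose_gy", "n_fractions", "prob") %in%
                  names(scheme_mix)))
  if (abs(sum(scheme_mix$prob) - 1) > 1e-9) {
    stop("scheme mix probabilities must sum to 1")
  }
  if (any(scheme_mix$prob < 0)) stop("scheme mix probabilities must be >= 0")
  if (n_tumors < 1) stop("need at least one tumor")
  if (!(volume_bounds_cc[1] < volume_median_cc &&
        volume_median_cc < volume_bounds_cc[2])) {
    stop("volume bounds must straddle the lognormal median")
  }
  if (followup_window_months[1] <= 0 ||
      diff(followup_window_months) <= 0) {
    stop("follow-up window must be positive and increasing")
  }
  generating_metric <- match.arg(generating_metric, dose_metric_names())
  structure(
    list(n_tumors = as.integer(n_tumors), scheme_mix = scheme_mix,
         volume_median_cc = volume_median_cc, volume_sdlog = volume_sdlog,
         volume_bounds_cc = volume_bounds_cc,
         followup_window_months = followup_window_months,
         event_window_months = event_window_months,
         generating_metric = generating_metric,
         tcp_params = tcp_params, ntcp_params = ntcp_params,
         d99_ratio_range = d99_ratio_range,
         d95_ratio_range = d95_ratio_range,
         dmax_ratio_range = dmax_ratio_range,
         steepness_range_gy = steepness_range_gy,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' DVH shape parameters for the PTV generator
#'
#' Target D99/D95/maximum dose as multiples of the prescription dose, and a
#' shoulder width (`steepness_gy`) controlling how quickly coverage falls
#' off below D99. In the limit of all ratios 1 and steepness near 0 the
#' generated DVH degenerates to a step function at the prescription dose.
#'
#' @param d99_ratio,d95_ratio,dmax_ratio Dimensionless multiples of the
#'   prescription dose with `d99_ratio <= d95_ratio <= dmax_ratio`.
#' @param steepness_gy Shoulder width in Gy (> 0).
#' @return An object of class `dvh_shape_params`.
#' @export
dvh_shape_params <- function(d99_ratio = 0.97, d95_ratio = 1.00,
                             dmax_ratio = 1.17, steepness_gy = 2) {
  if (!(d99_ratio <= d95_ratio && d95_ratio <= dmax_ratio)) {
    stop("shape ratios must satisfy d99 <= d95 <= dmax")
  }
  if (!is.finite(steepness_gy) || steepness_gy <= 0) {
    stop("steepness must be positive")
  }
  structure(
    list(d99_ratio = d99_ratio, d95_ratio = d95_ratio,
         dmax_ratio = dmax_ratio, steepness_gy = steepness_gy),
    class = "dvh_shape_params"
  )
}

#' Generate a sigmoid-shaped PTV cumulative DVH
#'
#' Builds a smooth monotone cumulative DVH through anchor points placed so
#' that the interpolated D99, D95 and maximum dose land on
#' `rx * (respective ratio)`: full coverage up to a shoulder below D99,
#' 99%/95% coverage at the D99/D95 anchors, and a sigmoid tail falling to
#' zero just past the maximum-dose anchor. The curve is a monotone Hermite
#' spline (Fritsch-Carlson) sampled on a 0.1-Gy grid.
#'
#' @param rx_dose_gy Prescription dose in Gy (> 0).
#' @param shape A [dvh_shape_params()].
#' @param label Structure label.
#' @return A [cumulative_dvh()].
#' @export
generate_ptv_dvh <- function(rx_dose_gy, shape = dvh_shape_params(),
                             label = "PTV") {
  stopifnot(inherits(shape, "dvh_shape_params"))
  if (!is.finite(rx_dose_gy) || rx_dose_gy <= 0) {
    stop("prescription dose must be positive")
  }
  sep <- max(shape$steepness_gy * 0.05, 0.02)
  d95 <- rx_dose_gy * shape$d95_ratio
  d99 <- min(rx_dose_gy * shape$d99_ratio, d95 - sep)
  dmax <- max(rx_dose_gy * shape$dmax_ratio, d95 + 2 * sep)
  shoulder <- min(max(d99 - shape$steepness_gy, 0), d99 - sep)
  mid <- min(max(d95 + 0.55 * (dmax - d95), d95 + sep), dmax - sep)
  end <- dmax + max(shape$steepness_gy * 0.5, 0.05)
  x <- c(0, shoulder, d99, d95, mid, dmax, end)
  y <- c(1, 1, 0.99, 0.95, 0.45, .eps_min, 0)
  if (shoulder <= 0) {
    x <- x[-2]
    y <- y[-2]
  }
  for (i in seq_along(x)[-1]) {        # guard strict increase
    if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + 1e-3
  }
  f <- stats::splinefun(x, y, method = "monoH.FC")
  grid <- seq(0, ceiling(max(x) * 10) / 10 + 0.1, by = 0.1)
  v <- f(grid)
  v[grid >= max(x)] <- 0
  v <- cummin(pmin(pmax(v, 0), 1))
  v[1] <- 1
  cumulative_dvh(grid, v, label = label)
}

#' Generate a synthetic SBRT cohort
#'
#' Draws `n_tumors` virtual lesions from a [cohort_spec()]: fractionation
#' schemes multinomial from the mix, target volumes truncated-lognormal
#' (sphere-equivalent diameters), per-tumor DVH shape parameters, and a
#' sigmoid PTV DVH per tumor via [generate_ptv_dvh()]. Location and
#' histology labels are generated with the emulated cohort's frequencies
#' but carry no effect in the outcome model. Fully reproducible from the
#' spec's seed, and draws are prefix-stable: growing `n_tumors` leaves
#' earlier tumors unchanged.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame of class `sbrt_cohort`, one row per tumor, with
#'   columns `tumor_id`, `target_volume_cc`, `diameter_cm`, `total_dose_gy`,
#'   `n_fractions`, `location`, `histology` and list-column `ptv_dvh`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_tumors
  mix <- spec$scheme_mix
  scheme_idx <- with_stream(spec$seed, 1L,
    sample.int(nrow(mix), n, replace = TRUE, prob = mix$prob))
  lo <- spec$volume_bounds_cc[1]
  hi <- spec$volume_bounds_cc[2]
  mu <- log(spec$volume_median_cc)
  u <- with_stream(spec$seed, 2L,
    stats::runif(n, stats::plnorm(lo, mu, spec$volume_sdlog),
                 stats::plnorm(hi, mu, spec$volume_sdlog)))
  volume <- stats::qlnorm(u, mu, spec$volume_sdlog)
  d95r <- with_stream(spec$seed, 3L,
    stats::runif(n, spec$d95_ratio_range[1], spec$d95_ratio_range[2]))
  d99r <- with_stream(spec$seed, 4L,
    stats::runif(n, spec$d99_ratio_range[1], spec$d99_ratio_range[2]))
  d99r <- pmin(d99r, d95r)
  dmaxr <- with_stream(spec$seed, 5L,
    stats::runif(n, spec$dmax_ratio_range[1], spec$dmax_ratio_range[2]))
  dmaxr <- pmax(dmaxr, d95r)
  steep <- with_stream(spec$seed, 6L,
    stats::runif(n, spec$steepness_range_gy[1], spec$steepness_range_gy[2]))
  location <- with_stream(spec$seed, 7L,
    ifelse(stats::runif(n) < 0.12, "central", "peripheral"))
  histology <- with_stream(spec$seed, 8L,
    sample(c("adenocarcinoma", "squamous", "other"), n, replace = TRUE,
           prob = c(0.55, 0.25, 0.20)))
  dvhs <- lapply(seq_len(n), function(i) {
    generate_ptv_dvh(
      mix$total_dose_gy[scheme_idx[i]],
      dvh_shape_params(d99r[i], d95r[i], dmaxr[i], steep[i])
    )
  })
  out <- data.frame(
    tumor_id = sprintf("T%05d", seq_len(n)),
    target_volume_cc = volume,
    diameter_cm = diameter_from_volume(volume),
    total_dose_gy = mix$total_dose_gy[scheme_idx],
    n_fractions = mix$n_fractions[scheme_idx],
    location = location,
    histology = histology
  )
  out$ptv_dvh <- dvhs
  class(out) <- c("sbrt_cohort", "data.frame")
  out
}

#' Simulate recurrence outcomes from the TCP model
#'
#' For each tumor, recurrence-by-2-years is Bernoulli(1 - TCP) with TCP
#' computed from the spec's generating dose metric on the tumor's own DVH.
#' Recurrence times are uniform on the event window, censoring times uniform
#' on the follow-up window; the observed time is the earlier of the two with
#' the event flag set accordingly.
#'
#' @param cohort Cohort from [generate_cohort()].
#' @param spec The same [cohort_spec()] (supplies the generating metric,
#'   TCP parameters, windows and seed).
#' @return Data frame with columns `tumor_id`, `time` (months), `event`
#'   (logical), and the generating `tcp` per tumor.
#' @seealso [add_followup()] to attach these columns to the cohort.
#' @export
simulate_outcomes <- function(cohort, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cohort <- check_cohort(cohort)
  n <- nrow(cohort)
  tab <- parameterize_cohort(cohort, spec$generating_metric, spec$tcp_params)
  recur <- with_stream(spec$seed, 11L, stats::runif(n)) < (1 - tab$tcp)
  ev_t <- with_stream(spec$seed, 12L,
    stats::runif(n, spec$event_window_months[1], spec$event_window_months[2]))
  cens <- with_stream(spec$seed, 13L,
    stats::runif(n, spec$followup_window_months[1],
                 spec$followup_window_months[2]))
  observed_event <- recur & ev_t <= cens
  data.frame(
    tumor_id = cohort$tumor_id,
    time = ifelse(observed_event, ev_t, cens),
    event = observed_event,
    tcp = tab$tcp
  )
}

#' Attach simulated follow-up to a cohort
#'
#' @param cohort Cohort from [generate_cohort()].
#' @param followup Output of [simulate_outcomes()] (or any data frame with
#'   `tumor_id`, `time`, `event`).
#' @return The cohort with columns `followup_months` and `recurrence_event`
#'   added.
#' @export
add_followup <- function(cohort, followup) {
  i <- match(cohort$tumor_id, followup$tumor_id)
  if (anyNA(i)) stop("follow-up records missing for some tumors")
  cohort$followup_months <- followup$time[i]
  cohort$recurrence_event <- followup$event[i]
  cohort
}

# mean EQD of a weight vector over bin centers, for the OAR builder
#' @keywords internal
#' @noRd
.mean_eqd <- function(centers, weights, n_fx, alpha_beta) {
  sum(weights * centers * (alpha_beta + centers / n_fx) / (alpha_beta + 2))
}

#' Generate synthetic organ-at-risk differential DVHs
#'
#' Builds per-patient differential DVHs for the total-lung-minus-ITV
#' ("lung") or rib structures. Each DVH is a three-component mixture: a
#' near-zero-dose spike, a low-dose exponential tail, and a high-dose
#' component near the prescription dose whose weight is solved so that the
#' structure's EUD (at the given NTCP parameters) hits a per-patient target
#' drawn from a lognormal. The lung target distribution is calibrated so
#' the cohort mean predicted pneumonitis incidence lands at the few-percent
#' scale; the rib targets land near a 13% mean. Rib DVHs are generated only
#' for a subset of peripheral tumors (default fraction 21/109). These are
#' synthetic stand-ins for planning DVHs, not anatomically realistic dose
#' distributions.
#'
#' @param cohort Cohort from [generate_cohort()].
#' @param organ `"lung"` or `"rib"`.
#' @param params [ntcp_params()] used for the EUD calibration.
#' @param seed Seed for the per-patient draws.
#' @param rib_fraction Fraction of tumors with a rib structure at risk.
#' @return Named list (by `tumor_id`) of [differential_dvh()] objects.
#' @export
generate_oar_dvhs <- function(cohort, organ = c("lung", "rib"),
                              params = ntcp_params(), seed = 1L,
                              rib_fraction = 21 / 109) {
  organ <- match.arg(organ)
  cohort <- check_cohort(cohort)
  n_all <- nrow(cohort)
  if (organ == "lung") {
    idx <- seq_len(n_all)
    eud_meanlog <- log(20.5)
    eud_sdlog <- 0.22
    w_low <- 0.30
    low_scale <- 4
    hi_ratio <- 0.90
    stream0 <- 21L
  } else {
    peripheral <- which(cohort$location == "peripheral")
    n_rib <- max(1L, round(rib_fraction * n_all))
    ord <- with_stream(seed, 31L, sample(peripheral))
    idx <- sort(ord[seq_len(min(n_rib, length(ord)))])
    eud_meanlog <- log(27.5)
    eud_sdlog <- 0.25
    w_low <- 0.25
    low_scale <- 5
    hi_ratio <- 1.00
    stream0 <- 32L
  }
  n <- length(idx)
  eud_target <- with_stream(seed, stream0,
    stats::qlnorm(stats::runif(n), eud_meanlog, eud_sdlog))
  out <- lapply(seq_len(n), function(j) {
    i <- idx[j]
    rx <- cohort$total_dose_gy[i]
    n_fx <- cohort$n_fractions[i]
    ab <- params$alpha_beta_gy
    cap <- 1.1 * rx
    centers <- seq(0.25, cap, by = 0.5)
    nb <- length(centers)
    eqd_c <- centers * (ab + centers / n_fx) / (ab + 2)
    # low-dose exponential component (doses up to ~3 scale lengths)
    low <- exp(-centers / low_scale) * (centers <= 3 * low_scale)
    low <- low / sum(low)
    q_low <- sum(low * eqd_c)
    # high-dose component spread over three bins around hi_ratio * rx
    k <- which.min(abs(centers - hi_ratio * rx))
    kk <- unique(pmin(pmax(c(k - 1, k, k + 1), 1), nb))
    hi <- numeric(nb)
    hi[kk] <- c(0.25, 0.5, 0.25)[seq_along(kk)]
    hi <- hi / sum(hi)
    q_hi <- sum(hi * eqd_c)
    q0 <- eqd_c[1]
    w_hi <- (eud_target[j] - q0 - w_low * (q_low - q0)) / (q_hi - q0)
    w_hi <- min(max(w_hi, 0.005), 0.45)
    p0 <- 1 - w_low - w_hi
    w <- numeric(nb)
    w[1] <- p0
    w <- w + w_low * low + w_hi * hi
    w <- w / sum(w)
    differential_dvh(centers, w,
                     label = paste0(organ, "-", cohort$tumor_id[i]))
  })
  names(out) <- cohort$tumor_id[idx]
  out
}
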
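#' @keywords internal
#' @noRd
check_cohort <- function(cohort, need_followup = FALSE) {
  cohort <- as.data.frame(cohort)
  need <- c("tumor_id", "target_volume_cc", "diameter_cm", "total_dose_gy",
            "n_fractions", "ptv_dvh")
  if (need_followup) need <- c(need, "followup_months", "recurrence_event")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(cohort) == 0) stop("empty cohort")
  if (!all(vapply(cohort$ptv_dvh, inherits, logical(1), "cumulative_dvh"))) {
    stop("column 'ptv_dvh' must hold cumulative_dvh objects")
  }
  # sanity bound: PTV must actually receive something close to prescription
  dmax <- vapply(cohort$ptv_dvh, function(d) max(d$dose_gy), numeric(1))
  bad <- dmax < 0.8 * cohort$total_dose_gy
  if (any(bad)) {
    stop("PTV DVH maximum dose below 80% of prescription for tumor(s): ",
         paste(utils::head(cohort$tumor_id[bad], 5), collapse = ", "))
  }
  cohort
}

# per-tumor metric table (rows = tumors, columns = the seven metrics), Gy
#' @keywords internal
#' @noRd
cohort_dose_metrics <- function(cohort) {
  m <- t(mapply(function(dvh, rx) extract_metrics(dvh, rx),
                cohort$ptv_dvh, cohort$total_dose_gy))
  rownames(m) <- cohort$tumor_id
  m
}

#' Per-tumor TCP table under one PTV dose parameterization
#'
#' For each tumor: extracts the chosen PTV dose metric, converts it to BED
#' at the tumor's own fractionation (alpha/beta from `params`), applies the
#' size adjustment with the tumor's diameter, and evaluates the logistic
#' TCP.
#'
#' @param cohort Cohort data frame (one row per tumor) with columns
#'   `tumor_id`, `target_volume_cc`, `diameter_cm`, `total_dose_gy`,
#'   `n_fractions` and list-column `ptv_dvh` of [cumulative_dvh()] objects,
#'   e.g. from [generate_cohort()] or [read_cohort()].
#' @param metric One of [dose_metric_names()].
#' @param params A [tcp_params()].
#' @param metrics Optional precomputed metric matrix (internal reuse).
#' @return Data frame with columns `tumor_id`, `metric`, `metric_dose_gy`,
#'   `bed10_gy`, `sbed_gy`, `tcp`.
#' @export
parameterize_cohort <- function(cohort, metric = "D99",
                                params = tcp_params(), metrics = NULL) {
  cohort <- check_cohort(cohort)
  metric <- match.arg(metric, dose_metric_names())
  stopifnot(inherits(params, "tcp_params"))
  if (is.null(metrics)) metrics <- cohort_dose_metrics(cohort)
  dose <- metrics[, metric]
  bed10 <- dose * (1 + dose / cohort$n_fractions / params$alpha_beta_gy)
  sb <- sbed(bed10, cohort$diameter_cm, params)
  data.frame(
    tumor_id = cohort$tumor_id,
    metric = metric,
    metric_dose_gy = as.numeric(dose),
    bed10_gy = as.numeric(bed10),
    sbed_gy = as.numeric(sb),
    tcp = tcp(sb, params),
    row.names = NULL
  )
}

#' Bin tumors by sBED and compare predicted with observed control
#'
#' Sorts tumors by their size-adjusted BED and splits them into `n_bins`
#' contiguous near-equal groups (any remainder goes to the lowest-sBED
#' bins, so 109 tumors in 4 bins gives sizes 28/27/27/27). Each bin reports
#' the mean and SD of member sBED, the predicted control (mean member TCP)
#' and the observed control (the bin's own Kaplan-Meier actuarial rate at
#' the horizon).
#'
#' @param table Output of [parameterize_cohort()].
#' @param cohort The matching cohort data frame, including follow-up columns
#'   `followup_months` and `recurrence_event`.
#' @param n_bins Number of bins (>= 2, <= number of tumors); default 4.
#' @param horizon_months Actuarial horizon; default 24 (2 years).
#' @return Data frame with one row per bin: `bin`, `n`, `mean_sbed_gy`,
#'   `sd_sbed_gy`, `predicted_control`, `observed_control`, plus a
#'   list-column `tumor_ids`.
#' @export
bin_by_sbed <- function(table, cohort, n_bins = 4, horizon_months = 24) {
  cohort <- check_cohort(cohort, need_followup = TRUE)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2) stop("need at least 2 bins")
  n <- nrow(table)
  if (n_bins > n) stop("more bins than tumors")
  if (!identical(sort(table$tumor_id), sort(cohort$tumor_id))) {
    stop("TCP table and cohort hold different tumors")
  }
  tab <- table[order(table$sbed_gy, table$tumor_id), ]
  base <- n %/% n_bins
  sizes <- base + (seq_len(n_bins) <= n %% n_bins)
  bin_of <- rep(seq_len(n_bins), times = sizes)
  fu <- cohort[match(tab$tumor_id, cohort$tumor_id),
               c("followup_months", "recurrence_event")]
  names(fu) <- c("time", "event")
  out <- lapply(seq_len(n_bins), function(b) {
    idx <- which(bin_of == b)
    curve <- km_fit(fu[idx, ])
    data.frame(
      bin = b,
      n = length(idx),
      mean_sbed_gy = mean(tab$sbed_gy[idx]),
      sd_sbed_gy = stats::sd(tab$sbed_gy[idx]),
      predicted_control = mean(tab$tcp[idx]),
      observed_control = actuarial_rate(curve, horizon_months)
    )
  })
  out <- do.call(rbind, out)
  out$tumor_ids <- lapply(seq_len(n_bins),
                          function(b) tab$tumor_id[bin_of == b])
  out
}

#' Pearson correlation of observed vs predicted bin control rates
#'
#' Sample Pearson correlation between the per-bin observed (Kaplan-Meier)
#' and predicted (mean TCP) control rates, with the usual two-sided p-value
#' from the t distribution with `n_bins - 2` degrees of freedom.
#'
#' @param bins Output of [bin_by_sbed()].
#' @return Data frame with columns `pearson_r`, `p_value`, `n_bins`.
#' @export
correlate_observed_predicted <- function(bins) {
  obs <- bins$observed_control
  pred <- bins$predicted_control
  if (length(obs) < 3 || anyNA(obs) || anyNA(pred) ||
      any(!is.finite(c(obs, pred)))) {
    stop("need at least 3 bins with finite observed and predicted values")
  }
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    stop("undefined correlation: zero variance in observed or predicted rates")
  }
  ct <- stats::cor.test(obs, pred, method = "pearson",
                        alternative = "two.sided")
  data.frame(pearson_r = unname(ct$estimate), p_value = ct$p.value,
             n_bins = length(obs))
}

#' Rank the seven PTV dose parameterizations by predictive power
#'
#' Runs parameterize -> bin -> correlate for every metric in
#' [dose_metric_names()] and ranks the results by descending Pearson r
#' (ties: ascending p, then metric name). Also reports each
#' parameterization's cohort summary (mean and SD of per-tumor TCP), the
#' Table-style "predicted control" spread.
#'
#' @inheritParams bin_by_sbed
#' @param cohort Cohort data frame including follow-up columns.
#' @param params A [tcp_params()].
#' @return Data frame, one row per metric, sorted by rank: `metric`,
#'   `mean_tcp`, `sd_tcp`, `pearson_r`, `p_value`, `n_bins`.
#' @export
rank_parameterizations <- function(cohort, params = tcp_params(),
                                   n_bins = 4, horizon_months = 24) {
  cohort <- check_cohort(cohort, need_followup = TRUE)
  metrics <- cohort_dose_metrics(cohort)
  rows <- lapply(dose_metric_names(), function(m) {
    tab <- parameterize_cohort(cohort, m, params, metrics = metrics)
    bins <- bin_by_sbed(tab, cohort, n_bins, horizon_months)
    cr <- correlate_observed_predicted(bins)
    data.frame(metric = m, mean_tcp = mean(tab$tcp),
               sd_tcp = stats::sd(tab$tcp),
               pearson_r = cr$pearson_r, p_value = cr$p_value,
               n_bins = cr$n_bins)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$pearson_r, res$p_value, res$metric), ]
  rownames(res) <- NULL
  res
}

#' Predicted toxicity incidence from organ-at-risk DVHs
#'
#' Per structure: EUD of the differential DVH under its fractionation, then
#' the logistic NTCP. The cohort-level predicted incidence is the arithmetic
#' mean of the per-structure NTCPs.
#'
#' @param ddvhs List of [differential_dvh()] objects (e.g. total lung minus
#'   ITV, or ribs), one per patient/tumor.
#' @param schemes List of matching [fractionation_scheme()] objects (or a
#'   single scheme recycled for all).
#' @param params An [ntcp_params()].
#' @return List with `ntcp` (numeric vector, one per structure),
#'   `predicted_incidence` (their mean) and `n`.
#' @export
predict_toxicity <- function(ddvhs, schemes, params = ntcp_params()) {
  if (length(ddvhs) == 0) stop("no DVHs supplied")
  if (inherits(schemes, "fractionation_scheme")) {
    schemes <- rep(list(schemes), length(ddvhs))
  }
  if (length(schemes) != length(ddvhs)) {
    stop("need one fractionation scheme per DVH")
  }
  p <- mapply(function(dd, sc) ntcp(eud(dd, sc, params), params),
              ddvhs, schemes)
  p <- as.numeric(p)
  names(p) <- names(ddvhs)
  list(ntcp = p, predicted_incidence = mean(p), n = length(p))
}

#' Compare observed toxicity counts with a predicted incidence
#'
#' One-degree-of-freedom chi-squared goodness of fit of the observed
#' (events, non-events) split against the expected split under the
#' predicted incidence. When either expected cell is below 5 the chi-squared
#' approximation is unreliable and the exact two-sided binomial test is
#' substituted (flagged in the output).
#'
#' @param observed_events Number of observed toxicity events (0..n).
#' @param n Number of patients evaluated (> 0).
#' @param predicted_incidence Model-predicted incidence, strictly in (0, 1).
#' @return List with `p_value`, `statistic` (chi-squared branch only, else
#'   `NA`), `expected_events`, `method` and logical `exact`.
#' @export
#' @examples
#' compare_toxicity(2, 21, 0.13)  # exact branch, non-significant
compare_toxicity <- function(observed_events, n, predicted_incidence) {
  n <- as.integer(n)
  observed_events <- as.integer(observed_events)
  if (is.na(n) || n <= 0) stop("n must be a positive count")
  if (is.na(observed_events) || observed_events < 0 || observed_events > n) {
    stop("observed events must lie in 0..n")
  }
  p <- predicted_incidence
  if (!is.finite(p) || p <= 0 || p >= 1) {
    stop("predicted incidence must lie strictly in (0, 1)")
  }
  expected <- c(n * p, n * (1 - p))
  if (min(expected) < 5) {
    bt <- stats::binom.test(observed_events, n, p = p,
                            alternative = "two.sided")
    list(p_value = bt$p.value, statistic = NA_real_,
         expected_events = expected[1],
         method = "exact binomial (expected cell < 5)", exact = TRUE)
  } else {
    ct <- suppressWarnings(
      stats::chisq.test(c(observed_events, n - observed_events),
                        p = c(p, 1 - p))
    )
    list(p_value = ct$p.value, statistic = unname(ct$statistic),
         expected_events = expected[1],
         method = "chi-squared goodness of fit", exact = FALSE)
  }
}
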
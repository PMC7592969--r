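#' Kaplan-Meier product-limit fit of local control
#'
#' Fits the product-limit estimator to right-censored follow-up records
#' (time in months since treatment, event = local recurrence observed).
#' At each distinct event time the survival drops by the factor
#' `1 - d_j / n_j`; records censored at a time reduce the risk set after
#' that time (ties between events and censorings at the same time count the
#' events first). Estimation is delegated to [survival::survfit()].
#'
#' @param followup A data frame with numeric column `time` (months, > 0,
#'   finite) and logical/0-1 column `event`, one row per tumor. Extra
#'   columns (e.g. `tumor_id`) are ignored.
#' @return A `km_curve`: data frame with one row per distinct event time and
#'   columns `time`, `n_risk`, `n_event`, `survival`.
#' @seealso [actuarial_rate()]
#' @export
#' @examples
#' fu <- data.frame(time = c(5, 8, 12), event = c(TRUE, FALSE, TRUE))
#' km_fit(fu)
km_fit <- function(followup) {
  followup <- as.data.frame(followup)
  if (nrow(followup) == 0) stop("cannot fit a survival curve to zero records")
  if (!all(c("time", "event") %in% names(followup))) {
    stop("follow-up records need columns 'time' and 'event'")
  }
  tm <- as.numeric(followup$time)
  ev <- as.logical(followup$event)
  if (anyNA(tm) || anyNA(ev) || any(!is.finite(tm)) || any(tm <= 0)) {
    stop("follow-up times must be finite and positive")
  }
  fit <- survival::survfit(survival::Surv(tm, ev) ~ 1, conf.type = "none")
  keep <- fit$n.event > 0
  out <- data.frame(
    time = fit$time[keep],
    n_risk = fit$n.risk[keep],
    n_event = fit$n.event[keep],
    survival = fit$surv[keep]
  )
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Actuarial control rate at a fixed horizon
#'
#' Step-function evaluation of a Kaplan-Meier curve at a horizon (24 months
#' for "2-year actuarial local control"): the survival after the last event
#' time at or before the horizon, or 1 if no event occurred by then. An
#' event at exactly the horizon counts as pre-horizon (closed interval), the
#' usual actuarial convention.
#'
#' @param curve A `km_curve` from [km_fit()].
#' @param horizon_months Evaluation time in months (> 0).
#' @return Survival probability at the horizon.
#' @export
actuarial_rate <- function(curve, horizon_months = 24) {
  stopifnot(inherits(curve, "km_curve"))
  if (!is.finite(horizon_months) || horizon_months <= 0) {
    stop("horizon must be positive")
  }
  at_or_before <- curve$time <= horizon_months
  if (!any(at_or_before)) return(1)
  curve$survival[max(which(at_or_before))]
}
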
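#' Fractionation scheme
#'
#' Total prescribed dose and number of fractions; the per-fraction dose
#' `total_dose_gy / n_fractions` drives both the BED and EQD conversions.
#' SBRT schemes in this package are of the 40-60 Gy in 3-5 fraction type,
#' but any scheme with per-fraction dose in (0, 40] Gy is accepted.
#'
#' @param total_dose_gy Total physical dose in Gy (> 0).
#' @param n_fractions Positive integer number of fractions.
#' @return An object of class `fractionation_scheme`.
#' @export
#' @examples
#' fractionation_scheme(50, 5)
fractionation_scheme <- function(total_dose_gy, n_fractions) {
  if (!is.finite(total_dose_gy) || total_dose_gy <= 0) {
    stop("total dose must be positive")
  }
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1) {
    stop("number of fractions must be a positive integer")
  }
  d <- total_dose_gy / n_fractions
  if (d > 40) stop("dose per fraction above 40 Gy is outside the model range")
  structure(
    list(total_dose_gy = as.numeric(total_dose_gy),
         n_fractions = n_fractions),
    class = "fractionation_scheme"
  )
}

#' @export
print.fractionation_scheme <- function(x, ...) {
  cat(sprintf("%g Gy in %d fractions (%.2f Gy/fx)\n",
              x$total_dose_gy, x$n_fractions,
              x$total_dose_gy / x$n_fractions))
  invisible(x)
}

#' TCP model parameters
#'
#' Constants of the size-adjusted-BED logistic tumor control model:
#' `tcp = exp(z) / (1 + exp(z))` with `z = (sBED - tcd50) / k` and
#' `sBED = BED10 - c * L` for tumor diameter `L` (cm). Defaults are the
#' published multi-institutional fit for 2-year local control after
#' hypofractionated lung radiotherapy: `tcd50 = 0` Gy with slope `k = 31` Gy,
#' size penalty `c = 10` Gy/cm, and alpha/beta = 10 Gy for tumor.
#'
#' @param tcd50_gy sBED giving 50% control, Gy.
#' @param k_gy Logistic slope parameter, Gy (> 0).
#' @param c_gy_per_cm Size-adjustment constant, Gy per cm of diameter.
#' @param alpha_beta_gy Tumor alpha/beta ratio, Gy (> 0).
#' @return An object of class `tcp_params`.
#' @export
tcp_params <- function(tcd50_gy = 0, k_gy = 31, c_gy_per_cm = 10,
                       alpha_beta_gy = 10) {
  if (!is.finite(k_gy) || k_gy <= 0) stop("k must be positive")
  if (!is.finite(alpha_beta_gy) || alpha_beta_gy <= 0) {
    stop("alpha/beta must be positive")
  }
  structure(
    list(tcd50_gy = as.numeric(tcd50_gy), k_gy = as.numeric(k_gy),
         c_gy_per_cm = as.numeric(c_gy_per_cm),
         alpha_beta_gy = as.numeric(alpha_beta_gy)),
    class = "tcp_params"
  )
}

#' NTCP model parameters
#'
#' Constants of the Lyman-type logistic complication model evaluated on the
#' generalized equivalent uniform dose:
#' `ntcp = 1 / (1 + (td50 / EUD)^(4 * gamma50))`, with per-bin conversion to
#' 2-Gy-fraction equivalent dose at the organ's alpha/beta. Defaults are the
#' validated normal-lung set for grade >=2 radiation pneumonitis:
#' `td50 = 45` Gy, `gamma50 = 1.2`, volume-effect exponent `a = 1` (parallel
#' organ, EUD = mean EQD), alpha/beta = 3 Gy. The same set is reused for rib
#' by default (configurable), as no separate rib fit is published alongside.
#'
#' @param td50_gy EUD giving 50% complication probability, Gy (> 0).
#' @param gamma50 Normalized slope at the midpoint (dimensionless).
#' @param a Volume-effect exponent of the generalized mean (nonzero).
#' @param alpha_beta_gy Organ alpha/beta ratio, Gy (> 0).
#' @return An object of class `ntcp_params`.
#' @export
ntcp_params <- function(td50_gy = 45, gamma50 = 1.2, a = 1,
                        alpha_beta_gy = 3) {
  if (!is.finite(td50_gy) || td50_gy <= 0) stop("TD50 must be positive")
  if (!is.finite(alpha_beta_gy) || alpha_beta_gy <= 0) {
    stop("alpha/beta must be positive")
  }
  if (!is.finite(a) || a == 0) {
    stop("volume-effect exponent a = 0 (geometric mean) is not defined here")
  }
  structure(
    list(td50_gy = as.numeric(td50_gy), gamma50 = as.numeric(gamma50),
         a = as.numeric(a), alpha_beta_gy = as.numeric(alpha_beta_gy)),
    class = "ntcp_params"
  )
}

#' Biologically effective dose (linear-quadratic model)
#'
#' `BED = D * (1 + d / (alpha/beta))` with per-fraction dose
#' `d = D / n_fractions`: the whole dose `D` is taken as delivered over the
#' scheme's fractions. With alpha/beta = 10 Gy this is the BED10 entering
#' the TCP model.
#'
#' @param dose_gy Total dose in Gy (>= 0); vectorized.
#' @param scheme A [fractionation_scheme()] (only `n_fractions` is used).
#' @param alpha_beta_gy Alpha/beta ratio in Gy (> 0).
#' @return BED in Gy.
#' @export
#' @examples
#' bed(50, fractionation_scheme(50, 5), 10)  # 100 Gy
bed <- function(dose_gy, scheme, alpha_beta_gy = 10) {
  stopifnot(inherits(scheme, "fractionation_scheme"))
  if (!is.finite(alpha_beta_gy) || alpha_beta_gy <= 0) {
    stop("alpha/beta must be positive")
  }
  if (any(dose_gy < 0)) stop("dose must be non-negative")
  d <- dose_gy / scheme$n_fractions
  dose_gy * (1 + d / alpha_beta_gy)
}

#' Size-adjusted biologically effective dose
#'
#' `sBED = BED10 - c * L`: the BED penalized linearly by tumor diameter `L`
#' in cm, with `c` (Gy/cm) from the TCP parameter set.
#'
#' @param bed10_gy BED at alpha/beta = 10, Gy; vectorized.
#' @param diameter_cm Tumor diameter in cm (> 0); vectorized.
#' @param params A [tcp_params()].
#' @return sBED in Gy.
#' @export
sbed <- function(bed10_gy, diameter_cm, params = tcp_params()) {
  stopifnot(inherits(params, "tcp_params"))
  if (any(diameter_cm <= 0)) stop("tumor diameter must be positive")
  bed10_gy - params$c_gy_per_cm * diameter_cm
}

# overflow-safe logistic: exp(z)/(1+exp(z)) without overflow for large |z|
.logistic <- function(z) {
  p <- numeric(length(z))
  pos <- z >= 0
  p[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  p[!pos] <- ez / (1 + ez)
  p
}

#' Tumor control probability from size-adjusted BED
#'
#' Logistic dose-response for 2-year local control:
#' `TCP = exp(z) / (1 + exp(z))`, `z = (sBED - TCD50) / k`. Evaluated in an
#' overflow-safe form; strictly increasing in sBED with limits 0 and 1.
#'
#' @param sbed_gy Size-adjusted BED in Gy; vectorized.
#' @param params A [tcp_params()].
#' @return Probability in (0, 1).
#' @export
#' @examples
#' tcp(0)    # 0.5 at sBED = TCD50
#' tcp(51)   # ~0.838
tcp <- function(sbed_gy, params = tcp_params()) {
  stopifnot(inherits(params, "tcp_params"))
  if (any(!is.finite(sbed_gy))) stop("sBED must be finite")
  .logistic((sbed_gy - params$tcd50_gy) / params$k_gy)
}

#' Equivalent dose in 2-Gy fractions (per DVH bin)
#'
#' `EQD = D * (alpha/beta + d) / (alpha/beta + 2)` with per-bin per-fraction
#' dose `d = D / n_fractions` (each bin's dose is delivered over the scheme's
#' fractions). A bin at exactly 2 Gy per fraction is returned unchanged.
#'
#' @param bin_dose_gy Total bin dose in Gy (>= 0); vectorized.
#' @param scheme A [fractionation_scheme()] (only `n_fractions` is used).
#' @param alpha_beta_gy Organ alpha/beta in Gy (> 0); 3 Gy for normal lung.
#' @return EQD in Gy.
#' @export
#' @examples
#' eqd(60, fractionation_scheme(50, 5), 3)  # 180 Gy
eqd <- function(bin_dose_gy, scheme, alpha_beta_gy = 3) {
  stopifnot(inherits(scheme, "fractionation_scheme"))
  if (!is.finite(alpha_beta_gy) || alpha_beta_gy <= 0) {
    stop("alpha/beta must be positive")
  }
  if (any(bin_dose_gy < 0)) stop("dose must be non-negative")
  d <- bin_dose_gy / scheme$n_fractions
  bin_dose_gy * (alpha_beta_gy + d) / (alpha_beta_gy + 2)
}

#' Generalized equivalent uniform dose of a differential DVH
#'
#' Converts each bin dose to EQD at the organ's alpha/beta, then reduces the
#' distribution with the generalized mean `EUD = (sum v_i EQD_i^a)^(1/a)`.
#' `a = 1` (parallel organ) gives the volume-weighted mean EQD.
#'
#' @param ddvh A [differential_dvh()].
#' @param scheme A [fractionation_scheme()].
#' @param params An [ntcp_params()] supplying `a` and alpha/beta.
#' @return EUD in Gy.
#' @export
eud <- function(ddvh, scheme, params = ntcp_params()) {
  stopifnot(inherits(ddvh, "differential_dvh"),
            inherits(params, "ntcp_params"))
  eqd_i <- eqd(ddvh$bin_dose_gy, scheme, params$alpha_beta_gy)
  a <- params$a
  sum(ddvh$bin_volume_fraction * eqd_i^a)^(1 / a)
}

#' Normal tissue complication probability from EUD
#'
#' Lyman-type logistic in the equivalent uniform dose:
#' `NTCP = 1 / (1 + (TD50 / EUD)^(4 * gamma50))`; 0.5 at `EUD = TD50`,
#' strictly increasing in EUD, and 0 at zero dose (by continuity).
#'
#' @param eud_gy Equivalent uniform dose in Gy (>= 0); vectorized.
#' @param params An [ntcp_params()].
#' @return Probability in `[0, 1)`.
#' @export
#' @examples
#' ntcp(45)  # 0.5 at TD50
ntcp <- function(eud_gy, params = ntcp_params()) {
  stopifnot(inherits(params, "ntcp_params"))
  if (any(!is.finite(eud_gy)) || any(eud_gy < 0)) {
    stop("EUD must be finite and non-negative")
  }
  p <- numeric(length(eud_gy))
  pos <- eud_gy > 0
  # log-space power avoids overflow at tiny EUD; (td50/0)^g -> Inf -> p = 0
  r <- exp(4 * params$gamma50 * (log(params$td50_gy) - log(eud_gy[pos])))
  p[pos] <- 1 / (1 + r)
  p
}

#' Sphere-equivalent diameter of a target volume
#'
#' `L = 2 * (3 V / (4 pi))^(1/3)` in cm for a volume in cc: the diameter of
#' the sphere with the same volume. Used as the default tumor diameter `L`
#' of the size adjustment when no measured diameter is supplied.
#'
#' @param volume_cc Target volume in cc (> 0); vectorized.
#' @return Diameter in cm.
#' @export
#' @examples
#' diameter_from_volume(22.4)  # ~3.50 cm
diameter_from_volume <- function(volume_cc) {
  if (any(!is.finite(volume_cc)) || any(volume_cc <= 0)) {
    stop("volume must be positive")
  }
  2 * (3 * volume_cc / (4 * pi))^(1 / 3)
}
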
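#' Cumulative dose-volume histogram
#'
#' Construct and validate a cumulative DVH: the fraction of a structure's
#' volume receiving at least each dose. This is the container behind every
#' dose metric in the package (D95/D98/D99, mean, min, max dose) and, after
#' conversion to differential form, behind the EUD reduction used for NTCP.
#'
#' @param dose_gy Numeric vector of dose edges in Gy; strictly increasing,
#'   starting at 0.
#' @param volume_fraction Numeric vector of relative volumes in `[0, 1]`, one
#'   per dose edge; must start at 1 (the whole structure receives at least
#'   0 Gy), be non-increasing, and end at 0 at the maximum dose.
#' @param label Structure label (e.g. `"PTV"`, `"lung-ITV"`).
#' @return An object of class `cumulative_dvh`: a list with elements
#'   `dose_gy`, `volume_fraction`, `label`.
#' @seealso [read_dvh()], [dose_at_volume()], [extract_metrics()],
#'   [cumulative_to_differential()]
#' @export
#' @examples
#' cumulative_dvh(c(0, 48, 55), c(1, 1, 0), label = "PTV")
cumulative_dvh <- function(dose_gy, volume_fraction, label = "") {
  dose_gy <- as.numeric(dose_gy)
  volume_fraction <- as.numeric(volume_fraction)
  if (length(dose_gy) != length(volume_fraction)) {
    stop("malformed DVH: dose and volume vectors differ in length")
  }
  if (length(dose_gy) < 1 || anyNA(dose_gy) || anyNA(volume_fraction)) {
    stop("malformed DVH: missing values")
  }
  if (any(dose_gy < 0)) stop("malformed DVH: negative dose")
  if (dose_gy[1] != 0) stop("malformed DVH: dose edges must start at 0 Gy")
  if (length(dose_gy) > 1 && any(diff(dose_gy) <= 0)) {
    stop("malformed DVH: dose edges must be strictly increasing")
  }
  tol <- 1e-6
  if (any(volume_fraction < -tol) || any(volume_fraction > 1 + tol)) {
    stop("malformed DVH: volume fraction outside [0, 1]")
  }
  if (length(volume_fraction) > 1 && any(diff(volume_fraction) > tol)) {
    stop("malformed DVH: volume fraction must be non-increasing with dose")
  }
  if (abs(volume_fraction[1] - 1) > tol) {
    stop("malformed DVH: volume fraction at 0 Gy must equal 1")
  }
  n <- length(volume_fraction)
  if (abs(volume_fraction[n]) > tol) {
    stop("malformed DVH: volume fraction must reach 0 at the maximum dose")
  }
  # snap small numeric noise so downstream invariants hold exactly
  volume_fraction <- cummin(pmin(pmax(volume_fraction, 0), 1))
  volume_fraction[1] <- 1
  volume_fraction[n] <- 0
  structure(
    list(dose_gy = dose_gy, volume_fraction = volume_fraction,
         label = as.character(label)),
    class = "cumulative_dvh"
  )
}

#' @export
print.cumulative_dvh <- function(x, ...) {
  cat(sprintf("Cumulative DVH%s: %d dose edges, 0-%.1f Gy\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$dose_gy), max(x$dose_gy)))
  invisible(x)
}

#' Differential dose-volume histogram
#'
#' A binned dose distribution: the fraction of structure volume receiving a
#' dose in each bin, with bin centers in Gy. The bin volumes `v_i` and bin
#' doses `D_i` feed the generalized-EUD sum used by the NTCP model.
#'
#' @param bin_dose_gy Numeric vector of bin-center doses (Gy), strictly
#'   increasing, non-negative.
#' @param bin_volume_fraction Non-negative fractions summing to 1 (within
#'   1e-9).
#' @param label Structure label.
#' @return An object of class `differential_dvh`.
#' @export
differential_dvh <- function(bin_dose_gy, bin_volume_fraction, label = "") {
  bin_dose_gy <- as.numeric(bin_dose_gy)
  bin_volume_fraction <- as.numeric(bin_volume_fraction)
  if (length(bin_dose_gy) != length(bin_volume_fraction)) {
    stop("malformed differential DVH: vectors differ in length")
  }
  if (any(bin_dose_gy < 0)) stop("malformed differential DVH: negative dose")
  if (length(bin_dose_gy) > 1 && any(diff(bin_dose_gy) <= 0)) {
    stop("malformed differential DVH: bin doses must be strictly increasing")
  }
  if (any(bin_volume_fraction < -1e-12)) {
    stop("malformed differential DVH: negative bin volume")
  }
  s <- sum(bin_volume_fraction)
  if (abs(s - 1) > 1e-9) {
    stop("malformed differential DVH: bin volumes must sum to 1 (got ",
         format(s, digits = 12), ")")
  }
  structure(
    list(bin_dose_gy = bin_dose_gy,
         bin_volume_fraction = pmax(bin_volume_fraction, 0),
         label = as.character(label)),
    class = "differential_dvh"
  )
}

#' @export
print.differential_dvh <- function(x, ...) {
  cat(sprintf("Differential DVH%s: %d bins, mean dose %.2f Gy\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$bin_dose_gy),
              sum(x$bin_dose_gy * x$bin_volume_fraction)))
  invisible(x)
}

#' The seven PTV dose parameterizations
#'
#' Names of the PTV dose metrics from which size-adjusted BED (and thus TCP)
#' can be computed: prescription dose (RX), minimum/mean/maximum dose, and
#' the minimum dose to 95/98/99% of the PTV.
#'
#' @return Character vector `c("RX","DMIN","DMEAN","DMAX","D95","D98","D99")`.
#' @export
dose_metric_names <- function() {
  c("RX", "DMIN", "DMEAN", "DMAX", "D95", "D98", "D99")
}

#' Read a cumulative DVH from a two-column CSV file
#'
#' The expected dialect is the common treatment-planning-system export: two
#' numeric columns, dose in Gy and relative volume, an optional header row,
#' and an optional leading comment line `# <structure label>`. Volumes may be
#' percent (0-100) or fractions (0-1); percent is assumed when any volume
#' exceeds 1.5 and is normalized to fractions.
#'
#' @param path Path to the CSV file.
#' @param label Structure label; defaults to a `#` comment header if present,
#'   else the file name without extension.
#' @return A [cumulative_dvh()].
#' @export
read_dvh <- function(path, label = NULL) {
  if (!file.exists(path)) stop("DVH file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  comment_label <- NULL
  is_comment <- startsWith(trimws(lines), "#")
  if (any(is_comment)) {
    comment_label <- sub("^\\s*#\\s*", "", lines[which(is_comment)[1]])
    lines <- lines[!is_comment]
  }
  if (length(lines) == 0) stop("malformed DVH: empty file ", path)
  # drop a non-numeric header row if present
  first <- strsplit(lines[1], ",")[[1]]
  if (suppressWarnings(anyNA(as.numeric(first)))) lines <- lines[-1]
  if (length(lines) == 0) stop("malformed DVH: no data rows in ", path)
  mat <- utils::read.csv(text = paste(lines, collapse = "\n"),
                         header = FALSE, colClasses = "numeric")
  if (ncol(mat) < 2) stop("malformed DVH: expected two columns in ", path)
  dose <- mat[[1]]
  vol <- mat[[2]]
  if (any(vol > 1.5)) vol <- vol / 100  # percent dialect
  if (is.null(label)) {
    label <- if (!is.null(comment_label)) comment_label else
      tools::file_path_sans_ext(basename(path))
  }
  cumulative_dvh(dose, vol, label = label)
}

#' Write a cumulative DVH to a two-column CSV file
#'
#' Inverse of [read_dvh()]: writes a `# label` comment line, a header, and
#' dose/volume-percent rows at full precision, so that a read/write
#' round-trip reproduces the bins to better than 1e-9.
#'
#' @param dvh A [cumulative_dvh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(dvh, path) {
  stopifnot(inherits(dvh, "cumulative_dvh"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(dvh$label)) writeLines(paste0("# ", dvh$label), con)
  writeLines("dose_gy,volume_pct", con)
  writeLines(sprintf("%.12g,%.12g", dvh$dose_gy, dvh$volume_fraction * 100),
             con)
  invisible(path)
}

#' Convert a cumulative DVH to differential form
#'
#' Bin volumes are the drops of the cumulative curve between adjacent dose
#' edges and bin doses are the edge midpoints; the bin volumes of a valid
#' cumulative DVH sum to exactly 1.
#'
#' @param dvh A [cumulative_dvh()].
#' @return A [differential_dvh()].
#' @export
cumulative_to_differential <- function(dvh) {
  stopifnot(inherits(dvh, "cumulative_dvh"))
  n <- length(dvh$dose_gy)
  if (n < 2) stop("degenerate DVH: need at least two dose edges")
  d <- dvh$dose_gy
  v <- dvh$volume_fraction
  differential_dvh(
    bin_dose_gy = (d[-n] + d[-1]) / 2,
    bin_volume_fraction = v[-n] - v[-1],
    label = dvh$label
  )
}

#' Dose covering a given fraction of the structure (Dq)
#'
#' `dose_at_volume(dvh, q)` returns the classical DVH statistic D_q: the
#' largest dose such that at least a fraction `q` of the structure volume
#' receives it, obtained by linear interpolation of the cumulative curve
#' between bracketing dose edges. `q = 0.95` gives D95 ("minimum dose to 95%
#' of the volume"); `q = 1` gives the largest dose still covering the full
#' volume.
#'
#' @param dvh A [cumulative_dvh()].
#' @param q Coverage fraction(s) in `(0, 1]`; vectorized.
#' @return Dose(s) in Gy, same length as `q`.
#' @export
#' @examples
#' dvh <- cumulative_dvh(c(0, 40, 60), c(1, 1, 0))
#' dose_at_volume(dvh, 0.95)  # 41 Gy
dose_at_volume <- function(dvh, q) {
  stopifnot(inherits(dvh, "cumulative_dvh"))
  q <- as.numeric(q)
  if (any(!is.finite(q)) || any(q <= 0) || any(q > 1)) {
    stop("coverage fraction q must lie in (0, 1]")
  }
  d <- dvh$dose_gy
  v <- dvh$volume_fraction
  n <- length(d)
  vapply(q, function(qi) {
    i <- max(which(v >= qi))        # v[1] = 1 >= qi always
    if (v[i] == qi || i == n) return(d[i])
    # interpolate on the falling segment [i, i+1]: v[i] > qi > v[i+1]
    d[i] + (v[i] - qi) / (v[i] - v[i + 1]) * (d[i + 1] - d[i])
  }, numeric(1))
}

# coverage level used to define DMIN / DMAX robustly on near-flat tails
.eps_min <- 1e-4

#' Extract the seven PTV dose metrics from a cumulative DVH
#'
#' Computes the dose parameterizations of the TCP model: prescription dose
#' (RX, supplied), minimum and maximum dose (defined by interpolation at
#' coverage `1 - 1e-4` and `1e-4` to be robust to near-flat DVH tails), mean
#' dose (volume-weighted mean of the differential DVH), and D95/D98/D99.
#'
#' @param dvh A [cumulative_dvh()] of the PTV.
#' @param rx_dose_gy Prescription dose in Gy (> 0).
#' @return Named numeric vector over [dose_metric_names()], in Gy.
#' @export
extract_metrics <- function(dvh, rx_dose_gy) {
  stopifnot(inherits(dvh, "cumulative_dvh"))
  if (!is.finite(rx_dose_gy) || rx_dose_gy <= 0) {
    stop("prescription dose must be positive")
  }
  dd <- cumulative_to_differential(dvh)
  c(
    RX = as.numeric(rx_dose_gy),
    DMIN = dose_at_volume(dvh, 1 - .eps_min),
    DMEAN = sum(dd$bin_dose_gy * dd$bin_volume_fraction),
    DMAX = dose_at_volume(dvh, .eps_min),
    D95 = dose_at_volume(dvh, 0.95),
    D98 = dose_at_volume(dvh, 0.98),
    D99 = dose_at_volume(dvh, 0.99)
  )
}
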
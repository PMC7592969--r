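#' Write a cohort to a directory of plain-text files
#'
#' Emits `cohort.csv` (columns `tumor_id`, `target_volume_cc`,
#' `diameter_cm`, `total_dose_gy`, `n_fractions`, `followup_months`,
#' `recurrence_event`, `dvh_file`, plus any label columns present) and one
#' two-column DVH CSV per tumor under `dvh/`.
#'
#' @param cohort Cohort data frame with list-column `ptv_dvh`; follow-up
#'   columns are written if present.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, dir) {
  cohort <- check_cohort(cohort)
  dvh_dir <- file.path(dir, "dvh")
  dir.create(dvh_dir, recursive = TRUE, showWarnings = FALSE)
  dvh_file <- file.path("dvh", paste0(cohort$tumor_id, ".csv"))
  for (i in seq_len(nrow(cohort))) {
    write_dvh(cohort$ptv_dvh[[i]], file.path(dir, dvh_file[i]))
  }
  flat <- cohort[setdiff(names(cohort), "ptv_dvh")]
  flat$dvh_file <- dvh_file
  utils::write.csv(flat, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from a cohort.csv plus DVH files
#'
#' Inverse of [write_cohort()]. `diameter_cm` is optional in the CSV; when
#' absent it is filled with the sphere-equivalent diameter of
#' `target_volume_cc`.
#'
#' @param path Path to the cohort CSV file.
#' @param dvh_dir Directory against which `dvh_file` entries are resolved;
#'   defaults to the CSV's directory.
#' @return An `sbrt_cohort` data frame.
#' @export
read_cohort <- function(path, dvh_dir = dirname(path)) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tumor_id", "target_volume_cc", "total_dose_gy", "n_fractions",
            "dvh_file")
  missing <- setdiff(need, names(flat))
  if (length(missing)) {
    stop("cohort CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(flat$diameter_cm)) {
    flat$diameter_cm <- diameter_from_volume(flat$target_volume_cc)
  }
  flat$ptv_dvh <- lapply(file.path(dvh_dir, flat$dvh_file), read_dvh)
  flat$dvh_file <- NULL
  class(flat) <- c("sbrt_cohort", "data.frame")
  check_cohort(flat)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML file holding the model constants and analysis settings and
#' returns them as package objects. Recognized top-level keys: `tcp`
#' (fields of [tcp_params()]), `ntcp` (fields of [ntcp_params()]), `n_bins`,
#' `horizon_months`, `seed`; all optional, defaults applied.
#'
#' @param path Path to a YAML file.
#' @return List with elements `tcp_params`, `ntcp_params`, `n_bins`,
#'   `horizon_months`, `seed`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  cfg <- yaml::read_yaml(path)
  list(
    tcp_params = do.call(tcp_params, as.list(cfg$tcp)),
    ntcp_params = do.call(ntcp_params, as.list(cfg$ntcp)),
    n_bins = if (is.null(cfg$n_bins)) 4L else as.integer(cfg$n_bins),
    horizon_months = if (is.null(cfg$horizon_months)) 24 else
      as.numeric(cfg$horizon_months),
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  )
}
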
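# File formats: trial CSV + JSON sidecar, filter coefficient export,
# calibration persistence, and validated run configuration.

#' Write a time-series trial as CSV with a JSON sidecar
#'
#' The CSV holds one row per sample (`time_s` plus channel columns); the
#' sidecar (`<path>.json`) records sampling rate, units, condition, seed and
#' any spec fields; numbers print with full precision so a trial round-trips
#' to within text-serialization accuracy (~1 ulp).
#'
#' @param data Data frame with `time_s` and channel columns.
#' @param path Output CSV path.
#' @param sample_rate Sampling rate, Hz.
#' @param units Named list of units per channel.
#' @param condition Optional condition label.
#' @param seed Optional seed.
#' @param extra Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path, sample_rate, units = list(),
                            condition = NULL, seed = NULL, extra = list()) {
  stopifnot(is.data.frame(data), "time_s" %in% names(data))
  utils::write.csv(data, path, row.names = FALSE)
  side <- c(list(sample_rate = sample_rate, units = units,
                 columns = names(data)),
            if (!is.null(condition)) list(condition = condition),
            if (!is.null(seed)) list(seed = seed),
            extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trial written by [write_trial_csv()]
#'
#' @param path CSV path.
#' @return Tibble with the sidecar attached as attribute `sidecar`.
#' @export
read_trial_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  sc <- paste0(path, ".json")
  if (file.exists(sc)) attr(out, "sidecar") <- jsonlite::read_json(sc)
  out
}

#' Export FIR filter coefficients as JSON
#'
#' Full-precision export for faithful replay of a designed filter.
#'
#' @param filt A `bg_fir`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_filter_json <- function(filt, path) {
  stopifnot(inherits(filt, "bg_fir"))
  jsonlite::write_json(
    list(coef = filt$coef, sample_rate = filt$sample_rate, order = filt$order),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read FIR filter coefficients from JSON
#'
#' @param path JSON path written by [write_filter_json()].
#' @return A `bg_fir` (response checks are not re-run on load).
#' @export
read_filter_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coef = as.numeric(j$coef), sample_rate = j$sample_rate,
                 order = j$order),
            class = "bg_fir")
}

#' Persist / restore a decoder calibration as JSON
#'
#' @param calib A `bg_decoder_calibration`.
#' @param path JSON path.
#' @return `path` (write) or the calibration (read).
#' @export
write_calibration_json <- function(calib, path) {
  stopifnot(inherits(calib, "bg_decoder_calibration"))
  jsonlite::write_json(unclass(calib), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$plateau_df <- unlist(j$plateau_df)
  j$plateau_pf <- unlist(j$plateau_pf)
  structure(j, class = "bg_decoder_calibration")
}

# recognised run-configuration keys
run_config_keys_ <- function() {
  c("seed", "out_dir", "n_per_group", "afferent_range", "slope_spec",
    "noise", "conditions", "n_cycles", "body_mass", "spindle", "controller",
    "comparison_families")
}

#' Read and validate a run configuration
#'
#' Accepts JSON or YAML. Unknown top-level keys are rejected (naming the
#' offending key), `seed` must be an integer and `conditions` must come from
#' the closed condition set.
#'
#' @param path Configuration file (`.json`, `.yaml` or `.yml`).
#' @return Named list of validated configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(cfg), run_config_keys_())
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$seed) && cfg$seed != as.integer(cfg$seed)) {
    stop("`seed` must be an integer", call. = FALSE)
  }
  if (!is.null(cfg$conditions)) {
    bad <- setdiff(cfg$conditions, gait_conditions())
    if (length(bad)) {
      stop("unknown condition(s) in config: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg
}
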
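#' Write a recording to CSV
#'
#' Columns `t_s, v_mV, stim520_ph_um2_s, stim365_ph_um2_s`, preceded by
#' `#`-prefixed metadata lines (seed, cell type, recording mode, sampling
#' rate, noise SD, start time). An events sidecar CSV
#' (`t_s, wavelength_nm, strength_ph_um2, label`) is written when
#' `events_path` is given.
#'
#' @param rec A `pr_recording`.
#' @param path Output CSV path.
#' @param events_path Optional sidecar path for the flash annotations.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, events_path = NULL) {
  stopifnot(inherits(rec, "pr_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# seed=%d", rec$seed),
    sprintf("# cell_type=%s", rec$spec$cell_type),
    sprintf("# mode=%s", rec$spec$mode),
    sprintf("# fs_hz=%.10g", rec$fs_hz),
    sprintf("# noise_sd_mV=%.10g", rec$noise_sd_mV),
    sprintf("# t_start_min=%.10g", rec$t_start_min),
    sprintf("# temperature_C=%.10g", rec$spec$temperature_C)
  ), con)
  df <- data.frame(t_s = rec$t_s, v_mV = rec$v_mV,
                   stim520_ph_um2_s = rec$stim520_ph_um2_s,
                   stim365_ph_um2_s = rec$stim365_ph_um2_s)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = NA),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(events_path)) {
    ev <- rec$events[, c("t_abs_s", "wavelength_nm", "strength_ph_um2",
                         "duration_ms", "label")]
    names(ev)[1] <- "t_s"
    utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a recording from CSV
#'
#' Validates the documented schema: required columns present, time base
#' strictly increasing and uniform, equal channel lengths. Metadata from
#' `#` header lines is restored into the returned object.
#'
#' @param path Recording CSV path.
#' @param events_path Optional events sidecar path.
#' @return A `pr_recording` (with a minimal `cell_spec` rebuilt from the
#'   metadata; kinetics parameters are defaults, not serialized).
#' @export
read_recording <- function(path, events_path = NULL) {
  header <- character()
  con <- file(path, "r")
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  close(con)
  meta <- list()
  for (h in header) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.csv(path, comment.char = "#")
  required <- c("t_s", "v_mV", "stim520_ph_um2_s", "stim365_ph_um2_s")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("recording file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) < 2 || is.unsorted(df$t_s, strictly = TRUE)) {
    stop("column t_s must be strictly increasing")
  }
  fs <- if (!is.null(meta$fs_hz)) as.numeric(meta$fs_hz)
        else 1 / stats::median(diff(df$t_s))
  events <- if (!is.null(events_path)) {
    ev <- utils::read.csv(events_path)
    names(ev)[names(ev) == "t_s"] <- "t_abs_s"
    ev
  } else {
    data.frame(t_abs_s = numeric(0), wavelength_nm = numeric(0),
               strength_ph_um2 = numeric(0), duration_ms = numeric(0),
               label = character(0))
  }
  ct <- if (!is.null(meta$cell_type)) meta$cell_type else "rod"
  md <- if (!is.null(meta$mode)) meta$mode else "loose_seal"
  spec <- cell_spec(ct, md,
                    temperature_C = if (!is.null(meta$temperature_C))
                      as.numeric(meta$temperature_C) else 24)
  structure(
    list(t_s = df$t_s, v_mV = df$v_mV,
         stim520_ph_um2_s = df$stim520_ph_um2_s,
         stim365_ph_um2_s = df$stim365_ph_um2_s,
         events = events, spec = spec, fs_hz = fs,
         seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NA_integer_,
         noise_sd_mV = if (!is.null(meta$noise_sd_mV))
           as.numeric(meta$noise_sd_mV) else NA_real_,
         t_start_min = if (!is.null(meta$t_start_min))
           as.numeric(meta$t_start_min) else 0),
    class = "pr_recording"
  )
}

#' Write measurement results
#'
#' Flat CSV with one row per measured flash, plus an optional JSON summary.
#'
#' @param measurements A data frame from [analyze_recording()].
#' @param path Output CSV path.
#' @param summary_path Optional JSON path; `summary` (a named list of
#'   scalars/vectors) is serialized there.
#' @param summary Optional named list written to `summary_path`.
#' @return `path`, invisibly.
#' @export
write_results <- function(measurements, path, summary_path = NULL,
                          summary = NULL) {
  utils::write.csv(measurements, path, row.names = FALSE)
  if (!is.null(summary_path) && !is.null(summary)) {
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
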
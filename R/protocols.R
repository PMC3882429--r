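#' Construct a flash stimulus event
#'
#' @param wavelength_nm 520 (green) or 365 (ultraviolet).
#' @param strength_ph_um2 Flash strength (photons·µm^-2), >= 0.
#' @param t_on_s Onset time within the sweep (s).
#' @param duration_ms Flash duration (ms), in [1, 10]. Default 5. Flashes
#'   are treated as instantaneous for waveform timing; the duration is
#'   bookkeeping for the flux-times-duration strength budget.
#' @param label Role label, e.g. `"dim"`, `"bright_a"`, `"bright_b"`,
#'   `"pre"`.
#' @return A one-row data frame.
#' @export
flash <- function(wavelength_nm, strength_ph_um2, t_on_s, duration_ms = 5,
                  label = "dim") {
  if (!wavelength_nm %in% c(520, 365)) {
    stop("wavelength_nm must be 520 or 365")
  }
  if (strength_ph_um2 < 0) stop("strength_ph_um2 must be >= 0")
  if (duration_ms < 1 || duration_ms > 10) {
    stop("duration_ms must lie in [1, 10]")
  }
  data.frame(wavelength_nm = wavelength_nm,
             strength_ph_um2 = strength_ph_um2,
             t_on_s = t_on_s, duration_ms = duration_ms,
             label = label, stringsAsFactors = FALSE)
}

bright_labels <- c("bright_a", "bright_b")

#' Construct a stimulus protocol
#'
#' @param sweeps A list of sweeps; each sweep is a list with `flashes` (a
#'   data frame of [flash()] rows, time-ordered) and optionally
#'   `backgrounds` (data frame with `wavelength_nm`, `flux_ph_um2_s`,
#'   `t_on_s`, `t_off_s`).
#' @param inter_sweep_s Interval between consecutive sweep starts (s).
#' @param name Protocol name (metadata).
#' @param min_bright_interval_s Minimal allowed spacing between consecutive
#'   bright flashes (s); default 12. Pre-flash/test pairs (later flash
#'   preceded by a `"pre"`-labelled flash) are exempt, as the pre-flash
#'   protocol explicitly prescribes a shorter gap.
#' @return A validated object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(sweeps, inter_sweep_s = 15,
                              name = "protocol",
                              min_bright_interval_s = 12) {
  p <- structure(
    list(sweeps = sweeps, inter_sweep_s = inter_sweep_s, name = name,
         min_bright_interval_s = min_bright_interval_s),
    class = "stimulus_protocol"
  )
  validate_protocol(p)
  p
}

#' Validate a stimulus protocol
#'
#' Checks that events within each sweep are time-ordered and that
#' consecutive bright flashes (labels `bright_a`/`bright_b` and `pre`) are
#' separated by at least `min_bright_interval_s` on the absolute timeline,
#' except across a pre-flash/test pair.
#'
#' @param protocol A `stimulus_protocol`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  ev <- protocol_events(protocol)
  for (sw in protocol$sweeps) {
    if (is.unsorted(sw$flashes$t_on_s)) stop("sweep events must be time-ordered")
  }
  br <- ev[ev$label %in% c(bright_labels, "pre"), , drop = FALSE]
  if (nrow(br) >= 2) {
    for (i in 2:nrow(br)) {
      gap <- br$t_abs_s[i] - br$t_abs_s[i - 1]
      pre_pair <- br$label[i - 1] == "pre"
      if (!pre_pair && gap < protocol$min_bright_interval_s) {
        stop(sprintf(
          "bright flashes %d and %d are %.2f s apart (< %g s minimum)",
          i - 1, i, gap, protocol$min_bright_interval_s))
      }
    }
  }
  invisible(TRUE)
}

#' Flatten a protocol to an absolute-time event table
#'
#' @param protocol A `stimulus_protocol`.
#' @return A data frame of all flashes with columns of [flash()] plus
#'   `sweep` and `t_abs_s` (absolute onset time, using [sweep_start_times()]
#'   offsets).
#' @export
protocol_events <- function(protocol) {
  starts <- sweep_start_times(protocol)
  out <- do.call(rbind, lapply(seq_along(protocol$sweeps), function(k) {
    fl <- protocol$sweeps[[k]]$flashes
    fl$sweep <- k
    fl$t_abs_s <- fl$t_on_s + starts[k]
    fl
  }))
  rownames(out) <- NULL
  out
}

#' @rdname protocol_events
#' @return For `sweep_start_times`: absolute start time (s) of each sweep.
#'   Sweep k+1 starts `inter_sweep_s` after the last event of sweep k.
#' @export
sweep_start_times <- function(protocol) {
  n <- length(protocol$sweeps)
  starts <- numeric(n)
  for (k in seq_len(n)[-1]) {
    prev <- protocol$sweeps[[k - 1]]
    t_last <- max(prev$flashes$t_on_s,
                  if (!is.null(prev$backgrounds)) prev$backgrounds$t_off_s else -Inf)
    starts[k] <- starts[k - 1] + t_last + protocol$inter_sweep_s
  }
  starts
}

#' Background epochs of a protocol on the absolute timeline
#'
#' @param protocol A `stimulus_protocol`.
#' @return A data frame (possibly empty) with `wavelength_nm`,
#'   `flux_ph_um2_s`, `t_on_s`, `t_off_s` in absolute time.
#' @export
protocol_backgrounds <- function(protocol) {
  starts <- sweep_start_times(protocol)
  rows <- lapply(seq_along(protocol$sweeps), function(k) {
    bg <- protocol$sweeps[[k]]$backgrounds
    if (is.null(bg) || nrow(bg) == 0) return(NULL)
    bg$t_on_s <- bg$t_on_s + starts[k]
    bg$t_off_s <- bg$t_off_s + starts[k]
    bg
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(wavelength_nm = numeric(0), flux_ph_um2_s = numeric(0),
                      t_on_s = numeric(0), t_off_s = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Build the kinetics protocol
#'
#' Three sweeps of green (520 nm) flashes. Each sweep delivers a dim test
#' flash, a rod-saturating bright flash (`bright_a`), and a second dim test
#' flash at an increasing delay after the bright flash (1, 2.5, 4 s across
#' sweeps).
#'
#' @param dim_ph_um2 Dim strength (photons·µm^-2). Default 16.6.
#' @param bright_ph_um2 Bright (`bright_a`) strength. Default 1570.
#' @param delays_s Delays of the post-bright dim flash (s).
#' @param t_dim1_s,t_bright_s Onset times of the first dim and the bright
#'   flash within each sweep (s).
#' @param inter_sweep_s Interval between sweeps (s). Default 15; must keep
#'   bright flashes >= 12 s apart.
#' @return A `stimulus_protocol`.
#' @export
build_kinetics_protocol <- function(dim_ph_um2 = 16.6, bright_ph_um2 = 1570,
                                    delays_s = c(1, 2.5, 4),
                                    t_dim1_s = 1, t_bright_s = 3,
                                    inter_sweep_s = 15) {
  sweeps <- lapply(delays_s, function(d) {
    list(flashes = rbind(
      flash(520, dim_ph_um2, t_dim1_s, label = "dim"),
      flash(520, bright_ph_um2, t_bright_s, label = "bright_a"),
      flash(520, dim_ph_um2, t_bright_s + d, label = "dim")
    ))
  })
  stimulus_protocol(sweeps, inter_sweep_s = inter_sweep_s,
                    name = "kinetics")
}

#' Build the spectral protocol
#'
#' Four sequences probing green-versus-ultraviolet preference: (1) dim G
#' and dim UV, (2) bright `bright_b` G and UV, (3) a green rod-saturating
#' pre-flash followed by bright_b G, (4) the same pre-flash followed by
#' bright_b UV. Dim G and dim UV strengths are equal in photons·µm^-2; the
#' pre-flash is always green.
#'
#' @param dim_ph_um2 Dim strength. Default 16.6.
#' @param bright_ph_um2 `bright_b` strength. Default 3140.
#' @param pre_ph_um2 Pre-flash strength. Default 1570 (green,
#'   rod-saturating for > 1 s).
#' @param pre_gap_s Pre-flash to test-flash delay (s). Default 0.5 (inside
#'   the rod saturation window).
#' @param pair_gap_s Spacing of the two flashes within the dim sweep (s).
#' @param inter_sweep_s Interval between sweeps (s).
#' @return A `stimulus_protocol`.
#' @export
build_spectral_protocol <- function(dim_ph_um2 = 16.6, bright_ph_um2 = 3140,
                                    pre_ph_um2 = 1570, pre_gap_s = 0.5,
                                    pair_gap_s = 4, inter_sweep_s = 15) {
  sweeps <- list(
    list(flashes = rbind(
      flash(520, dim_ph_um2, 1, label = "dim"),
      flash(365, dim_ph_um2, 1 + pair_gap_s, label = "dim")
    )),
    list(flashes = rbind(
      flash(520, bright_ph_um2, 1, label = "bright_b"),
      flash(365, bright_ph_um2, 1 + max(pair_gap_s, 12), label = "bright_b")
    )),
    list(flashes = rbind(
      flash(520, pre_ph_um2, 1, label = "pre"),
      flash(520, bright_ph_um2, 1 + pre_gap_s, label = "bright_b")
    )),
    list(flashes = rbind(
      flash(520, pre_ph_um2, 1, label = "pre"),
      flash(365, bright_ph_um2, 1 + pre_gap_s, label = "bright_b")
    ))
  )
  stimulus_protocol(sweeps, inter_sweep_s = inter_sweep_s, name = "spectral")
}

#' Build the background protocol
#'
#' Control kinetics-style deliveries, a 5-minute rod-saturating continuous
#' background (6100 photons·µm^-2·s^-1 at 520 nm; only bright flashes are
#' delivered during the background, no dim flashes), then post-offset dim
#' and bright deliveries tracking recovery.
#'
#' @param dim_ph_um2,bright_ph_um2 Flash strengths. Defaults 16.6 / 1570.
#' @param bg_flux_ph_um2_s Background photon flux density. Default 6100.
#' @param bg_duration_s Background duration (s). Default 300.
#' @param n_control Number of pre-background control deliveries.
#' @param control_period_s Spacing of control and recovery deliveries (s).
#'   Default 30.
#' @param recovery_duration_s Length of the post-offset tracking window (s).
#'   Default 300.
#' @return A single-sweep `stimulus_protocol` on an absolute timeline.
#' @export
build_background_protocol <- function(dim_ph_um2 = 16.6,
                                      bright_ph_um2 = 1570,
                                      bg_flux_ph_um2_s = 6100,
                                      bg_duration_s = 300,
                                      n_control = 2,
                                      control_period_s = 30,
                                      recovery_duration_s = 300) {
  t <- 1
  rows <- list()
  for (i in seq_len(n_control)) {
    rows[[length(rows) + 1]] <- flash(520, dim_ph_um2, t, label = "dim")
    rows[[length(rows) + 1]] <- flash(520, bright_ph_um2, t + 3, label = "bright_a")
    t <- t + control_period_s
  }
  bg_on <- t
  bg_off <- bg_on + bg_duration_s
  # bright flashes only while the background is on
  tb <- bg_on + 60
  while (tb < bg_off - 10) {
    rows[[length(rows) + 1]] <- flash(520, bright_ph_um2, tb, label = "bright_a")
    tb <- tb + 60
  }
  # post-offset recovery tracking: dim flash every control_period_s
  tr <- bg_off + control_period_s
  while (tr <= bg_off + recovery_duration_s) {
    rows[[length(rows) + 1]] <- flash(520, dim_ph_um2, tr, label = "dim")
    tr <- tr + control_period_s
  }
  flashes <- do.call(rbind, rows)
  flashes <- flashes[order(flashes$t_on_s), , drop = FALSE]
  bg <- data.frame(wavelength_nm = 520, flux_ph_um2_s = bg_flux_ph_um2_s,
                   t_on_s = bg_on, t_off_s = bg_off)
  stimulus_protocol(list(list(flashes = flashes, backgrounds = bg)),
                    inter_sweep_s = 15, name = "background")
}

#' Photon flux density from power density
#'
#' `flux = P * lambda / (h * c)` with h = 6.62607015e-34 J·s and
#' c = 2.99792458e8 m·s^-1.
#'
#' @param power_W_um2 Power density (W·µm^-2), > 0.
#' @param wavelength_nm Wavelength (nm), > 0.
#' @return Photon flux density (photons·µm^-2·s^-1).
#' @export
#' @examples
#' photon_flux_from_power(1e-12, 520)  # ~2.617e6
photon_flux_from_power <- function(power_W_um2, wavelength_nm) {
  if (any(power_W_um2 <= 0) || any(wavelength_nm <= 0)) {
    stop("power and wavelength must be positive")
  }
  h <- 6.62607015e-34
  c0 <- 2.99792458e8
  power_W_um2 * (wavelength_nm * 1e-9) / (h * c0)
}

#' Serialize / restore a protocol as JSON
#'
#' The round trip `read_protocol_json(write_protocol_json(p, f))` restores
#' an identical event list.
#'
#' @param protocol A `stimulus_protocol`.
#' @param path File path.
#' @return `path` invisibly (writer); a `stimulus_protocol` (reader).
#' @export
write_protocol_json <- function(protocol, path) {
  payload <- list(
    name = protocol$name,
    inter_sweep_s = protocol$inter_sweep_s,
    min_bright_interval_s = protocol$min_bright_interval_s,
    sweeps = lapply(protocol$sweeps, function(sw) {
      out <- list(flashes = sw$flashes)
      if (!is.null(sw$backgrounds)) out$backgrounds <- sw$backgrounds
      out
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = TRUE)
  sweeps <- lapply(seq_len(nrow_or_len(payload$sweeps)), function(k) {
    sw <- extract_sweep(payload$sweeps, k)
    sw
  })
  stimulus_protocol(sweeps,
                    inter_sweep_s = payload$inter_sweep_s,
                    name = payload$name,
                    min_bright_interval_s = payload$min_bright_interval_s)
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

extract_sweep <- function(sweeps, k) {
  sw <- if (is.data.frame(sweeps)) lapply(sweeps, `[[`, k) else sweeps[[k]]
  fl <- as.data.frame(sw$flashes)
  fl <- fl[, c("wavelength_nm", "strength_ph_um2", "t_on_s",
               "duration_ms", "label")]
  out <- list(flashes = fl)
  bg <- sw$backgrounds
  if (!is.null(bg) && nrow_or_len(bg) > 0) {
    out$backgrounds <- as.data.frame(bg)
  }
  out
}
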
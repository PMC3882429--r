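#' Coupling trajectory parameters
#'
#' Describes the spontaneous, minutes-scale growth of the summed rod-cone
#' junctional conductance during a cone recording as a monotone logistic
#' curve from `g0 * g_max_pS` toward `g_max_pS`.
#'
#' @param g0 Initial relative coupling, fraction of `g_max_pS` in [0, 1].
#' @param g_max_pS Plateau summed junctional conductance (pS).
#' @param rate_per_min Logistic growth rate (min^-1); 0 gives a constant
#'   trajectory.
#' @param lag_min Onset lag: logistic midpoint time (min).
#' @return A list of class `coupling_trajectory`.
#' @export
trajectory_params <- function(g0 = 0.1, g_max_pS = 3872, rate_per_min = 0.5,
                              lag_min = 5) {
  stopifnot(g0 >= 0, g0 <= 1, g_max_pS >= 0, rate_per_min >= 0)
  structure(list(g0 = g0, g_max_pS = g_max_pS, rate_per_min = rate_per_min,
                 lag_min = lag_min),
            class = "coupling_trajectory")
}

#' Junctional conductance at a recording time
#'
#' Monotone non-decreasing logistic trajectory with `g(0) = g0 * g_max` and
#' asymptote `g_max`.
#'
#' @param t_min Time(s) since seal formation (min), >= 0.
#' @param traj A [trajectory_params()] object.
#' @return Summed junctional conductance(s) in pS.
#' @export
coupling_trajectory <- function(t_min, traj) {
  stopifnot(inherits(traj, "coupling_trajectory"), all(t_min >= 0))
  if (traj$rate_per_min == 0) {
    return(rep(traj$g0 * traj$g_max_pS, length(t_min)))
  }
  sig <- function(t) 1 / (1 + exp(-traj$rate_per_min * (t - traj$lag_min)))
  s0 <- sig(0)
  l <- (sig(t_min) - s0) / (1 - s0)
  traj$g_max_pS * (traj$g0 + (1 - traj$g0) * l)
}

#' Specification of a synthetic cell
#'
#' @param cell_type `"rod"` or `"cone"`.
#' @param mode Recording mode: `"perforated_patch"`, `"loose_seal"` or
#'   `"whole_cell"`. Loose seal is valid only for rods.
#' @param rod_kinetics A [rod_kinetics_params()] object (rod cells, and the
#'   rod pool feeding a cone).
#' @param cone_kinetics A [cone_kinetics_params()] object (cones only).
#' @param circuit A [circuit_params()] object (cones only; defines the
#'   quasi-static divider).
#' @param trajectory A [trajectory_params()] object (cones only).
#' @param rundown Rundown mode: `"none"`, `"rod_patch_kinetics"` or
#'   `"cone_wholecell_amplitude"`.
#' @param temperature_C Temperature preset label (24 or 36); metadata, the
#'   kinetics parameters carry the actual values.
#' @param blocker `NULL`, or a [blocker_config()] describing gap-junction
#'   blocker superfusion.
#' @return A list of class `cell_spec`.
#' @export
cell_spec <- function(cell_type = c("rod", "cone"),
                      mode = c("perforated_patch", "loose_seal", "whole_cell"),
                      rod_kinetics = rod_kinetics_params(),
                      cone_kinetics = NULL,
                      circuit = NULL,
                      trajectory = NULL,
                      rundown = "none",
                      temperature_C = 24,
                      blocker = NULL) {
  cell_type <- match.arg(cell_type)
  mode <- match.arg(mode)
  if (cell_type == "cone" && mode == "loose_seal") {
    stop("loose-seal recordings can be obtained only from rods")
  }
  if (cell_type == "cone") {
    if (is.null(cone_kinetics)) cone_kinetics <- cone_kinetics_params()
    if (is.null(circuit)) circuit <- circuit_params()
    if (is.null(trajectory)) trajectory <- trajectory_params()
  } else {
    if (!is.null(trajectory)) {
      stop("coupling trajectory parameters apply to cones only")
    }
  }
  if (!rundown %in% c("none", "rod_patch_kinetics", "cone_wholecell_amplitude")) {
    stop("unknown rundown mode '", rundown, "'")
  }
  structure(
    list(cell_type = cell_type, mode = mode, rod_kinetics = rod_kinetics,
         cone_kinetics = cone_kinetics, circuit = circuit,
         trajectory = trajectory, rundown = rundown,
         temperature_C = temperature_C, blocker = blocker),
    class = "cell_spec"
  )
}

#' Gap-junction blocker configuration
#'
#' Minutes-scale exponential decay of the junctional conductance after the
#' start of blocker superfusion; intrinsic cone responses and rod
#' recordings are unaffected.
#'
#' @param t_start_min Superfusion start time (min).
#' @param tau_min Pharmacodynamic time constant (min). Default 8.
#' @return A list of class `blocker_config`.
#' @export
blocker_config <- function(t_start_min, tau_min = 8) {
  stopifnot(t_start_min >= 0, tau_min > 0)
  structure(list(t_start_min = t_start_min, tau_min = tau_min),
            class = "blocker_config")
}

#' Apply a gap-junction blocker to a cell specification
#'
#' Returns a copy of `spec` whose effective coupling trajectory decays
#' exponentially toward 0 after `t_start_min`. Rod specifications are
#' returned unchanged (the blocker has essentially no effect on rods).
#'
#' @param spec A [cell_spec()].
#' @param t_start_min Superfusion start (min).
#' @param config Optional [blocker_config()]; built from `t_start_min` if
#'   omitted.
#' @return The modified `cell_spec`.
#' @export
apply_blocker <- function(spec, t_start_min,
                          config = blocker_config(t_start_min)) {
  stopifnot(inherits(spec, "cell_spec"))
  if (spec$cell_type == "rod") return(spec)
  spec$blocker <- config
  spec
}

#' Effective junctional conductance including blocker action
#'
#' @param spec A [cell_spec()] (cone).
#' @param t_min Time(s) since seal formation (min).
#' @return Conductance(s) in pS; 0 for rods.
#' @export
effective_coupling <- function(spec, t_min) {
  if (spec$cell_type == "rod") return(rep(0, length(t_min)))
  g <- coupling_trajectory(t_min, spec$trajectory)
  if (!is.null(spec$blocker)) {
    b <- spec$blocker
    g <- g * exp(-pmax(0, t_min - b$t_start_min) / b$tau_min)
  }
  g
}

#' Set the rundown mode of a cell specification
#'
#' `"rod_patch_kinetics"` (rods in patch modes) inflates the dim-flash
#' time-to-peak from the loose-seal value toward the patched-rod mean over
#' tens of minutes; `"cone_wholecell_amplitude"` decays the intrinsic cone
#' amplitude exponentially; `"none"` (and loose seal generally) is the
#' identity.
#'
#' @param spec A [cell_spec()].
#' @param mode Rundown mode.
#' @return The modified `cell_spec`.
#' @export
apply_rundown <- function(spec, mode) {
  stopifnot(inherits(spec, "cell_spec"))
  if (mode == "rod_patch_kinetics" &&
      (spec$cell_type != "rod" || spec$mode == "loose_seal")) {
    stop("rod_patch_kinetics rundown applies to patched rods only")
  }
  if (mode == "cone_wholecell_amplitude" && spec$cell_type != "cone") {
    stop("cone_wholecell_amplitude rundown applies to cones only")
  }
  spec$rundown <- mode
  spec
}

# rundown targets (calibration; the patched-rod mean is the printed 288 ms)
.rundown_ttp_target_ms <- 288
.rundown_ttp_tau_min <- 15
.rundown_cone_amp_tau_min <- 20

rundown_ttp_ms <- function(spec, t_min) {
  base <- spec$rod_kinetics$ttp_dim_ms
  if (spec$rundown != "rod_patch_kinetics") return(rep(base, length(t_min)))
  base + (.rundown_ttp_target_ms - base) *
    (1 - exp(-t_min / .rundown_ttp_tau_min))
}

rundown_cone_rmax_mV <- function(spec, t_min) {
  base <- spec$cone_kinetics$r_max_mV
  if (spec$rundown != "cone_wholecell_amplitude") {
    return(rep(base, length(t_min)))
  }
  base * exp(-t_min / .rundown_cone_amp_tau_min)
}

# evaluate code with a local, restored RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# summed flash components of the rod pathway over a trace
# gain_fun(t_abs_s) multiplies each flash component (1 for rod recordings,
# the quasi-static divider attenuation for the rod-driven cone component);
# ttp_fun(t_abs_s) supplies the (possibly running-down) dim-flash TTP.
rod_pathway_trace <- function(t_s, events, backgrounds, params,
                              gain_fun = function(t) 1,
                              ttp_fun = function(t) params$ttp_dim_ms,
                              guv_ratio = params$guv_dim_ratio) {
  v <- numeric(length(t_s))
  bg_factor_at <- function(tt) {
    f <- 1
    if (nrow(backgrounds) > 0) {
      for (b in seq_len(nrow(backgrounds))) {
        f <- f * background_responsiveness(tt, as.list(backgrounds[b, ]), params)
      }
    }
    f
  }
  last_sat_t <- -Inf
  last_sat_ieff <- NA_real_
  ord <- order(events$t_abs_s)
  for (i in ord) {
    ev <- events[i, ]
    tf <- ev$t_abs_s
    i_eff <- if (ev$wavelength_nm == 365) {
      ev$strength_ph_um2 / params$uv_shift
    } else ev$strength_ph_um2
    resp <- bg_factor_at(tf)
    if (is.finite(last_sat_t)) {
      resp <- resp * fractional_recovery(tf - last_sat_t, params,
                                         i_bright = last_sat_ieff)
    }
    amp_full <- amplitude_vs_intensity(ev$strength_ph_um2, params,
                                       ev$wavelength_nm)
    saturating <- amp_full >= 0.95 * params$r_max_mV
    rel <- t_s - tf
    if (saturating) {
      comp <- saturating_flash_response(rel, ev$strength_ph_um2, params,
                                        ev$wavelength_nm) * resp
      if (resp > 0.5) {
        last_sat_t <- tf
        last_sat_ieff <- i_eff
      }
    } else {
      amp <- if (ev$wavelength_nm == 365) {
        amplitude_vs_intensity(ev$strength_ph_um2, params, 520) / guv_ratio
      } else amp_full
      comp <- dim_flash_waveform(rel, ttp_fun(tf), amp * resp,
                                 params$waveform_n)
    }
    v <- v + comp * gain_fun(tf)
  }
  v
}

#' Generate a synthetic photovoltage recording
#'
#' Composes the photoresponse templates, the stimulus protocol and (for
#' cones) the quasi-static coupled-circuit divider into a sampled voltage
#' trace with aligned per-LED stimulus channels. Cone traces are the sum of
#' an intrinsic component (fast kinetics, spectral-model amplitudes) and a
#' rod-pool component attenuated through the divider at the instantaneous
#' junctional conductance, with coupled dim-flash kinetics at the coupled
#' time-to-peak. Baseline noise is additive white Gaussian. Deterministic
#' given `seed`.
#'
#' @param spec A [cell_spec()].
#' @param protocol A `stimulus_protocol`.
#' @param noise_sd_mV Raw baseline noise SD (mV). The default 1.5 leaves a
#'   20 ms box-car-filtered baseline SD of about 0.15 mV at 5 kHz. Use 0
#'   for noise-free traces.
#' @param seed Integer seed.
#' @param fs_hz Sampling rate (Hz). Default 5000.
#' @param t_start_min Recording time at protocol onset (min since seal
#'   formation); positions the coupling trajectory and rundown.
#' @param tail_s Trace tail after the last event (s).
#' @return An object of class `pr_recording`: list with `t_s`, `v_mV`,
#'   `stim520_ph_um2_s`, `stim365_ph_um2_s`, `events`, `spec`, `fs_hz`,
#'   `seed`, `noise_sd_mV`, `t_start_min`.
#' @export
generate_recording <- function(spec, protocol, noise_sd_mV = 1.5, seed = 1,
                               fs_hz = 5000, t_start_min = 0, tail_s = 2) {
  stopifnot(inherits(spec, "cell_spec"),
            inherits(protocol, "stimulus_protocol"),
            noise_sd_mV >= 0, fs_hz > 0)
  events <- protocol_events(protocol)
  backgrounds <- protocol_backgrounds(protocol)
  t_end <- max(events$t_abs_s,
               if (nrow(backgrounds)) backgrounds$t_off_s else 0) + tail_s
  t_s <- seq(0, t_end, by = 1 / fs_hz)
  rp <- spec$rod_kinetics
  t_min_at <- function(tt) t_start_min + tt / 60

  if (spec$cell_type == "rod") {
    v_dark <- dark_rod_potential(spec)
    v <- v_dark + rod_pathway_trace(
      t_s, events, backgrounds, rp,
      ttp_fun = function(tt) rundown_ttp_ms(spec, t_min_at(tt))
    )
  } else {
    cp <- spec$circuit
    ck <- spec$cone_kinetics
    g0 <- effective_coupling(spec, t_start_min)
    v_dark <- solve_steady_state(cp, g_gj_pS = g0)$v_cone_mV
    gain_fun <- function(tt) {
      coupling_attenuation(cp, effective_coupling(spec, t_min_at(tt)))
    }
    v <- v_dark + rod_pathway_trace(
      t_s, events, backgrounds, rp, gain_fun = gain_fun,
      ttp_fun = function(tt) ck$ttp_coupled_ms
    )
    # intrinsic cone component: fast, unaffected by rod saturation state
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      i_half <- effective_half_sat(ck$mix$f_m, ev$wavelength_nm, ck$constants)
      amp <- saturation_response(ev$strength_ph_um2, i_half,
                                 rundown_cone_rmax_mV(spec, t_min_at(ev$t_abs_s)))
      v <- v + dim_flash_waveform(t_s - ev$t_abs_s, ck$ttp_intrinsic_ms,
                                  amp, ck$waveform_n)
    }
  }

  if (noise_sd_mV > 0) {
    v <- v + with_seed(seed, stats::rnorm(length(t_s), 0, noise_sd_mV))
  }

  stim520 <- numeric(length(t_s))
  stim365 <- numeric(length(t_s))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    dur_s <- ev$duration_ms / 1000
    idx <- t_s >= ev$t_abs_s & t_s < ev$t_abs_s + dur_s
    flux <- ev$strength_ph_um2 / dur_s
    if (ev$wavelength_nm == 520) stim520[idx] <- stim520[idx] + flux
    else stim365[idx] <- stim365[idx] + flux
  }
  if (nrow(backgrounds)) {
    for (b in seq_len(nrow(backgrounds))) {
      bg <- backgrounds[b, ]
      idx <- t_s >= bg$t_on_s & t_s < bg$t_off_s
      if (bg$wavelength_nm == 520) stim520[idx] <- stim520[idx] + bg$flux_ph_um2_s
      else stim365[idx] <- stim365[idx] + bg$flux_ph_um2_s
    }
  }

  structure(
    list(t_s = t_s, v_mV = v, stim520_ph_um2_s = stim520,
         stim365_ph_um2_s = stim365, events = events, spec = spec,
         fs_hz = fs_hz, seed = seed, noise_sd_mV = noise_sd_mV,
         t_start_min = t_start_min),
    class = "pr_recording"
  )
}

dark_rod_potential <- function(spec) {
  cp <- spec$circuit
  if (is.null(cp)) cp <- circuit_params()
  g_p <- cp$g_photo_rod_dark_pS
  g_l <- cp$g_leak_rod_pS
  (g_p * cp$e_os_mV + g_l * cp$e_leak_mV) / (g_p + g_l)
}

#' Default population parameters for synthetic cohorts
#'
#' Per-cell parameter distributions for cohort generation. Rod dim-flash
#' time-to-peak: Normal(258, 25) ms in loose seal, Normal(288, 51) ms in
#' patch modes, truncated at 0. Rod dim green/ultraviolet amplitude ratio:
#' Normal(2.7, 0.2 * sqrt(8)) (mean and between-cell SD recovered from the
#' reported SEM at n = 8), truncated at 0.2.
#'
#' @param mode Recording mode for rods.
#' @param temperature_C 24 (default) or 36. The 36 degree preset uses
#'   faster kinetics and, for cones, modest junctional conductances
#'   (uniform on 60-260 pS) so coupled dim-flash amplitudes fall in the
#'   observed 0.28-1.70 mV band.
#' @return A list of class `cell_population`.
#' @export
default_rod_population <- function(mode = "loose_seal", temperature_C = 24) {
  patch <- mode != "loose_seal"
  ttp <- if (temperature_C == 36) c(mean = 140, sd = 15)
         else if (patch) c(mean = 288, sd = 51) else c(mean = 258, sd = 25)
  structure(
    list(cell_type = "rod", mode = mode, temperature_C = temperature_C,
         ttp_mean_ms = unname(ttp["mean"]), ttp_sd_ms = unname(ttp["sd"]),
         guv_ratio_mean = 2.7, guv_ratio_sd = 0.2 * sqrt(8),
         tau_rec_s = if (temperature_C == 36) 0.5 else 1.0),
    class = "cell_population"
  )
}

#' @rdname default_rod_population
#' @export
default_cone_population <- function(temperature_C = 24) {
  if (temperature_C == 36) {
    structure(
      list(cell_type = "cone", mode = "perforated_patch",
           temperature_C = 36,
           ttp_coupled_mean_ms = 120, ttp_coupled_sd_ms = 20,
           g0_range = c(1, 1), g_max_range_pS = c(60, 260),
           rate_range_per_min = c(0, 0)),
      class = "cell_population"
    )
  } else {
    structure(
      list(cell_type = "cone", mode = "perforated_patch",
           temperature_C = 24,
           ttp_coupled_mean_ms = 197, ttp_coupled_sd_ms = 35,
           g0_range = c(0.1, 0.9), g_max_range_pS = c(2500, 3872),
           rate_range_per_min = c(0.2, 1)),
      class = "cell_population"
    )
  }
}

rnorm_trunc <- function(n, mean, sd, lower = 0) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= lower)
  }
  x
}

#' Generate a cohort of synthetic recordings
#'
#' Draws per-cell parameters from the population distributions, builds a
#' [cell_spec()] per cell and generates one recording per cell. Pure
#' function of `(population, protocol, master_seed, ...)`.
#'
#' @param n Number of cells, >= 1.
#' @param population A `cell_population` from [default_rod_population()] or
#'   [default_cone_population()].
#' @param protocol A `stimulus_protocol`.
#' @param master_seed Integer master seed; all per-cell draws and per-cell
#'   noise seeds derive from it.
#' @param noise_sd_mV Raw noise SD (mV).
#' @param fs_hz Sampling rate (Hz).
#' @return A list of `pr_recording` objects with attributes `population`
#'   and `cells` (the per-cell parameter table).
#' @export
generate_cohort <- function(n, population, protocol, master_seed,
                            noise_sd_mV = 1.5, fs_hz = 5000) {
  stopifnot(n >= 1, inherits(population, "cell_population"))
  pars <- with_seed(master_seed, {
    if (population$cell_type == "rod") {
      data.frame(
        cell = seq_len(n),
        ttp_ms = rnorm_trunc(n, population$ttp_mean_ms, population$ttp_sd_ms),
        guv_ratio = rnorm_trunc(n, population$guv_ratio_mean,
                                population$guv_ratio_sd, lower = 0.2),
        seed = sample.int(.Machine$integer.max - 1L, n)
      )
    } else {
      data.frame(
        cell = seq_len(n),
        ttp_coupled_ms = rnorm_trunc(n, population$ttp_coupled_mean_ms,
                                     population$ttp_coupled_sd_ms),
        g0 = stats::runif(n, population$g0_range[1], population$g0_range[2]),
        g_max_pS = stats::runif(n, population$g_max_range_pS[1],
                                population$g_max_range_pS[2]),
        rate_per_min = stats::runif(n, population$rate_range_per_min[1],
                                    population$rate_range_per_min[2]),
        seed = sample.int(.Machine$integer.max - 1L, n)
      )
    }
  })
  recs <- lapply(seq_len(n), function(i) {
    if (population$cell_type == "rod") {
      rk <- rod_kinetics_params(ttp_dim_ms = pars$ttp_ms[i],
                                guv_dim_ratio = pars$guv_ratio[i],
                                tau_rec_s = population$tau_rec_s)
      spec <- cell_spec("rod", population$mode, rod_kinetics = rk,
                        temperature_C = population$temperature_C)
    } else {
      ck <- cone_kinetics_params(ttp_coupled_ms = pars$ttp_coupled_ms[i])
      tr <- trajectory_params(g0 = pars$g0[i], g_max_pS = pars$g_max_pS[i],
                              rate_per_min = pars$rate_per_min[i])
      spec <- cell_spec("cone", population$mode, cone_kinetics = ck,
                        trajectory = tr,
                        temperature_C = population$temperature_C)
    }
    generate_recording(spec, protocol, noise_sd_mV = noise_sd_mV,
                       seed = pars$seed[i], fs_hz = fs_hz)
  })
  attr(recs, "population") <- population
  attr(recs, "cells") <- pars
  recs
}
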
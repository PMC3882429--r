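#' Rod photoresponse kinetics parameters
#'
#' Phenomenological parameters of the rod photovoltage model: dim-flash
#' time-to-peak and amplitude, hyperbolic intensity-response parameters, the
#' saturation-duration law for bright flashes, recovery time constants, and
#' the rod spectral parameters (green/ultraviolet half-saturation shift and
#' dim-flash amplitude ratio).
#'
#' The saturation duration follows `T_sat(I) = tau_d * ln(I / I_ref)`
#' (floored at 0); defaults solve `T_sat(1570) = 1.2 s` and
#' `T_sat(3140) = 1.7 s`, keeping bright flashes of 1570-3140 photons·µm^-2
#' saturating for 1-2 s.
#'
#' @param ttp_dim_ms Dim-flash time-to-peak (ms). Default 258 (loose-seal).
#' @param r_max_mV Saturating photovoltage amplitude (mV). Default 25.
#' @param i_half Half-saturating flash strength at 520 nm (photons·µm^-2).
#'   Default 30 (calibration: 16.6 photons·µm^-2 gives a large
#'   sub-saturating response; 1570 saturates).
#' @param uv_shift Factor by which ultraviolet strengths are divided before
#'   entering the hyperbola (rightward shift of the response profile).
#'   Default 2.2.
#' @param guv_dim_ratio Dim-flash green/ultraviolet amplitude ratio applied
#'   when synthesizing spectral-protocol responses. Default 2.7. Kept
#'   independent of `uv_shift`: under a pure sensitivity shift the
#'   equal-strength amplitude ratio is bounded by the shift factor, so the
#'   measured 2.7 cannot arise from the 2.2 shift alone.
#' @param tau_d_s Dominant saturation time constant (s).
#' @param i_ref Reference intensity of the saturation-duration law
#'   (photons·µm^-2).
#' @param tau_rec_s Recovery time constant of dim-flash responsiveness after
#'   a bright flash (s).
#' @param tau_bg_s Recovery time constant after a saturating background
#'   offset (s). Default 50 s, placing 90% recovery at ~115 s (~2 min).
#' @param tau_rise_ms Rising-edge time constant of saturating responses (ms).
#' @param waveform_n Sharpness exponent of the dim-flash alpha-like
#'   waveform.
#' @param sat_flux_threshold Background photon flux density
#'   (photons·µm^-2·s^-1, 520 nm) at or above which rods are held saturated.
#' @return A list of class `rod_kinetics`.
#' @export
rod_kinetics_params <- function(ttp_dim_ms = 258, r_max_mV = 25, i_half = 30,
                                uv_shift = 2.2, guv_dim_ratio = 2.7,
                                tau_d_s = 0.5 / log(2),
                                i_ref = 1570 / exp(1.2 * log(2) / 0.5),
                                tau_rec_s = 1.0, tau_bg_s = 50,
                                tau_rise_ms = 30, waveform_n = 4,
                                sat_flux_threshold = 6100) {
  stopifnot(ttp_dim_ms > 0, r_max_mV > 0, i_half > 0, uv_shift > 0,
            guv_dim_ratio > 0, tau_d_s > 0, i_ref > 0, tau_rec_s > 0,
            tau_bg_s > 0, tau_rise_ms > 0, waveform_n > 0)
  structure(
    list(ttp_dim_ms = ttp_dim_ms, r_max_mV = r_max_mV, i_half = i_half,
         uv_shift = uv_shift, guv_dim_ratio = guv_dim_ratio,
         tau_d_s = tau_d_s, i_ref = i_ref, tau_rec_s = tau_rec_s,
         tau_bg_s = tau_bg_s, tau_rise_ms = tau_rise_ms,
         waveform_n = waveform_n, sat_flux_threshold = sat_flux_threshold),
    class = "rod_kinetics"
  )
}

#' Cone photoresponse kinetics parameters
#'
#' @param ttp_intrinsic_ms Time-to-peak of the cone's intrinsic (fast)
#'   response (ms). Default 70 (calibration; figure-scale only).
#' @param ttp_coupled_ms Time-to-peak of the rod-driven dim-flash component
#'   recorded in the cone (ms). Default 197; the rod-to-cone kinetic
#'   speed-up is imposed phenomenologically.
#' @param r_max_mV Intrinsic saturating amplitude (mV). Default 12.
#' @param mix An [opsin_mix()]; intrinsic half-saturations per wavelength
#'   come from the spectral model.
#' @param constants A [spectral_constants()] object.
#' @param waveform_n Sharpness exponent of the intrinsic waveform.
#' @return A list of class `cone_kinetics`.
#' @export
cone_kinetics_params <- function(ttp_intrinsic_ms = 70, ttp_coupled_ms = 197,
                                 r_max_mV = 12,
                                 mix = m_fraction_for_latitude("ventral_third"),
                                 constants = spectral_constants(),
                                 waveform_n = 4) {
  stopifnot(ttp_intrinsic_ms > 0, ttp_coupled_ms > 0, r_max_mV > 0,
            inherits(mix, "opsin_mix"))
  structure(
    list(ttp_intrinsic_ms = ttp_intrinsic_ms, ttp_coupled_ms = ttp_coupled_ms,
         r_max_mV = r_max_mV, mix = mix, constants = constants,
         waveform_n = waveform_n),
    class = "cone_kinetics"
  )
}

#' Dim-flash photovoltage waveform
#'
#' Alpha-like single-lobed template
#' `w(t) = (t/TTP)^n * exp(n * (1 - t/TTP))`, zero for `t <= 0`, peaking at
#' exactly `t = TTP` with magnitude `amplitude`, hyperpolarizing (negative).
#' It returns below 5% of peak by `5 * TTP`.
#'
#' @param t_s Time grid (s), relative to flash onset.
#' @param ttp_ms Time-to-peak (ms), > 0.
#' @param amplitude_mV Peak deflection magnitude (mV), >= 0.
#' @param n Sharpness exponent (default 4).
#' @return Voltage deflection trace (mV, negative-going).
#' @export
dim_flash_waveform <- function(t_s, ttp_ms, amplitude_mV, n = 4) {
  if (ttp_ms <= 0) stop("ttp_ms must be > 0")
  if (amplitude_mV < 0) stop("amplitude_mV must be >= 0")
  ttp_s <- ttp_ms / 1000
  x <- t_s / ttp_s
  w <- ifelse(x > 0, exp(n * (log(pmax(x, 0)) + 1 - x)), 0)
  -amplitude_mV * w
}

#' Saturation duration of a bright rod flash
#'
#' `T_sat(I) = tau_d * ln(I / I_ref)`, floored at 0.
#'
#' @param intensity Flash strength (photons·µm^-2).
#' @param params A [rod_kinetics_params()] object.
#' @return Saturation duration (s).
#' @export
saturation_time <- function(intensity, params = rod_kinetics_params()) {
  pmax(0, params$tau_d_s * log(intensity / params$i_ref))
}

#' Rod response amplitude versus flash strength
#'
#' Hyperbolic saturation `R = r_max * I_eff / (I_eff + i_half)` where
#' ultraviolet strengths are first divided by the green/ultraviolet shift
#' factor (`I_eff = I / uv_shift` at 365 nm).
#'
#' @param intensity Flash strength(s) (photons·µm^-2), >= 0.
#' @param params A [rod_kinetics_params()] object.
#' @param wavelength_nm 520 (green, default) or 365 (ultraviolet).
#' @return Amplitude(s) in mV.
#' @export
amplitude_vs_intensity <- function(intensity, params = rod_kinetics_params(),
                                   wavelength_nm = 520) {
  if (any(intensity < 0)) stop("intensity must be >= 0")
  i_eff <- if (wavelength_nm == 365) intensity / params$uv_shift else intensity
  params$r_max_mV * i_eff / (i_eff + params$i_half)
}

#' Saturating rod flash response
#'
#' Fast trough to `-r_max` (exponential rise with `tau_rise_ms`), a plateau
#' lasting `saturation_time(I)`, then exponential recovery with
#' `tau_rec_s`. Sub-saturating strengths (amplitude below 95% of `r_max`)
#' fall back to the dim-flash template scaled by [amplitude_vs_intensity()].
#'
#' @param t_s Time grid (s) relative to flash onset.
#' @param intensity Flash strength (photons·µm^-2).
#' @param params A [rod_kinetics_params()] object.
#' @param wavelength_nm Stimulus wavelength.
#' @return Voltage deflection trace (mV, negative-going), causal.
#' @export
saturating_flash_response <- function(t_s, intensity,
                                      params = rod_kinetics_params(),
                                      wavelength_nm = 520) {
  amp <- amplitude_vs_intensity(intensity, params, wavelength_nm)
  if (amp < 0.95 * params$r_max_mV) {
    return(dim_flash_waveform(t_s, params$ttp_dim_ms, amp, params$waveform_n))
  }
  tau_r <- params$tau_rise_ms / 1000
  i_eff <- if (wavelength_nm == 365) intensity / params$uv_shift else intensity
  t_plateau_end <- saturation_time(i_eff, params)
  v <- numeric(length(t_s))
  rising <- t_s > 0 & t_s <= t_plateau_end
  v[rising] <- -params$r_max_mV * (1 - exp(-t_s[rising] / tau_r))
  rec <- t_s > t_plateau_end
  v_end <- -params$r_max_mV * (1 - exp(-max(t_plateau_end, 1e-9) / tau_r))
  v[rec] <- v_end * exp(-(t_s[rec] - t_plateau_end) / params$tau_rec_s)
  v
}

#' Fractional recovery of rod dim-flash responsiveness after a bright flash
#'
#' Zero while the rod is saturated (`dt <= T_sat(I)`), then
#' `1 - exp(-(dt - T_sat) / tau_rec_s)`: monotone non-decreasing toward 1.
#' The dim-flash amplitude at delay `dt` is the control amplitude times
#' this fraction.
#'
#' @param dt_s Delay(s) after the bright flash (s), >= 0.
#' @param params A [rod_kinetics_params()] object.
#' @param i_bright Strength of the preceding bright flash (photons·µm^-2).
#' @return Fraction(s) in [0, 1].
#' @export
fractional_recovery <- function(dt_s, params = rod_kinetics_params(),
                                i_bright = 1570) {
  stopifnot(all(dt_s >= 0))
  t_sat <- saturation_time(i_bright, params)
  1 - exp(-pmax(0, dt_s - t_sat) / params$tau_rec_s)
}

#' Rod-pathway responsiveness under and after a saturating background
#'
#' Zero while a rod-saturating background is on (photon flux density at or
#' above `params$sat_flux_threshold` at 520 nm), then recovering
#' monotonically to 1 with time constant `tau_bg_s` after offset. The
#' factor scales rod (and rod-driven cone) flash responses only; intrinsic
#' cone responses are unaffected.
#'
#' @param t_s Time(s) at which to evaluate (s).
#' @param background A list with `flux_ph_um2_s`, `t_on_s`, `t_off_s` (and
#'   optionally `wavelength_nm`).
#' @param params A [rod_kinetics_params()] object.
#' @return Responsiveness factor(s) in [0, 1].
#' @export
background_responsiveness <- function(t_s, background,
                                      params = rod_kinetics_params()) {
  stopifnot(background$flux_ph_um2_s >= 0)
  saturating <- background$flux_ph_um2_s >= params$sat_flux_threshold
  if (!saturating) return(rep(1, length(t_s)))
  f <- rep(1, length(t_s))
  on <- t_s >= background$t_on_s & t_s < background$t_off_s
  f[on] <- 0
  after <- t_s >= background$t_off_s
  f[after] <- 1 - exp(-(t_s[after] - background$t_off_s) / params$tau_bg_s)
  f
}
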
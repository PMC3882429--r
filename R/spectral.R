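#' Fixed spectral constants for mouse photoreceptor pigments
#'
#' Relative absorbance weights of the three mouse visual pigments at the two
#' stimulus wavelengths used throughout the package (green 520 nm and
#' ultraviolet 365 nm), together with the reference normalized cone flash
#' sensitivity. Each pigment carries weight 1 at its preferred test
#' wavelength; M-opsin retains 20% of maximum at 365 nm (beta-band), S-opsin
#' drops 4 log-units at 520 nm, and rhodopsin is 1/2.2 as sensitive in the
#' ultraviolet as in the green.
#'
#' @param s_ref Reference normalized flash sensitivity of a cone probed at
#'   its weight-1 wavelength, in fractional response per photon·µm^-2.
#'   Default 0.00042 (i.e. 0.042% photons^-1·µm^2).
#' @return An object of class `spectral_constants`: a list with the
#'   absorbance weight table, `s_ref`, and pigment peak wavelengths (nm,
#'   metadata only).
#' @export
#' @examples
#' sc <- spectral_constants()
#' relative_absorbance("M", 365, sc)   # 0.2
spectral_constants <- function(s_ref = 0.00042) {
  stopifnot(is.numeric(s_ref), length(s_ref) == 1L, s_ref > 0)
  weights <- matrix(
    c(1.0,   0.2,        # M:   520, 365
      1e-4,  1.0,        # S:   520, 365
      1.0,   1 / 2.2),   # rhodopsin: 520, 365
    nrow = 3, byrow = TRUE,
    dimnames = list(c("M", "S", "rhodopsin"), c("520", "365"))
  )
  structure(
    list(
      weights = weights,
      s_ref = s_ref,
      peak_nm = c(M = 508, S = 359, rhodopsin = 498)
    ),
    class = "spectral_constants"
  )
}

#' Relative absorbance of a pigment at a stimulus wavelength
#'
#' @param pigment One of `"M"`, `"S"`, `"rhodopsin"`.
#' @param wavelength_nm Stimulus wavelength, 520 or 365 nm.
#' @param constants A [spectral_constants()] object.
#' @return Dimensionless weight in (0, 1].
#' @export
relative_absorbance <- function(pigment, wavelength_nm,
                                constants = spectral_constants()) {
  if (!is.character(pigment) || length(pigment) != 1L ||
      !pigment %in% rownames(constants$weights)) {
    stop("unknown pigment '", paste(pigment, collapse = ","),
         "'; must be one of ", paste(rownames(constants$weights), collapse = ", "))
  }
  wl <- as.character(wavelength_nm)
  if (length(wavelength_nm) != 1L || !wl %in% colnames(constants$weights)) {
    stop("unsupported wavelength '", paste(wavelength_nm, collapse = ","),
         "' nm; supported: ", paste(colnames(constants$weights), collapse = ", "))
  }
  constants$weights[pigment, wl]
}

#' Relative sensitivity of a mixed S/M cone
#'
#' Equal-total-opsin weighted sum of the M and S absorbance weights:
#' `f_m * w(M, lambda) + (1 - f_m) * w(S, lambda)`.
#'
#' @param f_m Fraction of M-opsin in the cone's opsin complement, in [0, 1].
#' @inheritParams relative_absorbance
#' @return Dimensionless sensitivity weight in (0, 1].
#' @export
cone_relative_sensitivity <- function(f_m, wavelength_nm,
                                      constants = spectral_constants()) {
  stopifnot(is.numeric(f_m), all(f_m >= 0), all(f_m <= 1))
  f_m * relative_absorbance("M", wavelength_nm, constants) +
    (1 - f_m) * relative_absorbance("S", wavelength_nm, constants)
}

#' Half-saturating flash strength from a normalized flash sensitivity
#'
#' For a hyperbolic saturation function the small-signal slope of the
#' normalized response is `1 / I_half`, so a normalized sensitivity `s_n`
#' (fractional response per photon·µm^-2) implies `I_half = 1 / s_n`.
#'
#' @param s_n Normalized flash sensitivity, > 0.
#' @return Half-saturating flash strength in photons·µm^-2.
#' @export
#' @examples
#' round(half_sat_from_sensitivity(0.00042))  # 2381
half_sat_from_sensitivity <- function(s_n) {
  stopifnot(is.numeric(s_n))
  if (any(s_n <= 0)) stop("s_n must be > 0")
  1 / s_n
}

#' Effective half-saturating strength of a mixed cone at a wavelength
#'
#' The reference half-saturation (from `constants$s_ref`) scaled up by the
#' reciprocal of the cone's relative sensitivity at that wavelength.
#'
#' @inheritParams cone_relative_sensitivity
#' @return I_half in photons·µm^-2.
#' @export
effective_half_sat <- function(f_m, wavelength_nm,
                               constants = spectral_constants()) {
  half_sat_from_sensitivity(constants$s_ref) /
    cone_relative_sensitivity(f_m, wavelength_nm, constants)
}

#' Hyperbolic (Michaelis-Menten) saturation response
#'
#' `R = r_max * I / (I + i_half)`.
#'
#' @param intensity Flash strength(s), photons·µm^-2, >= 0.
#' @param i_half Half-saturating strength, > 0.
#' @param r_max Maximal response amplitude (default 1, normalized).
#' @return Response amplitude(s) in `[0, r_max)`.
#' @export
saturation_response <- function(intensity, i_half, r_max = 1) {
  stopifnot(is.numeric(intensity), i_half > 0, r_max > 0)
  if (any(intensity < 0)) stop("intensity must be >= 0")
  r_max * intensity / (intensity + i_half)
}

#' M-opsin fraction at a named retinal latitude
#'
#' Tabulated average %M-opsin values for cones in horizontal slices of the
#' mouse retina (dorsal M-dominant to ventral S-dominant), plus the pure-S
#' cone population.
#'
#' @param label One of `"dorsalmost"`, `"dorsal_third"`, `"ventral_third"`,
#'   `"ventralmost"`, `"pure_S"`.
#' @return A list of class `opsin_mix` with fields `f_m` and `latitude`.
#' @export
m_fraction_for_latitude <- function(label) {
  tab <- c(dorsalmost = 0.64, dorsal_third = 0.24,
           ventral_third = 0.047, ventralmost = 0.012, pure_S = 0)
  if (!is.character(label) || length(label) != 1L || !label %in% names(tab)) {
    stop("unknown latitude label '", paste(label, collapse = ","),
         "'; valid labels: ", paste(names(tab), collapse = ", "))
  }
  opsin_mix(unname(tab[label]), latitude = label)
}

#' Construct an opsin mix
#'
#' @param f_m M-opsin fraction in [0, 1].
#' @param latitude Optional latitude label (metadata).
#' @return An object of class `opsin_mix`.
#' @export
opsin_mix <- function(f_m, latitude = NULL) {
  stopifnot(is.numeric(f_m), length(f_m) == 1L, f_m >= 0, f_m <= 1)
  structure(list(f_m = f_m, latitude = latitude), class = "opsin_mix")
}

#' Default log-spaced intensity grid
#'
#' 50 points per decade from 1 to 1e8 photons·µm^-2.
#'
#' @param from,to Grid endpoints (photons·µm^-2).
#' @param per_decade Points per decade.
#' @return Sorted numeric vector of intensities.
#' @export
default_intensity_grid <- function(from = 1, to = 1e8, per_decade = 50) {
  stopifnot(from > 0, to > from, per_decade >= 1)
  10^seq(log10(from), log10(to), by = 1 / per_decade)
}

#' Predicted normalized cone flash-response profile
#'
#' Evaluates the hyperbolic saturation function with the effective
#' half-saturation of a mixed S/M cone at the requested wavelength over an
#' intensity grid (normalized `r_max = 1`).
#'
#' @param mix An [opsin_mix()] (or a latitude label string, resolved via
#'   [m_fraction_for_latitude()]).
#' @param wavelength_nm 520 or 365.
#' @param intensities Strictly positive, sorted intensity grid.
#' @param constants A [spectral_constants()] object.
#' @return A data frame with columns `intensity_ph_um2` and `response_norm`,
#'   with attributes `f_m`, `wavelength_nm`, `i_half`.
#' @export
predicted_profile <- function(mix, wavelength_nm,
                              intensities = default_intensity_grid(),
                              constants = spectral_constants()) {
  if (is.character(mix)) mix <- m_fraction_for_latitude(mix)
  stopifnot(inherits(mix, "opsin_mix"))
  if (any(intensities <= 0)) stop("intensities must be strictly positive")
  if (is.unsorted(intensities, strictly = TRUE)) {
    stop("intensities must be sorted strictly increasing")
  }
  i_half <- effective_half_sat(mix$f_m, wavelength_nm, constants)
  out <- data.frame(
    intensity_ph_um2 = intensities,
    response_norm = saturation_response(intensities, i_half)
  )
  attr(out, "f_m") <- mix$f_m
  attr(out, "wavelength_nm") <- wavelength_nm
  attr(out, "i_half") <- i_half
  out
}

#' Write a predicted profile to CSV
#'
#' Columns `intensity_ph_um2, response_norm`, preceded by `#`-prefixed
#' metadata lines recording `f_m`, wavelength and `i_half`.
#'
#' @param profile A data frame from [predicted_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# f_m=%.6g", attr(profile, "f_m")),
    sprintf("# wavelength_nm=%g", attr(profile, "wavelength_nm")),
    sprintf("# i_half_ph_um2=%.10g", attr(profile, "i_half"))
  ), con)
  utils::write.table(profile, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
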
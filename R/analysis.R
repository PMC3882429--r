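#' Box-car (moving-average) filter
#'
#' Centered running mean over `round(window_ms * fs_hz / 1000)` samples,
#' with truncated windows at the trace edges. Linear in the input.
#'
#' @param x Numeric trace.
#' @param fs_hz Sampling rate (Hz).
#' @param window_ms Window length (ms). Default 20.
#' @return Filtered trace, same length as `x`.
#' @export
boxcar_filter <- function(x, fs_hz, window_ms = 20) {
  stopifnot(window_ms > 0, fs_hz > 0)
  k <- round(window_ms * fs_hz / 1000)
  if (k < 1) stop("window shorter than one sample at this sampling rate")
  n <- length(x)
  if (k == 1 || n == 0) return(x)
  half_lo <- floor((k - 1) / 2)
  half_hi <- k - 1 - half_lo
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Measure a flash response on a filtered recording
#'
#' Baseline is the mean over a pre-flash window; deflections are taken
#' relative to the linear trend of that window extrapolated through the
#' search window, which keeps responses measurable when they ride on the
#' recovery tail of a preceding bright flash. For bright flashes the peak
#' is the largest absolute deflection in the search window (ties resolved
#' to the earliest sample); for dim flashes it is the largest interior
#' local extremum of the deflection, so a purely monotone drift (a rod
#' still saturated) yields amplitude 0 rather than a spurious edge value.
#' The plateau (bright flashes) is the mean deflection over 0.4-0.6 s post
#' flash.
#'
#' @param rec A `pr_recording`.
#' @param event A one-row data frame from `rec$events` (or an index into
#'   it).
#' @param baseline_ms Pre-flash baseline window (ms). Default 200.
#' @param search_ms Peak search window (ms); defaults to 1000 for dim
#'   flashes and 400 (fast peak) for bright flashes.
#' @param window_ms Box-car window applied before measurement (ms);
#'   default 20.
#' @param plateau_window_s Plateau window relative to flash onset (s).
#' @param refine_peak When `TRUE`, the dim-flash peak is refined by a local
#'   least-squares parabola fitted over +/- 2 filter windows around the peak
#'   sample: the time-to-peak is the vertex position and the amplitude the
#'   vertex value. This suppresses both the rightward jitter the sample
#'   argmax picks up on the flat top of a noisy response and the upward
#'   amplitude inflation of extremum selection in noise. Default `FALSE`
#'   (sample-exact argmax).
#' @return A list of class `measured_response`: `flash` (the event row),
#'   `baseline_mV`, `amplitude_mV` (magnitude), `polarity`
#'   (`"hyperpolarizing"`/`"depolarizing"`), `ttp_ms`, `plateau_mV` (NA for
#'   dim flashes).
#' @export
measure_response <- function(rec, event, baseline_ms = 200,
                             search_ms = NULL, window_ms = 20,
                             plateau_window_s = c(0.4, 0.6),
                             refine_peak = FALSE) {
  stopifnot(inherits(rec, "pr_recording"))
  if (is.numeric(event) && length(event) == 1L) event <- rec$events[event, ]
  tf <- event$t_abs_s
  t <- rec$t_s
  if (tf < min(t) || tf > max(t)) stop("flash time lies outside the trace")
  bright <- event$label %in% c("bright_a", "bright_b", "pre")
  if (is.null(search_ms)) search_ms <- if (bright) 400 else 1000
  v <- boxcar_filter(rec$v_mV, rec$fs_hz, window_ms)
  base_idx <- t >= tf - baseline_ms / 1000 & t < tf
  if (!any(base_idx)) stop("baseline window lies outside the trace")
  baseline <- mean(v[base_idx])
  bt <- t[base_idx]
  # slope from the raw trace (honest standard error: unfiltered samples are
  # independent); applied only when clearly non-zero, so flat baselines are
  # not tilted by a noise-driven slope extrapolated across the search window
  slope <- 0
  if (length(bt) >= 3 && stats::var(bt) > 0) {
    bfit <- stats::lm(rec$v_mV[base_idx] ~ bt)
    sm <- suppressWarnings(summary(bfit))$coefficients
    if (nrow(sm) == 2 && is.finite(sm[2, 3]) && abs(sm[2, 3]) >= 3) {
      slope <- unname(sm[2, 1])
    }
  }
  trend_at <- function(tt) baseline + slope * (tt - mean(bt))
  search_idx <- which(t > tf & t <= tf + search_ms / 1000)
  if (!length(search_idx)) stop("search window lies outside the trace")
  defl <- v[search_idx] - trend_at(t[search_idx])
  if (bright) {
    j <- which.max(abs(defl))   # earliest on ties
  } else {
    nw <- length(defl)
    k <- max(1L, round(window_ms * rec$fs_hz / 1000))
    cand <- integer(0)
    if (nw >= 2 * k + 3) {
      i2 <- (k + 1):(nw - k)
      up <- defl[i2] - defl[i2 - 1]
      dn <- defl[i2 + 1] - defl[i2]
      is_ext <- (up >= 0 & dn <= 0 & (up > 0 | dn < 0)) |
        (up <= 0 & dn >= 0 & (up < 0 | dn > 0))
      # a genuine peak is also extremal at the filter-window scale; noise
      # bumps riding a monotone drift (e.g. the recovery tail of a bright
      # flash while the rod is still saturated) are not
      at_scale <- (defl[i2] >= defl[i2 - k] & defl[i2] >= defl[i2 + k]) |
        (defl[i2] <= defl[i2 - k] & defl[i2] <= defl[i2 + k])
      # and a genuine response is a transient: the deflection must return
      # below half of the candidate peak later in the window, which a
      # monotone drift never does
      suf_min <- rev(cummin(rev(defl)))
      suf_max <- rev(cummax(rev(defl)))
      transient <- ifelse(defl[i2] >= 0,
                          suf_min[i2] <= 0.5 * defl[i2],
                          suf_max[i2] >= 0.5 * defl[i2])
      cand <- i2[is_ext & at_scale & transient]
    }
    j <- if (length(cand)) cand[which.max(abs(defl[cand]))] else NA_integer_
  }
  if (is.na(j)) {
    amplitude <- 0
    polarity <- NA_character_
    ttp_ms <- NA_real_
  } else {
    amplitude <- abs(defl[j])
    polarity <- if (defl[j] <= 0) "hyperpolarizing" else "depolarizing"
    ttp_ms <- (t[search_idx[j]] - tf) * 1000
    if (refine_peak && !bright) {
      tc <- t[search_idx[j]]
      sel <- which(t >= tc - 2 * window_ms / 1000 &
                     t <= tc + 2 * window_ms / 1000)
      if (length(sel) >= 5) {
        dt <- t[sel] - tc
        cf <- stats::coef(stats::lm(v[sel] ~ dt + I(dt^2)))
        if (is.finite(cf[3]) && cf[3] != 0) {
          vert <- -cf[2] / (2 * cf[3])
          # accept the vertex only inside the fitted neighbourhood
          if (abs(vert) <= 2 * window_ms / 1000) {
            ttp_ms <- (tc + vert - tf) * 1000
            v_vert <- cf[1] + cf[2] * vert + cf[3] * vert^2
            amplitude <- abs(v_vert - trend_at(tc + vert))
          }
        }
      }
    }
  }
  plateau <- NA_real_
  if (bright) {
    pl_idx <- t >= tf + plateau_window_s[1] & t <= tf + plateau_window_s[2]
    if (any(pl_idx)) plateau <- abs(mean(v[pl_idx]) - trend_at(mean(t[pl_idx])))
  }
  structure(
    list(flash = event, baseline_mV = baseline, amplitude_mV = amplitude,
         polarity = polarity, ttp_ms = ttp_ms, plateau_mV = plateau),
    class = "measured_response"
  )
}

#' Measure every flash in a recording
#'
#' @param rec A `pr_recording`.
#' @param ... Passed to [measure_response()].
#' @return A data frame with one row per flash: the event columns plus
#'   `baseline_mV`, `amplitude_mV`, `polarity`, `ttp_ms`, `plateau_mV`.
#' @export
analyze_recording <- function(rec, ...) {
  rows <- lapply(seq_len(nrow(rec$events)), function(i) {
    m <- measure_response(rec, i, ...)
    cbind(m$flash,
          data.frame(baseline_mV = m$baseline_mV,
                     amplitude_mV = m$amplitude_mV,
                     polarity = m$polarity, ttp_ms = m$ttp_ms,
                     plateau_mV = m$plateau_mV))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize dim-flash amplitudes to the bright-flash amplitude
#'
#' @param dim_amplitudes Numeric vector of dim amplitudes (mV).
#' @param bright_amplitude Bright (`bright_a`) amplitude (mV), > 0.
#' @return Dimensionless normalized amplitudes.
#' @export
normalize_to_bright <- function(dim_amplitudes, bright_amplitude) {
  if (is.na(bright_amplitude) || length(bright_amplitude) != 1L ||
      bright_amplitude <= 0) {
    stop("bright-flash amplitude is zero or absent; normalization undefined")
  }
  dim_amplitudes / bright_amplitude
}

#' Green-over-ultraviolet response ratio
#'
#' Ratio of peak response amplitudes to green versus ultraviolet flashes of
#' equal photon strength. Values above 1 indicate green (M/rod-like)
#' preference, below 1 ultraviolet (S) preference.
#'
#' @param peak_g,peak_uv Peak amplitudes (mV) at equal strength.
#' @param noise_floor_mV Amplitudes at or below this are treated as no
#'   response; the ratio is then `NA` with attribute `undefined = TRUE`.
#' @return The ratio, or `NA` (flagged) when the ultraviolet response is at
#'   or below the noise floor.
#' @export
guv_ratio <- function(peak_g, peak_uv, noise_floor_mV = 0) {
  if (is.na(peak_uv) || peak_uv <= noise_floor_mV) {
    return(structure(NA_real_, undefined = TRUE))
  }
  peak_g / peak_uv
}

#' Recovery curve from kinetics-protocol measurements
#'
#' Dim-flash amplitudes at the post-bright delays, normalized to the
#' bright-flash amplitude, with the pre-bright dim response included as the
#' control point (`delay_s = NA`).
#'
#' @param measurements A data frame from [analyze_recording()] of a
#'   kinetics-protocol recording.
#' @return A data frame with `sweep`, `delay_s` (NA for the control
#'   point), `amplitude_mV` and `norm_amplitude`.
#' @export
recovery_curve <- function(measurements) {
  out <- list()
  for (k in sort(unique(measurements$sweep))) {
    sw <- measurements[measurements$sweep == k, , drop = FALSE]
    dims <- sw[sw$label == "dim", , drop = FALSE]
    br <- sw[sw$label == "bright_a", , drop = FALSE]
    if (nrow(dims) < 2 || nrow(br) < 1) next  # partial sweep: explicit gap
    bright_amp <- br$amplitude_mV[1]
    delay <- dims$t_abs_s[2] - br$t_abs_s[1]
    out[[length(out) + 1]] <- data.frame(
      sweep = k,
      delay_s = c(NA, delay),
      amplitude_mV = dims$amplitude_mV[1:2],
      norm_amplitude = normalize_to_bright(dims$amplitude_mV[1:2], bright_amp)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit a hyperbolic (Michaelis-Menten) intensity-response function
#'
#' Least-squares fit of `R = r_max * I / (I + i_half)` by a deterministic
#' log-grid search over `i_half` (with `r_max` solved analytically at each
#' candidate) followed by 1-D local refinement.
#'
#' @param intensities Flash strengths (photons·µm^-2), >= 3 distinct
#'   values, > 0 allowed alongside zeros.
#' @param amplitudes Response amplitudes (>= 0), same length.
#' @param grid_decades Log10 search range for `i_half` around the data.
#' @return A list of class `mm_fit`: `i_half`, `r_max`, `rss`, `fitted`.
#' @export
fit_michaelis_menten <- function(intensities, amplitudes,
                                 grid_decades = c(-3, 3)) {
  stopifnot(length(intensities) == length(amplitudes),
            all(amplitudes >= 0), all(intensities >= 0))
  pos <- intensities > 0
  if (length(unique(intensities[pos])) < 3) {
    stop("need at least 3 distinct positive intensities to identify the fit")
  }
  rss_at <- function(log10_ih) {
    ih <- 10^log10_ih
    x <- intensities / (intensities + ih)
    rmax <- sum(amplitudes * x) / sum(x^2)
    sum((amplitudes - rmax * x)^2)
  }
  lo <- log10(min(intensities[pos])) + grid_decades[1]
  hi <- log10(max(intensities[pos])) + grid_decades[2]
  grid <- seq(lo, hi, by = 0.02)
  rss_grid <- vapply(grid, rss_at, numeric(1))
  j <- which.min(rss_grid)
  opt <- stats::optimize(rss_at,
                         lower = grid[max(1, j - 2)],
                         upper = grid[min(length(grid), j + 2)],
                         tol = 1e-10)
  i_half <- 10^opt$minimum
  x <- intensities / (intensities + i_half)
  r_max <- sum(amplitudes * x) / sum(x^2)
  structure(
    list(i_half = i_half, r_max = r_max, rss = opt$objective,
         fitted = r_max * x),
    class = "mm_fit"
  )
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' U statistic with tie correction; exact enumeration of all group
#' assignments when the combined sample size is at most 12 (valid with
#' ties), normal approximation with tie correction and continuity
#' correction otherwise.
#'
#' @param group_a,group_b Numeric vectors, each non-empty.
#' @return A list with `U` (for `group_a`), `p_value` (two-sided) and
#'   `method` (`"exact"` or `"normal_approximation"`).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) < 1 || length(group_b) < 1) {
    stop("both groups must be non-empty")
  }
  m <- length(group_a)
  n <- length(group_b)
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u <- u_stat(group_a, group_b)
  mu <- m * n / 2
  if (m + n <= 12) {
    pool <- c(group_a, group_b)
    idx <- utils::combn(m + n, m)
    us <- apply(idx, 2, function(sel) u_stat(pool[sel], pool[-sel]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "exact"
  } else {
    r <- rank(c(group_a, group_b))
    nt <- table(r)
    tie_term <- sum(nt^3 - nt) / ((m + n) * (m + n - 1))
    sigma2 <- m * n / 12 * (m + n + 1 - tie_term)
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal_approximation"
  }
  list(U = u, p_value = p, method = method)
}

#' Extrapolate the dim-flash amplitude to time zero
#'
#' Ordinary least-squares line over the measurements in the early window
#' (first 2 min of recording by default), evaluated at t = 0 and floored
#' at 0. Estimates the unperturbed (pre-patch) coupling level of a cone.
#'
#' @param t_min Measurement times (min since seal formation).
#' @param amplitude_mV Dim-flash amplitudes (mV).
#' @param early_window_min Early-window length (min). Default 2.
#' @param slope_se_threshold Confidence flag is `FALSE` when the slope
#'   standard error exceeds this (mV/min). Default 1.
#' @return A list with `estimate_mV` (NA when fewer than 2 early points),
#'   `confident` (logical), `n_early`, `slope`, `slope_se`.
#' @export
extrapolate_initial_coupling <- function(t_min, amplitude_mV,
                                         early_window_min = 2,
                                         slope_se_threshold = 1) {
  keep <- which(t_min <= early_window_min)
  if (length(keep) < 2) {
    return(list(estimate_mV = NA_real_, confident = FALSE,
                n_early = length(keep), slope = NA_real_,
                slope_se = NA_real_))
  }
  fit <- stats::lm(amplitude_mV[keep] ~ t_min[keep])
  est <- max(0, unname(stats::coef(fit)[1]))
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(sm[2, 1])
  slope_se <- unname(sm[2, 2])
  confident <- is.finite(slope_se) && slope_se <= slope_se_threshold
  list(estimate_mV = est, confident = confident, n_early = length(keep),
       slope = slope, slope_se = slope_se)
}

#' Per-cell dim-flash time-to-peak across a cohort
#'
#' For each recording, measures the pre-bright ("control") dim flash of
#' every sweep after box-car filtering and averages its time-to-peak; the
#' pre-bright flash is used because its baseline is unperturbed by the
#' bright-flash recovery tail.
#'
#' @param recordings A list of `pr_recording` objects (e.g. from
#'   [generate_cohort()]) under the kinetics protocol.
#' @param refine_peak Use parabolic vertex refinement of the peak
#'   (default `TRUE`; see [measure_response()]).
#' @param ... Passed to [measure_response()].
#' @return Numeric vector of per-cell mean TTPs (ms).
#' @export
cohort_dim_ttp <- function(recordings, refine_peak = TRUE, ...) {
  vapply(recordings, function(rec) {
    m <- analyze_recording(rec, refine_peak = refine_peak, ...)
    ttps <- unlist(lapply(split(m, m$sweep), function(sw) {
      br <- sw$t_abs_s[sw$label %in% c("bright_a", "bright_b")]
      first_bright <- if (length(br)) min(br) else Inf
      sw$ttp_ms[sw$label == "dim" & sw$t_abs_s < first_bright]
    }))
    mean(ttps, na.rm = TRUE)
  }, numeric(1))
}

#' Per-cell dim green/ultraviolet amplitude ratio across a cohort
#'
#' For each recording under the spectral protocol, measures the dim green
#' and dim ultraviolet flashes (equal photon strength) and forms their
#' amplitude ratio. Parabolic peak refinement (see [measure_response()])
#' avoids the downward ratio bias that extremum selection in noise would
#' otherwise introduce.
#'
#' @inheritParams cohort_dim_ttp
#' @return Numeric vector of per-cell ratios.
#' @export
cohort_guv_ratio <- function(recordings, refine_peak = TRUE, ...) {
  vapply(recordings, function(rec) {
    m <- analyze_recording(rec, refine_peak = refine_peak, ...)
    g <- m$amplitude_mV[m$label == "dim" & m$wavelength_nm == 520]
    u <- m$amplitude_mV[m$label == "dim" & m$wavelength_nm == 365]
    as.numeric(guv_ratio(mean(g), mean(u)))
  }, numeric(1))
}

#' Post-background recovery time of the rod dim-flash response
#'
#' Runs the background protocol analysis: dim-flash amplitudes measured
#' before the background epoch serve as the control level; the first
#' post-offset dim flash whose amplitude reaches `criterion` times the
#' control defines the recovery time.
#'
#' @param rec A `pr_recording` generated under [build_background_protocol()].
#' @param criterion Recovery criterion as a fraction of control. Default
#'   0.9.
#' @param ... Passed to [measure_response()].
#' @return A list with `recovery_min` (minutes after background offset,
#'   `NA` if the criterion is never met), `control_mV`, and the
#'   post-offset measurement table.
#' @export
background_recovery_time <- function(rec, criterion = 0.9, ...) {
  m <- analyze_recording(rec, ...)
  bg <- protocol_backgrounds_of(rec)
  stopifnot(nrow(bg) >= 1)
  t_on <- bg$t_on_s[1]
  t_off <- bg$t_off_s[1]
  dims <- m[m$label == "dim", , drop = FALSE]
  control <- mean(dims$amplitude_mV[dims$t_abs_s < t_on])
  post <- dims[dims$t_abs_s >= t_off, , drop = FALSE]
  post$t_after_off_min <- (post$t_abs_s - t_off) / 60
  hit <- which(post$amplitude_mV >= criterion * control)
  list(
    recovery_min = if (length(hit)) post$t_after_off_min[min(hit)] else NA_real_,
    control_mV = control,
    post = post
  )
}

# background epochs of the protocol a recording was generated under,
# recovered from the stimulus channels (so it also works for files read
# back from disk)
protocol_backgrounds_of <- function(rec) {
  find_epochs <- function(ch, wl) {
    # continuous (non-flash) illumination: runs much longer than a flash
    on <- ch > 0
    r <- rle(on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths > rec$fs_hz  # > 1 s of light
    if (!any(keep)) return(NULL)
    data.frame(wavelength_nm = wl,
               flux_ph_um2_s = vapply(which(keep), function(k) {
                 stats::median(ch[starts[k]:ends[k]])
               }, numeric(1)),
               t_on_s = rec$t_s[starts[keep]],
               t_off_s = rec$t_s[ends[keep]])
  }
  out <- rbind(find_epochs(rec$stim520_ph_um2_s, 520),
               find_epochs(rec$stim365_ph_um2_s, 365))
  if (is.null(out)) {
    out <- data.frame(wavelength_nm = numeric(0), flux_ph_um2_s = numeric(0),
                      t_on_s = numeric(0), t_off_s = numeric(0))
  }
  out
}
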
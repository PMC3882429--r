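test_that("box-car filter preserves constants and averages noise", {
  expect_equal(boxcar_filter(rep(3.5, 500), 5000), rep(3.5, 500))
  # unit impulse becomes a rectangle of height 1/k
  x <- numeric(1001)
  x[501] <- 1
  f <- boxcar_filter(x, 5000, 20)
  expect_equal(max(f), 1 / 100)
  expect_equal(sum(f > 0), 100)
  # white noise SD drops by sqrt(k) in the interior
  set.seed(3)
  n <- 50000
  f <- boxcar_filter(rnorm(n), 5000, 20)
  expect_equal(sd(f[200:(n - 200)]), 0.1, tolerance = 0.05)
  # linearity
  y <- rnorm(300)
  expect_equal(boxcar_filter(2 * y, 1000), 2 * boxcar_filter(y, 1000))
  expect_error(boxcar_filter(y, 10, 20), "one sample")
})

test_that("measurement round-trips a clean synthetic dim flash", {
  fs <- 5000
  t <- seq(0, 3, by = 1 / fs)
  v <- -42 + dim_flash_waveform(t - 1, 258, 1.0)
  rec <- structure(list(
    t_s = t, v_mV = v, stim520_ph_um2_s = numeric(length(t)),
    stim365_ph_um2_s = numeric(length(t)),
    events = flash_event(520, 16.6, 1), spec = NULL, fs_hz = fs,
    seed = 0, noise_sd_mV = 0, t_start_min = 0), class = "pr_recording")
  m <- measure_response(rec, 1)
  expect_equal(m$amplitude_mV, 1.0, tolerance = 5e-3)
  expect_equal(m$ttp_ms, 258, tolerance = 0.5)
  expect_identical(m$polarity, "hyperpolarizing")
  expect_equal(m$baseline_mV, -42)
  # linearity of the pipeline: scaling the trace scales the amplitude
  rec$v_mV <- -42 + 3 * (v + 42)
  m3 <- measure_response(rec, 1)
  expect_equal(m3$amplitude_mV, 3 * m$amplitude_mV, tolerance = 1e-9)
  expect_equal(m3$ttp_ms, m$ttp_ms)
})

test_that("a flat trace measures zero amplitude and flagged polarity", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  rec <- structure(list(
    t_s = t, v_mV = rep(-40, length(t)),
    stim520_ph_um2_s = numeric(length(t)),
    stim365_ph_um2_s = numeric(length(t)),
    events = flash_event(520, 16.6, 1), spec = NULL, fs_hz = fs,
    seed = 0, noise_sd_mV = 0, t_start_min = 0), class = "pr_recording")
  m <- measure_response(rec, 1)
  expect_equal(m$amplitude_mV, 0)
  expect_true(is.na(m$polarity))
  expect_error(measure_response(rec, flash_event(520, 16.6, 99)),
               "outside the trace")
})

test_that("depolarizing deflections are classified as such", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  v <- 20 - dim_flash_waveform(t - 1, 150, 4)  # reversed-polarity response
  rec <- structure(list(
    t_s = t, v_mV = v, stim520_ph_um2_s = numeric(length(t)),
    stim365_ph_um2_s = numeric(length(t)),
    events = flash_event(520, 3140, 1, label = "bright_b"), spec = NULL,
    fs_hz = fs, seed = 0, noise_sd_mV = 0, t_start_min = 0),
    class = "pr_recording")
  m <- measure_response(rec, 1)
  expect_identical(m$polarity, "depolarizing")
  expect_equal(m$amplitude_mV, 4, tolerance = 0.05)
})

test_that("normalization to the bright flash guards its precondition", {
  expect_equal(normalize_to_bright(c(1, 2), 2), c(0.5, 1))
  expect_equal(normalize_to_bright(2, 2), 1)
  expect_equal(normalize_to_bright(c(0, 0), 5), c(0, 0))
  expect_error(normalize_to_bright(1, 0), "undefined")
  expect_error(normalize_to_bright(1, NA), "undefined")
})

test_that("G/UV ratio handles saturating, preferring and absent responses", {
  expect_equal(guv_ratio(5, 5), 1)
  expect_equal(guv_ratio(5.4, 2), 2.7)
  expect_lt(guv_ratio(2, 5), 1)  # S-dominant intrinsic preference
  und <- guv_ratio(3, 0.1, noise_floor_mV = 0.45)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("recovery curve round-trips the generator's recovery model", {
  kin <- build_kinetics_protocol()
  sp <- cell_spec("rod", "loose_seal")
  r <- generate_recording(sp, kin, noise_sd_mV = 0, seed = 1)
  rc <- recovery_curve(analyze_recording(r))
  ctrl <- rc[is.na(rc$delay_s), ]
  post <- rc[!is.na(rc$delay_s), ]
  expect_equal(post$delay_s, c(1, 2.5, 4))
  # control point: dim amplitude over bright amplitude
  amp_dim <- amplitude_vs_intensity(16.6, sp$rod_kinetics)
  expect_equal(ctrl$amplitude_mV, rep(amp_dim, 3), tolerance = 0.01)
  # post-bright amplitudes follow control x fractional recovery
  fr <- fractional_recovery(c(1, 2.5, 4), sp$rod_kinetics)
  expect_equal(post$amplitude_mV, amp_dim * fr, tolerance = 0.1)
  # monotone increase across delays
  expect_true(all(diff(post$amplitude_mV) > 0))
  # uncoupled cone: all dim points at zero
  un <- cell_spec("cone", trajectory = trajectory_params(
    g0 = 0, g_max_pS = 0, rate_per_min = 0))
  rcu <- recovery_curve(analyze_recording(
    generate_recording(un, kin, noise_sd_mV = 0, seed = 1, fs_hz = 1000)))
  expect_true(all(rcu$norm_amplitude < 0.05))
})

test_that("Michaelis-Menten fit recovers exact and shifted parameters", {
  I <- c(3, 10, 30, 100, 300)
  R <- 25 * I / (I + 30)
  fit <- fit_michaelis_menten(I, R)
  expect_equal(fit$i_half, 30, tolerance = 1e-6)
  expect_equal(fit$r_max, 25, tolerance = 1e-6)
  # zero-amplitude row at I = 0 is tolerated
  fit0 <- fit_michaelis_menten(c(0, I), c(0, R))
  expect_equal(fit0$i_half, 30, tolerance = 1e-6)
  expect_error(fit_michaelis_menten(c(10, 10, 10), c(1, 1, 1)), "distinct")
  # independent nonlinear least-squares oracle on noisy data
  skip_if_not_installed("minpack.lm")
  set.seed(21)
  In <- 10^seq(0, 3, length.out = 9)
  Rn <- 25 * In / (In + 30) + rnorm(9, 0, 0.4)
  Rn <- pmax(Rn, 0)
  mine <- fit_michaelis_menten(In, Rn)
  orac <- minpack.lm::nlsLM(Rn ~ rmax * In / (In + ih),
                            start = list(rmax = 20, ih = 50))
  expect_equal(mine$i_half, coef(orac)[["ih"]], tolerance = 1e-4)
  expect_equal(mine$r_max, coef(orac)[["rmax"]], tolerance = 1e-4)
})

test_that("rank-sum test enumerates exactly and approximates for large n", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)
  expect_identical(r$method, "exact")
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  # agrees with the reference implementation where both are exact
  set.seed(14)
  for (i in 1:20) {
    a <- round(rnorm(5), 2)
    b <- round(rnorm(6), 2)
    mine <- mann_whitney(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    expect_equal(mine$U, unname(ref$statistic))
    if (!any(duplicated(c(a, b)))) {
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
  # exact and normal branches agree within 0.02 at combined n = 12
  set.seed(15)
  for (i in 1:20) {
    a <- rnorm(6)
    b <- rnorm(6)
    exact_p <- mann_whitney(a, b)$p_value
    approx_p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
  # large-sample branch tracks the reference normal approximation
  set.seed(16)
  a <- rnorm(15)
  b <- rnorm(18, 0.5)
  mine <- mann_whitney(a, b)
  expect_identical(mine$method, "normal_approximation")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("time-zero extrapolation recovers constant and lagged onsets", {
  ex <- extrapolate_initial_coupling(c(0.5, 1, 1.5, 2), rep(2.2, 4))
  expect_equal(ex$estimate_mV, 2.2)
  expect_true(ex$confident)
  # linear growth extrapolates to the intercept, floored at zero
  ex2 <- extrapolate_initial_coupling(c(0.5, 1, 1.5, 2),
                                      c(0.1, 0.6, 1.1, 1.6))
  expect_equal(ex2$estimate_mV, 0, tolerance = 1e-9)  # intercept -0.4 -> 0
  ex3 <- extrapolate_initial_coupling(c(3, 4, 5), c(1, 2, 3))
  expect_true(is.na(ex3$estimate_mV))
  expect_equal(ex3$n_early, 0)
})

test_that("time-zero extrapolation round-trips synthetic coupling onsets", {
  kin <- build_kinetics_protocol()
  measure_at <- function(spec, t_min) {
    vapply(t_min, function(tm) {
      r <- generate_recording(spec, kin, noise_sd_mV = 0, seed = 1,
                              fs_hz = 1000, t_start_min = tm)
      m <- analyze_recording(r)
      mean(m$amplitude_mV[m$label == "dim" & m$t_on_s == 1])
    }, numeric(1))
  }
  times <- c(0.25, 0.75, 1.25, 1.75)
  # late onset: amplitude stays near zero over the early window
  late <- cell_spec("cone", trajectory = trajectory_params(
    g0 = 0, g_max_pS = 3872, rate_per_min = 1.5, lag_min = 8))
  exl <- extrapolate_initial_coupling(times, measure_at(late, times))
  expect_lt(exl$estimate_mV, 0.1)
  # known initial coupling: estimate matches the true initial amplitude
  known <- cell_spec("cone", trajectory = trajectory_params(
    g0 = 0.4, g_max_pS = 3872, rate_per_min = 0.3, lag_min = 5))
  amps <- measure_at(known, times)
  exk <- extrapolate_initial_coupling(times, amps)
  true0 <- measure_at(known, 0)
  expect_equal(exk$estimate_mV, true0, tolerance = 0.1 * true0)
})
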
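# independent dense linear-solver oracle for the two-node network
oracle_solve <- function(e_os, e_leak, g_pc, g_lc, g_pr, g_lr, g_gj,
                         clamp) {
  if (clamp$mode == "voltage_clamp") {
    v_c <- clamp$v_hold_mV
    a <- matrix(g_pr + g_lr + g_gj, 1, 1)
    b <- g_pr * e_os + g_lr * e_leak + g_gj * v_c
    v_r <- solve(a, b)[1]
  } else {
    a <- matrix(c(g_pc + g_lc + g_gj, -g_gj,
                  -g_gj, g_pr + g_lr + g_gj), 2, 2, byrow = TRUE)
    b <- c(g_pc * e_os + g_lc * e_leak + clamp$i_inj_pA * 1e3,
           g_pr * e_os + g_lr * e_leak)
    v <- solve(a, b)
    v_c <- v[1]
    v_r <- v[2]
  }
  c(v_c = v_c, v_r = v_r)
}

kirchhoff_residuals <- function(params, st, g_pr_pool, g_pc, g_gj) {
  i_cone_branches <- (g_pc * (st$v_cone_mV - params$e_os_mV) +
    params$g_leak_cone_pS * (st$v_cone_mV - params$e_leak_mV)) * 1e-3
  i_rod_branches <- (g_pr_pool * (st$v_rod_mV - params$e_os_mV) +
    params$g_leak_rod_pool_pS * (st$v_rod_mV - params$e_leak_mV)) * 1e-3
  c(cone = st$i_pip_pA - i_cone_branches - st$i_gj_pA,
    rod = st$i_gj_pA - i_rod_branches)
}

test_that("summed junctional conductance gives exact and rounded values", {
  s <- summed_junctional_conductance(121, 32)
  expect_equal(s$exact_pS, 3872)
  expect_equal(s$rounded_pS, 3900)
  expect_equal(summed_junctional_conductance(121, 0)$exact_pS, 0)
  s25 <- summed_junctional_conductance(121, 25)
  expect_equal(s25$exact_pS, 3025)
  expect_equal(s25$rounded_pS, 3000)
  expect_error(summed_junctional_conductance(-1, 3), ">= 0")
})

test_that("junctional current follows g * dV in pA with the sign convention", {
  expect_equal(junctional_current(3900, 0, -4), 15.6)
  expect_equal(signif(junctional_current(3900, 0, -4), 2), 16)
  expect_equal(junctional_current(3872, 0, -4), 15.488)
  expect_equal(junctional_current(5000, -40, -40), 0)
  # positive current leaves the cone when the cone is more depolarized
  expect_gt(junctional_current(100, -30, -40), 0)
})

test_that("uncoupled current clamp reduces to the cone conductance divider", {
  p <- circuit_params(coupling = coupling_params(121, 0))
  st <- solve_steady_state(p)
  expected <- (p$g_photo_cone_dark_pS * p$e_os_mV +
                 p$g_leak_cone_pS * p$e_leak_mV) /
    (p$g_photo_cone_dark_pS + p$g_leak_cone_pS)
  expect_equal(st$v_cone_mV, expected)
  expect_equal(st$i_gj_pA, 0)
  expect_equal(st$v_cone_mV, -44)  # default calibration
})

test_that("default dark potentials sit at the calibrated values", {
  p <- circuit_params(coupling = coupling_params(0, 32))
  st <- solve_steady_state(p)
  expect_equal(st$v_cone_mV, -44)
  expect_equal(st$v_rod_mV, -40)
})

test_that("an enormous junctional conductance short-circuits the two nodes", {
  p <- circuit_params()
  st <- solve_steady_state(p, g_gj_pS = 1e12)
  expect_lt(abs(st$v_cone_mV - st$v_rod_mV), 1e-6)
  # the common voltage is the parallel-combination divider
  g_tot <- p$g_photo_cone_dark_pS + p$g_leak_cone_pS +
    p$g_photo_rod_pool_pS + p$g_leak_rod_pool_pS
  s_tot <- (p$g_photo_cone_dark_pS + p$g_photo_rod_pool_pS) * p$e_os_mV +
    (p$g_leak_cone_pS + p$g_leak_rod_pool_pS) * p$e_leak_mV
  expect_equal(st$v_cone_mV, s_tot / g_tot, tolerance = 1e-6)
})

test_that("steady-state solver matches the dense oracle on random draws", {
  set.seed(101)
  for (i in 1:200) {
    e_os <- runif(1, -10, 10)
    e_leak <- runif(1, -90, -40)
    g_pc <- runif(1, 10, 5000)
    g_lc <- runif(1, 10, 5000)
    g_pr <- runif(1, 10, 2000)
    g_lr <- runif(1, 10, 2000)
    n <- sample(1:50, 1)
    g_pair <- runif(1, 0, 300)
    clamp <- if (i %% 2 == 0) current_clamp(runif(1, -50, 50))
             else voltage_clamp(runif(1, -80, 70))
    p <- circuit_params(e_os, e_leak, g_pc, g_lc, g_pr, g_lr,
                        coupling_params(g_pair, n))
    st <- solve_steady_state(p, clamp = clamp)
    or <- oracle_solve(e_os, e_leak, g_pc, g_lc, g_pr * n, g_lr * n,
                       g_pair * n, clamp)
    expect_equal(st$v_cone_mV, unname(or["v_c"]), tolerance = 1e-9)
    expect_equal(st$v_rod_mV, unname(or["v_r"]), tolerance = 1e-9)
    res <- kirchhoff_residuals(p, st, g_pr * n, g_pc, g_pair * n)
    expect_true(all(abs(res) < 1e-9))
  }
})

test_that("voltage clamp holds the cone and balances the pipette current", {
  p <- circuit_params()
  st <- solve_steady_state(p, clamp = voltage_clamp(20))
  expect_identical(st$v_cone_mV, 20)
  res <- kirchhoff_residuals(p, st, p$g_photo_rod_pool_pS,
                             p$g_photo_cone_dark_pS, p$coupling$g_gj_pS)
  expect_true(all(abs(res) < 1e-9))
})

test_that("singular systems are rejected", {
  p <- circuit_params(g_photo_cone_dark_pS = 0, g_leak_cone_pS = 0,
                      g_photo_rod_dark_pS = 0, g_leak_rod_pS = 0,
                      coupling = coupling_params(0, 0))
  expect_error(solve_steady_state(p), "singular")
})

test_that("cone deflection is monotone in coupling and bounded by the rod", {
  p <- circuit_params()
  drive <- function(g_gj) {
    dark <- solve_steady_state(p, g_gj_pS = g_gj)
    lit <- solve_steady_state(p, p$g_photo_rod_pool_pS * 0.7, g_gj_pS = g_gj)
    c(cone = lit$v_cone_mV - dark$v_cone_mV,
      rod = lit$v_rod_mV - dark$v_rod_mV)
  }
  gs <- c(0, 10, 100, 500, 1000, 3872, 1e4, 1e5)
  d <- t(vapply(gs, drive, numeric(2)))
  expect_true(all(diff(abs(d[, "cone"])) >= 0))
  expect_true(all(abs(d[, "cone"]) <= abs(d[, "rod"]) + 1e-12))
  # the free rod deflection bounds the attenuation at 1
  att <- vapply(gs, function(g) coupling_attenuation(p, g), numeric(1))
  expect_true(all(att >= 0 & att <= 1))
  expect_true(all(diff(att) >= 0))
  expect_equal(coupling_attenuation(p, 0), 0)
})

test_that("polarity classification matches the simulated deflection signs", {
  set.seed(77)
  tol <- 0.5
  for (i in 1:60) {
    p <- circuit_params(
      e_os_mV = 0, e_leak_mV = runif(1, -80, -50),
      g_photo_cone_dark_pS = runif(1, 100, 1000),
      g_leak_cone_pS = runif(1, 100, 1500),
      g_photo_rod_dark_pS = runif(1, 100, 600),
      g_leak_rod_pS = runif(1, 100, 800),
      coupling = coupling_params(runif(1, 10, 400), 32)
    )
    i_inj <- runif(1, 0, 200)
    cl <- current_clamp(i_inj)
    dark <- solve_steady_state(p, clamp = cl)
    out <- classify_polarity(dark$v_rod_mV, p$e_os_mV, tol)
    dim_lit <- solve_steady_state(p, p$g_photo_rod_pool_pS * 0.9, clamp = cl)
    dim_defl <- dim_lit$v_cone_mV - dark$v_cone_mV
    if (out == "concordant_depolarizing") {
      expect_gt(dim_defl, 0)
    } else if (out == "opposite_polarities") {
      expect_lt(dim_defl, 0)
    }
    # the fast intrinsic component of a bright flash (cone photoconductance
    # closing) depolarizes a cone held beyond E_OS, whatever the rod state
    if (dark$v_cone_mV > p$e_os_mV + tol) {
      bright <- solve_steady_state(p,
                                   g_photo_cone_pS =
                                     p$g_photo_cone_dark_pS * 0.3,
                                   clamp = cl)
      expect_gt(bright$v_cone_mV - dark$v_cone_mV, 0)
    }
  }
})

test_that("all three polarity branches are reachable in simulation", {
  p <- circuit_params()
  tol <- 0.5
  # resting cone: rods sit well below E_OS -> opposite polarities (the
  # observed current-clamp case)
  rest <- solve_steady_state(p, clamp = current_clamp(0))
  expect_identical(classify_polarity(rest$v_rod_mV, 0, tol),
                   "opposite_polarities")
  # strong coupling and strong depolarizing injection pull the rods to and
  # beyond E_OS
  strong <- circuit_params(coupling = coupling_params(121 * 20, 32))
  # injection that lands the rod pool near E_OS -> dim responses null
  f <- function(i) solve_steady_state(strong,
                                      clamp = current_clamp(i))$v_rod_mV
  i_null <- uniroot(f, c(0, 5000))$root
  expect_identical(classify_polarity(f(i_null), 0, tol), "dim_null")
  # pushing further reaches the never-observed concordant branch
  expect_identical(classify_polarity(f(i_null * 2), 0, tol),
                   "concordant_depolarizing")
})

test_that("polarity branches split on the stated tolerance", {
  expect_identical(classify_polarity(-2, 0, 0.5), "opposite_polarities")
  expect_identical(classify_polarity(0, 0, 0.5), "dim_null")
  expect_identical(classify_polarity(3, 0, 0.5), "concordant_depolarizing")
  expect_identical(classify_polarity(0.4, 0, 0.5), "dim_null")
})

test_that("transjunctional gating defaults to unity and shapes a sigmoid", {
  expect_equal(transjunctional_gating(0), 1)
  expect_equal(transjunctional_gating(100), 1)  # disabled by default
  g <- gating_config(enabled = TRUE, v_half_mV = 40, floor = 0.5)
  expect_equal(transjunctional_gating(0, g), 1)
  expect_equal(transjunctional_gating(40, g), 0.75)
  expect_equal(transjunctional_gating(-40, g), 0.75)
  dv <- seq(0, 120, by = 5)
  f <- transjunctional_gating(dv, g)
  expect_true(all(diff(f) <= 0))
  expect_true(all(f > g$floor & f <= 1))
})
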
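#' Rod-cone junctional coupling parameters
#'
#' @param g_pair_pS Junctional conductance of one rod-cone pair (pS).
#' @param n_rods Rod-to-cone convergence (number of rods contacting the cone).
#' @return A list of class `coupling_params` with `g_pair_pS`, `n_rods` and
#'   the summed conductance `g_gj_pS = g_pair_pS * n_rods`.
#' @export
coupling_params <- function(g_pair_pS = 121, n_rods = 32) {
  stopifnot(g_pair_pS >= 0, n_rods >= 0, n_rods == round(n_rods))
  structure(
    list(g_pair_pS = g_pair_pS, n_rods = as.integer(n_rods),
         g_gj_pS = g_pair_pS * n_rods),
    class = "coupling_params"
  )
}

#' Summed junctional conductance of a cone's rod pool
#'
#' Product of the per-pair conductance and the rod-cone convergence, with a
#' two-significant-figure presentation value alongside the exact product.
#'
#' @inheritParams coupling_params
#' @return A list with `exact_pS` and `rounded_pS` (2 significant figures).
#' @export
#' @examples
#' summed_junctional_conductance(121, 32)  # 3872 exact, 3900 rounded
summed_junctional_conductance <- function(g_pair_pS, n_rods) {
  if (g_pair_pS < 0 || n_rods < 0) stop("conductance and convergence must be >= 0")
  exact <- g_pair_pS * n_rods
  list(exact_pS = exact, rounded_pS = signif(exact, 2))
}

#' Junctional current through the summed gap-junction conductance
#'
#' `i_GJ = g_GJ * (V_cone - V_rod)` with pS x mV giving fA, reported in pA.
#' Positive current flows out of the cone into the rod pool.
#'
#' @param g_gj_pS Summed junctional conductance (pS), >= 0.
#' @param v_cone_mV,v_rod_mV Cone and rod membrane potentials (mV).
#' @return Junctional current in pA.
#' @export
#' @examples
#' junctional_current(3900, 0, -4)  # 15.6 pA (~16 at 2 significant figures)
junctional_current <- function(g_gj_pS, v_cone_mV, v_rod_mV) {
  if (any(g_gj_pS < 0)) stop("g_gj_pS must be >= 0")
  g_gj_pS * (v_cone_mV - v_rod_mV) * 1e-3
}

#' Parameters of the coupled rod-cone equivalent circuit
#'
#' A cone node and a lumped rod-pool node, each with a light-sensitive
#' (photo) conductance reversing at `e_os_mV` and a leak conductance
#' reversing at `e_leak_mV`, joined by the summed junctional conductance.
#' Rod-pool conductances are per-rod values times the convergence.
#'
#' Defaults place the uncoupled dark potentials at -44 mV (cone) and
#' -40 mV (rod), with E_OS = 0 mV.
#'
#' @param e_os_mV Reversal potential of the light-sensitive conductance.
#' @param e_leak_mV Leak reversal potential.
#' @param g_photo_cone_dark_pS Cone dark photoconductance (pS).
#' @param g_leak_cone_pS Cone leak conductance (pS).
#' @param g_photo_rod_dark_pS Per-rod dark photoconductance (pS).
#' @param g_leak_rod_pS Per-rod leak conductance (pS).
#' @param coupling A [coupling_params()] object.
#' @return A list of class `circuit_params`. Rod-pool totals are in
#'   `g_photo_rod_pool_pS` and `g_leak_rod_pool_pS`.
#' @export
circuit_params <- function(e_os_mV = 0, e_leak_mV = -65,
                           g_photo_cone_dark_pS = 420, g_leak_cone_pS = 880,
                           g_photo_rod_dark_pS = 300, g_leak_rod_pS = 480,
                           coupling = coupling_params()) {
  stopifnot(g_photo_cone_dark_pS >= 0, g_leak_cone_pS >= 0,
            g_photo_rod_dark_pS >= 0, g_leak_rod_pS >= 0,
            inherits(coupling, "coupling_params"))
  n <- coupling$n_rods
  structure(
    list(
      e_os_mV = e_os_mV, e_leak_mV = e_leak_mV,
      g_photo_cone_dark_pS = g_photo_cone_dark_pS,
      g_leak_cone_pS = g_leak_cone_pS,
      g_photo_rod_dark_pS = g_photo_rod_dark_pS,
      g_leak_rod_pS = g_leak_rod_pS,
      g_photo_rod_pool_pS = g_photo_rod_dark_pS * n,
      g_leak_rod_pool_pS = g_leak_rod_pS * n,
      coupling = coupling
    ),
    class = "circuit_params"
  )
}

#' @rdname solve_steady_state
#' @param i_inj_pA Injected pipette current (pA).
#' @export
current_clamp <- function(i_inj_pA = 0) {
  structure(list(mode = "current_clamp", i_inj_pA = i_inj_pA),
            class = "clamp")
}

#' @rdname solve_steady_state
#' @param v_hold_mV Holding potential (mV).
#' @export
voltage_clamp <- function(v_hold_mV) {
  structure(list(mode = "voltage_clamp", v_hold_mV = v_hold_mV),
            class = "clamp")
}

#' Steady-state solution of the coupled rod-cone circuit
#'
#' Solves the two-node resistive network. In current clamp the pipette
#' injects `i_inj_pA` into the cone node; in voltage clamp the cone node is
#' held at `v_hold_mV` and the pipette current balances the cone node.
#' Kirchhoff's current law holds at both nodes. Units: pS, mV, pA
#' (pS x mV = fA, converted).
#'
#' @param params A [circuit_params()] object.
#' @param g_photo_rod_pool_pS Instantaneous rod-pool photoconductance (pS);
#'   defaults to the dark pool value. Light closes this conductance.
#' @param g_photo_cone_pS Instantaneous cone photoconductance (pS); defaults
#'   to the dark value.
#' @param clamp A [current_clamp()] or [voltage_clamp()] object.
#' @param g_gj_pS Junctional conductance override (pS); defaults to
#'   `params$coupling$g_gj_pS`.
#' @return A list of class `circuit_state` with `v_cone_mV`, `v_rod_mV`,
#'   `i_gj_pA` (positive from cone into rods) and `i_pip_pA`.
#' @export
solve_steady_state <- function(params,
                               g_photo_rod_pool_pS = params$g_photo_rod_pool_pS,
                               g_photo_cone_pS = params$g_photo_cone_dark_pS,
                               clamp = current_clamp(0),
                               g_gj_pS = params$coupling$g_gj_pS) {
  stopifnot(inherits(params, "circuit_params"), inherits(clamp, "clamp"),
            g_photo_rod_pool_pS >= 0, g_photo_cone_pS >= 0, g_gj_pS >= 0)
  e_os <- params$e_os_mV
  e_lk <- params$e_leak_mV
  g_c <- g_photo_cone_pS + params$g_leak_cone_pS      # cone-to-ground
  g_r <- g_photo_rod_pool_pS + params$g_leak_rod_pool_pS
  # source terms (fA): currents pulled toward the reversal potentials
  s_c <- g_photo_cone_pS * e_os + params$g_leak_cone_pS * e_lk
  s_r <- g_photo_rod_pool_pS * e_os + params$g_leak_rod_pool_pS * e_lk

  if (clamp$mode == "voltage_clamp") {
    v_c <- clamp$v_hold_mV
    if (g_gj_pS == 0) {
      # decoupled rod pool: its node solves (or vanishes) on its own
      v_r <- if (g_r > 0) s_r / g_r else NA_real_
      i_gj <- 0
    } else {
      v_r <- (s_r + g_gj_pS * v_c) / (g_r + g_gj_pS)
      i_gj <- g_gj_pS * (v_c - v_r) * 1e-3
    }
    # pipette balances all currents leaving the cone node
    i_pip <- ((g_photo_cone_pS * (v_c - e_os) +
                 params$g_leak_cone_pS * (v_c - e_lk)) * 1e-3) + i_gj
  } else {
    i_inj_fA <- clamp$i_inj_pA * 1e3
    b1 <- s_c + i_inj_fA
    b2 <- s_r
    if (g_gj_pS == 0) {
      if (g_c <= 0) stop("singular system: a node has no conductance to ground")
      v_c <- b1 / g_c
      v_r <- if (g_r > 0) b2 / g_r else NA_real_
      i_gj <- 0
    } else {
      # [g_c + g_gj, -g_gj; -g_gj, g_r + g_gj] [v_c; v_r] = [b1; b2]
      # determinant expanded to avoid cancellation at very large g_gj
      det <- g_c * g_r + g_gj_pS * (g_c + g_r)
      if (det <= 0) {
        stop("singular system: a node has no conductance to ground")
      }
      v_c <- ((g_r + g_gj_pS) * b1 + g_gj_pS * b2) / det
      v_r <- (g_gj_pS * b1 + (g_c + g_gj_pS) * b2) / det
      i_gj <- g_gj_pS * (v_c - v_r) * 1e-3
    }
    i_pip <- clamp$i_inj_pA
  }
  structure(
    list(v_cone_mV = v_c, v_rod_mV = v_r, i_gj_pA = i_gj, i_pip_pA = i_pip),
    class = "circuit_state"
  )
}

#' Quasi-static attenuation of a rod-pool voltage deflection seen at the cone
#'
#' Ratio of the steady-state cone deflection to the unloaded (g_GJ = 0)
#' rod-pool deflection for a small light-induced drop of the rod
#' photoconductance. Used by the synthetic-recording generator to scale the
#' rod-driven component of cone traces.
#'
#' @param params A [circuit_params()] object.
#' @param g_gj_pS Junctional conductance (pS).
#' @param frac_closure Fraction of the rod-pool dark photoconductance closed
#'   by the probe stimulus (small; linear circuit makes the ratio almost
#'   insensitive to it).
#' @return Attenuation factor in [0, 1].
#' @export
coupling_attenuation <- function(params, g_gj_pS, frac_closure = 0.05) {
  g_dark <- params$g_photo_rod_pool_pS
  g_lit <- g_dark * (1 - frac_closure)
  free0 <- solve_steady_state(params, g_dark, g_gj_pS = 0)
  free1 <- solve_steady_state(params, g_lit, g_gj_pS = 0)
  dv_free <- free1$v_rod_mV - free0$v_rod_mV
  if (dv_free == 0) return(0)
  c0 <- solve_steady_state(params, g_dark, g_gj_pS = g_gj_pS)
  c1 <- solve_steady_state(params, g_lit, g_gj_pS = g_gj_pS)
  (c1$v_cone_mV - c0$v_cone_mV) / dv_free
}

#' Classify the predicted dim/bright response-polarity outcome
#'
#' When a coupled cone is held depolarized beyond E_OS, the junctional
#' current depolarizes its rods beyond, at, or below E_OS; the dark rod
#' potential relative to E_OS determines the combination of dim and bright
#' flash response polarities.
#'
#' @param v_rod_dark_mV Dark rod-pool potential under the clamp (mV).
#' @param e_os_mV Reversal potential of the light-sensitive conductance.
#' @param tol_mV Non-negative tolerance (mV) around E_OS; default 0.5.
#' @return One of `"concordant_depolarizing"` (rods beyond E_OS; the
#'   never-observed branch), `"dim_null"` (rods at E_OS: dim response absent,
#'   bright reversed), `"opposite_polarities"` (rods below E_OS).
#' @export
classify_polarity <- function(v_rod_dark_mV, e_os_mV = 0, tol_mV = 0.5) {
  stopifnot(tol_mV >= 0)
  if (v_rod_dark_mV > e_os_mV + tol_mV) "concordant_depolarizing"
  else if (v_rod_dark_mV < e_os_mV - tol_mV) "opposite_polarities"
  else "dim_null"
}

#' Transjunctional voltage-gating configuration
#'
#' Cx36-type gap junctions reduce conductance under large transjunctional
#' voltage differentials. No quantitative gating curve is imposed by
#' default (`enabled = FALSE`, factor 1); when enabled, a symmetric
#' sigmoid with a conductance floor is applied.
#'
#' @param enabled Logical; default `FALSE`.
#' @param v_half_mV Half-attenuation voltage (mV), > 0.
#' @param floor Minimal relative conductance in [0, 1), default 0.5.
#' @param exponent Sigmoid steepness, > 0.
#' @return A list of class `gating_config`.
#' @export
gating_config <- function(enabled = FALSE, v_half_mV = 40, floor = 0.5,
                          exponent = 2) {
  stopifnot(v_half_mV > 0, floor >= 0, floor < 1, exponent > 0)
  structure(list(enabled = enabled, v_half_mV = v_half_mV, floor = floor,
                 exponent = exponent),
            class = "gating_config")
}

#' Transjunctional gating attenuation factor
#'
#' Monotone non-increasing in `|dv|`, equal to 1 at `dv = 0` and to the
#' midpoint between 1 and the floor at `|dv| = v_half_mV`.
#'
#' @param dv_mV Transjunctional voltage (mV); vectorized.
#' @param config A [gating_config()] object.
#' @return Attenuation factor(s) in (0, 1].
#' @export
transjunctional_gating <- function(dv_mV, config = gating_config()) {
  if (!config$enabled) return(rep(1, length(dv_mV)))
  x <- (abs(dv_mV) / config$v_half_mV)^config$exponent
  config$floor + (1 - config$floor) / (1 + x)
}
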
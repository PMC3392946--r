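#' State-vector layout for a buffering scheme
#'
#' The dynamical state of the model is `(V, h, n1, n3, k, Ca)` plus the
#' bound-buffer pools required by the active scheme: `PVCa`, `PVMg` for the
#' PV scheme, `BCa` for single-site buffers, nothing for `"none"`.
#' The instantaneous gates m and a are functions of V and are not state
#' variables.
#'
#' @param scheme a [buffer_scheme()].
#' @return Character vector of state names in integration order.
#' @export
state_names <- function(scheme) {
  base <- c("V", "h", "n1", "n3", "k", "Ca")
  switch(scheme$kind,
         pv = c(base, "PVCa", "PVMg"),
         slow = , fast = c(base, "BCa"),
         none = base)
}

#' Canonical initial state
#'
#' Builds a physiologically sensible starting state: gates at their
#' steady-state values for the given voltage, k at its steady state for
#' resting Ca2+, free Ca2+ at `Ca_rest`, and bound-buffer pools at chemical
#' equilibrium with (`Ca_rest`, `Mg_i`). The burn-in integration
#' ([equilibrate()]) then removes the residual electrical transient.
#'
#' @param params an [fs_params()] object.
#' @param scheme a [buffer_scheme()].
#' @param V starting membrane potential (mV).
#' @return Named state vector (see [state_names()]).
#' @export
initial_state <- function(params, scheme, V = -70) {
  g <- steady_state_gates(V, params)
  k <- sk_gate_kinetics(params$Ca_rest, params)$k_inf
  st <- c(V = V, h = g$h_inf, n1 = g$n1_inf, n3 = g$n3_inf, k = k,
          Ca = params$Ca_rest)
  occ <- equilibrium_occupancy(params$Ca_rest, params$Mg_i, scheme)
  if (scheme$kind == "pv")
    st <- c(st, PVCa = occ$bound_ca_uM, PVMg = occ$bound_mg_uM)
  else if (scheme$kind %in% c("slow", "fast"))
    st <- c(st, BCa = occ$bound_ca_uM)
  st
}

check_state <- function(state, scheme) {
  nm <- state_names(scheme)
  if (!all(nm %in% names(state)))
    stop("state must contain: ", paste(nm, collapse = ", "))
  x <- state[c("h", "n1", "n3", "k")]
  if (any(x < -1e-9) || any(x > 1 + 1e-9))
    stop("gating variables must lie in [0, 1]")
  if (state[["Ca"]] <= 0) stop("Ca must be > 0")
  if (scheme$kind == "pv") {
    if (state[["PVCa"]] < 0 || state[["PVMg"]] < 0 ||
        state[["PVCa"]] + state[["PVMg"]] > scheme$B_T * (1 + 1e-9))
      stop("PV pools must be >= 0 and sum to <= B_T")
  } else if (scheme$kind %in% c("slow", "fast")) {
    if (state[["BCa"]] < 0 || state[["BCa"]] > scheme$B_T * (1 + 1e-9))
      stop("BCa must lie in [0, B_T]")
  }
  invisible(state[nm])
}

#' Membrane currents at a given state
#'
#' Evaluates the six ionic currents, in the positive-outward convention
#' (`units: nS * mV = pA`):
#' \itemize{
#'   \item `I_Na  = g_Na  * m_inf(V)^3 * h * (V - V_Na)`
#'   \item `I_Kv1 = g_Kv1 * n1^4 * (V - V_K)`
#'   \item `I_Kv3 = g_Kv3 * n3^2 * (V - V_K)`
#'   \item `I_SK  = g_SK  * k^sk_exponent * (V - V_K)` (reference exponent 1)
#'   \item `I_Ca  = g_Ca  * a_inf(V)^2 * (V - V_Ca)`
#'   \item `I_leak = g_leak * (V - V_leak)`
#' }
#'
#' @param state named state vector with at least `V`, `h`, `n1`, `n3`, `k`.
#' @param params an [fs_params()] object.
#' @param gates optional precomputed [steady_state_gates()] output at `V`.
#' @return Named vector of the six currents (pA).
#' @examples
#' p <- fs_params()
#' s <- initial_state(p, buffer_scheme("none"))
#' ionic_currents(s, p)
#' @export
ionic_currents <- function(state, params, gates = NULL) {
  V <- state[["V"]]
  if (is.null(gates)) gates <- steady_state_gates(V, params)
  c(I_Na = params$g_Na * gates$m_inf^3 * state[["h"]] * (V - params$V_Na),
    I_Kv1 = params$g_Kv1 * state[["n1"]]^4 * (V - params$V_K),
    I_Kv3 = params$g_Kv3 * state[["n3"]]^2 * (V - params$V_K),
    I_SK = params$g_SK * state[["k"]]^params$sk_exponent * (V - params$V_K),
    I_Ca = params$g_Ca * gates$a_inf^2 * (V - params$V_Ca),
    I_leak = params$g_leak * (V - params$V_leak))
}

#' Full right-hand side of the model ODEs
#'
#' Reference (pure-R) implementation of the model vector field, mirroring the
#' compiled integrator core. Membrane equation:
#' `C_m dV/dt = -(I_Na + I_Kv1 + I_Kv3 + I_Ca + I_SK + I_leak) + I_app`;
#' gates h, n1, n3 follow `dx/dt = alpha_x(V)(1-x) - beta_x(V) x`; the SK
#' gate relaxes to `k_inf(Ca)` with time constant `tau_k(Ca)`
#' ([sk_gate_kinetics()]); calcium and buffer pools follow
#' [calcium_derivatives()].
#'
#' This function is used for equilibrium solving and Jacobian work in the
#' bifurcation tools, and as a cross-check of the compiled core; time
#' stepping goes through [fs_integrate()].
#'
#' @param state named state vector (see [state_names()]).
#' @param params an [fs_params()] object.
#' @param scheme a [buffer_scheme()].
#' @param I_app applied current (pA, positive depolarising).
#' @return Named vector of time derivatives (per ms).
#' @export
fs_rhs <- function(state, params, scheme, I_app = 0) {
  V <- state[["V"]]
  gates <- params$rates$gates
  ar <- function(g) rate_value(gates[[g]]$alpha, V)
  br <- function(g) rate_value(gates[[g]]$beta, V)
  am <- ar("m"); bm <- br("m")
  m_inf <- am / (am + bm)
  g <- list(m_inf = m_inf, a_inf = ca_activation_inf(V))
  I <- ionic_currents(state, params, gates = g)
  sk <- sk_gate_kinetics(state[["Ca"]], params)
  dca <- calcium_derivatives(state, I[["I_Ca"]], params, scheme)
  d <- c(
    V = (-sum(I) + I_app) / params$C_m,
    h = ar("h") * (1 - state[["h"]]) - br("h") * state[["h"]],
    n1 = ar("n1") * (1 - state[["n1"]]) - br("n1") * state[["n1"]],
    n3 = ar("n3") * (1 - state[["n3"]]) - br("n3") * state[["n3"]],
    k = (sk$k_inf - state[["k"]]) / sk$tau_k
  )
  c(d, dca)
}
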
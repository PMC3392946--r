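#' Model parameters for the FS interneuron
#'
#' Constructs the full parameter set of the fast-spiking interneuron model.
#' Defaults are the reference parameterisation of the model: conductances and
#' reversal potentials chosen to match the known FS membrane capacitance
#' (25--30 pF), input resistance (400 Mohm) and resting potential near -70 mV,
#' plus the calcium-shell geometry and SK gating constants.
#'
#' Units follow the standard convention for single-cell models: conductances
#' nS, potentials mV, currents pA (nS x mV = pA), capacitance pF, time ms,
#' concentrations uM, lengths um. With these, `C_m` in pF and currents in pA
#' give dV/dt directly in mV/ms.
#'
#' `K_SK`, the SK half-activation calcium concentration, is not a free
#' parameter: it is the ratio `k_off_sk / k_on_sk` of the two-state SK gating
#' scheme (0.2 / 0.4 = 0.5 uM by default) and is stored as a derived field.
#'
#' @param C_m membrane capacitance (pF).
#' @param g_Na,g_Kv1,g_Kv3,g_SK,g_Ca,g_leak maximal conductances (nS).
#' @param V_Na,V_K,V_Ca,V_leak reversal potentials (mV).
#' @param k_on_sk Ca2+ binding rate of the SK gating site (uM^-1 ms^-1).
#' @param k_off_sk Ca2+ unbinding rate of the SK gating site (ms^-1).
#' @param sk_exponent exponent of the SK gating variable in
#'   `I_SK = g_SK * k^sk_exponent * (V - V_K)`. The reference
#'   parameterisation uses 1 (the SK conductance proportional to the open
#'   fraction of the two-state gating scheme); the squared convention is
#'   available as `sk_exponent = 2`. See the methods vignette for the
#'   rationale.
#' @param gamma first-order Ca2+ clearance rate of the shell (ms^-1).
#' @param d submembrane shell thickness (um).
#' @param A cell surface area (um^2).
#' @param Ca_rest resting free Ca2+ concentration (uM).
#' @param Mg_i fixed intracellular Mg2+ concentration (uM); Mg2+ is held
#'   constant and is not a state variable.
#' @param F Faraday constant (C mol^-1).
#' @param literal_tau_k logical; if `TRUE` use the literal reciprocal form
#'   `tau_k = 1/(K_SK + Ca)` (value read as ms) for the SK gate relaxation
#'   time instead of the default mass-action form
#'   `1/(k_on_sk * Ca + k_off_sk)`. See [sk_gate_kinetics()].
#' @param rates gating-rate coefficient set for the h, n1, n3 (and m) gates,
#'   as returned by [load_gating_rates()]. Defaults to the coefficient file
#'   shipped with the package.
#'
#' @return An object of class `fs_params`: a named list of parameters with the
#'   derived field `K_SK` attached.
#' @examples
#' p <- fs_params()
#' p$K_SK            # 0.5 uM
#' input_resistance(p)  # 400 Mohm
#' @export
fs_params <- function(C_m = 30, g_Na = 700, g_Kv1 = 2, g_Kv3 = 300,
                      g_SK = 2, g_Ca = 30, g_leak = 2.5,
                      V_Na = 74, V_K = -90, V_Ca = 80, V_leak = -68,
                      k_on_sk = 0.4, k_off_sk = 0.2,
                      gamma = 1, d = 0.2, A = 3000,
                      Ca_rest = 0.07, Mg_i = 500, F = 96485,
                      literal_tau_k = FALSE, sk_exponent = 1,
                      rates = NULL) {
  p <- list(C_m = C_m, g_Na = g_Na, g_Kv1 = g_Kv1, g_Kv3 = g_Kv3,
            g_SK = g_SK, g_Ca = g_Ca, g_leak = g_leak,
            V_Na = V_Na, V_K = V_K, V_Ca = V_Ca, V_leak = V_leak,
            k_on_sk = k_on_sk, k_off_sk = k_off_sk,
            gamma = gamma, d = d, A = A,
            Ca_rest = Ca_rest, Mg_i = Mg_i, F = F,
            sk_exponent = sk_exponent,
            literal_tau_k = isTRUE(literal_tau_k))
  num <- p[setdiff(names(p), "literal_tau_k")]
  bad <- !vapply(num, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                 logical(1))
  if (any(bad))
    stop("non-finite or non-scalar parameter(s): ",
         paste(names(num)[bad], collapse = ", "))
  for (g in c("g_Na", "g_Kv1", "g_Kv3", "g_SK", "g_Ca", "g_leak"))
    if (p[[g]] < 0) stop("conductance ", g, " must be >= 0")
  if (p$C_m <= 0) stop("C_m must be > 0")
  if (p$d <= 0 || p$A <= 0) stop("shell geometry d, A must be > 0")
  if (p$gamma < 0) stop("gamma must be >= 0")
  if (p$Ca_rest <= 0) stop("Ca_rest must be > 0")
  if (p$Mg_i < 0) stop("Mg_i must be >= 0")
  if (p$k_on_sk <= 0 || p$k_off_sk <= 0) stop("SK rates must be > 0")
  if (p$sk_exponent <= 0) stop("sk_exponent must be > 0")
  p$K_SK <- p$k_off_sk / p$k_on_sk
  p$rates <- if (is.null(rates)) load_gating_rates() else rates
  class(p) <- "fs_params"
  p
}

#' @export
print.fs_params <- function(x, ...) {
  cat("FS interneuron model parameters\n")
  cat(sprintf("  conductances (nS): Na %g, Kv1 %g, Kv3 %g, SK %g, Ca %g, leak %g\n",
              x$g_Na, x$g_Kv1, x$g_Kv3, x$g_SK, x$g_Ca, x$g_leak))
  cat(sprintf("  reversals (mV): Na %g, K %g, Ca %g, leak %g; C_m %g pF\n",
              x$V_Na, x$V_K, x$V_Ca, x$V_leak, x$C_m))
  cat(sprintf("  SK: k_on %g uM^-1 ms^-1, k_off %g ms^-1 (K_SK %g uM)%s\n",
              x$k_on_sk, x$k_off_sk, x$K_SK,
              if (x$literal_tau_k) " [literal tau_k]" else ""))
  cat(sprintf("  shell: d %g um, A %g um^2 (vol %g um^3); gamma %g ms^-1; Ca_rest %g uM; Mg_i %g uM\n",
              x$d, x$A, x$A * x$d, x$gamma, x$Ca_rest, x$Mg_i))
  invisible(x)
}

#' Input resistance of the model at rest
#'
#' The model's input resistance is set by the leak conductance alone
#' (the voltage-gated conductances are essentially closed at rest), so
#' `R_in = 1 / g_leak`. With the default `g_leak = 2.5` nS this is 400 Mohm,
#' the experimental constraint the leak was chosen to match.
#'
#' @param params an [fs_params()] object.
#' @return Input resistance in Mohm.
#' @export
input_resistance <- function(params) {
  1000 / params$g_leak   # nS -> Mohm
}

#' Conversion factor from Ca2+ current to shell concentration rate
#'
#' A calcium current `I_Ca` (pA) entering the submembrane shell of volume
#' `A*d` (um^3) changes the free concentration at a rate
#' `-I_Ca / (2 F A d)` in uM/ms once units are collected: 1 pA = 1e-15 C/ms,
#' divided by 2F C/mol (two charges per ion) and by the shell volume in
#' litres (`A*d * 1e-15` L), times 1e6 uM/M. For the default shell
#' (600 um^3) the factor is about 8.637e-3 uM ms^-1 pA^-1.
#'
#' @param params an [fs_params()] object.
#' @return Scalar factor `phi` such that the influx term is `-phi * I_Ca`.
#' @export
ca_influx_factor <- function(params) {
  1e6 / (2 * params$F * params$A * params$d)
}
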
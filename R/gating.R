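#' Load the gating-rate coefficient set
#'
#' Reads the voltage-dependent opening/closing rate coefficients of the Na+
#' gates (m, h) and the delayed-rectifier gates (n1 for Kv1, n3 for Kv3) from
#' a JSON coefficient file. The model treats these rates as data: the shipped
#' file transcribes the fast-spiking interneuron kinetics of Erisir et
#' al. (1999) as corrected by Mancilla et al. (2007), and alternative sets can
#' be supplied in the same format.
#'
#' Each rate is one of four templates of the Hodgkin--Huxley tradition
#' (`V` in mV, result in ms^-1):
#' \describe{
#'   \item{linoid}{`C * (V - V_h) / (exp((V - V_h)/s) - 1)`, with the analytic
#'     limit `C * s` at the removable singularity `V = V_h`.}
#'   \item{exponential}{`C * exp((V - V_h)/s)`.}
#'   \item{sigmoid}{`C / (1 + exp(-(V - V_h)/s))`.}
#'   \item{constant}{`C`.}
#' }
#'
#' @param path path to a coefficient file; defaults to the file shipped in
#'   `inst/extdata/gating_rates.json`.
#' @return An object of class `fs_rates`: a named list of gates, each with
#'   `alpha` and `beta` template descriptions, plus the file's source string.
#' @export
load_gating_rates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gating_rates.json", package = "fsneuron",
                        mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gates <- raw$gates
  needed <- c("m", "h", "n1", "n3")
  if (!all(needed %in% names(gates)))
    stop("coefficient file must define gates: ", paste(needed, collapse = ", "))
  templates <- c("linoid", "exponential", "sigmoid", "constant")
  for (g in needed) {
    for (side in c("alpha", "beta")) {
      r <- gates[[g]][[side]]
      if (is.null(r$template) || !(r$template %in% templates))
        stop("gate ", g, " ", side, ": unknown template '", r$template, "'")
      if (!all(c("C", "s") %in% names(r)))
        stop("gate ", g, " ", side, ": missing coefficients")
      if (is.null(r$V_h)) gates[[g]][[side]]$V_h <- 0
    }
  }
  structure(list(gates = gates, source = raw$source %||% ""),
            class = "fs_rates")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a single rate template
#'
#' @param rate a list with `template`, `C`, `V_h`, `s` (one alpha or beta
#'   entry of an [load_gating_rates()] set).
#' @param V membrane potential (mV), vectorised.
#' @return Rate in ms^-1. Linoid singularities at `V = V_h` are resolved by
#'   the analytic limit `C * s`.
#' @export
rate_value <- function(rate, V) {
  C <- rate$C; Vh <- rate$V_h %||% 0; s <- rate$s
  switch(rate$template,
    linoid = {
      u <- (V - Vh) / s
      out <- numeric(length(V))
      sing <- abs(u) < 1e-7
      out[sing] <- C * s * (1 - u[sing] / 2)
      out[!sing] <- C * (V[!sing] - Vh) / (expm1(u[!sing]))
      out
    },
    exponential = C * exp((V - Vh) / s),
    sigmoid = C / (1 + exp(-(V - Vh) / s)),
    constant = rep(C, length(V))
  )
}

#' Steady-state values and time constants of the voltage-dependent gates
#'
#' For each gate x with rates alpha_x(V), beta_x(V), the steady state is
#' `x_inf = alpha/(alpha+beta)` and the time constant `tau_x = 1/(alpha+beta)`.
#' The Na+ activation gate m is instantaneous in the model (`m = m_inf(V)`),
#' so only its steady state is used. The HVA Ca2+ activation gate a is also
#' instantaneous, with the Boltzmann steady state
#' `a_inf = 1 / (1 + exp((-6 - V)/7.775))` (half-activation at -6 mV,
#' activating with depolarisation).
#'
#' @param V membrane potential (mV), vectorised.
#' @param params an [fs_params()] object (supplies the rate coefficient set).
#' @return List with `m_inf`, `a_inf`, `h_inf`, `n1_inf`, `n3_inf` and
#'   `tau_h`, `tau_n1`, `tau_n3` (ms).
#' @examples
#' g <- steady_state_gates(-6, fs_params())
#' g$a_inf  # 0.5 at the half-activation voltage
#' @export
steady_state_gates <- function(V, params) {
  stopifnot(all(is.finite(V)))
  gates <- params$rates$gates
  ab <- function(g) list(a = rate_value(gates[[g]]$alpha, V),
                         b = rate_value(gates[[g]]$beta, V))
  m <- ab("m"); h <- ab("h"); n1 <- ab("n1"); n3 <- ab("n3")
  list(
    m_inf = m$a / (m$a + m$b),
    a_inf = ca_activation_inf(V),
    h_inf = h$a / (h$a + h$b),
    n1_inf = n1$a / (n1$a + n1$b),
    n3_inf = n3$a / (n3$a + n3$b),
    tau_h = 1 / (h$a + h$b),
    tau_n1 = 1 / (n1$a + n1$b),
    tau_n3 = 1 / (n3$a + n3$b)
  )
}

#' @rdname steady_state_gates
#' @export
ca_activation_inf <- function(V) {
  1 / (1 + exp((-6 - V) / 7.775))
}

#' Activation time constant of the HVA Ca2+ current (documented variant)
#'
#' The model treats the HVA activation gate as instantaneous, so this time
#' constant never enters the default dynamics; it is provided for completeness
#' and for exploring a non-instantaneous variant through [fs_rhs()]'s
#' machinery at the user's own initiative. The published expression for this
#' quantity is typographically ambiguous in its operator grouping; the parse
#' implemented here reads it as the reciprocal of a sum of a saturating
#' exponential term and a linoid term,
#' `tau_a = 1 / (8.01 * exp(-0.072*(V - 5)) + 0.1*(V + 8.9)/(exp(0.2*(V + 8.9)) - 1))`,
#' which is positive over the physiological range. Treat it as indicative
#' only.
#'
#' @param V membrane potential (mV), vectorised.
#' @return Time constant (ms).
#' @export
ca_activation_tau <- function(V) {
  u <- 0.2 * (V + 8.9)
  lin <- ifelse(abs(u) < 1e-7, 0.5, 0.1 * (V + 8.9) / expm1(u))
  1 / (8.01 * exp(-0.072 * (V - 5)) + lin)
}

#' SK channel gating kinetics
#'
#' The SK activation gate k follows first-order two-state kinetics in free
#' Ca2+: `dk/dt = (k_inf - k)/tau_k` with `k_inf = Ca/(K_SK + Ca)` and, in
#' the mass-action form of the two-state scheme,
#' `tau_k = 1/(k_on_sk * Ca + k_off_sk)` where `K_SK = k_off_sk/k_on_sk`.
#' Setting `literal_tau_k = TRUE` in [fs_params()] replaces the relaxation
#' time by the simplified reciprocal `1/(K_SK + Ca)` (read as ms), a form
#' sometimes quoted for this scheme but dimensionally informal.
#'
#' @param Ca free Ca2+ concentration (uM), > 0; vectorised.
#' @param params an [fs_params()] object.
#' @return List with `k_inf` (dimensionless, in (0,1)) and `tau_k` (ms).
#' @examples
#' sk_gate_kinetics(0.5, fs_params())$k_inf  # 0.5 at Ca = K_SK
#' @export
sk_gate_kinetics <- function(Ca, params) {
  if (!is.numeric(Ca) || any(Ca <= 0)) stop("Ca must be > 0")
  k_inf <- Ca / (params$K_SK + Ca)
  tau_k <- if (params$literal_tau_k) 1 / (params$K_SK + Ca)
           else 1 / (params$k_on_sk * Ca + params$k_off_sk)
  list(k_inf = k_inf, tau_k = tau_k)
}
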
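#' Calcium buffering scheme
#'
#' Describes the buffering condition of the calcium shell. Four kinds are
#' supported:
#' \describe{
#'   \item{`"pv"`}{parvalbumin-like buffer: one class of sites for which Ca2+
#'     and Mg2+ compete. Because Ca2+ can only bind after the (slow) Mg2+
#'     unbinding, PV behaves as a slow buffer at rest even though its
#'     metal-free sites bind Ca2+ fast.}
#'   \item{`"slow"`}{single-site buffer with EGTA-like kinetics
#'     (k_on = 0.01 uM^-1 ms^-1, K_D = 0.1 uM).}
#'   \item{`"fast"`}{single-site buffer with the kinetics of metal-free PV,
#'     BAPTA-like (k_on = 0.1 uM^-1 ms^-1, K_D = 0.01 uM).}
#'   \item{`"none"`}{no buffer; the shell sees only influx and clearance.}
#' }
#'
#' For single-site buffers the unbinding rate is derived as
#' `k_off = k_on * K_D`. For PV the rates are primary and the affinities are
#' derived: `K_D_ca = k_off_ca/k_on_ca = 0.01` uM and
#' `K_D_mg = k_off_mg/k_on_mg = 0.03125/0.001 = 31.25` uM (commonly quoted
#' rounded to 31 uM).
#'
#' @param kind one of `"pv"`, `"slow"`, `"fast"`, `"none"`.
#' @param B_T total buffer concentration (uM). Default 1000 uM, the reference
#'   concentration used for the bifurcation analysis; physiological PV levels
#'   span roughly 1--1800 uM across interneuron types.
#' @param k_on_ca,k_off_ca Ca2+ binding/unbinding rates of PV
#'   (uM^-1 ms^-1, ms^-1).
#' @param k_on_mg,k_off_mg Mg2+ binding/unbinding rates of PV.
#' @param k_on,K_D binding rate and affinity of the single-site buffers.
#' @return An object of class `fs_buffer`: list with the kinetic constants and
#'   derived affinities for the chosen kind.
#' @examples
#' buffer_scheme("pv", B_T = 1000)
#' buffer_scheme("fast", B_T = 50)
#' @export
buffer_scheme <- function(kind = c("pv", "slow", "fast", "none"), B_T = 1000,
                          k_on_ca = 0.1, k_off_ca = 0.001,
                          k_on_mg = 0.0008, k_off_mg = 0.025,
                          k_on = NULL, K_D = NULL) {
  kind <- match.arg(tolower(kind[1L]), c("pv", "slow", "fast", "none"))
  if (!is.numeric(B_T) || length(B_T) != 1L || !is.finite(B_T) || B_T < 0)
    stop("B_T must be a finite scalar >= 0")
  s <- list(kind = kind, B_T = B_T)
  if (kind == "none") {
    s$B_T <- 0
  } else if (kind == "pv") {
    s$k_on_ca <- k_on_ca; s$k_off_ca <- k_off_ca
    s$k_on_mg <- k_on_mg; s$k_off_mg <- k_off_mg
    if (any(c(k_on_ca, k_off_ca, k_on_mg, k_off_mg) <= 0))
      stop("PV kinetic rates must be > 0")
    s$K_D_ca <- k_off_ca / k_on_ca
    s$K_D_mg <- k_off_mg / k_on_mg
  } else {
    if (is.null(k_on)) k_on <- if (kind == "fast") 0.1 else 0.01
    if (is.null(K_D)) K_D <- if (kind == "fast") 0.01 else 0.1
    if (k_on <= 0 || K_D <= 0) stop("k_on and K_D must be > 0")
    s$k_on <- k_on
    s$K_D <- K_D
    s$k_off <- k_on * K_D
  }
  class(s) <- "fs_buffer"
  s
}

#' @export
print.fs_buffer <- function(x, ...) {
  switch(x$kind,
    none = cat("Calcium buffer: none\n"),
    pv = cat(sprintf(
      "Calcium buffer: PV-like (Ca/Mg competition), B_T = %g uM\n  Ca: k_on %g, k_off %g (K_D %g uM); Mg: k_on %g, k_off %g (K_D %g uM)\n",
      x$B_T, x$k_on_ca, x$k_off_ca, x$K_D_ca, x$k_on_mg, x$k_off_mg, x$K_D_mg)),
    cat(sprintf(
      "Calcium buffer: %s single-site, B_T = %g uM (k_on %g uM^-1 ms^-1, K_D %g uM)\n",
      x$kind, x$B_T, x$k_on, x$K_D)))
  invisible(x)
}

#' Equilibrium buffer occupancy
#'
#' Fraction of buffer sites free, Ca2+-bound and (for PV) Mg2+-bound at
#' chemical equilibrium with fixed free Ca2+ and Mg2+. For PV the sites are
#' competitive single sites, so occupancies follow
#' `free : Ca-bound : Mg-bound = 1 : Ca/K_D_ca : Mg/K_D_mg`; for single-site
#' buffers the bound fraction is `Ca / (Ca + K_D)`.
#'
#' @param Ca free Ca2+ concentration (uM), > 0.
#' @param Mg free Mg2+ concentration (uM); ignored for non-PV schemes.
#' @param scheme a [buffer_scheme()].
#' @return List with `free`, `bound_ca`, `bound_mg` fractions (summing to 1)
#'   and the corresponding concentrations `free_uM`, `bound_ca_uM`,
#'   `bound_mg_uM`.
#' @examples
#' equilibrium_occupancy(0.07, 500, buffer_scheme("pv"))
#' @export
equilibrium_occupancy <- function(Ca, Mg = 0, scheme) {
  if (!is.numeric(Ca) || any(Ca <= 0)) stop("Ca must be > 0")
  if (any(Mg < 0)) stop("Mg must be >= 0")
  if (scheme$kind == "none") {
    out <- list(free = 1, bound_ca = 0, bound_mg = 0)
  } else if (scheme$kind == "pv") {
    w_ca <- Ca / scheme$K_D_ca
    w_mg <- Mg / scheme$K_D_mg
    z <- 1 + w_ca + w_mg
    out <- list(free = 1 / z, bound_ca = w_ca / z, bound_mg = w_mg / z)
  } else {
    b <- Ca / (Ca + scheme$K_D)
    out <- list(free = 1 - b, bound_ca = b, bound_mg = 0)
  }
  out$free_uM <- out$free * scheme$B_T
  out$bound_ca_uM <- out$bound_ca * scheme$B_T
  out$bound_mg_uM <- out$bound_mg * scheme$B_T
  out
}

#' Differential buffering capacity
#'
#' Diagnostic ratio `d[bound]/d[Ca]` at equilibrium: how many ions the buffer
#' absorbs per unit rise of free Ca2+. For a single-site buffer this is
#' `B_T * K_D / (Ca + K_D)^2`; for PV the effective dissociation constant is
#' raised by Mg2+ competition, `K_eff = K_D_ca * (1 + Mg/K_D_mg)`, giving
#' `B_T * K_eff / (Ca + K_eff)^2`. Zero when there is no buffer.
#'
#' @param Ca free Ca2+ concentration (uM), > 0.
#' @param scheme a [buffer_scheme()].
#' @param Mg free Mg2+ concentration (uM), used for PV only.
#' @return Dimensionless capacity, >= 0; vectorised over `Ca`.
#' @export
buffering_capacity <- function(Ca, scheme, Mg = 500) {
  if (!is.numeric(Ca) || any(Ca <= 0)) stop("Ca must be > 0")
  if (scheme$kind == "none" || scheme$B_T == 0) return(rep(0, length(Ca)))
  K <- if (scheme$kind == "pv") scheme$K_D_ca * (1 + Mg / scheme$K_D_mg)
       else scheme$K_D
  scheme$B_T * K / (Ca + K)^2
}

#' Calcium shell and buffer derivatives
#'
#' Right-hand side of the calcium balance of the submembrane shell: influx
#' through the HVA Ca2+ current (`-I_Ca / (2 F A d)`, positive for inward
#' current), first-order clearance towards `Ca_rest`, and mass-action exchange
#' with the buffer. Only Ca2+ binding withdraws free Ca2+; the PV Mg2+ pool
#' evolves (as sites are freed or taken) but does not enter the Ca2+ balance
#' because Mg2+ is held at a fixed concentration.
#'
#' @param state named state vector containing `Ca` and, depending on the
#'   scheme, `PVCa` and `PVMg` (PV) or `BCa` (single-site).
#' @param I_Ca calcium current (pA, positive outward).
#' @param params an [fs_params()] object.
#' @param scheme a [buffer_scheme()].
#' @return Named vector of derivatives (uM/ms) for `Ca` and the bound pools.
#' @export
calcium_derivatives <- function(state, I_Ca, params, scheme) {
  Ca <- state[["Ca"]]
  influx <- -I_Ca * ca_influx_factor(params)
  clear <- -params$gamma * (Ca - params$Ca_rest)
  if (scheme$kind == "none") {
    return(c(Ca = influx + clear))
  }
  if (scheme$kind == "pv") {
    PVCa <- state[["PVCa"]]; PVMg <- state[["PVMg"]]
    free <- scheme$B_T - PVCa - PVMg
    if (free < -1e-9 * max(scheme$B_T, 1))
      stop("negative free PV concentration: state corrupted")
    dPVCa <- scheme$k_on_ca * Ca * free - scheme$k_off_ca * PVCa
    dPVMg <- scheme$k_on_mg * params$Mg_i * free - scheme$k_off_mg * PVMg
    c(Ca = influx + clear - dPVCa, PVCa = dPVCa, PVMg = dPVMg)
  } else {
    BCa <- state[["BCa"]]
    free <- scheme$B_T - BCa
    if (free < -1e-9 * max(scheme$B_T, 1))
      stop("negative free buffer concentration: state corrupted")
    dBCa <- scheme$k_on * Ca * free - scheme$k_off * BCa
    c(Ca = influx + clear - dBCa, BCa = dBCa)
  }
}
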
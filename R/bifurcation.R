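# Equilibrium continuation, Hopf detection and SNLC location by simulation
# bisection. All equilibrium work uses the pure-R vector field (fs_rhs);
# trajectory classification uses the compiled integrator.

rhs_fixed <- function(params, scheme, I_app) {
  function(y) {
    st <- setNames(y, state_names(scheme))
    unname(fs_rhs(st, params, scheme, I_app = I_app))
  }
}

#' Finite-difference Jacobian of the vector field
#'
#' Central differences with a relative step of 1e-6 per component (absolute
#' floor 1e-9), evaluated at a point of the state space.
#'
#' @param f vector field `f(y)`.
#' @param y evaluation point.
#' @param rel_step relative finite-difference step.
#' @param abs_floor absolute step floor.
#' @return Square Jacobian matrix.
#' @keywords internal
numeric_jacobian <- function(f, y, rel_step = 1e-6, abs_floor = 1e-9) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- max(rel_step * abs(y[j]), abs_floor)
    yp <- y; yp[j] <- y[j] + h
    ym <- y; ym[j] <- y[j] - h
    J[, j] <- (f(yp) - f(ym)) / (2 * h)
  }
  J
}

newton_solve <- function(f, y0, tol = 1e-10, max_iter = 60) {
  y <- y0
  fy <- f(y)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(fy^2)) < tol) return(list(y = y, iter = it, ok = TRUE))
    J <- numeric_jacobian(f, y)
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step)) return(list(y = y, iter = it, ok = FALSE))
    lam <- 1
    repeat {  # damped: halve until the residual decreases
      y_new <- y + lam * step
      f_new <- tryCatch(f(y_new), error = function(e) rep(Inf, length(y)))
      if (all(is.finite(f_new)) &&
          sum(f_new^2) < sum(fy^2) * (1 - 1e-4 * lam) + 1e-300) break
      lam <- lam / 2
      if (lam < 1e-8) return(list(y = y, iter = it, ok = FALSE))
    }
    y <- y_new; fy <- f_new
  }
  list(y = y, iter = max_iter, ok = sqrt(sum(fy^2)) < tol)
}

# At an equilibrium every gate sits at its steady state and the buffer
# carries no net flux, so the shell calcium has the closed form
# Ca_eq = Ca_rest - phi * I_Ca(V) / gamma and the whole fixed-point problem
# reduces to one dimension: net membrane current F(V) = 0.
equilibrium_state_at_V <- function(V, params, scheme) {
  g <- steady_state_gates(V, params)
  I_Ca <- params$g_Ca * g$a_inf^2 * (V - params$V_Ca)
  Ca <- params$Ca_rest - ca_influx_factor(params) * I_Ca / params$gamma
  k <- sk_gate_kinetics(Ca, params)$k_inf
  st <- c(V = V, h = g$h_inf, n1 = g$n1_inf, n3 = g$n3_inf, k = k, Ca = Ca)
  occ <- equilibrium_occupancy(Ca, params$Mg_i, scheme)
  if (scheme$kind == "pv")
    st <- c(st, PVCa = occ$bound_ca_uM, PVMg = occ$bound_mg_uM)
  else if (scheme$kind %in% c("slow", "fast"))
    st <- c(st, BCa = occ$bound_ca_uM)
  st
}

#' Find an equilibrium of the model at fixed applied current
#'
#' Solves `f(y) = 0` for the full vector field at a fixed `I_app` and
#' attaches the local Jacobian eigenvalues (central finite differences).
#' Because all gates and buffer pools are slaved to `V` at a fixed point,
#' the solve reduces to robust 1-D root bracketing on the net membrane
#' current, expanding a bracket around the guess voltage; a damped-Newton
#' iteration on the full system is the fallback (and the only path when
#' `gamma = 0`, where the calcium closed form is unavailable). The
#' equilibrium is stable when every eigenvalue has negative real part.
#'
#' @param params an [fs_params()] object.
#' @param scheme a [buffer_scheme()].
#' @param I_app applied current (pA).
#' @param guess initial state guess; defaults to the canonical state at
#'   -67 mV. Only its voltage seeds the 1-D bracket.
#' @return Object of class `fs_equilibrium`: list with `I_app`, `state`,
#'   `eigenvalues` (complex, ms^-1), `stable`, `residual`.
#' @export
find_equilibrium <- function(params, scheme, I_app, guess = NULL) {
  if (is.null(guess)) guess <- initial_state(params, scheme, V = -67)
  f <- rhs_fixed(params, scheme, I_app)
  nm <- state_names(scheme)
  y <- NULL
  if (params$gamma > 0) {
    Fnet <- function(V) {
      st <- equilibrium_state_at_V(V, params, scheme)
      I_app - sum(ionic_currents(st, params))
    }
    V0 <- unname(guess[["V"]])
    lo <- V0 - 2; hi <- V0 + 2
    for (i in 1:12) {
      flo <- Fnet(lo); fhi <- Fnet(hi)
      if (is.finite(flo) && is.finite(fhi) && sign(flo) != sign(fhi)) break
      lo <- max(lo - 2^i, -150); hi <- min(hi + 2^i, 60)
    }
    if (sign(Fnet(lo)) != sign(Fnet(hi))) {
      V_star <- stats::uniroot(Fnet, c(lo, hi), tol = 1e-12)$root
      y <- unname(equilibrium_state_at_V(V_star, params, scheme))
    }
  }
  if (is.null(y)) {
    sol <- newton_solve(f, unname(guess[nm]))
    if (!sol$ok)
      stop(sprintf("equilibrium solve did not converge at I_app = %g pA",
                   I_app))
    y <- sol$y
  }
  J <- numeric_jacobian(f, y)
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(I_app = I_app, state = setNames(y, nm), eigenvalues = ev,
                 stable = max(Re(ev)) < 0,
                 residual = sqrt(sum(f(y)^2))),
            class = "fs_equilibrium")
}

#' @export
print.fs_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium at I_app = %g pA: V = %.3f mV, %s (max Re lambda = %.4g ms^-1)\n",
              x$I_app, x$state[["V"]], if (x$stable) "stable" else "unstable",
              max(Re(x$eigenvalues))))
  invisible(x)
}

#' Natural-parameter continuation of the equilibrium branch
#'
#' Sweeps `I_app` over a range, solving for the equilibrium at each value
#' with the previous solution as the Newton guess, and records voltage,
#' leading eigenvalue real part and stability along the branch. Failures at
#' individual currents are reported as gaps (NA rows), not silently skipped.
#'
#' @param params an [fs_params()] object.
#' @param scheme a [buffer_scheme()].
#' @param I_range `c(min, max)` applied current (pA).
#' @param step continuation step (pA), > 0.
#' @return Object of class `fs_branch`: data frame with `I_app`, `V`,
#'   `max_re_lambda`, `stable`, plus the list of equilibria as attribute
#'   `"equilibria"`.
#' @export
equilibrium_branch <- function(params, scheme, I_range = c(0, 120), step = 1) {
  if (step <= 0) stop("step must be > 0")
  I_grid <- seq(I_range[1], I_range[2], by = step)
  eq <- vector("list", length(I_grid))
  guess <- NULL
  rows <- data.frame(I_app = I_grid, V = NA_real_,
                     max_re_lambda = NA_real_, stable = NA)
  for (i in seq_along(I_grid)) {
    e <- tryCatch(find_equilibrium(params, scheme, I_grid[i], guess = guess),
                  error = function(err) NULL)
    if (is.null(e)) {
      warning(sprintf("continuation gap at I_app = %g pA", I_grid[i]))
      next
    }
    eq[[i]] <- e
    guess <- e$state
    rows$V[i] <- e$state[["V"]]
    rows$max_re_lambda[i] <- max(Re(e$eigenvalues))
    rows$stable[i] <- e$stable
  }
  structure(rows, equilibria = eq, class = c("fs_branch", "data.frame"))
}

#' Locate the Hopf bifurcation on the equilibrium branch
#'
#' Bisects `I_app` for the zero crossing of the maximal eigenvalue real part
#' of the equilibrium Jacobian. The equilibrium at each trial current is
#' found by Newton iteration continued from the nearest solved point. The
#' critical eigenvalue pair must be complex at the crossing (a Hopf
#' bifurcation, where a spiral equilibrium loses stability and periodic
#' solutions are born), otherwise a fold is flagged as an error.
#'
#' @param params an [fs_params()] object.
#' @param scheme a [buffer_scheme()].
#' @param I_range bracketing interval (pA); stability must differ at its ends.
#' @param tol bisection tolerance (pA).
#' @return The Hopf current `I_HB` (pA), with the critical equilibrium as
#'   attribute `"equilibrium"`.
#' @export
find_hopf <- function(params, scheme, I_range = c(0, 120), tol = 0.1) {
  # walk up the branch in moderate steps so Newton always has a close guess
  I_grid <- seq(I_range[1], I_range[2], length.out = 25)
  eqs <- vector("list", length(I_grid))
  eqs[[1]] <- find_equilibrium(params, scheme, I_grid[1])
  flip <- NULL
  for (i in seq_along(I_grid)[-1]) {
    eqs[[i]] <- find_equilibrium(params, scheme, I_grid[i],
                                 guess = eqs[[i - 1]]$state)
    if (sign(max(Re(eqs[[i]]$eigenvalues))) !=
        sign(max(Re(eqs[[i - 1]]$eigenvalues)))) {
      flip <- i
      break
    }
  }
  if (is.null(flip))
    stop("stability does not change over I_range; no Hopf point bracketed")
  I_range <- c(I_grid[flip - 1], I_grid[flip])
  f_lo <- max(Re(eqs[[flip - 1]]$eigenvalues))
  last <- eqs[[flip - 1]]
  while (diff(I_range) > tol) {
    mid <- mean(I_range)
    e <- find_equilibrium(params, scheme, mid, guess = last$state)
    last <- e
    if (sign(max(Re(e$eigenvalues))) == sign(f_lo)) I_range[1] <- mid
    else I_range[2] <- mid
  }
  ev <- last$eigenvalues
  crit <- ev[which.max(Re(ev))]
  if (abs(Im(crit)) < 1e-8)
    stop("critical eigenvalue is real: stability change is a fold, not a Hopf")
  structure(mean(I_range), equilibrium = last)
}

classify_oscillating <- function(params, scheme, I_app, init, settle_ms,
                                 dt, criterion = "regular", min_spikes = 2,
                                 cv_max = 0.05) {
  stim <- fs_stimulus(data.frame(duration = settle_ms, mode = "hold",
                                 start = I_app, end = I_app))
  traj <- fs_integrate(init, params, scheme, stim, dt = dt,
                       record_stride = 5L)
  sp <- detect_spikes(traj)
  late <- sp$times[sp$times >= settle_ms - 1000]
  if (criterion == "persistent") return(length(late) >= min_spikes)
  # regular: a settled periodic orbit, not sporadic/stuttering firing
  if (length(late) < 4) return(FALSE)
  isi <- diff(late)
  stats::sd(isi) / mean(isi) <= cv_max
}

#' Locate the onset of sustained periodic spiking (saddle-node of limit cycles)
#'
#' The stable large-amplitude periodic branch of the model appears at a
#' saddle-node of limit cycles (SNLC). This routine estimates the SNLC
#' current by bisection on a trajectory classification evaluated over the
#' final 1 s of a `settle_ms` integration (spikes = upward 0 mV crossings,
#' so small-amplitude subthreshold oscillations never count):
#' \describe{
#'   \item{`"regular"` (default)}{sustained spiking with regular interspike
#'     intervals (ISI coefficient of variation below `cv_max`). This detects
#'     the settled tonic limit cycle -- the object whose fold is the SNLC.
#'     Between the Hopf point and the SNLC the model can still fire sparse,
#'     irregular (stuttering-like) spikes, which this criterion deliberately
#'     excludes: those trajectories are not on a stable periodic orbit.}
#'   \item{`"persistent"`}{any spiking in the final second (at least
#'     `min_spikes` events). Bisection with this criterion instead finds the
#'     lower edge of the irregular-firing regime.}
#' }
#' Two initial conditions are used to expose hysteresis:
#' \itemize{
#'   \item a spiking state inherited from a run at the top of the range --
#'     the onset from this initialisation is the SNLC estimate, since the
#'     stable cycle is tracked down in current until it disappears;
#'   \item the near-equilibrium state (equilibrium perturbed by +0.5 mV) --
#'     classified with the `"persistent"` criterion, marking where quiescence
#'     or the small subthreshold attractor gives way to spiking.
#' }
#' The two thresholds bracket the window of coexisting behaviours.
#'
#' @param params an [fs_params()] object.
#' @param scheme a [buffer_scheme()].
#' @param I_range current range to search (pA); must span quiescent and
#'   spiking behaviour.
#' @param tol bisection tolerance (pA).
#' @param settle_ms integration length per classification (ms).
#' @param dt integration step (ms).
#' @param criterion `"regular"` or `"persistent"` (see above).
#' @param cv_max ISI coefficient-of-variation bound for `"regular"`.
#' @return List of class `fs_onset` with `I_osc_onset` (pA, SNLC estimate),
#'   `bracket` (`c(onset_spiking_init, onset_quiet_init)`) and the
#'   classification tables for both initialisations.
#' @export
find_oscillation_onset <- function(params, scheme, I_range = c(45, 100),
                                   tol = 0.5, settle_ms = 6000, dt = 0.01,
                                   criterion = c("regular", "persistent"),
                                   cv_max = 0.05) {
  criterion <- match.arg(criterion)
  # spiking initial condition inherited from the top of the range
  eq0 <- equilibrate(params, scheme, duration = 2000, dt = dt)
  stim_hi <- fs_stimulus(data.frame(duration = 2000, mode = "hold",
                                    start = I_range[2], end = I_range[2]))
  spiking_init <- final_state(
    fs_integrate(eq0, params, scheme, stim_hi, dt = dt))

  quiet_init_at <- function(I_app) {
    # walk the equilibrium up from 0 pA so Newton always has a close guess;
    # if the walk fails (strongly unstable branch), fall back to the
    # canonical near-rest state -- still a quiescent initial condition
    g <- tryCatch({
      steps <- seq(0, I_app, by = 2.5)
      if (steps[length(steps)] != I_app) steps <- c(steps, I_app)
      gg <- eq0
      for (s in steps)
        gg <- find_equilibrium(params, scheme, s, guess = gg)$state
      gg
    }, error = function(e) initial_state(params, scheme, V = -67))
    g[["V"]] <- g[["V"]] + 0.5
    g
  }

  bisect <- function(init_fun, crit) {
    lo <- I_range[1]; hi <- I_range[2]
    osc_lo <- classify_oscillating(params, scheme, lo, init_fun(lo),
                                   settle_ms, dt, crit, cv_max = cv_max)
    osc_hi <- classify_oscillating(params, scheme, hi, init_fun(hi),
                                   settle_ms, dt, crit, cv_max = cv_max)
    if (osc_lo == osc_hi)
      stop("classification identical across the whole range")
    trace <- data.frame(I_app = c(lo, hi), oscillating = c(osc_lo, osc_hi))
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      osc <- classify_oscillating(params, scheme, mid, init_fun(mid),
                                  settle_ms, dt, crit, cv_max = cv_max)
      trace <- rbind(trace, data.frame(I_app = mid, oscillating = osc))
      if (osc == osc_hi) hi <- mid else lo <- mid
    }
    list(onset = (lo + hi) / 2, trace = trace[order(trace$I_app), ])
  }

  from_spiking <- bisect(function(I) spiking_init, criterion)
  from_quiet <- tryCatch(bisect(quiet_init_at, "persistent"),
                         error = function(e) NULL)

  structure(list(
    I_osc_onset = from_spiking$onset,
    bracket = c(spiking_init = from_spiking$onset,
                quiet_init = if (is.null(from_quiet)) NA_real_
                             else from_quiet$onset),
    trace_spiking = from_spiking$trace,
    trace_quiet = if (is.null(from_quiet)) NULL else from_quiet$trace
  ), class = "fs_onset")
}

#' @export
print.fs_onset <- function(x, ...) {
  cat(sprintf("Oscillation onset (SNLC estimate): %.2f pA\n", x$I_osc_onset))
  cat(sprintf("  bracket: spiking init %.2f pA, near-equilibrium init %s pA\n",
              x$bracket[["spiking_init"]],
              format(x$bracket[["quiet_init"]], digits = 4)))
  invisible(x)
}

#' Full bifurcation report
#'
#' Combines the equilibrium branch, the Hopf point and the simulation-based
#' oscillation onset into one report of the model's class-2 excitability
#' structure: a stable equilibrium branch ending at a Hopf bifurcation
#' (I_HB), an unstable periodic branch, and large-amplitude periodic
#' spiking appearing at the SNLC (I_osc_onset > I_HB) at a non-zero
#' frequency.
#'
#' @inheritParams find_oscillation_onset
#' @param I_range current range (pA).
#' @param branch_step continuation step (pA).
#' @return List of class `fs_bifurcation`: `I_HB`, `I_osc_onset`,
#'   `bistability_bracket`, `branch` (the [equilibrium_branch()] table).
#' @export
bifurcation_report <- function(params, scheme, I_range = c(0, 120),
                               branch_step = 2, tol = 0.1,
                               settle_ms = 6000, dt = 0.01) {
  branch <- equilibrium_branch(params, scheme, I_range, step = branch_step)
  I_HB <- find_hopf(params, scheme, I_range, tol = tol)
  onset <- find_oscillation_onset(params, scheme,
                                  I_range = c(max(I_range[1], I_HB + 1),
                                              I_range[2]),
                                  tol = max(tol, 0.5), settle_ms = settle_ms,
                                  dt = dt)
  structure(list(I_HB = as.numeric(I_HB), I_osc_onset = onset$I_osc_onset,
                 bistability_bracket = onset$bracket, branch = branch,
                 onset = onset),
            class = "fs_bifurcation")
}

#' @export
print.fs_bifurcation <- function(x, ...) {
  cat("FS model bifurcation report\n")
  cat(sprintf("  Hopf bifurcation:          I_HB  = %.2f pA\n", x$I_HB))
  cat(sprintf("  Oscillation onset (SNLC):  I_osc = %.2f pA\n", x$I_osc_onset))
  cat(sprintf("  bistable window bracket:   [%.2f, %.2f] pA\n",
              min(x$bistability_bracket, na.rm = TRUE),
              max(x$bistability_bracket, na.rm = TRUE)))
  invisible(x)
}
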
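# packing helpers for the compiled core ---------------------------------

.pack_params <- function(params) {
  c(params$C_m, params$g_Na, params$g_Kv1, params$g_Kv3, params$g_SK,
    params$g_Ca, params$g_leak, params$V_Na, params$V_K, params$V_Ca,
    params$V_leak, params$k_on_sk, params$k_off_sk, params$gamma,
    params$d, params$A, params$Ca_rest, params$Mg_i, params$F,
    as.numeric(params$literal_tau_k), params$sk_exponent)
}

.template_code <- c(linoid = 0, exponential = 1, sigmoid = 2, constant = 3)

.pack_rates <- function(rates) {
  rows <- list()
  for (g in c("m", "h", "n1", "n3"))
    for (side in c("alpha", "beta")) {
      r <- rates$gates[[g]][[side]]
      rows[[length(rows) + 1L]] <-
        c(.template_code[[r$template]], r$C, r$V_h %||% 0, r$s)
    }
  do.call(rbind, rows)
}

.scheme_code <- c(none = 0L, pv = 1L, slow = 2L, fast = 3L)

.pack_scheme <- function(scheme) {
  switch(scheme$kind,
         none = numeric(5),
         pv = c(scheme$B_T, scheme$k_on_ca, scheme$k_off_ca,
                scheme$k_on_mg, scheme$k_off_mg),
         c(scheme$B_T, scheme$k_on, scheme$k_off, 0, 0))
}

#' Integrate the model with fixed-step RK4
#'
#' Runs the classic fourth-order Runge--Kutta scheme with a fixed step over
#' the full span of a stimulus, evaluating the applied current at the RK4
#' substep times. Integration is deterministic: the model has no stochastic
#' terms and identical inputs reproduce bitwise-identical trajectories.
#'
#' The default step `dt = 0.01` ms resolves the sub-millisecond action
#' potentials of the model comfortably (halving it leaves spike times
#' unchanged to well under 0.1 ms); samples are recorded every
#' `record_stride` steps (default 5, i.e. 50 us sampling).
#'
#' @param initial named initial state (see [initial_state()], [equilibrate()]).
#' @param params an [fs_params()] object.
#' @param scheme a [buffer_scheme()].
#' @param stim an [fs_stimulus()]; integration covers `[t0, t0 + duration]`.
#' @param dt integration step (ms).
#' @param record_stride record every this many steps.
#' @param t0 time of the first sample (ms); the stimulus is evaluated in the
#'   same clock.
#' @return An object of class `fs_trajectory`: list with `time` (ms), `state`
#'   (matrix, one column per state variable), `currents` (pA, columns I_Na,
#'   I_Kv1, I_Kv3, I_SK, I_Ca, I_leak), `iapp` (pA), and the run metadata
#'   (`dt`, `record_stride`, `params`, `scheme`, `stimulus`).
#' @examples
#' p <- fs_params(); b <- buffer_scheme("none")
#' stim <- build_protocol("step", 100, 200)
#' traj <- fs_integrate(initial_state(p, b), p, b, stim)
#' @export
fs_integrate <- function(initial, params, scheme, stim, dt = 0.01,
                         record_stride = 5L, t0 = 0) {
  initial <- check_state(initial, scheme)
  n_steps <- round(stim$duration / dt)
  if (abs(n_steps * dt - stim$duration) > 1e-6)
    n_steps <- ceiling(stim$duration / dt)
  res <- .cpp_integrate(unname(initial), t0, dt, as.integer(n_steps),
                        as.integer(record_stride), .pack_params(params),
                        .pack_rates(params$rates),
                        .scheme_code[[scheme$kind]], .pack_scheme(scheme),
                        stim_matrix_shifted(stim, t0))
  colnames(res$state) <- state_names(scheme)
  colnames(res$currents) <- c("I_Na", "I_Kv1", "I_Kv3", "I_SK", "I_Ca",
                              "I_leak")
  structure(list(time = res$time, state = res$state, currents = res$currents,
                 iapp = res$iapp, dt = dt, record_stride = record_stride,
                 params = params, scheme = scheme, stimulus = stim),
            class = "fs_trajectory")
}

stim_matrix_shifted <- function(stim, t0) {
  m <- stim_matrix(stim)
  m[, 1] <- m[, 1] + t0
  m[, 2] <- m[, 2] + t0
  m
}

#' Burn-in equilibration
#'
#' Integrates the model at a constant holding current (default 0 pA) for
#' `duration` ms (default 4000 ms, i.e. 4 s) starting from the canonical
#' initial state at -70 mV, and returns the final state. This removes the
#' transients of the arbitrary initial condition before a protocol is
#' applied; all protocol simulations are run from such a burn-in state.
#'
#' The residual vector-field norm at the returned state is attached as
#' attribute `"residual"`. A warning is issued when it exceeds `tol`, which
#' happens when the model fires spontaneously at the holding current (no
#' quiescent state exists there).
#'
#' @param params an [fs_params()] object.
#' @param scheme a [buffer_scheme()].
#' @param hold_current holding current during the burn-in (pA).
#' @param duration burn-in length (ms).
#' @param dt integration step (ms).
#' @param tol residual-norm threshold for the convergence warning.
#' @return Named state vector with attribute `residual`.
#' @export
equilibrate <- function(params, scheme, hold_current = 0, duration = 4000,
                        dt = 0.01, tol = 1e-4) {
  if (duration <= 0) stop("duration must be > 0")
  stim <- fs_stimulus(data.frame(duration = duration, mode = "hold",
                                 start = hold_current, end = hold_current))
  traj <- fs_integrate(initial_state(params, scheme), params, scheme, stim,
                       dt = dt, record_stride = max(1L, round(1 / dt)))
  st <- final_state(traj)
  res <- sqrt(sum(fs_rhs(st, params, scheme, I_app = hold_current)^2))
  if (res > tol)
    warning(sprintf(
      "burn-in did not settle (residual %.3g): spontaneous activity at %g pA?",
      res, hold_current))
  attr(st, "residual") <- res
  st
}

#' @rdname fs_integrate
#' @param traj an `fs_trajectory`.
#' @export
final_state <- function(traj) {
  setNames(traj$state[nrow(traj$state), ], colnames(traj$state))
}

#' @export
print.fs_trajectory <- function(x, ...) {
  cat(sprintf(
    "FS model trajectory: %d samples over %g ms (dt %g ms, stride %d)\n",
    length(x$time), x$time[length(x$time)] - x$time[1], x$dt,
    x$record_stride))
  cat(sprintf("  scheme %s (B_T = %g uM); V range [%.1f, %.1f] mV; Ca range [%.4f, %.4f] uM\n",
              x$scheme$kind, x$scheme$B_T, min(x$state[, "V"]),
              max(x$state[, "V"]), min(x$state[, "Ca"]),
              max(x$state[, "Ca"])))
  invisible(x)
}

#' @export
summary.fs_trajectory <- function(object, threshold = 0, ...) {
  sp <- detect_spikes(object, threshold = threshold)
  win <- range(object$time)
  structure(list(
    n_samples = length(object$time),
    span_ms = diff(win),
    n_spikes = length(sp$times),
    mean_frequency_hz = mean_frequency(sp, win),
    V_range = range(object$state[, "V"]),
    Ca_range = range(object$state[, "Ca"])
  ), class = "summary.fs_trajectory")
}

#' @export
print.summary.fs_trajectory <- function(x, ...) {
  cat(sprintf("%d samples over %g ms; %d spikes (%.2f Hz over the span)\n",
              x$n_samples, x$span_ms, x$n_spikes, x$mean_frequency_hz))
  cat(sprintf("V in [%.1f, %.1f] mV; Ca in [%.4f, %.4f] uM\n",
              x$V_range[1], x$V_range[2], x$Ca_range[1], x$Ca_range[2]))
  invisible(x)
}

#' @export
as.data.frame.fs_trajectory <- function(x, ...) {
  df <- data.frame(time_ms = x$time, x$state, x$currents,
                   Iapp_pA = x$iapp, check.names = FALSE)
  names(df)[match(c("V", "Ca"), names(df))] <- c("V_mV", "Ca_uM")
  df
}

#' @export
plot.fs_trajectory <- function(x, what = c("V", "Ca", "I_SK"), ...) {
  what <- match.arg(what)
  y <- switch(what, V = x$state[, "V"], Ca = x$state[, "Ca"],
              I_SK = x$currents[, "I_SK"])
  ylab <- switch(what, V = "V (mV)", Ca = "[Ca2+]i (uM)", I_SK = "I_SK (pA)")
  graphics::plot(x$time, y, type = "l", xlab = "time (ms)", ylab = ylab, ...)
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' One row per recorded sample with columns `time_ms`, the state variables,
#' the six membrane currents (pA) and `Iapp_pA`. A `#`-prefixed header line
#' records dt, stride, scheme and a hash of the parameter set for provenance.
#'
#' @param traj an `fs_trajectory`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  hdr <- sprintf("# fsneuron trajectory; dt=%g ms; stride=%d; scheme=%s; B_T=%g uM; params_hash=%s",
                 traj$dt, traj$record_stride, traj$scheme$kind,
                 traj$scheme$B_T, params_hash(traj$params))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

params_hash <- function(params) {
  v <- .pack_params(params)
  h <- 0
  for (x in v) h <- (h * 31 + abs(x) %% 1e6) %% 2147483647
  sprintf("%08x", as.integer(h))
}
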
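#' Detect spikes in a voltage trajectory
#'
#' A spike is an upward crossing of a voltage threshold (default 0 mV); the
#' spike time is obtained by linear interpolation between the samples
#' bracketing the crossing. Crossings closer than `refractory` ms (default
#' 1 ms) to the previous accepted spike are discarded, which suppresses
#' double counts from sampling noise without ever merging genuine FS spikes
#' (interspike intervals in this model are > 5 ms).
#'
#' @param traj an `fs_trajectory` (from [fs_integrate()]).
#' @param threshold detection threshold (mV).
#' @param refractory minimal separation between spikes (ms).
#' @return An object of class `fs_spikes`: list with `times` (ms), `window`
#'   (the trajectory span), `threshold`, `refractory`.
#' @export
detect_spikes <- function(traj, threshold = 0, refractory = 1) {
  t <- traj$time
  V <- traj$state[, "V"]
  if (length(t) < 2) stop("trajectory too short")
  up <- which(V[-length(V)] < threshold & V[-1] >= threshold)
  times <- t[up] + (threshold - V[up]) / (V[up + 1] - V[up]) * (t[up + 1] - t[up])
  if (length(times) > 1) {
    # refractory is relative to the last *accepted* spike
    acc <- times[1]
    for (i in seq_along(times)[-1])
      if (times[i] - acc[length(acc)] >= refractory) acc <- c(acc, times[i])
    times <- acc
  }
  structure(list(times = times, window = range(t), threshold = threshold,
                 refractory = refractory),
            class = "fs_spikes")
}

#' @export
print.fs_spikes <- function(x, ...) {
  cat(sprintf("%d spikes in [%g, %g] ms (threshold %g mV)\n",
              length(x$times), x$window[1], x$window[2], x$threshold))
  invisible(x)
}

#' Mean firing frequency over a window
#'
#' The mean frequency is the number of spikes falling inside the window
#' divided by the window duration (so 31 spikes during a 1 s stimulus is
#' 31 Hz). The alternative interval-based estimate
#' `(N - 1) / (t_N - t_1)` is available with `method = "isi"`.
#'
#' @param spikes an [detect_spikes()] result, or a numeric vector of spike
#'   times (ms).
#' @param window `c(start, end)` in ms; spikes with `start <= t < end` are
#'   counted.
#' @param method `"count"` (default) or `"isi"`.
#' @return Frequency in Hz.
#' @export
mean_frequency <- function(spikes, window, method = c("count", "isi")) {
  method <- match.arg(method)
  times <- if (inherits(spikes, "fs_spikes")) spikes$times else spikes
  if (diff(window) <= 0) stop("window must have positive length")
  inside <- times[times >= window[1] & times < window[2]]
  if (method == "count") return(length(inside) / diff(window) * 1000)
  if (length(inside) < 2) return(0)
  (length(inside) - 1) / (inside[length(inside)] - inside[1]) * 1000
}

#' Interspike calcium and SK-current envelopes
#'
#' For each pair of consecutive spikes, extracts the extrema of free Ca2+
#' and of the SK current over the interval, plus the buffer Ca2+ occupancy
#' at the Ca2+ minimum. The sequence of per-interval Ca2+ minima is the
#' lower envelope of the calcium transients -- the residual calcium that
#' drives SK channels between action potentials -- and the maxima form the
#' upper envelope.
#'
#' Maxima are taken over the half-open interval `[t_i, t_{i+1})` (so the
#' post-spike transient peak is attributed to its spike) and minima over the
#' open interval, evaluated on the recorded samples.
#'
#' @param traj an `fs_trajectory`.
#' @param spikes an [detect_spikes()] result for `traj` (computed if `NULL`).
#' @return Data frame of class `fs_envelopes`, one row per interspike
#'   interval: `t_start`, `t_end` (ms), `ca_min`, `ca_max` (uM), `isk_min`,
#'   `isk_max` (pA), `occupancy` (bound-Ca fraction of B_T at the Ca
#'   minimum; `NA` for the unbuffered scheme).
#' @export
extract_envelopes <- function(traj, spikes = NULL) {
  if (is.null(spikes)) spikes <- detect_spikes(traj)
  st <- spikes$times
  if (length(st) < 2) stop("need at least 2 spikes to form interspike intervals")
  t <- traj$time
  Ca <- traj$state[, "Ca"]
  ISK <- traj$currents[, "I_SK"]
  BT <- traj$scheme$B_T
  bound_ca <- if (traj$scheme$kind == "pv") traj$state[, "PVCa"]
              else if (traj$scheme$kind %in% c("slow", "fast")) traj$state[, "BCa"]
              else NULL
  n <- length(st) - 1
  out <- data.frame(t_start = st[-length(st)], t_end = st[-1],
                    ca_min = NA_real_, ca_max = NA_real_,
                    isk_min = NA_real_, isk_max = NA_real_,
                    occupancy = NA_real_)
  for (i in seq_len(n)) {
    closed <- which(t >= st[i] & t < st[i + 1])
    open <- which(t > st[i] & t < st[i + 1])
    if (length(open) == 0) next
    imin <- open[which.min(Ca[open])]
    out$ca_min[i] <- Ca[imin]
    out$ca_max[i] <- max(Ca[closed])
    out$isk_min[i] <- min(ISK[open])
    out$isk_max[i] <- max(ISK[open])
    if (!is.null(bound_ca) && BT > 0) out$occupancy[i] <- bound_ca[imin] / BT
  }
  class(out) <- c("fs_envelopes", class(out))
  out
}

#' Steady-state plateau window of a calcium envelope
#'
#' During a sustained train the lower calcium envelope rises and then
#' settles on a plateau where influx and clearance balance. This function
#' returns the earliest time window from which consecutive lower-envelope
#' values keep changing by less than `rel_tol` (relative, default 1%)
#' through the end of the train. If no such window exists a warning is
#' issued and the fixed convention window (see [plateau_preset()]) is
#' returned.
#'
#' @param envelopes an [extract_envelopes()] result.
#' @param rel_tol relative per-interval tolerance.
#' @param preset fallback window (ms) when no plateau is found.
#' @return `c(start, end)` in ms, with attribute `"interval_index"` giving
#'   the first plateau interval (NA if the preset was used).
#' @export
plateau_window <- function(envelopes, rel_tol = 0.01, preset = NULL) {
  lo <- envelopes$ca_min
  if (length(lo) == 0) stop("empty envelope sequence")
  ok <- abs(diff(lo)) < rel_tol * abs(lo[-length(lo)])
  # first index from which all subsequent consecutive changes are small
  start_idx <- NA_integer_
  if (length(ok) > 0) {
    run <- rev(cumprod(rev(ok)))  # 1 where all later diffs are small
    hit <- which(run == 1)
    if (length(hit) > 0) start_idx <- hit[1]
  } else start_idx <- 1L
  if (is.na(start_idx)) {
    if (is.null(preset))
      preset <- c(envelopes$t_start[1], envelopes$t_end[nrow(envelopes)])
    warning("no steady-state plateau found; returning preset window")
    return(structure(preset, interval_index = NA_integer_))
  }
  structure(c(envelopes$t_start[start_idx], envelopes$t_end[nrow(envelopes)]),
            interval_index = start_idx)
}

#' Fixed plateau convention for 5-s trains
#'
#' The reporting convention for steady-state interspike statistics during a
#' 5-s train: the 4th and 5th second of the stimulus, i.e.
#' `stimulus onset + c(4000, 5000)` ms.
#'
#' @param stim an [fs_stimulus()] built by [build_protocol()] (uses its
#'   onset attribute), or a numeric stimulus-onset time in ms.
#' @return `c(start, end)` in ms.
#' @export
plateau_preset <- function(stim = 0) {
  onset <- if (inherits(stim, "fs_stimulus")) attr(stim, "onset") %||% 0
           else stim
  onset + c(4000, 5000)
}

#' Interspike statistics over a window
#'
#' Summarises the interspike calcium and SK-current levels over the
#' intervals fully contained in a window (typically the steady-state plateau
#' window). Calcium extrema come from [extract_envelopes()]. SK-current
#' levels are evaluated on the slow (subthreshold) segment of each interval:
#' the action-potential waveforms are excised by the standard rate-of-rise
#' criterion, keeping the largest contiguous run of samples with
#' `|dV/dt| <= dvdt_max` (default 5 mV/ms). On this segment `isk_max_mean`
#' is the level the slowly evolving interspike SK current reaches just
#' before the next spike takes off, `isk_min_mean` its minimum, and
#' `isk_median` the pooled median level across all interspike samples.
#'
#' The segment delimiter matters only for the pre-spike maximum: moving
#' `dvdt_max` from 5 to 10 mV/ms lets the segment reach a few mV further up
#' the spike foot and raises `isk_max_mean` by roughly 5--10%.
#'
#' @param traj an `fs_trajectory`.
#' @param window `c(start, end)` in ms.
#' @param spikes optional precomputed [detect_spikes()].
#' @param dvdt_max rate-of-rise bound delimiting the slow segment (mV/ms).
#' @return List with `ca_min_mean`, `ca_max_mean`, `isk_min_mean`,
#'   `isk_max_mean`, `isk_median`, `occupancy_mean`, `n_intervals`.
#' @export
interspike_stats <- function(traj, window, spikes = NULL, dvdt_max = 5) {
  if (is.null(spikes)) spikes <- detect_spikes(traj)
  env <- extract_envelopes(traj, spikes)
  inwin <- env$t_start >= window[1] & env$t_end <= window[2]
  if (!any(inwin)) stop("no complete interspike interval inside the window")
  env <- env[inwin, , drop = FALSE]
  t <- traj$time
  V <- traj$state[, "V"]
  ISK <- traj$currents[, "I_SK"]
  dVdt <- c(0, diff(V) / diff(t))
  seg_stats <- lapply(seq_len(nrow(env)), function(i) {
    sel <- which(t > env$t_start[i] & t < env$t_end[i] &
                   abs(dVdt) <= dvdt_max)
    if (length(sel) == 0) return(NULL)
    runs <- split(sel, cumsum(c(1, diff(sel) != 1)))
    main <- runs[[which.max(lengths(runs))]]
    list(min = min(ISK[main]), max = max(ISK[main]), samples = ISK[main])
  })
  seg_stats <- Filter(Negate(is.null), seg_stats)
  if (length(seg_stats) == 0) stop("no subthreshold interspike segments found")
  list(ca_min_mean = mean(env$ca_min), ca_max_mean = mean(env$ca_max),
       isk_min_mean = mean(vapply(seg_stats, `[[`, numeric(1), "min")),
       isk_max_mean = mean(vapply(seg_stats, `[[`, numeric(1), "max")),
       isk_median = median(unlist(lapply(seg_stats, `[[`, "samples"))),
       occupancy_mean = mean(env$occupancy),
       n_intervals = nrow(env))
}

#' Firing frequency as a function of buffer concentration
#'
#' Runs the full pipeline (burn-in, stimulus, spike detection, mean
#' frequency over the stimulus window) for each total buffer concentration
#' and returns a tidy table. The central regulatory result of the model is
#' that this relationship is non-increasing: more buffer means higher
#' residual interspike Ca2+, stronger SK activation, longer AHPs and lower
#' firing rates.
#'
#' @param params an [fs_params()] object.
#' @param scheme_kind `"pv"`, `"slow"` or `"fast"`.
#' @param concentrations total buffer concentrations (uM), >= 0.
#' @param protocol an [fs_stimulus()]; default 5-s 100-pA step.
#' @param burn_in_ms burn-in duration before the protocol (ms).
#' @param dt integration step (ms).
#' @return Data frame with columns `scheme`, `B_T`, `frequency_Hz`.
#' @export
frequency_vs_concentration <- function(params, scheme_kind = "pv",
                                       concentrations,
                                       protocol = build_protocol("step", 100, 5000),
                                       burn_in_ms = 4000, dt = 0.01) {
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  freq <- vapply(concentrations, function(bt) {
    scheme <- if (bt == 0) buffer_scheme("none")
              else buffer_scheme(scheme_kind, B_T = bt)
    st <- equilibrate(params, scheme, duration = burn_in_ms, dt = dt)
    traj <- fs_integrate(st, params, scheme, protocol, dt = dt)
    win <- c(attr(protocol, "onset") %||% 0,
             attr(protocol, "offset") %||% protocol$duration)
    mean_frequency(detect_spikes(traj), win)
  }, numeric(1))
  data.frame(scheme = scheme_kind, B_T = concentrations, frequency_Hz = freq)
}
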
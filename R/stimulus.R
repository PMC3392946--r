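#' Current-clamp stimulus
#'
#' A stimulus is an ordered list of segments, each a hold (constant current)
#' or a ramp (linear interpolation between a start and an end amplitude).
#' `I_app(t)` is evaluated piecewise over the concatenated segments and is 0
#' outside them.
#'
#' @param segments data frame with columns `duration` (ms, > 0), `mode`
#'   (`"hold"` or `"ramp"`), `start` and `end` (pA). For holds, `end` is
#'   ignored and set to `start`.
#' @return An object of class `fs_stimulus` with the segment table (including
#'   absolute onsets `t0`, `t1`) and total `duration`.
#' @seealso [build_protocol()] for the standard step/ramp protocols.
#' @export
fs_stimulus <- function(segments) {
  segments <- as.data.frame(segments)
  need <- c("duration", "mode", "start")
  if (!all(need %in% names(segments)))
    stop("segments need columns: ", paste(need, collapse = ", "))
  if (nrow(segments) == 0) stop("stimulus needs at least one segment")
  if (any(segments$duration <= 0)) stop("segment durations must be > 0")
  if (!all(segments$mode %in% c("hold", "ramp")))
    stop("segment mode must be 'hold' or 'ramp'")
  if (is.null(segments$end)) segments$end <- segments$start
  segments$end[segments$mode == "hold"] <-
    segments$start[segments$mode == "hold"]
  segments$t1 <- cumsum(segments$duration)
  segments$t0 <- segments$t1 - segments$duration
  structure(list(segments = segments, duration = sum(segments$duration)),
            class = "fs_stimulus")
}

#' Standard current-clamp protocols
#'
#' \describe{
#'   \item{step}{0 pA for `pre_ms`, a constant `amplitude` for `duration`,
#'     0 pA for `post_ms`.}
#'   \item{ramp}{0 pA for `pre_ms`, a linear ramp from 0 to
#'     `ramp_rate * duration / 1000` pA over `duration`, 0 pA for `post_ms`.}
#' }
#' The reference protocols of the model are a 1 s (or 5 s) step of 100 pA and
#' a 1 s ramp of 200 pA/s.
#'
#' @param name `"step"` or `"ramp"`.
#' @param amplitude step amplitude (pA); ignored for ramps.
#' @param duration stimulus duration (ms).
#' @param pre_ms,post_ms zero-current padding before/after (ms).
#' @param ramp_rate ramp slope (pA per second); ignored for steps.
#' @return An [fs_stimulus()].
#' @examples
#' stim <- build_protocol("step", amplitude = 100, duration = 1000)
#' stim_current(stim, 500)  # 100 pA mid-step
#' @export
build_protocol <- function(name = c("step", "ramp"), amplitude = 100,
                           duration = 1000, pre_ms = 0, post_ms = 0,
                           ramp_rate = 200) {
  name <- match.arg(name)
  if (duration <= 0) stop("duration must be > 0")
  if (pre_ms < 0 || post_ms < 0) stop("padding must be >= 0")
  seg <- list()
  if (pre_ms > 0)
    seg[[length(seg) + 1L]] <- data.frame(duration = pre_ms, mode = "hold",
                                          start = 0, end = 0)
  seg[[length(seg) + 1L]] <- if (name == "step")
    data.frame(duration = duration, mode = "hold",
               start = amplitude, end = amplitude)
  else
    data.frame(duration = duration, mode = "ramp",
               start = 0, end = ramp_rate * duration / 1000)
  if (post_ms > 0)
    seg[[length(seg) + 1L]] <- data.frame(duration = post_ms, mode = "hold",
                                          start = 0, end = 0)
  stim <- fs_stimulus(do.call(rbind, seg))
  attr(stim, "protocol") <- name
  attr(stim, "onset") <- pre_ms
  attr(stim, "offset") <- pre_ms + duration
  stim
}

#' Evaluate a stimulus
#'
#' @param stim an [fs_stimulus()].
#' @param t time (ms), vectorised.
#' @return Applied current `I_app(t)` in pA (0 outside the stimulus span).
#' @export
stim_current <- function(stim, t) {
  s <- stim$segments
  out <- numeric(length(t))
  for (i in seq_len(nrow(s))) {
    inside <- if (i == nrow(s)) t >= s$t0[i] & t <= s$t1[i]
              else t >= s$t0[i] & t < s$t1[i]
    if (!any(inside)) next
    out[inside] <- if (s$mode[i] == "hold") s$start[i]
    else s$start[i] + (s$end[i] - s$start[i]) *
      (t[inside] - s$t0[i]) / (s$t1[i] - s$t0[i])
  }
  out
}

#' @export
print.fs_stimulus <- function(x, ...) {
  cat(sprintf("Current-clamp stimulus, %g ms total:\n", x$duration))
  s <- x$segments
  for (i in seq_len(nrow(s)))
    cat(sprintf("  [%g, %g) ms: %s %g -> %g pA\n",
                s$t0[i], s$t1[i], s$mode[i], s$start[i], s$end[i]))
  invisible(x)
}

# segment matrix for the compiled core: columns t0, t1, I0, I1, mode(0 hold/1 ramp)
stim_matrix <- function(stim) {
  s <- stim$segments
  cbind(s$t0, s$t1, s$start, s$end, as.numeric(s$mode == "ramp"))
}
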
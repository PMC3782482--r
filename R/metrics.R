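#' Chain-index time series
#'
#' Per-frame chain indices at 1 Hz, the rate at which all behavioral metrics
#' are defined. `t0_playback` marks sound onset (flies sit in silence for the
#' first 5 min of the standard assay).
#'
#' @param values non-negative integer chain index per frame.
#' @param fps frames per second; metrics assume 1.
#' @param t0_playback seconds at which playback starts (default 300).
#' @return Object of class `chain_series`.
#' @export
chain_series <- function(values, fps = 1, t0_playback = 300) {
  if (any(values < 0)) stop("chain indices are non-negative", call. = FALSE)
  structure(list(values = as.numeric(values), fps = fps,
                 t0_playback = t0_playback),
            class = "chain_series")
}

#' @export
print.chain_series <- function(x, ...) {
  cat(sprintf("<chain_series> %d frames at %g fps, playback at %g s, mean %.2f\n",
              length(x$values), x$fps, x$t0_playback, mean(x$values)))
  invisible(x)
}

#' Block-average a chain series
#'
#' Non-overlapping means over `window` frames (10 by default, i.e. 10-s bins
#' at 1 fps), the smoothing applied before plotting time courses. A final
#' partial block is averaged over its remaining frames.
#'
#' @param s a [chain_series] or numeric vector.
#' @param window block length in frames (>= 1).
#' @return numeric vector of block means.
#' @export
smooth_series <- function(s, window = 10) {
  v <- if (inherits(s, "chain_series")) s$values else as.numeric(s)
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  blk <- (seq_along(v) - 1) %/% window
  as.numeric(tapply(v, blk, mean))
}

#' Phase window
#'
#' A named analysis window, half-open `[start, end)` in seconds. The standard
#' phases are 60 s each (silent / immediate / later, or phases I-V of the
#' plasticity protocol).
#'
#' @param name label.
#' @param start,end seconds; `end > start`.
#' @return Object of class `phase_window`.
#' @export
phase_window <- function(name, start, end) {
  if (end <= start) stop("`end` must exceed `start`", call. = FALSE)
  structure(list(name = name, start = start, end = end),
            class = "phase_window")
}

#' Cumulative chain index over a phase window
#'
#' Sum of the per-frame chain indices over `[start, end)`. At 1 fps a 60-s
#' window of constant index 2 accumulates 120.
#'
#' @param s a [chain_series].
#' @param w a [phase_window] within the series span.
#' @return numeric sum.
#' @export
cumulative_index <- function(s, w) {
  stopifnot(inherits(s, "chain_series"), inherits(w, "phase_window"))
  t <- (seq_along(s$values) - 1) / s$fps
  sel <- t >= w$start & t < w$end
  if (!any(sel))
    stop(sprintf("window [%g, %g) does not overlap the series", w$start, w$end),
         call. = FALSE)
  sum(s$values[sel])
}

#' Per-fly chain probability
#'
#' The cumulative chain index normalized by its maximum: divided by the
#' number of flies and by `window_s * fps` frames. For the standard 2.5-min
#' window at 1 fps the per-fly maximum is 150, so a chamber of 6 flies all
#' chaining for 150 s gives probability 1.
#'
#' @param cum cumulative chain index over the window.
#' @param n_flies flies in the chamber (>= 1).
#' @param window_s window length in seconds (> 0).
#' @param fps frame rate of the underlying series (default 1).
#' @return proportion in `[0, 1]`.
#' @export
chain_probability <- function(cum, n_flies, window_s, fps = 1) {
  if (n_flies < 1) stop("`n_flies` must be >= 1", call. = FALSE)
  if (window_s <= 0) stop("`window_s` must be > 0", call. = FALSE)
  p <- cum / (n_flies * window_s * fps)
  if (any(p > 1 + 1e-9))
    stop("cumulative index exceeds its maximum; inconsistent inputs",
         call. = FALSE)
  pmin(p, 1)
}

#' Arcsine-square-root (angular) transform
#'
#' Variance-stabilizing transform applied to chain probabilities before
#' computing rates: `asin(sqrt(p))`, mapping `[0, 1]` onto `[0, pi/2]`.
#'
#' @param p proportion(s) in `[0, 1]`.
#' @return radians.
#' @export
angular_transform <- function(p) {
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  asin(sqrt(p))
}

#' Rate of change between two angular-transformed cumulative indices
#'
#' `rate = (AC2 - AC1) / AC1`, the suppression, recovery or drop rate when
#' evaluated on the corresponding protocol window pair. Undefined when
#' `AC1 = 0` (no baseline behavior).
#'
#' @param AC1,AC2 angular transforms (radians) of the first and second
#'   cumulative chain indices of a window pair.
#' @return Object of class `rate_result`: `AC1`, `AC2`, `rate`.
#' @export
rate_of_change <- function(AC1, AC2) {
  if (AC1 <= 0) stop("rate undefined: AC1 must be > 0", call. = FALSE)
  structure(list(AC1 = AC1, AC2 = AC2, rate = (AC2 - AC1) / AC1),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("<rate_result> AC1 = %.4f, AC2 = %.4f rad, rate = %+.3f\n",
              x$AC1, x$AC2, x$rate))
  invisible(x)
}

#' Standard protocol windows
#'
#' Window pairs of the playback protocols, all 60 s and half-open:
#' \describe{
#'   \item{suppression}{first playback onset of the continuous pulse song,
#'     5'11"-6'10" = `[311, 371)`, vs its end, 23'51"-24'50" = `[1431, 1491)`.}
#'   \item{recovery}{the minute before vs the minute after the
#'     continuous-to-intermittent shift at 25 min.}
#'   \item{drop}{the minute before vs after the intermittent-to-continuous
#'     shift at 40 min.}
#'   \item{three-phase}{silent (last pre-playback minute), immediate
#'     (playback onset) and later (end of the 12-min assay) phases.}
#'   \item{five-phase}{the five 1-min phases of the plasticity protocol in
#'     order: playback onset (I), end of the first continuous playback (II),
#'     the minute after the 25-min shift (III), and the minutes before (IV)
#'     and after (V) the 40-min shift.}
#' }
#'
#' @param protocol one of `"suppression"`, `"recovery"`, `"drop"`,
#'   `"three-phase"`, `"five-phase"`.
#' @param t0_playback playback onset in seconds (default 300); the
#'   three-phase windows are anchored to it.
#' @return list of [phase_window]s (a pair, except for the phase protocols).
#' @export
protocol_windows <- function(protocol = c("suppression", "recovery", "drop",
                                          "three-phase", "five-phase"),
                             t0_playback = 300) {
  protocol <- match.arg(protocol)
  w <- function(name, start) phase_window(name, start, start + 60)
  switch(protocol,
    suppression = list(w("playback-onset", 311), w("playback-end", 1431)),
    recovery    = list(w("pre-shift-25min", 25 * 60 - 60),
                       w("post-shift-25min", 25 * 60)),
    drop        = list(w("pre-shift-40min", 40 * 60 - 60),
                       w("post-shift-40min", 40 * 60)),
    `three-phase` = list(w("silent", t0_playback - 60),
                         w("immediate", t0_playback),
                         w("later", t0_playback + 6 * 60)),
    `five-phase` = list(w("I", 311), w("II", 1431), w("III", 25 * 60),
                        w("IV", 40 * 60 - 60), w("V", 40 * 60)))
}

#' Full metric report for a chain series
#'
#' Convenience wrapper: cumulative index, per-fly probability and angular
#' transform for each protocol window, plus the protocol rate for paired
#' protocols.
#'
#' @param s a [chain_series].
#' @param protocol passed to [protocol_windows].
#' @param n_flies flies in the chamber.
#' @return list with `windows` (data.frame: name, start, end, cumulative,
#'   probability, AC) and, for paired protocols, `rate` (a `rate_result`).
#' @export
metric_report <- function(s, protocol = "suppression", n_flies = 6) {
  ws <- protocol_windows(protocol, t0_playback = s$t0_playback)
  rows <- lapply(ws, function(w) {
    cum <- cumulative_index(s, w)
    p <- chain_probability(cum, n_flies, w$end - w$start, s$fps)
    data.frame(name = w$name, start = w$start, end = w$end,
               cumulative = cum, probability = p,
               AC = angular_transform(p))
  })
  tab <- do.call(rbind, rows)
  out <- list(windows = tab)
  if (protocol %in% c("suppression", "recovery", "drop") && tab$AC[1L] > 0)
    out$rate <- rate_of_change(tab$AC[1L], tab$AC[2L])
  out
}
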
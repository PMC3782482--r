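#' Stimulus specification for synthetic courtship songs
#'
#' Parametric description of a playback song. Pulse songs are trains of brief
#' pulses — `pulse_cycles` carrier cycles each — at a fixed or oscillating
#' inter-pulse interval (IPI, onset to onset); sine songs are a continuous
#' carrier tone. Bursts of `burst_s` seconds are separated by `silence_s`
#' seconds of silence (`silence_s = 0` gives the uninterrupted "continuous"
#' song). Carrier defaults reflect the species-typical intrapulse
#' frequencies: 167 Hz (*D. melanogaster*) and 333 Hz (*D. simulans*).
#'
#' @param kind `"pulse"` or `"sine"`.
#' @param ipi_ms inter-pulse interval in ms (pulse songs).
#' @param carrier_hz intrapulse / sine frequency in Hz.
#' @param pulse_cycles carrier cycles per pulse (default 2, ~12 ms at 167 Hz).
#' @param burst_s sound-period length in s (default 1).
#' @param silence_s inter-burst silence in s (default 2; 0 = continuous).
#' @param total_s total song duration in s.
#' @param oscillation `NULL`, or `list(period_s, ipi_min_ms, ipi_max_ms)` for
#'   sinusoidally oscillating IPIs (defaults 58 s, 29 ms, 40 ms via
#'   [make_oscillating_ipi]).
#' @param fixed_pulses `NULL`, or a pulse count per burst; the burst then
#'   extends to fit that many pulses (e.g. 29 pulses at 105-ms IPI span ~3 s).
#' @param amplitude peak amplitude (default 0.9).
#' @param sample_rate audio sample rate in Hz (default 8000).
#' @return Object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("pulse", "sine"), ipi_ms = 35,
                          carrier_hz = 167, pulse_cycles = 2, burst_s = 1,
                          silence_s = 2, total_s = 60, oscillation = NULL,
                          fixed_pulses = NULL, amplitude = 0.9,
                          sample_rate = 8000) {
  kind <- match.arg(kind)
  if (total_s <= 0 || burst_s <= 0 || silence_s < 0)
    stop("durations must be positive (silence may be 0)", call. = FALSE)
  if (sample_rate < 4 * carrier_hz)
    stop("`sample_rate` must be at least 4x the carrier", call. = FALSE)
  pulse_ms <- pulse_cycles / carrier_hz * 1000
  if (kind == "pulse" && is.null(oscillation) && ipi_ms < pulse_ms)
    stop("`ipi_ms` shorter than the pulse duration: pulses would overlap",
         call. = FALSE)
  if (!is.null(oscillation)) {
    o <- oscillation
    if (o$ipi_min_ms >= o$ipi_max_ms)
      stop("oscillation needs ipi_min < ipi_max", call. = FALSE)
  }
  structure(list(kind = kind, ipi_ms = ipi_ms, carrier_hz = carrier_hz,
                 pulse_cycles = pulse_cycles, burst_s = burst_s,
                 silence_s = silence_s, total_s = total_s,
                 oscillation = oscillation, fixed_pulses = fixed_pulses,
                 amplitude = amplitude, sample_rate = sample_rate),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %s song, carrier %g Hz, %g s total at %g Hz\n",
              x$kind, x$carrier_hz, x$total_s, x$sample_rate))
  if (x$kind == "pulse")
    cat(sprintf("  IPI %g ms, %g-cycle pulses, burst %g s / silence %g s%s\n",
                x$ipi_ms, x$pulse_cycles, x$burst_s, x$silence_s,
                if (!is.null(x$oscillation)) " [oscillating IPI]" else ""))
  invisible(x)
}

#' Single song pulse
#'
#' A sine pulse of `cycles` carrier cycles (duration `cycles / carrier_hz`),
#' peak amplitude 1, with a 10% raised-cosine taper at each end to avoid
#' clicks.
#'
#' @param carrier_hz intrapulse frequency, Hz.
#' @param cycles carrier cycles per pulse (>= 1).
#' @param sample_rate Hz, at least 4x the carrier.
#' @return A `waveform`: list `samples`, `sample_rate`.
#' @export
make_pulse <- function(carrier_hz, cycles = 2, sample_rate = 8000) {
  if (cycles < 1) stop("`cycles` must be >= 1", call. = FALSE)
  if (sample_rate < 4 * carrier_hz)
    stop("`sample_rate` must be at least 4x the carrier", call. = FALSE)
  dur <- cycles / carrier_hz
  n <- max(2L, round(dur * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  s <- sin(2 * pi * carrier_hz * t)
  s <- s * taper_window(n, 0.1)
  waveform(s, sample_rate)
}

taper_window <- function(n, frac) {
  w <- rep(1, n)
  m <- max(1L, floor(n * frac))
  ramp <- (1 - cos(pi * seq_len(m) / m)) / 2
  w[seq_len(m)] <- ramp
  w[n + 1L - seq_len(m)] <- ramp
  w
}

#' Waveform container
#' @param samples numeric amplitude sequence.
#' @param sample_rate Hz.
#' @return Object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate) {
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples at %g Hz (%.3f s), peak %.3f\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, max(abs(x$samples))))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Pulses per burst
#'
#' With pulse onsets at multiples of the IPI starting at 0, the count is the
#' largest n for which the n-th pulse still ends within the burst:
#' `(n - 1) * ipi + pulse_duration <= burst * 1000`. With the default 2-cycle
#' 167-Hz pulse (~12 ms) a 1-s burst holds 66 pulses at 15-ms IPI, 29 at
#' 35 ms and 10 at 105 ms.
#'
#' @param ipi_ms inter-pulse interval, ms (>= `pulse_duration_ms`).
#' @param burst_s burst length, s.
#' @param pulse_duration_ms pulse length, ms.
#' @return integer pulse count (>= 1 whenever one pulse fits).
#' @export
count_pulses_per_burst <- function(ipi_ms, burst_s, pulse_duration_ms) {
  if (ipi_ms < pulse_duration_ms)
    stop("`ipi_ms` must be at least the pulse duration", call. = FALSE)
  if (pulse_duration_ms > burst_s * 1000) return(0L)
  as.integer(floor((burst_s * 1000 - pulse_duration_ms) / ipi_ms) + 1)
}

#' Sinusoidally oscillating IPI sequence
#'
#' Successive IPIs drawn from a sinusoid evaluated at the current pulse time:
#' `ipi(t) = mean + half_range * sin(2*pi*t / period_s)` with mean
#' `(min + max)/2` and half-range `(max - min)/2`. Defaults reproduce the
#' natural *D. melanogaster* IPI rhythm: period 58 s, IPIs spanning 29-40 ms.
#'
#' @param period_s oscillation period, s.
#' @param ipi_min_ms,ipi_max_ms IPI range, ms.
#' @param total_s duration over which to generate pulse times.
#' @return list `onsets_s` (pulse onset times, s) and `ipi_ms` (the IPI
#'   following each onset; one element fewer is used than onsets).
#' @export
make_oscillating_ipi <- function(period_s = 58, ipi_min_ms = 29,
                                 ipi_max_ms = 40, total_s) {
  if (total_s <= 0) stop("`total_s` must be > 0", call. = FALSE)
  m <- (ipi_min_ms + ipi_max_ms) / 2
  h <- (ipi_max_ms - ipi_min_ms) / 2
  onsets <- numeric(0)
  ipis <- numeric(0)
  t <- 0
  while (t < total_s) {
    onsets <- c(onsets, t)
    ipi <- m + h * sin(2 * pi * t / period_s)
    ipis <- c(ipis, ipi)
    t <- t + ipi / 1000
  }
  list(onsets_s = onsets, ipi_ms = ipis)
}

#' Render a song waveform from a specification
#'
#' Pulse songs place identical pulses at IPI spacing inside each burst
#' (burst pulse count per [count_pulses_per_burst], or `fixed_pulses` with
#' the burst extended to fit); bursts are separated by exact silence. With
#' `silence_s = 0` the pulse train runs uninterrupted at the IPI — the
#' "continuous" song. Sine songs play the carrier during bursts. Oscillating
#' IPIs are phase-continuous: each interval is read off the sinusoid at the
#' current pulse time, across burst boundaries.
#'
#' @param spec a [stimulus_spec].
#' @return A `waveform` of `round(total_s * sample_rate)` samples.
#' @export
make_song <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  sr <- spec$sample_rate
  n_total <- round(spec$total_s * sr)
  out <- numeric(n_total)
  amp <- spec$amplitude

  if (spec$kind == "sine") {
    t <- (seq_len(n_total) - 1) / sr
    cyc <- spec$burst_s + spec$silence_s
    in_burst <- if (spec$silence_s == 0) rep(TRUE, n_total)
                else (t %% cyc) < spec$burst_s
    out[in_burst] <- amp * sin(2 * pi * spec$carrier_hz * t[in_burst])
    return(waveform(out, sr))
  }

  pulse <- make_pulse(spec$carrier_hz, spec$pulse_cycles, sr)$samples
  pulse_ms <- spec$pulse_cycles / spec$carrier_hz * 1000

  onsets_s <- if (!is.null(spec$oscillation)) {
    o <- spec$oscillation
    tr <- make_oscillating_ipi(o$period_s %||% 58, o$ipi_min_ms %||% 29,
                               o$ipi_max_ms %||% 40, spec$total_s)
    tr$onsets_s
  } else if (spec$silence_s == 0) {
    seq(0, spec$total_s, by = spec$ipi_ms / 1000)
  } else {
    n_pulses <- if (!is.null(spec$fixed_pulses)) spec$fixed_pulses
                else count_pulses_per_burst(spec$ipi_ms, spec$burst_s, pulse_ms)
    if (n_pulses < 1) stop("no pulse fits in the burst", call. = FALSE)
    burst_dur <- ((n_pulses - 1) * spec$ipi_ms + pulse_ms) / 1000
    period <- max(burst_dur, spec$burst_s) + spec$silence_s
    starts <- seq(0, spec$total_s, by = period)
    as.numeric(vapply(starts, function(b)
      b + (seq_len(n_pulses) - 1) * spec$ipi_ms / 1000,
      numeric(n_pulses)))
  }

  if (!is.null(spec$oscillation) && spec$silence_s > 0) {
    # gate the phase-continuous train by the burst/silence cycle
    cyc <- spec$burst_s + spec$silence_s
    onsets_s <- onsets_s[(onsets_s %% cyc) + pulse_ms / 1000 <= spec$burst_s]
  }

  for (t0 in onsets_s) {
    i0 <- round(t0 * sr) + 1L
    i1 <- i0 + length(pulse) - 1L
    if (i1 > n_total) break
    out[i0:i1] <- amp * pulse
  }
  waveform(out, sr)
}

#' Burst duration in fixed-pulse-count mode
#'
#' Length of one burst holding exactly `n_pulses` pulses at the given IPI:
#' `(n - 1) * ipi + pulse_duration`. 29 pulses at 105-ms IPI with a 2-cycle
#' 167-Hz pulse span 2.95 s, i.e. a burst that rounds to 3 s.
#'
#' @param n_pulses pulses per burst.
#' @param ipi_ms inter-pulse interval, ms.
#' @param pulse_duration_ms pulse length, ms.
#' @return burst duration in seconds.
#' @export
burst_duration <- function(n_pulses, ipi_ms, pulse_duration_ms) {
  ((n_pulses - 1) * ipi_ms + pulse_duration_ms) / 1000
}
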
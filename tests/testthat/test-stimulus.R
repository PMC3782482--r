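test_that("pulses last the stated number of carrier cycles", {
  p167 <- make_pulse(167, cycles = 2, sample_rate = 8000)
  expect_equal(length(p167) / 8000, 2 / 167, tolerance = 0.01)
  p333 <- make_pulse(333, cycles = 2, sample_rate = 8000)
  expect_equal(length(p333) / 8000, 2 / 333, tolerance = 0.01)
  expect_equal(max(abs(p167$samples)), 1, tolerance = 0.02)
  expect_error(make_pulse(167, cycles = 0), ">= 1")
  expect_error(make_pulse(167, sample_rate = 500), "4x")
})

test_that("pulse counts per burst reproduce the printed stimulus arithmetic", {
  pd <- 2 / 167 * 1000                       # ~11.98 ms
  expect_equal(count_pulses_per_burst(15, 1, pd), 66L)
  expect_equal(count_pulses_per_burst(35, 1, pd), 29L)
  expect_equal(count_pulses_per_burst(105, 1, pd), 10L)
  # IPI longer than the burst: a single pulse still fits
  expect_equal(count_pulses_per_burst(2000, 1, pd), 1L)
  expect_error(count_pulses_per_burst(5, 1, pd), "pulse duration")
  # 29 pulses at 105-ms IPI span a burst that rounds to 3 s
  expect_equal(round(burst_duration(29, 105, pd)), 3)
})

test_that("intermittent songs alternate exact silence with carrier bursts", {
  spec <- stimulus_spec("sine", carrier_hz = 167, burst_s = 1, silence_s = 2,
                        total_s = 9)
  w <- make_song(spec)
  expect_length(w, 9 * 8000)
  t <- (seq_along(w$samples) - 1) / 8000
  silent_period <- (t %% 3) >= 1
  expect_true(all(w$samples[silent_period] == 0))
  expect_equal(mean(w$samples == 0), 2 / 3, tolerance = 0.01)
})

test_that("continuous pulse songs keep every onset gap at one IPI", {
  spec <- stimulus_spec("pulse", ipi_ms = 35, silence_s = 0, total_s = 5)
  w <- make_song(spec)
  on <- which(abs(w$samples) > 1e-9)
  gaps <- diff(on)
  onset_gaps <- gaps[gaps > 1]               # jumps between pulses
  expect_true(all(abs(onset_gaps + 95 - 35 / 1000 * 8000) <= 2))
})

test_that("intermittent and continuous songs share identical burst blocks", {
  ic <- make_song(stimulus_spec("pulse", ipi_ms = 35, silence_s = 0,
                                total_s = 4))
  ii <- make_song(stimulus_spec("pulse", ipi_ms = 35, silence_s = 2,
                                burst_s = 1, total_s = 4))
  # the first burst second is sample-identical; the following 2 s differ
  # only by the silence insertion
  expect_equal(ii$samples[1:8000], ic$samples[1:8000])
  expect_true(all(ii$samples[(8000 + 760):(3 * 8000)] == 0))
})

test_that("fixed-pulse-count bursts extend to hold the requested pulses", {
  w <- make_song(stimulus_spec("pulse", ipi_ms = 105, fixed_pulses = 29,
                               total_s = 12))
  on <- which(abs(w$samples) > 1e-9)
  # pulse onsets: starts of active runs
  starts <- on[c(TRUE, diff(on) > 1)]
  # first burst: 29 onsets spaced 105 ms, spanning ~2.95 s
  first_burst <- starts[starts <= 3.1 * 8000]
  expect_length(first_burst, 29L)
  expect_true(all(abs(diff(first_burst) - 0.105 * 8000) <= 1))
})

test_that("oscillating IPIs trace a 58-s sinusoid between 29 and 40 ms", {
  tr <- make_oscillating_ipi(58, 29, 40, total_s = 290)
  expect_equal(min(tr$ipi_ms), 29, tolerance = 0.01)
  expect_equal(max(tr$ipi_ms), 40, tolerance = 0.01)
  # mean over whole periods
  whole <- tr$ipi_ms[tr$onsets_s < 232]
  expect_equal(mean(whole), 34.5, tolerance = 0.5)
  # dominant period by autocorrelation of IPI(t) resampled at 10 Hz
  tg <- seq(0, 289, by = 0.1)
  it <- approx(tr$onsets_s, tr$ipi_ms, xout = tg, rule = 2)$y
  ac <- acf(it, lag.max = 800, plot = FALSE)$acf[-1]
  peak_lag <- which.max(ac[300:800]) + 299
  expect_equal(peak_lag * 0.1, 58, tolerance = 0.05)
})

test_that("pulse-song energy is concentrated near the carrier", {
  for (carrier in c(167, 333)) {
    w <- make_song(stimulus_spec("pulse", ipi_ms = 35, carrier_hz = carrier,
                                 silence_s = 0, total_s = 4))
    sp <- Mod(stats::fft(w$samples))[1:(length(w) / 2)]^2
    freq <- (seq_along(sp) - 1) / 4
    # spectral centroid sits on the carrier; most power within +-60 Hz
    centroid <- sum(freq * sp) / sum(sp)
    expect_lt(abs(centroid - carrier) / carrier, 0.1)
    expect_gte(sum(sp[abs(freq - carrier) <= 60]) / sum(sp), 0.6)
  }
})

test_that("WAV files round-trip within quantization", {
  w <- make_song(stimulus_spec("pulse", ipi_ms = 35, total_s = 2))
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, f)
  back <- read_wav(f)
  expect_equal(back$sample_rate, 8000)
  expect_lt(max(abs(back$samples - w$samples)), 1 / 32767 + 1e-9)
  # float path is near-exact
  write_wav(w, f, bits = 32)
  expect_lt(max(abs(read_wav(f)$samples - w$samples)), 1e-6)
  expect_error(write_wav(w, file.path(tempdir(), "no", "such", "dir.wav")),
               "cannot open")
  expect_error(read_wav(file.path(tempdir(), "absent.wav")), "no such file")
})
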
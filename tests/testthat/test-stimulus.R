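test_that("generated ramp-and-hold traces satisfy the protocol shape", {
  shape <- ramp_shape(relaxation_amplitude = 0)
  tr <- generate_ramp_hold(stimulus_protocol("III"), shape = shape)
  proto <- stimulus_protocol("III")
  plateau <- 1.35
  # zero during the gap
  expect_true(all(tr$forces[tr$times <= shape$gap_delay] == 0))
  # monotone rise through the ramp, reaching the plateau
  ramp_end <- shape$gap_delay +
    plateau / (proto$target_peak_dforce * proto$dforce_unit_scale)
  ramp <- tr$forces[tr$times > shape$gap_delay & tr$times < ramp_end]
  expect_true(all(diff(ramp) > 0))
  expect_gte(max(tr$forces), 0.98 * plateau)
  # with zero relaxation the plateau samples are all equal
  hold <- tr$forces[tr$times >= ramp_end + 10]
  expect_true(all(hold == plateau))
})

test_that("plateau relaxes toward plateau*(1 - amplitude) during the hold", {
  shape <- ramp_shape(relaxation_amplitude = 0.1,
                      relaxation_time_constant = 300)
  tr <- generate_ramp_hold(stimulus_protocol("III", hold_duration = 4000),
                           shape = shape)
  hold <- tr$forces[tr$times > 600]
  expect_true(all(diff(hold) <= 0))
  expect_equal(hold[length(hold)], 1.35 * 0.9, tolerance = 1e-3)
})

test_that("trace generation is deterministic and ordered across types", {
  a <- generate_ramp_hold(stimulus_protocol("II"), seed = 7)
  b <- generate_ramp_hold(stimulus_protocol("II"), seed = 7)
  expect_identical(a$forces, b$forces)

  traces <- lapply(c("I", "II", "III", "IV", "V"),
                   function(ty) generate_ramp_hold(stimulus_protocol(ty)))
  names(traces) <- c("I", "II", "III", "IV", "V")
  # peak first-difference rate increases with ramp-rate level
  peak_rate <- vapply(traces, function(tr) max(diff(tr$forces)), numeric(1))
  expect_true(peak_rate[["I"]] < peak_rate[["II"]])
  expect_true(peak_rate[["II"]] < peak_rate[["III"]])
  # hold-phase force increases with hold depth
  hold_mean <- vapply(traces, function(tr)
    mean(tr$forces[tr$times > max(tr$times) - 3000]), numeric(1))
  expect_true(hold_mean[["III"]] < hold_mean[["IV"]])
  expect_true(hold_mean[["IV"]] < hold_mean[["V"]])
  expect_gt(max(traces[["V"]]$forces), max(traces[["III"]]$forces))
})

test_that("the generated force crosses 1 N after the commanded ramp start", {
  tr <- generate_ramp_hold(stimulus_protocol("I"),
                           shape = ramp_shape(gap_delay = 150))
  onset <- detect_onset(tr)
  expect_gt(onset, 150)
})

test_that("generator rejects non-positive durations and rates", {
  expect_error(stimulus_protocol("I", hold_duration = 0), "positive")
  expect_error(stimulus_protocol("I", sampling_rate = -1), "positive")
  expect_error(ramp_shape(relaxation_amplitude = 1), "\\[0, 1\\)")
})

test_that("the Gaussian low-pass filter passes DC and removes above-cutoff tones", {
  rate <- 100
  times <- seq(0, 5000, by = 10)
  dc <- force_trace(times, rep(2, length(times)), rate)
  out <- gaussian_lowpass(dc)
  expect_equal(out$forces, dc$forces, tolerance = 1e-12)

  # unpadded circular filtering removes an integer-cycle 30 Hz tone exactly
  times5 <- seq(0, by = 10, length.out = 500)  # 150 full cycles of 30 Hz
  tone <- force_trace(times5, 2 + 0.5 * sin(2 * pi * 30 * times5 / 1000),
                      rate)
  out <- gaussian_lowpass(tone, pad = FALSE)
  expect_lt(max(abs(out$forces - 2)), 1e-9)
  # padded filtering is clean away from the edges; a tone that has not
  # settled at the trace ends rings only in the few edge samples
  out_pad <- gaussian_lowpass(tone)
  expect_lt(max(abs(out_pad$forces[51:450] - 2)), 1e-4)
})

test_that("filtered white noise has essentially no power above the cutoff", {
  set.seed(301)
  n <- 4096
  times <- seq(0, by = 10, length.out = n)
  noise <- force_trace(times, rnorm(n), 100)
  # periodogram oracle computed directly from the DFT of each series
  power_above <- function(x) {
    spec <- Mod(stats::fft(x))^2
    freqs <- seq(0, length(x) - 1) * (100 / length(x))
    freqs <- pmin(freqs, 100 - freqs)
    sum(spec[freqs > 15])
  }
  out <- gaussian_lowpass(noise, cutoff = 15, pad = FALSE)
  expect_lt(power_above(out$forces) / power_above(noise$forces), 1e-6)
  # padding re-smears a little truncation leakage into the stop band
  out_pad <- gaussian_lowpass(noise, cutoff = 15)
  expect_lt(power_above(out_pad$forces) / power_above(noise$forces), 1e-4)
})

test_that("repeated filtering only attenuates further (taper is not a projection)", {
  set.seed(302)
  times <- seq(0, by = 10, length.out = 512)
  tr <- force_trace(times, 1 + 0.2 * rnorm(512), 100)
  once <- gaussian_lowpass(tr)
  twice <- gaussian_lowpass(once)
  dev_once <- sum((once$forces - mean(once$forces))^2)
  dev_twice <- sum((twice$forces - mean(twice$forces))^2)
  expect_lte(dev_twice, dev_once)
})

test_that("filter rejects cutoffs at or above Nyquist", {
  tr <- force_trace(seq(0, 90, 10), rep(1, 10), 100)
  expect_error(gaussian_lowpass(tr, cutoff = 50), "Nyquist")
  expect_error(gaussian_lowpass(tr, cutoff = 60), "Nyquist")
})

test_that("additive noise is zero-mean, seeded, and degenerate at sd 0", {
  times <- seq(0, by = 10, length.out = 1e4)
  tr <- force_trace(times, rep(1, 1e4), 100)
  expect_identical(add_noise(tr, sd = 0, seed = 1)$forces, tr$forces)
  a <- add_noise(tr, sd = 0.1, seed = 5)
  b <- add_noise(tr, sd = 0.1, seed = 5)
  expect_identical(a$forces, b$forces)
  # law-of-large-numbers bound on the sample mean of the perturbation
  expect_lt(abs(mean(a$forces - tr$forces)), 4 * 0.1 / sqrt(1e4))
  expect_error(add_noise(tr, sd = -0.1), "non-negative")
})
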
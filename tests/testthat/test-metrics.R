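test_that("interspike intervals are consecutive differences", {
  expect_equal(isi(c(10, 30, 60)), c(20, 30))
  expect_equal(isi(c(42)), numeric(0))
  expect_equal(isi(numeric(0)), numeric(0))
  expect_equal(isi(seq(0, 500, 50)), rep(50, 10))
  # sum property: ISIs sum to last - first
  set.seed(9)
  times <- sort(runif(40, 0, 5000))
  expect_equal(sum(isi(times)), max(times) - min(times))
  expect_error(isi(c(3, 2, 5)), "strictly increasing")
})

test_that("onset detection follows the force and force-rate rules", {
  tr <- force_trace(c(0, 10, 20, 30), c(0, 0.5, 1.2, 2.0), 100)
  expect_equal(detect_onset(tr), 20)
  expect_equal(detect_onset(tr, threshold = 1.5), 30)
  sub <- force_trace(c(0, 10, 20, 30), c(0, 0.2, 0.5, 0.9), 100)
  expect_true(is.na(detect_onset(sub)))
  # force-rate rule: first sample whose backward difference exceeds the rate
  flat_then_ramp <- force_trace(seq(0, 90, 10),
                                c(rep(0, 5), seq(0.02, 0.1, 0.02)), 100)
  expect_equal(detect_onset(flat_then_ramp, mode = "dforce_threshold",
                            threshold = 5e-4), 50)
})

test_that("peak detection takes the earliest maximum", {
  ramp_flat <- force_trace(seq(0, 50, 10), c(0, 1, 2, 3, 3, 3), 100)
  expect_equal(detect_peak(ramp_flat), 30)
})

test_that("phase windows gate which ISIs count toward each mean", {
  w <- phase_windows(onset_time = 0, peak_time = 30)
  s <- phase_isi_means(spike_train(c(5, 15, 30)), w)
  expect_equal(s$dyn_isi_mean, 12.5)
  expect_equal(s$n_dyn_isis, 2)

  # periodic spikes filling the static window -> mean 50
  w <- phase_windows(onset_time = 0, peak_time = 300)
  s <- phase_isi_means(spike_train(seq(2000, 5000, 50)), w)
  expect_equal(s$stat_isi_mean, 50)
  expect_equal(s$n_stat_isis, 60)

  # no spikes inside the static window -> undefined mean, count 0
  s <- phase_isi_means(spike_train(c(10, 40, 90)), w)
  expect_true(is.na(s$stat_isi_mean))
  expect_equal(s$n_stat_isis, 0)

  # an ISI straddling a window edge belongs to no window
  s <- phase_isi_means(spike_train(c(1990, 2050, 2100)), w)
  expect_equal(s$n_stat_isis, 1)
  expect_equal(s$stat_isi_mean, 50)
})

test_that("window enlargement never loses ISIs", {
  set.seed(21)
  times <- sort(runif(60, 0, 6000))
  narrow <- phase_windows(0, 100, static_offsets = c(2500, 4500))
  wide <- phase_windows(0, 100, static_offsets = c(2000, 5000))
  n1 <- phase_isi_means(spike_train(times), narrow)$n_stat_isis
  n2 <- phase_isi_means(spike_train(times), wide)$n_stat_isis
  expect_gte(n2, n1)
})

test_that("first-spike latency is measured from onset", {
  expect_equal(first_spike_latency(c(254.9, 300), onset_time = 100), 154.9)
  expect_equal(first_spike_latency(c(100, 150), onset_time = 100), 0)
  expect_true(is.na(first_spike_latency(c(10, 50), onset_time = 100)))
})

test_that("static-ISI coefficient of variation uses the sample SD", {
  w <- phase_windows(0, 0, static_offsets = c(0, 5000))
  # ISIs 40, 60: sample SD = 10*sqrt(2), mean 50 -> CV = 0.28284
  st <- spike_train(c(100, 140, 200))
  expect_equal(static_isi_cv(st, w), 10 * sqrt(2) / 50, tolerance = 1e-12)
  # periodic spikes -> CV 0
  expect_equal(static_isi_cv(spike_train(seq(100, 2100, 50)), w), 0)
  # scale invariance
  st2 <- spike_train(c(100, 180, 300))
  expect_equal(static_isi_cv(st2, w), static_isi_cv(st, w), tolerance = 1e-12)
  # fewer than two static ISIs -> undefined
  expect_true(is.na(static_isi_cv(spike_train(c(100, 140)), w)))
})
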
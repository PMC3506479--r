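test_that("rest stays at rest under zero current", {
  p <- lif_params(tau = 50, C = 1e-06, v_threshold = 20)
  st <- integrate_lif(constant_current(0), p, record_potential = TRUE)
  expect_length(st$spike_times, 0)
  expect_true(all(attr(st, "potential") == 0))
})

test_that("steady ISIs match the closed-form oracle across the suprathreshold range", {
  p <- end_params()
  lp <- lif_params(p$tau, p$C, p$v_threshold)
  R <- p$tau / p$C
  I_rheo <- p$v_threshold / R
  for (mult in seq(1.1, 10, length.out = 20)) {
    I <- mult * I_rheo
    expected <- oracle_isi(I, p$tau, p$C, p$v_threshold)
    st <- integrate_lif(constant_current(I, duration_ms = 12 * expected), lp)
    isis <- isi(st)
    expect_gte(length(isis), 3)
    expect_true(all(abs(isis[-1] - expected) <= 2 * lp$dt),
                label = sprintf("ISIs at %.1fx rheobase within 2dt", mult))
  }
})

test_that("the published parameter set fires at ~51.5 ms under a held 2 N force", {
  # frozen from the independent closed form: 1 + tau*log(RI/(RI - v_th))
  # with I = beta + k_s * 2 = 1.2672e-06 mA
  p <- end_params()
  lp <- lif_params(p$tau, p$C, p$v_threshold)
  st <- integrate_lif(constant_current(1.2672e-06, 2000), lp)
  expect_equal(mean(isi(st)), 51.50827, tolerance = 2 * lp$dt / 51.5)
})

test_that("closed-form helper handles rheobase and subthreshold currents", {
  lp <- lif_params(tau = 100, C = 1e-06, v_threshold = 30, refractory = 0)
  R <- 100 / 1e-06
  expect_true(is.na(lif_constant_current_isi(30 / R, lp)))
  expect_true(is.na(lif_constant_current_isi(1e-08, lp)))
  expect_equal(lif_constant_current_isi(2 * 30 / R, lp), 100 * log(2))
})

test_that("no ISI ever undercuts the refractory period (fuzzed currents)", {
  set.seed(77)
  lp <- lif_params(tau = 71.409, C = 9.7e-07, v_threshold = 47.3)
  times <- seq(0, 1990, 10)
  for (k in 1:12) {
    kind <- k %% 3
    I <- if (kind == 0) {
      # step current
      c(rep(0, 50), rep(runif(1, 1e-06, 5e-05), 150))
    } else if (kind == 1) {
      # ramp
      seq(0, runif(1, 1e-06, 1e-04), length.out = 200)
    } else {
      # noisy positive current
      abs(rnorm(200, mean = runif(1, 1e-06, 2e-05), sd = 1e-05))
    }
    st <- integrate_lif(current_trace(times, I, 100), lp)
    if (length(st$spike_times) > 1)
      expect_gte(min(isi(st)), lp$refractory)
  }
})

test_that("larger constant currents give shorter ISIs", {
  p <- end_params()
  lp <- lif_params(p$tau, p$C, p$v_threshold)
  I_rheo <- p$v_threshold * p$C / p$tau
  isis <- vapply(c(1.5, 2.5, 4, 8) * I_rheo, function(I)
    mean(isi(integrate_lif(constant_current(I, 1500), lp))), numeric(1))
  expect_true(all(diff(isis) < 0))
})

test_that("halving dt moves the first spike and every ISI by less than dt", {
  # spike times are quantized to step boundaries, so each spike's rounding
  # is independent: the first spike and every interval move by < dt, while
  # absolute times late in a long train may accumulate several roundings
  times <- seq(0, 1490, 10)
  I <- 2e-06 * (1 - exp(-times / 300))
  cur <- current_trace(times, I, 100)
  st1 <- integrate_lif(cur, lif_params(71.409, 9.7e-07, 47.3, dt = 0.01))
  st2 <- integrate_lif(cur, lif_params(71.409, 9.7e-07, 47.3, dt = 0.005))
  expect_equal(length(st1$spike_times), length(st2$spike_times))
  expect_lt(abs(st1$spike_times[1] - st2$spike_times[1]), 0.01)
  expect_lt(max(abs(isi(st1) - isi(st2))), 0.01)
})

test_that("integration rejects empty input and reports overflow", {
  expect_error(current_trace(numeric(0), numeric(0), 100), "at least 2")
  # current/C overflows double range -> reported with the offending time
  tiny_C <- lif_params(50, 1e-312, 20)
  huge <- current_trace(seq(0, 90, 10), rep(1e+300, 10), 100)
  expect_error(integrate_lif(huge, tiny_C), "non-finite")
})

test_that("zero-order hold and linear interpolation agree on constant current", {
  lp <- lif_params(71.409, 9.7e-07, 47.3)
  cur <- constant_current(1.5e-06, 1500)
  a <- integrate_lif(cur, lp, interpolation = "hold")
  b <- integrate_lif(cur, lp, interpolation = "linear")
  expect_equal(a$spike_times, b$spike_times, tolerance = 1e-10)
})
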
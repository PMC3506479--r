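test_that("train/test split is stratified, disjoint and seed-reproducible", {
  types <- rep(c("I", "II", "III", "IV", "V"), times = 6)
  sp <- split_train_test(types, fraction = 2/3, seed = 3)
  expect_length(sp$train, 20)
  expect_length(sp$test, 10)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_true(all(table(types[sp$train]) == 4))
  expect_true(all(table(types[sp$test]) == 2))
  sp2 <- split_train_test(types, fraction = 2/3, seed = 3)
  expect_identical(sp, sp2)
  expect_error(split_train_test(types, fraction = 1), "between 0 and 1")
  expect_error(split_train_test(types, fraction = 0), "between 0 and 1")
})

test_that("joint scaling of (beta, k_s, k_d, C) leaves spike times unchanged", {
  base <- end_params()
  tr <- generate_ramp_hold(stimulus_protocol("IV",
                                             hold_duration = 3000))
  ref <- predict_response(tr, base)$spikes$spike_times
  for (alpha in c(0.1, 10)) {
    scaled <- model_params(base$beta * alpha, base$k_s * alpha,
                           base$k_d * alpha, base$tau, base$C * alpha,
                           base$v_threshold)
    expect_identical(predict_response(tr, scaled)$spikes$spike_times, ref)
    expect_equal(identifiable_params(scaled), identifiable_params(base),
                 tolerance = 1e-12)
  }
})

test_that("an already-optimal start terminates immediately on a smooth objective", {
  truth <- end_params()
  traces <- simulate_experiment(types = c("III", "IV", "V"), blocks = 2,
                                noise_sd = 0, filter = FALSE, seed = 1,
                                hold_duration = 3000)
  tab <- predict_isi_table(traces, truth)
  ag <- stats::aggregate(cbind(dyn_isi_ms, stat_isi_ms) ~ type, tab, mean)
  obs <- observed_targets(ag$type, ag$dyn_isi_ms, ag$stat_isi_ms)
  fit <- rsm_fit(traces, obs, truth,
                 settings = rsm_control(max_iterations = 3))
  # at the optimum (FSS = 1) no probe can improve; the log keeps only the start
  expect_equal(fit$iterations$fss[1], 1)
  expect_lte(max(fit$iterations$iteration), 1)
  expect_equal(coef(fit), coef(fit), tolerance = 0)
})

test_that("the fitted session log is non-decreasing and validate matches fss", {
  truth <- end_params()
  traces <- simulate_experiment(types = c("III", "V"), blocks = 2,
                                noise_sd = 0.02, seed = 8,
                                hold_duration = 3000)
  tab <- predict_isi_table(traces, truth)
  ag <- stats::aggregate(cbind(dyn_isi_ms, stat_isi_ms) ~ type, tab, mean)
  obs <- observed_targets(ag$type, ag$dyn_isi_ms, ag$stat_isi_ms)
  start <- model_params(truth$beta, truth$k_s * 1.15, truth$k_d * 0.85,
                        truth$tau * 1.1, truth$C, truth$v_threshold * 0.9)
  fit <- rsm_fit(traces, obs, start,
                 settings = rsm_control(max_iterations = 4))
  expect_true(all(diff(fit$iterations$fss) >= 0))
  expect_gte(fit$fss$fss, fit$iterations$fss[1])
  # validating on the training set reproduces the final training FSS
  val <- validate(fit, traces, obs)
  expect_equal(val$fss, fit$fss$fss, tolerance = 1e-12)
  # methods are coherent
  expect_named(coef(fit),
               c("beta", "k_s", "k_d", "tau", "C", "v_threshold"))
  res <- residuals(fit)
  expect_true(all(c("dyn_residual_ms", "stat_residual_ms") %in% names(res)))
  sim <- simulate(fit, nsim = 1)
  expect_length(sim[[1]], length(traces))
})

test_that("rsm_fit demands every observed type among the training traces", {
  truth <- end_params()
  traces <- simulate_experiment(types = c("III"), blocks = 2, noise_sd = 0,
                                seed = 1, hold_duration = 2000)
  obs <- observed_targets(c("III", "IV"), c(15, 15), c(99, 55))
  expect_error(rsm_fit(traces, obs, truth), "represented")
})

test_that("seeded pseudorandom target selection picks one defined pair per type", {
  tab <- data.frame(type = rep(c("I", "II"), each = 3),
                    dyn_isi_ms = c(20, 21, NA, 18, 17, 16),
                    stat_isi_ms = c(90, 91, 92, NA, 71, 70))
  sel1 <- select_observed_targets(tab, seed = 2)
  sel2 <- select_observed_targets(tab, seed = 2)
  expect_identical(sel1, sel2)
  expect_equal(nrow(sel1), 2)
  # never selects a row with an undefined mean
  expect_false(any(is.na(sel1$obs_dyn_isi_ms)))
  expect_false(any(is.na(sel1$obs_stat_isi_ms)))
})
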
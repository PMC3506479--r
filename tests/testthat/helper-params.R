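# Published end-of-fit parameter set used throughout the tests.
end_params <- function() {
  model_params(beta = 2.72e-08, k_s = 6.20e-07, k_d = 2.71e-04,
               tau = 71.409, C = 9.70e-07, v_threshold = 47.300)
}

# independent closed-form oracle: steady ISI under constant current,
# written directly from the membrane solution, not via the package
oracle_isi <- function(I, tau, C, v_th, t_ref = 1) {
  R <- tau / C
  if (R * I <= v_th) return(NA_real_)
  t_ref + tau * log((R * I) / (R * I - v_th))
}

constant_current <- function(I, duration_ms = 2000, rate = 100) {
  times <- seq(0, duration_ms, by = 1000 / rate)
  current_trace(times, rep(I, length(times)), rate)
}
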
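#' Transduction parameters
#'
#' The three coefficients of the linear force-to-current transduction
#' model `I(t) = beta + k_s * f(t) + k_d * f'(t)`: an intercept `beta`
#' (mA) absorbing per-sensor baseline, a static gain `k_s` (mA/N) driving
#' the sustained-hold response, and a dynamic gain `k_d` (mA·s/N)
#' multiplying the backward-difference force rate `f'(t)` (N/ms) that
#' dominates during ramp-up. The product `k_d * f'` is taken as a plain
#' numeric product with no hidden unit conversion, the only convention
#' under which published parameter values combine to currents
#' commensurate with `k_s * f`.
#'
#' @param beta Intercept in mA.
#' @param k_s Static gain in mA/N.
#' @param k_d Dynamic gain in mA·s/N (numeric-product convention).
#' @param h Backward-difference step in ms (default 10, one sample at
#'   100 Hz).
#' @return A `"transduction_params"` list.
#' @export
transduction_params <- function(beta, k_s, k_d, h = 10) {
  vals <- c(beta = beta, k_s = k_s, k_d = k_d, h = h)
  if (!all(is.finite(vals))) stop("transduction parameters must be finite",
                                  call. = FALSE)
  if (h <= 0) stop("`h` must be positive (ms)", call. = FALSE)
  structure(as.list(vals), class = "transduction_params")
}

#' Backward-difference force rate
#'
#' Computes `f'(t) = (f(t) - f(t - h)) / h` in N/ms at every sample after
#' stimulus onset. The derivative is defined as 0 at the onset sample
#' itself, at all samples before onset, and wherever `t - h` precedes the
#' trace start. `h` must be a positive integer multiple of the sampling
#' interval.
#'
#' @param trace A [force_trace()].
#' @param h Difference step in ms (default 10).
#' @param onset_index Index of the stimulus-onset sample (see
#'   [detect_onset()]); samples up to and including it get `f' = 0`. Use
#'   `0` to compute the raw backward difference everywhere it exists.
#' @return Numeric vector of force rates (N/ms), same length as the trace.
#' @export
force_derivative <- function(trace, h = 10, onset_index = 1L) {
  stopifnot(inherits(trace, "force_trace"))
  step <- sampling_interval_ms(trace)
  k <- h / step
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop(sprintf("`h` must be a positive integer multiple of the %g ms sampling interval",
                 step), call. = FALSE)
  k <- as.integer(round(k))
  n <- length(trace$forces)
  if (!is.numeric(onset_index) || length(onset_index) != 1 ||
      onset_index < 0 || onset_index > n)
    stop("`onset_index` must be 0 or index a sample of the trace",
         call. = FALSE)
  d <- numeric(n)
  idx <- seq_len(n)
  ok <- idx > onset_index & idx > k
  d[ok] <- (trace$forces[idx[ok]] - trace$forces[idx[ok] - k]) / h
  d
}

#' Transduce a force trace into transmembrane current
#'
#' Applies the linear transduction model sample by sample:
#' `I(t) = beta + k_s * f(t) + k_d * f'(t)`, with `f'` the
#' backward-difference rate of [force_derivative()]. During a perfect
#' plateau the current is constant at `beta + k_s * plateau`; during the
#' ramp the dynamic term contributes an extra `k_d * rate`.
#'
#' @param trace A [force_trace()].
#' @param params A [transduction_params()].
#' @param onset_index Onset sample index passed to [force_derivative()].
#' @return A [current_trace()].
#' @examples
#' tr <- force_trace(seq(0, 90, 10), rep(1, 10))
#' p <- transduction_params(beta = 2.72e-08, k_s = 6.20e-07, k_d = 2.71e-04)
#' transduce(tr, p)$currents[1]  # beta + k_s * 1
#' @export
transduce <- function(trace, params, onset_index = 1L) {
  stopifnot(inherits(trace, "force_trace"),
            inherits(params, "transduction_params"))
  d <- force_derivative(trace, h = params$h, onset_index = onset_index)
  I <- params$beta + params$k_s * trace$forces + params$k_d * d
  current_trace(trace$times, I, trace$sampling_rate)
}
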
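#' Leaky integrate-and-fire membrane parameters
#'
#' The neural-dynamics sub-model is a leaky integrate-and-fire (RC)
#' membrane: `du/dt = -u/tau + I(t)/C`, with `u` in mV, `t` in ms, `I` in
#' mA and `C` in mF; the membrane resistance is `R = tau / C` (Ohm). With
#' this unit bookkeeping both `u/R` and `C du/dt` are in mA and no hidden
#' conversion factors are needed. A spike is emitted when `u` reaches the
#' threshold `v_threshold`, after which `u` resets to `u0` and is held
#' there for the absolute refractory period. The resting baseline is
#' simplified to 0 mV so the threshold is a positive value.
#'
#' @param tau Membrane time constant in ms (> 0).
#' @param C Membrane capacitance in mF (> 0).
#' @param v_threshold Firing threshold in mV (> 0).
#' @param refractory Absolute refractory period in ms (default 1).
#' @param dt Integration step in ms (default 0.01).
#' @param u0 Resting/reset potential in mV (default 0).
#' @return A `"lif_params"` list; `R` (Ohm) is derived as `tau / C`.
#' @export
lif_params <- function(tau, C, v_threshold, refractory = 1, dt = 0.01,
                       u0 = 0) {
  vals <- c(tau = tau, C = C, v_threshold = v_threshold,
            refractory = refractory, dt = dt, u0 = u0)
  if (!all(is.finite(vals))) stop("LIF parameters must be finite", call. = FALSE)
  if (tau <= 0) stop("`tau` must be positive (ms)", call. = FALSE)
  if (C <= 0) stop("`C` must be positive (mF)", call. = FALSE)
  if (v_threshold <= 0) stop("`v_threshold` must be positive (mV)", call. = FALSE)
  if (refractory < 0) stop("`refractory` must be >= 0 (ms)", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive (ms)", call. = FALSE)
  p <- as.list(vals)
  p$R <- tau / C
  structure(p, class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat(sprintf(
    "<lif_params> tau %.4g ms, C %.4g mF (R %.4g Ohm), threshold %.4g mV, refractory %g ms, dt %g ms\n",
    x$tau, x$C, x$R, x$v_threshold, x$refractory, x$dt))
  invisible(x)
}

#' Spike train container
#'
#' Ordered spike times in ms from trace start, together with the stimulus
#' landmarks (onset, peak, stimulus end) needed to window
#' interspike-interval statistics.
#'
#' @param spike_times Strictly increasing numeric vector of spike times
#'   (ms); may be empty.
#' @param onset_time Stimulus onset time in ms (`NA` if not detected).
#' @param peak_time Time of peak indentation in ms.
#' @param stimulus_end End of the integrated stimulus in ms.
#' @return A `"spike_train"` list.
#' @export
spike_train <- function(spike_times, onset_time = NA_real_,
                        peak_time = NA_real_, stimulus_end = NA_real_) {
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) > 1 && any(diff(spike_times) <= 0))
    stop("spike times must be strictly increasing", call. = FALSE)
  if (is.finite(stimulus_end) && length(spike_times) &&
      (any(spike_times < 0) || any(spike_times > stimulus_end + 1e-9)))
    stop("spike times must lie within [0, stimulus_end]", call. = FALSE)
  structure(list(spike_times = spike_times, onset_time = onset_time,
                 peak_time = peak_time, stimulus_end = stimulus_end),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", length(x$spike_times)))
  if (length(x$spike_times))
    cat(sprintf(" in [%.2f, %.2f] ms", min(x$spike_times), max(x$spike_times)))
  if (is.finite(x$onset_time)) cat(sprintf(", onset %.1f ms", x$onset_time))
  if (is.finite(x$peak_time)) cat(sprintf(", peak %.1f ms", x$peak_time))
  cat("\n")
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$spike_times)

#' Integrate the LIF membrane over a current trace
#'
#' Advances the membrane equation `du/dt = -u/tau + I(t)/C` with the
#' classical fourth-order Runge-Kutta scheme at fixed step `dt` (0.01 ms
#' by default), from `u = u0` at the first current sample to the last
#' sample (stimulus offset). The current is held constant over each
#' sampling interval (zero-order hold, the default) or linearly
#' interpolated. Whenever `u >= v_threshold` at a step boundary, that
#' boundary is recorded as a spike time, `u` resets to `u0`, and the
#' membrane is clamped at `u0` for the refractory period. Spike times are
#' therefore quantized to multiples of `dt` and consecutive spikes are
#' never closer than the refractory period.
#'
#' @param current A [current_trace()].
#' @param params A [lif_params()].
#' @param interpolation `"hold"` (zero-order hold, default) or
#'   `"linear"`.
#' @param onset_time,peak_time Optional stimulus landmarks stored in the
#'   returned train.
#' @param record_potential If `TRUE`, also return the membrane potential
#'   sampled at the current trace's resolution (for plotting).
#' @return A [spike_train()]; with `record_potential`, the potential is
#'   attached as attribute `"potential"`.
#' @examples
#' cur <- current_trace(seq(0, 990, 10), rep(1.2672e-06, 100))
#' p <- lif_params(tau = 71.409, C = 9.70e-07, v_threshold = 47.300)
#' diff(integrate_lif(cur, p)$spike_times)[1]  # ~51.5 ms
#' @export
integrate_lif <- function(current, params,
                          interpolation = c("hold", "linear"),
                          onset_time = NA_real_, peak_time = NA_real_,
                          record_potential = FALSE) {
  stopifnot(inherits(current, "current_trace"), inherits(params, "lif_params"))
  interpolation <- match.arg(interpolation)
  if (length(current$currents) < 2)
    stop("current trace is empty or too short to integrate", call. = FALSE)
  res <- lif_integrate_cpp(current$currents, sampling_interval_ms(current),
                           params$dt, params$tau, params$C,
                           params$v_threshold, params$refractory, params$u0,
                           interpolation == "linear", record_potential)
  offset <- current$times[1]
  st <- spike_train(res$spike_times + offset, onset_time = onset_time,
                    peak_time = peak_time,
                    stimulus_end = current$times[length(current$times)])
  if (record_potential) attr(st, "potential") <- res$potential
  st
}

#' Closed-form constant-current interspike interval
#'
#' For a constant suprathreshold current the membrane potential rises as
#' `u(t) = R*I*(1 - exp(-t/tau))` from reset, so the time to threshold is
#' `tau * log(R*I / (R*I - v_threshold))` and the steady interspike
#' interval adds the refractory period. When `R*I <= v_threshold`
#' (at or below rheobase) the threshold is never reached and `NA` is
#' returned. This closed form is the independent oracle for the RK4
#' integrator.
#'
#' @param I Constant current in mA.
#' @param params A [lif_params()].
#' @return Steady-state ISI in ms, or `NA_real_` when no spike can occur.
#' @export
lif_constant_current_isi <- function(I, params) {
  stopifnot(inherits(params, "lif_params"))
  drive <- params$R * I
  if (!is.finite(drive) || drive <= params$v_threshold) return(NA_real_)
  params$refractory + params$tau * log(drive / (drive - params$v_threshold))
}
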
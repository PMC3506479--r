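#' The six free model parameters
#'
#' Bundles the transduction coefficients (`beta`, `k_s`, `k_d`) and the
#' membrane constants (`tau`, `C`, `v_threshold`) that parameter fitting
#' adjusts. The remaining constants are fixed: 1 ms refractory period,
#' 0.01 ms integration step, 0 mV rest/reset.
#'
#' Note the built-in degeneracy: scaling `beta`, `k_s`, `k_d` and `C`
#' jointly by any positive factor leaves `I(t)/C`, hence every spike
#' time, unchanged. Only the ratios `beta/C`, `k_s/C`, `k_d/C` together
#' with `tau` and `v_threshold` are identifiable from spike data; see
#' [identifiable_params()].
#'
#' @param beta Intercept, mA.
#' @param k_s Static gain, mA/N.
#' @param k_d Dynamic gain, mA·s/N.
#' @param tau Membrane time constant, ms.
#' @param C Membrane capacitance, mF.
#' @param v_threshold Firing threshold, mV.
#' @param h Backward-difference step for the force rate, ms (fixed
#'   constant, default 10).
#' @param refractory,dt,u0 Fixed membrane constants (defaults 1 ms,
#'   0.01 ms, 0 mV).
#' @return A `"model_params"` list.
#' @examples
#' model_params(2.72e-08, 6.20e-07, 2.71e-04, 71.409, 9.70e-07, 47.300)
#' @export
model_params <- function(beta, k_s, k_d, tau, C, v_threshold, h = 10,
                         refractory = 1, dt = 0.01, u0 = 0) {
  free <- c(beta = beta, k_s = k_s, k_d = k_d, tau = tau, C = C,
            v_threshold = v_threshold)
  if (!all(is.finite(free))) stop("model parameters must be finite", call. = FALSE)
  if (tau <= 0 || C <= 0 || v_threshold <= 0)
    stop("`tau`, `C` and `v_threshold` must be positive", call. = FALSE)
  structure(list(beta = unname(beta), k_s = unname(k_s), k_d = unname(k_d),
                 tau = unname(tau), C = unname(C),
                 v_threshold = unname(v_threshold), h = unname(h),
                 refractory = unname(refractory), dt = unname(dt),
                 u0 = unname(u0)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  beta  %.6g mA      k_s %.6g mA/N   k_d %.6g mA.s/N\n",
              x$beta, x$k_s, x$k_d))
  cat(sprintf("  tau   %.6g ms      C   %.6g mF     v_threshold %.6g mV\n",
              x$tau, x$C, x$v_threshold))
  invisible(x)
}

as_param_vector <- function(p) {
  c(beta = p$beta, k_s = p$k_s, k_d = p$k_d, tau = p$tau, C = p$C,
    v_threshold = p$v_threshold)
}

params_from_vector <- function(v, template) {
  model_params(v[["beta"]], v[["k_s"]], v[["k_d"]], v[["tau"]], v[["C"]],
               v[["v_threshold"]], h = template$h,
               refractory = template$refractory, dt = template$dt,
               u0 = template$u0)
}

transduction_of <- function(p) transduction_params(p$beta, p$k_s, p$k_d, p$h)

lif_of <- function(p) lif_params(p$tau, p$C, p$v_threshold, p$refractory,
                                 p$dt, p$u0)

#' Identifiable parameter combinations
#'
#' Returns the five combinations that spike data can pin down:
#' `beta/C`, `k_s/C`, `k_d/C`, `tau`, `v_threshold`. Two parameter sets
#' related by the joint `(beta, k_s, k_d, C)` scaling produce identical
#' spike trains and identical identifiable vectors.
#'
#' @param params A [model_params()].
#' @return Named numeric vector of length 5.
#' @export
identifiable_params <- function(params) {
  stopifnot(inherits(params, "model_params"))
  c(beta_over_C = params$beta / params$C,
    k_s_over_C = params$k_s / params$C,
    k_d_over_C = params$k_d / params$C,
    tau = params$tau,
    v_threshold = params$v_threshold)
}

#' Predict the spiking response to a force trace
#'
#' Runs the full forward model on one conditioned force trace: detect
#' onset (1 N rule by default) and peak, transduce force and force rate
#' into current, integrate the LIF membrane, and summarize the spike
#' train with phase-windowed ISI statistics.
#'
#' @param trace A conditioned [force_trace()] (filter/noise applied
#'   upstream as desired).
#' @param params A [model_params()].
#' @param onset_mode,onset_threshold Passed to [detect_onset()].
#' @param interpolation Current interpolation for [integrate_lif()].
#' @return A list with `spikes` (a [spike_train()]), `summary` (an
#'   `"isi_summary"`), `onset_time` and `peak_time`.
#' @examples
#' tr <- generate_ramp_hold(stimulus_protocol("III"))
#' p <- model_params(2.72e-08, 6.20e-07, 2.71e-04, 71.409, 9.70e-07, 47.300)
#' predict_response(tr, p)$summary
#' @export
predict_response <- function(trace, params,
                             onset_mode = "force_threshold",
                             onset_threshold = NULL,
                             interpolation = "hold") {
  stopifnot(inherits(trace, "force_trace"), inherits(params, "model_params"))
  onset_time <- detect_onset(trace, mode = onset_mode,
                             threshold = onset_threshold)
  peak_time <- detect_peak(trace)
  onset_index <- if (is.finite(onset_time))
    which(trace$times == onset_time)[1] else 0L
  current <- transduce(trace, transduction_of(params), onset_index)
  spikes <- integrate_lif(current, lif_of(params),
                          interpolation = interpolation,
                          onset_time = onset_time, peak_time = peak_time)
  summ <- if (is.finite(onset_time) && is.finite(peak_time))
    phase_isi_means(spikes) else
      structure(list(dyn_isi_mean = NA_real_, stat_isi_mean = NA_real_,
                     first_spike_latency = NA_real_, stat_isi_cv = NA_real_,
                     n_dyn_isis = 0L, n_stat_isis = 0L),
                class = "isi_summary")
  list(spikes = spikes, summary = summ, onset_time = onset_time,
       peak_time = peak_time)
}

#' Predicted ISI table for a set of labelled traces
#'
#' Applies [predict_response()] to every trace and collects the
#' per-trace dependent metrics in a data frame, one row per trace, with
#' the indentation type and block labels carried through — the shape the
#' fitting objective and the block-design ANOVA consume.
#'
#' @param traces A list of [force_trace()]s, each carrying `type` and
#'   `block` attributes (as produced by [simulate_experiment()]), or a
#'   bare list plus explicit `types`/`blocks` vectors.
#' @param params A [model_params()].
#' @param types,blocks Optional explicit labels overriding the trace
#'   attributes.
#' @inheritParams predict_response
#' @return A data frame with columns `type`, `block`, `dyn_isi_ms`,
#'   `stat_isi_ms`, `latency_ms`, `stat_cv`, `n_spikes`.
#' @export
predict_isi_table <- function(traces, params, types = NULL, blocks = NULL,
                              onset_mode = "force_threshold",
                              onset_threshold = NULL) {
  stopifnot(is.list(traces), length(traces) >= 1)
  if (is.null(types))
    types <- vapply(traces, function(tr) attr(tr, "type") %||% NA_character_,
                    character(1))
  if (is.null(blocks))
    blocks <- vapply(traces, function(tr) attr(tr, "block") %||% NA_integer_,
                     numeric(1))
  rows <- lapply(seq_along(traces), function(i) {
    pr <- predict_response(traces[[i]], params, onset_mode = onset_mode,
                           onset_threshold = onset_threshold)
    s <- pr$summary
    data.frame(type = types[i], block = blocks[i],
               dyn_isi_ms = s$dyn_isi_mean, stat_isi_ms = s$stat_isi_mean,
               latency_ms = s$first_spike_latency, stat_cv = s$stat_isi_cv,
               n_spikes = length(pr$spikes$spike_times))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
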
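#' @export
print.ss_fit <- function(x, ...) {
  cat("Spiking-sensor model fit (response-surface steepest ascent)\n")
  n_iter <- max(x$iterations$iteration)
  cat(sprintf("  %d accepted iteration(s); FSS %.4f -> %.4f\n",
              n_iter, x$iterations$fss[1], x$fss$fss))
  cat(sprintf("  components: dynamic %.4f, static %.4f (weights %.2g/%.2g)\n",
              x$fss$dyn_component, x$fss$stat_component,
              x$weights[1], x$weights[2]))
  cat("  end parameters:\n")
  v <- as_param_vector(x$end_params)
  cat(sprintf("    %s\n", paste(names(v), signif(v, 5), sep = " = ",
                                collapse = ", ")))
  invisible(x)
}

#' Summary of a spiking-sensor model fit
#'
#' Prints the session log — one row per accepted iteration with the six
#' parameter values and the FSS reached — followed by the per-type
#' comparison of observed targets and fitted predictions.
#'
#' @param object An `"ss_fit"` from [rsm_fit()].
#' @param ... Unused.
#' @return `object`, invisibly.
#' @export
summary.ss_fit <- function(object, ...) {
  print(object)
  cat("\nSession log:\n")
  log <- object$iterations
  log[] <- lapply(log, function(col) if (is.numeric(col)) signif(col, 5)
                  else col)
  print(log, row.names = FALSE)
  cat("\nObserved vs fitted per-type means:\n")
  print(fitted_vs_observed(object), row.names = FALSE)
  invisible(object)
}

fitted_vs_observed <- function(object) {
  pred <- predict(object)
  agg <- stats::aggregate(pred[c("dyn_isi_ms", "stat_isi_ms")],
                          by = list(type = pred$type), FUN = mean)
  m <- merge(object$observed, agg, by = "type")
  names(m)[names(m) == "dyn_isi_ms"] <- "fit_dyn_isi_ms"
  names(m)[names(m) == "stat_isi_ms"] <- "fit_stat_isi_ms"
  m
}

#' Fitted model parameters
#'
#' @param object An `"ss_fit"` from [rsm_fit()].
#' @param ... Unused.
#' @return Named numeric vector of the six fitted parameters.
#' @export
coef.ss_fit <- function(object, ...) as_param_vector(object$end_params)

#' Predict ISI metrics from a fitted model
#'
#' Runs the fitted parameters forward over traces (the training traces
#' by default) and returns the per-trace dependent metrics.
#'
#' @param object An `"ss_fit"`.
#' @param newdata Optional list of type-labelled [force_trace()]s;
#'   defaults to the training traces.
#' @param ... Unused.
#' @return A data frame as from [predict_isi_table()].
#' @export
predict.ss_fit <- function(object, newdata = NULL, ...) {
  traces <- newdata %||% object$train_traces
  predict_isi_table(traces, object$end_params,
                    onset_mode = object$onset_mode,
                    onset_threshold = object$onset_threshold)
}

#' Residuals of a spiking-sensor model fit
#'
#' Observed minus predicted ISI means, one row per training trace, for
#' each phase.
#'
#' @param object An `"ss_fit"`.
#' @param ... Unused.
#' @return A data frame with columns `type`, `block`, `dyn_residual_ms`,
#'   `stat_residual_ms`.
#' @export
residuals.ss_fit <- function(object, ...) {
  pred <- predict(object)
  m <- merge(pred, object$observed, by = "type")
  data.frame(type = m$type, block = m$block,
             dyn_residual_ms = m$obs_dyn_isi_ms - m$dyn_isi_ms,
             stat_residual_ms = m$obs_stat_isi_ms - m$stat_isi_ms)
}

#' Plot the FSS trajectory of a fitting session
#'
#' @param x An `"ss_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ss_fit <- function(x, ...) {
  graphics::plot(x$iterations$iteration, x$iterations$fss, type = "b",
                 xlab = "iteration", ylab = "FSS", ...)
  invisible(x)
}

#' Simulate spike trains from a fitted model
#'
#' Applies the fitted parameters to traces (the training traces by
#' default) and returns the resulting spike trains.
#'
#' @param object An `"ss_fit"`.
#' @param nsim Number of repetitions (the forward model is deterministic,
#'   so repetitions are identical; `nsim > 1` is mainly for API
#'   symmetry).
#' @param seed Unused (kept for the [stats::simulate()] signature).
#' @param traces Optional list of [force_trace()]s.
#' @param ... Unused.
#' @return A list (length `nsim`) of lists of [spike_train()]s.
#' @export
simulate.ss_fit <- function(object, nsim = 1, seed = NULL, traces = NULL,
                            ...) {
  traces <- traces %||% object$train_traces
  one <- lapply(traces, function(tr)
    predict_response(tr, object$end_params,
                     onset_mode = object$onset_mode,
                     onset_threshold = object$onset_threshold)$spikes)
  rep(list(one), nsim)
}
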
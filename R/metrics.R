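#' Interspike intervals
#'
#' `ISI_i = t_{i+1} - t_i`, the time difference between consecutive
#' spikes. A train with fewer than two spikes yields an empty vector.
#'
#' @param spikes A [spike_train()] or a numeric vector of strictly
#'   increasing spike times (ms).
#' @return Numeric vector of ISIs in ms, length `n_spikes - 1`.
#' @examples
#' isi(c(10, 30, 60))  # 20 30
#' @export
isi <- function(spikes) {
  times <- spike_times_of(spikes)
  if (length(times) < 2) return(numeric(0))
  diff(times)
}

spike_times_of <- function(spikes) {
  if (inherits(spikes, "spike_train")) return(spikes$spike_times)
  if (is.numeric(spikes)) {
    if (length(spikes) > 1 && any(diff(spikes) <= 0))
      stop("spike times must be strictly increasing", call. = FALSE)
    return(as.numeric(spikes))
  }
  stop("`spikes` must be a spike_train or numeric spike times", call. = FALSE)
}

#' Detect stimulus onset and peak in a force trace
#'
#' Onset is the first sample whose force exceeds a threshold
#' (`mode = "force_threshold"`, default 1 N — the rule used for the
#' sensor-in-substrate traces), or the first sample whose
#' backward-difference force rate exceeds a rate threshold
#' (`mode = "dforce_threshold"`, default 5e-4 N/ms = 0.5 mN/ms — the rule
#' used for afferent recordings). If the threshold is never crossed the
#' result is `NA_real_`, distinguishable from an onset at time 0.
#'
#' The peak is the time at which force reaches its maximum; ties resolve
#' to the earliest such sample, so a monotone ramp followed by a flat
#' plateau peaks at the first plateau sample.
#'
#' @param trace A [force_trace()].
#' @param mode Onset rule, `"force_threshold"` or `"dforce_threshold"`.
#' @param threshold Threshold in N (force mode) or N/ms (dforce mode);
#'   defaults 1 and 5e-4 respectively.
#' @param h Difference step (ms) for the dforce rule; defaults to one
#'   sampling interval.
#' @return `detect_onset()`: onset time in ms or `NA_real_`;
#'   `detect_peak()`: peak time in ms.
#' @export
detect_onset <- function(trace,
                         mode = c("force_threshold", "dforce_threshold"),
                         threshold = NULL, h = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  mode <- match.arg(mode)
  if (mode == "force_threshold") {
    if (is.null(threshold)) threshold <- 1
    idx <- which(trace$forces > threshold)
  } else {
    if (is.null(threshold)) threshold <- 5e-4
    if (is.null(h)) h <- sampling_interval_ms(trace)
    rate <- force_derivative(trace, h = h, onset_index = 0L)
    idx <- which(rate > threshold)
  }
  if (!length(idx)) return(NA_real_)
  trace$times[idx[1]]
}

#' @rdname detect_onset
#' @export
detect_peak <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  trace$times[which.max(trace$forces)]
}

#' Phase windows for interspike-interval statistics
#'
#' The dynamic window runs from stimulus onset to the time of peak
#' indentation; the static window runs from 2 to 5 seconds after onset,
#' inside the sustained hold. Both windows are closed: spikes exactly on
#' an edge belong to the window, and an ISI belongs to a window only when
#' both of its spikes do.
#'
#' @param onset_time Stimulus onset in ms.
#' @param peak_time Peak-indentation time in ms.
#' @param static_offsets Start/end of the static window relative to
#'   onset, ms (default `c(2000, 5000)`).
#' @return A `"phase_windows"` list with `onset_time`, `peak_time`,
#'   `static_start`, `static_end`.
#' @export
phase_windows <- function(onset_time, peak_time,
                          static_offsets = c(2000, 5000)) {
  if (!is.finite(onset_time) || !is.finite(peak_time))
    stop("onset and peak times must be finite", call. = FALSE)
  w <- list(onset_time = onset_time, peak_time = peak_time,
            static_start = onset_time + static_offsets[1],
            static_end = onset_time + static_offsets[2])
  if (!(w$onset_time <= w$peak_time && w$peak_time <= w$static_start &&
        w$static_start < w$static_end))
    stop("windows must satisfy onset <= peak <= static_start < static_end",
         call. = FALSE)
  structure(w, class = "phase_windows")
}

windows_for <- function(spikes) {
  phase_windows(spikes$onset_time, spikes$peak_time)
}

isis_within <- function(times, lo, hi) {
  inside <- times >= lo & times <= hi
  keep <- inside[-length(inside)] & inside[-1]
  diff(times)[keep]
}

#' Phase-windowed ISI summary
#'
#' Computes the dependent metrics of the model: the mean ISI over the
#' dynamic ramp-up window (onset to peak), the mean ISI over the static
#' hold window (2-5 s after onset), the first-spike latency, and the
#' coefficient of variation of static-window ISIs. Means are `NA` (with a
#' zero count) when no ISI falls entirely inside the window.
#'
#' @param spikes A [spike_train()] carrying onset and peak times, or any
#'   spike train plus an explicit `windows` argument.
#' @param windows A [phase_windows()]; defaults to the train's own
#'   landmarks.
#' @return An `"isi_summary"` list: `dyn_isi_mean`, `stat_isi_mean`,
#'   `first_spike_latency`, `stat_isi_cv`, `n_dyn_isis`, `n_stat_isis`.
#' @export
phase_isi_means <- function(spikes, windows = NULL) {
  times <- spike_times_of(spikes)
  if (is.null(windows)) windows <- windows_for(spikes)
  stopifnot(inherits(windows, "phase_windows"))
  dyn <- if (length(times) >= 2)
    isis_within(times, windows$onset_time, windows$peak_time) else numeric(0)
  stat <- if (length(times) >= 2)
    isis_within(times, windows$static_start, windows$static_end) else numeric(0)
  structure(list(
    dyn_isi_mean = if (length(dyn)) mean(dyn) else NA_real_,
    stat_isi_mean = if (length(stat)) mean(stat) else NA_real_,
    first_spike_latency = first_spike_latency(times, windows$onset_time),
    stat_isi_cv = if (length(stat) >= 2) stats::sd(stat) / mean(stat)
                  else NA_real_,
    n_dyn_isis = length(dyn),
    n_stat_isis = length(stat)
  ), class = "isi_summary")
}

#' @export
print.isi_summary <- function(x, ...) {
  cat(sprintf(
    "<isi_summary> dyn %.2f ms (n=%d), stat %.2f ms (n=%d), latency %.2f ms, stat CV %.3f\n",
    x$dyn_isi_mean, x$n_dyn_isis, x$stat_isi_mean, x$n_stat_isis,
    x$first_spike_latency, x$stat_isi_cv))
  invisible(x)
}

#' First-spike latency
#'
#' Time elapsed from stimulus onset to the first spike at or after onset;
#' `NA_real_` when there is no such spike.
#'
#' @param spikes A [spike_train()] or numeric spike times (ms).
#' @param onset_time Stimulus onset in ms.
#' @return Latency in ms (>= 0) or `NA_real_`.
#' @export
first_spike_latency <- function(spikes, onset_time) {
  times <- spike_times_of(spikes)
  if (!is.finite(onset_time)) return(NA_real_)
  after <- times[times >= onset_time]
  if (!length(after)) return(NA_real_)
  after[1] - onset_time
}

#' Coefficient of variation of static-window ISIs
#'
#' Standard deviation over mean of the ISIs lying entirely within the
#' static hold window, using the sample (n-1) standard deviation.
#' Requires at least two static-window ISIs; otherwise `NA_real_`.
#'
#' @inheritParams phase_isi_means
#' @return Dimensionless CV, or `NA_real_`.
#' @export
static_isi_cv <- function(spikes, windows = NULL) {
  phase_isi_means(spikes, windows)$stat_isi_cv
}
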
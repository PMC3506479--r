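#' Force and current trace containers
#'
#' A `force_trace` is a uniformly sampled force time series `f(t)` — the
#' model's stand-in for the force detected by a sensor embedded in an
#' elastic, skin-like substrate. A `current_trace` is the transmembrane
#' current series `I(t)` produced from it by [transduce()]. Both store
#' times in ms from trace start and enforce exactly uniform spacing of
#' `1000 / sampling_rate` ms.
#'
#' @param times Numeric vector of sample times in ms, uniformly spaced,
#'   starting at any offset (conventionally 0).
#' @param forces Numeric vector of forces in N, same length as `times`.
#' @param sampling_rate Sampling rate in Hz (default 100, i.e. 10 ms
#'   spacing).
#' @return An object of class `"force_trace"` (or `"current_trace"`): a
#'   list with the time and value vectors plus the sampling rate.
#' @examples
#' tr <- force_trace(seq(0, 90, by = 10), rep(2, 10))
#' tr
#' @export
force_trace <- function(times, forces, sampling_rate = 100) {
  validate_uniform_times(times, sampling_rate)
  if (length(forces) != length(times))
    stop("`forces` and `times` must have the same length", call. = FALSE)
  if (!all(is.finite(forces)))
    stop("forces must be finite", call. = FALSE)
  structure(list(times = as.numeric(times), forces = as.numeric(forces),
                 sampling_rate = sampling_rate),
            class = "force_trace")
}

#' @param currents Numeric vector of transmembrane currents in mA.
#' @rdname force_trace
#' @export
current_trace <- function(times, currents, sampling_rate = 100) {
  validate_uniform_times(times, sampling_rate)
  if (length(currents) != length(times))
    stop("`currents` and `times` must have the same length", call. = FALSE)
  if (!all(is.finite(currents)))
    stop("currents must be finite", call. = FALSE)
  structure(list(times = as.numeric(times), currents = as.numeric(currents),
                 sampling_rate = sampling_rate),
            class = "current_trace")
}

# spacing must equal 1000/sampling_rate exactly (to fp tolerance);
# length >= 2 so a spacing exists
validate_uniform_times <- function(times, sampling_rate) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be a positive number (Hz)", call. = FALSE)
  if (length(times) < 2)
    stop("a trace needs at least 2 samples", call. = FALSE)
  dt <- 1000 / sampling_rate
  gaps <- diff(times)
  if (any(abs(gaps - dt) > 1e-6 * dt))
    stop(sprintf("sample times must be uniformly spaced at %g ms", dt),
         call. = FALSE)
  invisible(TRUE)
}

sampling_interval_ms <- function(trace) 1000 / trace$sampling_rate

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %d samples @ %g Hz, %.0f-%.0f ms, peak %.3g N\n",
              length(x$times), x$sampling_rate, min(x$times), max(x$times),
              max(x$forces)))
  invisible(x)
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples @ %g Hz, peak %.4g mA\n",
              length(x$times), x$sampling_rate, max(x$currents)))
  invisible(x)
}

#' @export
as.data.frame.force_trace <- function(x, ...) {
  data.frame(time_ms = x$times, force_N = x$forces)
}

#' @export
as.data.frame.current_trace <- function(x, ...) {
  data.frame(time_ms = x$times, current_mA = x$currents)
}

#' @export
length.force_trace <- function(x) length(x$times)

#' @export
length.current_trace <- function(x) length(x$times)

#' @export
plot.force_trace <- function(x, ..., xlab = "time (ms)", ylab = "force (N)",
                             type = "l") {
  graphics::plot(x$times, x$forces, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# seeded evaluation that leaves the caller's RNG stream untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
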
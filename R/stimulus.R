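#' Ramp-and-hold stimulus protocols
#'
#' The experimental design uses five coded indentation types. Types I, II
#' and III share a 1.2 mm commanded hold depth but ramp up at increasing
#' peak rates of force change (dForce levels 1.43, 1.78, 2.19); types IV
#' and V share type III's (highest) ramp rate but hold at 1.3 and 1.4 mm.
#' Each indentation holds for about 5 s and stimuli are presented at 60 s
#' intervals (metadata only — traces are generated independently).
#'
#' `dforce_unit_scale` converts the coded dForce level to N/ms. The
#' default `4.6e-3` was derived by inverting the closed-form
#' constant-current interspike interval against the dynamic-phase ISI
#' regime the model is meant to reproduce (mean ISIs of roughly 15-22 ms
#' during ramp-up under the published end-of-fit parameters): it yields
#' late-ramp force rates of 6.6e-3 to 1.0e-2 N/ms, ramp durations well
#' under 500 ms for plateau forces inside the sensor's 0-4.44 N range,
#' and a ramp current dominated by the dynamic term, as the transduction
#' model describes.
#'
#' @param indentation_type One of `"I"`..`"V"` (roman-numeral codes).
#' @param hold_duration Hold-phase duration in ms (default 5000).
#' @param sampling_rate Sampling rate in Hz (default 100).
#' @param dforce_unit_scale Multiplier turning the coded dForce level into
#'   N/ms (default `1e-3`).
#' @return A `"stimulus_protocol"` list with the coded treatment, hold
#'   depth (mm), ramp-rate level, target peak dForce, and timing fields.
#' @examples
#' stimulus_protocol("III")
#' @export
stimulus_protocol <- function(indentation_type = c("I", "II", "III", "IV", "V"),
                              hold_duration = 5000,
                              sampling_rate = 100,
                              dforce_unit_scale = 4.6e-3) {
  indentation_type <- match.arg(indentation_type)
  if (hold_duration <= 0) stop("`hold_duration` must be positive", call. = FALSE)
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive", call. = FALSE)
  depth <- c(I = 1.2, II = 1.2, III = 1.2, IV = 1.3, V = 1.4)[[indentation_type]]
  level <- c(I = "low", II = "med", III = "high", IV = "high",
             V = "high")[[indentation_type]]
  dforce <- c(low = 1.43, med = 1.78, high = 2.19)[[level]]
  structure(list(
    indentation_type = indentation_type,
    hold_depth = depth,
    ramp_rate_level = level,
    target_peak_dforce = dforce,
    dforce_unit_scale = dforce_unit_scale,
    hold_duration = hold_duration,
    start_gap = 0.6,
    sampling_rate = sampling_rate,
    inter_stimulus_interval = 60
  ), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "<stimulus_protocol> type %s: hold %.1f mm, ramp level %s (dForce %.2f), hold %g ms @ %g Hz\n",
    x$indentation_type, x$hold_depth, x$ramp_rate_level, x$target_peak_dforce,
    x$hold_duration, x$sampling_rate))
  invisible(x)
}

#' Generator shape settings for synthetic ramp-and-hold traces
#'
#' Controls the deterministic shape of the synthetic sensor-detected force
#' profile: a substrate-induced onset delay, a linear ramp at the
#' protocol's peak dForce rate, an optional first-order lag that rounds
#' the ramp shoulder, and a single-exponential plateau relaxation during
#' the hold.
#'
#' The default hold-depth to plateau-force map (1.2/1.3/1.4 mm to
#' 1.35/1.92/2.37 N) was chosen from the closed-form constant-current
#' interspike interval so that the published end-of-fit model parameters
#' place hold-phase firing in the tens-of-ms static-ISI regime typical of
#' SAI afferents, with the 1 N onset rule just above the rheobase force.
#'
#' @param gap_delay Delay before ramp start in ms, emulating the indenter
#'   travelling the 0.6 mm start gap and the substrate's lagged response
#'   (default 100).
#' @param rise_time_constant First-order lag applied to the commanded
#'   profile, ms; 0 (default) keeps the piecewise-linear ramp exact.
#' @param plateau_force Plateau force in N, or `NULL` to map from the
#'   protocol's hold depth via `plateau_map`.
#' @param plateau_map Named vector mapping hold depth (mm, as character)
#'   to plateau force (N).
#' @param relaxation_amplitude Fraction of the plateau lost to substrate
#'   relaxation during the hold (default 0.05).
#' @param relaxation_time_constant Relaxation time constant in ms
#'   (default 800).
#' @param retraction If `TRUE`, append a ramp-down back to zero at the
#'   ramp rate after the hold (off by default; the retraction phase is
#'   not analyzed).
#' @return A `"ramp_shape"` settings list.
#' @export
ramp_shape <- function(gap_delay = 100,
                       rise_time_constant = 0,
                       plateau_force = NULL,
                       plateau_map = c("1.2" = 1.35, "1.3" = 1.92, "1.4" = 2.37),
                       relaxation_amplitude = 0.05,
                       relaxation_time_constant = 800,
                       retraction = FALSE) {
  if (gap_delay < 0) stop("`gap_delay` must be >= 0", call. = FALSE)
  if (rise_time_constant < 0) stop("`rise_time_constant` must be >= 0", call. = FALSE)
  if (!is.null(plateau_force) && plateau_force <= 0)
    stop("`plateau_force` must be positive", call. = FALSE)
  if (relaxation_amplitude < 0 || relaxation_amplitude >= 1)
    stop("`relaxation_amplitude` must be in [0, 1)", call. = FALSE)
  if (relaxation_time_constant <= 0)
    stop("`relaxation_time_constant` must be positive", call. = FALSE)
  structure(list(gap_delay = gap_delay,
                 rise_time_constant = rise_time_constant,
                 plateau_force = plateau_force,
                 plateau_map = plateau_map,
                 relaxation_amplitude = relaxation_amplitude,
                 relaxation_time_constant = relaxation_time_constant,
                 retraction = retraction),
            class = "ramp_shape")
}

#' Generate a synthetic ramp-and-hold force trace
#'
#' Emulates the force detected by a sensor embedded in an elastic
#' substrate during a ramp-and-hold indentation: zero force during the
#' onset gap, a monotone linear rise at the protocol's peak dForce rate
#' up to the plateau, then a slow single-exponential relaxation toward
#' `plateau * (1 - relaxation_amplitude)` over the ~5 s hold. The profile
#' is deterministic; measurement noise is added separately by
#' [add_noise()] and conditioned by [gaussian_lowpass()].
#'
#' @param protocol A [stimulus_protocol()].
#' @param shape A [ramp_shape()] settings list.
#' @param seed Optional integer seed (the default shape is deterministic;
#'   the seed is honoured so noisy extensions stay reproducible).
#' @return A [force_trace()].
#' @examples
#' tr <- generate_ramp_hold(stimulus_protocol("III"))
#' max(tr$forces)
#' @export
generate_ramp_hold <- function(protocol, shape = ramp_shape(), seed = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (!inherits(shape, "ramp_shape")) shape <- do.call(ramp_shape, shape)
  plateau <- shape$plateau_force
  if (is.null(plateau)) {
    key <- format(protocol$hold_depth, nsmall = 1)
    plateau <- unname(shape$plateau_map[[key]])
    if (is.null(plateau) || is.na(plateau))
      stop("no plateau force mapped for hold depth ", key, call. = FALSE)
  }
  if (plateau <= 0) stop("plateau force must be positive", call. = FALSE)
  rate <- protocol$target_peak_dforce * protocol$dforce_unit_scale  # N/ms
  if (rate <= 0) stop("ramp rate must be positive", call. = FALSE)

  step <- 1000 / protocol$sampling_rate
  ramp_dur <- plateau / rate
  total <- shape$gap_delay + ramp_dur + protocol$hold_duration
  if (isTRUE(shape$retraction)) total <- total + ramp_dur
  times <- seq(0, by = step, length.out = floor(total / step) + 1)

  t_ramp0 <- shape$gap_delay
  t_hold0 <- shape$gap_delay + ramp_dur
  t_hold1 <- t_hold0 + protocol$hold_duration

  commanded <- function(t) {
    f <- numeric(length(t))
    ramp <- t > t_ramp0 & t < t_hold0
    f[ramp] <- rate * (t[ramp] - t_ramp0)
    hold <- t >= t_hold0 & t <= t_hold1
    f[hold] <- plateau * (1 - shape$relaxation_amplitude *
                            (1 - exp(-(t[hold] - t_hold0) /
                                       shape$relaxation_time_constant)))
    if (isTRUE(shape$retraction)) {
      retr <- t > t_hold1
      f_end <- plateau * (1 - shape$relaxation_amplitude *
                            (1 - exp(-protocol$hold_duration /
                                       shape$relaxation_time_constant)))
      f[retr] <- pmax(0, f_end - rate * (t[retr] - t_hold1))
    }
    f
  }
  forces <- with_seed(seed, commanded(times))

  if (shape$rise_time_constant > 0) {
    # first-order lag y' = (u - y)/tc, discretized exactly per sample
    a <- exp(-step / shape$rise_time_constant)
    y <- numeric(length(forces))
    for (i in seq_along(forces)[-1])
      y[i] <- a * y[i - 1] + (1 - a) * forces[i]
    forces <- y
  }
  force_trace(times, forces, protocol$sampling_rate)
}

#' Low-pass Gaussian filter for force traces
#'
#' Removes sensor noise above the cutoff the way the bench instrumentation
#' does: forward FFT, multiplication of the spectrum by a Gaussian taper
#' (unity gain at DC, standard deviation set so the gain at the cutoff is
#' `cutoff_gain`), a hard zero above the cutoff, inverse FFT, real part.
#' The trace is mirror-padded to the next power of two before the
#' transform to suppress wrap-around transients at the trace edges, then
#' truncated back.
#'
#' Because the taper is strictly below 1 everywhere except DC, the filter
#' is not idempotent: filtering twice attenuates pass-band content
#' further (each application multiplies the spectrum by the taper).
#' Above-cutoff content, however, is removed in one pass.
#'
#' With `pad = TRUE` (the default) the trace is extended before the
#' transform, which suppresses the wrap-around transient a circular DFT
#' would otherwise smear across the onset, at the cost of a small amount
#' of truncation leakage back into the stop band (relative residual
#' power around 1e-5 for white noise). `pad = FALSE` filters the raw
#' circular DFT: the stop band is then zeroed exactly, but traces whose
#' ends differ (a ramp-and-hold) ring at the edges.
#'
#' @param trace A [force_trace()].
#' @param cutoff Cutoff frequency in Hz (default 15); must be below the
#'   Nyquist frequency.
#' @param cutoff_gain Taper gain at the cutoff (default `1e-3`); fixes the
#'   Gaussian's standard deviation via
#'   `sigma = cutoff / sqrt(-2 * log(cutoff_gain))`.
#' @param pad Mirror-pad to the next power of two before transforming
#'   (default `TRUE`).
#' @return A filtered [force_trace()] of the same length and rate.
#' @export
gaussian_lowpass <- function(trace, cutoff = 15, cutoff_gain = 1e-3,
                             pad = TRUE) {
  stopifnot(inherits(trace, "force_trace"))
  nyquist <- trace$sampling_rate / 2
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= nyquist)
    stop(sprintf("`cutoff` must lie in (0, %g) Hz (below Nyquist)", nyquist),
         call. = FALSE)
  if (cutoff_gain <= 0 || cutoff_gain >= 1)
    stop("`cutoff_gain` must be in (0, 1)", call. = FALSE)
  x <- trace$forces
  n <- length(x)
  if (pad) {
    npad <- 2^ceiling(log2(2 * n))
    # hold the last value out to npad/2, then reflect: the result is an
    # even, npad-periodic, continuous extension, so no wrap-around
    # transient leaks into the retained first n samples
    half <- npad / 2
    xp <- c(x, rep(x[n], half - n))
    ext <- c(xp, rev(xp))
  } else {
    npad <- n
    ext <- x
  }
  freqs <- seq(0, npad - 1) * (trace$sampling_rate / npad)
  freqs <- pmin(freqs, trace$sampling_rate - freqs)  # two-sided
  sigma <- cutoff / sqrt(-2 * log(cutoff_gain))
  gain <- exp(-freqs^2 / (2 * sigma^2))
  gain[freqs > cutoff] <- 0
  y <- Re(stats::fft(stats::fft(ext) * gain, inverse = TRUE)) / npad
  force_trace(trace$times, y[seq_len(n)], trace$sampling_rate)
}

#' Add Gaussian measurement noise to a force trace
#'
#' Adds i.i.d. zero-mean Gaussian perturbations to every sample,
#' reproducibly for a fixed seed. In the default pipeline noise is added
#' to the clean synthetic profile and then conditioned by
#' [gaussian_lowpass()], mirroring bench filtering; leaving the noise
#' unfiltered raises interspike-interval irregularity downstream.
#'
#' @param trace A [force_trace()].
#' @param sd Noise standard deviation in N (>= 0).
#' @param seed Optional integer seed.
#' @return A [force_trace()] with perturbed forces.
#' @export
add_noise <- function(trace, sd, seed = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  if (!is.numeric(sd) || length(sd) != 1 || !is.finite(sd) || sd < 0)
    stop("`sd` must be a single non-negative number (N)", call. = FALSE)
  if (sd == 0) return(trace)
  noise <- with_seed(seed, stats::rnorm(length(trace$forces), 0, sd))
  force_trace(trace$times, trace$forces + noise, trace$sampling_rate)
}
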
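#' Define a light-stimulation protocol
#'
#' A stimulus protocol describes the optogenetic light input driving GEF
#' recruitment and the observation windows around it: a pre-stimulus
#' baseline window, a single light pulse whose effective GEF-input window is
#' either a boxcar or an exponentially decaying profile, and a regular
#' sampling grid over the simulation horizon. All times are in seconds.
#'
#' @param t_start Stimulus onset (s).
#' @param light_duration Effective GEF-input window (s); must be positive.
#'   For the `"exponential_decay"` shape this still delimits the protocol
#'   bookkeeping (e.g. breakpoints) but the input itself decays from
#'   `t_start` onwards.
#' @param amplitude Dimensionless height of the input signal (default 1).
#' @param baseline_window Length-2 numeric, the pre-stimulus window (s) used
#'   for fold-change normalisation. Must lie entirely before `t_start`.
#' @param sampling_interval Sampling interval of the observation grid (s).
#' @param t_end Simulation horizon (s).
#' @param input_shape `"boxcar"` (default) or `"exponential_decay"`.
#' @param decay_rate Decay rate (1/s); required when
#'   `input_shape = "exponential_decay"`.
#'
#' @return An object of class `stimulus_protocol`.
#' @examples
#' prot <- stimulus_protocol()
#' active_gef_input(prot, c(100, 150, 200))
#' @export
stimulus_protocol <- function(t_start = 150, light_duration = 30,
                              amplitude = 1,
                              baseline_window = c(0, 150),
                              sampling_interval = 1, t_end = 600,
                              input_shape = c("boxcar", "exponential_decay"),
                              decay_rate = NULL) {
  input_shape <- match.arg(input_shape)
  stopifnot(is.numeric(t_start), length(t_start) == 1L, is.finite(t_start),
            is.numeric(light_duration), length(light_duration) == 1L,
            is.numeric(amplitude), length(amplitude) == 1L,
            is.numeric(baseline_window), length(baseline_window) == 2L,
            is.numeric(sampling_interval), length(sampling_interval) == 1L,
            is.numeric(t_end), length(t_end) == 1L)
  if (light_duration <= 0) stop("light_duration must be > 0")
  if (sampling_interval <= 0) stop("sampling_interval must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (baseline_window[1] >= baseline_window[2])
    stop("baseline_window must be an increasing pair of times")
  if (baseline_window[2] > t_start)
    stop("baseline_window must lie entirely before t_start")
  if (t_start + light_duration > t_end)
    stop("t_start + light_duration must not exceed t_end")
  if (input_shape == "exponential_decay") {
    if (is.null(decay_rate) || !is.finite(decay_rate) || decay_rate <= 0)
      stop("decay_rate (> 0) is required for the exponential_decay shape")
  } else {
    decay_rate <- 0
  }
  structure(
    list(t_start = t_start, light_duration = light_duration,
         amplitude = amplitude, baseline_window = baseline_window,
         sampling_interval = sampling_interval, t_end = t_end,
         input_shape = input_shape, decay_rate = decay_rate),
    class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol> ", x$input_shape,
      sprintf(" pulse at %g s for %g s, amplitude %g;", x$t_start,
              x$light_duration, x$amplitude),
      sprintf(" baseline [%g, %g] s, grid 0..%g by %g s\n",
              x$baseline_window[1], x$baseline_window[2], x$t_end,
              x$sampling_interval))
  invisible(x)
}

#' Evaluate the light-driven GEF input signal
#'
#' The input `f_signal(t)` is the fixed, time-dependent drive of GEF
#' recruitment: for the boxcar shape it equals `amplitude` on
#' `[t_start, t_start + light_duration)` and 0 elsewhere; for the
#' exponential shape it is `amplitude * exp(-decay_rate * (t - t_start))`
#' for `t >= t_start` and 0 before the stimulus.
#'
#' @param protocol A [stimulus_protocol()].
#' @param t Numeric vector of times (s); must lie within `[0, t_end]`.
#' @return Numeric vector of signal values (dimensionless).
#' @export
active_gef_input <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"), is.numeric(t))
  if (any(t < 0 | t > protocol$t_end))
    stop("t outside the simulation horizon [0, ", protocol$t_end, "]")
  out <- numeric(length(t))
  if (protocol$input_shape == "boxcar") {
    on <- t >= protocol$t_start &
      t < protocol$t_start + protocol$light_duration
    out[on] <- protocol$amplitude
  } else {
    on <- t >= protocol$t_start
    out[on] <- protocol$amplitude *
      exp(-protocol$decay_rate * (t[on] - protocol$t_start))
  }
  out
}

#' Sampling grid of a protocol
#'
#' @param protocol A [stimulus_protocol()].
#' @return Numeric vector `seq(0, t_end, by = sampling_interval)`.
#' @export
protocol_times <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  seq(0, protocol$t_end, by = protocol$sampling_interval)
}

# integration breakpoints where the input is non-smooth
protocol_breaks <- function(protocol) {
  if (protocol$input_shape == "boxcar") {
    c(protocol$t_start, protocol$t_start + protocol$light_duration)
  } else {
    protocol$t_start
  }
}
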
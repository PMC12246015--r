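#' Dynamic compression loading protocol
#'
#' A single raised-cosine compression-release cycle: the piston moves down
#' from the scaffold top face and back, with peak compression equal to
#' `amplitude_fraction` of the scaffold height at mid-cycle. Displacement
#' and velocity are both zero at the cycle ends.
#'
#' @param frequency loading frequency, Hz.
#' @param amplitude_fraction peak compression as a fraction of scaffold
#'   height (0 < a < 1); default 5 %.
#' @param scaffold_height mm.
#' @param timestep simulation time-step, s.
#' @return An object of class `loading_protocol` with the above fields plus
#'   `period` (s), `amplitude` (mm) and `n_timesteps` per cycle.
#' @export
loading_protocol <- function(frequency = 1, amplitude_fraction = 0.05,
                             scaffold_height = 4.8, timestep = 0.01) {
  stopifnot_scalar(frequency, "frequency", positive = TRUE)
  stopifnot_scalar(amplitude_fraction, "amplitude_fraction", positive = TRUE)
  if (amplitude_fraction >= 1)
    stop("'amplitude_fraction' must be < 1", call. = FALSE)
  stopifnot_scalar(scaffold_height, "scaffold_height", positive = TRUE)
  stopifnot_scalar(timestep, "timestep", positive = TRUE)
  period <- 1 / frequency
  structure(
    list(frequency = frequency, amplitude_fraction = amplitude_fraction,
         scaffold_height = scaffold_height, timestep = timestep,
         period = period, amplitude = amplitude_fraction * scaffold_height,
         n_timesteps = round(period / timestep)),
    class = "loading_protocol")
}

#' @export
print.loading_protocol <- function(x, ...) {
  cat(sprintf(paste0("Compression protocol: %g Hz, %.1f%% amplitude ",
                     "(%.3g mm), dt = %g s\n"),
              x$frequency, 100 * x$amplitude_fraction, x$amplitude,
              x$timestep))
  invisible(x)
}

protocol_times <- function(protocol) {
  seq(0, protocol$period, by = protocol$timestep)
}

check_cycle_time <- function(protocol, t) {
  if (any(t < -1e-12) || any(t > protocol$period + 1e-12))
    stop(sprintf("time outside the loading cycle [0, %g] s", protocol$period),
         call. = FALSE)
  invisible(t)
}

#' Piston displacement and velocity during the loading cycle
#'
#' `d(t) = A/2 (1 - cos(2 pi f t))` with `A` the peak compression in mm;
#' maximum `A` at mid-cycle (t = 0.5 s for 1 Hz), zero at the cycle ends.
#' The velocity is the analytic derivative `A pi f sin(2 pi f t)`, zero at
#' t = 0, mid-cycle and cycle end.
#'
#' @param protocol a [loading_protocol()].
#' @param t time(s) within the cycle, s.
#' @return Displacement in mm (velocity in mm/s for
#'   `piston_velocity()`); vectorised over `t`.
#' @examples
#' pr <- loading_protocol()
#' piston_displacement(pr, 0.5)  # 0.24 mm = 5% of 4.8 mm
#' @export
piston_displacement <- function(protocol, t) {
  stopifnot(inherits(protocol, "loading_protocol"))
  check_cycle_time(protocol, t)
  protocol$amplitude / 2 * (1 - cos(2 * pi * protocol$frequency * t))
}

#' @rdname piston_displacement
#' @export
piston_velocity <- function(protocol, t) {
  stopifnot(inherits(protocol, "loading_protocol"))
  check_cycle_time(protocol, t)
  protocol$amplitude * pi * protocol$frequency *
    sin(2 * pi * protocol$frequency * t)
}
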
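#' Harmonic optical trap model
#'
#' Describes the optical tweezers as a 2-D harmonic potential: the restoring
#' force on the bead is `F = kappa * (center - x)` per axis.
#'
#' @param kappa_x Trap stiffness along x (pN/um), > 0.
#' @param kappa_y Trap stiffness along y (pN/um), > 0. Defaults to `kappa_x`.
#' @param center Trap center, length-2 numeric (um).
#' @param temperature Absolute temperature (K), > 0. Default 303.15 K (30 C,
#'   the assay's growth and observation temperature).
#' @return An object of class `trap_model`.
#' @export
trap_model <- function(kappa_x, kappa_y = kappa_x, center = c(0, 0),
                       temperature = 303.15) {
  if (!is.numeric(kappa_x) || length(kappa_x) != 1L || !is.finite(kappa_x) ||
      kappa_x <= 0) {
    stop("'kappa_x' must be a single positive number (pN/um)")
  }
  if (!is.numeric(kappa_y) || length(kappa_y) != 1L || !is.finite(kappa_y) ||
      kappa_y <= 0) {
    stop("'kappa_y' must be a single positive number (pN/um)")
  }
  if (!is.numeric(center) || length(center) != 2L || any(!is.finite(center))) {
    stop("'center' must be a finite length-2 numeric (um)")
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("'temperature' must be a single positive number (K)")
  }
  structure(
    list(kappa = c(x = kappa_x, y = kappa_y),
         center = c(x = center[[1]], y = center[[2]]),
         temperature = temperature),
    class = "trap_model"
  )
}

#' @export
print.trap_model <- function(x, ...) {
  cat(sprintf(
    "<trap_model> kappa = (%.4g, %.4g) pN/um, center = (%.3g, %.3g) um, T = %.2f K\n",
    x$kappa[["x"]], x$kappa[["y"]], x$center[["x"]], x$center[["y"]],
    x$temperature))
  invisible(x)
}

#' Bead geometry and hydrodynamics
#'
#' Stores the bead radius and medium viscosity together with the derived
#' Stokes drag `gamma = 6 pi eta a` and Stokes-Einstein diffusion coefficient
#' `D = kB T / gamma`.
#'
#' @param radius Bead radius (um), > 0. The assay uses 0.5 um (1 um diameter,
#'   free swimmers) and 1.5 um (3 um diameter, trapped beads).
#' @param viscosity Dynamic viscosity (Pa s, numerically equal to pN s/um^2).
#'   Default 1.0e-3 (aqueous growth medium).
#' @param temperature Absolute temperature (K) used for the diffusion
#'   coefficient. Default 303.15 K.
#' @return An object of class `bead_geometry` with fields `radius`,
#'   `viscosity`, `drag` (pN s/um) and `diffusion` (um^2/s).
#' @export
bead_geometry <- function(radius, viscosity = 1.0e-3, temperature = 303.15) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("'radius' must be a single positive number (um)")
  }
  if (!is.numeric(viscosity) || length(viscosity) != 1L ||
      !is.finite(viscosity) || viscosity <= 0) {
    stop("'viscosity' must be a single positive number (Pa s)")
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("'temperature' must be a single positive number (K)")
  }
  drag <- stokes_drag(radius, viscosity)
  structure(
    list(radius = radius, viscosity = viscosity, temperature = temperature,
         drag = drag, diffusion = kB * temperature / drag),
    class = "bead_geometry"
  )
}

#' @export
print.bead_geometry <- function(x, ...) {
  cat(sprintf(
    "<bead_geometry> a = %.3g um, eta = %.3g Pa s, gamma = %.4g pN s/um, D = %.4g um^2/s\n",
    x$radius, x$viscosity, x$drag, x$diffusion))
  invisible(x)
}

#' Closed-form thermal reference quantities for a trapped bead
#'
#' The fluctuation statistics of a bead in a harmonic trap have closed forms
#' that anchor the thermal-fluctuation calibration: per-axis stationary
#' position variance `kB T / kappa`, relaxation time `gamma / kappa`,
#' Lorentzian corner frequency `kappa / (2 pi gamma)` and free diffusion
#' coefficient `kB T / gamma`.
#'
#' @param trap A [trap_model()].
#' @param bead A [bead_geometry()].
#' @return A list with per-axis `stationary_variance` (um^2),
#'   `relaxation_time` (s) and `corner_frequency` (Hz), plus scalar
#'   `diffusion` (um^2/s).
#' @export
thermal_reference <- function(trap, bead) {
  stopifnot(inherits(trap, "trap_model"), inherits(bead, "bead_geometry"))
  kT <- kB * trap$temperature
  list(
    stationary_variance = kT / trap$kappa,
    relaxation_time = bead$drag / trap$kappa,
    corner_frequency = trap$kappa / (2 * pi * bead$drag),
    diffusion = kT / bead$drag
  )
}

#' Uniformly sampled 2-D trajectory
#'
#' A bead (or flagellated-pole) position time series. Sampling must be
#' uniform; at least two samples are required.
#'
#' @param times Monotone increasing times (s), uniformly spaced.
#' @param x,y Positions (um).
#' @param frame_rate Sampling rate (Hz). Inferred from `times` if missing.
#' @param pole Logical; `TRUE` marks a flagellated-pole track of a
#'   surface-attached cell rather than a bead trajectory.
#' @return A data frame of class `trajectory` (and `pole_track` when
#'   `pole = TRUE`) with columns `t`, `x`, `y` and attribute `frame_rate`.
#' @export
trajectory <- function(times, x, y, frame_rate = NULL, pole = FALSE) {
  if (length(times) < 2L) {
    stop("a trajectory needs at least 2 samples")
  }
  if (length(x) != length(times) || length(y) != length(times)) {
    stop("'times', 'x' and 'y' must have equal length")
  }
  dt <- diff(times)
  if (any(dt <= 0)) stop("'times' must be strictly increasing")
  if (diff(range(dt)) > 1e-9) {
    stop("sampling must be uniform (within 1e-9 s)")
  }
  if (is.null(frame_rate)) frame_rate <- 1 / mean(dt)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("positions contain missing or non-finite samples")
  }
  out <- data.frame(t = as.numeric(times), x = as.numeric(x),
                    y = as.numeric(y))
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c(if (pole) "pole_track", "trajectory", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<%s> %d frames at %.4g Hz, %.4g s\n",
              if (inherits(x, "pole_track")) "pole_track" else "trajectory",
              nrow(x), frame_rate(x), x$t[nrow(x)] - x$t[1]))
  invisible(x)
}

#' Frame rate of a trajectory or image stack
#' @param x A `trajectory` or `image_stack`.
#' @return Sampling rate in Hz.
#' @export
frame_rate <- function(x) {
  fr <- attr(x, "frame_rate", exact = TRUE)
  if (is.null(fr) && is.list(x) && !is.null(x$frame_rate)) fr <- x$frame_rate
  fr
}

#' Behavioral event table
#'
#' Ordered, non-overlapping intervals of behavioral states. Emitted as ground
#' truth by the simulators and as inference output by [classify_states()].
#'
#' @param state Character vector of state labels.
#' @param start,end Interval bounds (s), sorted and non-overlapping.
#' @param attributes Optional list (one element per interval) of
#'   state-specific attributes.
#' @return A data frame of class `event_table` with columns `state`, `start`,
#'   `end` and a list-column `attributes`.
#' @export
event_table <- function(state, start, end, attributes = NULL) {
  n <- length(state)
  if (length(start) != n || length(end) != n) {
    stop("'state', 'start' and 'end' must have equal length")
  }
  if (n > 0) {
    if (any(end <= start)) stop("event durations must be positive")
    if (is.unsorted(start)) stop("events must be sorted by start time")
    if (n > 1 && any(start[-1] < end[-n] - 1e-9)) {
      stop("events must not overlap")
    }
  }
  if (is.null(attributes)) attributes <- rep(list(NULL), n)
  out <- data.frame(state = as.character(state), start = as.numeric(start),
                    end = as.numeric(end))
  out$attributes <- attributes
  class(out) <- c("event_table", "data.frame")
  out
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d intervals\n", nrow(x)))
  if (nrow(x) > 0) {
    print.data.frame(data.frame(state = x$state,
                                start = round(x$start, 3),
                                end = round(x$end, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' Behavioral schedule for a simulation
#'
#' Contiguous ground-truth program of behavioral states starting at time 0.
#'
#' @param state Character vector of states. Trapped-bead simulations accept
#'   `gyration`, `pilus_cycle`, `long_axis_rotation`, `brownian`; pole-track
#'   simulations accept `bending`, `long_axis_rotation`, `released`.
#' @param duration Segment durations (s), > 0.
#' @param params Optional list of per-segment parameter lists overriding the
#'   config defaults (e.g. `list(freq = 25, direction = "CCW")`).
#' @return A data frame of class `behavior_schedule` with columns `state`,
#'   `start`, `duration` and list-column `params`.
#' @export
behavior_schedule <- function(state, duration, params = NULL) {
  n <- length(state)
  if (length(duration) != n) stop("'state' and 'duration' lengths differ")
  if (any(duration <= 0)) stop("durations must be positive")
  if (is.null(params)) params <- rep(list(NULL), n)
  if (length(params) != n) stop("'params' must have one element per segment")
  out <- data.frame(state = as.character(state),
                    start = cumsum(c(0, duration[-n])),
                    duration = as.numeric(duration))
  out$params <- params
  class(out) <- c("behavior_schedule", "data.frame")
  out
}

#' @export
print.behavior_schedule <- function(x, ...) {
  cat(sprintf("<behavior_schedule> %d segments, %.4g s total\n",
              nrow(x), sum(x$duration)))
  print.data.frame(data.frame(state = x$state, start = round(x$start, 3),
                              duration = round(x$duration, 3)),
                   row.names = FALSE)
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles trap, bead and per-scenario driving parameters. Missing blocks are
#' filled from [paper_defaults()].
#'
#' @param trap A [trap_model()].
#' @param bead A [bead_geometry()].
#' @param frame_rate Output sampling rate (Hz).
#' @param integration_step Euler-Maruyama step (s). Default
#'   `min(1e-3, 1/(10*frame_rate))`; must not exceed `1/(2*frame_rate)`.
#' @param seed Integer seed for the track's random stream.
#' @param driving,pilus,swim,pole Named lists of scenario parameters; see
#'   [paper_defaults()] for the fields and default values.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(trap = NULL, bead = NULL, frame_rate = 100,
                       integration_step = NULL, seed = 1L,
                       driving = list(), pilus = list(), swim = list(),
                       pole = list()) {
  defaults <- paper_defaults()
  if (is.null(trap)) {
    trap <- trap_model(defaults$physical$kappa_trap,
                       temperature = defaults$physical$temperature)
  }
  if (is.null(bead)) {
    bead <- bead_geometry(defaults$physical$bead_radius_trapped,
                          defaults$physical$viscosity,
                          trap$temperature)
  }
  if (is.null(integration_step)) {
    integration_step <- min(1e-3, 1 / (10 * frame_rate))
  }
  if (integration_step > 1 / (2 * frame_rate)) {
    stop("'integration_step' must be <= 1/(2*frame_rate)")
  }
  merge_block <- function(user, def) utils::modifyList(def, user)
  cfg <- structure(
    list(trap = trap, bead = bead, frame_rate = frame_rate,
         integration_step = integration_step, seed = as.integer(seed),
         driving = merge_block(driving, defaults$driving),
         pilus = merge_block(pilus, defaults$pilus),
         swim = merge_block(swim, defaults$swim),
         pole = merge_block(pole, defaults$pole)),
    class = "sim_config"
  )
  stopifnot(cfg$driving$rot_force >= 0, cfg$driving$trans_force >= 0,
            cfg$driving$gyration_freq >= 0, cfg$pilus$retract_speed >= 0,
            cfg$pilus$release_speed_factor >= 1,
            cfg$swim$v_push >= 0, cfg$swim$v_pull >= 0)
  if (cfg$swim$tau_push <= 0 || cfg$swim$tau_pull <= 0) {
    stop("swim dwell means 'tau_push'/'tau_pull' must be positive")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> frame_rate = %g Hz, dt = %g s, seed = %d\n",
              x$frame_rate, x$integration_step, x$seed))
  print(x$trap)
  print(x$bead)
  invisible(x)
}
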
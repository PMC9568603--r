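#' Per-frame trap restoring forces
#'
#' Converts a calibrated trapped-bead trajectory into the time-resolved force
#' the trap exerts on the bead, `F = kappa * (center - x)` per axis. In
#' steady state this balances the force generated by the cell's appendages,
#' so the trap force read out here is the measurement of the flagellar and
#' pilus forces. The force is decomposed into radial and tangential
#' components about the trap center, and the signed angular velocity of the
#' bead about the center is computed from the unwrapped polar angle
#' (Savitzky-Golay smoothed derivative by default; CCW positive).
#'
#' @param traj A [trajectory()].
#' @param trap A [trap_model()] with calibrated (or planted) stiffness. The
#'   trap center defaults to the model's center; pass the long-run mean of a
#'   Brownian segment when the center is unknown.
#' @param sg_window Savitzky-Golay window (frames, odd) for the angular
#'   velocity; `0` uses raw centered differences.
#' @return A data frame of class `force_series`: columns `t`, `fx`, `fy`
#'   (pN), `f_radial`, `f_tangential` (pN, signed, about the center),
#'   `radius` (um), `angular_velocity` (rad/s, `NA`-free; frames at the exact
#'   center get 0 and are listed in attribute `degenerate_frames`).
#' @export
displacement_force <- function(traj, trap, sg_window = 5) {
  stopifnot(inherits(traj, "trajectory"), inherits(trap, "trap_model"))
  dx <- traj$x - trap$center[["x"]]
  dy <- traj$y - trap$center[["y"]]
  fx <- -trap$kappa[["x"]] * dx
  fy <- -trap$kappa[["y"]] * dy
  r <- sqrt(dx^2 + dy^2)
  degenerate <- which(r < 1e-12)
  ur_x <- ifelse(r > 1e-12, dx / r, 0)
  ur_y <- ifelse(r > 1e-12, dy / r, 0)
  f_rad <- fx * ur_x + fy * ur_y
  f_tan <- -fx * ur_y + fy * ur_x

  theta <- unwrap_angle(atan2(dy, dx))
  fr <- frame_rate(traj)
  n <- length(theta)
  if (sg_window >= 5 && n > sg_window) {
    p <- min(3, sg_window - 2)
    omega <- signal::sgolayfilt(theta, p = p, n = sg_window, m = 1) * fr
  } else {
    omega <- c(theta[2] - theta[1],
               (theta[3:n] - theta[1:(n - 2)]) / 2,
               theta[n] - theta[n - 1]) * fr
  }
  omega[degenerate] <- 0

  out <- data.frame(t = traj$t, fx = fx, fy = fy, f_radial = f_rad,
                    f_tangential = f_tan, radius = r,
                    angular_velocity = omega)
  attr(out, "frame_rate") <- fr
  attr(out, "degenerate_frames") <- degenerate
  class(out) <- c("force_series", "data.frame")
  out
}

# Unwrap a phase series (remove 2 pi jumps).
unwrap_angle <- function(theta) {
  d <- diff(theta)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  theta - 2 * pi * jumps
}

#' Summary flagellar forces from a force series
#'
#' Two headline numbers of the trapped-bead assay:
#' \describe{
#'   \item{`F_rot`}{net rotational (tangential driving) force of the
#'     flagellum, from drag balance at the bead:
#'     `F_rot = gamma_eff * <|angular velocity|> * <radius>` over the
#'     gyration frames. `gamma_eff` defaults to the bead-only Stokes drag,
#'     a declared lower bound (the attached cell adds unmodeled drag).}
#'   \item{`F_trans_max`}{maximal translational force,
#'     `kappa * max radial displacement` over the whole track; the radial
#'     trace is boxcar-smoothed (default 1 s) first so the maximum reflects
#'     sustained driving rather than a single thermal excursion.}
#' }
#'
#' @param fs A `force_series` from [displacement_force()].
#' @param geometry A [bead_geometry()]; its drag is `gamma_eff`.
#' @param events An [event_table()] whose `gyration` / `long_axis_rotation`
#'   intervals define the gyration frames (ground truth or
#'   [classify_states()] output).
#' @param trap The [trap_model()] used in [displacement_force()].
#' @param smooth_window Boxcar width (s) for the radial trace.
#' @param drag Optional override of `gamma_eff` (pN s/um).
#' @return A list with `F_rot` (pN, `NULL` when no gyration interval exists —
#'   absent, not zero), `F_trans_max` (pN), `n_gyration_frames`.
#' @export
summarize_forces <- function(fs, geometry, events, trap,
                             smooth_window = 1, drag = NULL) {
  stopifnot(inherits(fs, "force_series"), inherits(geometry, "bead_geometry"),
            inherits(events, "event_table"), inherits(trap, "trap_model"))
  if (is.null(drag)) drag <- geometry$drag
  fr <- attr(fs, "frame_rate")

  gyr <- events[events$state %in% c("gyration", "long_axis_rotation"), ,
                drop = FALSE]
  in_gyr <- rep(FALSE, nrow(fs))
  for (i in seq_len(nrow(gyr))) {
    in_gyr <- in_gyr | (fs$t >= gyr$start[i] & fs$t < gyr$end[i])
  }
  F_rot <- if (any(in_gyr)) {
    drag * mean(abs(fs$angular_velocity[in_gyr])) * mean(fs$radius[in_gyr])
  } else {
    NULL
  }

  w <- max(1L, round(smooth_window * fr))
  r_smooth <- if (nrow(fs) > w) running_mean(fs$radius, w) else fs$radius
  F_trans_max <- max(trap$kappa) * max(r_smooth)

  list(F_rot = F_rot, F_trans_max = F_trans_max,
       n_gyration_frames = sum(in_gyr))
}

# Centered running mean, window w frames (edges use the available samples).
running_mean <- function(z, w) {
  cs <- cumsum(c(0, z))
  n <- length(z)
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
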
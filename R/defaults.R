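.defaults_cache <- new.env(parent = emptyenv())

#' Headline assay parameter fixture
#'
#' Returns the package's central parameter fixture: every reported summary
#' value of the bacteria-on-a-bead assay (swim speeds and dwell times, pilus
#' cycle and inter-cycle statistics with and without a flagellum, pole
#' rotation frequencies, activity-stage durations, time-partition values),
#' plus declared physical defaults for quantities the study does not print
#' (trap stiffness, viscosity, gyration rate and orbit radius). Shipped as
#' `inst/extdata/paper_defaults.json`; the force pair driving the gyration is
#' derived at load time from the consistency relations `trans = kappa * r0`
#' and `rot = gamma * 2 pi f * r0` (see [gyration_forces()]).
#'
#' @return A nested list with blocks `physical`, `driving`, `pilus`, `swim`,
#'   `pole`, `stages`, `partition`.
#' @export
paper_defaults <- function() {
  if (!is.null(.defaults_cache$defaults)) return(.defaults_cache$defaults)
  path <- system.file("extdata", "paper_defaults.json", package = "beadcycle")
  if (path == "") {
    stop("paper_defaults.json not found; is the package installed?")
  }
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  d$comment <- NULL
  gamma <- stokes_drag(d$physical$bead_radius_trapped, d$physical$viscosity)
  ff <- gyration_forces(d$driving$gyration_freq, d$driving$orbit_radius,
                        kappa = d$physical$kappa_trap, drag = gamma)
  d$driving$rot_force <- ff[["rot_force"]]
  d$driving$trans_force <- ff[["trans_force"]]
  # mean-preserving symmetric truncation windows for the pole frequencies
  d$pole$freq_ccw_max <- 2 * d$pole$freq_ccw_mean - d$pole$freq_min
  d$pole$freq_cw_max <- 2 * d$pole$freq_cw_mean - d$pole$freq_min
  .defaults_cache$defaults <- d
  d
}

#' Self-consistent gyration force pair
#'
#' For a bead orbiting the trap center at radius `r0` and frequency `f`
#' (angular rate `w = 2 pi f`), force balance in the overdamped limit requires
#' a radial driving force `kappa * r0` (against the trap) and a tangential
#' driving force `gamma * w * r0` (against drag). Planting this pair makes the
#' noiseless steady state exactly a circular orbit of radius `r0` at `f`, so
#' drag-balance force inference recovers `rot_force` exactly.
#'
#' @param freq Gyration frequency (Hz).
#' @param radius Orbit radius (um).
#' @param kappa Trap stiffness (pN/um).
#' @param drag Bead drag (pN s/um).
#' @return Named numeric: `rot_force`, `trans_force` (pN).
#' @export
gyration_forces <- function(freq, radius, kappa, drag) {
  c(rot_force = drag * 2 * pi * freq * radius,
    trans_force = kappa * radius)
}
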
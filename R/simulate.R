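#' @title Overdamped Langevin machinery
#' @description Internal: one linear-drift Euler-Maruyama segment.
#' @details
#' All trapped-bead states reduce to a linear SDE per axis,
#' `dx = (-(kappa + k_add) x + f(t)) dt / gamma + sqrt(2 D) dW`,
#' with a state-specific deterministic forcing `f(t)` (trap center pull,
#' rotating gyration force, or stiff-tether pull toward a prescribed pilus
#' path). The Euler-Maruyama recursion `x[n+1] = a x[n] + u[n]` has constant
#' coefficient `a` within a segment, so it is evaluated with
#' `stats::filter(..., method = "recursive")` (C speed, bit-reproducible).
#' @noRd
ou_segment <- function(n_steps, dt, x0, kappa, k_add, gamma, sigma, fx, fy) {
  a <- 1 - (kappa + k_add) * dt / gamma
  if (any(a <= -1)) {
    stop("integration step too coarse for the stiffest restoring force; ",
         "reduce 'integration_step'")
  }
  out <- matrix(0, n_steps, 2)
  for (ax in 1:2) {
    u <- (if (ax == 1) fx else fy) * dt / gamma
    if (sigma > 0) u <- u + sigma * stats::rnorm(n_steps)
    out[, ax] <- stats::filter(u, a[ax], method = "recursive",
                               init = x0[ax])
  }
  out
}

#' Simulate a trapped bacteria-on-a-bead trajectory
#'
#' Integrates the overdamped motion of a bead held in a harmonic optical trap
#' while the attached predivisional cell executes a programmed behavioral
#' schedule. Supported states:
#' \describe{
#'   \item{`gyration`}{The rotating flagellum drives the bead around the trap
#'     center: a rotating force vector with radial component `trans_force` and
#'     tangential component `rot_force`, its phase advancing at
#'     `gyration_freq` (CCW positive).}
#'   \item{`long_axis_rotation`}{Same driving with the tangential force and
#'     phase rate scaled by `slow_rotation_factor` (default 0.5): the daughter
#'     cell spins about its long axis and the gyration proceeds slower.}
#'   \item{`pilus_cycle`}{A kinematic tether drags the bead from its current
#'     position along a fixed anchor bearing at `retract_speed` until the
#'     radial displacement reaches `hold_displacement`, holds, and releases at
#'     the end of the segment (the bead then relaxes back under the trap with
#'     time constant `gamma/kappa`, which is >= `release_speed_factor` times
#'     faster than retraction by construction). Sub-phase times are recorded
#'     in the event attributes.}
#'   \item{`brownian`}{Thermal motion in the trap only.}
#' }
#'
#' @param config A [sim_config()].
#' @param schedule A [behavior_schedule()] with states among `gyration`,
#'   `pilus_cycle`, `long_axis_rotation`, `brownian`.
#' @param noise Logical; `FALSE` forces the diffusion coefficient to zero
#'   (deterministic limit, used by construction tests).
#' @return A list with elements `trajectory` (a [trajectory()] sampled at
#'   `config$frame_rate`) and `events` (ground-truth [event_table()], one
#'   interval per schedule segment, pilus sub-phases in `attributes`).
#' @export
simulate_trapped_bead <- function(config, schedule, noise = TRUE) {
  stopifnot(inherits(config, "sim_config"),
            inherits(schedule, "behavior_schedule"))
  ok <- c("gyration", "pilus_cycle", "long_axis_rotation", "brownian")
  if (!all(schedule$state %in% ok)) {
    stop("trapped-bead schedule states must be among: ",
         paste(ok, collapse = ", "))
  }
  trap <- config$trap
  bead <- config$bead
  drv <- config$driving
  pil <- config$pilus
  if (any(schedule$state == "pilus_cycle")) {
    if (drv$trans_force > 0 &&
        min(trap$kappa) * pil$hold_displacement > 50 * drv$trans_force) {
      stop("unphysical configuration: hold_displacement implies a pilus ",
           "force far beyond the flagellar driving scale")
    }
    # release speed is set by trap relaxation; verify the planted ratio
    rel_speed <- min(trap$kappa) * pil$hold_displacement *
      pil$tether_stiffness / (min(trap$kappa) + pil$tether_stiffness) /
      bead$drag
    if (pil$retract_speed > 0 &&
        rel_speed < pil$release_speed_factor * pil$retract_speed) {
      warning("trap relaxation gives release/retract speed ratio below ",
              "'release_speed_factor'; stiffen the trap or slow retraction")
    }
  }
  tau <- bead$drag / max(trap$kappa)
  if (config$integration_step > tau / 10) {
    warning(sprintf(
      "integration step %.3g s exceeds relaxation time / 10 (%.3g s)",
      config$integration_step, tau / 10))
  }

  fr <- config$frame_rate
  spf <- max(1L, round(1 / (fr * config$integration_step)))
  dt <- 1 / (fr * spf)
  sigma <- if (noise) sqrt(2 * bead$diffusion * dt) else 0
  cx <- trap$center[["x"]]
  cy <- trap$center[["y"]]

  set.seed(config$seed)
  total <- sum(schedule$duration)
  bnd <- round(cumsum(c(0, schedule$duration)) / dt)
  x <- c(cx, cy)
  pos <- matrix(NA_real_, bnd[length(bnd)] + 1L, 2)
  pos[1, ] <- x
  ev_state <- schedule$state
  ev_attr <- vector("list", nrow(schedule))

  for (i in seq_len(nrow(schedule))) {
    n_i <- bnd[i + 1] - bnd[i]
    if (n_i == 0) next
    st <- schedule$state[i]
    par <- schedule$params[[i]]
    tloc <- dt * seq_len(n_i)
    k_add <- 0
    fx <- rep(trap$kappa[["x"]] * cx, n_i)
    fy <- rep(trap$kappa[["y"]] * cy, n_i)

    if (st %in% c("gyration", "long_axis_rotation")) {
      fac <- if (st == "long_axis_rotation") drv$slow_rotation_factor else 1
      freq <- fac * (par$freq %||% drv$gyration_freq)
      rot <- fac * (par$rot_force %||% drv$rot_force)
      trans <- par$trans_force %||% drv$trans_force
      s <- if ((par$direction %||% drv$gyration_direction) == "CCW") 1 else -1
      phi0 <- atan2(x[2] - cy, x[1] - cx)
      if (!is.finite(phi0)) phi0 <- 0
      phi <- phi0 + s * 2 * pi * freq * tloc
      fx <- fx + trans * cos(phi) - s * rot * sin(phi)
      fy <- fy + trans * sin(phi) + s * rot * cos(phi)
      ev_attr[[i]] <- list(freq = freq, direction = if (s > 0) "CCW" else "CW",
                           rot_force = rot, trans_force = trans)
    } else if (st == "pilus_cycle") {
      k_add <- pil$tether_stiffness
      bear0 <- atan2(x[2] - cy, x[1] - cx)
      if (!is.finite(bear0) || sqrt(sum((x - c(cx, cy))^2)) < 1e-6) {
        bear0 <- stats::runif(1, -pi, pi)
      }
      jit <- pil$anchor_jitter_deg * pi / 180
      bearing <- par$anchor_bearing %||%
        (bear0 + stats::runif(1, -jit, jit))
      hold_d <- par$hold_displacement %||% pil$hold_displacement
      v_r <- par$retract_speed %||% pil$retract_speed
      q <- c(cx, cy) + hold_d * c(cos(bearing), sin(bearing))
      dvec <- q - x
      dist <- sqrt(sum(dvec^2))
      dur <- schedule$duration[i]
      t_r <- if (v_r > 0) min(dist / v_r, 0.8 * dur) else 0
      # prescribed bead path: linear to the clamped endpoint, then hold
      endp <- if (dist > 0) x + dvec * min(1, v_r * t_r / dist) else x
      frac <- if (t_r > 0) pmin(tloc / t_r, 1) else rep(1, n_i)
      bx <- x[1] + (endp[1] - x[1]) * frac
      by <- x[2] + (endp[2] - x[2]) * frac
      # tether point placed so the trap+tether equilibrium sits on the path
      scale <- (trap$kappa + k_add) / k_add
      px <- cx + (bx - cx) * scale[["x"]]
      py <- cy + (by - cy) * scale[["y"]]
      fx <- fx + k_add * px
      fy <- fy + k_add * py
      ev_attr[[i]] <- list(anchor_bearing = bearing,
                           retract_speed = v_r,
                           attach = schedule$start[i],
                           retract_end = schedule$start[i] + t_r,
                           hold_end = schedule$start[i] + dur,
                           hold_displacement = hold_d)
    } else {
      ev_attr[[i]] <- list()
    }

    seg <- ou_segment(n_i, dt, x, trap$kappa, k_add, bead$drag, sigma, fx, fy)
    pos[(bnd[i] + 2):(bnd[i + 1] + 1), ] <- seg
    x <- seg[n_i, ]
  }

  n_frames <- floor(total * fr) + 1L
  idx <- 1L + (0:(n_frames - 1L)) * spf
  traj <- trajectory(times = (0:(n_frames - 1L)) / fr,
                     x = pos[idx, 1], y = pos[idx, 2], frame_rate = fr)
  ev_end <- schedule$start + schedule$duration
  # every simulated frame is covered by exactly one ground-truth state
  ev_end[length(ev_end)] <- max(ev_end[length(ev_end)], total + 0.5 / fr)
  events <- event_table(ev_state, schedule$start, ev_end, ev_attr)
  list(trajectory = traj, events = events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a free-swimming bacteria-on-a-bead
#'
#' Run-reverse swimmer in a quasi-2D chamber: push (forward, CW flagellar
#' motor) and pull (backward, CCW motor) sequences strictly alternate. Dwell
#' times are a refractory minimum plus an exponential tail with total mean
#' `tau_push` / `tau_pull`; per-sequence speeds are drawn from mean-matched
#' truncated normals ([rtnorm_matched()]). The body axis undergoes rotational
#' diffusion and flips by pi at every reversal; translational Brownian noise
#' of the whole assembly is added on top of the swimming displacement.
#'
#' @param config A [sim_config()]; the `swim` block supplies `v_push`,
#'   `v_push_sd`, `v_pull`, `v_pull_sd`, `speed_min`, `tau_push`, `tau_pull`,
#'   `refractory` and `rotational_diffusion`, and `config$bead` should
#'   describe the effective (bead + cell) assembly hydrodynamics.
#' @param n_sequences Total number of swim sequences to generate.
#' @param noise Logical; `FALSE` disables positional noise and rotational
#'   diffusion (deterministic back-and-forth limit).
#' @return A list with `trajectory` (with per-frame ground-truth body-axis
#'   angle in attribute `heading`) and `events` (states `swim_push` /
#'   `swim_pull`, per-sequence speed in `attributes`).
#' @export
simulate_free_swimmer <- function(config, n_sequences = 100, noise = TRUE) {
  stopifnot(inherits(config, "sim_config"), n_sequences >= 1)
  sw <- config$swim
  if (sw$refractory >= min(sw$tau_push, sw$tau_pull)) {
    stop("'refractory' must be below both dwell means")
  }
  set.seed(config$seed)
  n <- as.integer(n_sequences)
  dir <- rep_len(c(1L, -1L), n) # +1 push, -1 pull; strict alternation
  dur <- numeric(n)
  spd <- numeric(n)
  for (d in c(1L, -1L)) {
    k <- which(dir == d)
    tau <- if (d > 0) sw$tau_push else sw$tau_pull
    m <- if (d > 0) sw$v_push else sw$v_pull
    s <- if (d > 0) sw$v_push_sd else sw$v_pull_sd
    dur[k] <- sw$refractory + stats::rexp(length(k), 1 / (tau - sw$refractory))
    spd[k] <- rtnorm_matched(length(k), m, s, lower = sw$speed_min)
  }
  start <- cumsum(c(0, dur[-n]))

  fr <- config$frame_rate
  spf <- max(1L, round(1 / (fr * config$integration_step)))
  dt <- 1 / (fr * spf)
  total <- sum(dur)
  n_steps <- ceiling(total / dt)
  tt <- dt * (seq_len(n_steps) - 0.5) # mid-step time for state lookup
  seq_id <- findInterval(tt, start)
  v_step <- spd[seq_id] * dir[seq_id]

  if (noise && sw$rotational_diffusion > 0) {
    dalpha <- sqrt(2 * sw$rotational_diffusion * dt) * stats::rnorm(n_steps)
  } else {
    dalpha <- numeric(n_steps)
  }
  alpha <- stats::runif(1, -pi, pi) + cumsum(dalpha)
  sigma <- if (noise) sqrt(2 * config$bead$diffusion * dt) else 0
  dx <- v_step * cos(alpha) * dt
  dy <- v_step * sin(alpha) * dt
  if (sigma > 0) {
    dx <- dx + sigma * stats::rnorm(n_steps)
    dy <- dy + sigma * stats::rnorm(n_steps)
  }
  xs <- c(0, cumsum(dx))
  ys <- c(0, cumsum(dy))
  alpha_full <- c(alpha[1], alpha)

  n_frames <- floor(total * fr) + 1L
  idx <- 1L + (0:(n_frames - 1L)) * spf
  idx <- idx[idx <= n_steps + 1L]
  traj <- trajectory(times = (seq_along(idx) - 1) / fr,
                     x = xs[idx], y = ys[idx], frame_rate = fr)
  attr(traj, "heading") <- alpha_full[idx]
  end_t <- start + dur
  end_t[n] <- max(end_t[n], traj$t[nrow(traj)] + 0.5 / fr)
  events <- event_table(ifelse(dir > 0, "swim_push", "swim_pull"),
                        start, end_t,
                        lapply(seq_len(n), function(i) {
                          list(speed = spd[i],
                               direction = if (dir[i] > 0) "push" else "pull")
                        }))
  list(trajectory = traj, events = events)
}

#' Simulate a flagellated-pole track of a surface-attached predivisional cell
#'
#' Generates the position of the flagellated pole through the cell-separation
#' stages observed for cells grown on glass:
#' \describe{
#'   \item{`bending`}{slow (sub-Hz) large-amplitude oscillation of the pole
#'     along a bending axis while the septum is still stiff;}
#'   \item{`long_axis_rotation`}{quadrature circular signal
#'     `x = A cos(phi), y = A sin(phi)` with `dphi/dt = +/- 2 pi f` (CCW
#'     positive), frequency and direction per sub-interval, phase-continuous
#'     across switches;}
#'   \item{`released`}{ballistic drift after cell separation.}
#' }
#' Gaussian localization noise with standard deviation `amplitude / snr` is
#' added to every frame.
#'
#' Segment `params` may supply `freq` and `direction` (single rotation
#' interval), or `intervals` (data frame with columns `freq`, `direction`,
#' `duration`) for within-segment motor switching; otherwise dwell times
#' (`dwell_cw`, `dwell_ccw`) and mean-matched truncated-normal frequencies
#' from the `pole` block are drawn.
#'
#' @param config A [sim_config()]; uses the `pole` block.
#' @param schedule A [behavior_schedule()] with states among `bending`,
#'   `long_axis_rotation`, `released`.
#' @param noise Logical; `FALSE` disables localization noise.
#' @return A list with `trajectory` (a `pole_track`) and ground-truth
#'   `events` (one interval per rotation sub-interval, with `freq` and
#'   `direction` attributes).
#' @export
simulate_pole_track <- function(config, schedule, noise = TRUE) {
  stopifnot(inherits(config, "sim_config"),
            inherits(schedule, "behavior_schedule"))
  ok <- c("bending", "long_axis_rotation", "released")
  if (!all(schedule$state %in% ok)) {
    stop("pole-track schedule states must be among: ",
         paste(ok, collapse = ", "))
  }
  po <- config$pole
  fr <- config$frame_rate
  set.seed(config$seed)

  total <- sum(schedule$duration)
  n_frames <- floor(total * fr) + 1L
  tgrid <- (0:(n_frames - 1L)) / fr
  xs <- numeric(n_frames)
  ys <- numeric(n_frames)
  ev_state <- character(0)
  ev_start <- numeric(0)
  ev_end <- numeric(0)
  ev_attr <- list()
  origin <- c(0, 0)

  for (i in seq_len(nrow(schedule))) {
    t0 <- schedule$start[i]
    t1 <- t0 + schedule$duration[i]
    sel <- which(tgrid >= t0 - 1e-9 & tgrid < t1 - 1e-9)
    if (i == nrow(schedule)) sel <- which(tgrid >= t0 - 1e-9)
    tl <- tgrid[sel] - t0
    st <- schedule$state[i]
    par <- schedule$params[[i]]

    if (st == "bending") {
      amp <- par$amplitude %||% po$bend_amplitude
      fb <- par$freq %||% po$bend_freq
      psi <- par$axis %||% stats::runif(1, -pi, pi)
      if (fb >= fr / 4) stop("bending frequency violates frame_rate >= 4*f")
      w <- amp * sin(2 * pi * fb * tl)
      xs[sel] <- origin[1] + w * cos(psi)
      ys[sel] <- origin[2] + w * sin(psi)
      ev_state <- c(ev_state, "bending")
      ev_start <- c(ev_start, t0)
      ev_end <- c(ev_end, t1)
      ev_attr <- c(ev_attr, list(list(amplitude = amp, freq = fb)))
    } else if (st == "long_axis_rotation") {
      amp <- par$amplitude %||% po$amplitude
      iv <- par$intervals
      if (is.null(iv)) {
        if (!is.null(par$freq)) {
          iv <- data.frame(freq = par$freq,
                           direction = par$direction %||% "CCW",
                           duration = schedule$duration[i])
        } else {
          iv <- draw_rotation_intervals(schedule$duration[i], po)
        }
      }
      if (any(iv$freq >= fr / 4)) {
        stop(sprintf(
          "aliasing: rotation frequency %.3g Hz needs frame_rate >= %.3g Hz",
          max(iv$freq), 4 * max(iv$freq)))
      }
      iv_start <- cumsum(c(0, iv$duration[-nrow(iv)]))
      k <- findInterval(tl, iv_start)
      s <- ifelse(iv$direction[k] == "CCW", 1, -1)
      # phase-continuous integration of dphi = s * 2 pi f dt
      phi0 <- stats::runif(1, -pi, pi)
      dphi <- s * 2 * pi * iv$freq[k] / fr
      phi <- phi0 + cumsum(dphi) - dphi[1]
      xs[sel] <- amp * cos(phi)
      ys[sel] <- amp * sin(phi)
      ev_state <- c(ev_state, rep("long_axis_rotation", nrow(iv)))
      ev_start <- c(ev_start, t0 + iv_start)
      ev_end <- c(ev_end, t0 + iv_start + iv$duration)
      ev_attr <- c(ev_attr, lapply(seq_len(nrow(iv)), function(j) {
        list(freq = iv$freq[j], direction = iv$direction[j], amplitude = amp)
      }))
      origin <- c(0, 0)
    } else { # released
      vdir <- stats::runif(1, -pi, pi)
      v <- par$speed %||% 15
      x_at <- if (length(sel) && sel[1] > 1) c(xs[sel[1] - 1], ys[sel[1] - 1]) else origin
      xs[sel] <- x_at[1] + v * cos(vdir) * tl
      ys[sel] <- x_at[2] + v * sin(vdir) * tl
      ev_state <- c(ev_state, "released")
      ev_start <- c(ev_start, t0)
      ev_end <- c(ev_end, t1)
      ev_attr <- c(ev_attr, list(list(speed = v)))
    }
  }

  if (noise) {
    sd_loc <- po$amplitude / po$snr
    xs <- xs + stats::rnorm(n_frames, 0, sd_loc)
    ys <- ys + stats::rnorm(n_frames, 0, sd_loc)
  }
  # clamp ground-truth event ends to the realized track
  ev_end[length(ev_end)] <- max(ev_end[length(ev_end)], tgrid[n_frames])
  traj <- trajectory(tgrid, xs, ys, frame_rate = fr, pole = TRUE)
  list(trajectory = traj,
       events = event_table(ev_state, ev_start, ev_end, ev_attr))
}

# Alternating CW/CCW rotation sub-intervals with drawn frequencies.
draw_rotation_intervals <- function(duration, po) {
  dirs <- character(0)
  durs <- numeric(0)
  d <- if (stats::runif(1) < 0.5) "CW" else "CCW"
  tacc <- 0
  while (tacc < duration) {
    dw <- stats::rexp(1, 1 / (if (d == "CW") po$dwell_cw else po$dwell_ccw))
    dw <- min(dw, duration - tacc)
    if (dw > 1e-6) {
      dirs <- c(dirs, d)
      durs <- c(durs, dw)
      tacc <- tacc + dw
    }
    d <- if (d == "CW") "CCW" else "CW"
  }
  f <- numeric(length(dirs))
  cw <- dirs == "CW"
  if (any(cw)) {
    f[cw] <- rtnorm_matched(sum(cw), po$freq_cw_mean, po$freq_cw_sd,
                            po$freq_min, po$freq_cw_max)
  }
  if (any(!cw)) {
    f[!cw] <- rtnorm_matched(sum(!cw), po$freq_ccw_mean, po$freq_ccw_sd,
                             po$freq_min, po$freq_ccw_max)
  }
  data.frame(freq = f, direction = dirs, duration = durs)
}
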
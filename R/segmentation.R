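#' Windowed trajectory features for behavioral classification
#'
#' Computes, per sliding window (default 0.5 s, 50% overlap), the geometric
#' signatures that distinguish flagellar gyration, pilus attachment phases and
#' Brownian motion: mean radial distance and radial velocity about the trap
#' center, net signed angular displacement and mean angular speed of the
#' bearing, total positional variance, and directedness (net displacement /
#' path length on a coarse-grained version of the window, in [0, 1]).
#' Positions are boxcar-smoothed (default 0.15 s) before the geometric
#' features are formed; the positional variance uses the raw positions so it
#' retains the thermal scale.
#'
#' @param traj A [trajectory()].
#' @param center Trap center, length-2 (um).
#' @param window Window length (s); must cover at least 5 frames.
#' @param overlap Fractional window overlap (default 0.5).
#' @param smooth Position smoothing timescale (s).
#' @return A data frame of class `feature_series`: columns `t` (window
#'   center), `start`, `end`, `r_mean`, `r_vel`, `ang_net`, `ang_speed`,
#'   `consistency`, `var_pos`, `directedness`.
#' @export
compute_features <- function(traj, center = c(0, 0), window = 0.5,
                             overlap = 0.5, smooth = 0.15) {
  stopifnot(inherits(traj, "trajectory"))
  fr <- frame_rate(traj)
  wlen <- round(window * fr)
  if (wlen < 5) stop("'window' must cover at least 5 frames")
  n <- nrow(traj)
  if (n < wlen) stop("track shorter than one window")
  hop <- max(1L, round(wlen * (1 - overlap)))
  sw <- max(1L, round(smooth * fr))
  xs <- running_mean(traj$x, sw) - center[1]
  ys <- running_mean(traj$y, sw) - center[2]
  r <- sqrt(xs^2 + ys^2)
  theta <- unwrap_angle(atan2(ys, xs))
  dth <- c(0, diff(theta))

  starts <- seq(1L, n - wlen + 1L, by = hop)
  feats <- lapply(starts, function(i0) {
    i1 <- i0 + wlen - 1L
    idx <- i0:i1
    tt <- traj$t[idx]
    rr <- r[idx]
    # closed-form regression slope of r on t
    r_vel <- stats::cov(tt, rr) / stats::var(tt)
    ang_net <- theta[i1] - theta[i0]
    path_ang <- sum(abs(dth[(i0 + 1L):i1]))
    cons <- if (path_ang > 1e-12) abs(ang_net) / path_ang else 0
    ang_speed <- path_ang / (tt[wlen] - tt[1])
    var_pos <- stats::var(traj$x[idx]) + stats::var(traj$y[idx])
    step <- max(1L, wlen %/% 10L)
    ci <- seq(i0, i1, by = step)
    dx <- diff(xs[ci])
    dy <- diff(ys[ci])
    path <- sum(sqrt(dx^2 + dy^2))
    net <- sqrt((xs[i1] - xs[i0])^2 + (ys[i1] - ys[i0])^2)
    c(t = mean(tt[c(1, wlen)]), start = tt[1],
      end = tt[wlen] + 1 / fr, r_mean = mean(rr), r_vel = r_vel,
      ang_net = ang_net, ang_speed = ang_speed, consistency = cons,
      var_pos = var_pos,
      directedness = min(if (path > 1e-12) net / path else 0, 1))
  })
  out <- as.data.frame(do.call(rbind, feats))
  attr(out, "window") <- window
  attr(out, "hop") <- hop / fr
  attr(out, "center") <- center
  attr(out, "frame_rate") <- fr
  attr(out, "track_span") <- c(traj$t[1], traj$t[n] + 1 / fr)
  class(out) <- c("feature_series", "data.frame")
  out
}

#' Default classification thresholds
#'
#' @param trap A [trap_model()] (sets the displacement threshold at three
#'   thermal standard deviations and the hold-variance gate at half the free
#'   Brownian variance in the trap).
#' @return Named list of thresholds; see [classify_states()].
#' @export
default_thresholds <- function(trap) {
  kT <- kB * trap$temperature
  sig2 <- mean(kT / trap$kappa)
  list(
    r_thresh = 3 * sqrt(sig2),     # um; pilus/gyration displacement gate
    d_thresh = 0.7,                # directedness gate (retraction/release)
    a_thresh = pi / 2,             # rad net rotation per window (gyration)
    rv_thresh = 0.05,              # um/s sustained outward radial velocity
    var_hold = kT / trap$kappa[["x"]] + kT / trap$kappa[["y"]], # um^2, halved below
    consistency_thresh = 0.6,      # rotation sign consistency
    min_duration = 0.4,            # s; hysteresis merging of short segments
    slow_frac = 0.7                # long-axis rotation = below this x fast speed
  )
}

#' Classify trajectory windows into behavioral states
#'
#' Rule cascade over the windowed features, operationalizing the assay's
#' visual criteria:
#' \itemize{
#'   \item `pilus_attached`: mean radial distance above `r_thresh` AND
#'     (sustained outward radial velocity in the retraction regime, OR a
#'     low-variance, rotation-free hold off-center, OR strongly directed
#'     motion);
#'   \item `gyration`: radial distance above `r_thresh` (the orbit stands off
#'     the center well above the thermal cloud) AND net angular displacement
#'     above `a_thresh` with consistent sign;
#'   \item `long_axis_rotation`: gyration windows whose angular speed falls
#'     below `slow_frac` of the track's fast-gyration reference (0.9
#'     quantile) — the slowed gyration of a daughter cell spinning about its
#'     long axis;
#'   \item `brownian`: everything else.
#' }
#' Windows satisfying both the pilus and gyration rules are labeled pilus
#' (pilus attachment arrests gyration). Segments shorter than `min_duration`
#' are merged into their longer neighbor (hysteresis).
#'
#' @param features A `feature_series` from [compute_features()].
#' @param trap A [trap_model()]; used for [default_thresholds()].
#' @param thresholds Named list overriding any of the defaults.
#' @return An [event_table()] covering the track, states among
#'   `pilus_attached`, `gyration`, `long_axis_rotation`, `brownian`, with the
#'   thresholds used stored in attribute `thresholds`.
#' @export
classify_states <- function(features, trap, thresholds = list()) {
  stopifnot(inherits(features, "feature_series"))
  th <- utils::modifyList(default_thresholds(trap), thresholds)
  if (th$r_thresh <= 0 && th$a_thresh <= 0 && th$d_thresh <= 0) {
    stop("configuration error: all thresholds zero makes states unreachable")
  }
  # pilus phases are rotation-free: the angular gate keeps thermal radial
  # drifts during gyration from masquerading as retraction
  pilus <- features$r_mean > th$r_thresh &
    abs(features$ang_net) < th$a_thresh &
    (features$r_vel > th$rv_thresh |
       features$var_pos < th$var_hold / 2 |
       features$directedness > th$d_thresh)
  gyr <- features$r_mean > th$r_thresh &
    abs(features$ang_net) > th$a_thresh &
    features$consistency > th$consistency_thresh
  lab <- ifelse(pilus, "pilus_attached",
                ifelse(gyr, "gyration", "brownian"))
  if (any(lab == "gyration")) {
    om_ref <- stats::quantile(features$ang_speed[lab == "gyration"], 0.9)
    slow <- lab == "gyration" & features$ang_speed < th$slow_frac * om_ref
    lab[slow] <- "long_axis_rotation"
  }

  # window labels -> per-hop timeline, nearest window center
  span <- attr(features, "track_span")
  hop <- attr(features, "hop")
  grid <- seq(span[1], span[2] - hop / 2, by = hop)
  nearest <- vapply(grid + hop / 2, function(g) {
    which.min(abs(features$t - g))
  }, integer(1))
  tl <- lab[nearest]

  runs <- rle(tl)
  seg <- data.frame(state = runs$values,
                    len = runs$lengths * hop)
  # hysteresis: absorb short segments into the longer neighbor
  repeat {
    short <- which(seg$len < th$min_duration)
    if (!length(short) || nrow(seg) == 1) break
    i <- short[which.min(seg$len[short])]
    left <- if (i > 1) seg$len[i - 1] else -Inf
    right <- if (i < nrow(seg)) seg$len[i + 1] else -Inf
    j <- if (left >= right) i - 1 else i + 1
    seg$len[j] <- seg$len[j] + seg$len[i]
    seg <- seg[-i, , drop = FALSE]
    runs <- rle(seg$state)
    if (any(runs$lengths > 1)) {
      lens <- tapply(seg$len, rep(seq_along(runs$lengths), runs$lengths), sum)
      seg <- data.frame(state = runs$values, len = as.numeric(lens))
    }
  }
  ends <- span[1] + cumsum(seg$len)
  ends[length(ends)] <- span[2]
  starts <- c(span[1], ends[-length(ends)])
  ev <- event_table(seg$state, starts, ends)
  attr(ev, "thresholds") <- th
  attr(ev, "center") <- attr(features, "center")
  ev
}

#' State label at given times
#'
#' @param events An [event_table()].
#' @param times Times (s).
#' @param default Label for times not covered by any interval.
#' @return Character vector of state labels.
#' @export
state_at <- function(events, times, default = NA_character_) {
  out <- rep(default, length(times))
  for (i in seq_len(nrow(events))) {
    out[times >= events$start[i] & times < events$end[i]] <- events$state[i]
  }
  out
}

#' Extract pilus attachment cycles with sub-phases
#'
#' Each `pilus_attached` interval is split into the four steps of an
#' attachment cycle — attachment (interval start), retraction (sustained
#' outward radial motion), hold (radial plateau), release (fast return to the
#' trap center at the interval end; by observation one order of magnitude
#' faster than retraction). Sub-phases are resolved on the smoothed radial
#' trace; intervals spanning fewer than 3 windows are emitted with
#' sub-phases marked unresolved, and intervals running into the end of the
#' track without a release are flagged incomplete (censored).
#'
#' @param events An [event_table()] containing `pilus_attached` (or
#'   ground-truth `pilus_cycle`) intervals.
#' @param traj The [trajectory()] the events refer to.
#' @param center Trap center; defaults to the center recorded by
#'   [classify_states()].
#' @param smooth Radial smoothing timescale (s).
#' @param window Window length (s) used for the resolvability check.
#' @return A data frame of class `pilus_cycles`: columns `attach`,
#'   `retract_end`, `hold_end`, `release_time`, `duration` (s),
#'   `retract_speed`, `release_speed` (um/s), `anchor_bearing` (rad),
#'   `resolved`, `complete`.
#' @export
extract_pilus_cycles <- function(events, traj, center = NULL,
                                 smooth = 0.15, window = 0.5) {
  stopifnot(inherits(events, "event_table"), inherits(traj, "trajectory"))
  if (is.null(center)) center <- attr(events, "center") %||% c(0, 0)
  fr <- frame_rate(traj)
  sw <- max(1L, round(smooth * fr))
  xs <- running_mean(traj$x, sw) - center[1]
  ys <- running_mean(traj$y, sw) - center[2]
  r <- sqrt(xs^2 + ys^2)
  t_end <- traj$t[nrow(traj)]

  piv <- events[events$state %in% c("pilus_attached", "pilus_cycle"), ,
                drop = FALSE]
  rows <- lapply(seq_len(nrow(piv)), function(i) {
    s <- piv$start[i]
    e <- piv$end[i]
    idx <- which(traj$t >= s & traj$t < e)
    resolved <- (e - s) >= 3 * window && length(idx) >= 10
    complete <- e < t_end - 1.5 / fr
    out <- data.frame(attach = s, retract_end = NA_real_, hold_end = e,
                      release_time = e, duration = e - s,
                      retract_speed = NA_real_, release_speed = NA_real_,
                      anchor_bearing = NA_real_,
                      resolved = resolved, complete = complete)
    if (!resolved) return(out)
    rr <- r[idx]
    tt <- traj$t[idx]
    plateau <- stats::quantile(rr, 0.9)
    k <- which(rr >= 0.95 * plateau)[1]
    if (is.na(k) || k < 2) k <- length(idx)
    out$retract_end <- tt[k]
    out$retract_speed <- (rr[k] - rr[1]) / max(tt[k] - tt[1], 1 / fr)
    hold_idx <- idx[k:length(idx)]
    out$anchor_bearing <- atan2(mean(ys[hold_idx]), mean(xs[hold_idx]))
    if (complete) {
      rel_idx <- which(traj$t >= e - 0.3 & traj$t <= min(e + 0.5, t_end))
      if (length(rel_idx) > 2) {
        vr <- -diff(r[rel_idx]) * fr
        out$release_speed <- max(vr)
      }
    }
    out
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(attach = numeric(0), retract_end = numeric(0),
               hold_end = numeric(0), release_time = numeric(0),
               duration = numeric(0), retract_speed = numeric(0),
               release_speed = numeric(0), anchor_bearing = numeric(0),
               resolved = logical(0), complete = logical(0))
  class(out) <- c("pilus_cycles", "data.frame")
  out
}

#' Summary statistics of a segmented track
#'
#' Aggregates an event table (and extracted pilus cycles) into the assay's
#' headline per-track quantities: pilus cycle duration and inter-cycle period
#' (mean, SD, n), time fractions of pilus- vs flagellum-driven displacement,
#' overall flagellar activity duration (onset of the first rotation interval
#' to the transition into the terminal Brownian interval) and the duration of
#' the pre-separation long-axis rotation stage. Empty categories are reported
#' absent (`NULL`), not zero.
#'
#' @param events An [event_table()].
#' @param cycles Optional `pilus_cycles` from [extract_pilus_cycles()].
#' @return A list of class `summary_stats`.
#' @export
summarize_events <- function(events, cycles = NULL) {
  stopifnot(inherits(events, "event_table"))
  st <- events$state
  dur <- events$end - events$start
  pil <- st %in% c("pilus_attached", "pilus_cycle")
  flag <- st %in% c("gyration", "long_axis_rotation")

  msd <- function(x) {
    if (!length(x)) return(NULL)
    list(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
         n = length(x))
  }
  # inter-cycle periods: gaps between consecutive pilus intervals
  gaps <- NULL
  pidx <- which(pil)
  if (length(pidx) > 1) {
    gaps <- events$start[pidx[-1]] - events$end[pidx[-length(pidx)]]
    gaps <- gaps[gaps > 0]
  }
  pili_time <- sum(dur[pil])
  flag_time <- sum(dur[flag])
  fractions <- if (pili_time + flag_time > 0) {
    list(pili = pili_time / (pili_time + flag_time),
         flagellum = flag_time / (pili_time + flag_time))
  } else {
    NULL
  }

  onset <- if (any(flag)) events$start[which(flag)[1]] else NULL
  separation <- if (nrow(events) > 1 &&
                    st[nrow(events)] == "brownian") {
    events$start[nrow(events)]
  } else {
    NULL
  }
  activity <- if (!is.null(onset) && !is.null(separation) &&
                  separation > onset) separation - onset else NULL
  rotation_stage <- if (any(st == "long_axis_rotation")) {
    sum(dur[st == "long_axis_rotation"])
  } else {
    NULL
  }

  cyc <- NULL
  if (!is.null(cycles) && nrow(cycles)) {
    cyc <- msd(cycles$duration[cycles$complete])
  } else if (any(pil)) {
    cyc <- msd(dur[pil])
  }

  structure(
    list(cycle_duration = cyc, intercycle_period = msd(gaps),
         time_fraction = fractions, pili_time = pili_time,
         flagellum_time = flag_time, activity_duration = activity,
         rotation_stage_duration = rotation_stage),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("<summary_stats>\n")
  fmt <- function(name, v) {
    if (is.null(v)) return()
    if (is.list(v) && !is.null(v$mean)) {
      cat(sprintf("  %s: %.3g +/- %.3g (n = %d)\n", name, v$mean, v$sd, v$n))
    } else if (is.numeric(v)) {
      cat(sprintf("  %s: %.4g\n", name, v))
    }
  }
  fmt("pilus cycle duration (s)", x$cycle_duration)
  fmt("inter-cycle period (s)", x$intercycle_period)
  if (!is.null(x$time_fraction)) {
    cat(sprintf("  time fraction pili / flagellum: %.2f / %.2f\n",
                x$time_fraction$pili, x$time_fraction$flagellum))
  }
  fmt("flagellar activity duration (s)", x$activity_duration)
  fmt("long-axis rotation stage (s)", x$rotation_stage_duration)
  invisible(x)
}
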
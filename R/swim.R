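#' Classify push/pull swim sequences of a free bacteria-on-a-bead
#'
#' The sign of the velocity projection on the flagellated-pole-to-bead body
#' axis defines the swimming direction: positive = forward = push (CW
#' flagellar motor, pole trailing), negative = backward = pull (CCW motor).
#' Contiguous same-sign runs whose smoothed speed stays above the speed floor
#' become sequences; sub-`min_seq` flickers are merged into their neighbors.
#'
#' @param traj A [trajectory()]; when produced by [simulate_free_swimmer()]
#'   it carries the ground-truth body-axis angle in attribute `heading`.
#' @param axis `"ground_truth"` (use the `heading` attribute) or
#'   `"estimate"` (smoothed local velocity direction, continuous modulo a
#'   global sign; push/pull labels are then defined up to a global flip).
#' @param speed_floor Minimum smoothed speed for a frame to count as moving
#'   (um/s).
#' @param min_seq Minimum sequence duration (s); shorter runs are absorbed.
#' @return A data frame of class `swim_sequences`: columns `direction`
#'   (`push`/`pull`), `start`, `end`, `duration` (s), `mean_speed` (um/s).
#' @export
classify_swim_sequences <- function(traj, axis = c("ground_truth", "estimate"),
                                    speed_floor = 2, min_seq = 0.2) {
  stopifnot(inherits(traj, "trajectory"))
  axis <- match.arg(axis)
  fr <- frame_rate(traj)
  n <- nrow(traj)
  # centered velocity (halves the per-frame noise vs forward differences)
  vx <- c(traj$x[2] - traj$x[1],
          (traj$x[3:n] - traj$x[1:(n - 2)]) / 2,
          traj$x[n] - traj$x[n - 1]) * fr
  vy <- c(traj$y[2] - traj$y[1],
          (traj$y[3:n] - traj$y[1:(n - 2)]) / 2,
          traj$y[n] - traj$y[n - 1]) * fr

  if (axis == "ground_truth") {
    alpha <- attr(traj, "heading", exact = TRUE)
    if (is.null(alpha)) {
      stop("no ground-truth 'heading' attribute; use axis = \"estimate\"")
    }
  } else {
    sw <- max(3L, round(0.25 * fr))
    sx <- running_mean(vx, sw)
    sy <- running_mean(vy, sw)
    spd <- sqrt(sx^2 + sy^2)
    if (stats::median(spd) < speed_floor / 2) {
      stop("trajectory too noisy to estimate a body axis; failing span: ",
           sprintf("%.2f-%.2f s", traj$t[1], traj$t[n]))
    }
    # axis direction modulo pi, made continuous by doubling the angle
    phi2 <- unwrap_angle(atan2(2 * sx * sy, sx^2 - sy^2)) / 2
    alpha <- phi2
  }

  proj <- vx * cos(alpha) + vy * sin(alpha)
  proj <- stats::runmed(proj, 3)
  moving <- running_mean(abs(proj), max(3L, round(0.25 * fr))) >= speed_floor
  lab <- ifelse(moving, ifelse(proj >= 0, 1L, -1L), 0L)

  # absorb runs shorter than min_seq into the longer neighbor
  min_frames <- max(1L, round(min_seq * fr))
  runs <- rle(lab)
  repeat {
    short <- which(runs$lengths < min_frames & runs$values != 0L)
    if (!length(short) || length(runs$lengths) == 1) break
    i <- short[which.min(runs$lengths[short])]
    left <- if (i > 1) runs$lengths[i - 1] else -1L
    right <- if (i < length(runs$lengths)) runs$lengths[i + 1] else -1L
    j <- if (left >= right) i - 1 else i + 1
    runs$values[i] <- runs$values[j]
    lab <- inverse.rle(runs)
    runs <- rle(lab)
  }

  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  keep <- runs$values != 0L
  if (!any(keep)) {
    out <- data.frame(direction = character(0), start = numeric(0),
                      end = numeric(0), duration = numeric(0),
                      mean_speed = numeric(0))
    class(out) <- c("swim_sequences", "data.frame")
    return(out)
  }
  out <- data.frame(
    direction = ifelse(runs$values[keep] > 0, "push", "pull"),
    start = traj$t[starts[keep]],
    end = traj$t[ends[keep]] + 1 / fr,
    mean_speed = vapply(which(keep), function(i) {
      idx <- starts[i]:ends[i]
      # trim the straddling frames: the centered difference mixes the two
      # directions across a reversal and would bias the speed down
      if (length(idx) > 4) idx <- idx[-c(1L, length(idx))]
      mean(abs(proj[idx]))
    }, numeric(1))
  )
  out$duration <- out$end - out$start
  out <- out[, c("direction", "start", "end", "duration", "mean_speed")]
  class(out) <- c("swim_sequences", "data.frame")
  out
}

#' Swim sequence statistics
#'
#' Mean and SD of duration and speed per direction, plus the count fraction
#' and cumulative time fraction of each direction (both are reported because
#' the assay's "2/3 pushing" can be read either way; the run-reverse renewal
#' process makes the time fraction `tau_push / (tau_push + tau_pull)`).
#' Directions with no sequences are reported absent, not zero.
#'
#' @param seqs A `swim_sequences` data frame.
#' @return A list of class `swim_stats` with elements `push`, `pull` (each
#'   `NULL` or a list with `duration_mean`, `duration_sd`, `speed_mean`,
#'   `speed_sd`, `n`), `count_fraction` and `time_fraction` (named push/pull).
#' @export
swim_statistics <- function(seqs) {
  stopifnot(inherits(seqs, "swim_sequences"))
  if (!nrow(seqs)) stop("no swim sequences to summarize")
  one <- function(d) {
    s <- seqs[seqs$direction == d, , drop = FALSE]
    if (!nrow(s)) return(NULL)
    list(duration_mean = mean(s$duration),
         duration_sd = if (nrow(s) > 1) stats::sd(s$duration) else 0,
         speed_mean = mean(s$mean_speed),
         speed_sd = if (nrow(s) > 1) stats::sd(s$mean_speed) else 0,
         n = nrow(s))
  }
  tot_n <- nrow(seqs)
  tot_t <- sum(seqs$duration)
  frac <- function(d, what) {
    s <- seqs[seqs$direction == d, , drop = FALSE]
    if (what == "count") nrow(s) / tot_n else sum(s$duration) / tot_t
  }
  structure(
    list(push = one("push"), pull = one("pull"),
         count_fraction = c(push = frac("push", "count"),
                            pull = frac("pull", "count")),
         time_fraction = c(push = frac("push", "time"),
                           pull = frac("pull", "time"))),
    class = "swim_stats"
  )
}

#' @export
print.swim_stats <- function(x, ...) {
  cat("<swim_stats>\n")
  for (d in c("push", "pull")) {
    v <- x[[d]]
    if (is.null(v)) {
      cat(sprintf("  %s: absent\n", d))
    } else {
      cat(sprintf(
        "  %s: %.3g +/- %.3g s, %.3g +/- %.3g um/s (n = %d)\n",
        d, v$duration_mean, v$duration_sd, v$speed_mean, v$speed_sd, v$n))
    }
  }
  cat(sprintf("  time fraction push = %.3f, count fraction push = %.3f\n",
              x$time_fraction[["push"]], x$count_fraction[["push"]]))
  invisible(x)
}

#' Rotation frequency and direction of a flagellated-pole track
#'
#' Sliding-window spectral analysis of the pole position: per window
#' (default 0.5 s, 50% overlap) the frequency is the significant spectral
#' peak of the detrended x signal (Hann window, zero-padded periodogram) and
#' the rotation direction is the sign of the mean cross-quadrature
#' `<x dy/dt - y dx/dt>` (positive = CCW). Adjacent windows with the same
#' direction and frequencies within 20% are merged into intervals, and the
#' interval frequency is refined on the full interval with quadratic
#' interpolation of the log-periodogram around the peak. Windows without a
#' significant peak are left unclassified.
#'
#' @param pole A `pole_track` (or any [trajectory()]).
#' @param window Window length (s).
#' @param min_freq Lowest admissible rotation frequency (Hz).
#' @param sig Peak significance: peak power must exceed `sig` times the
#'   median in-band power.
#' @return A data frame of class `rotation_estimates`: columns `start`,
#'   `end`, `frequency` (Hz), `direction` (`CW`/`CCW`), `amplitude` (um).
#' @export
rotation_frequency <- function(pole, window = 0.5, min_freq = 1, sig = 8) {
  stopifnot(inherits(pole, "trajectory"))
  fr <- frame_rate(pole)
  n <- nrow(pole)
  wlen <- round(window * fr)
  if (wlen < 8 || n < wlen) stop("track shorter than one analysis window")
  hop <- max(1L, wlen %/% 2L)
  starts <- seq(1L, n - wlen + 1L, by = hop)

  win_est <- lapply(starts, function(i0) {
    idx <- i0:(i0 + wlen - 1L)
    x <- detrend_lin(pole$x[idx])
    y <- detrend_lin(pole$y[idx])
    pk <- spectral_peak(x, fr, min_freq)
    if (is.null(pk)) return(NULL)
    if (pk$snr < sig) return(NULL)
    dx <- diff(x)
    dy <- diff(y)
    cross <- mean(x[-wlen] * dy - y[-wlen] * dx) * fr
    list(i0 = i0, i1 = i0 + wlen - 1L, f = pk$f,
         dir = if (cross >= 0) "CCW" else "CW",
         amp = sqrt(mean(x^2 + y^2)))
  })
  win_est <- Filter(Negate(is.null), win_est)
  if (!length(win_est)) {
    out <- data.frame(start = numeric(0), end = numeric(0),
                      frequency = numeric(0), direction = character(0),
                      amplitude = numeric(0))
    class(out) <- c("rotation_estimates", "data.frame")
    return(out)
  }

  # merge adjacent windows with same direction and frequency within 20%
  groups <- list()
  cur <- win_est[[1]]
  cur$members <- list(win_est[[1]])
  for (w in win_est[-1]) {
    contiguous <- w$i0 <= cur$i1 + hop
    same <- w$dir == cur$dir &&
      abs(w$f - cur$f) <= 0.2 * max(w$f, cur$f)
    if (contiguous && same) {
      cur$i1 <- w$i1
      cur$f <- (cur$f + w$f) / 2
      cur$members <- c(cur$members, list(w))
    } else {
      groups <- c(groups, list(cur))
      cur <- w
      cur$members <- list(w)
    }
  }
  groups <- c(groups, list(cur))

  # windows straddling a direction switch blend both rotations; drop
  # single-window groups that overlap a multi-window neighbor
  if (length(groups) > 1) {
    nmem <- vapply(groups, function(g) length(g$members), integer(1))
    drop <- vapply(seq_along(groups), function(i) {
      if (nmem[i] > 1) return(FALSE)
      prev_ok <- i > 1 && nmem[i - 1] > 1 &&
        groups[[i]]$i0 <= groups[[i - 1]]$i1
      next_ok <- i < length(groups) && nmem[i + 1] > 1 &&
        groups[[i + 1]]$i0 <= groups[[i]]$i1
      prev_ok || next_ok
    }, logical(1))
    if (any(drop) && !all(drop)) groups <- groups[!drop]
  }

  rows <- lapply(groups, function(g) {
    idx <- g$i0:g$i1
    x <- detrend_lin(pole$x[idx])
    pk <- spectral_peak(x, fr, min_freq)
    f <- if (!is.null(pk)) pk$f else g$f
    data.frame(start = pole$t[g$i0], end = pole$t[g$i1] + 1 / fr,
               frequency = f, direction = g$dir,
               amplitude = mean(vapply(g$members, `[[`, numeric(1), "amp")))
  })
  out <- do.call(rbind, rows)
  out <- out[out$frequency >= min_freq & out$frequency < fr / 2, ,
             drop = FALSE]
  class(out) <- c("rotation_estimates", "data.frame")
  out
}

detrend_lin <- function(z) {
  t <- seq_along(z)
  stats::residuals(stats::lm.fit(cbind(1, t), z))
}

# Hann-windowed, zero-padded periodogram peak with quadratic interpolation
# of the log power. Returns NULL when no in-band bin exists.
spectral_peak <- function(z, fs, min_freq) {
  n <- length(z)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  nfft <- stats::nextn(4 * n, 2)
  sp <- abs(stats::fft(c(z * w, rep(0, nfft - n))))^2
  nf <- nfft %/% 2
  f <- (1:nf) * fs / nfft
  p <- sp[2:(nf + 1)]
  band <- which(f >= min_freq & f <= 0.45 * fs)
  if (!length(band)) return(NULL)
  k <- band[which.max(p[band])]
  fhat <- f[k]
  if (k > 1 && k < nf && p[k] > 0) {
    lp <- log(pmax(p[(k - 1):(k + 1)], 1e-300))
    den <- lp[1] - 2 * lp[2] + lp[3]
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (lp[1] - lp[3]) / den
      delta <- max(min(delta, 0.5), -0.5)
      fhat <- f[k] + delta * fs / nfft
    }
  }
  list(f = fhat, snr = p[k] / max(stats::median(p[band]), 1e-300))
}

#' Bending metrics of a pole track
#'
#' Bending amplitude (maximal pole displacement from the pre-onset baseline)
#' and bending duration for the pre-separation bending stage of a
#' surface-attached predivisional cell.
#'
#' @param pole A `pole_track`.
#' @param events An [event_table()] identifying the `bending` interval(s)
#'   (ground truth or external annotation).
#' @return `NULL` when no bending interval exists; otherwise a list with
#'   `amplitude` (um) and `duration` (s).
#' @export
bending_metrics <- function(pole, events) {
  stopifnot(inherits(pole, "trajectory"), inherits(events, "event_table"))
  bend <- events[events$state == "bending", , drop = FALSE]
  if (!nrow(bend)) return(NULL)
  s <- bend$start[1]
  e <- bend$end[1]
  pre <- which(pole$t < s)
  base <- if (length(pre) >= 3) {
    c(mean(pole$x[pre]), mean(pole$y[pre]))
  } else {
    idx0 <- which(pole$t >= s & pole$t < s + 0.25)
    c(mean(pole$x[idx0]), mean(pole$y[idx0]))
  }
  idx <- which(pole$t >= s & pole$t < e)
  disp <- sqrt((pole$x[idx] - base[1])^2 + (pole$y[idx] - base[2])^2)
  list(amplitude = max(disp), duration = sum(bend$end - bend$start))
}
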
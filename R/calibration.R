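#' Trap stiffness by equipartition (thermal fluctuation calibration)
#'
#' For a bead in a harmonic trap at temperature T, equipartition gives
#' `kappa = kB T / var(x)` per axis. The caller asserts that the trajectory
#' segment is Brownian-only (no active driving); the mean is subtracted per
#' axis. Confidence intervals come from a block bootstrap with blocks of
#' `10 * relaxation time` (trapped-bead samples are autocorrelated on the
#' relaxation timescale, so an i.i.d. bootstrap would understate the CI; the
#' relaxation time is estimated from the lag-1 autocorrelation).
#'
#' @param traj A [trajectory()] of a quiescent (Brownian-only) segment.
#' @param temperature Absolute temperature (K).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level for the half-widths.
#' @return An object of class `calibration_result`: list with `kappa`
#'   (named x/y, pN/um), `method = "equipartition"`, `n_samples`,
#'   `ci_half_width` (per axis) and `reliable`.
#' @export
stiffness_equipartition <- function(traj, temperature = 303.15,
                                    n_boot = 1000, conf = 0.95) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  if (n < 100) stop("refusing to calibrate on fewer than 100 samples")
  kT <- kB * temperature
  pos <- cbind(traj$x - mean(traj$x), traj$y - mean(traj$y))
  v <- apply(pos, 2, stats::var)
  if (any(v <= 0)) stop("zero positional variance; cannot calibrate")
  kappa <- kT / v
  fr <- frame_rate(traj)

  ci <- vapply(1:2, function(ax) {
    z <- pos[, ax]
    rho1 <- stats::cor(z[-n], z[-1])
    tau <- if (is.finite(rho1) && rho1 > 0 && rho1 < 1) {
      -1 / (fr * log(rho1))
    } else {
      1 / fr
    }
    block <- max(2L, min(ceiling(10 * tau * fr), floor(n / 10)))
    m <- floor(n / block)
    idx <- matrix(seq_len(m * block), nrow = block)
    bs1 <- colSums(matrix(z[idx], nrow = block))        # block sums
    bs2 <- colSums(matrix(z[idx]^2, nrow = block))      # block sums of squares
    pick <- matrix(sample.int(m, m * n_boot, replace = TRUE), ncol = n_boot)
    s1 <- colSums(matrix(bs1[pick], ncol = n_boot))
    s2 <- colSums(matrix(bs2[pick], ncol = n_boot))
    nn <- m * block
    vb <- (s2 - s1^2 / nn) / (nn - 1)
    kb <- kT / vb
    unname(diff(stats::quantile(kb, c((1 - conf) / 2, (1 + conf) / 2))) / 2)
  }, numeric(1))

  structure(
    list(kappa = c(x = unname(kappa[1]), y = unname(kappa[2])),
         method = "equipartition", n_samples = n,
         ci_half_width = c(x = ci[1], y = ci[2]),
         reliable = n >= 1e4),
    class = "calibration_result"
  )
}

#' Trap stiffness from the power spectral density
#'
#' The position power spectrum of a trapped bead is Lorentzian,
#' `S(f) = D / (2 pi^2 (fc^2 + f^2))`, with corner frequency
#' `fc = kappa / (2 pi gamma)`. A Welch-averaged one-sided periodogram is
#' log-binned and the Lorentzian fitted per axis; then `kappa = 2 pi gamma fc`.
#' The estimate is flagged unreliable when the fit fails, `fc` exceeds a
#' quarter of the sampling rate (aliasing regime), or `fc` falls below twice
#' the spectral resolution (untrapped limit).
#'
#' @param traj A Brownian-only [trajectory()].
#' @param temperature Absolute temperature (K).
#' @param drag Bead drag coefficient gamma (pN s/um).
#' @param n_segments Welch segments (default 16).
#' @return A `calibration_result` with `kappa`, `corner_frequency` and
#'   `diffusion` per axis, `method = "psd"`, `n_samples`, `reliable`.
#' @export
stiffness_psd <- function(traj, temperature = 303.15, drag, n_segments = 16) {
  stopifnot(inherits(traj, "trajectory"), drag > 0)
  n <- nrow(traj)
  if (n < 100) stop("refusing to calibrate on fewer than 100 samples")
  fr <- frame_rate(traj)
  pos <- cbind(traj$x - mean(traj$x), traj$y - mean(traj$y))

  fit_axis <- function(z) {
    ps <- welch_psd(z, fr, n_segments)
    keep <- ps$f > 0 & ps$f <= 0.45 * fr
    f <- ps$f[keep]
    S <- ps$S[keep]
    # log-spaced bins stabilize the fit across four decades of power
    nb <- 40
    brk <- exp(seq(log(min(f)), log(max(f)) * (1 + 1e-9), length.out = nb + 1))
    bin <- cut(f, brk, include.lowest = TRUE)
    fb <- tapply(f, bin, mean)
    Sb <- tapply(S, bin, mean)
    cb <- tapply(S, bin, length)
    okb <- is.finite(fb) & is.finite(Sb) & Sb > 0
    fb <- fb[okb]
    Sb <- Sb[okb]
    cb <- cb[okb]
    # exact spectrum of the *sampled* trapped-bead process (AR(1) form):
    # equals the Lorentzian with all aliasing folds summed, so the fit is
    # unbiased at any frame rate, where a naive Lorentzian reads fc too high
    obj <- function(p) {
      fc <- exp(p[1])
      D <- exp(p[2])
      a <- exp(-2 * pi * fc / fr)
      sx2 <- D / (2 * pi * fc)
      model <- (2 * sx2 * (1 - a^2) / fr) /
        (1 + a^2 - 2 * a * cos(2 * pi * fb / fr))
      sum(cb * (log(Sb) - log(model))^2)
    }
    D0 <- kB * temperature / drag
    fc_grid <- exp(seq(log(min(fb)), log(max(fb)), length.out = 25))
    sse <- vapply(fc_grid, function(fc) obj(log(c(fc, D0))), numeric(1))
    p0 <- log(c(fc_grid[which.min(sse)], D0))
    opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    list(fc = exp(opt$par[1]), D = exp(opt$par[2]),
         converged = opt$convergence == 0, df = min(diff(fb)))
  }

  fits <- apply(pos, 2, fit_axis)
  fc <- vapply(fits, `[[`, numeric(1), "fc")
  Dhat <- vapply(fits, `[[`, numeric(1), "D")
  kappa <- 2 * pi * drag * fc
  res_f <- fr / (n / n_segments) # Welch segment resolution
  reliable <- all(vapply(fits, `[[`, logical(1), "converged")) &&
    all(fc < fr / 4) && all(fc > 2 * res_f)
  structure(
    list(kappa = c(x = kappa[1], y = kappa[2]),
         corner_frequency = c(x = fc[1], y = fc[2]),
         diffusion = c(x = Dhat[1], y = Dhat[2]),
         method = "psd", n_samples = n, reliable = reliable),
    class = "calibration_result"
  )
}

# One-sided Welch periodogram (Hann window, 50% overlap), density units um^2/Hz.
welch_psd <- function(z, fs, n_segments = 16) {
  n <- length(z)
  seg <- 2^floor(log2(2 * n / (n_segments + 1)))
  seg <- max(min(seg, n), 64)
  hop <- seg %/% 2
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg) / (seg + 1)))
  u <- sum(w^2)
  starts <- seq(1, n - seg + 1, by = hop)
  acc <- numeric(seg %/% 2)
  for (s in starts) {
    zz <- z[s:(s + seg - 1)] * w
    sp <- abs(stats::fft(zz))^2 / (u * fs)
    acc <- acc + sp[2:(seg %/% 2 + 1)]
  }
  S <- 2 * acc / length(starts) # one-sided
  f <- (1:(seg %/% 2)) * fs / seg
  list(f = f, S = S)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> method = %s, n = %d%s\n", x$method,
              x$n_samples, if (isTRUE(x$reliable)) "" else " (unreliable)"))
  cat(sprintf("  kappa_x = %.4g pN/um, kappa_y = %.4g pN/um\n",
              x$kappa[["x"]], x$kappa[["y"]]))
  if (!is.null(x$ci_half_width)) {
    cat(sprintf("  CI half-widths: (%.3g, %.3g)\n",
                x$ci_half_width[["x"]], x$ci_half_width[["y"]]))
  }
  invisible(x)
}
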
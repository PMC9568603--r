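#' Render a synthetic image stack from a trajectory
#'
#' Produces a bright-spot movie of the bead: each frame is a 2-D Gaussian
#' spot of width `spot_sigma` centered at the bead position on a constant
#' background, with noise at the requested signal-to-noise ratio. This is the
#' synthetic stand-in for the assay's high-speed bright-field recordings and
#' gives the tracker a ground-truth benchmark.
#'
#' Pixel convention: pixel centers at integer coordinates, `x` = column,
#' `y` = row, row 1 / column 1 at the top-left. The mapping to physical
#' coordinates (origin of pixel (1,1) in um, y axis flipped to mathematical
#' orientation) is stored in the stack so that tracking inverts it exactly.
#'
#' @param traj A [trajectory()] (um).
#' @param pixel_size Pixel size (um/px).
#' @param spot_sigma Gaussian spot width (px).
#' @param snr Peak signal amplitude / noise standard deviation; `Inf` for a
#'   noiseless stack.
#' @param fov Optional c(rows, cols). Default: tight field of view with a
#'   margin of `4 * spot_sigma + 1` px around the trajectory.
#' @param background,amplitude Background and peak intensity (arbitrary
#'   units; the stack is scaled to the bit depth on write).
#' @param noise_model `"gaussian"` (additive read noise) or `"poisson"`
#'   (shot noise with gain set so the peak SNR matches `snr`).
#' @param bit_depth Bits per sample for on-disk representation (8 or 16).
#' @param seed Optional seed for the noise stream.
#' @return An object of class `image_stack`: list with `frames`
#'   (rows x cols x n array), `pixel_size`, `frame_rate`, `bit_depth`,
#'   `origin` (um of pixel (1,1)), `spot_sigma`.
#' @export
render_image_stack <- function(traj, pixel_size = 0.1, spot_sigma = 2,
                               snr = 10, fov = NULL, background = 0.1,
                               amplitude = 1, noise_model = "gaussian",
                               bit_depth = 16, seed = NULL) {
  stopifnot(inherits(traj, "trajectory"), pixel_size > 0, spot_sigma > 0)
  noise_model <- match.arg(noise_model, c("gaussian", "poisson"))
  margin <- ceiling(4 * spot_sigma) + 1
  if (is.null(fov)) {
    ox <- min(traj$x) - margin * pixel_size
    oy <- max(traj$y) + margin * pixel_size
    ncol_ <- ceiling((max(traj$x) - min(traj$x)) / pixel_size) + 2 * margin + 1
    nrow_ <- ceiling((max(traj$y) - min(traj$y)) / pixel_size) + 2 * margin + 1
  } else {
    nrow_ <- fov[1]
    ncol_ <- fov[2]
    ox <- min(traj$x) - margin * pixel_size
    oy <- max(traj$y) + margin * pixel_size
  }
  # pixel (1,1) center sits at (ox, oy) um
  col_pos <- 1 + (traj$x - ox) / pixel_size
  row_pos <- 1 + (oy - traj$y) / pixel_size
  bad <- which(col_pos < margin / 2 | col_pos > ncol_ - margin / 2 + 1 |
                 row_pos < margin / 2 | row_pos > nrow_ - margin / 2 + 1)
  if (length(bad)) {
    stop("spot leaves the field of view in frame(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(traj)
  frames <- array(0, dim = c(nrow_, ncol_, n))
  rows <- seq_len(nrow_)
  cols <- seq_len(ncol_)
  for (k in seq_len(n)) {
    gr <- exp(-(rows - row_pos[k])^2 / (2 * spot_sigma^2))
    gc <- exp(-(cols - col_pos[k])^2 / (2 * spot_sigma^2))
    f <- background + amplitude * outer(gr, gc)
    if (is.finite(snr)) {
      if (noise_model == "gaussian") {
        f <- f + stats::rnorm(length(f), 0, amplitude / snr)
      } else {
        photons <- snr^2 * (background + amplitude) / amplitude^2
        f <- stats::rpois(length(f), pmax(f, 0) * photons) / photons
      }
    }
    frames[, , k] <- f
  }
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_rate = frame_rate(traj), bit_depth = bit_depth,
         origin = c(x = ox, y = oy), spot_sigma = spot_sigma),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_stack> %d frames of %d x %d px, %.3g um/px, %.4g Hz, %d-bit\n",
    d[3], d[1], d[2], x$pixel_size, x$frame_rate, x$bit_depth))
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Intensities are scaled to the stack's bit depth on write. A JSON sidecar
#' (`<path>.json`) carries the physical metadata (pixel size, frame rate,
#' origin) so a read stack tracks back to the same physical coordinates.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `write_image_stack` returns `path` invisibly; `read_image_stack`
#'   returns an `image_stack`.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$frames)[3]
  lo <- min(stack$frames)
  hi <- max(stack$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(n), function(k) {
    (stack$frames[, , k] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none")
  meta <- list(pixel_size = stack$pixel_size, frame_rate = stack$frame_rate,
               bit_depth = stack$bit_depth, origin = as.list(stack$origin),
               spot_sigma = stack$spot_sigma,
               intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    stop("metadata sidecar not found: ", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (k in seq_along(pages)) {
    frames[, , k] <- pages[[k]] * meta$intensity_scale + meta$intensity_offset
  }
  structure(
    list(frames = frames, pixel_size = meta$pixel_size,
         frame_rate = meta$frame_rate, bit_depth = meta$bit_depth,
         origin = c(x = meta$origin$x, y = meta$origin$y),
         spot_sigma = meta$spot_sigma),
    class = "image_stack"
  )
}
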
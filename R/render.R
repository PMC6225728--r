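#' Render ground-truth trajectories into a noisy spot movie
#'
#' Each frame is constant background plus a sum of 2D Gaussian spots
#' (sigma = `config$psf_sigma` pixels, peak amplitude `config$spot_intensity`)
#' at the observed (drift-included) positions, followed by Poisson shot noise
#' (`photon_scale` photons per camera unit; 0 = off) and Gaussian read noise.
#'
#' Coordinate convention: position (0, 0) nm is the center of the top-left
#' pixel; x runs along columns, y along rows.
#'
#' @param truth a `ground_truth` object from a `simulate_*` generator.
#' @param config an [acquisition_config()]; defaults to the one stored in
#'   `truth`.
#' @param edge what to do with particles outside the field of view:
#'   "clip" (warn, clamp to the border), "drop" (warn, omit that frame's
#'   spot) or "error".
#' @param seed RNG seed for the noise.
#' @return list with `frames` (h x w x n array) and `truth`.
#' @export
render_movie <- function(truth, config = truth$config,
                         edge = c("clip", "drop", "error"), seed = NULL) {
  edge <- match.arg(edge)
  with_seed(seed, {
    h <- config$image_shape[1]; w <- config$image_shape[2]
    n <- config$n_frames
    px <- config$pixel_size
    sig <- config$psf_sigma
    R <- ceiling(4 * sig)
    obs <- observed_positions(truth)
    frames <- array(config$background, c(h, w, n))
    n_out <- 0L
    for (f in seq_len(n)) {
      img <- frames[, , f]
      for (tr in obs) {
        xp <- tr[f, 1] / px; yp <- tr[f, 2] / px   # 0-based pixel coords
        if (xp < 0 || xp > w - 1 || yp < 0 || yp > h - 1) {
          n_out <- n_out + 1L
          if (edge == "error") stopf("particle left the field of view at frame %d", f)
          if (edge == "drop") next
          xp <- min(max(xp, 0), w - 1); yp <- min(max(yp, 0), h - 1)
        }
        rows <- max(1, round(yp) + 1 - R):min(h, round(yp) + 1 + R)
        cols <- max(1, round(xp) + 1 - R):min(w, round(xp) + 1 + R)
        gy <- exp(-((rows - 1 - yp)^2) / (2 * sig^2))
        gx <- exp(-((cols - 1 - xp)^2) / (2 * sig^2))
        img[rows, cols] <- img[rows, cols] +
          config$spot_intensity * outer(gy, gx)
      }
      if (config$photon_scale > 0)
        img <- stats::rpois(length(img), img * config$photon_scale) /
          config$photon_scale
      if (config$read_noise > 0)
        img <- img + stats::rnorm(length(img), sd = config$read_noise)
      frames[, , f] <- img
    }
    if (n_out > 0)
      warnf("%d spot renderings fell outside the field of view (%s)", n_out, edge)
    list(frames = frames, truth = truth)
  })
}

#' Write a rendered movie and its ground truth to disk
#'
#' @param movie output of [render_movie()].
#' @param tiff_path multi-page TIFF destination.
#' @param truth_path optional CSV destination for the ground truth.
#' @export
write_movie <- function(movie, tiff_path, truth_path = NULL) {
  write_tiff(movie$frames, tiff_path)
  if (!is.null(truth_path)) write_truth_csv(movie$truth, truth_path)
  invisible(tiff_path)
}
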
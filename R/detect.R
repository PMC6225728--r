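## Spot detection: single-scale Laplacian-of-Gaussian response, 8-neighbor
## local maxima, sub-pixel refinement by intensity-weighted centroid (default)
## or 2D Gaussian least squares.

## FFT convolution with zero padding; returns same-size response.
conv2_fft <- function(img, kernel) {
  R <- (dim(kernel) - 1) %/% 2
  h <- nrow(img); w <- ncol(img)
  hp <- h + 2 * R[1]; wp <- w + 2 * R[2]
  ## replicate-pad: a constant background then yields zero LoG response
  ## everywhere, including at the image border
  ri_pad <- c(rep(1L, R[1]), seq_len(h), rep(h, R[1]))
  ci_pad <- c(rep(1L, R[2]), seq_len(w), rep(w, R[2]))
  imgp <- img[ri_pad, ci_pad]
  kp <- matrix(0, hp, wp)
  ri <- ((seq_len(nrow(kernel)) - 1 - R[1]) %% hp) + 1
  ci <- ((seq_len(ncol(kernel)) - 1 - R[2]) %% wp) + 1
  kp[ri, ci] <- kernel
  out <- Re(stats::fft(stats::fft(imgp) * stats::fft(kp), inverse = TRUE)) /
    (hp * wp)
  out[R[1] + seq_len(h), R[2] + seq_len(w)]
}

## scale-normalized, sign-flipped LoG kernel: bright blobs -> positive peaks
log_kernel <- function(sigma) {
  R <- ceiling(4 * sigma)
  g <- seq(-R, R)
  r2 <- outer(g^2, g^2, `+`)
  k <- (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))
  k - mean(k)   # zero-mean: flat background gives zero response
}

local_maxima_2d <- function(m) {
  h <- nrow(m); w <- ncol(m)
  sh <- function(dr, dc) {
    out <- matrix(-Inf, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  ## strict on one half of the neighborhood, non-strict on the other:
  ## a two-pixel plateau yields exactly one maximum
  m > sh(-1, 0) & m > sh(0, -1) & m > sh(-1, -1) & m > sh(-1, 1) &
    m >= sh(1, 0) & m >= sh(0, 1) & m >= sh(1, 1) & m >= sh(1, -1)
}

## 2D Gaussian least-squares refinement on a window; returns x, y (0-based
## px), sigma (px), amplitude
gauss_refine <- function(img, r0, c0, sigma) {
  R <- ceiling(4 * sigma)
  h <- nrow(img); w <- ncol(img)
  rows <- max(1, r0 - R):min(h, r0 + R)
  cols <- max(1, c0 - R):min(w, c0 + R)
  z <- img[rows, cols]
  yy <- matrix(rows - 1, length(rows), length(cols))
  xx <- matrix(cols - 1, length(rows), length(cols), byrow = TRUE)
  p0 <- c(amp = max(z) - min(z), x0 = c0 - 1, y0 = r0 - 1,
          lsig = log(sigma), off = min(z))
  ssr <- function(p) {
    mu <- p[5] + p[1] * exp(-((xx - p[2])^2 + (yy - p[3])^2) /
                              (2 * exp(2 * p[4])))
    sum((z - mu)^2)
  }
  fit <- stats::optim(p0, ssr, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  c(x = unname(fit$par[2]), y = unname(fit$par[3]),
    sigma = exp(unname(fit$par[4])), amp = unname(fit$par[1]))
}

#' Detect diffraction-limited spots in a 2D frame
#'
#' Computes a single-scale Laplacian-of-Gaussian response at the expected
#' spot width, keeps 8-neighborhood local maxima above `threshold`, and
#' refines each to sub-pixel precision.  Position (0, 0) is the center of
#' the top-left pixel; x runs along columns.
#'
#' @param image numeric matrix (one frame).
#' @param sigma_px expected spot Gaussian width in pixels.
#' @param threshold minimum LoG response; `NULL` picks
#'   `5 * mad(response)` automatically.
#' @param pixel_size nm per pixel, used to report positions in nm.
#' @param refine "centroid" (intensity-weighted centroid in a window of
#'   radius `2*sigma_px`, fast) or "gaussian" (least-squares 2D Gaussian,
#'   accurate widths).
#' @param mask optional integer label matrix assigning pixels to nuclei;
#'   spots get `nucleus_id` from the label under their peak (0 elsewhere).
#' @return data.frame with columns nucleus_id, x_nm, y_nm, x_px, y_px,
#'   intensity, sigma_nm, sorted by descending intensity; possibly 0 rows.
#' @export
detect_spots_2d <- function(image, sigma_px = 1.3, threshold = NULL,
                            pixel_size = 66.3,
                            refine = c("centroid", "gaussian"),
                            mask = NULL) {
  refine <- match.arg(refine)
  if (!is.matrix(image)) stopf("'image' must be a 2D matrix")
  if (all(image == 0))
    return(empty_spots())
  resp <- conv2_fft(image, log_kernel(sigma_px))
  ## auto threshold: robust noise floor, with a relative floor so noiseless
  ## images do not surface FFT ripple as detections
  if (is.null(threshold))
    threshold <- max(5 * stats::mad(resp), 0.02 * max(resp))
  peaks <- which(local_maxima_2d(resp) & resp > threshold, arr.ind = TRUE)
  if (nrow(peaks) == 0) return(empty_spots())
  wr <- ceiling(2 * sigma_px)
  h <- nrow(image); w <- ncol(image)
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    r0 <- peaks[i, 1]; c0 <- peaks[i, 2]
    rows <- max(1, r0 - wr):min(h, r0 + wr)
    cols <- max(1, c0 - wr):min(w, c0 + wr)
    win <- image[rows, cols] - min(image[rows, cols])
    tot <- sum(win)
    if (tot <= 0) return(NULL)
    yy <- rows - 1; xx <- cols - 1
    xc <- sum(colSums(win) * xx) / tot
    yc <- sum(rowSums(win) * yy) / tot
    ## second central moment, corrected for the truncated window support
    s2 <- (sum(colSums(win) * (xx - xc)^2) +
           sum(rowSums(win) * (yy - yc)^2)) / (2 * tot)
    sg <- sqrt(max(s2, 1e-12)) / moment_trunc_factor(wr / sigma_px)
    if (refine == "gaussian") {
      gf <- gauss_refine(image, r0, c0, sigma_px)
      xc <- gf["x"]; yc <- gf["y"]; sg <- gf["sigma"]
    }
    nid <- if (is.null(mask)) 0L else as.integer(mask[r0, c0])
    data.frame(nucleus_id = nid, x_nm = xc * pixel_size, y_nm = yc * pixel_size,
               x_px = xc, y_px = yc, intensity = tot, sigma_nm = sg * pixel_size)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) return(empty_spots())
  rownames(out) <- NULL
  out[order(-out$intensity), , drop = FALSE]
}

## sd of a radially truncated unit Gaussian observed within radius k*sigma,
## relative to sigma; used to de-bias the moment estimator
moment_trunc_factor <- function(k) {
  ## E[x^2]/sigma^2 for 1D gaussian truncated at +-k (applied per axis)
  sqrt(1 - 2 * k * stats::dnorm(k) / (2 * stats::pnorm(k) - 1))
}

empty_spots <- function() {
  data.frame(nucleus_id = integer(0), x_nm = numeric(0), y_nm = numeric(0),
             x_px = numeric(0), y_px = numeric(0), intensity = numeric(0),
             sigma_nm = numeric(0))
}

#' Detect spots in every frame of a movie
#'
#' @param frames h x w x n_frames array.
#' @param ... passed to [detect_spots_2d()].
#' @return data.frame of spots with a 0-based `frame` column.
#' @export
detect_spots_movie <- function(frames, ...) {
  if (length(dim(frames)) != 3L) stopf("'frames' must be an h x w x n array")
  res <- lapply(seq_len(dim(frames)[3]), function(f) {
    s <- detect_spots_2d(frames[, , f], ...)
    if (nrow(s) > 0) s$frame <- f - 1L else s$frame <- integer(0)
    s
  })
  do.call(rbind, res)
}

#' Detect foci in a 3D stack or adopt a pre-detected foci table
#'
#' For voxel input, runs 26-neighborhood 3D local-maxima detection and
#' converts voxel indices to physical nm using the (mandatory) anisotropic
#' voxel spacing.  For a pre-detected table (columns x_nm, y_nm, z_nm and
#' optionally nucleus_id, channel, intensity), groups rows into
#' [nucleus_foci()] sets.
#'
#' @param x h x w x n_planes numeric array, or a data.frame foci table.
#' @param pixel_size lateral voxel size in nm (required for voxel input).
#' @param z_step axial step in um (required for voxel input).
#' @param threshold minimum voxel intensity for a peak; `NULL` picks
#'   `mean + 5 * sd` of the stack.
#' @param mask optional integer label matrix (h x w) assigning xy positions
#'   to nuclei; without it all foci belong to nucleus 0.
#' @return list of `nucleus_foci`, one per nucleus present.
#' @export
detect_foci_3d <- function(x, pixel_size = NULL, z_step = NULL,
                           threshold = NULL, mask = NULL) {
  if (is.data.frame(x)) {
    if (!all(c("x_nm", "y_nm", "z_nm") %in% names(x)))
      stopf("foci table needs columns x_nm, y_nm, z_nm")
    nid <- x$nucleus_id %||% rep(0L, nrow(x))
    ch <- x$channel %||% rep("A", nrow(x))
    out <- list()
    for (id in unique(nid)) for (cc in unique(ch[nid == id])) {
      sel <- nid == id & ch == cc
      out[[length(out) + 1L]] <- nucleus_foci(
        nucleus_id = id, channel = cc,
        positions = as.matrix(x[sel, c("x_nm", "y_nm", "z_nm")]),
        intensities = (x$intensity %||% rep(NA_real_, nrow(x)))[sel])
    }
    return(out)
  }
  if (length(dim(x)) != 3L) stopf("'x' must be a 3D array or a foci table")
  if (is.null(pixel_size) || is.null(z_step))
    stopf("voxel input requires explicit 'pixel_size' (nm) and 'z_step' (um); refusing to assume isotropy")
  if (all(x == 0) || length(x) == 0)
    return(list(nucleus_foci(0L, "A", matrix(numeric(0), 0, 3))))
  if (is.null(threshold)) threshold <- mean(x) + 5 * stats::sd(x)
  d <- dim(x)
  is_peak <- array(TRUE, d)
  for (dz in -1:1) for (dr in -1:1) for (dc in -1:1) {
    if (dz == 0 && dr == 0 && dc == 0) next
    shifted <- array(-Inf, d)
    rs <- seq_len(d[1]) + dr; cs <- seq_len(d[2]) + dc; zs <- seq_len(d[3]) + dz
    okr <- rs >= 1 & rs <= d[1]; okc <- cs >= 1 & cs <= d[2]
    okz <- zs >= 1 & zs <= d[3]
    shifted[okr, okc, okz] <- x[rs[okr], cs[okc], zs[okz]]
    strict <- (dz > 0) || (dz == 0 && (dr > 0 || (dr == 0 && dc > 0)))
    is_peak <- is_peak & (if (strict) x >= shifted else x > shifted)
  }
  idx <- which(is_peak & x > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(list(nucleus_foci(0L, "A", matrix(numeric(0), 0, 3))))
  ## sub-voxel centroid within a +-1 voxel window per axis
  pos <- t(apply(idx, 1, function(v) {
    rows <- max(1, v[1] - 1):min(d[1], v[1] + 1)
    cols <- max(1, v[2] - 1):min(d[2], v[2] + 1)
    planes <- max(1, v[3] - 1):min(d[3], v[3] + 1)
    win <- x[rows, cols, planes, drop = FALSE]
    win <- win - min(win)
    tot <- sum(win)
    if (tot <= 0) return(c(v[2] - 1, v[1] - 1, v[3] - 1))
    c(sum(apply(win, 2, sum) * (cols - 1)) / tot,
      sum(apply(win, 1, sum) * (rows - 1)) / tot,
      sum(apply(win, 3, sum) * (planes - 1)) / tot)
  }))
  nm <- cbind(pos[, 1] * pixel_size, pos[, 2] * pixel_size,
              pos[, 3] * z_step * .NM_PER_UM)
  inten <- x[idx]
  nid <- if (is.null(mask)) rep(0L, nrow(idx)) else
    as.integer(mask[cbind(idx[, 1], idx[, 2])])
  lapply(sort(unique(nid)), function(id) {
    sel <- nid == id
    nucleus_foci(id, "A", nm[sel, , drop = FALSE], inten[sel])
  })
}

#' Estimate the telomere spot diameter
#'
#' Median over isolated spots of the fitted Gaussian FWHM,
#' `2*sqrt(2*log(2)) * sigma`.  Isolated means the nearest neighbor is
#' farther than `isolation_nm` (default `6 *` median sigma).  Use
#' detection with `refine = "gaussian"` for unbiased widths.
#'
#' @param spots data.frame from [detect_spots_2d()] (needs x_nm, y_nm,
#'   sigma_nm).
#' @param diameter optional user override in nm, returned unchanged.
#' @param isolation_nm isolation radius in nm.
#' @return spot diameter in nm.
#' @export
estimate_spot_diameter <- function(spots, diameter = NULL,
                                   isolation_nm = NULL) {
  if (!is.null(diameter)) return(diameter)
  if (nrow(spots) >= 1) {
    iso <- isolation_nm %||% (6 * stats::median(spots$sigma_nm))
    if (nrow(spots) == 1) {
      isolated <- TRUE
    } else {
      dd <- as.matrix(stats::dist(spots[, c("x_nm", "y_nm")]))
      diag(dd) <- Inf
      isolated <- apply(dd, 1, min) > iso
    }
  } else isolated <- logical(0)
  if (sum(isolated) < 3)
    stopf("fewer than 3 isolated spots; supply the spot diameter explicitly via 'diameter'")
  2 * sqrt(2 * log(2)) * stats::median(spots$sigma_nm[isolated])
}
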
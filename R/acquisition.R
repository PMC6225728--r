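#' Acquisition configuration
#'
#' Describes how a time-lapse movie (or z-stack) is acquired and rendered.
#' Defaults mirror a spinning-disk confocal acquisition of nuclear loci:
#' 512 x 512 frames at 4 frames/s for 120 s (480 frames, dt = 0.25 s),
#' 66.3 nm pixels, 0.5 um z-steps, and a diffraction-limited PSF of
#' sigma = 1.3 px.
#'
#' @param n_frames number of frames (>= 2).
#' @param dt frame interval in seconds.
#' @param pixel_size lateral pixel size in nm.
#' @param image_shape integer (height, width) in pixels.
#' @param z_step axial step in um (z-stacks only).
#' @param psf_sigma spot Gaussian width in pixels.
#' @param spot_intensity peak spot amplitude in arbitrary camera units.
#' @param photon_scale photons per camera unit for Poisson shot noise;
#'   0 disables shot noise.
#' @param background constant background level (camera units).
#' @param read_noise Gaussian read noise SD (camera units); 0 disables.
#' @param drift whole-nucleus drift specification, see [drift_linear()].
#' @param seed optional RNG seed recorded with the configuration.
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(n_frames = 480L, dt = 0.25, pixel_size = 66.3,
                               image_shape = c(512L, 512L), z_step = 0.5,
                               psf_sigma = 1.3, spot_intensity = 100,
                               photon_scale = 1, background = 10,
                               read_noise = 2, drift = drift_none(),
                               seed = NULL) {
  assert_scalar_num(n_frames, "n_frames", min = 2)
  assert_scalar_num(dt, "dt", min = 0, strict_min = TRUE)
  assert_scalar_num(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  assert_scalar_num(psf_sigma, "psf_sigma", min = 0, strict_min = TRUE)
  assert_scalar_num(z_step, "z_step", min = 0, strict_min = TRUE)
  if (length(image_shape) != 2L || any(image_shape < 1))
    stopf("'image_shape' must be (height, width) in pixels")
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 pixel_size = pixel_size,
                 image_shape = as.integer(image_shape), z_step = z_step,
                 psf_sigma = psf_sigma, spot_intensity = spot_intensity,
                 photon_scale = photon_scale, background = background,
                 read_noise = read_noise, drift = drift, seed = seed),
            class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("<acquisition_config> %d frames @ dt=%gs, %dx%d px (%g nm/px), psf sigma %g px\n",
              x$n_frames, x$dt, x$image_shape[1], x$image_shape[2],
              x$pixel_size, x$psf_sigma))
  invisible(x)
}

#' Motion models for the trajectory generator
#'
#' A `motion_model` names one of the three generative diffusion laws used by
#' the simulator: free Brownian motion (ensemble MSD `4*D*t`), fractional
#' Brownian motion with anomalous exponent `alpha` (MSD `4*D*t^alpha`), or
#' confined-plus-macroscopic motion, a stationary Ornstein-Uhlenbeck process
#' superposed on slow Brownian escape (MSD `A*(1-exp(-t/tau)) + 4*D_macro*t`).
#'
#' @param kind one of "brownian", "fbm", "confined".
#' @param D diffusion coefficient in um^2/s (um^2/s^alpha for fbm).
#' @param alpha anomalous exponent in (0, 2]; fbm only.
#' @param A confinement plateau in um^2; confined only.
#' @param tau confinement relaxation time in s; confined only.
#' @param D_macro macroscopic escape coefficient in um^2/s; confined only.
#' @return an object of class `motion_model`.
#' @export
motion_model <- function(kind = c("brownian", "fbm", "confined"), D = 0.01,
                         alpha = 1, A = 0.04, tau = 2, D_macro = 0) {
  kind <- match.arg(kind)
  assert_scalar_num(D, "D", min = 0)
  if (kind == "fbm")
    assert_scalar_num(alpha, "alpha", min = 0, max = 2, strict_min = TRUE)
  if (kind == "confined") {
    assert_scalar_num(A, "A", min = 0)
    assert_scalar_num(tau, "tau", min = 0, strict_min = TRUE)
    assert_scalar_num(D_macro, "D_macro", min = 0)
  }
  structure(list(kind = kind, D = D, alpha = alpha, A = A, tau = tau,
                 D_macro = D_macro), class = "motion_model")
}

#' Whole-nucleus drift specifications
#'
#' Drift is a deterministic per-frame offset added identically to every
#' particle of a nucleus — the component that centroid-based drift
#' correction can remove.
#'
#' @param vx,vy constant velocity in nm per frame.
#' @param amplitude sinusoid amplitude in nm.
#' @param period sinusoid period in s.
#' @param axis "x", "y" or "xy" for the sinusoid direction.
#' @return a `drift_spec` object.
#' @export
drift_none <- function() structure(list(kind = "none"), class = "drift_spec")

#' @rdname drift_none
#' @export
drift_linear <- function(vx, vy = 0)
  structure(list(kind = "linear", vx = vx, vy = vy), class = "drift_spec")

#' @rdname drift_none
#' @export
drift_sine <- function(amplitude, period, axis = "x") {
  assert_scalar_num(period, "period", min = 0, strict_min = TRUE)
  structure(list(kind = "sine", amplitude = amplitude, period = period,
                 axis = axis), class = "drift_spec")
}

## n_frames x 2 matrix of offsets (nm), frame 0 at zero offset
drift_offsets <- function(drift, n_frames, dt) {
  f <- seq_len(n_frames) - 1
  switch(drift$kind,
    none = matrix(0, n_frames, 2),
    linear = cbind(drift$vx * f, drift$vy * f),
    sine = {
      s <- drift$amplitude * sin(2 * pi * f * dt / drift$period)
      switch(drift$axis,
             x = cbind(s, 0 * s), y = cbind(0 * s, s), xy = cbind(s, s))
    },
    stopf("unknown drift kind '%s'", drift$kind))
}
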
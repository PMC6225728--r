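## Trajectory generators.  All positions in nm, times in s.

## ---- fractional Gaussian noise --------------------------------------------

## autocovariance of one-step fGn increments with one-step variance var1,
## Hurst exponent H; gamma(k) for integer lags k >= 0.
fgn_autocov <- function(k, H, var1) {
  k <- abs(k)
  var1 / 2 * (abs(k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
}

## Exact fGn sampler: circulant embedding (Davies-Harte) with a Cholesky
## fallback if the embedding is not nonnegative-definite.  Returns an
## n_steps x n_series matrix of increments.
fgn_sample <- function(n_steps, n_series, H, var1) {
  if (n_steps < 1 || n_series < 1) return(matrix(0, max(n_steps, 0), max(n_series, 0)))
  if (H >= 1 - 1e-12) {
    ## ballistic limit: all increments of one series are a single N(0, var1) draw
    v <- stats::rnorm(n_series, sd = sqrt(var1))
    return(matrix(rep(v, each = n_steps), n_steps, n_series))
  }
  m <- 2^ceiling(log2(max(2 * n_steps, 8)))
  g <- fgn_autocov(0:(m / 2), H, var1)
  circ <- c(g, rev(g[2:(m / 2)]))
  ev <- Re(stats::fft(circ))
  if (min(ev) < -1e-8 * max(ev)) return(fgn_sample_chol(n_steps, n_series, H, var1))
  ev[ev < 0] <- 0
  half <- m / 2
  ## spectral synthesis with conjugate-symmetric complex normals
  Z <- matrix(0 + 0i, m, n_series)
  Z[1, ] <- sqrt(ev[1]) * stats::rnorm(n_series)
  Z[half + 1, ] <- sqrt(ev[half + 1]) * stats::rnorm(n_series)
  if (half > 1) {
    idx <- 2:half
    U <- matrix(stats::rnorm((half - 1) * n_series), half - 1, n_series)
    V <- matrix(stats::rnorm((half - 1) * n_series), half - 1, n_series)
    Zk <- sqrt(ev[idx] / 2) * (U + 1i * V)
    Z[idx, ] <- Zk
    Z[m + 2 - idx, ] <- Conj(Zk)
  }
  X <- Re(stats::mvfft(Z)) / sqrt(m)
  X[seq_len(n_steps), , drop = FALSE]
}

fgn_sample_chol <- function(n_steps, n_series, H, var1) {
  S <- stats::toeplitz(fgn_autocov(0:(n_steps - 1), H, var1))
  L <- t(chol(S + diag(1e-12 * var1, n_steps)))
  L %*% matrix(stats::rnorm(n_steps * n_series), n_steps, n_series)
}

## ---- ground truth container -----------------------------------------------

new_ground_truth <- function(trajectories, drift, motion, config) {
  structure(list(trajectories = trajectories, drift = drift, motion = motion,
                 config = config), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d trajectories x %d frames, motion: %s\n",
              length(x$trajectories), x$config$n_frames, x$motion$kind))
  invisible(x)
}

#' Observed positions of a ground truth set
#'
#' Intrinsic particle paths plus the whole-nucleus drift offset — what a
#' detector looking at the rendered movie would see.
#'
#' @param truth a `ground_truth` object.
#' @return list of n_frames x 2 matrices (nm).
#' @export
observed_positions <- function(truth) {
  lapply(truth$trajectories, function(p) p + truth$drift)
}

## uniform starts inside the central 80% of the field of view
random_starts <- function(n_traj, config) {
  h_nm <- config$image_shape[1] * config$pixel_size
  w_nm <- config$image_shape[2] * config$pixel_size
  cbind(stats::runif(n_traj, 0.1 * w_nm, 0.9 * w_nm),
        stats::runif(n_traj, 0.1 * h_nm, 0.9 * h_nm))
}

## ---- generators -----------------------------------------------------------

#' Simulate free Brownian trajectories
#'
#' Each axis increment is independent Gaussian with variance `2*D*dt`, so the
#' two-dimensional ensemble MSD is `4*D*t`.
#'
#' @param n_traj number of trajectories (>= 1).
#' @param config an [acquisition_config()].
#' @param D diffusion coefficient in um^2/s (>= 0).
#' @param seed RNG seed.
#' @return a `ground_truth` object; positions in nm.
#' @export
simulate_brownian <- function(n_traj, config = acquisition_config(), D = 0.01,
                              seed = NULL) {
  assert_scalar_num(n_traj, "n_traj", min = 1)
  assert_scalar_num(D, "D", min = 0)
  with_seed(seed, {
    n <- config$n_frames
    starts <- random_starts(n_traj, config)
    sd_nm <- .NM_PER_UM * sqrt(2 * D * config$dt)
    trajs <- lapply(seq_len(n_traj), function(i) {
      inc <- matrix(stats::rnorm(2 * (n - 1), sd = sd_nm), n - 1, 2)
      pos <- rbind(c(0, 0), apply(inc, 2, cumsum))
      sweep(pos, 2, starts[i, ], `+`)
    })
    new_ground_truth(trajs, drift_offsets(config$drift, n, config$dt),
                     motion_model("brownian", D = D), config)
  })
}

#' Simulate fractional Brownian motion trajectories
#'
#' Each axis is an exact fractional Brownian motion with Hurst exponent
#' `H = alpha/2` (circulant-embedding generation, Cholesky fallback), scaled
#' so the two-dimensional ensemble MSD is `4 * D_alpha * t^alpha`.
#'
#' @inheritParams simulate_brownian
#' @param D_alpha generalized coefficient in um^2/s^alpha.
#' @param alpha anomalous exponent in (0, 2]; `alpha = 1` is standard
#'   Brownian motion, `alpha < 1` subdiffusion.
#' @return a `ground_truth` object.
#' @export
simulate_fbm <- function(n_traj, config = acquisition_config(),
                         D_alpha = 0.01, alpha = 0.5, seed = NULL) {
  assert_scalar_num(n_traj, "n_traj", min = 1)
  assert_scalar_num(D_alpha, "D_alpha", min = 0)
  assert_scalar_num(alpha, "alpha", min = 0, max = 2, strict_min = TRUE)
  with_seed(seed, {
    n <- config$n_frames
    H <- alpha / 2
    ## per-axis Var X(t) = 2*D_alpha*t^alpha um^2  ->  one-step increment
    ## variance in nm^2:
    var1 <- 2 * D_alpha * config$dt^alpha * .NM2_PER_UM2
    inc <- fgn_sample(n - 1, 2 * n_traj, H, var1)  # columns: x1..xn, y1..yn
    starts <- random_starts(n_traj, config)
    trajs <- lapply(seq_len(n_traj), function(i) {
      pos <- rbind(c(0, 0),
                   cbind(cumsum(inc[, i]), cumsum(inc[, n_traj + i])))
      sweep(pos, 2, starts[i, ], `+`)
    })
    new_ground_truth(trajs, drift_offsets(config$drift, n, config$dt),
                     motion_model("fbm", D = D_alpha, alpha = alpha), config)
  })
}

#' Simulate confined + macroscopic trajectories
#'
#' Each particle is the sum of a stationary Ornstein-Uhlenbeck process per
#' axis (stationary variance `A/4` per axis, relaxation time `tau`, exact
#' discrete-time update) and an independent Brownian motion with coefficient
#' `D_macro`, so the two-dimensional ensemble MSD is exactly
#' `A*(1 - exp(-t/tau)) + 4*D_macro*t` from `t = 0`.
#'
#' @inheritParams simulate_brownian
#' @param A confinement plateau in um^2 (>= 0).
#' @param tau relaxation time in s (> 0).
#' @param D_macro macroscopic coefficient in um^2/s (>= 0).
#' @return a `ground_truth` object.
#' @export
simulate_confined <- function(n_traj, config = acquisition_config(),
                              A = 0.04, tau = 2, D_macro = 0, seed = NULL) {
  assert_scalar_num(n_traj, "n_traj", min = 1)
  assert_scalar_num(A, "A", min = 0)
  assert_scalar_num(tau, "tau", min = 0, strict_min = TRUE)
  assert_scalar_num(D_macro, "D_macro", min = 0)
  with_seed(seed, {
    n <- config$n_frames
    V <- A / 4 * .NM2_PER_UM2          # per-axis stationary variance, nm^2
    rho <- exp(-config$dt / tau)
    innov_sd <- sqrt(V * (1 - rho^2))
    bm_sd <- .NM_PER_UM * sqrt(2 * D_macro * config$dt)
    starts <- random_starts(n_traj, config)
    trajs <- lapply(seq_len(n_traj), function(i) {
      ou <- matrix(0, n, 2)
      ou[1, ] <- stats::rnorm(2, sd = sqrt(V))
      if (n > 1) {
        xi <- matrix(stats::rnorm(2 * (n - 1), sd = innov_sd), n - 1, 2)
        for (k in 2:n) ou[k, ] <- rho * ou[k - 1, ] + xi[k - 1, ]
      }
      bm <- rbind(c(0, 0),
                  apply(matrix(stats::rnorm(2 * (n - 1), sd = bm_sd),
                               n - 1, 2), 2, cumsum))
      sweep(ou + bm, 2, starts[i, ], `+`)
    })
    new_ground_truth(trajs, drift_offsets(config$drift, n, config$dt),
                     motion_model("confined", D = D_macro, A = A, tau = tau,
                                  D_macro = D_macro), config)
  })
}

#' Closed-form ensemble MSD of a motion model
#'
#' @param motion a [motion_model()].
#' @param t time lags in s.
#' @return MSD values in um^2.
#' @export
model_msd <- function(motion, t) {
  switch(motion$kind,
    brownian = 4 * motion$D * t,
    fbm = 4 * motion$D * t^motion$alpha,
    confined = motion$A * (1 - exp(-t / motion$tau)) + 4 * motion$D_macro * t)
}

#' Write ground-truth trajectories to CSV
#'
#' Long format with columns traj_id, frame, x_nm, y_nm, z_nm (empty for 2D),
#' using observed (drift-included) positions.
#'
#' @param truth a `ground_truth` object.
#' @param path output file.
#' @export
write_truth_csv <- function(truth, path) {
  obs <- observed_positions(truth)
  n <- truth$config$n_frames
  df <- do.call(rbind, lapply(seq_along(obs), function(i) {
    data.frame(traj_id = i, frame = 0:(n - 1),
               x_nm = obs[[i]][, 1], y_nm = obs[[i]][, 2], z_nm = NA_real_)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
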
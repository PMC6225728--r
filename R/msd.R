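#' Time-averaged mean squared displacement of one trajectory
#'
#' For lag `n` frames, averages the squared 2D displacement over all pairs
#' of present frames exactly `n` frames apart (gaps allowed; nothing is
#' interpolated).  Mode "standard" divides by the number of available
#' pairs.  Mode "literal" reproduces the published normalization
#' `1/(N-1-n) * sum_{i=1}^{N-1-n}`, which omits the final available pair:
#' the last pair is dropped and the sum divided by (pairs - 1).  For
#' gap-free trajectories this is exactly the printed estimator; the two
#' modes converge as N grows.
#'
#' @param traj a [trajectory()].
#' @param max_lag_frames largest lag in frames (< N); default `N - 1`.
#' @param mode "standard" or "literal".
#' @return an `msd_curve`: data.frame with columns lag_s, msd_um2, n_pairs
#'   (lags with no pairs omitted) plus attributes dt and traj_id.
#' @export
compute_msd <- function(traj, max_lag_frames = NULL,
                        mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  m <- length(traj$frames)
  if (m < 2) stopf("trajectory %s has fewer than 2 present frames", traj$traj_id)
  N <- traj$n_total_frames
  max_lag_frames <- max_lag_frames %||% (N - 1L)
  if (max_lag_frames >= N) stopf("max_lag_frames must be < N = %d", N)
  f <- traj$frames
  pos <- traj$positions
  lag_f <- integer(0); msd <- numeric(0); np <- integer(0)
  for (n in seq_len(max_lag_frames)) {
    j <- match(f + n, f)
    i <- which(!is.na(j))
    if (length(i) == 0) next
    j <- j[i]
    sq <- (pos[j, 1] - pos[i, 1])^2 + (pos[j, 2] - pos[i, 2])^2
    if (mode == "literal") {
      if (length(sq) < 2) next
      sq <- sq[-length(sq)]
    }
    lag_f <- c(lag_f, n); msd <- c(msd, mean(sq)); np <- c(np, length(sq))
  }
  new_msd_curve(lag_f, msd / .NM2_PER_UM2, np, traj$dt, traj$traj_id)
}

new_msd_curve <- function(lag_frames, msd_um2, n_pairs, dt, traj_id) {
  structure(data.frame(lag_s = lag_frames * dt, msd_um2 = msd_um2,
                       n_pairs = n_pairs),
            dt = dt, traj_id = traj_id, lag_frames = lag_frames,
            class = c("msd_curve", "data.frame"))
}

#' Ensemble mean MSD across trajectories
#'
#' Per lag: unweighted mean over trajectories reporting that lag, with the
#' standard error computed across trajectories (sample SD / sqrt(count)).
#' Lags reported by fewer than 2 trajectories are omitted.
#'
#' @param curves list of `msd_curve` objects sharing the same dt.
#' @return data.frame with lag_s, msd_um2, se_um2, n_traj; class
#'   `msd_curve` with traj_id "ensemble".
#' @export
ensemble_msd <- function(curves) {
  if (length(curves) < 2) stopf("need at least 2 MSD curves")
  dts <- vapply(curves, function(cv) attr(cv, "dt"), numeric(1))
  if (max(dts) - min(dts) > 1e-12 * max(dts))
    stopf("curves have mixed frame intervals")
  dt <- dts[1]
  lagf <- lapply(curves, function(cv) attr(cv, "lag_frames"))
  all_lags <- sort(unique(unlist(lagf)))
  rows <- lapply(all_lags, function(n) {
    vals <- unlist(lapply(seq_along(curves), function(i) {
      k <- match(n, lagf[[i]])
      if (is.na(k)) NULL else curves[[i]]$msd_um2[k]
    }))
    if (length(vals) < 2) return(NULL)
    data.frame(lag_frames = n, msd_um2 = mean(vals),
               se_um2 = stats::sd(vals) / sqrt(length(vals)),
               n_traj = length(vals))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stopf("no lag is reported by 2 or more trajectories")
  out <- new_msd_curve(rows$lag_frames, rows$msd_um2, rows$n_traj, dt,
                       "ensemble")
  out$se_um2 <- rows$se_um2
  out$n_traj <- rows$n_traj
  out
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve %s> %d lags, dt=%gs, MSD(dt)=%.4g um^2\n",
              attr(x, "traj_id"), nrow(x), attr(x, "dt"),
              if (nrow(x)) x$msd_um2[1] else NA))
  invisible(x)
}
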
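mk_spots <- function(frames, xy, nucleus = 0L) {
  data.frame(nucleus_id = nucleus, frame = frames, x_nm = xy[, 1],
             y_nm = xy[, 2])
}

test_that("two well-separated slow spots link into 2 full trajectories", {
  px <- 66.3
  f <- rep(0:9, each = 2)
  xy <- do.call(rbind, lapply(0:9, function(k)
    rbind(c(0, 0), c(10 * px, 0)) + k * c(px, 0)))
  trajs <- link_spots(mk_spots(f, xy), linking_params(),
                      n_total_frames = 10, dt = 0.25)
  expect_length(trajs, 2)
  expect_true(all(vapply(trajs, function(tr)
    identical(tr$frames, 0:9), logical(1))))
})

test_that("a jump beyond the link radius splits the trajectory when gaps are disallowed", {
  px <- 66.3
  x <- c(0, 1, 2, 3, 4, 5, 9, 10, 11, 12) * px   # 4 px jump frames 5 -> 6
  trajs <- link_spots(mk_spots(0:9, cbind(x, 0)),
                      linking_params(max_gap_frames = 0L),
                      n_total_frames = 10, dt = 0.25)
  expect_length(trajs, 2)
  expect_identical(trajs[[1]]$frames, 0:5)
  expect_identical(trajs[[2]]$frames, 6:9)
})

test_that("gap closing reconnects across missed frames within the capped radius", {
  px <- 66.3
  f <- c(0, 1, 2, 4, 5)                          # frame 3 missing
  x <- c(0, 1, 2, 4, 5) * px
  trajs <- link_spots(mk_spots(f, cbind(x, 0)), linking_params(),
                      n_total_frames = 6, dt = 0.25)
  expect_length(trajs, 1)
  expect_identical(trajs[[1]]$frames, c(0L, 1L, 2L, 4L, 5L))
})

test_that("duplicate spots are deduplicated with a warning; empty input returns empty", {
  sp <- mk_spots(c(0, 0, 1), rbind(c(0, 0), c(0, 0), c(10, 0)))
  expect_warning(trajs <- link_spots(sp, linking_params(),
                                     n_total_frames = 2), "duplicate")
  expect_length(trajs, 1)
  empty <- data.frame(nucleus_id = integer(0), frame = integer(0),
                      x_nm = numeric(0), y_nm = numeric(0))
  expect_identical(link_spots(empty), list())
})

test_that("linking partitions the input spots", {
  set.seed(20)
  n <- 30
  sp <- do.call(rbind, lapply(0:19, function(f)
    mk_spots(rep(f, n), matrix(runif(2 * n, 0, 20000), n, 2))))
  trajs <- link_spots(sp, linking_params(), n_total_frames = 20)
  total <- sum(vapply(trajs, function(tr) length(tr$frames), integer(1)))
  expect_identical(total, nrow(sp))
  key <- unlist(lapply(trajs, function(tr)
    paste(tr$frames, tr$positions[, 1], tr$positions[, 2])))
  expect_identical(sort(key), sort(paste(sp$frame, sp$x_nm, sp$y_nm)))
})

test_that("linking is invariant to spot order within a frame", {
  set.seed(21)
  sp <- do.call(rbind, lapply(0:9, function(f)
    mk_spots(rep(f, 5), matrix(runif(10, 0, 5000), 5, 2) +
                          f * 30)))
  t1 <- link_spots(sp, linking_params(), n_total_frames = 10)
  sp_shuf <- do.call(rbind, lapply(split(sp, sp$frame), function(g)
    g[sample(nrow(g)), , drop = FALSE]))
  t2 <- link_spots(sp_shuf, linking_params(), n_total_frames = 10)
  sig <- function(tr) paste(tr$frames, round(tr$positions[, 1], 9),
                            round(tr$positions[, 2], 9), collapse = ";")
  expect_setequal(vapply(t1, sig, character(1)),
                  vapply(t2, sig, character(1)))
})

test_that("half-loss boundary: 240/480 present kept, 239 discarded; small nuclei dropped", {
  mk <- function(id, n_present, nucleus = 0L)
    trajectory(id, nucleus, seq_len(n_present) - 1,
               matrix(0, n_present, 2), 480L, 0.25)
  kept <- filter_trajectories(c(lapply(1:5, mk, n_present = 240),
                                list(mk(6, 239))), linking_params())
  expect_length(kept, 5)
  expect_false(6 %in% vapply(kept, `[[`, numeric(1), "traj_id"))
  ## nucleus with only 4 survivors loses all of them
  two_nuc <- c(lapply(1:4, mk, n_present = 480, nucleus = 1L),
               lapply(5:10, mk, n_present = 480, nucleus = 2L))
  kept2 <- filter_trajectories(two_nuc, linking_params())
  expect_identical(vapply(kept2, `[[`, integer(1), "nucleus_id"),
                   rep(2L, 6))
  ## full-length 6-foci nucleus: all kept, order preserved, idempotent
  full <- lapply(1:6, mk, n_present = 480)
  kept3 <- filter_trajectories(full, linking_params())
  expect_identical(vapply(kept3, `[[`, numeric(1), "traj_id"), as.numeric(1:6))
  expect_identical(filter_trajectories(kept3, linking_params()), kept3)
})

test_that("constant-velocity drift is removed exactly from static spots", {
  acq <- acquisition_config(n_frames = 50, drift = drift_linear(5, -3))
  truth <- simulate_brownian(6, acq, D = 0, seed = 22)
  corrected <- drift_correct(truth_to_trajectories(truth))
  for (tr in corrected) {
    span <- apply(tr$positions, 2, function(v) max(v) - min(v))
    expect_lt(max(span), 1e-9)
  }
})

test_that("drift correction is a no-op without drift and idempotent on full-length sets", {
  acq <- acquisition_config(n_frames = 30)
  truth <- simulate_brownian(5, acq, D = 0.01, seed = 23)
  trajs <- truth_to_trajectories(truth)
  once <- drift_correct(trajs)
  twice <- drift_correct(once)
  for (i in seq_along(trajs)) {
    ## without drift the centroid still moves (finite sample), so correction
    ## subtracts it; applying twice must change nothing further
    expect_equal(twice[[i]]$positions, once[[i]]$positions, tolerance = 1e-12)
  }
  ## static spots without drift: exact identity
  truth0 <- simulate_brownian(5, acq, D = 0, seed = 24)
  t0 <- truth_to_trajectories(truth0)
  c0 <- drift_correct(t0)
  for (i in seq_along(t0))
    expect_equal(c0[[i]]$positions, t0[[i]]$positions)
})

test_that("drift + fBm: correction restores the no-drift exponent", {
  n <- 150
  acq_d <- acquisition_config(n_frames = 200, drift = drift_linear(8, 0))
  acq_0 <- acquisition_config(n_frames = 200)
  mean_alpha <- function(trajs) {
    a <- vapply(trajs, function(tr)
      fit_anomalous(compute_msd(tr, max_lag_frames = 100))$alpha, numeric(1))
    mean(a)
  }
  truth_d <- simulate_fbm(n, acq_d, D_alpha = 0.01, alpha = 0.5, seed = 25)
  truth_0 <- simulate_fbm(n, acq_0, D_alpha = 0.01, alpha = 0.5, seed = 25)
  a_nodrift <- mean_alpha(truth_to_trajectories(truth_0))
  a_corrected <- mean_alpha(drift_correct(truth_to_trajectories(truth_d)))
  a_raw <- mean_alpha(truth_to_trajectories(truth_d))
  expect_lt(abs(a_corrected - a_nodrift), 0.05)
  expect_gt(a_raw, a_nodrift + 0.05)   # uncorrected drift biases alpha up
})
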
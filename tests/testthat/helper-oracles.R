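## Independent oracles used across the suite.  These deliberately use the
## slowest, most transparent formulation available and never call the code
## paths they check.

## O(N^2) brute-force time-averaged MSD over all present-frame pairs.
brute_msd <- function(frames, positions, dt, max_lag, mode = "standard") {
  out <- data.frame(lag_s = numeric(0), msd_um2 = numeric(0),
                    n_pairs = integer(0))
  for (n in seq_len(max_lag)) {
    sq <- c()
    for (i in seq_along(frames)) for (j in seq_along(frames)) {
      if (frames[j] - frames[i] == n) {
        sq <- c(sq, sum((positions[j, ] - positions[i, ])^2))
      }
    }
    if (mode == "literal") {
      if (length(sq) < 2) next
      sq <- sq[-length(sq)]
    }
    if (length(sq) == 0) next
    out <- rbind(out, data.frame(lag_s = n * dt, msd_um2 = mean(sq) / 1e6,
                                 n_pairs = length(sq)))
  }
  out
}

## Union-find single-linkage clustering over all pairwise distances.
uf_clusters <- function(pos, threshold) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sqrt(sum((pos[i, ] - pos[j, ])^2)) <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots))
}

## random gapped trajectory for oracle comparisons
random_gapped_traj <- function(id, N = 60, keep_prob = 0.7, dt = 0.25) {
  frames <- sort(sample(0:(N - 1), max(2, rbinom(1, N, keep_prob))))
  trajectory(id, 0L, frames,
             matrix(rnorm(2 * length(frames), sd = 100), ncol = 2), N, dt)
}

## noiseless image with Gaussian spots at 0-based (x, y) positions
spot_image <- function(h, w, xy, amp = 100, sigma = 1.3, background = 0) {
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
  rr <- matrix(0:(h - 1), h, w)
  img <- matrix(background, h, w)
  for (k in seq_len(nrow(xy)))
    img <- img + amp * exp(-((cc - xy[k, 1])^2 + (rr - xy[k, 2])^2) /
                             (2 * sigma^2))
  img
}

## closed-form MSD curve as an msd_curve object (for fit tests)
model_curve <- function(motion, lags_frames, dt = 0.25) {
  t <- lags_frames * dt
  telodyn:::new_msd_curve(lags_frames, model_msd(motion, t),
                          rep(1000L, length(lags_frames)), dt, "model")
}
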
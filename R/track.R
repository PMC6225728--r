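#' Trajectory container
#'
#' Time-ordered positions of one locus, possibly with gaps (absent frames
#' are simply missing from `frames`; nothing is interpolated).
#'
#' @param traj_id integer id.
#' @param nucleus_id nucleus label.
#' @param frames 0-based frame indices, strictly increasing.
#' @param positions length(frames) x 2 matrix of (x, y) in nm.
#' @param n_total_frames movie length N.
#' @param dt frame interval in s.
#' @return a `trajectory` object.
#' @export
trajectory <- function(traj_id, nucleus_id, frames, positions,
                       n_total_frames, dt) {
  frames <- as.integer(frames)
  positions <- matrix(as.numeric(positions), length(frames), 2)
  if (length(frames) > 1 && any(diff(frames) <= 0))
    stopf("'frames' must be strictly increasing")
  structure(list(traj_id = traj_id, nucleus_id = nucleus_id, frames = frames,
                 positions = positions, n_total_frames = as.integer(n_total_frames),
                 dt = dt), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s> nucleus %s: %d/%d frames present\n",
              x$traj_id, x$nucleus_id, length(x$frames), x$n_total_frames))
  invisible(x)
}

#' Convert a ground-truth set to trajectories
#'
#' Bypasses rendering/detection: the observed (drift-included) positions
#' become gap-free trajectories, as if detection were perfect.
#'
#' @param truth a `ground_truth` object.
#' @param nucleus_id nucleus label for all trajectories.
#' @return list of `trajectory`.
#' @export
truth_to_trajectories <- function(truth, nucleus_id = 0L) {
  obs <- observed_positions(truth)
  n <- truth$config$n_frames
  lapply(seq_along(obs), function(i)
    trajectory(i, nucleus_id, 0:(n - 1), obs[[i]], n, truth$config$dt))
}

#' Linking parameters
#'
#' Defaults follow the published tracking recipe: link radius three pixels
#' (198.9 nm at 66.3 nm/px), discard trajectories that lost more than half
#' of the movie's frames, and keep only nuclei retaining at least 5 foci.
#'
#' @param max_link_dist maximum frame-to-frame link distance in nm.
#' @param max_gap_frames how many frames a trajectory may remain unmatched
#'   before it is closed; the link radius grows by `max_link_dist` per
#'   elapsed frame, capped at `2 * max_link_dist`.
#' @param min_present_fraction minimum fraction of movie frames a trajectory
#'   must cover (present in exactly half = kept).
#' @param min_foci_per_cell minimum surviving trajectories per nucleus.
#' @return a `linking_params` object.
#' @export
linking_params <- function(max_link_dist = 198.9, max_gap_frames = 5L,
                           min_present_fraction = 0.5,
                           min_foci_per_cell = 5L) {
  assert_scalar_num(max_link_dist, "max_link_dist", min = 0, strict_min = TRUE)
  assert_scalar_num(min_present_fraction, "min_present_fraction", 0, 1)
  structure(list(max_link_dist = max_link_dist,
                 max_gap_frames = as.integer(max_gap_frames),
                 min_present_fraction = min_present_fraction,
                 min_foci_per_cell = as.integer(min_foci_per_cell)),
            class = "linking_params")
}

#' Link per-frame detections into trajectories
#'
#' Frame-by-frame global greedy assignment: all (open trajectory, new spot)
#' pairs within the link radius are accepted in ascending distance order,
#' each trajectory and each spot used at most once.  Distance ties break
#' deterministically by lower trajectory id, then lower spot index.
#' Unmatched trajectories stay open for up to `max_gap_frames` frames
#' (radius growing with the gap, capped at twice the base radius), then
#' close; unmatched spots seed new trajectories.  Gap frames stay absent.
#'
#' @param spots data.frame with columns frame, x_nm, y_nm and optionally
#'   nucleus_id (linking is per nucleus).
#' @param params a [linking_params()].
#' @param n_total_frames movie length N; defaults to `max(frame) + 1`.
#' @param dt frame interval in s.
#' @return list of [trajectory()] objects (singletons included: the output
#'   partitions the input spots).
#' @export
link_spots <- function(spots, params = linking_params(),
                       n_total_frames = NULL, dt = 0.25) {
  if (nrow(spots) == 0) return(list())
  if (is.null(spots$nucleus_id)) spots$nucleus_id <- 0L
  key <- paste(spots$nucleus_id, spots$frame, spots$x_nm, spots$y_nm)
  if (anyDuplicated(key)) {
    warnf("removing %d duplicate (frame, position) spots", sum(duplicated(key)))
    spots <- spots[!duplicated(key), , drop = FALSE]
  }
  N <- n_total_frames %||% (max(spots$frame) + 1L)
  out <- list()
  for (nuc in unique(spots$nucleus_id)) {
    sp <- spots[spots$nucleus_id == nuc, , drop = FALSE]
    sp <- sp[order(sp$frame), , drop = FALSE]
    ## open trajectories: list(frames, pos, last_frame)
    open <- list(); closed <- list()
    next_id <- 1L
    for (f in sort(unique(sp$frame))) {
      cur <- sp[sp$frame == f, , drop = FALSE]
      pts <- cbind(cur$x_nm, cur$y_nm)
      n_open <- length(open); n_new <- nrow(cur)
      cand <- NULL
      if (n_open > 0 && n_new > 0) {
        last_pos <- t(vapply(open, function(o) o$pos[nrow(o$pos), ],
                             numeric(2)))
        elapsed <- f - vapply(open, function(o) o$last_frame, numeric(1))
        radius <- pmin(elapsed * params$max_link_dist,
                       2 * params$max_link_dist)
        d <- sqrt(outer(last_pos[, 1], pts[, 1], `-`)^2 +
                  outer(last_pos[, 2], pts[, 2], `-`)^2)
        ok <- which(d <= radius, arr.ind = TRUE)   # radius recycles by row
        if (nrow(ok) > 0) {
          ids <- vapply(open, function(o) o$traj_id, numeric(1))
          cand <- data.frame(ti = ok[, 1], si = ok[, 2], d = d[ok],
                             id = ids[ok[, 1]])
          cand <- cand[order(cand$d, cand$id, cand$si), , drop = FALSE]
        }
      }
      used_t <- logical(n_open); used_s <- logical(n_new)
      if (!is.null(cand)) for (k in seq_len(nrow(cand))) {
        ti <- cand$ti[k]; si <- cand$si[k]
        if (used_t[ti] || used_s[si]) next
        used_t[ti] <- TRUE; used_s[si] <- TRUE
        open[[ti]]$frames <- c(open[[ti]]$frames, f)
        open[[ti]]$pos <- rbind(open[[ti]]$pos, pts[si, ])
        open[[ti]]$last_frame <- f
      }
      for (si in which(!used_s)) {
        open[[length(open) + 1L]] <- list(traj_id = next_id, frames = f,
                                          pos = pts[si, , drop = FALSE],
                                          last_frame = f)
        next_id <- next_id + 1L
      }
      ## close trajectories that exceeded the allowed gap
      still <- vapply(open, function(o) f - o$last_frame <= params$max_gap_frames,
                      logical(1))
      closed <- c(closed, open[!still])
      open <- open[still]
    }
    closed <- c(closed, open)
    ids <- order(vapply(closed, function(o) o$traj_id, numeric(1)))
    for (o in closed[ids])
      out[[length(out) + 1L]] <- trajectory(o$traj_id, nuc, o$frames, o$pos,
                                            N, dt)
  }
  out
}

#' Apply the trajectory-loss and cell filters
#'
#' Keeps a trajectory iff it is present in at least
#' `ceil(N * min_present_fraction)` frames (exactly half present is kept;
#' losing more than half discards), then drops every trajectory of any
#' nucleus whose surviving count is below `min_foci_per_cell`.  Idempotent.
#'
#' @param trajectories list of [trajectory()].
#' @param params a [linking_params()].
#' @return filtered list, input order preserved.
#' @export
filter_trajectories <- function(trajectories, params = linking_params()) {
  if (length(trajectories) == 0) return(list())
  keep <- vapply(trajectories, function(tr)
    length(tr$frames) >= ceiling(tr$n_total_frames * params$min_present_fraction),
    logical(1))
  kept <- trajectories[keep]
  if (length(kept) == 0) return(list())
  nuc <- vapply(kept, function(tr) as.character(tr$nucleus_id), character(1))
  counts <- table(nuc)
  good <- names(counts)[counts >= params$min_foci_per_cell]
  kept[nuc %in% good]
}

#' Remove whole-nucleus drift from trajectories
#'
#' Per nucleus and frame, the cell center is the unweighted centroid of all
#' spot positions present in that frame; each position is corrected by
#' subtracting the center displacement relative to the first frame where
#' the nucleus has any spot.  Frames with no spots get a linearly
#' interpolated center (reported via a message).  Absent frames stay absent.
#'
#' @param trajectories list of [trajectory()].
#' @return list of corrected trajectories, same order.
#' @export
drift_correct <- function(trajectories) {
  if (length(trajectories) == 0) return(list())
  nuc <- vapply(trajectories, function(tr) as.character(tr$nucleus_id),
                character(1))
  out <- trajectories
  for (id in unique(nuc)) {
    sel <- which(nuc == id)
    N <- trajectories[[sel[1]]]$n_total_frames
    sx <- numeric(N); sy <- numeric(N); cnt <- integer(N)
    for (i in sel) {
      tr <- trajectories[[i]]
      fi <- tr$frames + 1L
      sx[fi] <- sx[fi] + tr$positions[, 1]
      sy[fi] <- sy[fi] + tr$positions[, 2]
      cnt[fi] <- cnt[fi] + 1L
    }
    cx <- ifelse(cnt > 0, sx / pmax(cnt, 1L), NA_real_)
    cy <- ifelse(cnt > 0, sy / pmax(cnt, 1L), NA_real_)
    if (anyNA(cx)) {
      message(sprintf("nucleus %s: interpolating cell center over %d empty frame(s)",
                      id, sum(is.na(cx))))
      ok <- which(!is.na(cx))
      cx <- stats::approx(ok, cx[ok], xout = seq_len(N), rule = 2)$y
      cy <- stats::approx(ok, cy[ok], xout = seq_len(N), rule = 2)$y
    }
    ref <- which(cnt > 0)[1]
    for (i in sel) {
      tr <- trajectories[[i]]
      fi <- tr$frames + 1L
      tr$positions[, 1] <- tr$positions[, 1] - (cx[fi] - cx[ref])
      tr$positions[, 2] <- tr$positions[, 2] - (cy[fi] - cy[ref])
      out[[i]] <- tr
    }
  }
  out
}

#' Trajectories to/from long-format data frames
#'
#' @param trajectories list of [trajectory()].
#' @return data.frame with traj_id, nucleus_id, frame, x_nm, y_nm.
#' @export
trajectories_to_df <- function(trajectories) {
  do.call(rbind, lapply(trajectories, function(tr)
    data.frame(traj_id = tr$traj_id, nucleus_id = tr$nucleus_id,
               frame = tr$frames, x_nm = tr$positions[, 1],
               y_nm = tr$positions[, 2])))
}

#' @rdname trajectories_to_df
#' @param df long-format data.frame as produced by [trajectories_to_df()].
#' @param n_total_frames movie length N.
#' @param dt frame interval (s).
#' @export
df_to_trajectories <- function(df, n_total_frames, dt = 0.25) {
  ids <- unique(df[, c("traj_id", "nucleus_id")])
  lapply(seq_len(nrow(ids)), function(i) {
    sel <- df$traj_id == ids$traj_id[i] & df$nucleus_id == ids$nucleus_id[i]
    sub <- df[sel, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    trajectory(ids$traj_id[i], ids$nucleus_id[i], sub$frame,
               cbind(sub$x_nm, sub$y_nm), n_total_frames, dt)
  })
}
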
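#' Simulate a two-channel 3D nucleus foci set
#'
#' Places foci uniformly in a sphere of radius `nucleus_radius`, optionally
#' planting clusters (pairs/triples of channel-A foci at a stated spacing)
#' and a stated fraction of channel-B foci within a stated offset of
#' channel-A foci.  Truth labels for clusters and colocalization are
#' returned so downstream aggregation/colocalization can be audited.
#'
#' @param n_foci channel-A foci count (>= 0).
#' @param nucleus_radius sphere radius in nm.
#' @param aggregate_spec `list(pairs =, triples =, distance =)`: number of
#'   planted pairs and triples and the spot-to-spot spacing in nm.  Planted
#'   cluster members count toward `n_foci`.
#' @param coloc_spec `list(fraction =, offset =)`: fraction of channel-B foci
#'   placed at `offset` nm (random direction) from distinct channel-A foci;
#'   remaining B foci are uniform.  `NULL` for a single-channel set.
#' @param n_foci_b channel-B foci count (defaults to `n_foci`).
#' @param seed RNG seed.
#' @return list with `channel_a`, `channel_b` (each a `nucleus_foci` object
#'   or NULL) and `truth` (`cluster_id` per A focus; `coloc` flag per B focus).
#' @export
make_nucleus_foci <- function(n_foci, nucleus_radius = 4000,
                              aggregate_spec = NULL, coloc_spec = NULL,
                              n_foci_b = n_foci, seed = NULL) {
  assert_scalar_num(n_foci, "n_foci", min = 0)
  with_seed(seed, {
    n_pairs <- aggregate_spec$pairs %||% 0L
    n_trip <- aggregate_spec$triples %||% 0L
    planted <- 2L * n_pairs + 3L * n_trip
    if (planted > n_foci)
      stopf("aggregate_spec plants %d foci but n_foci is only %d", planted, n_foci)

    unif_sphere <- function(k, r) {
      if (k == 0) return(matrix(numeric(0), 0, 3))
      v <- matrix(stats::rnorm(3 * k), k, 3)
      v <- v / sqrt(rowSums(v^2))
      v * r * stats::runif(k)^(1 / 3)
    }
    rand_dir <- function(k) {
      v <- matrix(stats::rnorm(3 * k), k, 3)
      v / sqrt(rowSums(v^2))
    }

    pos <- matrix(numeric(0), 0, 3)
    cluster_id <- integer(0)
    cl <- 0L
    d <- aggregate_spec$distance %||% 0
    ## anchors well inside the sphere so planted partners stay in the nucleus
    for (i in seq_len(n_pairs)) {
      cl <- cl + 1L
      anchor <- unif_sphere(1, max(nucleus_radius - d, 0))
      pos <- rbind(pos, anchor, anchor + rand_dir(1) * d)
      cluster_id <- c(cluster_id, cl, cl)
    }
    for (i in seq_len(n_trip)) {
      cl <- cl + 1L
      anchor <- unif_sphere(1, max(nucleus_radius - 2 * d, 0))
      b <- anchor + rand_dir(1) * d
      pos <- rbind(pos, anchor, b, b + rand_dir(1) * d)
      cluster_id <- c(cluster_id, cl, cl, cl)
    }
    n_free <- n_foci - planted
    pos <- rbind(pos, unif_sphere(n_free, nucleus_radius))
    cluster_id <- c(cluster_id, rep(0L, n_free))

    channel_a <- nucleus_foci(nucleus_id = 0L, channel = "A", positions = pos,
                              intensities = rep(1, nrow(pos)))
    channel_b <- NULL
    coloc_flag <- logical(0)
    if (!is.null(coloc_spec)) {
      frac <- coloc_spec$fraction %||% 0
      off <- coloc_spec$offset %||% 0
      n_co <- round(frac * n_foci_b)
      if (n_co > n_foci) stopf("coloc_spec needs %d A foci but only %d exist",
                               n_co, n_foci)
      hosts <- if (n_co > 0) sample.int(n_foci, n_co) else integer(0)
      pos_b <- rbind(
        if (n_co > 0) pos[hosts, , drop = FALSE] + rand_dir(n_co) * off,
        unif_sphere(n_foci_b - n_co, nucleus_radius))
      coloc_flag <- c(rep(TRUE, n_co), rep(FALSE, n_foci_b - n_co))
      channel_b <- nucleus_foci(nucleus_id = 0L, channel = "B",
                                positions = pos_b,
                                intensities = rep(1, nrow(pos_b)))
    }
    list(channel_a = channel_a, channel_b = channel_b,
         truth = list(cluster_id = cluster_id, coloc = coloc_flag))
  })
}

#' 3D foci set of one nucleus
#'
#' @param nucleus_id integer label.
#' @param channel channel name ("A" or "B").
#' @param positions n x 3 matrix of (x, y, z) in nm.
#' @param intensities per-focus intensity.
#' @param spot_diameter estimated spot diameter in nm, if known.
#' @return a `nucleus_foci` object.
#' @export
nucleus_foci <- function(nucleus_id, channel = "A", positions,
                         intensities = NULL, spot_diameter = NA_real_) {
  positions <- as.matrix(positions)
  if (nrow(positions) > 0 && ncol(positions) != 3L)
    stopf("'positions' must be an n x 3 matrix of nm coordinates")
  structure(list(nucleus_id = nucleus_id, channel = channel,
                 positions = positions,
                 intensities = intensities %||% rep(NA_real_, nrow(positions)),
                 spot_diameter = spot_diameter),
            class = "nucleus_foci")
}

#' @export
print.nucleus_foci <- function(x, ...) {
  cat(sprintf("<nucleus_foci> nucleus %s channel %s: %d foci\n",
              x$nucleus_id, x$channel, nrow(x$positions)))
  invisible(x)
}
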
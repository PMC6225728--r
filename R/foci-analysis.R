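#' Count telomere aggregations in one nucleus
#'
#' An aggregation is at least two foci clustering together with a maximum
#' spot-to-spot distance of half a spot diameter, in 3D physical
#' coordinates.  "Clustering together" is read as single linkage: clusters
#' are the connected components of the graph joining every pair at
#' distance <= `spot_diameter/2` (the boundary is inclusive).  A
#' complete-linkage alternative (every within-cluster pair within the
#' cutoff) is available via `linkage`.
#'
#' @param foci a [nucleus_foci()] or an n x 3 matrix of nm positions.
#' @param spot_diameter telomere spot diameter in nm (> 0).
#' @param linkage "single" or "complete".
#' @return an `aggregation_result`: nucleus_id, n_foci, n_aggregates
#'   (clusters of size >= 2), cluster_sizes (for those clusters),
#'   threshold_nm.
#' @export
count_aggregations <- function(foci, spot_diameter,
                               linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  assert_scalar_num(spot_diameter, "spot_diameter", min = 0, strict_min = TRUE)
  nucleus_id <- 0L
  if (inherits(foci, "nucleus_foci")) {
    nucleus_id <- foci$nucleus_id
    foci <- foci$positions
  }
  foci <- as.matrix(foci)
  thr <- spot_diameter / 2
  n <- nrow(foci)
  if (n < 2) {
    return(structure(list(nucleus_id = nucleus_id, n_foci = n,
                          n_aggregates = 0L, cluster_sizes = integer(0),
                          threshold_nm = thr), class = "aggregation_result"))
  }
  memb <- if (linkage == "single") {
    dd <- as.matrix(stats::dist(foci))
    adj <- dd <= thr
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::components(g)$membership
  } else {
    hc <- stats::hclust(stats::dist(foci), method = "complete")
    stats::cutree(hc, h = thr)
  }
  sizes <- as.integer(table(memb))
  agg <- sizes[sizes >= 2]
  structure(list(nucleus_id = nucleus_id, n_foci = n,
                 n_aggregates = length(agg),
                 cluster_sizes = sort(agg, decreasing = TRUE),
                 threshold_nm = thr), class = "aggregation_result")
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat(sprintf("<aggregation_result> nucleus %s: %d foci, %d aggregate(s) at <= %.1f nm\n",
              x$nucleus_id, x$n_foci, x$n_aggregates, x$threshold_nm))
  invisible(x)
}

#' Two-channel colocalization of nuclear foci
#'
#' One-to-one greedy matching in ascending distance order: (A, B) pairs are
#' accepted while their 3D distance is within `threshold`, each focus used
#' at most once (a single B focus can never serve several A foci).  The
#' colocalized fraction is matched A foci over all A foci.
#'
#' @param foci_a,foci_b [nucleus_foci()] objects or n x 3 nm matrices in
#'   the same coordinate frame.
#' @param threshold centroid distance cutoff in nm.
#' @return a `coloc_result`: nucleus_id, n_a, n_b, n_coloc, fraction
#'   (NA when channel A is empty), threshold_nm.
#' @export
colocalize <- function(foci_a, foci_b, threshold) {
  assert_scalar_num(threshold, "threshold", min = 0)
  nucleus_id <- 0L
  if (inherits(foci_a, "nucleus_foci")) {
    nucleus_id <- foci_a$nucleus_id
    foci_a <- foci_a$positions
  }
  if (inherits(foci_b, "nucleus_foci")) foci_b <- foci_b$positions
  A <- as.matrix(foci_a); B <- as.matrix(foci_b)
  na <- nrow(A); nb <- nrow(B)
  n_coloc <- 0L
  if (na > 0 && nb > 0) {
    d <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B), 0))
    cand <- which(d <= threshold, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(d[cand], cand[, 1], cand[, 2])
      used_a <- logical(na); used_b <- logical(nb)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used_a[i] || used_b[j]) next
        used_a[i] <- TRUE; used_b[j] <- TRUE
        n_coloc <- n_coloc + 1L
      }
    }
  }
  structure(list(nucleus_id = nucleus_id, n_a = na, n_b = nb,
                 n_coloc = n_coloc,
                 fraction = if (na > 0) n_coloc / na else NA_real_,
                 threshold_nm = threshold), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> nucleus %s: %d/%d A foci colocalized (%.1f%%) at <= %.0f nm\n",
              x$nucleus_id, x$n_coloc, x$n_a, 100 * x$fraction, x$threshold_nm))
  invisible(x)
}

#' Histogram of per-nucleus foci counts
#'
#' @param counts integer vector of foci counts, one per nucleus, or a list
#'   of [nucleus_foci()].
#' @param breaks increasing bin edges; bins are left-closed,
#'   right-open, last bin closed.
#' @return integer vector of per-bin nucleus counts.
#' @export
foci_count_histogram <- function(counts, breaks) {
  if (is.list(counts) && !is.data.frame(counts))
    counts <- vapply(counts, function(f) nrow(f$positions), integer(1))
  h <- graphics::hist(counts, breaks = breaks, right = FALSE,
                      include.lowest = TRUE, plot = FALSE)
  h$counts
}
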
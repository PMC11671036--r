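#' DBSCAN on a precomputed distance matrix
#'
#' Standard DBSCAN semantics: a core point has at least `min_samples`
#' points (itself included) within distance `epsilon`; clusters are the
#' connected components of core points under epsilon-reachability, plus
#' border points attached to the first cluster that reaches them. The outer
#' loop visits points in index order, so label assignment is deterministic
#' and ties for border points resolve toward the lowest-index core point's
#' cluster — the same convention as scikit-learn's implementation.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal.
#' @param epsilon neighbourhood radius, `> 0`.
#' @param min_samples minimum neighbourhood size (self included) for a core
#'   point, `>= 1`.
#' @return integer label vector: cluster labels `0, 1, ...` in order of
#'   discovery; noise points labelled `-1`.
#' @export
dbscan_labels <- function(d, epsilon, min_samples) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort_argument("`d` must be a symmetric distance matrix")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    abort_argument("`epsilon` must be a single positive value")
  }
  if (!is_count(min_samples, min = 1L)) {
    abort_argument("`min_samples` must be an integer >= 1")
  }
  n <- nrow(d)
  nbhd <- lapply(seq_len(n), function(i) which(d[i, ] <= epsilon))
  core <- lengths(nbhd) >= min_samples
  labels <- rep(NA_integer_, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      for (k in nbhd[[j]]) {
        if (is.na(labels[k])) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels[is.na(labels)] <- -1L
  labels
}

#' Cluster an MSA's sequences with DBSCAN
#'
#' Non-query rows are one-hot encoded ([encode_onehot()]) and clustered by
#' Euclidean distance; the query is excluded from the distance computation
#' and prepended to every output cluster. The input is expected to be
#' gap-filtered already (see [filter_by_gap_fraction()]).
#'
#' @param msa a gap-filtered [msa] with at least one non-query row.
#' @param epsilon DBSCAN neighbourhood radius on the one-hot Euclidean
#'   scale (squared distance = 2 x Hamming distance over match columns).
#' @param min_samples DBSCAN core-point threshold; default 3.
#' @return list of `sequence_cluster` objects (fields `label`, `members`
#'   — an [msa] with the query as row 0 —, and `size`, the number of
#'   non-query members), ordered by descending size then ascending label.
#' @export
cluster_msa <- function(msa, epsilon, min_samples = 3L) {
  stopifnot(inherits(msa, "msa"))
  if (n_rows(msa) < 2L) abort_argument("msa has no non-query rows to cluster")
  enc <- encode_onehot(msa)[-1L, , drop = FALSE]
  d <- as.matrix(dist(enc))
  labels <- dbscan_labels(d, epsilon, min_samples)
  clusters_from_labels(msa, labels)
}

# Assemble sequence_cluster objects from non-query row labels.
clusters_from_labels <- function(msa, labels) {
  out <- lapply(sort(unique(labels[labels >= 0L])), function(lab) {
    idx <- which(labels == lab) + 1L
    structure(list(
      label = lab,
      members = msa(c(msa$ids[1L], msa$ids[idx]), c(msa$seqs[1L], msa$seqs[idx])),
      size = length(idx)
    ), class = "sequence_cluster")
  })
  sizes <- vapply(out, `[[`, integer(1), "size")
  labs <- vapply(out, `[[`, integer(1), "label")
  out[order(-sizes, labs)]
}

#' @export
print.sequence_cluster <- function(x, ...) {
  cat(sprintf("sequence_cluster %d: %d members (+query)\n", x$label, x$size))
  invisible(x)
}

#' Scan DBSCAN epsilon values over an MSA
#'
#' Clusters the MSA at every grid value (the one-hot encoding and distance
#' matrix are computed once) and reports cluster and noise counts.
#' `epsmax` is the epsilon yielding the maximum number of clusters, ties
#' broken toward the smaller value — the AFcluster default choice, which
#' epsilon tuning explores upward from.
#'
#' @param msa a gap-filtered [msa].
#' @param eps_grid numeric vector of positive epsilon values; default
#'   `seq(3, 25, by = 0.5)`.
#' @param min_samples DBSCAN core-point threshold; default 3.
#' @return list with `scan`, a data.frame with one row per epsilon
#'   (`epsilon`, `n_clusters`, `n_noise`), and `epsmax`.
#' @export
scan_epsilon <- function(msa, eps_grid = seq(3, 25, by = 0.5), min_samples = 3L) {
  stopifnot(inherits(msa, "msa"))
  if (!length(eps_grid) || !is.numeric(eps_grid) || any(eps_grid <= 0)) {
    abort_argument("`eps_grid` must be a nonempty vector of positive values")
  }
  eps_grid <- sort(unique(eps_grid))
  enc <- encode_onehot(msa)[-1L, , drop = FALSE]
  d <- as.matrix(dist(enc))
  rows <- lapply(eps_grid, function(eps) {
    labels <- dbscan_labels(d, eps, min_samples)
    data.frame(epsilon = eps,
               n_clusters = length(unique(labels[labels >= 0L])),
               n_noise = sum(labels == -1L))
  })
  scan <- do.call(rbind, rows)
  list(scan = scan, epsmax = scan$epsilon[which.max(scan$n_clusters)])
}

#' Select epsilon by confidently classified state coverage
#'
#' Given an epsilon scan and per-epsilon state calls for the predicted
#' clusters, returns the epsilon that maximises the number of calls
#' confidently classified as active or inactive — state in
#' `{active, inactive}` (which under the 5.4 A rule already implies a
#' segment RMSD to one reference within the reference gap) and mean plDDT
#' above 70. Ties resolve toward the smaller epsilon.
#'
#' @param scan the `scan` data.frame from [scan_epsilon()] (or any
#'   data.frame with an `epsilon` column).
#' @param calls_per_eps list of state-call data.frames (see
#'   [classify_state()]), one per scan row, in scan row order.
#' @return the selected epsilon (numeric scalar), with the per-epsilon
#'   confident counts attached as attribute `"n_confident_classified"`.
#' @export
select_epsilon_by_state_coverage <- function(scan, calls_per_eps) {
  if (!is.data.frame(scan) || !nrow(scan) || is.null(scan$epsilon)) {
    abort_argument("`scan` must be a nonempty epsilon-scan data.frame")
  }
  if (length(calls_per_eps) != nrow(scan)) {
    abort_argument("`calls_per_eps` must have one call set per scan row")
  }
  n_conf <- vapply(calls_per_eps, function(calls) {
    if (is.null(calls) || !nrow(calls)) return(0L)
    sum(calls$state %in% c("active", "inactive") & calls$mean_plddt > 70)
  }, integer(1))
  ord <- order(scan$epsilon)
  best <- ord[which.max(n_conf[ord])]
  structure(scan$epsilon[best], n_confident_classified = n_conf)
}
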
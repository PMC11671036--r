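# Independent oracles and small generators shared across tests.

# Canonical relabelling (order of first appearance) so partitions can be
# compared up to label renaming; noise (-1) is kept as-is.
canon_labels <- function(lab) {
  out <- integer(length(lab))
  map <- new.env(parent = emptyenv())
  nxt <- 0L
  for (i in seq_along(lab)) {
    if (lab[i] == -1L) { out[i] <- -1L; next }
    key <- as.character(lab[i])
    if (is.null(map[[key]])) { map[[key]] <- nxt; nxt <- nxt + 1L }
    out[i] <- map[[key]]
  }
  out
}

# Reference DBSCAN: scikit-learn via the system python, one call for a
# whole batch of point sets. Returns a list of integer label vectors.
sklearn_dbscan <- function(pts_list, eps, min_samples) {
  dir <- tempfile("skdbscan_")
  dir.create(dir)
  df <- do.call(rbind, lapply(seq_along(pts_list), function(i) {
    cbind(inst = i, pts_list[[i]])
  }))
  utils::write.csv(as.data.frame(df), file.path(dir, "pts.csv"), row.names = FALSE)
  script <- file.path(dir, "run.py")
  writeLines(c(
    "import sys, pandas as pd",
    "from sklearn.cluster import DBSCAN",
    "df = pd.read_csv(sys.argv[1])",
    "eps, ms = float(sys.argv[2]), int(sys.argv[3])",
    "with open(sys.argv[4], 'w') as out:",
    "    for _, g in df.groupby('inst'):",
    "        lab = DBSCAN(eps=eps, min_samples=ms).fit(g.values[:, 1:]).labels_",
    "        out.write(','.join(map(str, lab)) + '\\n')"
  ), script)
  out <- file.path(dir, "labels.txt")
  status <- system2("python", c(script, file.path(dir, "pts.csv"),
                                format(eps), min_samples, out))
  stopifnot(status == 0L)
  lapply(strsplit(readLines(out), ","), as.integer)
}

# Brute-force minimal RMSD: numeric minimisation over axis-angle rotation
# parameters from many random starts (translation handled analytically by
# centroid alignment). Independent of the SVD route it checks.
brute_force_rmsd <- function(P, Q, n_starts = 30, seed = 1) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-14) return(diag(3))
    k <- v / th
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(v) sqrt(mean(rowSums((Pc %*% rot(v) - Qc)^2)))
  best <- Inf
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    v0 <- if (s == 1) c(0, 0, 0) else runif(3, -pi, pi)
    fit <- optim(v0, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 5000))
    best <- min(best, fit$value)
  }
  best
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_res)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Zero-rate planted MSA: exact distance regimes (within 0, between
# sqrt(4 * signature columns)).
planted_msa <- function(n_families = 2, rows = 10, L = 40, s = 3, seed = 1) {
  make_two_state_msa(n_families = n_families, rows_per_family = rows,
                     match_length = L, family_signature_columns = s,
                     background_mutation_rate = 0, gap_rate = 0, seed = seed)
}

# Planted family label of each non-query member of a cluster set, plus the
# matching predicted label vector, for ARI computations.
partition_vs_planted <- function(clusters, fx) {
  ids <- fx$msa$ids[-1L]
  pred <- rep(-1L, length(ids))
  for (cl in clusters) {
    pred[match(cl$members$ids[-1L], ids)] <- cl$label
  }
  list(pred = pred, truth = fx$labels)
}
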
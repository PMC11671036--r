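#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Minimal least-squares RMSD between two equal-size point sets after
#' optimal rigid superposition. Only proper rotations are allowed: a
#' reflection in the cross-covariance SVD is corrected by flipping the sign
#' of the smallest singular direction.
#'
#' @param P,Q numeric `N x 3` coordinate matrices (N >= 3). `P` is moved
#'   onto `Q`.
#' @return list with `rmsd` (Angstrom), `rotation` (3x3 matrix, row-vector
#'   convention: `P_aligned = P %*% rotation + translation`) and
#'   `translation` (length-3 vector).
#' @examples
#' P <- matrix(rnorm(30), ncol = 3)
#' kabsch_rmsd(P, P)$rmsd  # 0
#' @export
kabsch_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!identical(dim(P), dim(Q)) || ncol(P) != 3L) {
    abort_argument("`P` and `Q` must be N x 3 matrices of equal size")
  }
  if (nrow(P) < 3L) abort_argument("need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)          # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rmsd <- sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
  list(rmsd = rmsd, rotation = R, translation = as.numeric(cq - cp %*% R))
}
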
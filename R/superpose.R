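#' Optimal rigid-body superposition (Kabsch)
#'
#' Computes the proper rotation and translation minimizing the sum of squared
#' distances between paired points, \eqn{\sum_i \|R x_i + t - y_i\|^2}, with
#' the reflection excluded by forcing \eqn{\det R = +1}.
#'
#' @param ref_points n x 3 matrix of target (reference) coordinates.
#' @param mov_points n x 3 matrix of moving coordinates, paired row-wise.
#' @return A `RigidTransform`: list with `rotation` (3 x 3, orthonormal,
#'   det +1) and `translation` (length-3), mapping moving onto reference via
#'   `x %*% t(rotation) + translation`.
#' @export
kabsch <- function(ref_points, mov_points) {
  ref_points <- as.matrix(ref_points)
  mov_points <- as.matrix(mov_points)
  n <- nrow(ref_points)
  if (n != nrow(mov_points)) stop("point sets must have equal size")
  if (n < 3L) stop("need at least 3 point pairs")
  cr <- colMeans(ref_points)
  cm <- colMeans(mov_points)
  P <- sweep(mov_points, 2L, cm)
  Q <- sweep(ref_points, 2L, cr)
  # collinearity check: a 1-dimensional cloud leaves the rotation about the
  # line unconstrained
  sv <- svd(P)$d
  if (sv[2L] < 1e-8 * max(sv[1L], 1)) {
    stop("degenerate (collinear) point configuration")
  }
  H <- crossprod(P, Q)                   # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- as.numeric(cr - R %*% cm)
  structure(list(rotation = R, translation = t), class = "RigidTransform")
}

#' Apply a rigid transform to coordinates or a chain
#'
#' @param x n x 3 coordinate matrix or a `ProteinChain`.
#' @param transform A `RigidTransform`.
#' @return Object of the same type with transformed CA coordinates.
#' @export
apply_transform <- function(x, transform) {
  if (inherits(x, "ProteinChain")) {
    x$ca <- apply_transform(x$ca, transform)
    return(x)
  }
  sweep(as.matrix(x) %*% t(transform$rotation), 2L, transform$translation, "+")
}

identity_transform <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0)),
            class = "RigidTransform")
}

#' Superpose a chain onto a reference
#'
#' Fits `moving` onto `ref` over the given residue pairs (Kabsch) and reports
#' the RMSD over those pairs. The combinatorial-extension style discovery of
#' the residue pairing is out of scope here: pairs come from the caller, from
#' a 1:1 match by position when both chains have the same length, or the fit
#' is skipped entirely for coordinates already superposed externally
#' (`assume_aligned = TRUE`), in which case only the RMSD is computed.
#'
#' @param ref Reference `ProteinChain`.
#' @param moving `ProteinChain` to superpose.
#' @param pairs Two-column matrix/data.frame of 0-based residue indices
#'   (reference, moving); default pairs residue i with residue i when the
#'   chains have equal length.
#' @param assume_aligned If `TRUE`, keep coordinates as-is (identity
#'   transform) and just compute the RMSD.
#' @return List with `result` (an `AlignmentResult`: `transform`, `rmsd`,
#'   `residue_pairs`) and `chain` (the transformed copy of `moving`).
#' @export
align_to_reference <- function(ref, moving, pairs = NULL,
                               assume_aligned = FALSE) {
  if (is.null(pairs)) {
    if (n_residues(ref) != n_residues(moving)) {
      stop("chains differ in length; supply explicit residue pairs ",
           "or use assume_aligned")
    }
    pairs <- cbind(seq_len(n_residues(ref)) - 1L,
                   seq_len(n_residues(moving)) - 1L)
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  if (any(pairs[, 1L] < 0L) || any(pairs[, 1L] >= n_residues(ref)) ||
      any(pairs[, 2L] < 0L) || any(pairs[, 2L] >= n_residues(moving))) {
    stop("residue pair index out of range")
  }
  rp <- ref$ca[pairs[, 1L] + 1L, , drop = FALSE]
  mp <- moving$ca[pairs[, 2L] + 1L, , drop = FALSE]
  tr <- if (assume_aligned) identity_transform() else kabsch(rp, mp)
  moved <- apply_transform(moving, tr)
  fitted <- moved$ca[pairs[, 2L] + 1L, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((fitted - rp)^2)))
  result <- structure(list(transform = tr, rmsd = rmsd, residue_pairs = pairs),
                      class = "AlignmentResult")
  list(result = result, chain = moved)
}

#' Order chains for the juxtaposed view
#'
#' Reference first, remaining chains in ascending RMSD (stable: ties keep
#' input order), matching the juxtaposition ordering where the most similar
#' chains sit closest to the reference.
#'
#' @param results List of `AlignmentResult`, one per non-reference chain.
#' @param chains List of the corresponding chains (same order as `results`).
#' @param ref Reference `ProteinChain`.
#' @return List: `chains` (reference first, then sorted), `order` (integer
#'   permutation of `seq_along(chains)`), `rmsd` (sorted RMSDs).
#' @export
sort_by_rmsd <- function(results, chains, ref) {
  if (length(results) != length(chains)) {
    stop("need one alignment result per chain")
  }
  rmsd <- vapply(results, function(r) r$rmsd, numeric(1))
  ord <- order(rmsd)                     # order() is stable
  list(chains = c(list(ref), chains[ord]), order = ord, rmsd = rmsd[ord])
}
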
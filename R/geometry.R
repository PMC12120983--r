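# Rigid-body superposition (Kabsch), heavy-atom RMSD, and chirality
# consistency checks. Reflections are deliberately excluded from the
# superposition search: an improper alignment would hide exactly the
# handedness changes the preprocessing must detect.

#' Optimal proper-rotation superposition (Kabsch)
#'
#' Least-squares superposition of `test` onto `ref` over a subset of atoms,
#' restricted to proper rotations (determinant +1). The minimising rotation is
#' obtained from the SVD of the covariance matrix with the standard sign
#' correction, so mirror images are never superposed onto each other.
#'
#' @param ref N x 3 reference coordinates (Angstrom).
#' @param test N x 3 coordinates to superpose.
#' @param mask Integer vector of atom indices the fit is computed over.
#'   Defaults to all atoms.
#' @return A list of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length-3; the map is `test %*% rotation + translation`),
#'   `rmsd` (Angstrom over the masked atoms), and `rank_deficient` (`TRUE`
#'   when fewer than 3 atoms determine the fit).
#' @export
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' th <- pi / 3
#' rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
#' kabsch_superpose(a, a %*% rot + 2)$rmsd  # ~0
kabsch_superpose <- function(ref, test, mask = seq_len(nrow(ref))) {
  if (!is.matrix(ref) || !is.matrix(test) || ncol(ref) != 3L ||
      ncol(test) != 3L || nrow(ref) != nrow(test))
    stop("ref and test must be N x 3 matrices with equal N")
  mask <- as.integer(mask)
  if (length(mask) == 0L) stop("empty atom mask")
  a <- ref[mask, , drop = FALSE]
  b <- test[mask, , drop = FALSE]
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2, ca)
  b0 <- sweep(b, 2, cb)
  h <- crossprod(b0, a0)               # 3x3 covariance, test -> ref
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- b0 %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - a0)^2)))
  structure(
    list(rotation = rot,
         translation = as.numeric(ca - cb %*% rot),
         rmsd = rmsd,
         rank_deficient = length(mask) < 3L),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A%s\n", x$rmsd,
              if (x$rank_deficient) " (rank deficient: < 3 atoms)" else ""))
  invisible(x)
}

#' Kabsch RMSD between two coordinate sets
#'
#' @inheritParams kabsch_superpose
#' @return Minimum RMSD (Angstrom) over proper rotations and translations.
#' @export
kabsch_rmsd <- function(ref, test, mask = seq_len(nrow(ref))) {
  kabsch_superpose(ref, test, mask)$rmsd
}

#' Heavy-atom RMSD of every conformer to the reference
#'
#' RMSD (after optimal proper superposition) over non-hydrogen atoms of each
#' conformer relative to the ensemble's reference conformer, i.e. the one
#' with the lowest low-level energy.
#'
#' @param ensemble A `conformer_ensemble`.
#' @return Numeric vector, one value per conformer; exactly 0 at the
#'   reference position.
#' @export
rmsd_to_reference <- function(ensemble) {
  hv <- heavy_atoms(ensemble$elements)
  if (length(hv) == 0L) stop("structure has no heavy atoms")
  ref <- ensemble$coords[[ensemble$reference_index]]
  out <- vapply(seq_len(n_conformers(ensemble)), function(k) {
    if (k == ensemble$reference_index) return(0)
    kabsch_rmsd(ref, ensemble$coords[[k]], mask = hv)
  }, numeric(1))
  out
}

#' Pairwise heavy-atom RMSD matrix
#'
#' @param ensemble A `conformer_ensemble`.
#' @return Symmetric n x n matrix of heavy-atom Kabsch RMSD values (Angstrom).
#' @export
pairwise_rmsd <- function(ensemble) {
  hv <- heavy_atoms(ensemble$elements)
  n <- n_conformers(ensemble)
  m <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        m[i, j] <- m[j, i] <-
          kabsch_rmsd(ensemble$coords[[i]], ensemble$coords[[j]], mask = hv)
      }
    }
  }
  m
}

#' Detect chirality flips at 4-coordinate centres
#'
#' Tests every atom with exactly four bonded neighbours. The handedness of a
#' centre is the sign of the determinant of the three edge vectors to its
#' first three neighbours in atom-index order; a centre is flagged as flipped
#' when the signs in `ref` and `test` differ and both determinant magnitudes
#' exceed a planarity tolerance, so near-planar centres whose handedness is
#' numerically undefined are never flagged.
#'
#' @param ref N x 3 reference coordinates.
#' @param test N x 3 test coordinates (same atom order).
#' @param connectivity N x N logical adjacency matrix.
#' @param planarity_tol Determinant magnitude (Angstrom^3) below which a
#'   centre counts as planar. Default `1e-3`.
#' @return A list of class `chirality_report` with `centers` (indices tested)
#'   and `flipped` (subset with inverted handedness).
#' @export
detect_chirality_flips <- function(ref, test, connectivity,
                                   planarity_tol = 1e-3) {
  connectivity <- check_connectivity(connectivity, nrow(ref))
  if (!all(dim(ref) == dim(test)))
    stop("ref and test must have identical dimensions")
  deg <- rowSums(connectivity)
  centers <- which(deg == 4L)
  flipped <- integer(0)
  for (c in centers) {
    nb <- which(connectivity[c, ])[1:3]
    d_ref <- det(rbind(ref[nb[1], ] - ref[c, ],
                       ref[nb[2], ] - ref[c, ],
                       ref[nb[3], ] - ref[c, ]))
    d_test <- det(rbind(test[nb[1], ] - test[c, ],
                        test[nb[2], ] - test[c, ],
                        test[nb[3], ] - test[c, ]))
    if (abs(d_ref) > planarity_tol && abs(d_test) > planarity_tol &&
        sign(d_ref) != sign(d_test)) {
      flipped <- c(flipped, c)
    }
  }
  structure(list(centers = centers, flipped = flipped),
            class = "chirality_report")
}

#' @export
print.chirality_report <- function(x, ...) {
  cat(sprintf("chirality_report: %d centre%s tested, %d flipped\n",
              length(x$centers), if (length(x$centers) == 1L) "" else "s",
              length(x$flipped)))
  if (length(x$flipped))
    cat("  flipped atoms:", paste(x$flipped, collapse = ", "), "\n")
  invisible(x)
}

#' Remove chirality-flipped conformers from an ensemble
#'
#' Compares every conformer against a reference geometry (by default the
#' ensemble's lowest-energy conformer, standing in for the original input
#' structure) and drops conformers in which any tested stereocentre has
#' inverted. Relative energies, the reference conformer and
#' RMSD-to-reference are recomputed on the survivors.
#'
#' @param ensemble A `conformer_ensemble` with connectivity attached.
#' @param reference Optional N x 3 coordinates of the original input
#'   structure; defaults to the ensemble's reference conformer.
#' @param planarity_tol Passed to [detect_chirality_flips()].
#' @return The filtered `conformer_ensemble`, with an attribute `"removed"`
#'   holding the ids of dropped conformers.
#' @export
remove_flipped <- function(ensemble, reference = NULL, planarity_tol = 1e-3) {
  if (is.null(ensemble$connectivity))
    stop("ensemble has no connectivity matrix; attach one first")
  if (is.null(reference))
    reference <- ensemble$coords[[ensemble$reference_index]]
  keep <- vapply(seq_len(n_conformers(ensemble)), function(k) {
    rep <- detect_chirality_flips(reference, ensemble$coords[[k]],
                                  ensemble$connectivity, planarity_tol)
    length(rep$flipped) == 0L
  }, logical(1))
  if (!any(keep))
    stop("all conformers removed by the chirality filter")
  removed <- ensemble$ids[!keep]
  out <- ensemble[keep]
  attr(out, "removed") <- removed
  out
}
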
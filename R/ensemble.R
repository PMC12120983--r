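# The conformer_ensemble container: an ordered set of conformers sharing one
# atom ordering, with low-level energies, optional connectivity, and derived
# relative energies and heavy-atom RMSD to the reference conformer.

#' Construct a conformer ensemble
#'
#' Bundles conformer geometries that share one element sequence and atom
#' ordering with their low-level (e.g. GFN2-xTB) energies. Relative energies,
#' the reference conformer (lowest low-level energy, first on ties) and
#' heavy-atom RMSD to the reference are derived on construction.
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param coords List of N x 3 numeric matrices (Angstrom), one per conformer.
#' @param energy Numeric vector of per-conformer low-level energies in kJ/mol
#'   (absolute or already-relative; only differences are ever used).
#' @param connectivity Optional N x N logical adjacency matrix (symmetric,
#'   zero diagonal).
#' @param metal_index Optional integer index of the metal centre; detected
#'   from `elements` when `NULL` and detection is unambiguous.
#' @param ids Integer conformer identity labels, preserved through filtering.
#'   Defaults to `seq_along(coords)`.
#' @return An object of class `conformer_ensemble`: a list with fields
#'   `elements`, `coords`, `energy`, `rel_energy`, `reference_index`,
#'   `rmsd_ref`, `connectivity`, `metal_index`, `ids`.
#' @export
#' @examples
#' xyz <- matrix(rnorm(12), 4, 3)
#' ens <- conformer_ensemble(c("Rh", "P", "P", "C"),
#'                           list(xyz, xyz + 0.1), energy = c(-10, -9))
#' ens$rel_energy
conformer_ensemble <- function(elements, coords, energy,
                               connectivity = NULL, metal_index = NULL,
                               ids = NULL) {
  if (!is.list(coords) || length(coords) == 0L)
    stop("coords must be a non-empty list of N x 3 matrices")
  n <- length(coords)
  nat <- length(elements)
  if (nat == 0L) stop("elements must be non-empty")
  bad <- !(elements %in% .element_symbols)
  if (any(bad))
    stop("invalid element symbol(s): ", paste(unique(elements[bad]), collapse = ", "))
  for (k in seq_len(n)) {
    m <- coords[[k]]
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) != nat)
      stop("conformer ", k, ": coordinates must be a ", nat, " x 3 matrix")
    if (!all(is.finite(m)))
      stop("conformer ", k, ": non-finite coordinates")
    dimnames(coords[[k]]) <- NULL
    storage.mode(coords[[k]]) <- "double"
  }
  if (length(energy) != n) stop("one energy per conformer required")
  if (!all(is.finite(energy))) stop("non-finite energies")
  if (is.null(ids)) ids <- seq_len(n)
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("conformer ids must be unique")
  if (!is.null(connectivity)) connectivity <- check_connectivity(connectivity, nat)
  if (is.null(metal_index) && any(elements %in% .transition_metals)) {
    mi <- which(elements %in% .transition_metals)
    metal_index <- if (length(mi) == 1L) mi else NULL
  }
  if (!is.null(metal_index)) {
    metal_index <- as.integer(metal_index)
    if (metal_index < 1L || metal_index > nat) stop("metal_index out of range")
  }

  ens <- structure(
    list(elements = as.character(elements), coords = coords,
         energy = as.numeric(energy), rel_energy = NULL,
         reference_index = NA_integer_, rmsd_ref = NULL,
         connectivity = connectivity, metal_index = metal_index, ids = ids),
    class = "conformer_ensemble"
  )
  refresh_ensemble(ens)
}

# Recompute the derived fields (relative energies, reference conformer,
# heavy-atom RMSD to reference) after any change to membership or energies.
refresh_ensemble <- function(ens) {
  ens$rel_energy <- ens$energy - min(ens$energy)
  ens$reference_index <- which.min(ens$energy)
  ens$rmsd_ref <- rmsd_to_reference(ens)
  ens
}

check_connectivity <- function(connectivity, nat) {
  if (!is.matrix(connectivity) || nrow(connectivity) != nat ||
      ncol(connectivity) != nat)
    stop("connectivity must be a ", nat, " x ", nat, " matrix")
  mode(connectivity) <- "logical"
  if (any(diag(connectivity))) stop("connectivity has non-zero diagonal")
  if (!isTRUE(all(connectivity == t(connectivity))))
    stop("connectivity must be symmetric")
  connectivity
}

#' Number of conformers in an ensemble
#' @param x A `conformer_ensemble`.
#' @return Integer count.
#' @export
n_conformers <- function(x) length(x$coords)

#' Subset a conformer ensemble
#'
#' Keeps the given conformers (by position) and rederives relative energies,
#' the reference conformer and RMSD-to-reference on the subset. Identity
#' labels in `ids` are preserved.
#'
#' @param x A `conformer_ensemble`.
#' @param i Integer or logical index vector over conformer positions.
#' @param ... Unused.
#' @return A `conformer_ensemble` over the kept conformers.
#' @export
`[.conformer_ensemble` <- function(x, i, ...) {
  pos <- seq_len(n_conformers(x))[i]
  if (length(pos) == 0L) stop("cannot create an empty conformer ensemble")
  x$coords <- x$coords[pos]
  x$energy <- x$energy[pos]
  x$ids <- x$ids[pos]
  refresh_ensemble(x)
}

heavy_atoms <- function(elements) which(elements != "H")

#' @export
print.conformer_ensemble <- function(x, ...) {
  n <- n_conformers(x)
  cat(sprintf("conformer_ensemble: %d conformer%s, %d atoms (%d heavy)\n",
              n, if (n == 1L) "" else "s", length(x$elements),
              length(heavy_atoms(x$elements))))
  cat(sprintf("  reference (lowest energy): conformer %d (id %d)\n",
              x$reference_index, x$ids[x$reference_index]))
  cat(sprintf("  rel. energy span: %.2f kJ/mol; max RMSD to reference: %.3f A\n",
              max(x$rel_energy), max(x$rmsd_ref)))
  if (!is.null(x$metal_index))
    cat(sprintf("  metal: %s (atom %d)\n", x$elements[x$metal_index],
                x$metal_index))
  cat(sprintf("  connectivity: %s\n",
              if (is.null(x$connectivity)) "absent" else "present"))
  invisible(x)
}

#' @export
summary.conformer_ensemble <- function(object, ...) {
  df <- data.frame(
    id = object$ids,
    energy_kjmol = object$energy,
    rel_energy_kjmol = object$rel_energy,
    rmsd_ref_A = object$rmsd_ref
  )
  class(df) <- c("summary.conformer_ensemble", "data.frame")
  df
}
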
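# File formats: CREST-dialect multi-structure XYZ, MDL Molfile V2000
# connectivity, distilled DFT result tables, and selection files.

#' Read a multi-structure XYZ conformer ensemble
#'
#' Parses the CREST `crest_conformers.xyz` dialect: repeated frames of an
#' atom-count line, a comment line carrying the conformer energy, and one
#' `element x y z` line per atom. The energy is taken as the first token of
#' the comment line that parses as a number; CREST writes energies in
#' Hartree, the default unit.
#'
#' @param path Path to the XYZ file.
#' @param energy_unit Unit of the comment-line energies; one of `"hartree"`
#'   (default, converted with 1 Eh = 2625.4996394799 kJ/mol), `"kjmol"`,
#'   `"kcalmol"`, `"ev"`.
#' @param connectivity Optional N x N logical adjacency to attach (e.g. from
#'   [read_molfile_connectivity()]).
#' @param metal_index Optional metal atom index; auto-detected otherwise.
#' @return A [conformer_ensemble()].
#' @export
read_multi_xyz <- function(path, energy_unit = c("hartree", "kjmol",
                                                 "kcalmol", "ev"),
                           connectivity = NULL, metal_index = NULL) {
  energy_unit <- match.arg(energy_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  # drop trailing blank lines only; blank lines inside a frame are an error
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) stop("empty XYZ file: ", path)

  frames <- list()
  energies <- numeric(0)
  elements <- NULL
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat <= 0L)
      stop("frame ", frame, ": invalid atom-count line at line ", pos)
    if (pos + 1L + nat > length(lines))
      stop("frame ", frame, ": truncated file (expected ", nat, " atom lines)")
    comment <- lines[pos + 1L]
    e <- parse_comment_energy(comment)
    if (is.na(e))
      stop("frame ", frame, ": no parseable energy in comment line \"",
           comment, "\"")
    atom_lines <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(atom_lines), "[[:space:]]+")
    if (any(vapply(toks, length, integer(1)) < 4L))
      stop("frame ", frame, ": malformed atom line")
    el <- vapply(toks, `[[`, character(1), 1L)
    xyz <- matrix(NA_real_, nat, 3L)
    for (j in 1:3) {
      v <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), j + 1L)))
      if (anyNA(v)) stop("frame ", frame, ": non-numeric coordinate")
      xyz[, j] <- v
    }
    if (is.null(elements)) {
      elements <- el
    } else {
      if (length(el) != length(elements))
        stop("frame ", frame, ": atom count ", length(el),
             " differs from first frame (", length(elements), ")")
      if (!identical(el, elements))
        stop("frame ", frame, ": element order differs from first frame")
    }
    frames[[frame]] <- xyz
    energies[frame] <- e
    pos <- pos + 2L + nat
  }
  conformer_ensemble(elements, frames, to_kjmol(energies, energy_unit),
                     connectivity = connectivity, metal_index = metal_index)
}

# First token of an XYZ comment line that parses as a floating-point number.
parse_comment_energy <- function(comment) {
  toks <- strsplit(trimws(comment), "[[:space:]]+")[[1]]
  for (t in toks) {
    v <- suppressWarnings(as.numeric(t))
    if (!is.na(v)) return(v)
  }
  NA_real_
}

#' Write a multi-structure XYZ file
#'
#' Inverse of [read_multi_xyz()]; energies are written on the comment line in
#' the requested unit.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param path Output path.
#' @param energy_unit Unit used on comment lines (default `"kjmol"`).
#' @return Invisibly, `path`.
#' @export
write_multi_xyz <- function(ensemble, path,
                            energy_unit = c("kjmol", "hartree")) {
  energy_unit <- match.arg(energy_unit)
  e <- switch(energy_unit, kjmol = ensemble$energy,
              hartree = ensemble$energy / HARTREE_KJMOL)
  con <- file(path, "w")
  on.exit(close(con))
  nat <- length(ensemble$elements)
  for (k in seq_len(n_conformers(ensemble))) {
    writeLines(c(sprintf("%d", nat), sprintf("%.10f", e[k])), con)
    m <- ensemble$coords[[k]]
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", ensemble$elements,
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read connectivity from an MDL Molfile (V2000)
#'
#' Extracts the element sequence and a boolean adjacency matrix from the atom
#' and bond blocks of a V2000 Molfile. Bond orders are discarded; only
#' presence matters for the connectivity graph.
#'
#' @param path Path to the Molfile.
#' @return A list with `connectivity` (N x N logical, symmetric, zero
#'   diagonal) and `elements` (character vector, for cross-checking against
#'   the XYZ atom order).
#' @export
read_molfile_connectivity <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 4L) stop("Molfile too short: ", path)
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L || nbonds < 0L)
    stop("malformed counts line: \"", counts, "\"")
  if (length(lines) < 4L + natoms + nbonds)
    stop("Molfile truncated: expected ", natoms, " atom and ", nbonds,
         " bond lines")
  atom_lines <- lines[5:(4 + natoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  if (any(!nzchar(elements))) {
    # fall back to whitespace tokenisation for loosely formatted files
    elements <- vapply(strsplit(trimws(atom_lines), "[[:space:]]+"),
                       `[[`, character(1), 4L)
  }
  adj <- matrix(FALSE, natoms, natoms)
  if (nbonds > 0L) {
    bond_lines <- lines[(5 + natoms):(4 + natoms + nbonds)]
    a <- suppressWarnings(as.integer(substr(bond_lines, 1, 3)))
    b <- suppressWarnings(as.integer(substr(bond_lines, 4, 6)))
    if (anyNA(a) || anyNA(b)) stop("malformed bond line")
    if (any(a < 1L | a > natoms | b < 1L | b > natoms))
      stop("bond references out-of-range atom index")
    if (any(a == b)) stop("bond connects an atom to itself")
    adj[cbind(a, b)] <- TRUE
    adj[cbind(b, a)] <- TRUE
  }
  list(connectivity = adj, elements = elements)
}

#' Read a distilled DFT results table
#'
#' The high-level (DFT) outcome per conformer is consumed as a delimited
#' table rather than raw quantum-chemistry logs. Required columns:
#' `conformer_index`, `converged`, `energy_high`, `n_imaginary`; optional:
#' `gibbs`. Energies of non-converged rows may be empty.
#'
#' @param path Path to a CSV file.
#' @param energy_unit Unit of `energy_high` and `gibbs` columns (default
#'   `"kjmol"`).
#' @return A data.frame of class `dft_records` with columns
#'   `conformer_index` (integer), `converged` (logical), `energy_high`
#'   (kJ/mol, `NA` when not converged), `gibbs` (kJ/mol or `NA`),
#'   `n_imaginary` (integer).
#' @export
read_dft_table <- function(path, energy_unit = c("kjmol", "hartree",
                                                 "kcalmol", "ev")) {
  energy_unit <- match.arg(energy_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("conformer_index", "converged", "energy_high", "n_imaginary")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("DFT table missing column(s): ", paste(miss, collapse = ", "))
  dft_records(
    conformer_index = df$conformer_index,
    converged = df$converged,
    energy_high = to_kjmol(as.numeric(df$energy_high), energy_unit),
    gibbs = if ("gibbs" %in% names(df))
      to_kjmol(as.numeric(df$gibbs), energy_unit) else NA_real_,
    n_imaginary = df$n_imaginary
  )
}

#' Construct DFT outcome records
#'
#' @param conformer_index Integer conformer ids.
#' @param converged Logical convergence flags.
#' @param energy_high Electronic energies in kJ/mol (`NA` when not converged).
#' @param gibbs Optional Gibbs energies in kJ/mol.
#' @param n_imaginary Count of imaginary frequencies after reoptimisation.
#' @return A data.frame of class `dft_records`.
#' @export
dft_records <- function(conformer_index, converged, energy_high,
                        gibbs = NA_real_, n_imaginary = 0L) {
  n <- length(conformer_index)
  converged <- as.logical(converged)
  if (anyNA(converged)) stop("converged column must be TRUE/FALSE")
  energy_high <- as.numeric(energy_high)
  n_imaginary <- as.integer(n_imaginary)
  df <- data.frame(conformer_index = as.integer(conformer_index),
                   converged = converged,
                   energy_high = energy_high,
                   gibbs = as.numeric(gibbs),
                   n_imaginary = rep_len(n_imaginary, n))
  if (anyDuplicated(df$conformer_index))
    stop("duplicate conformer_index in DFT records")
  if (any(df$converged & !is.finite(df$energy_high)))
    stop("converged record without an energy")
  df$energy_high[!df$converged] <- NA_real_
  if (any(df$n_imaginary < 0L)) stop("n_imaginary must be non-negative")
  class(df) <- c("dft_records", "data.frame")
  df
}

#' Write a selection result to a JSON file
#'
#' Deterministic, machine-readable serialisation of a [selection_result]:
#' indices sorted, fixed key order, so re-serialising a read file is
#' byte-identical.
#'
#' @param result A `selection_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_selection <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  obj <- list(
    method = result$method,
    parameters = result$parameters,
    selected = sort(result$selected),
    eliminated = sort(result$eliminated)
  )
  if (!is.null(result$cluster_labels))
    obj$cluster_labels <- result$cluster_labels
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a selection result written by [write_selection()]
#'
#' @param path Path to the JSON file.
#' @return A `selection_result`.
#' @export
read_selection <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  selection_result(
    method = obj$method,
    parameters = as.list(obj$parameters),
    selected = as.integer(obj$selected),
    eliminated = as.integer(obj$eliminated),
    cluster_labels = if (!is.null(obj$cluster_labels))
      as.integer(obj$cluster_labels) else NULL
  )
}
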
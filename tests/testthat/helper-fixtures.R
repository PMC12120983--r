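# Small programmatic fixtures shared across tests.

# write a multi-frame XYZ file from a list of N x 3 matrices
write_xyz_text <- function(frames, comments, elements, path = tempfile()) {
  lines <- character(0)
  for (k in seq_along(frames)) {
    m <- frames[[k]]
    lines <- c(lines, nrow(m), comments[k],
               sprintf("%s %.6f %.6f %.6f", elements, m[, 1], m[, 2], m[, 3]))
  }
  writeLines(lines, path)
  path
}

# minimal V2000 Molfile text
write_mol_text <- function(elements, coords, bonds, path = tempfile()) {
  lines <- c("test", "", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     length(elements), nrow(bonds)))
  lines <- c(lines,
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     coords[, 1], coords[, 2], coords[, 3], elements))
  if (nrow(bonds))
    lines <- c(lines, sprintf("%3d%3d  1  0  0  0  0", bonds[, 1], bonds[, 2]))
  lines <- c(lines, "M  END")
  writeLines(lines, path)
  path
}

# ensemble built directly from coordinates (energies in kJ/mol)
ens_from_coords <- function(coords_list, elements, energy, ...) {
  conformer_ensemble(elements, coords_list, energy, ...)
}

# a rigid asymmetric 5-heavy-atom skeleton used in several geometry tests
skeleton5 <- function() {
  matrix(c(0, 0, 0,
           1.5, 0, 0,
           0, 1.4, 0,
           0, 0, 1.6,
           1.1, 1.2, 0.9), ncol = 3, byrow = TRUE)
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# methane-like tetrahedral centre: C at origin, 4 substituents
tetrahedral_coords <- function() {
  matrix(c(0, 0, 0,
           1, 1, 1,
           1, -1, -1,
           -1, 1, -1,
           -1, -1, 1) / sqrt(3) * 1.1, ncol = 3, byrow = TRUE)
}

tetrahedral_adj <- function() {
  adj <- matrix(FALSE, 5, 5)
  adj[1, 2:5] <- adj[2:5, 1] <- TRUE
  adj
}
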
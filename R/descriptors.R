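# Steric and geometric descriptors evaluated at the metal centre: percent
# buried volume (grid integration), exact ligand cone angle (minimal
# enclosing tangent cone), bite angle and donor distances.

#' Steric descriptor configuration
#'
#' Conventions for the buried-volume calculation. Defaults follow the common
#' buried-volume convention: a 4.0 Angstrom sphere at the metal, Bondi van
#' der Waals radii scaled by 1.17, hydrogens excluded, 0.10 Angstrom grid.
#'
#' @param sphere_radius Sphere radius about the metal centre (Angstrom).
#' @param radii_scale Scale factor applied to van der Waals radii.
#' @param include_h Include hydrogen atoms in the occupying set?
#' @param grid_spacing Cubic grid spacing (Angstrom).
#' @param radii_table Named function mapping element symbols to radii;
#'   defaults to [vdw_radius()].
#' @return A list of class `steric_config`.
#' @export
steric_config <- function(sphere_radius = 4.0, radii_scale = 1.17,
                          include_h = FALSE, grid_spacing = 0.10,
                          radii_table = vdw_radius) {
  if (sphere_radius <= 0) stop("sphere_radius must be positive")
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  if (radii_scale <= 0) stop("radii_scale must be positive")
  structure(list(sphere_radius = sphere_radius, radii_scale = radii_scale,
                 include_h = include_h, grid_spacing = grid_spacing,
                 radii_table = radii_table),
            class = "steric_config")
}

#' Percent buried volume at the metal centre
#'
#' Fraction (x100) of a sphere centred on the metal that lies inside any
#' scaled van der Waals sphere of the chosen atoms, integrated on a uniform
#' cubic grid. Deterministic for a fixed grid spacing.
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param elements Character vector of element symbols.
#' @param metal_index Index of the metal centre atom.
#' @param atom_subset Indices of atoms considered as occupying the sphere;
#'   must exclude `metal_index`. Hydrogens are dropped unless
#'   `config$include_h`.
#' @param config A [steric_config()].
#' @return Percent buried volume in `[0, 100]`. An empty effective subset
#'   yields `0` with a warning.
#' @export
buried_volume <- function(coords, elements, metal_index, atom_subset,
                          config = steric_config()) {
  stopifnot(inherits(config, "steric_config"))
  metal_index <- as.integer(metal_index)
  if (metal_index < 1L || metal_index > nrow(coords))
    stop("metal_index out of range")
  atom_subset <- as.integer(atom_subset)
  if (metal_index %in% atom_subset)
    stop("atom_subset must exclude the metal centre")
  if (!config$include_h)
    atom_subset <- atom_subset[elements[atom_subset] != "H"]
  if (length(atom_subset) == 0L) {
    warning("empty atom subset; buried volume is 0")
    return(0)
  }
  r_sph <- config$sphere_radius
  h <- config$grid_spacing
  ax <- seq(-r_sph, r_sph, by = h)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  inside <- rowSums(pts^2) <= r_sph^2
  pts <- pts[inside, , drop = FALSE]
  n_tot <- nrow(pts)

  centre <- coords[metal_index, ]
  radii <- config$radii_table(elements[atom_subset]) * config$radii_scale
  occupied <- rep(FALSE, n_tot)
  for (k in seq_along(atom_subset)) {
    a <- coords[atom_subset[k], ] - centre
    # atoms beyond reach of the sphere cannot occupy any grid point
    if (sqrt(sum(a^2)) > r_sph + radii[k]) next
    d2 <- (pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2 + (pts[, 3] - a[3])^2
    occupied <- occupied | (d2 <= radii[k]^2)
    if (all(occupied)) break
  }
  100 * sum(occupied) / n_tot
}

#' Exact ligand cone angle
#'
#' Apex angle (full aperture, degrees) of the smallest cone with apex at the
#' metal that contains the tangent cone of every chosen atom's van der Waals
#' sphere. Each atom at distance d with radius r subtends a half-angle
#' `asin(r/d)` about its metal->atom axis; the minimal enclosing cone is
#' determined by one, two or three boundary atoms, and all three candidate
#' families are enumerated, the two- and three-atom cases solved in closed
#' form and by root-finding respectively.
#'
#' Radii are used unscaled (Tolman-style convention).
#'
#' @inheritParams buried_volume
#' @param radii_table Function mapping element symbols to radii (Angstrom).
#' @return Cone aperture in degrees, in `(0, 360)`.
#' @export
exact_cone_angle <- function(coords, elements, metal_index, atom_subset,
                             radii_table = vdw_radius) {
  metal_index <- as.integer(metal_index)
  atom_subset <- as.integer(atom_subset)
  if (length(atom_subset) == 0L) stop("empty atom subset")
  if (metal_index %in% atom_subset)
    stop("atom_subset must exclude the metal centre")
  centre <- coords[metal_index, ]
  v <- sweep(coords[atom_subset, , drop = FALSE], 2, centre)
  d <- sqrt(rowSums(v^2))
  r <- radii_table(elements[atom_subset])
  if (any(d <= r))
    stop("metal apex lies inside the van der Waals sphere of atom(s) ",
         paste(atom_subset[d <= r], collapse = ", "))
  u <- v / d
  beta <- asin(r / d)
  m <- length(beta)

  cone_alpha <- function(axis) {
    ct <- pmin(1, pmax(-1, u %*% axis))
    max(acos(ct) + beta)
  }
  best <- list(alpha = Inf, axis = c(0, 0, 0))
  consider <- function(alpha, axis, best) {
    if (alpha < best$alpha - 1e-12) return(list(alpha = alpha, axis = axis))
    if (alpha < best$alpha + 1e-12) {
      # deterministic tie-break: lexicographically smallest axis
      for (j in 1:3) {
        if (axis[j] < best$axis[j] - 1e-12)
          return(list(alpha = alpha, axis = axis))
        if (axis[j] > best$axis[j] + 1e-12) return(best)
      }
    }
    best
  }
  tol <- 1e-9

  # one-atom candidates: the atom's own tangent cone
  for (i in seq_len(m)) {
    axis <- u[i, ]
    if (cone_alpha(axis) <= beta[i] + tol)
      best <- consider(beta[i], axis, best)
  }
  # two-atom candidates: cone tangent to both, axis in their plane
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        cg <- min(1, max(-1, sum(u[i, ] * u[j, ])))
        gamma <- acos(cg)
        alpha <- (gamma + beta[i] + beta[j]) / 2
        if (alpha < max(beta[i], beta[j])) next  # one cone inside the other
        w <- u[j, ] - cg * u[i, ]
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12) next                     # parallel axes
        w <- w / nw
        t <- alpha - beta[i]
        axis <- cos(t) * u[i, ] + sin(t) * w
        if (cone_alpha(axis) <= alpha + tol) best <- consider(alpha, axis, best)
      }
    }
  }
  # three-atom candidates: axis equidistant (in angle + beta) from all three
  if (m >= 3L) {
    for (i in seq_len(m - 2L)) {
      for (j in seq(i + 1L, m - 1L)) {
        for (k in seq(j + 1L, m)) {
          A <- rbind(u[i, ], u[j, ], u[k, ])
          if (abs(det(A)) < 1e-10) next          # coplanar axes: degenerate
          Ainv <- solve(A)
          b3 <- beta[c(i, j, k)]
          fn <- function(alpha) {
            n <- Ainv %*% cos(alpha - b3)
            sum(n^2) - 1
          }
          lo <- max(b3)
          grid <- seq(lo + 1e-8, pi, length.out = 200L)
          fv <- vapply(grid, fn, numeric(1))
          sgn <- sign(fv)
          roots <- numeric(0)
          for (s in seq_len(length(grid) - 1L)) {
            if (is.finite(fv[s]) && is.finite(fv[s + 1L]) &&
                sgn[s] != sgn[s + 1L]) {
              root <- stats::uniroot(fn, c(grid[s], grid[s + 1L]),
                                     tol = 1e-10)$root
              roots <- c(roots, root)
            }
          }
          for (alpha in roots) {
            n <- as.numeric(Ainv %*% cos(alpha - b3))
            n <- n / sqrt(sum(n^2))
            if (cone_alpha(n) <= alpha + tol) best <- consider(alpha, n, best)
          }
        }
      }
    }
  }
  if (!is.finite(best$alpha))
    stop("no feasible enclosing cone found (numerical failure)")
  unname(2 * best$alpha * 180 / pi)
}

#' Bite angle
#'
#' The donor--metal--donor angle of a bidentate ligand.
#'
#' @param coords N x 3 coordinate matrix.
#' @param metal_index Metal centre index.
#' @param donor_a,donor_b Donor atom indices (distinct, not the metal).
#' @return Angle in degrees, in `(0, 180]`.
#' @export
bite_angle <- function(coords, metal_index, donor_a, donor_b) {
  if (donor_a == donor_b) stop("donor indices must be distinct")
  if (metal_index %in% c(donor_a, donor_b))
    stop("donor indices must differ from metal_index")
  va <- coords[donor_a, ] - coords[metal_index, ]
  vb <- coords[donor_b, ] - coords[metal_index, ]
  na <- sqrt(sum(va^2))
  nb <- sqrt(sum(vb^2))
  if (na < 1e-9 || nb < 1e-9) stop("zero-length metal-donor vector")
  acos(min(1, max(-1, sum(va * vb) / (na * nb)))) * 180 / pi
}

#' Ligand atom subset from connectivity
#'
#' Deletes the metal from the connectivity graph and returns the union of
#' connected components containing the donor atoms -- i.e. the bidentate
#' ligand, excluding whatever is bound trans to it.
#'
#' @param connectivity N x N logical adjacency.
#' @param metal_index Metal centre index.
#' @param donors Integer vector of donor atom indices.
#' @return Sorted integer vector of ligand atom indices (metal excluded).
#' @export
ligand_subset <- function(connectivity, metal_index, donors) {
  n <- nrow(connectivity)
  adj <- connectivity
  adj[metal_index, ] <- FALSE
  adj[, metal_index] <- FALSE
  seen <- rep(FALSE, n)
  for (d in donors) {
    if (seen[d]) next
    queue <- d
    seen[d] <- TRUE
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[cur, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  sort(setdiff(which(seen), metal_index))
}

#' Per-conformer descriptor table
#'
#' Computes the steric/geometric descriptor set used by descriptor-based
#' selection for every conformer: percent buried volume, exact cone angle,
#' bite angle, donor distances, plus the ensemble's relative energy and
#' RMSD-to-reference columns.
#'
#' @param ensemble A `conformer_ensemble` with a metal centre.
#' @param donors Integer pair of donor atom indices.
#' @param config A [steric_config()].
#' @param subset `"ligand"` (default): atoms of the donor-containing
#'   components after deleting the metal (requires connectivity);
#'   `"all"`: every atom except the metal.
#' @return A data.frame of class `descriptor_table` with one row per
#'   conformer: `conformer_index`, `buried_volume_pct`, `cone_angle`,
#'   `bite_angle`, `donor_a_dist`, `donor_b_dist`, `rmsd_ref`, `rel_energy`.
#' @export
descriptor_table <- function(ensemble, donors, config = steric_config(),
                             subset = c("ligand", "all")) {
  subset <- match.arg(subset)
  mi <- ensemble$metal_index
  if (is.null(mi)) stop("ensemble has no metal centre")
  if (length(donors) != 2L) stop("donors must be a pair of atom indices")
  atoms <- if (subset == "ligand") {
    if (is.null(ensemble$connectivity))
      stop("ligand subset requires a connectivity matrix")
    ligand_subset(ensemble$connectivity, mi, donors)
  } else {
    setdiff(seq_along(ensemble$elements), mi)
  }
  # hydrogen spheres contribute to the tangent cone like any other atom
  cone_atoms <- atoms
  rows <- lapply(seq_len(n_conformers(ensemble)), function(k) {
    xyz <- ensemble$coords[[k]]
    tryCatch(
      data.frame(
        conformer_index = ensemble$ids[k],
        buried_volume_pct = buried_volume(xyz, ensemble$elements, mi, atoms,
                                          config),
        cone_angle = exact_cone_angle(xyz, ensemble$elements, mi, cone_atoms),
        bite_angle = bite_angle(xyz, mi, donors[1], donors[2]),
        donor_a_dist = sqrt(sum((xyz[donors[1], ] - xyz[mi, ])^2)),
        donor_b_dist = sqrt(sum((xyz[donors[2], ] - xyz[mi, ])^2)),
        rmsd_ref = ensemble$rmsd_ref[k],
        rel_energy = ensemble$rel_energy[k]
      ),
      error = function(e) stop("conformer ", ensemble$ids[k], ": ",
                               conditionMessage(e), call. = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("descriptor_table", "data.frame")
  out
}
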
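# Independent oracles the implementation is checked against. Each one takes a
# different computational route from the code under test: quaternion
# eigen-decomposition for RMSD, Monte-Carlo integration for buried volume,
# direction grid search for the cone angle, literal seed-expansion DBSCAN,
# and per-conformer enumeration of the confusion definitions.

# Horn's quaternion method: the optimal proper superposition follows from the
# largest eigenvalue of the 4x4 key matrix; no SVD involved.
oracle_quaternion_rmsd <- function(ref, test, mask = seq_len(nrow(ref))) {
  a <- scale(ref[mask, , drop = FALSE], scale = FALSE)
  b <- scale(test[mask, , drop = FALSE], scale = FALSE)
  m <- crossprod(b, a)  # test -> ref correlation matrix
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  key <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(key, symmetric = TRUE, only.values = TRUE)$values)
  e <- (sum(a^2) + sum(b^2) - 2 * lambda) / length(mask)
  sqrt(max(0, e))
}

# Monte-Carlo buried volume: uniform samples inside the sphere.
oracle_mc_buried_volume <- function(coords, elements, metal_index,
                                    atom_subset, config, n_samples = 1e6) {
  if (!config$include_h)
    atom_subset <- atom_subset[elements[atom_subset] != "H"]
  if (length(atom_subset) == 0L) return(0)
  r_sph <- config$sphere_radius
  dir <- matrix(rnorm(3 * n_samples), n_samples, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  pts <- dir * (r_sph * runif(n_samples)^(1 / 3))
  centre <- coords[metal_index, ]
  radii <- config$radii_table(elements[atom_subset]) * config$radii_scale
  hit <- rep(FALSE, n_samples)
  for (k in seq_along(atom_subset)) {
    a <- coords[atom_subset[k], ] - centre
    d2 <- (pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2 + (pts[, 3] - a[3])^2
    hit <- hit | (d2 <= radii[k]^2)
  }
  100 * mean(hit)
}

# Fibonacci-sphere direction grid search for the minimal enclosing cone,
# followed by Nelder-Mead refinement in spherical coordinates.
oracle_grid_cone_angle <- function(coords, elements, metal_index,
                                   atom_subset, radii_table = vdw_radius,
                                   n_dirs = 1e5) {
  centre <- coords[metal_index, ]
  v <- sweep(coords[atom_subset, , drop = FALSE], 2, centre)
  d <- sqrt(rowSums(v^2))
  r <- radii_table(elements[atom_subset])
  u <- v / d
  beta <- asin(r / d)
  aperture <- function(axis) {
    ct <- pmin(1, pmax(-1, u %*% axis))
    max(acos(ct) + beta)
  }
  i <- seq_len(n_dirs)
  golden <- (1 + sqrt(5)) / 2
  z <- 1 - (2 * i - 1) / n_dirs
  phi <- 2 * pi * i / golden
  rho <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(rho * cos(phi), rho * sin(phi), z)
  ct <- u %*% t(dirs)                   # atoms x directions
  ct[ct > 1] <- 1
  ct[ct < -1] <- -1
  vals <- apply(acos(ct) + beta, 2, max)
  best <- dirs[which.min(vals), ]
  sph <- c(acos(best[3]), atan2(best[2], best[1]))
  obj <- function(p) aperture(c(sin(p[1]) * cos(p[2]),
                                sin(p[1]) * sin(p[2]), cos(p[1])))
  opt <- optim(sph, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  2 * min(min(vals), opt$value) * 180 / pi
}

# Literal textbook DBSCAN: visit points in index order, seed a cluster at
# every unvisited core point, expand through the seed set; previously
# noise-labelled points are reclaimed as border points by the first cluster
# that reaches them.
oracle_textbook_dbscan <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(dist(x))
  region <- function(p) which(d[p, ] <= eps)
  labels <- rep(NA_integer_, n)  # NA = unvisited, -1 = noise
  cl <- -1L
  for (p in seq_len(n)) {
    if (!is.na(labels[p])) next
    nb <- region(p)
    if (length(nb) < min_pts) {
      labels[p] <- -1L
      next
    }
    cl <- cl + 1L
    labels[p] <- cl
    seeds <- setdiff(nb, p)
    while (length(seeds)) {
      q <- seeds[1]
      seeds <- seeds[-1]
      if (!is.na(labels[q]) && labels[q] == -1L) labels[q] <- cl  # border
      if (!is.na(labels[q])) next
      labels[q] <- cl
      nbq <- region(q)
      if (length(nbq) >= min_pts) seeds <- union(seeds, nbq)
    }
  }
  labels
}

# Selection rule applied to any labelling: cluster representatives (lowest
# rel_energy, then lowest position) plus all noise points.
dbscan_selection_from_labels <- function(labels, rel_energy, ids) {
  keep <- labels < 0L
  for (lab in unique(labels[labels >= 0L])) {
    members <- which(labels == lab)
    keep[members[order(rel_energy[members], members)[1]]] <- TRUE
  }
  sort(ids[keep])
}

# Per-conformer enumeration of the confusion-matrix definitions: a selected
# conformer is a true positive when no lower-indexed selected conformer
# shares its minimum; an eliminated conformer is a false negative when its
# minimum has no selected member and no lower-indexed eliminated member.
oracle_confusion <- function(selected, labels) {
  ids <- as.integer(names(labels))
  tp <- fp <- tn <- fn <- 0L
  for (c in ids) {
    m <- labels[as.character(c)]
    same <- ids[labels == m]
    if (c %in% selected) {
      others <- setdiff(intersect(same, selected), c)
      if (length(others) == 0L || all(others > c)) tp <- tp + 1L
      else fp <- fp + 1L
    } else {
      if (any(same %in% selected)) {
        tn <- tn + 1L
      } else {
        firsts <- setdiff(same, selected)
        if (min(firsts) == c) fn <- fn + 1L else tn <- tn + 1L
      }
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}
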
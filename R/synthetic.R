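# Seeded generator of basin-structured synthetic ensembles: many low-level
# conformers that collapse onto few high-level minima, with low-level
# energies decorrelated from the high-level ranking. Gives every pipeline
# stage a ground truth without running CREST or DFT.

#' Specification of a synthetic basin-structured ensemble
#'
#' Defaults describe the regime the workflow targets: a handful of
#' well-separated geometric basins (mutual heavy-atom RMSD above 1 Angstrom,
#' within-basin spread well below the 0.35 Angstrom pruning threshold),
#' high-level basin energies spaced more than the 5 kJ/mol
#' chemical-accuracy window apart, and low-level energies whose per-basin
#' offsets are large enough to scramble the high-level ranking.
#'
#' @param n_basins Number of high-level minima (geometric basins).
#' @param conformers_per_basin Integer range `c(lo, hi)`; each basin's
#'   conformer count is drawn uniformly from it.
#' @param dft_energy_spread Total span of the basin anchor energies in
#'   kJ/mol; anchors are evenly spaced over `[0, dft_energy_spread]`.
#'   Default `8 * (n_basins - 1)`, i.e. 8 kJ/mol between neighbouring
#'   minima.
#' @param within_rmsd Target heavy-atom RMSD (Angstrom) of a conformer to
#'   its basin template; realised values are rescaled to within 5%.
#' @param between_rmsd_min Minimum pairwise heavy-atom RMSD (Angstrom)
#'   between basin templates (enforced by rejection sampling).
#' @param xtb_bias_sd Standard deviation (kJ/mol) of the per-basin offset
#'   added to low-level energies; this is what decorrelates the low-level
#'   ranking from the high-level one.
#' @param xtb_min_gap Minimum separation (kJ/mol) between the offset basin
#'   anchor energies at the low level; offsets are redrawn until satisfied,
#'   keeping basins energetically resolvable while still misranked. Ignored
#'   when `xtb_bias_sd` is 0.
#' @param xtb_noise_sd Per-conformer low-level energy noise (kJ/mol),
#'   truncated at two standard deviations.
#' @param n_atoms Total atom count of the scaffold (metal + 2 donor P + C/H).
#' @param fraction_h Fraction of the non-core atoms that are hydrogens.
#' @param mirror_fraction Fraction of conformers reflected through the
#'   origin, to exercise the chirality filter.
#' @param seed Integer seed; every draw derives from it.
#' @return A list of class `basin_spec`.
#' @export
basin_spec <- function(n_basins = 2L, conformers_per_basin = c(4L, 14L),
                       dft_energy_spread = NULL, within_rmsd = 0.15,
                       between_rmsd_min = 1.0, xtb_bias_sd = 10,
                       xtb_min_gap = 8, xtb_noise_sd = 1.5, n_atoms = 16L,
                       fraction_h = 0.25, mirror_fraction = 0, seed = 1L) {
  n_basins <- as.integer(n_basins)
  if (n_basins < 1L) stop("n_basins must be at least 1")
  if (length(conformers_per_basin) == 1L)
    conformers_per_basin <- rep(conformers_per_basin, 2L)
  conformers_per_basin <- as.integer(conformers_per_basin)
  if (any(conformers_per_basin < 1L) ||
      conformers_per_basin[2] < conformers_per_basin[1])
    stop("conformers_per_basin must be a valid positive range")
  if (is.null(dft_energy_spread))
    dft_energy_spread <- 8 * (n_basins - 1L)
  if (!(between_rmsd_min > within_rmsd && within_rmsd > 0))
    stop("need between_rmsd_min > within_rmsd > 0")
  if (xtb_bias_sd < 0 || xtb_noise_sd < 0) stop("noise sds must be >= 0")
  if (mirror_fraction < 0 || mirror_fraction > 1)
    stop("mirror_fraction must be in [0, 1]")
  if (n_atoms < 6L) stop("n_atoms must be at least 6")
  structure(list(n_basins = n_basins,
                 conformers_per_basin = conformers_per_basin,
                 dft_energy_spread = dft_energy_spread,
                 within_rmsd = within_rmsd,
                 between_rmsd_min = between_rmsd_min,
                 xtb_bias_sd = xtb_bias_sd, xtb_min_gap = xtb_min_gap,
                 xtb_noise_sd = xtb_noise_sd, n_atoms = as.integer(n_atoms),
                 fraction_h = fraction_h, mirror_fraction = mirror_fraction,
                 seed = as.integer(seed)),
            class = "basin_spec")
}

rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

# Random rigid scaffold: Rh at the origin, two P donors, then carbons grown
# bond-by-bond and hydrogens attached last (the first carbon gets up to three
# so the scaffold always carries a proper stereocentre).
build_scaffold <- function(n_atoms, fraction_h) {
  for (attempt in 1:50) {
    n_extra <- n_atoms - 3L
    n_h <- round(n_extra * fraction_h)
    n_c <- n_extra - n_h
    elements <- c("Rh", "P", "P")
    th <- 87 * pi / 180
    coords <- rbind(c(0, 0, 0), c(2.3, 0, 0), 2.3 * c(cos(th), sin(th), 0))
    adj <- matrix(FALSE, n_atoms, n_atoms)
    adj[1, 2:3] <- adj[2:3, 1] <- TRUE
    deg_cap <- function(el) ifelse(el == "Rh", 6L, 4L)
    # every non-metal atom stays well clear of the metal's vdW sphere so the
    # cone-angle apex condition (distance > radius) holds with margin
    place <- function(parent, dist, min_sep, cur) {
      for (try in 1:300) {
        p <- cur$coords[parent, ] + dist * rand_unit()
        d <- sqrt(rowSums(sweep(cur$coords, 2, p)^2))
        if (min(d) >= min_sep && sqrt(sum(p^2)) >= 2.2) return(p)
      }
      NULL
    }
    cur <- list(elements = elements, coords = coords, adj = adj)
    ok <- TRUE
    for (i in seq_len(n_c)) {
      deg <- rowSums(cur$adj[seq_along(cur$elements),
                             seq_along(cur$elements), drop = FALSE])
      cand <- which(cur$elements %in% c("P", "C") &
                      deg < deg_cap(cur$elements))
      if (!length(cand)) { ok <- FALSE; break }
      parent <- if (length(cand) == 1L) cand else sample(cand, 1L)
      p <- place(parent, 1.52, 1.15, cur)
      if (is.null(p)) { ok <- FALSE; break }
      k <- length(cur$elements) + 1L
      cur$elements <- c(cur$elements, "C")
      cur$coords <- rbind(cur$coords, p)
      cur$adj[k, parent] <- cur$adj[parent, k] <- TRUE
    }
    if (!ok) next
    carbon_idx <- which(cur$elements == "C")
    for (i in seq_len(n_h)) {
      deg <- rowSums(cur$adj[seq_along(cur$elements),
                             seq_along(cur$elements), drop = FALSE])
      # saturate the first carbon before spreading hydrogens around
      first_open <- carbon_idx[deg[carbon_idx] < 4L]
      if (!length(first_open)) { ok <- FALSE; break }
      parent <- first_open[1]
      p <- place(parent, 1.09, 0.85, cur)
      if (is.null(p)) { ok <- FALSE; break }
      k <- length(cur$elements) + 1L
      cur$elements <- c(cur$elements, "H")
      cur$coords <- rbind(cur$coords, p)
      cur$adj[k, parent] <- cur$adj[parent, k] <- TRUE
    }
    if (!ok) next
    nat <- length(cur$elements)
    adj <- cur$adj[seq_len(nat), seq_len(nat)]
    # stereocentres must be decisively non-planar
    centers <- which(rowSums(adj) == 4L)
    planar <- any(vapply(centers, function(c) {
      nb <- which(adj[c, ])[1:3]
      abs(det(rbind(cur$coords[nb[1], ] - cur$coords[c, ],
                    cur$coords[nb[2], ] - cur$coords[c, ],
                    cur$coords[nb[3], ] - cur$coords[c, ]))) < 0.05
    }, logical(1)))
    if (planar) next
    dimnames(cur$coords) <- NULL
    return(list(elements = cur$elements, coords = cur$coords,
                connectivity = adj))
  }
  stop("failed to build a scaffold; relax n_atoms / fraction_h")
}

# Rescale a displacement until the realised heavy-atom Kabsch RMSD to `base`
# is within 2% of target. Displacement supplied as a function of scale.
rescale_to_rmsd <- function(base, displace, target, hv, max_iter = 40L) {
  scale <- 1
  for (i in seq_len(max_iter)) {
    cand <- displace(scale)
    if (is.null(cand) || any(!is.finite(cand))) {
      scale <- scale / 2           # overshoot into an invalid region: back off
      next
    }
    r <- kabsch_rmsd(base, cand, mask = hv)
    if (abs(r - target) <= 0.02 * target) return(cand)
    if (r < 1e-9) return(NULL)     # displacement has no effect at this scale
    scale <- scale * target / r
  }
  NULL
}

# distortions must not push any atom into the metal's cone-angle exclusion
# zone (apex strictly outside every vdW sphere)
clear_of_metal <- function(coords, elements) {
  d <- sqrt(rowSums(coords[-1, , drop = FALSE]^2))
  all(d > vdw_radius(elements[-1]) + 0.1)
}

chirality_signs <- function(coords, adj) {
  centers <- which(rowSums(adj) == 4L)
  vapply(centers, function(c) {
    nb <- which(adj[c, ])[1:3]
    det(rbind(coords[nb[1], ] - coords[c, ],
              coords[nb[2], ] - coords[c, ],
              coords[nb[3], ] - coords[c, ]))
  }, numeric(1))
}

#' Generate a synthetic basin-structured ensemble
#'
#' Builds a rigid scaffold, displaces copies of it into `n_basins` templates
#' whose pairwise heavy-atom RMSD stays above `between_rmsd_min` (smooth
#' orientation-preserving linear distortions, so no stereocentre ever flips
#' by accident), scatters conformers around each template at the target
#' within-basin RMSD, and assigns energies: high-level (DFT-like) energies
#' cluster tightly per basin, low-level (xTB-like) energies add a per-basin
#' offset and per-conformer noise so the two rankings decorrelate. An
#' optional fraction of conformers is reflected through the origin.
#'
#' @param spec A [basin_spec()].
#' @return A list of class `synthetic_ensemble`:
#'   `ensemble` (a [conformer_ensemble()] with connectivity, low-level
#'   energies in kJ/mol), `records` (a `dft_records` table), `truth` (a
#'   [minimum_assignment()] from the generator's bookkeeping), `basin`
#'   (per-conformer basin index in template order), `mirrored` (ids of
#'   reflected conformers), `templates`, `scaffold`, `spec`.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "basin_spec"))
  set.seed(spec$seed)
  scaf <- build_scaffold(spec$n_atoms, spec$fraction_h)
  hv <- which(scaf$elements != "H")
  nb <- spec$n_basins

  # basin templates by rejection sampling on pairwise RMSD
  templates <- NULL
  for (attempt in 1:100) {
    tpl <- list(scaf$coords)
    ok <- TRUE
    for (k in seq_len(nb - 1L)) {
      target <- spec$between_rmsd_min * (1 + 0.4 * (k - 1))
      made <- NULL
      for (try in 1:50) {
        A <- matrix(stats::rnorm(9, sd = 0.1), 3, 3)
        if (det(diag(3) + A) <= 0.05) next
        made <- rescale_to_rmsd(
          scaf$coords,
          function(s) {
            M <- diag(3) + s * A
            if (!is.finite(det(M)) || det(M) <= 0) return(NULL)
            scaf$coords %*% t(M)
          },
          target, hv
        )
        if (!is.null(made) && !clear_of_metal(made, scaf$elements))
          made <- NULL
        if (!is.null(made)) break
      }
      if (is.null(made)) { ok <- FALSE; break }
      tpl[[k + 1L]] <- made
    }
    if (!ok) next
    sep <- TRUE
    if (nb > 1L) {
      for (i in seq_len(nb - 1L)) {
        for (j in seq(i + 1L, nb)) {
          if (kabsch_rmsd(tpl[[i]], tpl[[j]], mask = hv) <
              spec$between_rmsd_min) {
            sep <- FALSE
          }
        }
      }
    }
    if (sep) { templates <- tpl; break }
  }
  if (is.null(templates))
    stop("could not realise the requested basin geometry; ",
         "relax between_rmsd_min or n_basins")

  size_range <- seq(spec$conformers_per_basin[1],
                    spec$conformers_per_basin[2])
  counts <- size_range[sample.int(length(size_range), nb, replace = TRUE)]
  n <- sum(counts)
  basin <- rep(seq_len(nb), counts)

  ref_signs <- chirality_signs(scaf$coords, scaf$connectivity)
  coords <- vector("list", n)
  for (i in seq_len(n)) {
    base <- templates[[basin[i]]]
    base_signs <- chirality_signs(base, scaf$connectivity)
    for (try in 1:100) {
      jit <- matrix(stats::rnorm(length(base)), nrow(base), 3)
      cand <- rescale_to_rmsd(base, function(s) base + s * jit,
                              spec$within_rmsd, hv)
      if (is.null(cand)) next
      s <- chirality_signs(cand, scaf$connectivity)
      if (all(abs(s) > 2e-3) && all(sign(s) == sign(base_signs)) &&
          clear_of_metal(cand, scaf$elements)) break
      cand <- NULL
    }
    if (is.null(cand))
      stop("could not realise within-basin jitter without touching a ",
           "stereocentre; reduce within_rmsd")
    coords[[i]] <- cand
  }

  anchors <- if (nb == 1L) 0 else
    seq(0, spec$dft_energy_spread, length.out = nb)
  e_dft <- anchors[basin] + stats::runif(n, 0, 1)

  bias <- rep(0, nb)
  if (spec$xtb_bias_sd > 0 && nb >= 1L) {
    for (try in 1:1000) {
      bias <- stats::rnorm(nb, sd = spec$xtb_bias_sd)
      shifted <- anchors + bias
      if (nb == 1L || min(dist(shifted)) >= spec$xtb_min_gap) break
      if (try == 1000) stop("could not separate low-level basin energies; ",
                            "lower xtb_min_gap or raise xtb_bias_sd")
    }
  }
  noise <- if (spec$xtb_noise_sd > 0) {
    z <- stats::rnorm(n)
    pmin(pmax(z, -2), 2) * spec$xtb_noise_sd
  } else rep(0, n)
  e_xtb <- e_dft + bias[basin] + noise

  mirrored_pos <- integer(0)
  n_mirror <- round(spec$mirror_fraction * n)
  if (n_mirror > 0L) {
    mirrored_pos <- sort(sample(n, n_mirror))
    for (i in mirrored_pos) coords[[i]] <- -coords[[i]]
  }

  ens <- conformer_ensemble(scaf$elements, coords, e_xtb,
                            connectivity = scaf$connectivity,
                            metal_index = 1L)
  records <- dft_records(conformer_index = ens$ids, converged = TRUE,
                         energy_high = e_dft, n_imaginary = 0L)

  # bookkeeping truth: label basins by ascending lowest high-level energy
  basin_min <- vapply(seq_len(nb), function(b) min(e_dft[basin == b]),
                      numeric(1))
  relabel <- order(basin_min)
  label_of <- match(seq_len(nb), relabel) - 1L
  truth <- minimum_assignment(
    stats::setNames(label_of[basin], ens$ids),
    sort(basin_min), window = 5.0
  )

  structure(list(ensemble = ens, records = records, truth = truth,
                 basin = basin, mirrored = ens$ids[mirrored_pos],
                 templates = templates, scaffold = scaf, spec = spec),
            class = "synthetic_ensemble")
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat(sprintf("synthetic_ensemble: %d conformers in %d basins (seed %d)\n",
              n_conformers(x$ensemble), x$spec$n_basins, x$spec$seed))
  if (length(x$mirrored))
    cat("  mirrored conformers:", paste(x$mirrored, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a multi-ensemble synthetic benchmark
#'
#' A suite of independent basin-structured ensembles with varying basin
#' counts and sizes, mimicking a screening campaign over many complexes.
#' Basin counts are drawn so most ensembles have one or two high-level
#' minima and a minority three or four.
#'
#' @param n_ensembles Number of ensembles (default 24).
#' @param seed Integer master seed; per-ensemble seeds derive from it.
#' @param ... Overrides passed to every [basin_spec()] call (e.g.
#'   `mirror_fraction`).
#' @return A list of `synthetic_ensemble` objects.
#' @export
generate_benchmark <- function(n_ensembles = 24L, seed = 1L, ...) {
  set.seed(seed)
  basins <- sample(1:4, n_ensembles, replace = TRUE,
                   prob = c(0.40, 0.30, 0.20, 0.10))
  seeds <- sample.int(.Machine$integer.max - 1L, n_ensembles)
  lapply(seq_len(n_ensembles), function(i) {
    generate_ensemble(basin_spec(n_basins = basins[i], seed = seeds[i], ...))
  })
}

#' Write a synthetic ensemble as a file fixture
#'
#' Serialises the generated objects through the same formats the readers
#' consume: a CREST-dialect multi-structure XYZ (energies in kJ/mol), an MDL
#' V2000 Molfile for connectivity, a CSV of DFT outcomes, and a CSV truth
#' table (`conformer_index,minimum_label`).
#'
#' @param x A `synthetic_ensemble`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(xyz = file.path(dir, "ensemble.xyz"),
             mol = file.path(dir, "complex.mol"),
             dft = file.path(dir, "dft.csv"),
             truth = file.path(dir, "truth.csv"))
  write_multi_xyz(x$ensemble, paths["xyz"], energy_unit = "kjmol")
  write_molfile(x$scaffold$elements, x$scaffold$coords,
                x$scaffold$connectivity, paths["mol"])
  df <- as.data.frame(x$records)
  utils::write.csv(df, paths["dft"], row.names = FALSE, quote = FALSE)
  truth_df <- data.frame(conformer_index = as.integer(names(x$truth$labels)),
                         minimum_label = unname(x$truth$labels))
  utils::write.csv(truth_df, paths["truth"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Write an MDL V2000 Molfile
#'
#' Minimal single-molecule writer: header, counts line, atom block, bond
#' block (all bond orders written as single bonds).
#'
#' @param elements Character vector of element symbols.
#' @param coords N x 3 coordinate matrix.
#' @param connectivity N x N logical adjacency.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_molfile <- function(elements, coords, connectivity, path) {
  n <- length(elements)
  bonds <- which(connectivity & upper.tri(connectivity), arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("synthetic complex", "  confsel", ""), con)
  writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     n, nrow(bonds)), con)
  writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     coords[, 1], coords[, 2], coords[, 3], elements), con)
  if (nrow(bonds))
    writeLines(sprintf("%3d%3d  1  0  0  0  0",
                       bonds[, 1], bonds[, 2]), con)
  writeLines("M  END", con)
  invisible(path)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Directory containing `ensemble.xyz`, `complex.mol`, `dft.csv`,
#'   `truth.csv`.
#' @return A list with `ensemble`, `records`, `truth`.
#' @export
read_fixture <- function(dir) {
  mol <- read_molfile_connectivity(file.path(dir, "complex.mol"))
  ens <- read_multi_xyz(file.path(dir, "ensemble.xyz"),
                        energy_unit = "kjmol",
                        connectivity = mol$connectivity)
  records <- read_dft_table(file.path(dir, "dft.csv"))
  truth_df <- utils::read.csv(file.path(dir, "truth.csv"))
  minima <- vapply(sort(unique(truth_df$minimum_label)), function(m) {
    ids <- truth_df$conformer_index[truth_df$minimum_label == m]
    min(records$energy_high[records$conformer_index %in% ids])
  }, numeric(1))
  truth <- minimum_assignment(
    stats::setNames(truth_df$minimum_label, truth_df$conformer_index),
    minima
  )
  list(ensemble = ens, records = records, truth = truth)
}
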
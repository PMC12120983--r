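# Conformer selection strategies: energy pruning, greedy RMSD pruning, the
# combined scheme, descriptor-extreme selection, PCA projection, and DBSCAN
# clustering on (relative energy, RMSD-to-reference).

#' Pruning thresholds
#'
#' @param energy_threshold Relative-energy cutoff in kJ/mol. The default
#'   12.55 kJ/mol is 3.0 kcal/mol.
#' @param rmsd_threshold Heavy-atom RMSD cutoff in Angstrom (default 0.35).
#' @return A list of class `pruning_config`.
#' @export
pruning_config <- function(energy_threshold = 12.55, rmsd_threshold = 0.35) {
  if (energy_threshold <= 0 || rmsd_threshold <= 0)
    stop("thresholds must be positive")
  structure(list(energy_threshold = energy_threshold,
                 rmsd_threshold = rmsd_threshold),
            class = "pruning_config")
}

#' DBSCAN clustering parameters
#'
#' @param epsilon Neighbourhood radius in the (standardized) feature space.
#' @param min_samples Minimum neighbourhood size (point included) for a core
#'   point; the default 2 means any point with one neighbour is core.
#' @param standardize Standardize each feature to zero mean, unit variance
#'   over the ensemble before clustering (default `TRUE`).
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(epsilon, min_samples = 2L, standardize = TRUE) {
  if (epsilon <= 0) stop("epsilon must be positive")
  min_samples <- as.integer(min_samples)
  if (min_samples < 2L) stop("min_samples must be at least 2")
  structure(list(epsilon = epsilon, min_samples = min_samples,
                 standardize = isTRUE(standardize)),
            class = "cluster_config")
}

#' Construct a selection result
#'
#' A partition of the conformer ids into a selected subset and its
#' complement, with provenance.
#'
#' @param method Name of the selection method.
#' @param parameters Named list of parameters the method was run with.
#' @param selected Integer ids of the kept conformers.
#' @param eliminated Integer ids of the removed conformers.
#' @param cluster_labels Optional integer vector of per-conformer cluster
#'   labels in ensemble order (`-1` = noise).
#' @return A list of class `selection_result`.
#' @export
selection_result <- function(method, parameters, selected, eliminated,
                             cluster_labels = NULL) {
  selected <- as.integer(selected)
  eliminated <- as.integer(eliminated)
  if (length(intersect(selected, eliminated)))
    stop("selected and eliminated sets overlap")
  structure(list(method = as.character(method), parameters = parameters,
                 selected = selected, eliminated = eliminated,
                 cluster_labels = cluster_labels),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  n <- length(x$selected) + length(x$eliminated)
  cat(sprintf("selection_result [%s]: %d of %d conformers selected\n",
              x$method, length(x$selected), n))
  if (length(x$parameters))
    cat("  parameters:",
        paste(names(x$parameters),
              vapply(x$parameters, function(p) paste(format(p), collapse = ","),
                     character(1)),
              sep = "=", collapse = ", "), "\n")
  if (!is.null(x$cluster_labels)) {
    k <- length(unique(x$cluster_labels[x$cluster_labels >= 0]))
    cat(sprintf("  clusters: %d, noise points: %d\n", k,
                sum(x$cluster_labels < 0)))
  }
  invisible(x)
}

#' Energy pruning
#'
#' Keeps conformers whose low-level relative energy does not exceed the
#' threshold; the boundary value itself is kept.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param config A [pruning_config()].
#' @return A [selection_result()].
#' @export
prune_energy <- function(ensemble, config = pruning_config()) {
  keep <- ensemble$rel_energy <= config$energy_threshold
  selection_result("energy",
                   list(energy_threshold = config$energy_threshold),
                   ensemble$ids[keep], ensemble$ids[!keep])
}

#' Greedy RMSD pruning
#'
#' Walks the conformers in ascending relative-energy order and keeps one only
#' if its heavy-atom Kabsch RMSD to every already-kept conformer exceeds the
#' threshold; geometric near-duplicates of any kept conformer are eliminated.
#' The lowest-energy conformer is always kept.
#'
#' @inheritParams prune_energy
#' @return A [selection_result()].
#' @export
prune_rmsd <- function(ensemble, config = pruning_config()) {
  n <- n_conformers(ensemble)
  hv <- heavy_atoms(ensemble$elements)
  ord <- order(ensemble$rel_energy, seq_len(n))
  kept <- integer(0)
  for (pos in ord) {
    dup <- FALSE
    for (kp in kept) {
      if (kabsch_rmsd(ensemble$coords[[kp]], ensemble$coords[[pos]],
                      mask = hv) <= config$rmsd_threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, pos)
  }
  keep <- seq_len(n) %in% kept
  selection_result("rmsd", list(rmsd_threshold = config$rmsd_threshold),
                   ensemble$ids[keep], ensemble$ids[!keep])
}

#' Combined energy + RMSD pruning
#'
#' Energy pruning first, then greedy RMSD pruning restricted to the
#' energy-surviving conformers.
#'
#' @inheritParams prune_energy
#' @return A [selection_result()].
#' @export
prune_combined <- function(ensemble, config = pruning_config()) {
  en <- prune_energy(ensemble, config)
  surv_pos <- which(ensemble$ids %in% en$selected)
  sub <- ensemble[surv_pos]
  rm <- prune_rmsd(sub, config)
  selected <- rm$selected
  selection_result("combined",
                   list(energy_threshold = config$energy_threshold,
                        rmsd_threshold = config$rmsd_threshold),
                   selected, setdiff(ensemble$ids, selected))
}

#' Descriptor-extreme selection
#'
#' Selects, among the candidate conformers, those with the minimum and
#' maximum percent buried volume and the minimum and maximum cone angle
#' (at most four; fewer when extremes coincide). Ties go to the lowest
#' conformer index. Conformers outside the candidate set -- e.g. removed by a
#' pruning stage -- count as eliminated.
#'
#' @param rows A [descriptor_table()] covering the full ensemble.
#' @param candidates Integer ids of candidate conformers (e.g. the
#'   `selected` set of a pruning step); defaults to all rows.
#' @return A [selection_result()].
#' @export
select_extremes <- function(rows, candidates = NULL) {
  if (is.null(candidates)) candidates <- rows$conformer_index
  if (length(candidates) == 0L) stop("empty candidate set")
  sub <- rows[rows$conformer_index %in% candidates, , drop = FALSE]
  if (nrow(sub) == 0L) stop("descriptor rows do not cover the candidate set")
  sub <- sub[order(sub$conformer_index), , drop = FALSE]  # tie -> lowest id
  pick <- function(col, fun) sub$conformer_index[fun(col)]
  selected <- sort(unique(c(
    pick(sub$buried_volume_pct, which.min),
    pick(sub$buried_volume_pct, which.max),
    pick(sub$cone_angle, which.min),
    pick(sub$cone_angle, which.max)
  )))
  universe <- rows$conformer_index
  selection_result("extremes", list(descriptors = c("buried_volume_pct",
                                                    "cone_angle")),
                   selected, setdiff(universe, selected))
}

#' Two-component PCA projection of a descriptor matrix
#'
#' Standardizes each feature to zero mean and unit variance (constant
#' features are dropped and recorded), performs principal component analysis,
#' and returns the first two component scores. Component signs follow the
#' convention that each component's largest-magnitude loading is positive.
#'
#' @param x Numeric matrix or data.frame; rows are conformers, columns are
#'   descriptors (typically including the RMSD-to-reference column).
#' @return A list of class `pca_projection`: `scores` (n x 2), `explained`
#'   (variance fractions of the first two components), `loadings` (p x 2),
#'   `dropped` (names of constant features removed).
#' @export
pca_project <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("descriptor matrix must be numeric")
  if (nrow(x) < 2L) stop("at least 2 conformers required")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0 | !is.finite(sds)]
  keep <- which(sds > 0 & is.finite(sds))
  if (length(keep) < 2L)
    stop("fewer than 2 non-constant features")
  p <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  k <- min(2L, ncol(p$rotation))
  scores <- matrix(0, nrow(x), 2L)
  loadings <- matrix(0, length(keep), 2L,
                     dimnames = list(colnames(x)[keep], c("PC1", "PC2")))
  explained <- c(0, 0)
  tot <- sum(p$sdev^2)
  for (j in seq_len(k)) {
    v <- p$rotation[, j]
    s <- p$x[, j]
    flip <- v[which.max(abs(v))] < 0
    if (flip) {
      v <- -v
      s <- -s
    }
    scores[, j] <- s
    loadings[, j] <- v
    explained[j] <- p$sdev[j]^2 / tot
  }
  colnames(scores) <- c("PC1", "PC2")
  structure(list(scores = scores, explained = explained,
                 loadings = loadings, dropped = dropped),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("pca_projection: %d points; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$explained[1], 100 * x$explained[2]))
  if (length(x$dropped))
    cat("  constant features dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Euclidean DBSCAN
#'
#' Density-based clustering: a point is core when at least `min_samples`
#' points (itself included) lie within `eps`; clusters are the connected
#' components of the core points under the eps-neighbour relation, plus the
#' non-core (border) points within eps of a core point. Border points
#' reachable from several clusters are claimed by the cluster whose lowest
#' core-point index is smallest, matching the classic seed-order expansion.
#' Remaining points are noise.
#'
#' @param x Numeric matrix of points (rows).
#' @param eps Neighbourhood radius (boundary inclusive).
#' @param min_samples Minimum neighbourhood size for a core point.
#' @return Integer vector of cluster labels, `0, 1, 2, ...` in order of each
#'   cluster's lowest core-point index; `-1` marks noise.
#' @export
dbscan_cluster <- function(x, eps, min_samples = 2L) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  nb <- d <= eps
  core <- rowSums(nb) >= min_samples
  labels <- rep(-1L, n)
  comp <- rep(NA_integer_, n)
  next_lab <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(comp[i])) next
    # BFS over core points connected through eps-neighbourhoods
    queue <- i
    comp[i] <- next_lab
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      reach <- which(nb[cur, ] & core & is.na(comp))
      comp[reach] <- next_lab
      queue <- c(queue, reach)
    }
    next_lab <- next_lab + 1L
  }
  labels[core] <- comp[core]
  # border points: claimed by the earliest-seeded cluster that reaches them
  for (i in which(!core)) {
    cand <- comp[nb[i, ] & core]
    if (length(cand)) labels[i] <- min(cand)
  }
  labels
}

#' DBSCAN-based conformer selection
#'
#' Clusters the conformers in the two-dimensional feature space of
#' (relative low-level energy, heavy-atom RMSD to the reference conformer),
#' each feature standardized over the ensemble, and keeps one representative
#' per cluster -- its lowest-energy member -- together with every noise
#' point, so sparse regions of the feature space are never discarded.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param config A [cluster_config()].
#' @param features Optional pre-scaled n x 2 feature matrix overriding the
#'   default (standardized over this ensemble alone); used by
#'   [epsilon_sweep()] to share one feature scale across many ensembles.
#' @return A [selection_result()] with per-conformer `cluster_labels`
#'   (`-1` = noise).
#' @export
dbscan_select <- function(ensemble, config, features = NULL) {
  stopifnot(inherits(config, "cluster_config"))
  if (is.null(features)) {
    feats <- cbind(rel_energy = ensemble$rel_energy,
                   rmsd_ref = ensemble$rmsd_ref)
    if (config$standardize) {
      feats <- apply(feats, 2, function(col) {
        s <- stats::sd(col)
        if (!is.finite(s) || s == 0) rep(0, length(col))
        else (col - mean(col)) / s
      })
      feats <- matrix(feats, ncol = 2L)
    }
  } else {
    feats <- as.matrix(features)
    if (nrow(feats) != n_conformers(ensemble))
      stop("features must have one row per conformer")
  }
  labels <- dbscan_cluster(feats, config$epsilon, config$min_samples)
  n <- n_conformers(ensemble)
  keep <- labels < 0L   # noise always retained
  for (lab in unique(labels[labels >= 0L])) {
    members <- which(labels == lab)
    rep_pos <- members[order(ensemble$rel_energy[members], members)[1]]
    keep[rep_pos] <- TRUE
  }
  selection_result("dbscan",
                   list(epsilon = config$epsilon,
                        min_samples = config$min_samples,
                        standardize = config$standardize),
                   ensemble$ids[keep], ensemble$ids[!keep],
                   cluster_labels = labels)
}
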
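# Selection strategies: pruning, extremes, PCA, DBSCAN.

three_family_ensemble <- function(seed = 71) {
  # three tight geometric families, far apart, energies interleaved
  x <- generate_ensemble(basin_spec(n_basins = 3,
                                    conformers_per_basin = c(4, 4),
                                    within_rmsd = 0.05,
                                    between_rmsd_min = 1.2, seed = seed))
  x
}

test_that("energy pruning keeps everything at or below the threshold", {
  a <- skeleton5()
  el <- c("Rh", "P", "P", "C", "C")
  ens <- ens_from_coords(list(a, a + 0.5, a + 1), el, c(0, 5, 13))
  sel <- prune_energy(ens)
  expect_equal(sort(sel$selected), c(1L, 2L))
  expect_equal(sort(sel$eliminated), 3L)

  # boundary value is kept
  ens_b <- ens_from_coords(list(a, a + 0.5), el, c(0, 12.55))
  expect_equal(sort(prune_energy(ens_b)$selected), c(1L, 2L))

  ens_0 <- ens_from_coords(list(a, a + 0.5, a + 1), el, c(0, 0, 0))
  expect_equal(sort(prune_energy(ens_0)$selected), 1:3)
})

test_that("rmsd pruning eliminates geometric duplicates greedily", {
  a <- skeleton5()
  el <- c("Rh", "P", "P", "C", "C")
  # exact duplicate of the reference is pruned
  ens <- ens_from_coords(list(a, a), el, c(0, 3))
  sel <- prune_rmsd(ens)
  expect_equal(sel$selected, 1L)
  expect_equal(sel$eliminated, 2L)

  # two genuinely different geometries both survive
  b <- a
  b[4, ] <- b[4, ] + c(3, 0, 0)
  expect_gt(kabsch_rmsd(a, b), 0.5)
  ens2 <- ens_from_coords(list(a, b), el, c(0, 3))
  expect_equal(sort(prune_rmsd(ens2)$selected), c(1L, 2L))

  # three tight families collapse to exactly three representatives
  x <- three_family_ensemble()
  sel3 <- prune_rmsd(x$ensemble, pruning_config(rmsd_threshold = 0.35))
  expect_equal(length(sel3$selected), 3L)
  # one representative per family, verified against generator bookkeeping
  fam <- x$basin[match(sel3$selected, x$ensemble$ids)]
  expect_equal(sort(fam), 1:3)
  # exhaustive check of the greedy invariant: no two selected conformers
  # are within the threshold of each other
  pr <- pairwise_rmsd(x$ensemble)
  pos <- match(sel3$selected, x$ensemble$ids)
  off <- pr[pos, pos][upper.tri(diag(length(pos)))]
  expect_true(all(off > 0.35))
})

test_that("pruning always retains the lowest-energy conformer", {
  for (seed in 81:84) {
    x <- generate_ensemble(basin_spec(n_basins = 2, seed = seed))
    ref_id <- x$ensemble$ids[x$ensemble$reference_index]
    for (sel in list(prune_energy(x$ensemble), prune_rmsd(x$ensemble),
                     prune_combined(x$ensemble))) {
      expect_true(ref_id %in% sel$selected)
      # the selected/eliminated sets partition the ensemble
      expect_setequal(c(sel$selected, sel$eliminated), x$ensemble$ids)
      expect_length(intersect(sel$selected, sel$eliminated), 0L)
    }
  }
})

test_that("energy pruning is monotone in its threshold", {
  x <- generate_ensemble(basin_spec(n_basins = 3, seed = 85))
  prev <- integer(0)
  for (th in c(2, 5, 10, 20, 40)) {
    cur <- prune_energy(x$ensemble, pruning_config(energy_threshold = th))
    expect_true(all(prev %in% cur$selected))
    prev <- cur$selected
  }
  # rmsd pruning: larger threshold never keeps more
  n_prev <- Inf
  for (th in c(0.05, 0.2, 0.5, 1.5)) {
    n_cur <- length(prune_rmsd(x$ensemble,
                               pruning_config(rmsd_threshold = th))$selected)
    expect_lte(n_cur, n_prev)
    n_prev <- n_cur
  }
})

test_that("combined pruning is energy-then-rmsd intersection", {
  x <- generate_ensemble(basin_spec(n_basins = 2, xtb_bias_sd = 15,
                                    seed = 86))
  cfg <- pruning_config()
  en <- prune_energy(x$ensemble, cfg)
  comb <- prune_combined(x$ensemble, cfg)
  expect_true(all(comb$selected %in% en$selected))
  expect_lte(length(comb$selected), length(en$selected))
  expect_lte(length(comb$selected),
             length(prune_rmsd(x$ensemble, cfg)$selected))
  # nothing above the energy cutoff can sneak back in
  above <- x$ensemble$ids[x$ensemble$rel_energy > cfg$energy_threshold]
  expect_length(intersect(comb$selected, above), 0L)
})

test_that("descriptor extremes select min/max of both descriptors", {
  rows <- data.frame(conformer_index = 1:3,
                     buried_volume_pct = c(10, 20, 30),
                     cone_angle = c(90, 80, 100))
  class(rows) <- c("descriptor_table", "data.frame")
  sel <- select_extremes(rows)
  expect_equal(sel$selected, 1:3)  # {1,3} volume, {2,3} cone

  # a single candidate: all four extremes coincide on it
  one <- select_extremes(rows, candidates = 2L)
  expect_equal(one$selected, 2L)
  expect_setequal(one$eliminated, c(1L, 3L))

  # ties go to the lowest conformer index
  tied <- data.frame(conformer_index = 1:3,
                     buried_volume_pct = c(5, 9, 9),
                     cone_angle = c(100, 100, 100))
  expect_equal(select_extremes(tied)$selected, c(1L, 2L))

  # candidates restrict selection; non-candidates count as eliminated
  sub <- select_extremes(rows, candidates = c(1, 2))
  expect_true(all(sub$selected %in% c(1L, 2L)))
  expect_true(3L %in% sub$eliminated)

  expect_error(select_extremes(rows, candidates = integer(0)), "empty")
})

test_that("pca projection standardizes, orders and signs components", {
  # rank-1: two perfectly correlated features
  x1 <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  p1 <- pca_project(x1)
  expect_equal(p1$explained[1], 1, tolerance = 1e-10)
  expect_equal(p1$explained[2], 0, tolerance = 1e-10)

  # symmetric square: isotropic, 50/50 split
  sq <- cbind(c(1, -1, -1, 1), c(1, 1, -1, -1))
  p2 <- pca_project(sq)
  expect_equal(p2$explained, c(0.5, 0.5), tolerance = 1e-10)

  # random matrix: scores match an SVD route up to sign
  set.seed(301)
  x3 <- matrix(rnorm(50), 10, 5)
  p3 <- pca_project(x3)
  z <- scale(x3)
  sv <- svd(z)
  ref_scores <- sv$u[, 1:2] %*% diag(sv$d[1:2])
  for (j in 1:2) {
    expect_equal(abs(p3$scores[, j]), abs(ref_scores[, j]), tolerance = 1e-8)
    expect_equal(p3$explained[j], sv$d[j]^2 / sum(sv$d^2), tolerance = 1e-10)
    # sign convention: dominant loading positive
    expect_gt(p3$loadings[which.max(abs(p3$loadings[, j])), j], 0)
  }

  # constant features are dropped and reported
  x4 <- cbind(k = rep(1, 5), a = rnorm(5), b = rnorm(5))
  expect_equal(pca_project(x4)$dropped, "k")
  expect_error(pca_project(cbind(rep(1, 4), rnorm(4))), "non-constant")
})

test_that("dbscan clustering agrees with textbook dbscan on random instances", {
  set.seed(302)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    pts <- matrix(rnorm(2 * n, sd = sample(c(0.3, 1, 3), 1)), n, 2)
    eps <- runif(1, 0.1, 1.5)
    minp <- sample(2:4, 1)
    mine <- dbscan_cluster(pts, eps, minp)
    ref <- oracle_textbook_dbscan(pts, eps, minp)
    # identical partition into clusters and noise
    expect_equal(mine, ref)
  }
})

test_that("dbscan selection keeps one representative per cluster plus noise", {
  # 7 points: two tight pairs-of-three and one isolated point
  pts <- rbind(c(0, 0), c(0.05, 0), c(0, 0.05),
               c(5, 5), c(5.05, 5), c(5, 5.05),
               c(10, 0))
  labels <- dbscan_cluster(pts, eps = 0.5, min_samples = 2)
  expect_equal(sort(unique(labels)), c(-1L, 0L, 1L))
  sel_ids <- dbscan_selection_from_labels(labels, rel_energy = 1:7, ids = 1:7)
  expect_equal(sel_ids, c(1L, 4L, 7L))  # two representatives + the outlier

  # through the full ensemble interface with standardization
  x <- generate_ensemble(basin_spec(n_basins = 2, seed = 99))
  cfg <- cluster_config(epsilon = 0.4)
  sel <- dbscan_select(x$ensemble, cfg)
  expect_setequal(c(sel$selected, sel$eliminated), x$ensemble$ids)
  labs <- sel$cluster_labels
  for (lab in unique(labs[labs >= 0])) {
    members <- which(labs == lab)
    expect_gte(length(members), cfg$min_samples)
    chosen <- intersect(x$ensemble$ids[members], sel$selected)
    expect_length(chosen, 1L)
    # representative is the cluster's lowest-energy member
    expect_equal(min(x$ensemble$rel_energy[members]),
                 x$ensemble$rel_energy[match(chosen, x$ensemble$ids)])
  }
  expect_true(all(x$ensemble$ids[labs < 0] %in% sel$selected))
})

test_that("dbscan selection limits behave as the clustering limits dictate", {
  x <- generate_ensemble(basin_spec(n_basins = 2, seed = 100))
  n <- n_conformers(x$ensemble)
  # epsilon -> 0: everything is noise, everything selected
  tiny <- dbscan_select(x$ensemble, cluster_config(1e-9))
  expect_equal(sort(tiny$selected), sort(x$ensemble$ids))
  expect_true(all(tiny$cluster_labels == -1L))
  # epsilon beyond the data diameter: one cluster, one representative
  huge <- dbscan_select(x$ensemble, cluster_config(1e4))
  expect_length(huge$selected, 1L)
  expect_equal(huge$selected, x$ensemble$ids[x$ensemble$reference_index])

  # single-conformer ensemble: the conformer is noise but selected
  one <- x$ensemble[1]
  sel1 <- dbscan_select(one, cluster_config(0.2))
  expect_equal(sel1$selected, one$ids)
  expect_equal(sel1$cluster_labels, -1L)

  # once every point is clustered, growing epsilon can only merge clusters
  k_prev <- Inf
  for (eps in c(0.5, 1, 2, 5, 20)) {
    sel <- dbscan_select(x$ensemble, cluster_config(eps))
    if (any(sel$cluster_labels < 0)) next
    k <- length(unique(sel$cluster_labels))
    expect_lte(k, k_prev)
    k_prev <- k
  }
})
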
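# Ground-truth grouping, confusion counts, sweeps and reports.

test_that("dft minima group greedily within the chemical-accuracy window", {
  rec <- dft_records(1:3, TRUE, c(0, 2, 10))
  g <- group_dft_minima(rec)
  expect_equal(n_minima(g), 2L)
  expect_equal(unname(g$labels[c("1", "2", "3")]), c(0L, 0L, 1L))
  expect_equal(g$minima, c(0, 10))

  # anchor convention: 8 is within 5 of 4 but not of the anchor 0
  g2 <- group_dft_minima(dft_records(1:3, TRUE, c(0, 4, 8)))
  expect_equal(n_minima(g2), 2L)
  expect_equal(unname(g2$labels[c("1", "2", "3")]), c(0L, 0L, 1L))

  g3 <- group_dft_minima(dft_records(1:4, TRUE, rep(3.3, 4)))
  expect_equal(n_minima(g3), 1L)

  # unconverged and imaginary-frequency records drop out of the universe
  rec4 <- dft_records(1:4, c(TRUE, FALSE, TRUE, TRUE), c(0, NA, 2, 9),
                      n_imaginary = c(0L, 0L, 0L, 1L))
  g4 <- group_dft_minima(rec4)
  expect_setequal(names(g4$labels), c("1", "3"))

  expect_error(group_dft_minima(dft_records(1, FALSE, NA)), "no converged")
})

test_that("grouping can rank by gibbs energy instead", {
  rec <- dft_records(1:2, TRUE, c(0, 1), gibbs = c(0, 20))
  expect_equal(n_minima(group_dft_minima(rec)), 1L)
  expect_equal(n_minima(group_dft_minima(rec, use_gibbs = TRUE)), 2L)
})

test_that("confusion reproduces the worked bookkeeping examples", {
  truth <- minimum_assignment(
    setNames(c(0L, 0L, 0L, 1L, 1L), 1:5), c(0, 10))
  sel <- function(s) selection_result("manual", list(), s,
                                      setdiff(1:5, s))
  cc <- confusion(sel(c(1, 4)), truth)
  expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(2L, 0L, 3L, 0L))

  cc2 <- confusion(sel(c(1, 2)), truth)
  expect_equal(c(cc2$tp, cc2$fp, cc2$tn, cc2$fn), c(1L, 1L, 2L, 1L))

  # selecting everything: TP = minima, FP = the rest
  cc3 <- confusion(sel(1:5), truth)
  expect_equal(c(cc3$tp, cc3$fp, cc3$tn, cc3$fn), c(2L, 3L, 0L, 0L))

  # selecting nothing: every minimum missed
  cc4 <- confusion(sel(integer(0)), truth)
  expect_equal(c(cc4$tp, cc4$fp, cc4$tn, cc4$fn), c(0L, 0L, 3L, 2L))

  bad <- selection_result("manual", list(), c(1L, 2L), c(3L, 4L))
  expect_error(confusion(bad, truth), "without a selection verdict")
})

test_that("confusion identities and brute-force agreement hold on random instances", {
  set.seed(501)
  for (i in 1:500) {
    n <- sample(2:25, 1)
    k <- sample(1:min(5, n), 1)
    raw <- sample(0:(k - 1), n, replace = TRUE)
    raw <- as.integer(factor(raw)) - 1L  # contiguous labels
    ids <- sort(sample(1:100, n))
    labels <- setNames(raw, ids)
    minima <- seq(0, by = 6, length.out = length(unique(raw)))
    truth <- minimum_assignment(labels, minima)
    s <- sample(ids, sample(0:n, 1))
    sel <- selection_result("manual", list(), s, setdiff(ids, s))
    cc <- confusion(sel, truth)
    # partition identities
    expect_equal(cc$tp + cc$fp, length(s))
    expect_equal(cc$tp + cc$fn, n_minima(truth))
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, n)
    # redundant/significant accounting
    expect_equal(cc$tn + cc$fp, n - n_minima(truth))
    # brute-force per-conformer application of the definitions
    ref <- oracle_confusion(s, labels)
    expect_equal(list(cc$tp, cc$fp, cc$tn, cc$fn),
                 list(ref$tp, ref$fp, ref$tn, ref$fn))
  }
})

test_that("labels must be contiguous and minima ascending", {
  expect_error(minimum_assignment(setNames(c(0L, 2L), 1:2), c(0, 1)),
               "contiguous")
  expect_error(minimum_assignment(setNames(c(0L, 1L), 1:2), c(5, 1)),
               "ascending")
})

test_that("growing a selection never hurts coverage", {
  set.seed(502)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    raw <- as.integer(factor(sample(0:2, n, replace = TRUE))) - 1L
    ids <- seq_len(n)
    truth <- minimum_assignment(setNames(raw, ids),
                                seq(0, by = 6,
                                    length.out = length(unique(raw))))
    s <- sample(ids, sample(0:(n - 1), 1))
    extra <- sample(setdiff(ids, s), 1)
    sel_small <- selection_result("m", list(), s, setdiff(ids, s))
    s2 <- c(s, extra)
    sel_big <- selection_result("m", list(), s2, setdiff(ids, s2))
    # adding a conformer never increases FN; removing never increases FP
    expect_lte(confusion(sel_big, truth)$fn, confusion(sel_small, truth)$fn)
    expect_lte(confusion(sel_small, truth)$fp, confusion(sel_big, truth)$fp)
  }
})

test_that("epsilon sweep aggregates confusion across ensembles", {
  bench <- lapply(c(601, 602), function(s)
    generate_ensemble(basin_spec(n_basins = 2, seed = s)))
  ens <- lapply(bench, `[[`, "ensemble")
  tr <- lapply(bench, `[[`, "truth")
  sw <- epsilon_sweep(ens, tr, grid = c(1e-9, 0.3, 1e4))
  expect_s3_class(sw, "epsilon_sweep")
  expect_equal(nrow(sw), 3L)
  # epsilon -> 0: all selected, nothing eliminated
  expect_equal(sw$tn[1], 0L)
  expect_equal(sw$fn[1], 0L)
  per <- attr(sw, "per_ensemble")
  expect_equal(nrow(per), 6L)
  expect_equal(sum(per$tn[per$epsilon == 0.3]), sw$tn[2])

  # epsilon -> infinity on single-minimum ensembles: TN = n - 1, FN = 0
  solo <- lapply(c(603, 604), function(s)
    generate_ensemble(basin_spec(n_basins = 1, seed = s)))
  sw1 <- epsilon_sweep(lapply(solo, `[[`, "ensemble"),
                       lapply(solo, `[[`, "truth"), grid = 1e4)
  n_tot <- sum(vapply(solo, function(x) n_conformers(x$ensemble), integer(1)))
  expect_equal(sw1$fn, 0L)
  expect_equal(sw1$tn, n_tot - 2L)
})

test_that("method report aggregates counts and lists missed minima", {
  bench <- lapply(c(605, 606, 607), function(s)
    generate_ensemble(basin_spec(n_basins = (s %% 3) + 1, seed = s)))
  ens <- lapply(bench, `[[`, "ensemble")
  tr <- lapply(bench, `[[`, "truth")
  rep <- method_report(ens, tr, cluster = cluster_config(0.3),
                       methods = c("energy", "rmsd", "combined", "dbscan"))
  expect_setequal(rep$counts$method, c("energy", "rmsd", "combined", "dbscan"))
  n_tot <- sum(vapply(ens, n_conformers, integer(1)))
  m_tot <- sum(vapply(tr, n_minima, integer(1)))
  for (r in seq_len(nrow(rep$counts))) {
    with(rep$counts[r, ], {
      expect_equal(tp + fp + tn + fn, n_tot)
      expect_equal(tp + fn, m_tot)
    })
  }
  expect_equal(rep$significant, m_tot)
  expect_equal(rep$redundant, n_tot - m_tot)
  # every missed row corresponds to an FN of its method
  if (nrow(rep$missed)) {
    fn_by_method <- table(rep$missed$method)
    for (m in names(fn_by_method)) {
      expect_equal(unname(fn_by_method[[m]]),
                   rep$counts$fn[rep$counts$method == m])
    }
  }
  # an ensemble whose conformers share one minimum can never be missed by a
  # non-empty selection
  one <- generate_ensemble(basin_spec(n_basins = 1, seed = 608))
  rep1 <- method_report(list(one$ensemble), list(one$truth))
  expect_equal(rep1$counts$fn, c(0L, 0L, 0L))
})
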
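# Ground-truth construction and scoring: grouping DFT-refined conformers
# into minima within a chemical-accuracy window, the confusion-matrix
# bookkeeping over selections, epsilon sweeps, and method comparison reports.

#' Construct a minimum assignment
#'
#' @param labels Named integer vector mapping conformer id (names) to a
#'   0-based minimum label.
#' @param minima Numeric vector of each minimum's lowest energy (kJ/mol),
#'   indexed by label + 1; must be ascending.
#' @param window Grouping window used (kJ/mol), for provenance.
#' @return A list of class `minimum_assignment`.
#' @export
minimum_assignment <- function(labels, minima, window = NA_real_) {
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (is.null(names(labels))) stop("labels must be named by conformer id")
  if (length(minima) == 0L) stop("at least one minimum required")
  if (is.unsorted(minima)) stop("minima energies must be ascending")
  lab_set <- sort(unique(labels))
  if (!identical(lab_set, seq_along(minima) - 1L))
    stop("labels must be contiguous 0..", length(minima) - 1L)
  structure(list(labels = labels, minima = as.numeric(minima),
                 window = window),
            class = "minimum_assignment")
}

#' @export
print.minimum_assignment <- function(x, ...) {
  cat(sprintf("minimum_assignment: %d conformers -> %d minima (window %s kJ/mol)\n",
              length(x$labels), length(x$minima),
              format(x$window)))
  invisible(x)
}

#' Number of distinct minima
#' @param truth A `minimum_assignment`.
#' @return Integer count.
#' @export
n_minima <- function(truth) length(truth$minima)

#' Group DFT-refined conformers into minima
#'
#' Converged conformers are sorted by ascending high-level energy and grouped
#' greedily: a conformer joins the current minimum if its energy lies within
#' the chemical-accuracy window of the group's anchor (its lowest member);
#' otherwise it starts a new minimum. Labels are 0-based in ascending energy
#' order. Records that did not converge, or that retain imaginary
#' frequencies, are excluded from the evaluable universe.
#'
#' @param records A `dft_records` data.frame (see [read_dft_table()]).
#' @param window Indistinguishability window in kJ/mol (default 5).
#' @param use_gibbs Rank and group by Gibbs energy instead of the electronic
#'   energy (requires a complete `gibbs` column on converged records).
#' @return A [minimum_assignment()].
#' @export
group_dft_minima <- function(records, window = 5.0, use_gibbs = FALSE) {
  ok <- records$converged & records$n_imaginary == 0L
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no converged records to group")
  e <- if (use_gibbs) rec$gibbs else rec$energy_high
  if (anyNA(e)) stop("missing energies on converged records")
  ord <- order(e, rec$conformer_index)
  rec <- rec[ord, , drop = FALSE]
  e <- e[ord]
  labels <- integer(nrow(rec))
  anchors <- e[1]
  cur <- 0L
  for (i in seq_along(e)[-1]) {
    if (e[i] - anchors[cur + 1L] <= window) {
      labels[i] <- cur
    } else {
      cur <- cur + 1L
      labels[i] <- cur
      anchors[cur + 1L] <- e[i]
    }
  }
  minimum_assignment(stats::setNames(labels, rec$conformer_index),
                     anchors, window = window)
}

#' Confusion counts for a conformer selection
#'
#' Scores a predicted subset against the DFT-minimum ground truth. Within
#' each minimum, one conformer is significant (needed to represent the
#' minimum) and the rest are redundant. A minimum with at least one selected
#' member contributes one true positive, its surplus selected members as
#' false positives, and its eliminated members as true negatives. A minimum
#' with no selected member contributes one false negative (the significant
#' conformer was wrongly eliminated) and its remaining members as true
#' negatives. Scoring is restricted to the evaluable universe: conformers
#' that carry a minimum label.
#'
#' @param selection A [selection_result()].
#' @param truth A [minimum_assignment()].
#' @return A list of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`,
#'   `n_minima`, `n_conformers`.
#' @export
confusion <- function(selection, truth) {
  universe <- as.integer(names(truth$labels))
  in_univ <- c(selection$selected, selection$eliminated)
  # conformers outside the evaluable universe (e.g. unconverged at DFT) are
  # ignored; conformers of the universe absent from the selection are an error
  missing <- setdiff(universe, in_univ)
  if (length(missing))
    stop("conformer(s) without a selection verdict: ",
         paste(missing, collapse = ", "))
  sel <- intersect(selection$selected, universe)
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (m in seq_len(n_minima(truth)) - 1L) {
    members <- universe[truth$labels[as.character(universe)] == m]
    s <- sum(members %in% sel)
    e <- length(members) - s
    if (s >= 1L) {
      tp <- tp + 1L
      fp <- fp + (s - 1L)
      tn <- tn + e
    } else {
      fn <- fn + 1L
      tn <- tn + (e - 1L)
    }
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 n_minima = n_minima(truth),
                 n_conformers = length(universe)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: TP %d  FP %d  TN %d  FN %d  (%d conformers, %d minima)\n",
              x$tp, x$fp, x$tn, x$fn, x$n_conformers, x$n_minima))
  invisible(x)
}

# elementwise sum of confusion counts
add_confusion <- function(a, b) {
  structure(list(tp = a$tp + b$tp, fp = a$fp + b$fp, tn = a$tn + b$tn,
                 fn = a$fn + b$fn, n_minima = a$n_minima + b$n_minima,
                 n_conformers = a$n_conformers + b$n_conformers),
            class = "confusion_counts")
}

# Standardize the (rel_energy, rmsd_ref) features of several ensembles with
# one pooled mean and standard deviation per feature, so a single epsilon
# means the same thing in every ensemble. Returns a list of feature matrices.
pooled_features <- function(ensembles) {
  feats <- lapply(ensembles, function(e)
    cbind(rel_energy = e$rel_energy, rmsd_ref = e$rmsd_ref))
  all_f <- do.call(rbind, feats)
  mu <- colMeans(all_f)
  s <- apply(all_f, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  lapply(feats, function(f) sweep(sweep(f, 2, mu), 2, s, "/"))
}

#' Sweep the DBSCAN radius over a benchmark of ensembles
#'
#' Runs [dbscan_select()] at each epsilon on every ensemble, scores each
#' selection against its ground truth, and aggregates the counts. By default
#' the (relative energy, RMSD) features of all ensembles are standardized
#' with one pooled mean and standard deviation per feature: a shared epsilon
#' presupposes a shared feature scale, and per-ensemble scaling would make
#' the same epsilon mean different things in a 5-conformer and a
#' 50-conformer ensemble.
#'
#' @param ensembles List of `conformer_ensemble` objects.
#' @param truths List of matching [minimum_assignment()] objects.
#' @param grid Numeric vector of epsilon values.
#' @param min_samples Passed to [cluster_config()].
#' @param scale `"pooled"` (default): one standardization across all
#'   ensembles; `"ensemble"`: standardize each ensemble on its own.
#' @return A data.frame of class `epsilon_sweep` with columns `epsilon`,
#'   `tp`, `fp`, `tn`, `fn`; attribute `"per_ensemble"` holds the breakdown.
#' @export
epsilon_sweep <- function(ensembles, truths, grid, min_samples = 2L,
                          scale = c("pooled", "ensemble")) {
  scale <- match.arg(scale)
  if (length(grid) == 0L) stop("empty epsilon grid")
  if (length(ensembles) != length(truths))
    stop("one truth per ensemble required")
  feats <- if (scale == "pooled") pooled_features(ensembles) else
    vector("list", length(ensembles))
  rows <- vector("list", length(grid))
  detail <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    eps <- grid[g]
    cfg <- cluster_config(eps, min_samples)
    agg <- structure(list(tp = 0L, fp = 0L, tn = 0L, fn = 0L,
                          n_minima = 0L, n_conformers = 0L),
                     class = "confusion_counts")
    per <- vector("list", length(ensembles))
    for (i in seq_along(ensembles)) {
      cc <- confusion(dbscan_select(ensembles[[i]], cfg,
                                    features = feats[[i]]),
                      truths[[i]])
      per[[i]] <- data.frame(epsilon = eps, ensemble = i, tp = cc$tp,
                             fp = cc$fp, tn = cc$tn, fn = cc$fn)
      agg <- add_confusion(agg, cc)
    }
    rows[[g]] <- data.frame(epsilon = eps, tp = agg$tp, fp = agg$fp,
                            tn = agg$tn, fn = agg$fn)
    detail[[g]] <- do.call(rbind, per)
  }
  out <- do.call(rbind, rows)
  attr(out, "per_ensemble") <- do.call(rbind, detail)
  class(out) <- c("epsilon_sweep", "data.frame")
  out
}

#' @export
plot.epsilon_sweep <- function(x, ...) {
  fn_levels <- sort(unique(x$fn))
  cols <- grDevices::hcl.colors(max(2L, length(fn_levels)), "Dark 3")
  col <- cols[match(x$fn, fn_levels)]
  graphics::plot(x$epsilon, x$tn, pch = 19, col = col,
                 xlab = expression(epsilon),
                 ylab = "true negatives (redundant conformers removed)", ...)
  graphics::legend("bottomright", legend = paste("FN =", fn_levels),
                   col = cols[seq_along(fn_levels)], pch = 19, bty = "n")
  invisible(x)
}

#' Compare selection methods on a benchmark
#'
#' Runs the pruning strategies (and optionally DBSCAN) over a set of
#' ensembles, aggregates confusion counts per method, and lists every missed
#' minimum (ensemble, minimum label, energy rank of the minimum).
#'
#' @param ensembles List of `conformer_ensemble` objects.
#' @param truths List of matching [minimum_assignment()] objects.
#' @param pruning A [pruning_config()].
#' @param cluster Optional [cluster_config()]; adds a `"dbscan"` row.
#' @param methods Character vector among `"energy"`, `"rmsd"`, `"combined"`,
#'   `"dbscan"`.
#' @param scale Feature scaling for the `"dbscan"` method; see
#'   [epsilon_sweep()].
#' @return A list of class `method_report`: `counts` (one aggregated
#'   confusion row per method), `missed` (data.frame of missed minima),
#'   `redundant` and `significant` totals.
#' @export
method_report <- function(ensembles, truths, pruning = pruning_config(),
                          cluster = NULL,
                          methods = c("energy", "rmsd", "combined"),
                          scale = c("pooled", "ensemble")) {
  methods <- match.arg(methods, c("energy", "rmsd", "combined", "dbscan"),
                       several.ok = TRUE)
  scale <- match.arg(scale)
  if ("dbscan" %in% methods && is.null(cluster))
    stop("dbscan method requires a cluster_config")
  feats <- if ("dbscan" %in% methods && scale == "pooled")
    pooled_features(ensembles) else vector("list", length(ensembles))
  run <- function(method, i) {
    ens <- ensembles[[i]]
    switch(method,
      energy = prune_energy(ens, pruning),
      rmsd = prune_rmsd(ens, pruning),
      combined = prune_combined(ens, pruning),
      dbscan = dbscan_select(ens, cluster, features = feats[[i]])
    )
  }
  counts <- list()
  missed <- list()
  for (method in methods) {
    agg <- structure(list(tp = 0L, fp = 0L, tn = 0L, fn = 0L,
                          n_minima = 0L, n_conformers = 0L),
                     class = "confusion_counts")
    for (i in seq_along(ensembles)) {
      sel <- run(method, i)
      truth <- truths[[i]]
      cc <- confusion(sel, truth)
      agg <- add_confusion(agg, cc)
      universe <- as.integer(names(truth$labels))
      for (m in seq_len(n_minima(truth)) - 1L) {
        members <- universe[truth$labels[as.character(universe)] == m]
        if (!any(members %in% sel$selected)) {
          missed[[length(missed) + 1L]] <-
            data.frame(method = method, ensemble = i, minimum_label = m,
                       energy_rank = m,
                       minimum_energy = truth$minima[m + 1L])
        }
      }
    }
    counts[[method]] <- data.frame(method = method, tp = agg$tp, fp = agg$fp,
                                   tn = agg$tn, fn = agg$fn,
                                   n_minima = agg$n_minima,
                                   n_conformers = agg$n_conformers)
  }
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL
  missed <- if (length(missed)) do.call(rbind, missed) else
    data.frame(method = character(0), ensemble = integer(0),
               minimum_label = integer(0), energy_rank = integer(0),
               minimum_energy = numeric(0))
  structure(list(counts = counts, missed = missed,
                 significant = sum(vapply(truths, n_minima, integer(1))),
                 redundant = sum(vapply(truths, function(t)
                   length(t$labels) - n_minima(t), integer(1)))),
            class = "method_report")
}

#' @export
print.method_report <- function(x, ...) {
  cat(sprintf("method_report: %d significant / %d redundant conformers\n",
              x$significant, x$redundant))
  print(x$counts, row.names = FALSE)
  if (nrow(x$missed)) {
    cat("missed minima:\n")
    print(x$missed, row.names = FALSE)
  } else {
    cat("no minima missed by any method\n")
  }
  invisible(x)
}
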
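#' Log2-fold-change trajectories relative to uninjured controls
#'
#' Per protein and timepoint, the mean log2 abundance of injured samples at
#' that timepoint minus the mean over control samples, computed on observed
#' values. Proteins never observed in the controls are dropped with a
#' warning; remaining missing cells (a protein unobserved at one timepoint)
#' are filled with 0 (no evidence of change) so the trajectory matrix is
#' complete, as downstream clustering requires.
#'
#' @param m an [abundance_matrix()].
#' @param samples sample metadata matching `m`; needs `group`,
#'   `timepoint_h` and (if present) `injured` columns.
#' @param control_group label of the uninjured control/sham group.
#' @param timepoints timepoints to include (default: all post-injury
#'   timepoints with injured samples).
#' @return `trajectory_matrix`: proteins x timepoints numeric matrix.
#' @export
logfc_trajectories <- function(m, samples, control_group,
                               timepoints = NULL) {
  m <- subset_to_samples(m, samples)
  is_ctrl <- samples$group == control_group
  if ("injured" %in% names(samples)) is_ctrl <- is_ctrl | samples$injured == 0
  assert_that(any(is_ctrl), "control group `%s` is empty", control_group)
  inj <- !is_ctrl
  if (is.null(timepoints)) {
    timepoints <- sort(unique(samples$timepoint_h[inj]))
  }
  vals <- unclass(m)
  ctrl_mean <- rowMeans(vals[, is_ctrl, drop = FALSE], na.rm = TRUE)
  seen_ctrl <- is.finite(ctrl_mean)
  if (!all(seen_ctrl)) {
    warning(sprintf("logfc_trajectories: dropping %d protein(s) unobserved in controls",
                    sum(!seen_ctrl)))
  }
  out <- matrix(NA_real_, sum(seen_ctrl), length(timepoints),
                dimnames = list(rownames(vals)[seen_ctrl], as.character(timepoints)))
  for (j in seq_along(timepoints)) {
    sel <- inj & samples$timepoint_h == timepoints[j]
    assert_that(any(sel), "no injured samples at timepoint %s", timepoints[j])
    out[, j] <- rowMeans(vals[seen_ctrl, sel, drop = FALSE], na.rm = TRUE) -
      ctrl_mean[seen_ctrl]
  }
  out[!is.finite(out)] <- 0
  structure(out, class = c("trajectory_matrix", "matrix", "array"))
}

#' k-means consensus clustering with CDF-area model selection
#'
#' For each k in `k_range`, repeatedly subsamples `item_fraction` of the
#' proteins, runs k-means (Euclidean distance, `n_starts` restarts, best
#' inertia kept), and accumulates a consensus matrix whose `(i, j)` entry is
#' the fraction of co-sampled runs in which proteins i and j co-clustered.
#' The per-k assignment is obtained by average-linkage agglomeration of
#' `1 - consensus`; the direct k-means labels are discarded. Model selection
#' follows the consensus-CDF criterion: `cdf_area(k)` is the area under the
#' empirical CDF of the off-diagonal consensus entries, `delta_area(k)` its
#' relative increase, and `chosen_k` the largest k reached before the
#' relative increase falls below `elbow_tol`.
#'
#' @param traj a [logfc_trajectories()] matrix (proteins x timepoints).
#' @param k_range integer cluster numbers to evaluate, within
#'   `[2, n_proteins - 1]`.
#' @param n_subsamples number of subsampled k-means runs per k.
#' @param item_fraction fraction of proteins drawn per run.
#' @param n_starts k-means restarts per run.
#' @param elbow_tol relative delta-area below which adding clusters is
#'   considered unproductive. The default 0.1 sits between the increments
#'   produced by genuine cluster splits (tens of percent) and the residual
#'   growth caused by subsamples splitting a true cluster inconsistently
#'   (under ten percent even on well-separated data).
#' @param seed integer seed.
#' @return `consensus_result`: list with `consensus` (per-k matrices),
#'   `assignment` (per-k vectors), `cdf_area`, `delta_area`, `chosen_k`,
#'   and `pruned` (chosen-k assignment after [prune_small_clusters()]).
#' @export
consensus_kmeans <- function(traj, k_range = 2:8, n_subsamples = 100,
                             item_fraction = 0.8, n_starts = 10,
                             elbow_tol = 0.1, seed = 1L) {
  n <- nrow(traj)
  assert_that(min(k_range) >= 2 && max(k_range) <= n - 1,
              "k_range must lie within [2, n_proteins - 1]")
  with_seed(seed, {
    ks <- sort(unique(as.integer(k_range)))
    consensus <- list(); assignment <- list()
    cdf_area <- stats::setNames(numeric(length(ks)), ks)
    for (ki in seq_along(ks)) {
      k <- ks[ki]
      co <- matrix(0, n, n)
      tog <- matrix(0, n, n)
      m_items <- max(k + 1, round(item_fraction * n))
      for (b in seq_len(n_subsamples)) {
        idx <- sort(sample.int(n, m_items))
        km <- stats::kmeans(traj[idx, , drop = FALSE], centers = k,
                            nstart = n_starts, iter.max = 50)
        tog[idx, idx] <- tog[idx, idx] + 1
        same <- outer(km$cluster, km$cluster, "==")
        co[idx, idx] <- co[idx, idx] + same
      }
      if (any(tog[upper.tri(tog)] == 0)) {
        stop("some protein pairs were never co-sampled; increase n_subsamples",
             call. = FALSE)
      }
      cons <- co / tog
      dimnames(cons) <- list(rownames(traj), rownames(traj))
      diag(cons) <- 1
      hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
      assignment[[as.character(k)]] <- stats::cutree(hc, k = k)
      consensus[[as.character(k)]] <- cons
      cdf_area[ki] <- consensus_cdf_area(cons)
    }
    delta_area <- c(cdf_area[1],
                    if (length(ks) > 1) diff(cdf_area) / utils::head(cdf_area, -1))
    names(delta_area) <- ks
    chosen_k <- ks[1]
    for (ki in seq_along(ks)[-1]) {
      if (delta_area[ki] < elbow_tol) break
      chosen_k <- ks[ki]
    }
    chosen <- assignment[[as.character(chosen_k)]]
    structure(list(consensus = consensus, assignment = assignment,
                   cdf_area = cdf_area, delta_area = delta_area,
                   chosen_k = chosen_k,
                   pruned = prune_small_clusters(chosen),
                   k_range = ks, seed = seed),
              class = "consensus_result")
  })
}

# Area under the empirical CDF of off-diagonal consensus entries over [0,1].
consensus_cdf_area <- function(cons) {
  x <- sort(cons[upper.tri(cons)])
  grid <- c(0, x, 1)
  cdf <- c(0, seq_along(x) / length(x), 1)
  sum(diff(grid) * utils::head(cdf, -1))
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus clustering over k in {%s}; chosen k = %d\n",
              paste(x$k_range, collapse = ","), x$chosen_k))
  tab <- table(x$pruned[x$pruned > 0])
  cat(sprintf("  %d cluster(s) after pruning, sizes: %s; %d unassigned\n",
              length(tab), paste(tab, collapse = ","), sum(x$pruned == 0)))
  invisible(x)
}

#' Remove clusters below a minimum size
#'
#' Clusters with fewer than `min_size` members are dissolved; their members
#' get cluster id 0 (unassigned) and the remaining clusters are renumbered
#' stably (by original id order).
#'
#' @param assignment named integer vector protein -> cluster id.
#' @param min_size smallest surviving cluster size.
#' @return renumbered assignment with 0 marking unassigned proteins.
#' @export
prune_small_clusters <- function(assignment, min_size = 3) {
  sizes <- table(assignment)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  out <- integer(length(assignment))
  names(out) <- names(assignment)
  for (i in seq_along(keep)) out[assignment == keep[i]] <- i
  out
}

#' Hypergeometric gene-set enrichment per cluster
#'
#' For each (cluster, gene set) pair, the upper-tail hypergeometric
#' probability of drawing at least the observed overlap when sampling the
#' cluster from the background universe, with BH correction within each
#' cluster. Sets with no members in the background are skipped.
#'
#' @param assignment pruned cluster assignment (0 = unassigned).
#' @param gene_sets named list of protein id vectors (e.g. [read_gmt()]).
#' @param background protein universe; must contain all cluster members.
#' @return data.frame: cluster, set, overlap, cluster_size, set_size,
#'   background_size, p, q.
#' @export
cluster_enrichment <- function(assignment, gene_sets, background) {
  assert_that(all(names(assignment) %in% background),
              "background must contain every clustered protein")
  N <- length(unique(background))
  rows <- list()
  for (cl in sort(unique(assignment[assignment > 0]))) {
    members <- names(assignment)[assignment == cl]
    n_cl <- length(members)
    cl_rows <- list()
    for (si in seq_along(gene_sets)) {
      set_bg <- intersect(gene_sets[[si]], background)
      K <- length(set_bg)
      if (K == 0) next
      o <- length(intersect(members, set_bg))
      p <- stats::phyper(o - 1, K, N - K, n_cl, lower.tail = FALSE)
      cl_rows[[length(cl_rows) + 1]] <- data.frame(
        cluster = cl, set = names(gene_sets)[si], overlap = o,
        cluster_size = n_cl, set_size = K, background_size = N, p = p,
        stringsAsFactors = FALSE)
    }
    if (!length(cl_rows)) next
    tab <- do.call(rbind, cl_rows)
    tab$q <- bh_adjust(tab$p)
    rows[[length(rows) + 1]] <- tab
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), set = character(), overlap = integer(),
               cluster_size = integer(), set_size = integer(),
               background_size = integer(), p = numeric(), q = numeric())
  rownames(out) <- NULL
  out
}
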
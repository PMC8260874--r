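#' Build a thresholded sample-correlation network
#'
#' Nodes are samples; pairwise Pearson correlations are computed across the
#' proteins observed in both samples (pairwise-complete, no imputation), and
#' the correlation threshold is chosen so that the edge count equals
#' `round(target_density * n(n-1)/2)`. Ties at the threshold are broken by
#' lexicographic sample-id order, making construction deterministic. Pairs
#' with fewer than 3 shared observed proteins have undefined correlation and
#' can never become edges (a warning is emitted).
#'
#' @param m an [abundance_matrix()] with >= 3 samples.
#' @param target_density fraction of possible edges to realize, in (0, 1].
#' @return a `sample_network`: list with `nodes`, `edges` (data.frame
#'   `from`, `to`, `weight` = correlation), `density`, `threshold`, `n`.
#' @export
build_sample_network <- function(m, target_density) {
  assert_that(ncol(m) >= 3, "need >= 3 samples to build a network")
  assert_that(target_density > 0 && target_density <= 1,
              "`target_density` must be in (0, 1]")
  vals <- unclass(m)
  n <- ncol(vals)
  cc <- suppressWarnings(stats::cor(vals, use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(vals))
  bad <- shared < 3
  diag(bad) <- FALSE
  if (any(bad & upper.tri(bad))) {
    warning(sprintf("build_sample_network: %d sample pair(s) share < 3 observed proteins; excluded",
                    sum(bad[upper.tri(bad)])))
  }
  cc[bad] <- -Inf
  cc[!is.finite(cc) & !bad] <- -Inf
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  w <- cc[ut]
  ids <- colnames(vals)
  ord <- order(-w, ids[ut[, 1]], ids[ut[, 2]])
  n_possible <- n * (n - 1) / 2
  n_edges <- min(round(target_density * n_possible), sum(is.finite(w)))
  take <- ord[seq_len(n_edges)]
  edges <- data.frame(from = ids[ut[take, 1]], to = ids[ut[take, 2]],
                      weight = w[take], stringsAsFactors = FALSE)
  structure(list(nodes = ids, edges = edges,
                 density = n_edges / n_possible,
                 threshold = if (n_edges > 0) min(edges$weight) else NA_real_,
                 n = n),
            class = "sample_network")
}

#' @export
print.sample_network <- function(x, ...) {
  cat(sprintf("Sample network: %d nodes, %d edges (density %.3f, threshold %.3f)\n",
              x$n, nrow(x$edges), x$density, x$threshold))
  invisible(x)
}

#' Newman modularity of a sample network under a given grouping
#'
#' `Q = sum_c (e_cc - a_c^2)` where `e_cc` is the fraction of edges falling
#' within group `c` and `a_c` the fraction of edge endpoints attached to
#' nodes of `c`. Computed on the binary thresholded graph by default;
#' `weighted = TRUE` uses the correlation weights (degree-weighted Q).
#' Delegates to [igraph::modularity()].
#'
#' @param net a `sample_network` from [build_sample_network()].
#' @param membership named vector (or vector ordered like `net$nodes`)
#'   assigning each sample to a group.
#' @param weighted use edge weights instead of the binary graph.
#' @return scalar Q in `[-1, 1]`.
#' @export
modularity_q <- function(net, membership, weighted = FALSE) {
  assert_that(inherits(net, "sample_network"), "`net` must be a sample_network")
  assert_that(nrow(net$edges) > 0, "modularity undefined on an empty edge set")
  if (!is.null(names(membership))) {
    assert_that(all(net$nodes %in% names(membership)),
                "every node needs a group in `membership`")
    membership <- membership[net$nodes]
  } else {
    assert_that(length(membership) == net$n,
                "`membership` must cover every node")
  }
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  comm <- as.integer(factor(membership))
  if (weighted) {
    igraph::modularity(g, comm, weights = igraph::E(g)$weight)
  } else {
    igraph::modularity(g, comm)
  }
}

#' Modularity as a function of network density for several groupings
#'
#' For each requested grouping column, builds sample networks over a grid of
#' densities and records Q, giving curves comparable across datasets because
#' density is realized by edge-count targeting. Groupings with a single
#' level are skipped with a warning. For cross-species comparisons, pass
#' `shared_timepoints` to restrict samples to the timepoints collected in
#' both species before building the networks.
#'
#' @param m an [abundance_matrix()].
#' @param samples sample metadata matching `m`.
#' @param groupings metadata columns to group samples by.
#' @param densities increasing density grid in (0, 1].
#' @param shared_timepoints optional vector of `timepoint_h` values to
#'   restrict to.
#' @param weighted passed to [modularity_q()].
#' @return data.frame with columns `grouping`, `density`, `Q`.
#' @export
modularity_curve <- function(m, samples, groupings,
                             densities = seq(0.05, 0.5, by = 0.05),
                             shared_timepoints = NULL, weighted = FALSE) {
  m <- subset_to_samples(m, samples)
  if (!is.null(shared_timepoints)) {
    keep <- samples$timepoint_h %in% shared_timepoints
    m <- abundance_matrix(unclass(m)[, keep, drop = FALSE], scale_tag(m))
    samples <- samples[keep, , drop = FALSE]
  }
  assert_that(all(groupings %in% names(samples)),
              "grouping columns absent from metadata: %s",
              paste(setdiff(groupings, names(samples)), collapse = ", "))
  assert_that(all(diff(densities) > 0) && all(densities > 0 & densities <= 1),
              "`densities` must be strictly increasing in (0,1]")
  nets <- lapply(densities, function(d) build_sample_network(m, d))
  rows <- list()
  for (grp in groupings) {
    memb <- stats::setNames(as.character(samples[[grp]]), samples$sample_id)
    if (length(unique(memb)) < 2) {
      warning(sprintf("modularity_curve: grouping `%s` has a single level; skipped", grp))
      next
    }
    q <- vapply(nets, modularity_q, 0, membership = memb, weighted = weighted)
    rows[[grp]] <- data.frame(grouping = grp, density = densities, Q = q,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
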
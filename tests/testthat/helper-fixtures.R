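# Shared fixtures: small study configurations sized for fast tests.

small_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_proteins = 120,
    shared_protein_fraction = 1,
    species_specs = list(
      human = species_spec(n_subjects_per_group = 8,
                           groups = c("control", "grade_A", "grade_B"),
                           timepoints = c(24, 48, 72, 96, 120),
                           n_batches = 2, paired = FALSE),
      pig = species_spec(n_subjects_per_group = 6,
                         groups = c("sham", "mild", "severe"),
                         timepoints = c(24, 48, 72, 96, 120),
                         n_batches = 2, paired = TRUE)),
    module_sizes = c(15, 15, 12, 12),
    de_fraction = 0.25,
    seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# A tiny deterministic abundance matrix with one missing cell.
tiny_abund <- function() {
  vals <- matrix(c(1, 2, 3, 4,
                   5, NA, 7, 8,
                   2, 2, 2, 9), nrow = 3, byrow = TRUE,
                 dimnames = list(c("P1", "P2", "P3"), paste0("s", 1:4)))
  abundance_matrix(vals, "log2")
}

# Brute-force Newman modularity via the per-edge formula, as an oracle
# independent of igraph: Q = (1/|E|) sum_edges [same group] - sum_c a_c^2.
brute_modularity <- function(edges, nodes, membership) {
  m <- nrow(edges)
  grp <- membership[nodes]
  within <- sum(grp[edges$from] == grp[edges$to]) / m
  ends <- c(edges$from, edges$to)
  a <- table(factor(grp[ends], levels = unique(grp))) / (2 * m)
  within - sum(a^2)
}

# Exhaustive hypergeometric upper tail P(X >= o) by enumerating all draws.
brute_hyper_tail <- function(o, K, N, n) {
  combos <- utils::combn(N, n)
  hits <- apply(combos, 2, function(draw) sum(draw <= K) >= o)
  mean(hits)
}

# Brute-force minimal DTW cost by enumerating all monotone boundary paths.
brute_dtw_cost <- function(cost) {
  n_i <- nrow(cost); n_j <- ncol(cost)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + cost[i, j]
    if (acc >= best) return()
    if (i == n_i && j == n_j) { best <<- acc; return() }
    if (i < n_i && j < n_j) recurse(i + 1, j + 1, acc)
    if (i < n_i) recurse(i + 1, j, acc)
    if (j < n_j) recurse(i, j + 1, acc)
  }
  recurse(1, 1, 0)
  best
}

# Brute-force BH from the step-up definition: q_i = min over j with
# p_j >= p_i of m * p_j / rank_j (capped at 1).
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ranks <- which(p[ord] >= p[i] - 1e-15)
    q[i] <- min(pmin(m * p[ord][ranks] / ranks, 1))
  }
  q
}

# Trajectory matrix with three well-separated planted temporal shapes.
shape_fixture_acc <- function(seed, n_per = 20, noise = 0.15) {
  set.seed(seed)
  tps <- c(24, 48, 72, 96, 120)
  shapes <- rbind(spike = c(3, 2, 1, 0.5, 0.2),
                  rise = c(0.2, 0.5, 1, 2, 3),
                  flat = c(1.5, 1.6, 1.5, 1.6, 1.5))
  truth <- rep(1:3, each = n_per)
  vals <- shapes[truth, ] + matrix(rnorm(3 * n_per * 5, 0, noise), 3 * n_per, 5)
  dimnames(vals) <- list(sprintf("P%03d", seq_len(3 * n_per)), tps)
  list(traj = structure(vals, class = c("trajectory_matrix", "matrix", "array")),
       truth = truth)
}

expect_abund <- function(m) {
  expect_s3_class(m, "abund")
  expect_true(all(is.finite(unclass(m)) | is.na(unclass(m))))
}
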
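#' Estimate the proportion of true null hypotheses (pi0 / pi1)
#'
#' Computes `pi0(lambda) = #(p > lambda) / (n (1 - lambda))` on a lambda
#' grid, fits a natural cubic smoothing spline to the curve and reads off
#' its value at the largest lambda (the smoother extrapolation to
#' `lambda -> 1`), clipped to `[0, 1]`. `pi1 = 1 - pi0` estimates the
#' proportion of true associations. Degenerate input (all p equal) returns
#' the conservative `pi0 = 1` with a warning.
#'
#' @param p p-values in `[0, 1]`.
#' @param lambda_grid tuning grid; default `seq(0.05, 0.95, 0.05)`.
#' @return list of class `pi0_estimate`: `pi0`, `pi1`, `lambda`,
#'   `pi0_lambda`, `method`.
#' @export
estimate_pi0 <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0,1]")
  n <- length(p)
  if (length(unique(p)) == 1L) {
    warning("estimate_pi0: degenerate p-value distribution; returning pi0 = 1")
    return(structure(list(pi0 = 1, pi1 = 0, lambda = lambda_grid,
                          pi0_lambda = rep(1, length(lambda_grid)),
                          method = "degenerate"), class = "pi0_estimate"))
  }
  pi0_lambda <- vapply(lambda_grid, function(l) sum(p > l) / (n * (1 - l)), 0)
  fit <- stats::smooth.spline(lambda_grid, pi0_lambda, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda_grid))$y
  pi0 <- min(max(pi0, 0), 1)
  structure(list(pi0 = pi0, pi1 = 1 - pi0, lambda = lambda_grid,
                 pi0_lambda = pi0_lambda, method = "smoother"),
            class = "pi0_estimate")
}

#' @export
print.pi0_estimate <- function(x, ...) {
  cat(sprintf("pi0 = %.3f (pi1 = %.3f), %s method on %d lambda values\n",
              x$pi0, x$pi1, x$method, length(x$lambda)))
  invisible(x)
}

#' Rank proteins by strength and direction of differential abundance
#'
#' Signed score `-log10(p) * sign(coef)`, sorted descending; ties broken by
#' `|coef|` (descending) then protein id, so the ranking is a deterministic
#' permutation of the universe. Zero p-values are floored at the smallest
#' positive double before taking logs.
#'
#' @param de a `de_result` from [fit_moderated_lm()] (or any data.frame with
#'   `protein`, `p`, `coef`).
#' @return `ranked_list`: data.frame `protein`, `score`, in rank order.
#' @export
rank_by_de <- function(de) {
  assert_that(all(c("protein", "p", "coef") %in% names(de)),
              "rank_by_de needs protein, p and coef columns")
  ok <- !is.na(de$p) & !is.na(de$coef)
  d <- de[ok, , drop = FALSE]
  p <- pmax(d$p, .Machine$double.xmin)
  score <- -log10(p) * sign(d$coef)
  ord <- order(-score, -abs(d$coef), d$protein)
  structure(data.frame(protein = d$protein[ord], score = score[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Rank-rank hypergeometric overlap grid
#'
#' Slides a pair of windows down two rankings of the same protein universe:
#' for prefix lengths `i`, `j` on a stride grid, computes the upper-tail
#' hypergeometric probability of the observed overlap between the top-i of
#' list `a` and top-j of list `b`, reported as `-log10 p`.
#'
#' @param a,b `ranked_list` objects over the identical universe.
#' @param step rank stride between evaluated prefix lengths; default
#'   `max(1, round(n/100))` for a roughly 100 x 100 grid.
#' @return `rrho_result`: list with `grid` (`-log10 p`, rows indexed by
#'   prefixes of `a`), `steps_a`, `steps_b`, `step`, `observed_max`, and
#'   `perm_p = NA` (see [rrho_permutation_test()]).
#' @export
rrho_map <- function(a, b, step = NULL) {
  ua <- a$protein; ub <- b$protein
  extra <- c(setdiff(ua, ub), setdiff(ub, ua))
  assert_that(length(extra) == 0 && length(ua) == length(ub),
              "ranked lists must cover the identical universe; asymmetric ids: %s",
              paste(utils::head(extra, 10), collapse = ", "))
  n <- length(ua)
  if (is.null(step)) step <- max(1L, round(n / 100))
  assert_that(step >= 1, "`step` must be >= 1")
  steps <- unique(c(seq(step, n, by = step), n))
  # bucket each protein by its (rank in a, rank in b) grid cell, then 2-D
  # cumulative sums give prefix overlaps in O(n + grid^2)
  rb <- match(ua, ub)            # rank in b of the protein at rank i of a
  ga <- findInterval(seq_len(n), steps + 1L) + 1L
  gb <- findInterval(rb, steps + 1L) + 1L
  counts <- matrix(0, length(steps), length(steps))
  for (i in seq_len(n)) counts[ga[i], gb[i]] <- counts[ga[i], gb[i]] + 1
  overlap <- apply(apply(counts, 2, cumsum), 1, cumsum)
  overlap <- t(overlap)
  grid <- matrix(0, length(steps), length(steps),
                 dimnames = list(steps, steps))
  for (ii in seq_along(steps)) {
    i <- steps[ii]
    grid[ii, ] <- -stats::phyper(overlap[ii, ] - 1, i, n - i, steps,
                                 lower.tail = FALSE, log.p = TRUE) / log(10)
  }
  structure(list(grid = grid, steps_a = steps, steps_b = steps, step = step,
                 n = n, observed_max = max(grid), perm_p = NA_real_),
            class = "rrho_result")
}

#' @export
print.rrho_result <- function(x, ...) {
  cat(sprintf("RRHO grid %dx%d (n = %d, step = %d): max -log10 p = %.2f",
              nrow(x$grid), ncol(x$grid), x$n, x$step, x$observed_max))
  if (!is.na(x$perm_p)) cat(sprintf(", permutation p = %.4g", x$perm_p))
  cat("\n")
  invisible(x)
}

#' RRHO significance by outcome-label permutation
#'
#' Builds the observed RRHO grid from the real outcome labels, then, for
#' each permutation, independently shuffles the outcome within each species
#' (within subject, when a paired design declares one), refits both
#' differential-abundance models, rebuilds the grid, and records its
#' maximum. The permutation p-value is the add-one fraction of null maxima
#' reaching the observed maximum.
#'
#' @param human_m,pig_m abundance matrices for the two species.
#' @param human_samples,pig_samples matching metadata.
#' @param human_design,pig_design [design_spec()]s fit within each species.
#' @param shared_map data.frame `human_id`, `pig_id` defining the shared
#'   universe the rankings are built on.
#' @param step RRHO stride (see [rrho_map()]).
#' @param n_perm number of permutations (0 returns the observed grid with
#'   `perm_p = NA`).
#' @param seed integer seed.
#' @return `rrho_result` with `perm_p` and the vector of `null_max` values.
#' @export
rrho_permutation_test <- function(human_m, pig_m, human_samples, pig_samples,
                                  human_design, pig_design, shared_map,
                                  step = NULL, n_perm = 1000, seed = 1L) {
  obs <- rrho_from_fits(human_m, pig_m, human_samples, pig_samples,
                        human_design, pig_design, shared_map, step)
  if (n_perm == 0) return(obs)
  # a permutation-invariant outcome cannot be tested
  assert_that(length(unique(stats::na.omit(human_samples[[human_design$outcome]]))) > 1 &&
                length(unique(stats::na.omit(pig_samples[[pig_design$outcome]]))) > 1,
              "outcome is constant; permutation test undefined")
  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    hs <- permute_outcome(human_samples, human_design)
    ps <- permute_outcome(pig_samples, pig_design)
    rrho_from_fits(human_m, pig_m, hs, ps, human_design, pig_design,
                   shared_map, step)$observed_max
  }, 0))
  obs$null_max <- null_max
  obs$perm_p <- perm_pvalue(obs$observed_max, null_max)
  obs
}

rrho_from_fits <- function(human_m, pig_m, human_samples, pig_samples,
                           human_design, pig_design, shared_map, step) {
  de_h <- fit_moderated_lm(human_m, human_samples, human_design)
  de_p <- fit_moderated_lm(pig_m, pig_samples, pig_design)
  ok_h <- de_h$protein[!is.na(de_h$p) & !is.na(de_h$coef)]
  ok_p <- de_p$protein[!is.na(de_p$p) & !is.na(de_p$coef)]
  shared_map <- shared_map[shared_map$human_id %in% ok_h &
                             shared_map$pig_id %in% ok_p, , drop = FALSE]
  de_h <- de_h[match(shared_map$human_id, de_h$protein), , drop = FALSE]
  de_p <- de_p[match(shared_map$pig_id, de_p$protein), , drop = FALSE]
  de_p$protein <- shared_map$human_id  # common namespace
  rrho_map(rank_by_de(de_h), rank_by_de(de_p), step = step)
}

# Shuffle the outcome column across samples (within subject for paired
# designs, preserving each subject's set of values).
permute_outcome <- function(samples, design) {
  y <- samples[[design$outcome]]
  if (!is.null(design$paired_subject)) {
    sub <- samples[[design$paired_subject]]
    for (s in unique(sub)) {
      idx <- which(sub == s)
      samples[[design$outcome]][idx] <- y[sample(idx)]
    }
  } else {
    samples[[design$outcome]] <- y[sample.int(length(y))]
  }
  samples
}

#' Neighborhood analysis of conserved coexpression (NACC)
#'
#' Builds independent protein-protein Pearson correlation networks within
#' each species (over that species' samples of the within-species z-scored
#' combined matrix). For each protein, its k nearest human coexpression
#' neighbors are looked up and the mean correlation between the protein and
#' those same neighbors is evaluated in pig; the procedure is repeated with
#' the species inverted and the two values averaged into a symmetric
#' conservation score in `[-1, 1]`.
#'
#' @param combined z-scored combined matrix from [zscore_within_species()].
#' @param k neighborhood size.
#' @return `nacc_result`: data.frame `protein`, `nacc_score`, plus the two
#'   directional components `d_hp`, `d_ph`; correlation matrices kept in
#'   attributes for the permutation stage.
#' @export
nacc_scores <- function(combined, k = 10) {
  check_scale(combined, "zscored", "nacc_scores")
  species <- attr(combined, "species")
  assert_that(!is.null(species), "combined matrix lacks a species attribute")
  n <- nrow(combined)
  assert_that(n >= k + 1, "need at least k + 1 shared proteins")
  for (sp in unique(species)) {
    assert_that(sum(species == sp) >= 3, "need >= 3 samples per species")
  }
  ch <- stats::cor(t(unclass(combined)[, species == "human", drop = FALSE]))
  cp <- stats::cor(t(unclass(combined)[, species == "pig", drop = FALSE]))
  ids <- rownames(combined)
  d_hp <- d_ph <- numeric(n)
  for (g in seq_len(n)) {
    nb_h <- top_k_neighbors(ch[g, ], g, k)
    nb_p <- top_k_neighbors(cp[g, ], g, k)
    d_hp[g] <- mean(cp[g, nb_h])
    d_ph[g] <- mean(ch[g, nb_p])
  }
  structure(data.frame(protein = ids, nacc_score = (d_hp + d_ph) / 2,
                       d_hp = d_hp, d_ph = d_ph, stringsAsFactors = FALSE),
            cor_human = ch, cor_pig = cp, k = k,
            class = c("nacc_result", "data.frame"))
}

top_k_neighbors <- function(cors, self, k) {
  cors[self] <- -Inf
  order(cors, decreasing = TRUE)[seq_len(k)]
}

#' Permutation test for per-protein NACC scores
#'
#' Compares each protein's observed NACC score against scores recomputed
#' from random "neighborhoods": for every null draw, k proteins are sampled
#' uniformly (excluding the protein itself) in each direction and the
#' symmetric score rebuilt. Reports the null mean/SD, the z-score and the
#' one-sided add-one permutation p (high scores = conserved).
#'
#' @param result a `nacc_result` from [nacc_scores()].
#' @param n_perm null draws per protein.
#' @param seed integer seed.
#' @return the input with `null_mean`, `null_sd`, `z`, `perm_p` columns.
#' @export
nacc_permutation_test <- function(result, n_perm = 1000, seed = 1L) {
  assert_that(inherits(result, "nacc_result"), "`result` must come from nacc_scores()")
  ch <- attr(result, "cor_human"); cp <- attr(result, "cor_pig")
  k <- attr(result, "k"); n <- nrow(result)
  assert_that(k < n - 1, "k must be smaller than the universe minus one")
  with_seed(seed, {
    null_mean <- null_sd <- z <- perm_p <- numeric(n)
    for (g in seq_len(n)) {
      pool <- setdiff(seq_len(n), g)
      null <- vapply(seq_len(n_perm), function(b) {
        (mean(cp[g, sample(pool, k)]) + mean(ch[g, sample(pool, k)])) / 2
      }, 0)
      null_mean[g] <- mean(null)
      null_sd[g] <- stats::sd(null)
      z[g] <- if (null_sd[g] > 0) (result$nacc_score[g] - null_mean[g]) / null_sd[g] else NA_real_
      perm_p[g] <- perm_pvalue(result$nacc_score[g], null)
    }
    result$null_mean <- null_mean
    result$null_sd <- null_sd
    result$z <- z
    result$perm_p <- perm_p
    result
  })
}

#' Gene-set level NACC conservation test
#'
#' Tests whether the mean NACC score of a gene set's members is higher
#' (conserved tail) or lower (divergent tail) than expected from
#' size-matched uniform random protein sets. Sets are filtered to those with
#' `size_bounds[1]`-`size_bounds[2]` scored members.
#'
#' @param result a `nacc_result` (scores computed).
#' @param gene_sets named list of protein id vectors.
#' @param size_bounds inclusive member-count bounds within the scored
#'   universe.
#' @param n_perm random sets per tested set.
#' @param seed integer seed.
#' @return data.frame: set, size, mean_score, null_mean, null_sd, z,
#'   p_conserved, p_divergent (both add-one permutation p-values).
#' @export
nacc_gene_set_test <- function(result, gene_sets, size_bounds = c(3, 50),
                               n_perm = 1000, seed = 1L) {
  assert_that(inherits(result, "nacc_result"), "`result` must come from nacc_scores()")
  scores <- stats::setNames(result$nacc_score, result$protein)
  members <- lapply(gene_sets, function(s) intersect(s, names(scores)))
  sz <- lengths(members)
  keep <- sz >= size_bounds[1] & sz <= size_bounds[2]
  if (!any(keep)) {
    warning("nacc_gene_set_test: no gene sets within the size bounds")
    return(data.frame(set = character(), size = integer(), mean_score = numeric(),
                      null_mean = numeric(), null_sd = numeric(), z = numeric(),
                      p_conserved = numeric(), p_divergent = numeric()))
  }
  with_seed(seed, {
    rows <- lapply(which(keep), function(si) {
      mem <- members[[si]]
      obs <- mean(scores[mem])
      null <- vapply(seq_len(n_perm), function(b) {
        mean(sample(scores, length(mem)))
      }, 0)
      nm <- mean(null); ns <- stats::sd(null)
      data.frame(set = names(gene_sets)[si], size = length(mem),
                 mean_score = obs, null_mean = nm, null_sd = ns,
                 z = if (ns > 0) (obs - nm) / ns else NA_real_,
                 p_conserved = perm_pvalue(obs, null),
                 p_divergent = (1 + sum(null <= obs)) / (1 + n_perm),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Local-polynomial smoothing of per-protein time courses
#'
#' Smooths each protein's series with a degree-2 local polynomial (loess)
#' and evaluates it on a dense common grid of `upsample_factor` times the
#' original resolution, interpolating only (no extrapolation beyond the
#' first/last timepoint). With fewer than seven timepoints, where a local
#' window cannot stably hold a quadratic, a global quadratic fit is used
#' instead.
#'
#' @param timepoints increasing numeric vector (length >= 3).
#' @param values proteins x timepoints matrix.
#' @param upsample_factor grid refinement factor.
#' @param span loess span; floored so each window holds >= 4 points.
#' @return list with `time` (dense grid) and `values` (proteins x grid).
#' @export
smooth_profiles <- function(timepoints, values, upsample_factor = 4,
                            span = 0.75) {
  assert_that(length(timepoints) >= 3, "need >= 3 timepoints to smooth")
  assert_that(all(diff(timepoints) > 0), "timepoints must be strictly increasing")
  values <- as.matrix(values)
  assert_that(ncol(values) == length(timepoints),
              "values must have one column per timepoint")
  n_t <- length(timepoints)
  grid <- seq(min(timepoints), max(timepoints),
              length.out = (n_t - 1) * upsample_factor + 1)
  out <- matrix(NA_real_, nrow(values), length(grid),
                dimnames = list(rownames(values), NULL))
  # below ~7 points a loess window holds too few observations for a stable
  # local quadratic; fall back to a single global quadratic fit
  use_global <- n_t < 7
  span <- max(span, min(1, 4 / n_t))
  for (g in seq_len(nrow(values))) {
    y <- values[g, ]
    if (use_global) {
      fit <- stats::lm(y ~ stats::poly(timepoints, degree = min(2, n_t - 1), raw = TRUE))
      out[g, ] <- stats::predict(fit, newdata = list(timepoints = grid))
    } else {
      fit <- stats::loess(y ~ timepoints, degree = 2, span = span,
                          control = stats::loess.control(surface = "direct"))
      out[g, ] <- stats::predict(fit, newdata = data.frame(timepoints = grid))
    }
  }
  list(time = grid, values = out)
}

#' Dynamic-time-warping alignment of two species' proteome time courses
#'
#' The local cost of pairing human time i with pig time j is the Euclidean
#' distance between the species' all-protein abundance vectors at those
#' times. The optimal monotone boundary-to-boundary path (steps down, right
#' or diagonal) is found by dynamic programming; ties prefer the diagonal,
#' making the backtrace deterministic.
#'
#' @param human_profiles,pig_profiles proteins x timepoints matrices on the
#'   (smoothed) grids, rows = shared protein universe, z-scored per species.
#' @param human_times,pig_times the time grids (hours); defaults to column
#'   indices.
#' @return `alignment_result`: list with `cost` (local cost matrix), `path`
#'   (data.frame `i`, `j`, `human_time`, `pig_time`), `total_cost`.
#' @export
dtw_align <- function(human_profiles, pig_profiles,
                      human_times = NULL, pig_times = NULL) {
  hp <- as.matrix(human_profiles); pp <- as.matrix(pig_profiles)
  shared <- intersect(rownames(hp), rownames(pp))
  if (is.null(rownames(hp)) && nrow(hp) == nrow(pp)) shared <- seq_len(nrow(hp))
  assert_that(length(shared) > 0, "empty shared protein set")
  hp <- hp[shared, , drop = FALSE]; pp <- pp[shared, , drop = FALSE]
  n_i <- ncol(hp); n_j <- ncol(pp)
  human_times <- human_times %||% seq_len(n_i)
  pig_times <- pig_times %||% seq_len(n_j)
  cost <- matrix(0, n_i, n_j)
  for (j in seq_len(n_j)) {
    cost[, j] <- sqrt(colSums((hp - pp[, j])^2))
  }
  dtw_from_cost(cost, human_times, pig_times)
}

# Dynamic-programming core over a precomputed local cost matrix.
dtw_from_cost <- function(cost, human_times = NULL, pig_times = NULL) {
  n_i <- nrow(cost); n_j <- ncol(cost)
  human_times <- human_times %||% seq_len(n_i)
  pig_times <- pig_times %||% seq_len(n_j)
  D <- matrix(Inf, n_i, n_j)
  D[1, 1] <- cost[1, 1]
  for (i in seq_len(n_i)) for (j in seq_len(n_j)) {
    if (i == 1 && j == 1) next
    prev <- c(if (i > 1 && j > 1) D[i - 1, j - 1] else Inf,
              if (i > 1) D[i - 1, j] else Inf,
              if (j > 1) D[i, j - 1] else Inf)
    D[i, j] <- cost[i, j] + min(prev)
  }
  # backtrace, diagonal preferred on ties
  path <- list(c(n_i, n_j))
  i <- n_i; j <- n_j
  while (i > 1 || j > 1) {
    cand <- rbind(
      if (i > 1 && j > 1) c(i - 1, j - 1, D[i - 1, j - 1]),
      if (i > 1) c(i - 1, j, D[i - 1, j]),
      if (j > 1) c(i, j - 1, D[i, j - 1]))
    best <- cand[which.min(cand[, 3]), ]
    i <- best[1]; j <- best[2]
    path[[length(path) + 1]] <- c(i, j)
  }
  path <- do.call(rbind, rev(path))
  pd <- data.frame(i = path[, 1], j = path[, 2],
                   human_time = human_times[path[, 1]],
                   pig_time = pig_times[path[, 2]])
  structure(list(cost = cost, path = pd, total_cost = D[n_i, n_j],
                 human_times = human_times, pig_times = pig_times),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("DTW alignment: %dx%d grid, path length %d, total cost %.4g, warp slope %.3f\n",
              nrow(x$cost), ncol(x$cost), nrow(x$path), x$total_cost,
              warp_slope(x)))
  invisible(x)
}

#' Warp slope of a DTW alignment
#'
#' Least-squares slope of matched human time against matched pig time along
#' the optimal path, excluding boundary-clamped cells (path points pinned to
#' the first/last row or column, which carry no rate information). This
#' estimates the factor by which pig dynamics run faster than human: a pig
#' sampled at t hours matching a human at `slope * t` hours.
#'
#' @param alignment an `alignment_result` from [dtw_align()].
#' @return scalar slope estimate d(human time)/d(pig time).
#' @export
warp_slope <- function(alignment) {
  p <- alignment$path
  n_i <- nrow(alignment$cost); n_j <- ncol(alignment$cost)
  interior <- p$i > 1 & p$i < n_i & p$j > 1 & p$j < n_j
  if (sum(interior) < 2) interior <- rep(TRUE, nrow(p))
  fit <- stats::lm(human_time ~ pig_time, data = p[interior, , drop = FALSE])
  unname(stats::coef(fit)[2])
}
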
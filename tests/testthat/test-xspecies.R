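# --- pi0 / pi1 ---------------------------------------------------------------

test_that("pi0 estimation behaves at the uniform, mixed and saturated extremes", {
  p_unif <- seq(1e-4, 1 - 1e-4, length.out = 1000)
  expect_gte(estimate_pi0(p_unif)$pi0, 0.95)

  set.seed(2)
  pi0_hat <- replicate(20, {
    p <- c(runif(1400), rbeta(600, 0.1, 1))   # 70% null / 30% alternative
    estimate_pi0(p)$pi0
  })
  expect_gt(median(pi0_hat), 0.6)
  expect_lt(median(pi0_hat), 0.8)

  set.seed(3)
  expect_lte(estimate_pi0(runif(500, 0, 0.001))$pi0, 0.05)
  expect_warning(d <- estimate_pi0(rep(0.5, 100)), "degenerate")
  expect_equal(d$pi0, 1)
})

# --- DE ranking --------------------------------------------------------------

test_that("DE ranking orders by signed significance with deterministic tie-breaks", {
  de <- data.frame(protein = c("up_strong", "up_weak", "down_strong"),
                   p = c(0.001, 0.01, 0.001), coef = c(1, 1, -1))
  r <- rank_by_de(de)
  expect_equal(r$protein, c("up_strong", "up_weak", "down_strong"))
  # equal p and |coef|: lexicographic id order
  de2 <- data.frame(protein = c("B", "A"), p = c(0.01, 0.01), coef = c(0.5, 0.5))
  expect_equal(rank_by_de(de2)$protein, c("A", "B"))
  # p = 0 underflow floored, still ranked first
  de3 <- data.frame(protein = c("zero", "tiny"), p = c(0, 1e-300), coef = c(1, 1))
  r3 <- rank_by_de(de3)
  expect_equal(r3$protein[1], "zero")
  expect_true(all(is.finite(r3$score)))
})

# --- RRHO --------------------------------------------------------------------

rl <- function(ids) structure(data.frame(protein = ids, score = rev(seq_along(ids))),
                              class = c("ranked_list", "data.frame"))

test_that("RRHO grid matches exact hypergeometric tails", {
  # n = 10, i = j = 4, perfect overlap: -log10(1/C(10,4))
  a <- rl(paste0("p", 1:10))
  r <- rrho_map(a, a, step = 4)
  expect_equal(r$grid["4", "4"], -log10(1 / 210), tolerance = 1e-10)
  # full-list corner: overlap n has probability 1
  expect_equal(r$grid[as.character(10), as.character(10)], 0)

  # exhaustive oracle on random rankings with n <= 15
  set.seed(4)
  for (rep in 1:10) {
    n <- sample(8:15, 1)
    ids <- paste0("x", 1:n)
    a <- rl(ids); b <- rl(sample(ids))
    r <- rrho_map(a, b, step = 3)
    for (ii in r$steps_a) for (jj in r$steps_b) {
      o <- length(intersect(a$protein[1:ii], b$protein[1:jj]))
      expect_equal(r$grid[as.character(ii), as.character(jj)],
                   -log10(brute_hyper_tail(o, ii, n, jj)), tolerance = 1e-9)
    }
  }
})

test_that("RRHO grid is invariant to joint relabeling and transposes on swap", {
  set.seed(8)
  ids <- paste0("g", 1:60)
  a <- rl(sample(ids)); b <- rl(sample(ids))
  r <- rrho_map(a, b, step = 10)
  # same permutation applied to both lists: identical grid
  perm <- setNames(paste0("h", 1:60), ids)
  a2 <- rl(unname(perm[a$protein])); b2 <- rl(unname(perm[b$protein]))
  expect_equal(rrho_map(a2, b2, step = 10)$grid, r$grid)
  # swapped lists: transposed grid
  expect_equal(rrho_map(b, a, step = 10)$grid, t(r$grid))
  # universe mismatch errors with the asymmetric ids
  expect_error(rrho_map(rl(ids[1:59]), rl(ids[2:60]), step = 10), "g1")
})

test_that("RRHO permutation test flags planted shared signal and respects B = 0", {
  st <- generate_study(small_config(seed = 41, de_fraction = 0.3,
                                    shared_effect_fraction = 1,
                                    effect_size_sd = 2))
  hs <- st$samples[st$samples$species == "human" &
                     (st$samples$injured == 0 | st$samples$timepoint_h == 48), ]
  ps <- st$samples[st$samples$species == "pig" &
                     (st$samples$injured == 0 | st$samples$timepoint_h == 48), ]
  des <- design_spec("injured", "binary")
  r <- rrho_permutation_test(st$human, st$pig, hs, ps, des, des,
                             st$ortholog_map, n_perm = 200, seed = 1)
  expect_lte(r$perm_p, 0.01)
  r0 <- rrho_permutation_test(st$human, st$pig, hs, ps, des, des,
                              st$ortholog_map, n_perm = 0, seed = 1)
  expect_true(is.na(r0$perm_p))
  expect_equal(r0$observed_max, r$observed_max)
})

# --- NACC --------------------------------------------------------------------

test_that("NACC on a duplicated species block equals the own-neighborhood mean", {
  set.seed(11)
  vals <- matrix(rnorm(20 * 8), 20, 8,
                 dimnames = list(paste0("P", 1:20), paste0("s", 1:8)))
  z <- t(scale(t(vals)))
  comb <- abundance_matrix(cbind(z, `colnames<-`(z, paste0("t", 1:8))), "log2")
  comb <- conservatome:::set_scale(comb, "zscored")
  attr(comb, "species") <- rep(c("human", "pig"), each = 8)
  sc <- nacc_scores(comb, k = 3)
  cc <- cor(t(z))
  for (g in c(1, 7, 20)) {
    own <- mean(sort(cc[g, -g], decreasing = TRUE)[1:3])
    expect_equal(sc$nacc_score[g], own, tolerance = 1e-12)
  }
  expect_true(all(sc$nacc_score >= -1 & sc$nacc_score <= 1))
})

test_that("NACC equals a hand-worked brute-force evaluation on a tiny instance", {
  # 4 proteins x 4 samples per species, k = 1
  h <- matrix(c(1, 2, 3, 4,
                2, 1, 4, 3,
                4, 3, 2, 1,
                1, 3, 2, 4), 4, 4, byrow = TRUE,
              dimnames = list(paste0("P", 1:4), paste0("h", 1:4)))
  p <- matrix(c(1, 2, 3, 5,
                4, 3, 1, 2,
                2, 4, 1, 3,
                4, 2, 3, 1), 4, 4, byrow = TRUE,
              dimnames = list(paste0("P", 1:4), paste0("g", 1:4)))
  zh <- t(scale(t(h))); zp <- t(scale(t(p)))
  comb <- abundance_matrix(cbind(zh, zp), "log2")
  comb <- conservatome:::set_scale(comb, "zscored")
  attr(comb, "species") <- rep(c("human", "pig"), each = 4)
  sc <- nacc_scores(comb, k = 1)
  ch <- cor(t(zh)); cp <- cor(t(zp))
  for (g in 1:4) {
    nb_h <- which.max(replace(ch[g, ], g, -Inf))
    nb_p <- which.max(replace(cp[g, ], g, -Inf))
    expect_equal(sc$nacc_score[g], (cp[g, nb_h] + ch[g, nb_p]) / 2, tolerance = 1e-12)
  }
})

test_that("NACC scores are symmetric under species exchange", {
  st <- generate_study(small_config(seed = 23))
  fh <- impute_half_min(filter_detection(st$human))
  fp <- impute_half_min(filter_detection(st$pig))
  comb <- zscore_within_species(fh, fp, st$ortholog_map)
  swapped <- comb
  attr(swapped, "species") <- ifelse(attr(comb, "species") == "human", "pig", "human")
  expect_equal(nacc_scores(comb, k = 5)$nacc_score,
               nacc_scores(swapped, k = 5)$nacc_score, tolerance = 1e-12)
})

test_that("unstructured cross-species data gives NACC scores near zero", {
  set.seed(31)
  means <- numeric(10)
  for (i in 1:10) {
    zh <- t(scale(t(matrix(rnorm(200 * 12), 200, 12))))
    zp <- t(scale(t(matrix(rnorm(200 * 12), 200, 12))))
    dimnames(zh) <- list(paste0("P", 1:200), paste0("h", 1:12))
    dimnames(zp) <- list(paste0("P", 1:200), paste0("g", 1:12))
    comb <- abundance_matrix(cbind(zh, zp), "log2")
    comb <- conservatome:::set_scale(comb, "zscored")
    attr(comb, "species") <- rep(c("human", "pig"), each = 12)
    means[i] <- mean(nacc_scores(comb, k = 10)$nacc_score)
  }
  expect_lt(abs(mean(means)), 0.05)
})

test_that("NACC permutation test is one-sided with the add-one convention", {
  st <- generate_study(small_config(seed = 3, within_module_corr = 0.8))
  fh <- impute_half_min(filter_detection(st$human))
  fp <- impute_half_min(filter_detection(st$pig))
  comb <- zscore_within_species(fh, fp, st$ortholog_map)
  sc <- nacc_permutation_test(nacc_scores(comb, k = 10), n_perm = 99, seed = 7)
  expect_true(all(sc$perm_p >= 1 / 100 & sc$perm_p <= 1))
  # conserved module members score high
  consv <- names(st$truth$module_membership)[
    st$truth$module_conserved[st$truth$module_membership]]
  consv <- intersect(consv, sc$protein)
  idx <- match(consv, sc$protein)
  expect_gt(mean(sc$z[idx] > 2 & sc$perm_p[idx] < 0.05), 0.9)
  # reproducible given seed
  sc2 <- nacc_permutation_test(nacc_scores(comb, k = 10), n_perm = 99, seed = 7)
  expect_identical(sc$perm_p, sc2$perm_p)
})

test_that("gene-set NACC separates conserved from divergent planted modules", {
  st <- generate_study(small_config(seed = 11, within_module_corr = 0.8))
  fh <- impute_half_min(filter_detection(st$human))
  fp <- impute_half_min(filter_detection(st$pig))
  comb <- zscore_within_species(fh, fp, st$ortholog_map)
  sc <- nacc_scores(comb, k = 10)
  mods <- split(names(st$truth$module_membership), st$truth$module_membership)
  names(mods) <- paste0("M", seq_along(mods))
  tab <- nacc_gene_set_test(sc, mods, n_perm = 500, seed = 5)
  consv <- st$truth$module_conserved
  expect_true(all(tab$p_conserved[consv] < 0.05))
  expect_true(all(tab$p_divergent[!consv] < 0.05))
  # size filter: sets outside [3,50] scored members are excluded
  mods$tiny <- mods$M1[1:2]
  tab2 <- nacc_gene_set_test(sc, mods, n_perm = 50, seed = 5)
  expect_false("tiny" %in% tab2$set)
})

# --- smoothing and DTW -------------------------------------------------------

test_that("local-polynomial smoothing reproduces polynomials exactly", {
  tp <- c(0, 24, 48, 72, 96)
  const <- matrix(3, 1, 5, dimnames = list("c", NULL))
  sm <- smooth_profiles(tp, const, upsample_factor = 3)
  expect_equal(unname(sm$values[1, ]), rep(3, length(sm$time)), tolerance = 1e-9)
  quad <- matrix(2 + 0.5 * tp - 0.01 * tp^2, 1, 5, dimnames = list("q", NULL))
  smq <- smooth_profiles(tp, quad, upsample_factor = 4)
  expect_equal(unname(smq$values[1, ]), 2 + 0.5 * smq$time - 0.01 * smq$time^2,
               tolerance = 1e-6)
  # grid respects the endpoints (interpolation only)
  expect_equal(range(smq$time), range(tp))
  expect_error(smooth_profiles(c(0, 24), matrix(1, 1, 2), 2), "3 timepoints")
})

test_that("smoothing a noisy signal beats linear interpolation in RMSE", {
  set.seed(6)
  tp <- seq(0, 120, by = 12)
  truth_fun <- function(t) sin(t / 25)
  rmse_sm <- rmse_lin <- numeric(20)
  for (i in 1:20) {
    y <- truth_fun(tp) + rnorm(length(tp), 0, 0.25)
    sm <- smooth_profiles(tp, matrix(y, 1, dimnames = list("s", NULL)),
                          upsample_factor = 4, span = 0.6)
    lin <- approx(tp, y, xout = sm$time)$y
    rmse_sm[i] <- sqrt(mean((sm$values[1, ] - truth_fun(sm$time))^2))
    rmse_lin[i] <- sqrt(mean((lin - truth_fun(sm$time))^2))
  }
  expect_lt(mean(rmse_sm), mean(rmse_lin))
})

test_that("DTW recovers the diagonal on identical profiles and exact small cases", {
  set.seed(9)
  prof <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(paste0("P", 1:30), NULL))
  al <- dtw_align(prof, prof)
  expect_equal(al$path$i, 1:6)
  expect_equal(al$path$j, 1:6)
  expect_equal(al$total_cost, 0)

  # 3x3 hand-checked cost matrix: diagonal path, total cost 3
  # (constructed via profiles whose pairwise distances give the target costs)
  costs <- matrix(c(1, 5, 5, 5, 1, 5, 5, 5, 1), 3, 3)
  al3 <- conservatome:::dtw_from_cost(costs)
  expect_equal(al3$path$i, 1:3)
  expect_equal(al3$total_cost, 3)
})

test_that("DTW minimal cost matches brute-force enumeration on small grids", {
  set.seed(13)
  for (rep in 1:25) {
    n_i <- sample(2:6, 1); n_j <- sample(2:6, 1)
    cost <- matrix(runif(n_i * n_j, 0.1, 3), n_i, n_j)
    al <- conservatome:::dtw_from_cost(cost)
    expect_equal(al$total_cost, brute_dtw_cost(cost), tolerance = 1e-12)
    # path validity: boundary anchored, monotone unit steps
    expect_equal(unlist(al$path[1, c("i", "j")]), c(i = 1, j = 1))
    expect_equal(unlist(al$path[nrow(al$path), c("i", "j")]), c(i = n_i, j = n_j))
    steps <- cbind(diff(al$path$i), diff(al$path$j))
    expect_true(all(steps %in% 0:1) && all(rowSums(steps) >= 1))
    expect_equal(al$total_cost, sum(cost[as.matrix(al$path[, c("i", "j")])]),
                 tolerance = 1e-12)
  }
})

test_that("the alignment slope recovers a planted two-fold time warp", {
  cfgw <- sim_config(seed = 9, warp_factor = 2, de_fraction = 0.5, effect_size_sd = 2,
                     n_proteins = 150, module_sizes = c(15, 15),
                     species_specs = list(
                       human = species_spec(8, c("control", "gA", "gB"),
                                            seq(12, 120, by = 12), 2, FALSE),
                       pig = species_spec(6, c("sham", "mild", "severe"),
                                          seq(6, 60, by = 6), 2, TRUE)))
  st <- generate_study(cfgw)
  fh <- impute_half_min(filter_detection(st$human))
  fp <- impute_half_min(filter_detection(st$pig))
  comb <- zscore_within_species(fh, fp, st$ortholog_map)
  species <- attr(comb, "species")
  tp <- st$samples$timepoint_h[match(colnames(comb), st$samples$sample_id)]
  prof <- function(sp) {
    sel <- species == sp & tp > 0
    tps <- sort(unique(tp[sel]))
    list(t = tps, m = sapply(tps, function(t)
      rowMeans(unclass(comb)[, sel & tp == t, drop = FALSE])))
  }
  hu <- prof("human"); pg <- prof("pig")
  sh <- smooth_profiles(hu$t, hu$m, 4)
  sp_ <- smooth_profiles(pg$t, pg$m, 4)
  al <- dtw_align(sh$values, sp_$values, sh$time, sp_$time)
  slope <- warp_slope(al)
  expect_gt(slope, 1.5)
  expect_lt(slope, 2.5)
})
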
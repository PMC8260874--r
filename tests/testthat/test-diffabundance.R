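# Shared small dataset: 40 proteins, two-group design, no missingness.
de_fixture <- function(seed = 1, n_p = 40, n_per = 8, effect_rows = 1:5) {
  set.seed(seed)
  n_s <- 2 * n_per
  row_sd <- exp(rnorm(n_p, log(0.7), 0.4))  # heteroscedastic: finite EB prior
  vals <- matrix(rnorm(n_p * n_s, 10, row_sd[rep(1:n_p, n_s)]), n_p, n_s,
                 dimnames = list(sprintf("P%03d", 1:n_p), sprintf("s%02d", 1:n_s)))
  grp <- rep(0:1, each = n_per)
  vals[effect_rows, grp == 1] <- vals[effect_rows, grp == 1] + 2
  meta <- data.frame(sample_id = colnames(vals), injured = grp,
                     subject = rep(sprintf("u%02d", 1:n_per), 2))
  list(m = abundance_matrix(vals, "log2"), meta = meta)
}

test_that("shrinkage limits: d0 = 0 reproduces OLS t, d0 = Inf pools variances", {
  fx <- de_fixture()
  des <- design_spec("injured", "binary")
  de0 <- fit_moderated_lm(fx$m, fx$meta, des, d0 = 0)
  # per-protein OLS oracle via lm()
  for (g in c(1, 7, 40)) {
    fit <- lm(unclass(fx$m)[g, ] ~ fx$meta$injured)
    t_ols <- summary(fit)$coefficients[2, "t value"]
    expect_equal(de0$t_mod[g], t_ols, tolerance = 1e-10)
    expect_equal(de0$df_total[g], fit$df.residual)
  }
  deI <- fit_moderated_lm(fx$m, fx$meta, des, d0 = Inf)
  expect_equal(length(unique(round(deI$t_mod / deI$coef, 8))), 1)
  # with equal n and pooled variance, |t| ordering equals |coef| ordering
  expect_equal(order(abs(deI$t_mod)), order(abs(deI$coef)))
})

test_that("moderated statistics agree with the limma oracle on complete data", {
  fx <- de_fixture(seed = 5, n_p = 80)
  des <- design_spec("injured", "binary")
  de <- fit_moderated_lm(fx$m, fx$meta, des)
  X <- model.matrix(~ injured, data = fx$meta)
  ebf <- limma::eBayes(limma::lmFit(unclass(fx$m), X))
  expect_equal(attr(de, "prior")$d0, ebf$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "prior")$s0_sq, ebf$s2.prior, tolerance = 1e-6)
  expect_equal(de$t_mod, unname(ebf$t[, "injured"]), tolerance = 1e-8)
  expect_equal(de$p, unname(ebf$p.value[, "injured"]), tolerance = 1e-8)
})

test_that("moderated variance is a convex combination of s2 and s0", {
  fx <- de_fixture(seed = 7)
  de <- fit_moderated_lm(fx$m, fx$meta, design_spec("injured", "binary"))
  pr <- attr(de, "prior")
  s2_post <- (pr$d0 * pr$s0_sq + de$df_residual * de$s_sq) / (pr$d0 + de$df_residual)
  lo <- pmin(de$s_sq, pr$s0_sq); hi <- pmax(de$s_sq, pr$s0_sq)
  expect_true(all(s2_post >= lo - 1e-12 & s2_post <= hi + 1e-12))
  # moderated t = OLS t rescaled by s/s_post
  de0 <- fit_moderated_lm(fx$m, fx$meta, design_spec("injured", "binary"), d0 = 0)
  expect_equal(de$t_mod, de0$t_mod * sqrt(de$s_sq / s2_post), tolerance = 1e-10)
})

test_that("EB prior recovers chi-square simulation truth and handles edge cases", {
  # s2 ~ s0^2 * chi^2_{d0} / d0 scaled by chi^2_df sampling noise
  d0_true <- 4; s0_true <- 1; df <- 6
  d0_hat <- s0_hat <- numeric(20)
  set.seed(11)
  for (i in 1:20) {
    # scaled-inverse-chi-square prior on the true variances, chi-square
    # sampling noise on top
    s2_g <- d0_true * s0_true / stats::rchisq(2000, df = d0_true)
    s2 <- s2_g * stats::rchisq(2000, df = df) / df
    pr <- fit_eb_prior(s2, df)
    d0_hat[i] <- pr$d0; s0_hat[i] <- pr$s0_sq
  }
  expect_gt(median(d0_hat), 3); expect_lt(median(d0_hat), 5.2)
  expect_gt(median(s0_hat), 0.9); expect_lt(median(s0_hat), 1.1)

  # all-equal variances: infinite prior at that value
  pr_eq <- fit_eb_prior(rep(2.5, 10), 5)
  expect_identical(pr_eq$d0, Inf)
  expect_equal(pr_eq$s0_sq, 2.5)
  # degenerate input triggers the fallback
  expect_warning(pr2 <- fit_eb_prior(c(1, 2), c(5, 5)), "3 proteins")
  expect_identical(pr2$d0, Inf)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(3)
  p <- runif(1000)^1.5
  expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("per-protein missingness is handled by complete-case subsetting", {
  fx <- de_fixture(seed = 9)
  vals <- unclass(fx$m)
  vals[2, 1:3] <- NA          # partially missing
  vals[3, 1:15] <- NA         # only one sample left: untestable
  m <- abundance_matrix(vals, "log2")
  de <- fit_moderated_lm(m, fx$meta, design_spec("injured", "binary"))
  expect_equal(de$n_obs[2], 13)
  expect_false(de$testable[3])
  expect_true(is.na(de$q[3]))
  # protein 2 matches an OLS fit on its observed samples
  obs <- !is.na(vals[2, ])
  fit <- lm(vals[2, obs] ~ fx$meta$injured[obs])
  de0 <- fit_moderated_lm(m, fx$meta, design_spec("injured", "binary"), d0 = 0)
  expect_equal(de0$t_mod[2], summary(fit)$coefficients[2, "t value"], tolerance = 1e-10)
})

test_that("paired designs absorb subject-level offsets", {
  set.seed(21)
  n_sub <- 10; n_p <- 150
  subj_off <- rnorm(n_sub, 0, 2)   # large per-subject intercepts
  vals <- matrix(rnorm(n_p * 2 * n_sub, 8, 0.5), n_p, 2 * n_sub)
  vals <- vals + rep(subj_off, each = 1)[rep(1:n_sub, 2)][col(vals)]
  dimnames(vals) <- list(sprintf("P%03d", 1:n_p), sprintf("s%02d", 1:(2 * n_sub)))
  meta <- data.frame(sample_id = colnames(vals),
                     injured = rep(0:1, each = n_sub),
                     subject = rep(sprintf("u%02d", 1:n_sub), 2))
  de <- fit_moderated_lm(abundance_matrix(vals, "log2"), meta,
                         design_spec("injured", "binary", paired_subject = "subject"))
  # no true effect: type-I error controlled despite subject offsets
  expect_lte(mean(de$p < 0.05), 0.07 + 2 * sqrt(0.05 * 0.95 / n_p))
})

test_that("ordinal, continuous and categorical encodings give sensible fits", {
  st <- generate_study(small_config(seed = 13))
  hs <- st$samples[st$samples$species == "human" & st$samples$injured == 1, ]
  m <- filter_detection(st$human)
  de_ord <- fit_moderated_lm(m, hs, design_spec("severity_grade", "ordinal_numeric"))
  truth_sev <- st$truth$severity_assoc
  strong <- truth_sev$protein[abs(truth_sev$slope) > 0.5]
  strong <- intersect(strong, de_ord$protein)
  expect_gt(mean(de_ord$q[match(strong, de_ord$protein)] < 0.05, na.rm = TRUE), 0.5)
  # recovered slopes correlate with planted slopes
  sl <- de_ord$coef[match(truth_sev$protein, de_ord$protein)]
  expect_gt(cor(sl, truth_sev$slope, use = "complete.obs"), 0.8)

  hs_all <- st$samples[st$samples$species == "human", ]  # 3 group levels
  de_cat <- fit_moderated_lm(m, hs_all, design_spec("group", "categorical"))
  expect_true(all(de_cat$t_mod[de_cat$testable] >= 0))  # moderated F
  expect_true(all(de_cat$p[de_cat$testable] >= 0 & de_cat$p[de_cat$testable] <= 1))
})

test_that("Jaccard overlap follows the set definition and conventions", {
  expect_equal(jaccard_de_overlap(list(a = c("A", "B", "C"), b = c("B", "C", "D")))["a", "b"], 0.5)
  j <- jaccard_de_overlap(list(x = c("A", "B"), y = c("A", "B"), z = c("C"), e = character()))
  expect_equal(j["x", "y"], 1)
  expect_equal(j["x", "z"], 0)
  expect_equal(j["e", "e"], 1)   # empty-empty convention
  expect_true(isSymmetric(j))
  expect_equal(unname(diag(j)), rep(1, 4))
})

test_that("recurrent associations count significant cells across analyses", {
  r1 <- data.frame(protein = c("A", "B", "C"), q = c(0.01, 0.2, 0.04))
  r2 <- data.frame(protein = c("A", "B", "C"), q = c(0.03, 0.01, 0.9))
  res <- recurrent_associations(list(sev24 = r1, sev48 = r2), q_threshold = 0.05)
  expect_equal(res$counts$n_significant[res$counts$protein == "A"], 2)
  expect_equal(res$recurrent$protein, "A")
  expect_false("C" %in% res$recurrent$protein)
})

test_that("a protein planted in both severity and outcome tops the recurrence ranking", {
  cfg <- small_config(seed = 17, severity_assoc_fraction = 0, outcome_assoc_fraction = 0,
                      de_fraction = 0.1)
  st <- generate_study(cfg)
  # plant one protein strongly in severity and outcome by direct injection
  hs <- st$samples[st$samples$species == "human" & st$samples$injured == 1, ]
  vals <- unclass(st$human)
  tgt <- setdiff(rownames(vals), st$truth$de_proteins$protein)[1]
  idx <- match(hs$sample_id, colnames(vals))
  vals[tgt, idx] <- vals[tgt, idx] + 1.5 * hs$severity_grade +
    1.5 * ifelse(is.na(hs$outcome_cont), 0, hs$outcome_cont)
  m <- abundance_matrix(vals, "log2")
  fits <- list()
  for (tp in c(48, 72)) {
    sub <- hs[hs$timepoint_h == tp, ]
    fits[[paste0("sev", tp)]] <- fit_moderated_lm(m, sub, design_spec("severity_grade", "ordinal_numeric"))
    fits[[paste0("out", tp)]] <- fit_moderated_lm(m, sub, design_spec("outcome_cont", "continuous"))
  }
  res <- recurrent_associations(fits)
  expect_equal(res$counts$protein[1], tgt)
  expect_gte(res$counts$n_significant[1], 2)
})
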
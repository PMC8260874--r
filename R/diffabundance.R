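#' Design specification for a univariate abundance model
#'
#' Describes how one clinical/experimental outcome is encoded and which
#' covariates enter the per-protein linear model. Outcome encodings follow
#' the study conventions: binary (e.g. injury status, grade improvement),
#' ordinal grades as equally-spaced numeric scores (A=0, B=1, C=2, ...),
#' continuous recovery measures as-is, or categorical (multi-df contrast,
#' tested with a moderated F).
#'
#' @param outcome metadata column to test.
#' @param encoding one of `"binary"`, `"ordinal_numeric"`, `"continuous"`,
#'   `"categorical"`.
#' @param covariates metadata columns adjusted for (e.g. `injury_level`,
#'   `batch`); non-numeric columns expand to indicator variables.
#' @param paired_subject optional subject column added as a fixed effect
#'   (the paired pig pre/post design).
#' @return list of class `design_spec`.
#' @export
design_spec <- function(outcome,
                        encoding = c("binary", "ordinal_numeric",
                                     "continuous", "categorical"),
                        covariates = character(),
                        paired_subject = NULL) {
  encoding <- match.arg(encoding)
  structure(list(outcome = outcome, encoding = encoding,
                 covariates = covariates, paired_subject = paired_subject),
            class = "design_spec")
}

# Build the model matrix for a design_spec; outcome columns come first after
# the intercept and are flagged via the "outcome_cols" attribute.
build_design_matrix <- function(samples, design) {
  cols <- c(design$outcome, design$covariates, design$paired_subject)
  missing_cols <- setdiff(cols, names(samples))
  assert_that(length(missing_cols) == 0,
              "design columns absent from metadata: %s",
              paste(missing_cols, collapse = ", "))
  y <- samples[[design$outcome]]
  out_var <- switch(design$encoding,
    binary = {
      u <- sort(unique(y[!is.na(y)]))
      assert_that(length(u) == 2, "binary outcome `%s` must have 2 levels", design$outcome)
      as.numeric(y == u[2])
    },
    ordinal_numeric = {
      if (is.numeric(y)) as.numeric(y)
      else as.numeric(factor(y, levels = sort(unique(y)))) - 1
    },
    continuous = as.numeric(y),
    categorical = factor(y))
  df <- data.frame(.outcome = out_var)
  for (cv in design$covariates) {
    v <- samples[[cv]]
    df[[cv]] <- if (is.numeric(v)) v else factor(v)
  }
  if (!is.null(design$paired_subject)) {
    df[[".subject"]] <- factor(samples[[design$paired_subject]])
  }
  complete <- stats::complete.cases(df)
  X <- stats::model.matrix(~., data = df[complete, , drop = FALSE])
  assign <- attr(X, "assign")
  outcome_cols <- which(assign == 1L)
  list(X = X, complete = which(complete), outcome_cols = outcome_cols)
}

#' Moderated linear-model differential abundance
#'
#' Fits an ordinary least-squares model per protein on that protein's
#' observed samples, shrinks the residual variances toward a common prior via
#' empirical Bayes ([fit_eb_prior()]), and reports moderated t (or F, for
#' categorical outcomes) statistics with Benjamini-Hochberg q-values over the
#' tested proteins. Proteins whose observed samples leave the design
#' rank-deficient (or with no residual df) are flagged untestable rather than
#' silently dropped, and are excluded from the BH family.
#'
#' @param m an [abundance_matrix()]; missing entries are handled by
#'   per-protein complete-case subsetting (no imputation here).
#' @param samples sample metadata matching `m`.
#' @param design a [design_spec()].
#' @param d0 optional override of the prior degrees of freedom: `0` turns
#'   shrinkage off (ordinary t), `Inf` pools all proteins to the common
#'   prior variance. `NULL` (default) estimates it from the data.
#' @return a `de_result` data.frame: protein, coef (log2 per outcome unit),
#'   se, df_residual, s_sq, t_mod, df_total, p, q, n_obs, testable; with the
#'   fitted [fit_eb_prior()] in attribute `prior`.
#' @export
fit_moderated_lm <- function(m, samples, design, d0 = NULL) {
  assert_that(inherits(design, "design_spec"), "`design` must come from design_spec()")
  # metadata may be a subset of the matrix columns: the analysis is fit on
  # exactly the samples listed
  orphans <- setdiff(samples$sample_id, colnames(m))
  assert_that(length(orphans) == 0, "samples absent from matrix: %s",
              paste(utils::head(orphans, 5), collapse = ", "))
  m <- abundance_matrix(unclass(m)[, samples$sample_id, drop = FALSE], scale_tag(m))
  dm <- build_design_matrix(samples, design)
  X <- dm$X
  vals <- unclass(m)[, dm$complete, drop = FALSE]
  n_prot <- nrow(vals)
  p_cols <- ncol(X)
  oc <- dm$outcome_cols
  q_df <- length(oc)
  is_f <- design$encoding == "categorical" && q_df > 1

  out <- data.frame(protein = rownames(vals),
                    coef = NA_real_, se = NA_real_, df_residual = NA_real_,
                    s_sq = NA_real_, stat_ols = NA_real_, n_obs = NA_integer_,
                    testable = FALSE, stringsAsFactors = FALSE)

  # group proteins by identical missingness pattern: one QR per pattern
  obs <- !is.na(vals)
  pat <- apply(obs, 1, function(z) paste(which(z), collapse = ","))
  for (pp in unique(pat)) {
    rows <- which(pat == pp)
    use <- obs[rows[1], ]
    n_use <- sum(use)
    out$n_obs[rows] <- n_use
    if (n_use <= p_cols) next
    Xs <- X[use, , drop = FALSE]
    qrx <- qr(Xs)
    if (qrx$rank < p_cols) next
    Y <- t(vals[rows, use, drop = FALSE])
    cf <- qr.coef(qrx, Y)
    res <- qr.resid(qrx, Y)
    df_res <- n_use - p_cols
    s2 <- colSums(res^2) / df_res
    XtXi <- chol2inv(chol(crossprod(Xs)))
    out$df_residual[rows] <- df_res
    out$s_sq[rows] <- s2
    out$testable[rows] <- TRUE
    if (is_f) {
      # extra SS for the outcome block via the reduced model
      X0 <- Xs[, -oc, drop = FALSE]
      res0 <- qr.resid(qr(X0), Y)
      out$stat_ols[rows] <- (colSums(res0^2) - colSums(res^2)) / q_df
      out$coef[rows] <- cf[oc[1], ]
    } else {
      out$coef[rows] <- cf[oc, ]
      unit <- sqrt(XtXi[oc, oc])
      out$se[rows] <- sqrt(s2) * unit
      out$stat_ols[rows] <- cf[oc, ] / out$se[rows]
    }
  }
  tested <- out$testable & out$s_sq > 0
  if (!any(tested)) stop("no testable proteins under this design", call. = FALSE)

  prior <- if (is.null(d0)) {
    fit_eb_prior(out$s_sq[tested], out$df_residual[tested])
  } else {
    s0 <- if (is.finite(d0) && d0 > 0) {
      fit_eb_prior(out$s_sq[tested], out$df_residual[tested])$s0_sq
    } else mean(out$s_sq[tested])
    list(d0 = d0, s0_sq = s0)
  }
  d0v <- prior$d0; s0 <- prior$s0_sq
  s2 <- out$s_sq; dfg <- out$df_residual
  s2_post <- if (is.infinite(d0v)) rep(s0, n_prot) else {
    if (d0v == 0) s2 else (d0v * s0 + dfg * s2) / (d0v + dfg)
  }
  df_total <- dfg + d0v
  out$df_total <- df_total
  shrink <- sqrt(s2 / s2_post)
  if (is_f) {
    out$t_mod <- out$stat_ols / s2_post
    out$p <- stats::pf(out$t_mod, q_df, df_total, lower.tail = FALSE)
  } else {
    out$t_mod <- out$stat_ols * shrink
    out$p <- 2 * stats::pt(-abs(out$t_mod), df_total)
  }
  out$p[!tested] <- NA
  out$q <- NA_real_
  out$q[tested] <- bh_adjust(out$p[tested])
  out$stat_ols <- NULL
  attr(out, "prior") <- prior
  attr(out, "design") <- design
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  pr <- attr(x, "prior")
  cat(sprintf("Moderated DE result: %d proteins (%d testable), d0 = %s, s0^2 = %.4g\n",
              nrow(x), sum(x$testable), format(pr$d0, digits = 4), pr$s0_sq))
  cat(sprintf("  q < 0.05: %d proteins\n", sum(x$q < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Empirical-Bayes prior for residual variances
#'
#' Moment-matching on log residual variances: with `s^2_g ~ s0^2 chi^2_d/d`
#' scaled-chi-square sampling, `log s^2_g` has known digamma/trigamma
#' moments; the prior df `d0` solves the excess of the observed log-variance
#' dispersion over the `trigamma(df/2)` expectation, and `s0^2` matches the
#' mean. When the empirical excess is non-positive the prior is infinite
#' (complete pooling).
#'
#' @param s_sq per-protein residual variances (> 0).
#' @param df per-protein residual degrees of freedom (>= 1); recycled.
#' @return list with `d0` (prior df, possibly `Inf`) and `s0_sq`.
#' @export
fit_eb_prior <- function(s_sq, df) {
  assert_that(all(s_sq > 0), "residual variances must be positive")
  df <- rep_len(df, length(s_sq))
  assert_that(all(df >= 1), "residual dfs must be >= 1")
  n <- length(s_sq)
  if (n < 3) {
    warning("fewer than 3 proteins: falling back to infinite prior df")
    return(list(d0 = Inf, s0_sq = mean(s_sq)))
  }
  z <- log(s_sq)
  e <- z - digamma(df / 2) + log(df / 2)
  e_bar <- mean(e)
  excess <- mean((e - e_bar)^2 * n / (n - 1) - trigamma(df / 2))
  if (!is.finite(excess) || excess <= 0) {
    # no excess dispersion beyond chi-square sampling noise: complete pooling
    return(list(d0 = Inf, s0_sq = mean(s_sq)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH over the supplied family (delegates to
#' [stats::p.adjust()]); errors on out-of-range p-values rather than
#' silently clipping.
#'
#' @param p vector of p-values in `[0,1]`.
#' @return q-values, order-preserving with respect to `p`.
#' @export
bh_adjust <- function(p) {
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Jaccard overlap between differential-abundance sets
#'
#' `J(A,B) = |A n B| / |A u B|`, with `J = 1` when both sets are empty
#' (logged convention: two timepoints at which nothing changes agree
#' perfectly).
#'
#' @param de_sets named list of protein id vectors (e.g. per timepoint).
#' @return symmetric matrix with unit diagonal.
#' @export
jaccard_de_overlap <- function(de_sets) {
  k <- length(de_sets)
  out <- matrix(1, k, k, dimnames = list(names(de_sets), names(de_sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    a <- de_sets[[i]]; b <- de_sets[[j]]
    u <- length(union(a, b))
    out[i, j] <- out[j, i] <- if (u == 0) 1 else length(intersect(a, b)) / u
  }
  out
}

#' Count recurrent protein-outcome associations
#'
#' Given moderated DE results over a grid of (outcome, timepoint) analyses,
#' counts per protein how many cells reach `q < q_threshold`, and returns
#' both the full count table and the subset with two or more significant
#' associations.
#'
#' @param results named list of `de_result` objects.
#' @param q_threshold significance cutoff on BH q-values.
#' @return list with `counts` (protein, n_significant, sorted decreasing)
#'   and `recurrent` (rows with `n_significant >= 2`).
#' @export
recurrent_associations <- function(results, q_threshold = 0.05) {
  univ <- unique(unlist(lapply(results, function(r) r$protein)))
  cnt <- stats::setNames(integer(length(univ)), univ)
  for (r in results) {
    sig <- r$protein[!is.na(r$q) & r$q < q_threshold]
    cnt[sig] <- cnt[sig] + 1L
  }
  counts <- data.frame(protein = names(cnt), n_significant = as.integer(cnt),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$n_significant, counts$protein), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts,
       recurrent = counts[counts$n_significant >= 2, , drop = FALSE])
}
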
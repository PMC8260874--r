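#' Remove batch effects from a log2 abundance matrix
#'
#' Per protein, fits least squares on `[preserve design | batch indicators]`
#' using observed entries only and subtracts the fitted batch component,
#' leaving any preserved design component untouched. Missing entries stay
#' missing — nothing is invented at this step. The fit is delegated to
#' `limma::removeBatchEffect`, which performs exactly this residualization.
#'
#' @param m an [abundance_matrix()] with `scale_tag = "log2"`.
#' @param samples sample metadata matching the columns of `m`.
#' @param batch_col metadata column holding the batch labels.
#' @param preserve character vector of metadata columns whose effects must
#'   not be absorbed into the batch correction (e.g. the group labels).
#' @return an [abundance_matrix()] with `scale_tag = "batch_corrected"`.
#' @export
remove_batch_effect <- function(m, samples, batch_col = "batch",
                                preserve = character()) {
  check_scale(m, "log2", "remove_batch_effect")
  validate_samples(samples, m)
  samples <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  batch <- factor(samples[[batch_col]])
  assert_that(!anyNA(batch), "batch column `%s` has missing values", batch_col)
  assert_that(all(table(batch) >= 2), "every batch needs >= 2 samples")
  if (nlevels(batch) < 2) {
    return(set_scale(m, "batch_corrected"))  # single batch: nothing to remove
  }
  design <- matrix(1, ncol(m), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(preserve)) {
    fml <- stats::as.formula(paste("~", paste(preserve, collapse = "+")))
    design <- stats::model.matrix(fml, data = samples)
  }
  bmat <- stats::model.matrix(~batch)[, -1, drop = FALSE]
  full <- cbind(design, bmat)
  if (qr(full)$rank < ncol(full)) {
    stop("batch is confounded with the preserved design (rank-deficient): ",
         paste(c(colnames(design)[-1], "batch"), collapse = ", "), call. = FALSE)
  }
  corrected <- limma::removeBatchEffect(unclass(m), batch = batch, design = design)
  out <- abundance_matrix(corrected, "log2")
  set_scale(out, "batch_corrected")
}

#' Filter proteins by detection rate
#'
#' Keeps proteins observed in at least `min_fraction` of samples (inclusive
#' comparison `observed/total >= min_fraction`); row order preserved.
#'
#' @param m an [abundance_matrix()].
#' @param min_fraction minimum observed fraction; default one third.
#' @return filtered [abundance_matrix()], same scale tag.
#' @export
filter_detection <- function(m, min_fraction = 1 / 3) {
  check_scale(m, c("log2", "batch_corrected"), "filter_detection")
  assert_that(min_fraction >= 0 && min_fraction <= 1,
              "`min_fraction` must be in [0,1]")
  frac <- rowMeans(!is.na(m))
  keep <- frac >= min_fraction
  if (!any(keep)) warning("filter_detection: no proteins pass; empty matrix returned")
  abundance_matrix(unclass(m)[keep, , drop = FALSE], scale_tag(m))
}

#' Half-minimum imputation of left-censored values
#'
#' Per protein, missing entries are set to half of the lowest measured value
#' on the linear scale, i.e. `(min observed log2) - 1` on the log2 scale.
#' Proteins with no observed values are dropped with a warning.
#'
#' @param m an [abundance_matrix()] (log2 or batch-corrected scale).
#' @param scope `"protein"` (default; per-protein minimum, the targeted-MS
#'   convention) or `"global"` (matrix-wide minimum).
#' @return fully observed [abundance_matrix()], same scale tag.
#' @export
impute_half_min <- function(m, scope = c("protein", "global")) {
  check_scale(m, c("log2", "batch_corrected"), "impute_half_min")
  scope <- match.arg(scope)
  vals <- unclass(m)
  all_missing <- rowSums(!is.na(vals)) == 0
  if (any(all_missing)) {
    warning(sprintf("impute_half_min: dropping %d fully-missing protein(s): %s",
                    sum(all_missing),
                    paste(utils::head(rownames(vals)[all_missing], 5), collapse = ", ")))
    vals <- vals[!all_missing, , drop = FALSE]
  }
  if (anyNA(vals)) {
    fill <- if (scope == "protein") {
      apply(vals, 1, min, na.rm = TRUE) - 1
    } else {
      rep(min(vals, na.rm = TRUE) - 1, nrow(vals))
    }
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- fill[idx[, 1]]
  }
  abundance_matrix(vals, scale_tag(m))
}

#' Combine two species into one within-species z-scored matrix
#'
#' Restricts both matrices to the orthologous protein pairs, stacks the pig
#' sample block next to the human one (rows keyed by the human id), and
#' standardizes each protein row to mean 0 / SD 1 separately within each
#' species' sample block. Proteins with zero within-species variance are
#' dropped with a warning. Requires fully observed input (impute first).
#'
#' @param human,pig imputed [abundance_matrix()] objects.
#' @param shared_map data.frame with columns `human_id`, `pig_id`.
#' @return an [abundance_matrix()] with `scale_tag = "zscored"` and a
#'   `species` attribute (character vector over columns).
#' @export
zscore_within_species <- function(human, pig, shared_map) {
  for (m in list(human, pig)) {
    check_scale(m, c("log2", "batch_corrected"), "zscore_within_species")
    assert_that(!anyNA(m), "zscore_within_species requires imputed (fully observed) input")
  }
  shared_map <- shared_map[shared_map$human_id %in% rownames(human) &
                             shared_map$pig_id %in% rownames(pig), , drop = FALSE]
  assert_that(nrow(shared_map) > 0, "empty shared protein set")
  h <- unclass(human)[shared_map$human_id, , drop = FALSE]
  p <- unclass(pig)[shared_map$pig_id, , drop = FALSE]
  zrow <- function(x) {
    s <- apply(x, 1, stats::sd)
    list(z = (x - rowMeans(x)) / s, ok = s > 0)
  }
  zh <- zrow(h); zp <- zrow(p)
  ok <- zh$ok & zp$ok
  if (!all(ok)) {
    warning(sprintf("zscore_within_species: dropping %d constant protein(s)", sum(!ok)))
  }
  combined <- cbind(zh$z[ok, , drop = FALSE], zp$z[ok, , drop = FALSE])
  rownames(combined) <- shared_map$human_id[ok]
  out <- abundance_matrix(combined, "log2")
  out <- set_scale(out, "zscored")
  attr(out, "species") <- c(rep("human", ncol(h)), rep("pig", ncol(p)))
  out
}
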
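#' Abundance matrix container
#'
#' A proteins x samples matrix of (log2-scale) abundance with `NA` marking
#' values below the detection limit, plus a `scale_tag` recording where the
#' matrix sits in the preprocessing chain. The tag may only move forward
#' along `raw -> log2 -> batch_corrected -> zscored`; each preprocessing
#' function checks it so that out-of-order calls fail loudly.
#'
#' @param values numeric matrix with unique rownames (protein ids) and unique
#'   colnames (sample ids); `NA` = missing (left-censored).
#' @param scale_tag one of `"raw"`, `"log2"`, `"batch_corrected"`, `"zscored"`.
#' @return an object of class `abund`: the matrix with a `scale_tag` attribute.
#' @export
abundance_matrix <- function(values, scale_tag = "log2") {
  assert_that(is.matrix(values) && is.numeric(values),
              "`values` must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "`values` must have protein rownames and sample colnames")
  assert_that(!anyDuplicated(rownames(values)),
              "duplicate protein ids in abundance matrix")
  assert_that(!anyDuplicated(colnames(values)),
              "duplicate sample ids in abundance matrix")
  scale_tag <- match.arg(scale_tag, scale_levels())
  assert_that(all(is.finite(values) | is.na(values)),
              "observed abundance values must be finite")
  structure(values, scale_tag = scale_tag, class = c("abund", "matrix", "array"))
}

scale_levels <- function() c("raw", "log2", "batch_corrected", "zscored")

#' @export
scale_tag <- function(m) attr(m, "scale_tag")

# Check that m's tag is one of `allowed`; used by every preprocessing stage.
check_scale <- function(m, allowed, op) {
  assert_that(inherits(m, "abund"), "%s() expects an `abund` matrix", op)
  assert_that(scale_tag(m) %in% allowed,
              "%s() requires scale_tag in {%s}, got '%s' (pipeline order: log2 -> batch -> filter -> impute -> z-score)",
              op, paste(allowed, collapse = ", "), scale_tag(m))
  invisible(TRUE)
}

set_scale <- function(m, tag) {
  attr(m, "scale_tag") <- match.arg(tag, scale_levels())
  m
}

#' @export
print.abund <- function(x, ...) {
  cat(sprintf("Abundance matrix [%s]: %d proteins x %d samples, %.1f%% missing\n",
              scale_tag(x), nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

# Restrict an abundance matrix to the samples listed in a metadata table
# (analysis subsetting); errors on metadata rows without a matrix column.
subset_to_samples <- function(m, samples) {
  validate_samples(samples)
  orphans <- setdiff(samples$sample_id, colnames(m))
  assert_that(length(orphans) == 0, "samples absent from matrix: %s",
              paste(utils::head(orphans, 5), collapse = ", "))
  abundance_matrix(unclass(m)[, samples$sample_id, drop = FALSE], scale_tag(m))
}

# Validate a sample metadata table against an abundance matrix.
validate_samples <- function(samples, m = NULL) {
  assert_that(is.data.frame(samples), "`samples` must be a data.frame")
  assert_that("sample_id" %in% names(samples), "`samples` needs a sample_id column")
  assert_that(!anyDuplicated(samples$sample_id), "duplicate sample_id in metadata")
  if (!is.null(m)) {
    orphan_m <- setdiff(colnames(m), samples$sample_id)
    orphan_s <- setdiff(samples$sample_id, colnames(m))
    if (length(orphan_m) || length(orphan_s)) {
      stop("sample id mismatch between matrix and metadata; orphans: ",
           paste(c(orphan_m, orphan_s), collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read an abundance matrix and its sample metadata
#'
#' The abundance TSV has protein ids in the first column and one column per
#' sample; empty cells are missing. The metadata TSV has one row per sample.
#' The two are cross-validated: every matrix column must appear exactly once
#' in the metadata and vice versa.
#'
#' @param path abundance TSV path.
#' @param metadata_path sample metadata TSV path.
#' @param scale_tag scale of the stored values (default `"log2"`).
#' @return list with elements `matrix` (an [abundance_matrix()]) and
#'   `samples` (data.frame), with metadata rows ordered to match the columns.
#' @export
read_abundance <- function(path, metadata_path, scale_tag = "log2") {
  assert_that(file.exists(path), "abundance file not found: %s", path)
  assert_that(file.exists(metadata_path), "metadata file not found: %s", metadata_path)
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  assert_that(ncol(tab) >= 2, "abundance table needs an id column plus samples")
  ids <- as.character(tab[[1]])
  assert_that(!anyDuplicated(ids), "duplicate protein id in %s", path)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  samples <- utils::read.delim(metadata_path, check.names = FALSE,
                               comment.char = "#", stringsAsFactors = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  m <- abundance_matrix(vals, scale_tag = scale_tag)
  validate_samples(samples)
  orphan <- setdiff(colnames(m), samples$sample_id)
  assert_that(length(orphan) == 0, "metadata is missing sample id(s): %s",
              paste(utils::head(orphan, 10), collapse = ", "))
  # metadata may describe additional samples (e.g. the other species' block
  # of a shared study file); keep the rows matching this matrix, in order
  samples <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  list(matrix = m, samples = samples)
}

#' Write an abundance matrix (and optionally metadata) as TSV
#'
#' Missing values are written as empty cells so that a write/read round-trip
#' reproduces the matrix and its missingness mask exactly.
#'
#' @param m an [abundance_matrix()].
#' @param path output TSV path.
#' @param provenance optional named list written as leading `#` comment lines.
#' @export
write_abundance <- function(m, path, provenance = NULL) {
  df <- data.frame(protein = rownames(m), m, check.names = FALSE)
  write_tsv_prov(df, path, provenance)
  invisible(path)
}

#' @rdname write_abundance
#' @param samples sample metadata data.frame.
#' @export
write_sample_table <- function(samples, path, provenance = NULL) {
  write_tsv_prov(samples, path, provenance)
  invisible(path)
}

# TSV writer with `#` provenance header lines; NA -> empty cell.
write_tsv_prov <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (k in names(provenance)) {
      writeLines(sprintf("# %s: %s", k,
                         paste(format(provenance[[k]], digits = 15), collapse = ",")), con)
    }
  }
  utils::write.table(format_tsv_na(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

format_tsv_na <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      x <- format(df[[j]], digits = 15, trim = TRUE, scientific = FALSE)
      x[is.na(df[[j]])] <- NA
      df[[j]] <- x
    }
  }
  df
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, `name TAB description TAB member TAB member ...`.
#'
#' @param path GMT file path.
#' @return named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), "GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an ortholog pairing table
#'
#' Two-column TSV `human_id TAB pig_id`, one pair per line.
#' @param path TSV path.
#' @return data.frame with columns `human_id`, `pig_id`.
#' @export
read_ortholog_map <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  assert_that(ncol(tab) >= 2, "ortholog map needs two columns")
  names(tab)[1:2] <- c("human_id", "pig_id")
  tab[, 1:2]
}
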
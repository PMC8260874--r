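#' Simulation configuration for a two-species biofluid proteomics study
#'
#' Bundles and validates every knob of the synthetic-data generator. Defaults
#' emulate a human acute-injury cohort (uninjured controls plus three ordinal
#' severity grades, five CSF/serum sampling timepoints over the first five
#' days) paired with a porcine injury model (sham plus three contusion
#' severities, paired pre-injury baselines, seven timepoints), targeted-MS
#' scale (~330 proteins, plate batch shifts, left-censoring at the LLOQ).
#'
#' @param n_proteins proteins quantified per species.
#' @param shared_protein_fraction fraction of proteins with a one-to-one
#'   ortholog quantified in both species.
#' @param species_specs named list (`human`, `pig`) of per-species designs;
#'   see [species_spec()].
#' @param module_sizes sizes of planted coexpression modules (drawn from the
#'   shared proteins).
#' @param within_module_corr within-module correlation of the noise component
#'   (latent one-factor model with loading `sqrt(within_module_corr)`).
#' @param conserved_module_fraction fraction of modules whose factor structure
#'   is shared across species; the rest get independently re-drawn pig
#'   loadings (divergent coexpression).
#' @param de_fraction fraction of proteins with a planted injury effect.
#' @param effect_size_sd SD (log2 units) of peak injury effect sizes: signs
#'   are random and magnitudes follow a half-normal with this scale,
#'   truncated below at `min_effect`.
#' @param min_effect smallest planted peak effect magnitude (log2). Defaults
#'   to `noise_sd`: an injected effect below one residual SD is not a
#'   meaningful ground-truth positive.
#' @param shared_effect_fraction fraction of injury-affected proteins whose
#'   effect is present in both species (the rest are human-only).
#' @param severity_assoc_fraction,severity_slope_sd fraction of proteins with
#'   a severity-grade trend and the SD (log2 per grade step) of its slope.
#' @param outcome_assoc_fraction,outcome_slope_sd fraction of proteins linked
#'   to the continuous recovery outcome and the SD of the per-unit slope.
#' @param outcome_severity_corr correlation between a subject's continuous
#'   recovery outcome and their (standardized) severity grade; negative by
#'   default (worse injuries recover less).
#' @param batch_sd SD (log2) of per-protein plate/batch offsets.
#' @param noise_sd SD (log2) of the residual noise component.
#' @param lod_quantile per-species quantile of the latent abundance below
#'   which values are left-censored (reported missing).
#' @param warp_factor factor by which pig dynamics run faster than human:
#'   a pig sampled at `t` hours is at the same biological stage as a human at
#'   `warp_factor * t` hours.
#' @param dropout fraction of scheduled samples lost at random (catheter
#'   loss etc.); 0 keeps the full design grid.
#' @param baseline_mean,baseline_sd distribution of per-protein baseline
#'   log2 abundance.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 330,
                       shared_protein_fraction = 0.8,
                       species_specs = list(
                         human = species_spec(
                           n_subjects_per_group = 20,
                           groups = c("control", "grade_A", "grade_B", "grade_C"),
                           timepoints = c(24, 48, 72, 96, 120),
                           n_batches = 4, paired = FALSE),
                         pig = species_spec(
                           n_subjects_per_group = 10,
                           groups = c("sham", "mild", "moderate", "severe"),
                           timepoints = c(12, 24, 48, 72, 120, 240),
                           n_batches = 3, paired = TRUE)),
                       module_sizes = c(25, 25, 20, 20),
                       within_module_corr = 0.6,
                       conserved_module_fraction = 0.5,
                       de_fraction = 0.3,
                       effect_size_sd = 1.5,
                       min_effect = NULL,
                       shared_effect_fraction = 0.8,
                       severity_assoc_fraction = 0.15,
                       severity_slope_sd = 0.5,
                       outcome_assoc_fraction = 0.15,
                       outcome_slope_sd = 0.5,
                       outcome_severity_corr = -0.5,
                       batch_sd = 0.3,
                       noise_sd = 0.5,
                       lod_quantile = 0.05,
                       warp_factor = 1,
                       dropout = 0,
                       baseline_mean = 18,
                       baseline_sd = 2,
                       seed = 1L) {
  cfg <- as.list(environment())
  frac_fields <- c("shared_protein_fraction", "conserved_module_fraction",
                   "de_fraction", "shared_effect_fraction",
                   "severity_assoc_fraction", "outcome_assoc_fraction",
                   "lod_quantile", "dropout")
  for (f in frac_fields) {
    assert_that(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1L &&
                  cfg[[f]] >= 0 && cfg[[f]] <= 1,
                "sim_config field `%s` must be a fraction in [0,1]", f)
  }
  assert_that(n_proteins >= 1, "sim_config field `n_proteins` must be positive")
  assert_that(sum(module_sizes) <= n_proteins,
              "sim_config field `module_sizes` must sum to <= n_proteins")
  assert_that(all(module_sizes >= 2),
              "sim_config field `module_sizes` entries must be >= 2")
  assert_that(within_module_corr >= 0 && within_module_corr <= 1,
              "sim_config field `within_module_corr` must be in [0,1]")
  assert_that(warp_factor > 0, "sim_config field `warp_factor` must be > 0")
  assert_that(all(c("human", "pig") %in% names(species_specs)),
              "sim_config field `species_specs` needs `human` and `pig` entries")
  for (sp in names(species_specs)) {
    s <- species_specs[[sp]]
    assert_that(all(diff(s$timepoints) > 0),
                "sim_config field `species_specs$%s$timepoints` must be strictly increasing", sp)
    assert_that(length(s$groups) >= 3,
                "sim_config field `species_specs$%s$groups` needs control plus >=2 grades", sp)
  }
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @param n_subjects_per_group subjects in each group (first group = uninjured
#'   control/sham).
#' @param groups group labels; the first is the control group, the rest are
#'   ordinal severity grades 1, 2, ...
#' @param timepoints post-injury sampling times, hours, strictly increasing.
#' @param n_batches number of processing plates/batches.
#' @param paired if TRUE every subject (including shams) also contributes a
#'   pre-injury baseline sample at t = 0 (the porcine intrathecal-port
#'   design); if FALSE controls are separate subjects sampled once.
#' @export
species_spec <- function(n_subjects_per_group, groups, timepoints,
                         n_batches = 1, paired = FALSE) {
  list(n_subjects_per_group = n_subjects_per_group, groups = groups,
       timepoints = timepoints, n_batches = n_batches, paired = paired)
}

# Signed truncated half-normal effect sizes: |e| ~ |N(0, sd)| given |e| >= lo.
rtrunc_signed <- function(n, sd, lo) {
  if (n == 0) return(numeric())
  f_lo <- 2 * stats::pnorm(lo / sd) - 1
  u <- stats::runif(n, f_lo, 1)
  mag <- sd * stats::qnorm((u + 1) / 2)
  sample(c(-1, 1), n, replace = TRUE) * mag
}

# Library of canonical post-injury temporal shapes, each scaled to peak
# magnitude 1 over t >= 0. T = latest human timepoint (hours).
temporal_profiles <- function(T) {
  list(
    early_spike = function(t) ifelse(t <= 0, 0, (t / (T / 5)) * exp(1 - t / (T / 5))),
    delayed_rise = function(t) ifelse(t <= 0, 0, stats::plogis((t - 0.6 * T) / (0.08 * T))),
    monotone_decline = function(t) ifelse(t <= 0, 0, exp(-t / (0.4 * T))),
    sustained = function(t) ifelse(t <= 0, 0, 1 - exp(-t / (0.15 * T)))
  )
}

#' Generate a paired two-species synthetic proteomics study
#'
#' Builds human and pig abundance matrices over a planted latent model:
#' per-protein baseline + injury effect x temporal profile (pig time warped
#' `warp_factor`x faster) + severity-grade slope + subject-outcome slope +
#' module factor + batch offset + noise, then left-censors values below the
#' per-species LLOQ quantile. Returns the matrices, a combined sample table
#' and a complete ground-truth ledger for parameter-recovery testing.
#'
#' @param config a [sim_config()].
#' @return list with `human`, `pig` ([abundance_matrix()], scale `log2`),
#'   `samples` (both species), `truth` (ground-truth ledger, see details),
#'   and `ortholog_map` (data.frame of shared protein id pairs).
#' @details The truth ledger records: `de_proteins` (id, per-species effect
#'   size, profile), `severity_assoc` and `outcome_assoc` slopes,
#'   `module_membership` and `module_conserved`, `batch_offsets`,
#'   `warp_map` (human hours -> pig hours: `h / warp_factor`),
#'   `censoring_threshold` per species, and the seed.
#' @export
generate_study <- function(config = sim_config()) {
  assert_that(inherits(config, "sim_config"), "`config` must come from sim_config()")
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  n <- cfg$n_proteins
  n_shared <- round(cfg$shared_protein_fraction * n)
  shared_ids <- sprintf("P%04d", seq_len(n_shared))
  prot_ids <- list(
    human = c(shared_ids, sprintf("HS%04d", seq_len(n - n_shared))),
    pig   = c(shared_ids, sprintf("SS%04d", seq_len(n - n_shared))))

  T_h <- max(cfg$species_specs$human$timepoints)
  profiles <- temporal_profiles(T_h)

  # --- planted protein-level truth (defined on the human id universe; the
  # shared prefix carries over to pig) ---
  # modules first, over shared proteins, mutually disjoint; mean effects
  # (injury/severity/outcome) are planted outside them so that module
  # correlations stay purely factor-driven (analytically known within- and
  # between-species correlations for the conservation tests)
  n_mod <- length(cfg$module_sizes)
  mod_pool <- sample.int(n_shared, sum(cfg$module_sizes))
  module_membership <- integer(n)
  off <- 0
  for (m in seq_len(n_mod)) {
    module_membership[mod_pool[off + seq_len(cfg$module_sizes[m])]] <- m
    off <- off + cfg$module_sizes[m]
  }
  free <- which(module_membership == 0)

  n_de <- min(round(cfg$de_fraction * n), length(free))
  de_idx <- sort(sample(free, n_de))
  de_effect <- rtrunc_signed(n_de, cfg$effect_size_sd,
                             cfg$min_effect %||% cfg$noise_sd)
  de_profile <- sample(names(profiles), n_de, replace = TRUE)
  # shared effects must live on shared proteins to be observable in pig
  de_shared <- de_idx <= n_shared &
    stats::runif(n_de) < cfg$shared_effect_fraction

  n_sev <- min(round(cfg$severity_assoc_fraction * n), length(free))
  sev_idx <- sort(sample(free, n_sev))
  sev_slope <- stats::rnorm(n_sev, 0, cfg$severity_slope_sd)

  n_out <- min(round(cfg$outcome_assoc_fraction * n), length(free))
  out_idx <- sort(sample(free, n_out))
  out_slope <- stats::rnorm(n_out, 0, cfg$outcome_slope_sd)
  module_conserved <- rep(FALSE, n_mod)
  if (n_mod > 0) {
    n_cons <- round(cfg$conserved_module_fraction * n_mod)
    module_conserved[seq_len(n_cons)] <- TRUE
  }

  baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)

  # per-protein vectors over the full universe
  eff_h <- numeric(n); eff_h[de_idx] <- de_effect
  eff_p <- numeric(n); eff_p[de_idx[de_shared]] <- de_effect[de_shared]
  prof_id <- character(n); prof_id[de_idx] <- de_profile
  sslope <- numeric(n); sslope[sev_idx] <- sev_slope
  oslope <- numeric(n); oslope[out_idx] <- out_slope

  rho <- cfg$within_module_corr
  load_h <- sqrt(rho) * (module_membership > 0)
  # divergent modules: the shared-factor loading is re-drawn onto per-member
  # independent pig factors, i.e. the module's coexpression exists in human
  # but not in pig (loading 0 on the common factor, full-variance noise)
  load_p <- load_h
  div_member <- module_membership > 0 & !module_conserved[pmax(module_membership, 1L)]
  load_p[div_member] <- 0

  species_out <- list()
  samples_all <- list()
  batch_offsets <- list()
  censor <- list()
  for (sp in c("human", "pig")) {
    ss <- cfg$species_specs[[sp]]
    des <- build_species_design(sp, ss, cfg)
    n_s <- nrow(des)
    # subject outcome linked to severity grade
    subj <- unique(des[, c("subject_id", "severity_grade", "group")])
    inj <- subj$severity_grade > 0
    r <- cfg$outcome_severity_corr
    zg <- as.numeric(scale(subj$severity_grade[inj]))
    if (any(!is.finite(zg))) zg <- rep(0, sum(inj))
    outc <- rep(NA_real_, nrow(subj))
    outc[inj] <- r * zg + sqrt(1 - r^2) * stats::rnorm(sum(inj))
    subj$outcome_cont <- outc
    subj$outcome_bin <- ifelse(is.na(outc), NA_integer_,
                               as.integer(outc > stats::median(outc, na.rm = TRUE)))
    des <- merge(des, subj[, c("subject_id", "outcome_cont", "outcome_bin")],
                 by = "subject_id", sort = FALSE)
    des <- des[order(des$sample_id), , drop = FALSE]

    # time at which a profile is evaluated: pig biology runs warp x faster
    bio_time <- if (sp == "pig") des$timepoint_h * cfg$warp_factor else des$timepoint_h
    prof_mat <- matrix(0, n, n_s)  # profile value per protein x sample
    for (pn in names(profiles)) {
      rows <- which(prof_id == pn)
      if (!length(rows)) next
      pv <- profiles[[pn]](bio_time) * des$injured
      prof_mat[rows, ] <- matrix(pv, length(rows), n_s, byrow = TRUE)
    }
    eff <- if (sp == "pig") eff_p else eff_h
    loadv <- if (sp == "pig") load_p else load_h

    bo <- matrix(stats::rnorm(ss$n_batches * n, 0, cfg$batch_sd), n, ss$n_batches)
    colnames(bo) <- paste0("batch", seq_len(ss$n_batches))
    fac <- matrix(stats::rnorm(max(n_mod, 1) * n_s), max(n_mod, 1), n_s)
    eps <- matrix(stats::rnorm(n * n_s), n, n_s)

    mod_row <- pmax(module_membership, 1L)
    noise <- cfg$noise_sd *
      (loadv * fac[mod_row, , drop = FALSE] +
         sqrt(1 - loadv^2) * eps)
    outcome_term <- ifelse(is.na(des$outcome_cont), 0, des$outcome_cont)
    latent <- baseline +
      eff * prof_mat +
      outer(sslope, des$severity_grade * des$injured) +
      outer(oslope, outcome_term) +
      bo[, des$batch, drop = FALSE] +
      noise

    thr <- stats::quantile(latent, cfg$lod_quantile, names = FALSE)
    vals <- latent
    vals[vals < thr] <- NA
    rownames(vals) <- prot_ids[[sp]]
    colnames(vals) <- des$sample_id
    species_out[[sp]] <- abundance_matrix(vals, "log2")
    samples_all[[sp]] <- des
    batch_offsets[[sp]] <- bo
    censor[[sp]] <- thr
  }

  samples <- do.call(rbind, samples_all)
  rownames(samples) <- NULL

  truth <- list(
    de_proteins = data.frame(
      protein = shared_universe_id(prot_ids$human, de_idx),
      effect_size = de_effect,
      profile = de_profile,
      shared = de_shared,
      stringsAsFactors = FALSE),
    severity_assoc = data.frame(
      protein = shared_universe_id(prot_ids$human, sev_idx),
      slope = sev_slope, stringsAsFactors = FALSE),
    outcome_assoc = data.frame(
      protein = shared_universe_id(prot_ids$human, out_idx),
      slope = out_slope, stringsAsFactors = FALSE),
    module_membership = stats::setNames(module_membership[module_membership > 0],
                                        prot_ids$human[module_membership > 0]),
    module_conserved = module_conserved,
    batch_offsets = batch_offsets,
    warp_map = list(type = "linear", human_to_pig_factor = 1 / cfg$warp_factor,
                    warp_factor = cfg$warp_factor),
    censoring_threshold = censor,
    seed = cfg$seed)

  list(human = species_out$human, pig = species_out$pig,
       samples = samples, truth = truth,
       ortholog_map = data.frame(human_id = shared_ids, pig_id = shared_ids,
                                 stringsAsFactors = FALSE))
}

shared_universe_id <- function(ids, idx) ids[idx]

# Expand a species design grid into one row per collected sample.
build_species_design <- function(sp, ss, cfg) {
  groups <- ss$groups
  grades <- seq_along(groups) - 1L  # control = 0
  subj <- data.frame(
    subject_id = sprintf("%s_s%03d", sp, seq_len(length(groups) * ss$n_subjects_per_group)),
    group = rep(groups, each = ss$n_subjects_per_group),
    severity_grade = rep(grades, each = ss$n_subjects_per_group),
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(subj))) {
    is_ctrl <- subj$severity_grade[i] == 0
    if (ss$paired) {
      tps <- c(0, ss$timepoints)
    } else {
      tps <- if (is_ctrl) 0 else ss$timepoints
    }
    rows[[i]] <- data.frame(
      subject_id = subj$subject_id[i], group = subj$group[i],
      severity_grade = subj$severity_grade[i], timepoint_h = tps,
      stringsAsFactors = FALSE)
  }
  des <- do.call(rbind, rows)
  des$injured <- as.integer(des$severity_grade > 0 & des$timepoint_h > 0)
  if (cfg$dropout > 0) {
    keep <- stats::runif(nrow(des)) >= cfg$dropout
    # never drop a subject's only sample
    des <- des[keep | !duplicated(des$subject_id), , drop = FALSE]
  }
  des$species <- sp
  des$biofluid <- "csf"
  des$injury_level <- sample(c("cervical", "thoracic", "lumbar"), nrow(des), replace = TRUE)
  des$batch <- sample(rep_len(seq_len(ss$n_batches), nrow(des)))
  des$sample_id <- sprintf("%s_%s_t%04d", des$subject_id,
                           substr(des$species, 1, 1), des$timepoint_h)
  des[order(des$sample_id),
      c("sample_id", "subject_id", "species", "biofluid", "timepoint_h",
        "group", "severity_grade", "injured", "injury_level", "batch")]
}

#' Generate a gene-set collection over a protein universe
#'
#' A stated fraction of sets coincide with planted module memberships
#' (positive controls for set-level conservation tests); the remainder are
#' uniform random draws with sizes from `size_range`.
#'
#' @param protein_ids protein universe.
#' @param n_sets number of sets.
#' @param size_range length-2 integer vector, inclusive size bounds.
#' @param overlap_with_modules fraction of sets copied from `modules`.
#' @param modules optional named list of character vectors (planted module
#'   memberships); required when `overlap_with_modules > 0`.
#' @param seed integer seed.
#' @return named list of character vectors (GMT-writable via [write_gmt()]).
#' @export
generate_gene_sets <- function(protein_ids, n_sets, size_range = c(3, 50),
                               overlap_with_modules = 0, modules = NULL,
                               seed = 1L) {
  assert_that(length(size_range) == 2 && size_range[1] >= 2 &&
                size_range[2] <= length(protein_ids) &&
                size_range[1] <= size_range[2],
              "size_range infeasible for a universe of %d proteins",
              length(protein_ids))
  if (overlap_with_modules > 0) {
    assert_that(!is.null(modules) && length(modules) > 0,
                "`modules` required when overlap_with_modules > 0")
  }
  with_seed(seed, {
    n_mod_sets <- round(overlap_with_modules * n_sets)
    sets <- list()
    if (n_mod_sets > 0) {
      pick <- rep_len(seq_along(modules), n_mod_sets)
      for (i in seq_len(n_mod_sets)) {
        sets[[sprintf("MODULE_SET_%02d", i)]] <- modules[[pick[i]]]
      }
    }
    for (i in seq_len(n_sets - n_mod_sets)) {
      sz <- sample(size_range[1]:size_range[2], 1L)
      sets[[sprintf("RANDOM_SET_%03d", i)]] <- sample(protein_ids, sz)
    }
    sets
  })
}

#' Write all generator outputs to a directory
#'
#' Emits `abundance_human.tsv`, `abundance_pig.tsv`, `metadata.tsv`,
#' `ortholog_map.tsv`, `gene_sets.gmt` and `truth.json`.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @param gene_sets optional gene-set list from [generate_gene_sets()].
#' @export
write_study <- function(study, dir, gene_sets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(tool = "conservatome", seed = study$truth$seed)
  write_abundance(study$human, file.path(dir, "abundance_human.tsv"), prov)
  write_abundance(study$pig, file.path(dir, "abundance_pig.tsv"), prov)
  write_sample_table(study$samples, file.path(dir, "metadata.tsv"), prov)
  write_tsv_prov(study$ortholog_map, file.path(dir, "ortholog_map.tsv"), prov)
  if (!is.null(gene_sets)) write_gmt(gene_sets, file.path(dir, "gene_sets.gmt"))
  truth <- study$truth
  truth$module_membership <- as.list(truth$module_membership)
  truth$batch_offsets <- lapply(truth$batch_offsets, function(b) {
    stats::setNames(lapply(seq_len(ncol(b)), function(j) unname(b[, j])), colnames(b))
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
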
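#' Read a pipeline configuration from JSON
#'
#' The config either names input files (`inputs`: abundance/metadata/
#' ortholog/GMT paths) or contains a `simulate` block of [sim_config()]
#' overrides — one of the two must be present. Stage toggles and per-stage
#' overrides live under `stages`; `out_dir` and `seed` are global.
#'
#' @param path JSON file path.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a config list built in code.
#' @export
as_pipeline_config <- function(cfg) {
  assert_that(!is.null(cfg$inputs) || !is.null(cfg$simulate),
              "pipeline config needs either an `inputs` or a `simulate` block")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "conservatome_out"
  cfg$stages <- cfg$stages %||% list()
  structure(cfg, class = "pipeline_config")
}

# Materialize the study named by a config: simulate or load from disk.
resolve_study <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sc <- do.call(sim_config, sim_args)
    study <- generate_study(sc)
    n_sets <- cfg$stages$gene_sets$n_sets %||% 40
    modules <- split(names(study$truth$module_membership),
                     study$truth$module_membership)
    study$gene_sets <- generate_gene_sets(
      rownames(study$human), n_sets = n_sets,
      overlap_with_modules = cfg$stages$gene_sets$overlap_with_modules %||% 0.2,
      modules = modules, seed = child_seed(cfg$seed, "gene_sets"))
    study$config <- sc
    return(study)
  }
  inp <- cfg$inputs
  hum <- read_abundance(inp$human_abundance, inp$metadata)
  pig <- if (!is.null(inp$pig_abundance)) {
    read_abundance(inp$pig_abundance, inp$metadata)
  }
  list(human = hum$matrix, pig = pig$matrix %||% NULL,
       samples = hum$samples,
       gene_sets = if (!is.null(inp$gmt)) read_gmt(inp$gmt),
       ortholog_map = if (!is.null(inp$ortholog_map)) read_ortholog_map(inp$ortholog_map),
       truth = NULL)
}

stage_on <- function(cfg, stage, default = TRUE) {
  v <- cfg$stages[[stage]]
  if (is.null(v)) return(default)
  if (is.logical(v)) return(v)
  !isFALSE(v$enabled)
}

prov <- function(cfg, stage, ...) {
  c(list(tool = paste("conservatome", utils::packageVersion("conservatome")),
         stage = stage, seed = cfg$seed), list(...))
}

#' Within-species biomarker workflow
#'
#' Runs the single-species analysis chain on one species' data: detection
#' filtering, per-timepoint moderated differential abundance for each
#' configured outcome, DE-count and Jaccard-overlap summaries, the
#' recurrent-association table, and (optionally) trajectory consensus
#' clustering with gene-set enrichment. Every table is written under
#' `out_dir` with `#` provenance headers; a stage failure aborts with the
#' stage named, keeping earlier outputs.
#'
#' @param cfg a `pipeline_config` (see [read_pipeline_config()]); relevant
#'   stage blocks: `de` (`outcomes`: list of [design_spec()] argument lists;
#'   `q_threshold`), `cluster` (`k_range`, `n_subsamples`, `gmt` toggles).
#' @param species which species block to analyze when the config simulates
#'   both.
#' @return invisible list with `de` (per outcome x timepoint), `de_counts`,
#'   `jaccard`, `recurrent`, `clustering`, `enrichment`, `study`.
#' @export
run_within_species <- function(cfg, species = "human") {
  cfg <- as_pipeline_config(unclass(cfg))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- run_stage("load", cfg, resolve_study(cfg))
  m <- study[[species]]
  samples <- study$samples[study$samples$species == species, , drop = FALSE]

  m <- run_stage("filter", cfg,
                 filter_detection(m, cfg$stages$filter$min_fraction %||% (1 / 3)))

  outcomes <- cfg$stages$de$outcomes %||% list(
    list(outcome = "injured", encoding = "binary"),
    list(outcome = "severity_grade", encoding = "ordinal_numeric"),
    list(outcome = "outcome_cont", encoding = "continuous"))
  q_thr <- cfg$stages$de$q_threshold %||% 0.05
  timepoints <- sort(unique(samples$timepoint_h[samples$timepoint_h > 0]))
  ctrl <- samples$timepoint_h == 0 | samples$injured == 0

  de <- run_stage("de", cfg, {
    res <- list()
    for (oc in outcomes) {
      d <- do.call(design_spec, oc)
      for (tp in timepoints) {
        sel <- if (d$outcome == "injured") {
          ctrl | samples$timepoint_h == tp
        } else {
          !ctrl & samples$timepoint_h == tp
        }
        sub <- samples[sel, , drop = FALSE]
        if (length(unique(stats::na.omit(sub[[d$outcome]]))) < 2) next
        key <- sprintf("%s@%g", d$outcome, tp)
        msub <- abundance_matrix(unclass(m)[, sub$sample_id, drop = FALSE],
                                 scale_tag(m))
        fit <- fit_moderated_lm(msub, sub, d)
        res[[key]] <- fit
        write_tsv_prov(
          fit[, c("protein", "coef", "t_mod", "p", "q", "n_obs")],
          file.path(cfg$out_dir, sprintf("de_%s_%s_t%g.tsv", species, d$outcome, tp)),
          prov(cfg, "de", outcome = d$outcome, timepoint = tp))
      }
    }
    res
  })

  summaries <- run_stage("de_summaries", cfg, {
    inj_keys <- grep("^injured@", names(de), value = TRUE)
    de_sets <- lapply(de[inj_keys], function(r) {
      r$protein[!is.na(r$q) & r$q < q_thr]
    })
    names(de_sets) <- sub("^injured@", "", inj_keys)
    jac <- if (length(de_sets) >= 2) jaccard_de_overlap(de_sets)
    counts <- data.frame(timepoint_h = names(de_sets),
                         n_de = lengths(de_sets))
    rec <- recurrent_associations(de, q_threshold = q_thr)
    write_tsv_prov(counts, file.path(cfg$out_dir, sprintf("de_counts_%s.tsv", species)),
                   prov(cfg, "de_summaries"))
    if (!is.null(jac)) {
      write_tsv_prov(data.frame(timepoint = rownames(jac), jac, check.names = FALSE),
                     file.path(cfg$out_dir, sprintf("jaccard_%s.tsv", species)),
                     prov(cfg, "de_summaries"))
    }
    write_tsv_prov(rec$counts, file.path(cfg$out_dir, sprintf("recurrent_%s.tsv", species)),
                   prov(cfg, "de_summaries", q_threshold = q_thr))
    list(de_sets = de_sets, jaccard = jac, counts = counts, recurrent = rec)
  })

  clustering <- enrichment <- NULL
  if (stage_on(cfg, "cluster")) {
    clustering <- run_stage("cluster", cfg, {
      ctrl_label <- samples$group[ctrl][1]
      traj <- logfc_trajectories(m, samples, control_group = ctrl_label,
                                 timepoints = timepoints)
      cc <- consensus_kmeans(
        traj,
        k_range = cfg$stages$cluster$k_range %||% 2:8,
        n_subsamples = cfg$stages$cluster$n_subsamples %||% 100,
        seed = child_seed(cfg$seed, "consensus"))
      write_tsv_prov(data.frame(protein = names(cc$pruned), cluster = cc$pruned),
                     file.path(cfg$out_dir, sprintf("clusters_%s.tsv", species)),
                     prov(cfg, "cluster", chosen_k = cc$chosen_k))
      write_tsv_prov(data.frame(k = cc$k_range, cdf_area = cc$cdf_area,
                                delta_area = cc$delta_area),
                     file.path(cfg$out_dir, sprintf("delta_area_%s.tsv", species)),
                     prov(cfg, "cluster"))
      list(trajectories = traj, consensus = cc)
    })
    if (!is.null(study$gene_sets)) {
      enrichment <- run_stage("enrichment", cfg, {
        cc <- clustering$consensus
        enr <- cluster_enrichment(cc$pruned[cc$pruned > 0], study$gene_sets,
                                  background = rownames(m))
        write_tsv_prov(enr, file.path(cfg$out_dir, sprintf("enrichment_%s.tsv", species)),
                       prov(cfg, "enrichment"))
        enr
      })
    }
  }
  invisible(list(de = de, de_counts = summaries$counts,
                 jaccard = summaries$jaccard, recurrent = summaries$recurrent,
                 clustering = clustering, enrichment = enrichment,
                 study = study))
}

#' Cross-species conservation workflow
#'
#' Runs the two-species chain: detection filtering and half-minimum
#' imputation per species, within-species z-normalization over the ortholog
#' pairs, shared-timepoint modularity curves, the per-timepoint-pair RRHO
#' battery, per-protein and gene-set NACC with permutation nulls, a pi1
#' estimate (testing in pig the proteins ranked by human DE), and DTW
#' alignment of the smoothed time courses.
#'
#' @param cfg a `pipeline_config`; relevant stage blocks: `rrho` (`step`,
#'   `n_perm`), `nacc` (`k`, `n_perm`), `dtw` (`upsample_factor`),
#'   `modularity` (`densities`, `groupings`).
#' @return invisible list with `modularity`, `rrho` (matrix of grid maxima
#'   plus the per-pair results), `nacc`, `nacc_sets`, `pi0`, `alignment`,
#'   `study`.
#' @export
run_cross_species <- function(cfg) {
  cfg <- as_pipeline_config(unclass(cfg))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- run_stage("load", cfg, resolve_study(cfg))
  assert_that(!is.null(study$pig), "cross-species workflow needs two species")
  samples <- study$samples

  prep <- run_stage("preprocess", cfg, {
    fh <- impute_half_min(filter_detection(study$human))
    fp <- impute_half_min(filter_detection(study$pig))
    combined <- zscore_within_species(fh, fp, study$ortholog_map)
    list(human = fh, pig = fp, combined = combined)
  })

  shared_tp <- intersect(samples$timepoint_h[samples$species == "human"],
                         samples$timepoint_h[samples$species == "pig"])
  shared_tp <- sort(shared_tp[shared_tp > 0])

  modres <- NULL
  if (stage_on(cfg, "modularity")) {
    modres <- run_stage("modularity", cfg, {
      groupings <- cfg$stages$modularity$groupings %||%
        c("timepoint_h", "severity_grade", "group")
      curves <- lapply(c("human", "pig"), function(sp) {
        msp <- prep[[sp]]
        ssp <- samples[samples$species == sp & samples$timepoint_h > 0, , drop = FALSE]
        msp <- abundance_matrix(unclass(msp)[, ssp$sample_id, drop = FALSE],
                                scale_tag(msp))
        cv <- modularity_curve(msp, ssp, groupings,
                               densities = cfg$stages$modularity$densities %||%
                                 seq(0.1, 0.5, by = 0.1),
                               shared_timepoints = shared_tp)
        cv$species <- sp
        cv
      })
      curves <- do.call(rbind, curves)
      write_tsv_prov(curves, file.path(cfg$out_dir, "modularity_curves.tsv"),
                     prov(cfg, "modularity"))
      curves
    })
  }

  rrho_res <- NULL
  if (stage_on(cfg, "rrho")) {
    rrho_res <- run_stage("rrho", cfg, {
      hs <- samples[samples$species == "human", , drop = FALSE]
      ps <- samples[samples$species == "pig", , drop = FALSE]
      des <- design_spec("injured", "binary")
      grids <- list()
      maxima <- matrix(NA_real_, length(shared_tp), length(shared_tp),
                       dimnames = list(shared_tp, shared_tp))
      for (th in shared_tp) for (tp in shared_tp) {
        sel_h <- hs$injured == 0 | hs$timepoint_h == th
        sel_p <- ps$injured == 0 | ps$timepoint_h == tp
        mh <- abundance_matrix(unclass(prep$human)[, hs$sample_id[sel_h], drop = FALSE],
                               scale_tag(prep$human))
        mp <- abundance_matrix(unclass(prep$pig)[, ps$sample_id[sel_p], drop = FALSE],
                               scale_tag(prep$pig))
        r <- rrho_permutation_test(
          mh, mp, hs[sel_h, ], ps[sel_p, ], des, des, study$ortholog_map,
          step = cfg$stages$rrho$step %||% NULL,
          n_perm = cfg$stages$rrho$n_perm %||% 0,
          seed = child_seed(cfg$seed, sprintf("rrho_%g_%g", th, tp)))
        grids[[sprintf("h%g_p%g", th, tp)]] <- r
        maxima[as.character(th), as.character(tp)] <- r$observed_max
      }
      write_tsv_prov(data.frame(human_tp = rownames(maxima), maxima,
                                check.names = FALSE),
                     file.path(cfg$out_dir, "rrho_maxima.tsv"), prov(cfg, "rrho"))
      list(maxima = maxima, grids = grids)
    })
  }

  nacc_res <- nacc_sets <- NULL
  if (stage_on(cfg, "nacc")) {
    nacc_res <- run_stage("nacc", cfg, {
      sc <- nacc_scores(prep$combined, k = cfg$stages$nacc$k %||% 10)
      sc <- nacc_permutation_test(sc, n_perm = cfg$stages$nacc$n_perm %||% 1000,
                                  seed = child_seed(cfg$seed, "nacc"))
      write_tsv_prov(as.data.frame(sc), file.path(cfg$out_dir, "nacc_proteins.tsv"),
                     prov(cfg, "nacc"))
      sc
    })
    if (!is.null(study$gene_sets)) {
      nacc_sets <- run_stage("nacc_sets", cfg, {
        tab <- nacc_gene_set_test(nacc_res, study$gene_sets,
                                  n_perm = cfg$stages$nacc$n_perm %||% 1000,
                                  seed = child_seed(cfg$seed, "nacc_sets"))
        write_tsv_prov(tab, file.path(cfg$out_dir, "nacc_gene_sets.tsv"),
                       prov(cfg, "nacc_sets"))
        tab
      })
    }
  }

  pi0_res <- NULL
  if (stage_on(cfg, "pi1")) {
    pi0_res <- run_stage("pi1", cfg, {
      # DE in one species, test in the other: pig p-values for the proteins
      # significant in human
      hs <- samples[samples$species == "human", , drop = FALSE]
      ps <- samples[samples$species == "pig", , drop = FALSE]
      des <- design_spec("injured", "binary")
      de_h <- fit_moderated_lm(prep$human, hs, des)
      de_p <- fit_moderated_lm(prep$pig, ps, des)
      map <- study$ortholog_map
      sig_h <- de_h$protein[!is.na(de_h$q) & de_h$q < 0.05]
      pig_ids <- map$pig_id[map$human_id %in% sig_h]
      pv <- de_p$p[match(pig_ids, de_p$protein)]
      pv <- pv[!is.na(pv)]
      est <- if (length(pv) >= 50) estimate_pi0(pv) else {
        warning("pi1 stage: fewer than 50 transferable p-values; skipping")
        NULL
      }
      if (!is.null(est)) {
        write_tsv_prov(data.frame(pi0 = est$pi0, pi1 = est$pi1, n = length(pv)),
                       file.path(cfg$out_dir, "pi1.tsv"), prov(cfg, "pi1"))
      }
      est
    })
  }

  align <- NULL
  if (stage_on(cfg, "dtw")) {
    align <- run_stage("dtw", cfg, {
      comb <- prep$combined
      species <- attr(comb, "species")
      tp_of <- samples$timepoint_h[match(colnames(comb), samples$sample_id)]
      mk_prof <- function(sp, drop_late = Inf) {
        sel <- species == sp & tp_of > 0 & tp_of <= drop_late
        tps <- sort(unique(tp_of[sel]))
        prof <- sapply(tps, function(t) {
          rowMeans(unclass(comb)[, sel & tp_of == t, drop = FALSE])
        })
        list(t = tps, m = prof)
      }
      hu <- mk_prof("human")
      pg <- mk_prof("pig", drop_late = cfg$stages$dtw$pig_max_h %||% Inf)
      up <- cfg$stages$dtw$upsample_factor %||% 4
      sh <- smooth_profiles(hu$t, hu$m, upsample_factor = up)
      sp_ <- smooth_profiles(pg$t, pg$m, upsample_factor = up)
      al <- dtw_align(sh$values, sp_$values, sh$time, sp_$time)
      write_tsv_prov(al$path, file.path(cfg$out_dir, "dtw_path.tsv"),
                     prov(cfg, "dtw", warp_slope = warp_slope(al)))
      al
    })
  }

  invisible(list(modularity = modres, rrho = rrho_res, nacc = nacc_res,
                 nacc_sets = nacc_sets, pi0 = pi0_res, alignment = align,
                 study = study, preprocessed = prep))
}

# Run a stage with failure attribution and one structured log line.
run_stage <- function(stage, cfg, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[conservatome] stage=%s seed=%s elapsed=%.1fs",
                  stage, cfg$seed %||% "NA", proc.time()[["elapsed"]] - t0))
  res
}
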
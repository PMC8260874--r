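# conservatome

Statistical toolkit for two-species time-course biofluid proteomics: given
targeted mass-spectrometry (MRM/PRM) abundance matrices from a human injury
cohort and a large-animal (porcine) injury model, it quantifies what changes
after injury, what tracks severity and recovery, how temporal programs
co-regulate proteins — and how much of the injury response is conserved
between the model species and the patient.

It is written for computational biologists analyzing cerebrospinal-fluid and
serum panels of a few hundred proteins sampled serially over days post
injury, in study designs with uninjured human controls and paired pre/post
animal subjects.

## What it computes

* **Synthetic studies with ground truth** — `generate_study()` emulates the
  full two-species design (group effects with temporal profiles, severity
  and recovery associations, coexpression modules that are conserved or
  divergent across species, plate batch shifts, left-censored missingness,
  a known cross-species time warp) and emits a truth ledger for
  parameter-recovery testing.
* **Preprocessing** — batch residualization on observed entries
  (`remove_batch_effect()`), the inclusive one-third detection filter
  (`filter_detection()`), per-protein half-minimum imputation
  (`impute_half_min()`), within-species z-normalization over ortholog pairs
  (`zscore_within_species()`), with enforced pipeline order.
* **Differential abundance** — per-protein linear models with
  empirical-Bayes variance shrinkage: the prior
  $(d_0, s_0^2)$ is moment-matched on log residual variances, the
  moderated statistic uses
  $\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ on $d_g + d_0$ df,
  and q-values are Benjamini–Hochberg over the tested proteins
  (`fit_moderated_lm()`, `fit_eb_prior()`, `bh_adjust()`), plus DE-set
  summaries (`jaccard_de_overlap()`, `recurrent_associations()`).
* **Sample-network modularity** — thresholded Pearson sample networks at
  target edge density and Newman's $Q = \sum_c (e_{cc} - a_c^2)$ as a
  function of density for any sample grouping (`build_sample_network()`,
  `modularity_q()`, `modularity_curve()`).
* **Trajectory consensus clustering** — k-means consensus over protein
  subsamples with CDF-area model selection, small-cluster pruning and
  hypergeometric gene-set enrichment (`consensus_kmeans()`,
  `prune_small_clusters()`, `cluster_enrichment()`).
* **Cross-species conservation** — π1 = 1 − π0 by the smoother method
  (`estimate_pi0()`); rank–rank hypergeometric overlap grids with
  label-permutation significance (`rrho_map()`,
  `rrho_permutation_test()`); neighborhood analysis of conserved
  coexpression with per-protein and gene-set permutation tests
  (`nacc_scores()`, `nacc_permutation_test()`, `nacc_gene_set_test()`);
  and dynamic-time-warping alignment of smoothed proteome time courses
  (`smooth_profiles()`, `dtw_align()`, `warp_slope()`).
* **Workflows** — `run_within_species()` and `run_cross_species()`
  orchestrate the stages from a single JSON config with provenance-headed
  TSV outputs; `inst/cli/conservatome.R` is a thin shell entry point.

## Worked example

```r
library(conservatome)

st <- generate_study(sim_config(seed = 42))
st$human
#> Abundance matrix [log2]: 330 proteins x 320 samples, 5.0% missing

# Differential abundance at 24 h post injury vs uninjured controls
hs <- st$samples[st$samples$species == "human", ]
de <- fit_moderated_lm(filter_detection(st$human),
                       hs[hs$injured == 0 | hs$timepoint_h == 24, ],
                       design_spec("injured", "binary"))
de
#> Moderated DE result: 323 proteins (322 testable), d0 = 14.54, s0^2 = 0.3032
#>   q < 0.05: 76 proteins
head(de[order(de$q), c("protein", "coef", "t_mod", "p", "q", "n_obs")], 3)
#>     protein  coef t_mod        p        q n_obs
#> 283  HS0025 -4.03 -31.1 5.97e-46 1.92e-43    66
#> 135   P0140  2.70  19.7 6.89e-35 1.11e-32    80
#> 115   P0120 -2.72 -21.7 1.91e-33 2.05e-31    60

# Cross-species conservation of coexpression (NACC) at the gene-set level
comb <- zscore_within_species(impute_half_min(filter_detection(st$human)),
                              impute_half_min(filter_detection(st$pig)),
                              st$ortholog_map)
mods <- split(names(st$truth$module_membership), st$truth$module_membership)
nacc_gene_set_test(nacc_scores(comb, k = 10),
                   setNames(mods, paste0("module_", 1:4)),
                   n_perm = 499, seed = 2)
#>        set size mean_score         z p_conserved p_divergent
#> 1 module_1   25 0.47991941  6.999183       0.002       1.000
#> 2 module_2   25 0.45797577  6.318701       0.002       1.000
#> 3 module_3   20 0.01318989 -4.360912       1.000       0.002
#> 4 module_4   19 0.02140651 -3.936602       1.000       0.002
```

Reading the output: `coef` is the log2 abundance difference per outcome
unit, `t_mod`/`q` the moderated statistic and BH-adjusted significance;
76 of 322 testable proteins change at 24 h at a 5% FDR in this simulated
cohort. In the NACC table, the two planted conserved modules score near
0.46–0.48 mean neighbor correlation across species (conserved-tail
permutation p = 0.002, the add-one floor at 499 permutations), while the
two planted divergent modules sit at ≈0 and are flagged on the divergent
tail — exactly the planted structure (`st$truth$module_conserved` is
`TRUE, TRUE, FALSE, FALSE`).

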
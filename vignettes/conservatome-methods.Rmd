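---
title: "Methods and design notes for cross-species proteomic conservation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conservatome)
```

## The analytical problem

Two-species biofluid proteomics studies of acute neurological injury collect
targeted mass-spectrometry (MRM/PRM) abundance measurements for a few hundred
preselected proteins in cerebrospinal fluid and serum, serially over the
first days post injury, in a patient cohort and in a large-animal (porcine)
injury model. The scientific questions are layered: which proteins change
after injury, and when; which track injury severity or later neurological
recovery; whether the proteome's dominant axis of variation is time or
severity; which temporal programs co-regulate groups of proteins; and — the
translational crux — how much of the injury response is conserved between
the model species and the patient, at the level of individual proteins,
pathways, and the pace of the response itself.

`conservatome` implements that statistical chain end to end: a
synthetic-data generator with a complete ground-truth ledger, the standard
preprocessing for targeted-MS abundance tables, moderated linear-model
differential abundance, sample-network modularity, k-means consensus
clustering of temporal trajectories, and a cross-species conservation suite
(π1, RRHO, NACC, dynamic time warping).

## The synthetic-data generator

The generator is first-class, tested code: every downstream claim in the
package's test suite is checked against quantities it plants. For protein
$g$ in sample $s$ (subject $i$, time $t$, severity grade $v_i$, recovery
outcome $y_i$, batch $b$):

$$
x_{gs} = \mu_g + \beta_g\, f_{p(g)}(w\,t) \cdot \mathbb{1}[\text{injured}]
       + \gamma_g v_i + \delta_g y_i + \lambda_g F_{m(g),s} + u_{b g}
       + \sigma \varepsilon_{gs}
$$

* **Baselines** $\mu_g \sim N(18, 2^2)$ log2 units, the scale of
  concentration measurements against spiked isotopic standards.
* **Injury effects.** A fraction `de_fraction` of proteins receive a peak
  effect $\beta_g$ with random sign and half-normal magnitude (scale
  `effect_size_sd`, default 1.5 log2) truncated below at `min_effect`
  (default one residual SD). The truncation is deliberate: an "effect"
  smaller than the noise floor is not a meaningful ground-truth positive,
  and its inclusion would make planted-recovery metrics reflect the tail of
  an arbitrary prior rather than the method under test.
* **Temporal profiles** $f_p$ come from a small parametric library — early
  spike-decay, delayed rise, monotone decline, sustained — each scaled to
  peak magnitude 1 over the sampled window. A free-form curve model would
  blur cluster structure; four canonical shapes reproduce the kind of
  temporally coregulated modules that trajectory clustering is meant to
  find.
* **Cross-species warp.** Pig profiles are evaluated at $w\,t$ with
  $w =$ `warp_factor`: pig dynamics run $w\times$ faster, so a pig sampled
  at $t$ hours matches a human at $w\,t$ hours. Consequently the DTW
  alignment slope reported by `warp_slope()` is
  $\mathrm{d}(\text{human time})/\mathrm{d}(\text{pig time}) \approx w$.
  Only proteins flagged `shared` in the truth ledger carry their injury
  effect into the pig matrix (fraction `shared_effect_fraction`).
* **Coexpression modules.** Disjoint modules over the shared proteins load
  a per-sample latent factor with loading $\sqrt{\rho}$
  (`within_module_corr`), the residual scaled by $\sqrt{1-\rho}$, so the
  within-module correlation of the noise component is exactly $\rho$ —
  analytically known for the conservation tests. Mean effects
  (injury/severity/outcome) are planted *outside* the modules so module
  correlations stay purely factor-driven. Divergent modules keep their
  human structure but lose the common factor in pig (per-member independent
  noise): coexpression present in one species, absent in the other, which
  is the contrast the set-level NACC test is designed to flag.
* **Severity and recovery.** Ordinal grades enter through per-protein
  slopes; each injured subject's continuous recovery outcome is drawn from
  a normal correlated with its standardized grade
  (`outcome_severity_corr`, default −0.5: worse injuries recover less),
  and a binary outcome thresholds it at the median.
* **Batches and censoring.** Plate offsets are i.i.d. $N(0,\texttt{batch\_sd}^2)$
  per protein; missingness is left-censoring only — everything below the
  per-species `lod_quantile` of the latent matrix is reported missing —
  mirroring lower-limit-of-quantitation behavior in targeted assays. There
  is no MCAR component by design.
* **Designs.** The human arm samples separate uninjured controls once and
  injured subjects at every timepoint; the pig arm is paired, with a
  pre-injury baseline for every animal (the intrathecal-port design).
  Sample dropout, which real catheter studies suffer, is modeled as uniform
  random thinning (`dropout`, default 0) — the mechanism is not
  identifiable from published designs, so the simplest one is used and
  flagged here.

Identical configuration and seed give bit-identical output; every
stochastic entry point in the package takes an explicit seed and restores
the caller's RNG state.

## Preprocessing

The chain is log2 → batch residualization → detection filter → imputation →
(for cross-species work) within-species z-scoring, and the `scale_tag`
carried by every abundance matrix makes out-of-order calls fail loudly.
Batch correction fits, per protein, least squares on
`[preserved design | batch indicators]` over observed entries only
(delegated to `limma::removeBatchEffect`) and subtracts the batch
component; nothing is imputed at that step. The detection filter keeps
proteins observed in at least one third of samples (inclusive comparison).
Half-minimum imputation is per protein — half the lowest measured linear
value, i.e. the observed log2 minimum minus 1 — with a `scope = "global"`
alternative exposed because "lowest measured value" is ambiguous between
conventions; per-protein is the targeted-proteomics default and keeps
proteins on comparable scales. Univariate model fits never use imputed
values: they subset to each protein's observed samples.

## Moderated differential abundance

Each protein gets an OLS fit on its observed samples; outcomes are encoded
per study convention (binary; ordinal grades as equally spaced numeric
scores, so one coefficient captures the trend; continuous; or categorical,
tested with a moderated F over the indicator block). The paired pig
pre/post design uses a subject fixed effect. Residual variances are shrunk
toward a common prior: writing $e_g = \log s^2_g - \psi(d_g/2) +
\log(d_g/2)$, the prior df $d_0$ solves
$\psi'(d_0/2) = \widehat{\mathrm{Var}}(e) - \overline{\psi'(d_g/2)}$ and
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$ — the classical
moment-matching on log variances under a scaled-inverse-chi-square prior.
When the empirical excess is non-positive the prior is infinite and
$s_0^2$ is the pooled mean variance. The moderated statistic uses
$\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ with $d_g + d_0$
degrees of freedom. The test suite checks both shrinkage limits ($d_0 = 0$
reproduces ordinary t; $d_0 = \infty$ pools completely) and exact agreement
with an independent reference implementation on complete data. Proteins
whose observed samples leave the design rank-deficient are flagged
untestable and excluded from the BH family; BH q-values are computed over
tested proteins only.

## Sample networks and modularity

Sample-sample Pearson correlations are computed over proteins observed in
both samples (pairwise-complete — this module deliberately avoids imputed
values). The network at target density $d$ takes the
$\mathrm{round}(d\,n(n-1)/2)$ largest correlations, with ties broken by
sample-id order so construction is deterministic; pairs sharing fewer than
three observed proteins can never become edges. Modularity is Newman's
$Q = \sum_c (e_{cc} - a_c^2)$ on the binary thresholded graph (via igraph),
with a `weighted` variant exposed because thresholded-but-weighted networks
admit either reading; the binary form is the default since edges are
defined by thresholding. Density grids are realized by edge-count targeting
rather than threshold sweeping so curves are comparable across datasets.

## Consensus clustering of trajectories

Trajectories are per-timepoint mean log2 fold changes versus uninjured
controls. For each candidate k, 100 subsamples of 80% of proteins are
clustered by k-means (Euclidean, 10 restarts, best inertia); the consensus
matrix records co-clustering fractions among co-sampled pairs, and the
final assignment comes from average-linkage agglomeration of
1 − consensus (the direct k-means labels are discarded). Model selection
uses the area under the consensus CDF: `chosen_k` is the largest k reached
before the relative area increment falls below `elbow_tol`. The default
tolerance is 0.10: even on perfectly separated clusters, adding a spurious
k splits one true cluster differently across subsamples and inflates the
area by roughly 5–8%, while genuine splits contribute tens of percent, so a
5% tolerance would never terminate and 10% sits cleanly between the two
regimes. Clusters with fewer than three members are pruned and their
members marked unassigned. Per-cluster gene-set enrichment is the standard
upper-tail hypergeometric test over flat GMT sets with BH within cluster —
no ontology graph is consumed, so no conditional (parent-child) variant is
attempted.

## Cross-species conservation suite

**π1.** $\pi_0(\lambda) = \#\{p > \lambda\}/(n(1-\lambda))$ on
$\lambda = 0.05, \dots, 0.95$, smoothed by a natural cubic smoothing spline
(3 df) and read off at the largest $\lambda$, clipped to $[0,1]$;
$\pi_1 = 1 - \pi_0$. With several hundred p-values the tail estimate
carries Poisson noise approaching 0.1, which is why recovery checks use a
median over replicate studies.

**RRHO.** Proteins are ranked by signed significance,
$-\log_{10}p \cdot \mathrm{sign}(\hat\beta)$, ties broken by $|\hat\beta|$
then id. For prefix lengths on a stride grid (default $\approx$100×100)
the upper-tail hypergeometric probability of the prefix overlap is
computed exactly; the permutation test shuffles outcome labels within each
species (within subject for paired designs), refits both models, and
compares the maximum $-\log_{10}p$ over the whole grid, with the add-one
estimator $(1 + \#\{ \max_b \ge \max_{obs}\})/(1+B)$. The maximum is taken
over the full grid rather than the enrichment quadrant only — the
conservative reading when the spec of the statistic is ambiguous.

**NACC.** Within each species a protein-protein Pearson correlation network
is built on the within-species z-scored data (where Pearson correlation
equals covariance). For protein $g$, its k = 10 nearest human neighbors are
evaluated in pig ($d_{hp}$), the roles are swapped ($d_{ph}$), and the
symmetric score is the average — identical under species exchange by
construction. Per-protein significance compares the observed score with
scores rebuilt from uniform random neighbor sets (both directions,
self-excluded); the set-level test uses the mean member score against
size-matched random protein sets, reporting both a conserved tail
(observed ≥ null) and a divergent tail (observed ≤ null). Size bounds of
3–50 scored members per set follow gene-set-analysis convention.

**DTW.** Controls and the late pig timepoint are removed, per-protein
series are smoothed by degree-2 local polynomials on an upsampled grid
(interpolation only; below seven timepoints a loess window cannot stably
hold a quadratic, so a single global quadratic is used), and the local cost
of pairing human time i with pig time j is the Euclidean distance between
the all-protein abundance vectors. Dynamic programming with steps
{(1,0),(0,1),(1,1)}, boundary-anchored and with diagonal-preferring
backtrace, yields the optimal path; `warp_slope()` fits a line to the
path's interior (boundary-clamped cells carry no rate information) and
reports d(human)/d(pig) — the factor by which the model species' dynamics
outpace the patient's.

All permutation p-values use the add-one estimator, so they live on the
achievable grid $\{1/(B+1), \dots, 1\}$ and are never exactly zero.

## Problem sizes and what the tests show

The test suite exercises the pipeline at deliberately chosen scales: full
default studies of ~330 proteins × ~300 samples per species for structural
checks; 200-protein single-timepoint nulls over 50 replicate seeds for
type-I calibration; 1000-protein studies for π1 recovery; 2000-protein
variance simulations for the EB prior; exhaustive brute-force oracles
(all monotone paths, all hypergeometric draws, the per-edge modularity
formula) on instances small enough to enumerate. These sizes make every
check sharp while keeping a full run within a few minutes.

Passing tests on generator output demonstrates that the machinery recovers
what was planted under the generator's assumptions — Gaussian noise, linear
effects, a single latent factor per module, left-censoring-only
missingness, uniform dropout. Real targeted-proteomics data violate several
of these: heavier-tailed noise, correlated batch structure, peptide-level
artifacts, informative dropout, and ortholog mappings that are not
one-to-one. The tests therefore validate the statistics, not the biology;
conclusions about any real cohort still require the usual diagnostics on
that cohort.

## Known limitations

* Gene sets are flat protein lists; no ontology topology is used, so
  enrichment is the standard (not conditional) hypergeometric test.
* The weighted-modularity variant passes correlation weights through
  unchanged; at very high densities negative-correlation edges make
  weighted Q hard to interpret, and the binary default is recommended.
* DTW has no slope constraint or window; with grossly mismatched sampling
  ranges the boundary tails dominate and only the interior slope is
  meaningful.
* The RRHO permutation refits the full moderated model per permutation —
  exact but expensive; large batteries should lower `n_perm` or parallelize
  outside the package.
* π1 estimates inherit the selection step of the transfer design: proteins
  significant in the discovery species carry detectable effects, so weak
  shared effects bias π1 slightly downward.
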
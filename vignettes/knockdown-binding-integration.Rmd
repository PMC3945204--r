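---
title: "Inferring functional transcription-factor binding from knockdown studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring functional transcription-factor binding from knockdown studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdbind)
```

## The scientific question

Genome-wide binding maps (ChIP-seq peaks, DNase footprints) tell us where a
transcription factor (TF) sits on the genome, but not whether any particular
binding event does anything. An operational way to ask the question is to
knock the factor down with siRNA, measure genome-wide expression, and call a
binding event *functional* when the nearby gene responds. kdbind implements
this integration end to end for array-based knockdown screens:

1. **Preprocessing** — probe filtering, quantile normalization, selection of
   negative-control genes, and removal of unwanted variation (RUV-style)
   anchored on those controls, with a data-driven choice of how many hidden
   factors to remove.
2. **Differential expression** — a per-gene likelihood-ratio test of
   knockdown vs pooled controls with Storey q-values.
3. **Binding maps** — union of peak- and footprint-derived records, one
   reference TSS per gene (highest CAGE score), window- or distal-link-based
   target assignment, chromatin-state annotation.
4. **Integration** — overlap of bound and differentially expressed genes,
   chromatin-state enrichment of functional binding, site-feature
   comparisons, co-occupancy, direction of effect, and window sensitivity.

Because the original laboratory data cannot be regenerated at desk scale,
the package ships a ground-truthed simulator (`simulate_study()`) that
reproduces the *statistical structure* of such a screen, so that every
downstream claim can be tested against a known truth.

## The differential-expression model

For gene $i$ on array $j$ the expression model is

$$Y_{ij} = \mu_i + \beta_j X_i + \varepsilon_{ij},$$

where $\mu_i$ is the gene's mean, $\beta_j$ indicates whether array $j$ is a
knockdown or a control, and $X_i$ is the knockdown effect. The model with
the $\beta_j X_i$ term is compared to the nested intercept-only model by a
likelihood-ratio test: with Gaussian errors and maximum-likelihood variance
estimates the statistic is $n\,\ln(\mathrm{RSS}_0/\mathrm{RSS}_1)$, referred
to a $\chi^2_1$ distribution. At the study's group sizes (3 knockdown arrays
vs 6 pooled control profiles) the $\chi^2$ reference is anti-conservative
(type-I error ≈ 9% at the nominal 5%); `lrt_gene(..., test = "f")` exposes
the exact-F version of the same nested comparison, which the package uses
wherever calibration matters (the choice-of-k diagnostics, the calibration
tests, the co-occupancy DE-factor sets). The default reported p-values keep
the $\chi^2$ reading, which is the convention for this analysis.

Multiple testing uses Storey q-values: $\hat\pi_0(\lambda)$ is evaluated on
$\lambda = 0, 0.05, \dots, 0.90$, smoothed with a cubic smoothing spline
(df = 3), taken at $\lambda = 0.90$ and clamped into $[1/m, 1]$;
$q_i = \hat\pi_0 \min_{p_{(j)} \ge p_i} p_{(j)} m / j$. Degenerate genes
(zero residual variance) are flagged, never dropped: a perfect two-group fit
gets the smallest representable p-value, while a gene constant across *all*
arrays — which quantile normalization can produce when a gene holds the same
rank in every column — carries no evidence and gets p = 1.

The per-gene *effect size in percent* is reported as
$(2^{|\mathrm{lfc}|} - 1) \cdot 100$ (symmetric on the log scale: a halving
and a doubling are both 100%); the asymmetric alternative
$(1 - 2^{-|\mathrm{lfc}|}) \cdot 100$ is available via
`de_test(..., effect_def = "fraction")`. Array-based knockdown efficiency is
$(1 - 2^{\mathrm{lfc}}) \cdot 100$, clamped to $[0, 100]$ with out-of-range
estimates flagged.

## Removal of unwanted variation

Control genes are the per-batch least-variable genes (variance of log2
values within each batch's arrays, after quantile normalization), intersected
across batches. The pipeline sizes the per-batch list at a quarter of the
candidate genes (capped at 2,000) — the proportion a 2,000-probe list
represents on a full-size array.

Factor scores $W$ are the first $k$ array-side singular vectors of the
row-centered control-gene submatrix; each gene is then replaced by its mean
plus the residual of regressing its centered row on $W$ (`fit_ruv()` /
`apply_ruv()`). Two practical points discovered on simulated data:

* **Design protection.** The plain per-gene regression lets a factor's own
  knockdown pattern (up to −3.3 log2 on three arrays) leak into its fitted
  factor component and shift its *control* columns, which makes every
  knocked-down factor appear spuriously differentially expressed in all
  *other* experiments. At a desk-scale array count this artifact is large
  (q-values down to 5e−4). `apply_ruv(..., design = )` therefore estimates
  the coefficients jointly with the condition design (exactly the
  `removeBatchEffect` construction), and the pipeline passes the experiment
  design by default. The unprotected regression remains the default of the
  exported operation, and its residual-orthogonality identity
  ($\max |r^\top W| \le 10^{-8}$) is tested as such.
* **Choosing k** (`choose_k()`): for each candidate $k$ the diagnostics are
  (a) the number of genes differentially expressed between control arrays of
  different batches — computed on the control arrays alone, so knockdown
  arrays cannot contaminate a control-vs-control null check — which should
  reach zero; (b) the number of DE genes shared between knockdown
  experiments repeated across batches, which adjustment should preserve; and
  (c) the correlation of $-\log_{10} p$ between the repeats. The selected
  $k$ is the smallest value with (a) = 0 whose (b) is within one Poisson
  standard error of the best — at desk scale (b) is a count of order 10 and
  a pure argmax would follow its sampling noise.

## What the simulator emulates

`sim_config()` defaults describe a three-batch siRNA screen: 10 knockdown
experiments in triplicate (two of them repeated in a second batch), six
matched negative-control arrays per batch, knockdown efficiencies drawn
uniformly from 50–90%, and signed TF→target effects whose median absolute
expression change is 10% (effects are $\log_2(1 + x)$ with $x$ exponential,
so the median percent change equals the configured value exactly in
distribution). Batch structure enters through `k_true = 3` hidden factors
with batch-level mean scores (sd 1.5 — transfection batches dominate), small
array-level jitter (sd 0.1) and Gaussian gene loadings (sd 0.3); the planted
structure is deliberately low-rank so that a control-gene factor adjustment
can provably remove it at the planted number of components. Gene-level technical
noise is lognormal around `noise_sd = 0.08` log2 — bead arrays average tens
of beads per probe, so probe-level technical SDs of 0.05–0.1 are realistic —
and gene-specific, which makes the least-variable gene lists concordant
across batches as they are on real arrays. Detection p-values are a logistic
function of intensity calibrated so ~85–95% of genes pass the detection
filter.

The synthetic genome is one chromosome with a gene locus every 100 kb, 1–3
candidate TSSs per gene with CAGE-like scores, and a complete chromatin-state
tiling: ±1 kb around each true TSS is "active_promoter"; other tiles draw
from a fixed background in which strong enhancers cover ~22% — the synthetic
chromosome only represents the ±10 kb neighbourhoods of expressed genes,
i.e. active chromatin, where enhancer states are common.

Binding density follows the study scale: each factor binds
`mean_out_degree = 120` of 1,500 genes (~8–20% of the expressed genome, as in
LCL binding maps). A fraction `functional_fraction = 0.35` of a factor's
bound genes are true regulatory targets; the rest are decoys at genes the
factor does not regulate. All sites are placed within ±10 kb of the assigned
gene's TSS, sampling a chromatin-state segment with probability proportional
to its width times `promoter_affinity = 8` for the promoter tile (all sites;
decoy binding is promoter-concentrated) times `enhancer_enrichment = 5` for
strong-enhancer tiles at functional sites only. Functional targets carry
more events (1 + Pois(1.2) vs 1 + Pois(0.3)), their footprint motif scores
are shifted by `motif_shift = 1` (on a sd-1 motif scale), and conservation
is *not* shifted (`cons_shift = 0`), so a correct analysis should find
enhancer enrichment, a motif shift, more sites and larger distances at
functional genes — and no conservation shift.

Factors are organised into co-regulatory modules of ~5: module members
regulate one another (TF transcripts are regulated *only* by module
co-members) and draw 70% of their targets from a shared pool slightly larger
than the out-degree. This plants the co-occupancy structure: knockdowns of
same-module factors share differentially expressed factors whose binding
concentrates at the genes both knockdowns affect.

**Propagation is one step.** Knocking down factor $t$ perturbs $t$ and its
direct targets only; deeper cascades are represented by targets that are
themselves TFs, not by iterating the dynamics. Two consequences worth
knowing: (i) the targets of *indirectly* affected factors are not
differentially expressed, so the chromatin-state and site-feature
comparisons are run on the directly targeted factor's events (in downstream
mode, indirect factors' functional — enhancer-rich — events would all land
in the non-DE group and cancel the planted contrast); (ii) real data has
indirect effects at all depths, so passing these tests shows the machinery
recovers planted structure, not that real cascades are modelled.

## Functional-binding integration

For each experiment the universe is its expressed genes (detection p < 0.01
on all knockdown replicates or on all control arrays). A gene is *bound*
when a relevant factor has an event within the window (10 kb by default,
inclusive; an inner exclusion radius gives the promoter-excluded annulus);
relevant factors are the targeted factor (`mode = "direct"`) or the targeted
factor plus every DE factor with a binding map (`mode = "downstream"`).
Functional = bound ∧ DE. The overlap table reports both marginal fractions,
the Fisher two-sided p (full hypergeometric enumeration), the sample odds
ratio (0.5 continuity correction on zero cells, reporting only), and the
relative enrichment $aN / ((a+b)(a+c))$.

The chromatin-state test is at the *event* level: each event inherits the DE
status of its assigned gene (any, if several), and each state's 2×2 (event
in state × gene DE) is tested with Fisher's exact test, BH-adjusted across
the states present in the experiment. Site-feature comparisons use the
Wilcoxon rank-sum test: exact enumeration when both groups have ≤ 8
observations, otherwise a tie-corrected normal approximation with continuity
correction. Motif and conservation scores exist only for footprint-derived
events.

Co-occupancy: for every pair of experiments the shared fraction of DE
factors is the Jaccard index of their DE-factor sets; pairs with an empty
intersection are excluded (and counted). The enrichment is the relative
enrichment of (gene DE in both) × (gene bound by ≥ 1 shared DE factor) over
genes expressed in both, and pairs are binned into quintiles of the shared
fraction. The underlying publication never defines this statistic; the
construction lives in one function (`cooccupancy_enrichment()`) so it can be
swapped.

## Numerical and testing choices

* Coordinates are 0-based half-open for all interval files; midpoints are
  $\lfloor (start + end)/2 \rfloor$; the window predicate is inclusive at
  both ends; the footprint posterior threshold is a strict $> 0.95$.
* Distances are reported in bp; the plotted transform is
  $\log_{10}(d_\mathrm{kb} + 0.001)$ (an event at the TSS maps to −3); a bp
  scale is available.
* Tolerances: $10^{-8}$ for orthogonality and idempotence identities on the
  log2 scale; $10^{-12}$ for agreement with enumeration oracles.
* Tie-breaks: reference-TSS ties take the floor-midpoint of the tied
  positions; duplicate binding records deduplicate on
  (factor, chrom, midpoint); equal-efficiency repeated knockdowns keep the
  alphabetically first experiment.
* Monte-Carlo test sizes were fixed with the suite's total runtime in mind:
  50 seeds at 600 genes/6 knockdowns for parameter recovery; 25 seeds per
  configuration at the default 1,500-gene/10-knockdown scale for
  planted-structure recovery; 20 seeds at 20 knockdowns for the co-occupancy
  trend (45 pairs from 10 knockdowns leave quintile medians dominated by
  sampling noise; the original screen had 59 knockdowns and 1,711 pairs);
  50 seeds at 500 genes for the null-integration check. The rank-sum
  approximation is validated on continuous data for group sizes 3–8 (maximum
  observed deviation from enumeration ≈ 0.04): with 2 observations per group
  the exact two-sided p cannot go below 1/3, and with heavily tied data in
  tiny samples the permutation distribution is too coarse for any continuous
  approximation — the exact path is used whenever both groups have ≤ 8
  observations, so the approximation only ever faces larger samples.

## Known limitations

* One-step propagation (above): downstream-mode integration quantities are
  computed and reported, but planted-structure recovery is only meaningful
  for direct binding.
* The default $\chi^2$ p-values are anti-conservative at these group sizes;
  calibrated analyses should pass `test = "f"` / `de_test_method = "f"`.
* The adjust-the-data factor removal attenuates knockdown effects by roughly
  $k/(n_\mathrm{arrays}-1)$ on the log2 scale even with design protection of
  the coefficients; array-based efficiencies are therefore mild
  underestimates at high efficiency.
* The simulator plants no probe-level artifacts beyond annotation flags, no
  intensity-dependent variance, and no chromatin states outside gene
  neighbourhoods; conclusions about real arrays need real arrays.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 600, n_tfs = 18, n_knockdowns = 6, seed = 1)
study <- simulate_study(cfg)
res <- analyze_fixtures(fixtures_from_study(study))

res$k                  # number of unwanted factors removed
res$overlap_direct     # per-experiment bound x DE overlap
glance(res$de_kept[[1]])

# or, file-based:
dir <- tempfile()
kd_simulate(cfg, dir)
kd_analyze(cfg, dir, file.path(dir, "out"))
```
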
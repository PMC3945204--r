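# kdbind

Most transcription-factor (TF) binding detected by ChIP-seq or DNase
footprinting has no measurable effect on the expression of nearby genes. An
operational way to separate functional from decoy binding is to knock the
factor down with siRNA, measure genome-wide expression on arrays, and call a
binding event *functional* when the gene within a window of its site is
differentially expressed. kdbind implements that integration end to end for
array-based knockdown screens, together with a ground-truthed simulator of
such a screen so that every inference step can be validated against a known
truth.

## What it computes

For gene *i* on array *j* the expression model is

    Y_ij = mu_i + beta_j * X_i + e_ij

with `beta_j` the knockdown/control status and `X_i` the knockdown effect.
Each gene is tested by a likelihood-ratio test of this model against the
intercept-only model, `n * ln(RSS0/RSS1)` against a chi-square with 1 df (an
exact-F variant is available for calibration-sensitive work), with
Storey q-values (`pi0` from a cubic-spline fit over the
`lambda = 0, 0.05, ..., 0.90` grid) for multiple testing. Before testing,
arrays are quantile normalized and hidden nuisance factors — estimated by SVD
from the least-variable genes shared across transfection batches — are
regressed out (RUV-style), with the number of factors chosen so that no gene
is differentially expressed between control arrays of different batches
while replication between batch-repeated knockdowns stays maximal.

Binding maps are the per-factor union of ChIP-style peaks and footprint
sites (posterior > 0.95), reduced to interval midpoints; one reference TSS
per gene is picked by highest CAGE score. A gene counts as bound when a
relevant factor has an event within 10 kb of its TSS (configurable, with a
promoter-excluding inner radius and a distal-element-link alternative). The
integration layer reports the bound-by-DE overlap per experiment (Fisher's
exact test by full hypergeometric enumeration, relative enrichment
`aN/((a+b)(a+c))`), chromatin-state enrichment of functional binding (per
state, BH-adjusted), rank-sum comparisons of motif score, conservation,
TSS distance and binding load between functional and non-functional targets,
co-occupancy binned by the shared fraction of DE factors, direction of
effect, and sensitivity of everything to the window size.

## A worked example

```r
library(kdbind)

cfg <- sim_config(n_genes = 600, n_tfs = 18, n_knockdowns = 6, seed = 1)
study <- simulate_study(cfg)                 # network + genome + arrays
res <- analyze_fixtures(fixtures_from_study(study))

res$k
#> [1] 2

glance(res$de_kept[[1]])
#> # A tibble: 1 × 7
#>   experiment target n_genes  n_de   pi0 median_effect_pct kd_efficiency_pct
#> 1 G00001.b2  G00001     456    79 0.555              11.3              83.6

dplyr::select(res$overlap_direct, experiment, n_expressed, n_bound,
              n_de, n_overlap, frac_bound_de, fisher_p)
#> # A tibble: 6 × 7
#>   experiment n_expressed n_bound  n_de n_overlap frac_bound_de fisher_p
#> 1 G00001.b2          456      78    79        21         0.269 0.0205
#> 2 G00002.b3          468      89   140        42         0.472 0.000162
#> 3 G00003.b3          467      62   110        23         0.371 0.00983
#> 4 G00004.b1          477      85   111        29         0.341 0.0110
#> 5 G00005.b2          456      75   124        24         0.32  0.322
#> 6 G00006.b3          468      76    71        23         0.303 0.000193

res$site_features
#> # A tibble: 5 × 6
#>   feature     n_functional n_nonfunctional statistic    shift       p
#> 1 motif_score          101             141     13676   0.518  0.00894
#> 2 cons_score           101             141     12748   0.0162 0.375
#> 3 distance             272             442    101291 916      0.130
#> 4 n_sites              162             303     40525   0      0.0189
#> 5 n_factors            162             303     37746   0      1
```

Reading this: two unwanted-variation components were removed; the first
knockdown achieved an array-estimated efficiency of 83.6% and changed 79 of
its 456 expressed genes at FDR 5% (median effect 11.3%); per experiment,
only 27–47% of genes bound by the targeted factor responded to its
knockdown, yet the overlap is more than expected by chance in 5 of 6
experiments; and binding near responsive genes sits at higher-scoring motifs
and denser sites, with no conservation shift — exactly the structure the
simulator planted.

The same pipeline runs from files:

```r
kd_simulate(cfg, "data_dir")                  # writes TSV/BED fixtures
kd_analyze(cfg, "data_dir", "out_dir")        # writes all result tables
```

A thin shell wrapper is installed under `exec/kdbind`
(`kdbind simulate --config cfg.yaml --out DIR`,
`kdbind analyze --config cfg.yaml --data DIR --out DIR`).

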
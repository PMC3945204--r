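#' Simulation configuration for a synthetic knockdown study
#'
#' Builds and validates the configuration object that drives every generator
#' in the package. The defaults describe a desk-scale study with the same
#' statistical structure as a multi-batch siRNA knockdown screen read out on
#' expression arrays: three transfection batches carrying shared unwanted
#' variation, three knockdown replicates per experiment compared against
#' pooled negative controls, knockdown efficiencies between 50% and 90%, and
#' signed regulatory effects whose median magnitude is a ~10% change in
#' expression.
#'
#' @param n_genes Number of genes on the synthetic chromosome.
#' @param n_tfs Number of genes designated as transcription factors
#'   (`n_tfs <= n_genes`); the first `n_knockdowns` of them are targeted by
#'   an siRNA experiment.
#' @param n_knockdowns Number of knockdown experiments (`<= n_tfs`).
#' @param n_batches Number of transfection batches.
#' @param replicates_per_kd Knockdown replicate arrays per experiment.
#' @param controls_per_batch Negative-control arrays in each batch. Control
#'   arrays carry a control "type" (1..controls_per_batch) that is matched
#'   across batches so control profiles can be averaged by type.
#' @param n_repeated_kd Number of knockdown experiments repeated in a second
#'   batch (used by the data-driven choice of the number of unwanted factors
#'   to remove). May be 0 for tiny fixtures.
#' @param kd_efficiency_range Length-2 numeric in (0,1): knockdown
#'   efficiencies are drawn uniformly from this range.
#' @param median_effect_pct Median absolute percent change in expression
#'   among true regulatory targets (the magnitude of `2^effect - 1`).
#' @param mean_out_degree Mean number of bound target genes per factor; also
#'   the mean regulatory out-degree scale.
#' @param functional_fraction Fraction of a factor's bound target genes that
#'   are true regulatory targets. 0 means binding is placed independently of
#'   the regulatory network (an entirely decoy binding map).
#' @param k_true Number of planted unwanted-variation factors.
#' @param enhancer_enrichment Multiplier applied to strong-enhancer segments
#'   when placing binding sites of functional edges (1 = no preference).
#' @param motif_shift Motif-score increment at functional sites.
#' @param cons_shift Conservation-score increment at functional sites
#'   (default 0: functional and decoy sites share one conservation
#'   distribution).
#' @param detection_tau,detection_s Location and scale of the logistic curve
#'   mapping log2 intensity to a detection p-value (`plogis((tau - y)/s)`).
#'   Defaults keep roughly 85-95% of genes above the detection threshold.
#' @param noise_sd Gene-wise Gaussian noise standard deviation (log2 scale).
#' @param factor_loading_sd SD of per-gene loadings on the unwanted factors.
#' @param batch_score_sd SD of the per-batch mean of each unwanted factor.
#' @param array_jitter_sd SD of the per-array jitter around the batch mean.
#' @param baseline_mean,baseline_sd Distribution of baseline log2 intensity.
#' @param gene_spacing Distance (bp) between consecutive gene loci on the
#'   single synthetic chromosome.
#' @param promoter_affinity Weight multiplier concentrating binding sites in
#'   the +/-1 kb promoter segment (applies to all sites; decoy binding is
#'   therefore promoter-concentrated).
#' @param motif_mean,motif_sd Baseline motif-score distribution.
#' @param module_size Transcription factors are grouped into co-regulatory
#'   modules of roughly this size; factors of one module draw a share of
#'   their targets from a common pool (which also contains the module's
#'   factors), emulating co-regulation.
#' @param within_module_frac Fraction of a factor's targets drawn from its
#'   module pool (0 disables module structure).
#' @param seed Integer root seed; every generator is a pure function of
#'   (config, seed).
#'
#' @return A `kd_sim_config` list with validated fields.
#' @examples
#' cfg <- sim_config(n_genes = 200, n_tfs = 10, n_knockdowns = 4, seed = 1)
#' cfg$n_batches
#' @export
sim_config <- function(n_genes = 1500,
                       n_tfs = 40,
                       n_knockdowns = 10,
                       n_batches = 3,
                       replicates_per_kd = 3,
                       controls_per_batch = 6,
                       n_repeated_kd = 2,
                       kd_efficiency_range = c(0.5, 0.9),
                       median_effect_pct = 10,
                       mean_out_degree = 120,
                       functional_fraction = 0.35,
                       k_true = 3,
                       enhancer_enrichment = 5,
                       motif_shift = 1,
                       cons_shift = 0,
                       detection_tau = 3.5,
                       detection_s = 0.5,
                       noise_sd = 0.08,
                       factor_loading_sd = 0.3,
                       batch_score_sd = 1.5,
                       array_jitter_sd = 0.1,
                       baseline_mean = 8,
                       baseline_sd = 2,
                       gene_spacing = 1e5,
                       promoter_affinity = 8,
                       motif_mean = 12,
                       motif_sd = 1,
                       module_size = 5,
                       within_module_frac = 0.7,
                       seed = 1L) {
  cfg <- structure(
    list(
      n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
      n_knockdowns = as.integer(n_knockdowns),
      n_batches = as.integer(n_batches),
      replicates_per_kd = as.integer(replicates_per_kd),
      controls_per_batch = as.integer(controls_per_batch),
      n_repeated_kd = as.integer(n_repeated_kd),
      kd_efficiency_range = as.numeric(kd_efficiency_range),
      median_effect_pct = as.numeric(median_effect_pct),
      mean_out_degree = as.numeric(mean_out_degree),
      functional_fraction = as.numeric(functional_fraction),
      k_true = as.integer(k_true),
      enhancer_enrichment = as.numeric(enhancer_enrichment),
      motif_shift = as.numeric(motif_shift),
      cons_shift = as.numeric(cons_shift),
      detection_tau = as.numeric(detection_tau),
      detection_s = as.numeric(detection_s),
      noise_sd = as.numeric(noise_sd),
      factor_loading_sd = as.numeric(factor_loading_sd),
      batch_score_sd = as.numeric(batch_score_sd),
      array_jitter_sd = as.numeric(array_jitter_sd),
      baseline_mean = as.numeric(baseline_mean),
      baseline_sd = as.numeric(baseline_sd),
      gene_spacing = as.numeric(gene_spacing),
      promoter_affinity = as.numeric(promoter_affinity),
      motif_mean = as.numeric(motif_mean),
      motif_sd = as.numeric(motif_sd),
      module_size = as.integer(module_size),
      within_module_frac = as.numeric(within_module_frac),
      seed = as.integer(seed)
    ),
    class = "kd_sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "kd_sim_config"))
  chk <- function(ok, msg) if (!ok) abort(msg, class = "kdbind_config_error")
  counts <- c("n_genes", "n_tfs", "n_knockdowns", "n_batches",
              "replicates_per_kd", "controls_per_batch")
  for (f in counts) {
    chk(length(cfg[[f]]) == 1L && !is.na(cfg[[f]]) && cfg[[f]] >= 1L,
        paste0("`", f, "` must be a positive count"))
  }
  chk(cfg$n_repeated_kd >= 0L && cfg$n_repeated_kd <= cfg$n_knockdowns,
      "`n_repeated_kd` must be between 0 and `n_knockdowns`")
  chk(cfg$n_repeated_kd == 0L || cfg$n_batches >= 2L,
      "repeated knockdowns require at least 2 batches")
  chk(cfg$n_tfs <= cfg$n_genes, "`n_tfs` must not exceed `n_genes`")
  chk(cfg$n_knockdowns <= cfg$n_tfs, "`n_knockdowns` must not exceed `n_tfs`")
  chk(length(cfg$kd_efficiency_range) == 2L &&
        all(cfg$kd_efficiency_range > 0 & cfg$kd_efficiency_range < 1) &&
        diff(cfg$kd_efficiency_range) >= 0,
      "`kd_efficiency_range` must be an increasing pair within (0,1)")
  chk(cfg$functional_fraction >= 0 && cfg$functional_fraction <= 1,
      "`functional_fraction` must be in [0,1]")
  chk(cfg$k_true >= 0L, "`k_true` must be >= 0")
  chk(cfg$median_effect_pct > 0, "`median_effect_pct` must be positive")
  chk(cfg$enhancer_enrichment > 0, "`enhancer_enrichment` must be positive")
  chk(cfg$noise_sd >= 0 && cfg$factor_loading_sd >= 0 &&
        cfg$array_jitter_sd >= 0 && cfg$batch_score_sd >= 0,
      "noise and factor scales must be non-negative")
  chk(cfg$gene_spacing >= 40000,
      "`gene_spacing` must leave room for a +/-10 kb window plus flanks")
  chk(cfg$module_size >= 1L, "`module_size` must be >= 1")
  chk(cfg$within_module_frac >= 0 && cfg$within_module_frac <= 1,
      "`within_module_frac` must be in [0,1]")
  chk(length(cfg$seed) == 1L && !is.na(cfg$seed),
      "`seed` must be a single integer")
  cfg
}

#' Read or write a simulation configuration as YAML
#'
#' The YAML file mirrors the `sim_config()` field names; missing fields fall
#' back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return `read_sim_config()` returns a validated `kd_sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "kdbind_io_error")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")),
          class = "kdbind_config_error")
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param cfg A `kd_sim_config` object.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "kd_sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.kd_sim_config <- function(x, ...) {
  cat("<kd_sim_config>\n")
  cat(sprintf("  %d genes (%d TFs), %d knockdowns x %d replicates, %d batches\n",
              x$n_genes, x$n_tfs, x$n_knockdowns, x$replicates_per_kd,
              x$n_batches))
  cat(sprintf("  knockdown efficiency %g-%g, median effect %g%%, k_true = %d\n",
              x$kd_efficiency_range[1], x$kd_efficiency_range[2],
              x$median_effect_pct, x$k_true))
  invisible(x)
}

# All generator randomness flows through the root seed with fixed per-stage
# offsets, so each stage is reproducible in isolation.
stage_seed <- function(cfg, stage) {
  offsets <- c(network = 11L, annotation = 101L, expression = 211L)
  (cfg$seed + offsets[[stage]]) %% .Machine$integer.max
}
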
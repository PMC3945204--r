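#' Simulate the raw expression matrix of the knockdown study
#'
#' Builds the array design (knockdown experiments in batches, matched
#' negative controls in every batch, and `n_repeated_kd` experiments repeated
#' in a second batch) and simulates probe-level log2 intensities:
#'
#' observed = baseline + knockdown effect `log2(1 - kappa)` on the targeted
#' factor + one-step propagated network effects (`sign * effect` at each
#' target of the knocked-down factor) + loadings x (`k_true` batch-correlated
#' unwanted factors) + gene-wise Gaussian noise.
#'
#' Unwanted factors have per-batch mean scores plus per-array jitter and act
#' on all genes through Gaussian loadings - the structure a control-gene
#' factor adjustment is designed to remove. A detection p-value is emitted
#' per cell as a decreasing logistic function of the simulated intensity.
#'
#' Probes: most genes are measured by one probe; a random 10% get a second
#' (non-3'-most) probe and a small fraction of probes carry disqualifying
#' annotation flags, so probe filtering has work to do.
#'
#' @param cfg A [sim_config()] object.
#' @param net A [generate_network()] result from the same config.
#' @return A list of class `kd_simulation` with elements:
#'   * `mat`: a [kd_expression()] object (raw log2 intensities, detection
#'     p-values, array metadata, probe-level rows),
#'   * `probe_annotation`: tibble of probe flags,
#'   * `truth`: list with `experiments` (experiment, target, batch, kappa),
#'     `targets` (experiment, gene, sign, effect, functional) and
#'     `factors` (the unwanted-factor scores actually used).
#' @export
simulate_expression <- function(cfg, net) {
  cfg <- validate_sim_config(cfg)
  stopifnot(inherits(net, "kd_network"))
  genes <- gene_ids(cfg$n_genes)
  kd_tfs <- attr(net, "kd_tfs")

  withr::local_seed(stage_seed(cfg, "expression"))

  ## ---- design ----
  batches <- rep(seq_len(cfg$n_batches), length.out = cfg$n_knockdowns)
  exp_tbl <- tibble(target = kd_tfs, batch = batches)
  if (cfg$n_repeated_kd > 0) {
    rep_tbl <- exp_tbl[seq_len(cfg$n_repeated_kd), ]
    rep_tbl$batch <- rep_tbl$batch %% cfg$n_batches + 1L
    exp_tbl <- dplyr::bind_rows(exp_tbl, rep_tbl)
  }
  exp_tbl$experiment <- paste0(exp_tbl$target, ".b", exp_tbl$batch)
  exp_tbl$kappa <- runif(nrow(exp_tbl), cfg$kd_efficiency_range[1],
                         cfg$kd_efficiency_range[2])

  kd_arrays <- tidyr::crossing(exp_tbl,
                               replicate = seq_len(cfg$replicates_per_kd)) %>%
    dplyr::transmute(
      array_id = paste0(.data$experiment, ".r", .data$replicate),
      batch = .data$batch, condition = .data$target,
      replicate = .data$replicate, experiment = .data$experiment
    )
  ctl_arrays <- tidyr::crossing(batch = seq_len(cfg$n_batches),
                                replicate = seq_len(cfg$controls_per_batch)) %>%
    dplyr::transmute(
      array_id = paste0("CTRL.b", .data$batch, ".t", .data$replicate),
      batch = .data$batch, condition = "CONTROL",
      replicate = .data$replicate, experiment = NA_character_
    )
  arrays <- dplyr::bind_rows(kd_arrays, ctl_arrays)
  n_arr <- nrow(arrays)

  ## ---- gene-level signal ----
  baseline <- rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  names(baseline) <- genes
  # factors entering the study were screened to be well expressed: keep
  # every TF transcript comfortably above the detection threshold
  tfs <- attr(net, "tf_list")
  baseline[tfs] <- runif(length(tfs), cfg$baseline_mean - 0.5,
                         cfg$baseline_mean + 2.5)
  signal <- matrix(baseline, nrow = cfg$n_genes, ncol = n_arr,
                   dimnames = list(genes, arrays$array_id))

  for (i in seq_len(nrow(exp_tbl))) {
    cols <- which(arrays$experiment %in% exp_tbl$experiment[i])
    tgt <- exp_tbl$target[i]
    signal[tgt, cols] <- signal[tgt, cols] + log2(1 - exp_tbl$kappa[i])
    ed <- net[net$tf == tgt, ]
    if (nrow(ed) > 0) {
      signal[ed$target, cols] <- signal[ed$target, cols] +
        ed$sign * ed$effect
    }
  }

  ## ---- unwanted variation + noise ----
  W_true <- NULL
  if (cfg$k_true > 0) {
    batch_means <- matrix(rnorm(cfg$n_batches * cfg$k_true,
                                sd = cfg$batch_score_sd),
                          nrow = cfg$n_batches)
    W_true <- batch_means[arrays$batch, , drop = FALSE] +
      matrix(rnorm(n_arr * cfg$k_true, sd = cfg$array_jitter_sd),
             nrow = n_arr)
    rownames(W_true) <- arrays$array_id
    loadings <- matrix(rnorm(cfg$n_genes * cfg$k_true,
                             sd = cfg$factor_loading_sd),
                       nrow = cfg$n_genes, dimnames = list(genes, NULL))
    signal <- signal + loadings %*% t(W_true)
  }
  if (cfg$noise_sd > 0) {
    # gene-specific technical noise (lognormal around noise_sd), so
    # least-variable gene lists are concordant across batches as on real
    # arrays
    gene_sd <- pmax(cfg$noise_sd * exp(rnorm(cfg$n_genes, 0, 0.25)),
                    cfg$noise_sd / 3)
    signal <- signal + matrix(rnorm(length(signal), sd = gene_sd),
                              nrow = nrow(signal))
  }

  ## ---- probes ----
  second <- sample(genes, round(0.1 * cfg$n_genes))
  probe_ann <- dplyr::bind_rows(
    tibble(gene_id = genes, three_prime_rank = 1L),
    tibble(gene_id = second, three_prime_rank = 2L)
  ) %>%
    dplyr::arrange(.data$gene_id, .data$three_prime_rank) %>%
    dplyr::mutate(
      probe_id = paste0(.data$gene_id, "_p", .data$three_prime_rank),
      maps_uniquely = runif(dplyr::n()) > 0.02,
      secondary_hit_1mm = runif(dplyr::n()) < 0.02,
      on_chrY = runif(dplyr::n()) < 0.01,
      het_snp_overlap = runif(dplyr::n()) < 0.02
    ) %>%
    dplyr::mutate(
      # assayed factors had usable probes by construction of the study
      maps_uniquely = .data$maps_uniquely | .data$gene_id %in% tfs,
      secondary_hit_1mm = .data$secondary_hit_1mm & !.data$gene_id %in% tfs,
      on_chrY = .data$on_chrY & !.data$gene_id %in% tfs,
      het_snp_overlap = .data$het_snp_overlap & !.data$gene_id %in% tfs
    ) %>%
    dplyr::select("probe_id", "gene_id", "maps_uniquely",
                  "secondary_hit_1mm", "on_chrY", "het_snp_overlap",
                  "three_prime_rank")

  values <- signal[probe_ann$gene_id, , drop = FALSE] +
    ifelse(probe_ann$three_prime_rank > 1,
           rnorm(nrow(probe_ann), sd = 0.05), 0)
  rownames(values) <- probe_ann$probe_id
  detection_p <- detection_pvalues(values, cfg$detection_tau, cfg$detection_s)

  mat <- kd_expression(values, detection_p, arrays)

  truth <- list(
    experiments = dplyr::select(exp_tbl, "experiment", "target", "batch",
                                "kappa"),
    targets = purrr::map_dfr(seq_len(nrow(exp_tbl)), function(i) {
      ed <- net[net$tf == exp_tbl$target[i], ]
      tibble(experiment = exp_tbl$experiment[i], gene = ed$target,
             sign = ed$sign, effect = ed$effect, functional = ed$functional)
    }),
    factors = W_true
  )

  structure(list(mat = mat, probe_annotation = probe_ann, truth = truth),
            class = "kd_simulation")
}

detection_pvalues <- function(values, tau, s) {
  p <- stats::plogis((tau - values) / s)
  dimnames(p) <- dimnames(values)
  p
}

#' Run all three generators under one configuration
#'
#' Convenience wrapper: network, genome annotation and expression matrix from
#' one config, sharing ground truth.
#'
#' @param cfg A [sim_config()] object.
#' @return A list of class `kd_study` with elements `cfg`, `network`,
#'   `genome` and the `kd_simulation` fields (`mat`, `probe_annotation`,
#'   `truth`).
#' @examples
#' study <- simulate_study(sim_config(n_genes = 200, n_tfs = 8,
#'                                    n_knockdowns = 3, seed = 2))
#' study$mat
#' @export
simulate_study <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  net <- generate_network(cfg)
  genome <- generate_annotation(cfg, net)
  sim <- simulate_expression(cfg, net)
  structure(c(list(cfg = cfg, network = net, genome = genome), unclass(sim)),
            class = "kd_study")
}

#' Expression-matrix container
#'
#' A light container for genes-or-probes x arrays log2 intensities with a
#' matching detection p-value matrix and tidy array metadata.
#'
#' @param values Numeric matrix (rows = probes/genes, columns = arrays) of
#'   log2 intensities, with dimnames.
#' @param detection_p Numeric matrix of the same shape (detection p-values),
#'   or NULL.
#' @param arrays Tibble with one row per column of `values`, containing at
#'   least `array_id`, `batch`, `condition`, `replicate` (and optionally
#'   `experiment`).
#' @return An object of class `kd_expression`.
#' @export
kd_expression <- function(values, detection_p = NULL, arrays) {
  values <- as.matrix(values)
  arrays <- as_tibble(arrays)
  if (is.null(colnames(values))) colnames(values) <- arrays$array_id
  stopifnot(ncol(values) == nrow(arrays),
            all(colnames(values) == arrays$array_id))
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    stopifnot(all(dim(detection_p) == dim(values)))
    dimnames(detection_p) <- dimnames(values)
  }
  if (anyNA(values)) abort("expression matrix contains missing cells",
                           class = "kdbind_consistency_error")
  structure(list(values = values, detection_p = detection_p, arrays = arrays),
            class = "kd_expression")
}

#' @export
print.kd_expression <- function(x, ...) {
  cat(sprintf("<kd_expression> %d features x %d arrays (%d batches)\n",
              nrow(x$values), ncol(x$values),
              dplyr::n_distinct(x$arrays$batch)))
  invisible(x)
}

#' @export
dim.kd_expression <- function(x) dim(x$values)
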
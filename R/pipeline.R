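#' Run the full knockdown-binding analysis on a fixture set
#'
#' Executes the complete pipeline on in-memory fixtures: probe filtering,
#' quantile normalization, per-experiment detection filtering, control-gene
#' selection, choice of the number of unwanted factors (unless `k` is
#' forced), factor removal, control pooling, per-experiment
#' likelihood-ratio differential expression, binding-map construction, TSS
#' selection, window and distal-link target assignment, chromatin-state
#' annotation, and every downstream comparison.
#'
#' When a knockdown condition was run in more than one batch, only the
#' repeat with the higher array-based knockdown efficiency is carried into
#' the downstream comparisons.
#'
#' @param fx A `kd_fixtures` list ([read_fixtures()] or
#'   [fixtures_from_study()]).
#' @param fdr FDR threshold for DE calls (default 0.05).
#' @param window TSS window half-width in bp (default 10000).
#' @param inner Inner exclusion radius in bp (default 0).
#' @param k Number of unwanted factors to remove; NULL (default) selects it
#'   with [choose_k()].
#' @param k_grid Candidate grid for [choose_k()].
#' @param de_test_method Reference distribution for the per-gene group test
#'   (see [lrt_gene()]): `"chisq"` (the asymptotic likelihood-ratio reading)
#'   or `"f"` (exact under Gaussian errors; calibrated at these small group
#'   sizes).
#' @param n_control_probes Per-batch control-probe list size. The default
#'   (NULL) uses a quarter of the candidate genes, capped at 2000 - the same
#'   proportion of the expressed-gene universe that a 2000-probe list
#'   represents on a full-size array study.
#' @param windows Window grid for the sensitivity analysis.
#' @param full If FALSE, skip the expensive downstream batteries
#'   (state enrichment, site features, co-occupancy, window sensitivity,
#'   distal reanalysis) and return the core results only; useful when a
#'   caller needs one specific downstream comparison and will run it
#'   directly.
#' @return A list of class `kd_results`; see the individual elements:
#'   `k` (`kd_k_choice` or forced value), `de` (named list of `kd_de`),
#'   `efficiency`, `overlap_direct`, `overlap_downstream` (per-experiment
#'   summary tibbles), `state_enrichment`, `site_features`, `cooccupancy`,
#'   `direction`, `window_sensitivity`, `overlap_distal`, `qc` (RLE + PCA
#'   before/after adjustment), `assignment`, `tss`, `expressed`.
#' @export
analyze_fixtures <- function(fx, fdr = 0.05, window = 10000, inner = 0,
                             k = NULL, k_grid = 0:10,
                             n_control_probes = NULL,
                             windows = c(1, 2, 5, 10, 15, 20) * 1000,
                             de_test_method = c("chisq", "f"),
                             full = TRUE) {
  de_test_method <- match.arg(de_test_method)
  stopifnot(inherits(fx, "kd_fixtures"))

  ## ---- preprocessing ----
  probes <- filter_probes(fx$probe_annotation)
  mat <- apply_probe_filter(fx$mat, probes)
  mat <- quantile_normalize(mat)

  experiments <- sort(unique(mat$arrays$experiment[
    !is.na(mat$arrays$experiment)]))
  expressed <- lapply(experiments, function(e) detection_filter(mat, e))
  names(expressed) <- experiments

  candidates <- Reduce(union, expressed)
  n_control_probes <- n_control_probes %||%
    min(2000, round(0.25 * length(candidates)))
  controls <- select_control_probes(mat, candidates = candidates,
                                    n_per_batch = min(n_control_probes,
                                                      length(candidates)))

  k_choice <- NULL
  if (is.null(k)) {
    k_choice <- choose_k(mat, controls, k_grid = k_grid, fdr = fdr)
    k <- k_choice$k
  }
  protect <- ifelse(mat$arrays$condition == "CONTROL", "CONTROL",
                    mat$arrays$experiment)
  adj <- apply_ruv(mat, fit_ruv(mat, controls, k), design = protect)
  pooled <- average_controls(adj)

  qc <- list(
    rle_raw = rle_stats(mat), rle_adjusted = rle_stats(adj),
    pca_raw = pca_diagnostics(mat), pca_adjusted = pca_diagnostics(adj)
  )

  ## ---- differential expression ----
  de <- lapply(experiments, function(e) {
    de_test(pooled, e, genes = expressed[[e]], test = de_test_method)
  })
  names(de) <- experiments

  efficiency <- purrr::map_dfr(de, function(d) {
    dplyr::mutate(knockdown_efficiency(d), experiment = attr(d, "experiment"),
                  .before = 1)
  })

  # keep the better-knocked-down repeat of conditions run in two batches
  keep <- tibble(experiment = experiments,
                 target = vapply(de, function(d) attr(d, "target"),
                                 character(1)),
                 eff = efficiency$efficiency_pct) %>%
    dplyr::group_by(.data$target) %>%
    dplyr::arrange(dplyr::desc(.data$eff), .data$experiment, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::pull(.data$experiment)
  de_kept <- de[sort(keep)]

  ## ---- binding ----
  chip <- fx$binding[fx$binding$source == "chip", ]
  dnase <- fx$binding[fx$binding$source == "dnase", ]
  events <- unify_binding_events(chip_peaks = chip, dnase_sites = dnase)
  tss <- select_reference_tss(fx$tss_candidates)
  assignment <- assign_targets_window(events, tss, window = window,
                                      inner = inner)
  assignment <- annotate_site_state(assignment, fx$states)

  ## ---- integration ----
  fc_direct <- purrr::compact(lapply(de_kept, function(d) {
    classify_functional(assignment, d, fdr = fdr, mode = "direct")
  }))
  fc_down <- purrr::compact(lapply(de_kept, function(d) {
    classify_functional(assignment, d, fdr = fdr, mode = "downstream")
  }))

  overlap_of <- function(fcs) {
    purrr::map_dfr(fcs, function(fc) {
      dplyr::mutate(fc$overlap, experiment = fc$experiment, .before = 1)
    })
  }

  state_enr <- site_features <- cooc <- wsens <- NULL
  fc_distal <- list()
  if (full) {
    state_enr <- purrr::map_dfr(fc_direct, function(fc) {
      dplyr::mutate(state_enrichment(assignment, fc),
                    experiment = fc$experiment, .before = 1)
    })

    site_features <- purrr::map_dfr(
      c("motif_score", "cons_score", "distance", "n_sites", "n_factors"),
      function(f) compare_site_features(assignment, fc_direct, feature = f)
    )

    cooc <- if (length(de_kept) >= 2) {
      cooccupancy_enrichment(de_kept, assignment, fdr = fdr)
    } else NULL

    wsens <- window_sensitivity(events, tss, de_kept, windows = windows,
                                fdr = fdr)

    distal_assignment <- assign_targets_distal(events, fx$links, tss = tss)
    fc_distal <- purrr::compact(lapply(de_kept, function(d) {
      classify_functional(distal_assignment, d, fdr = fdr, mode = "direct")
    }))
  }

  direction <- purrr::map_dfr(fc_direct, function(fc) {
    direction_of_effect(fc, de_kept[[fc$experiment]])
  })

  structure(list(
    k = k, k_choice = k_choice, controls = controls,
    de = de, de_kept = de_kept, efficiency = efficiency,
    overlap_direct = overlap_of(fc_direct),
    overlap_downstream = overlap_of(fc_down),
    functional_direct = fc_direct, functional_downstream = fc_down,
    state_enrichment = state_enr, site_features = site_features,
    cooccupancy = cooc, direction = direction,
    window_sensitivity = wsens,
    overlap_distal = overlap_of(fc_distal),
    qc = qc, assignment = assignment, tss = tss, expressed = expressed
  ), class = "kd_results")
}

#' Simulate a study and write its fixtures (pipeline entry point)
#'
#' @param config Path to a YAML configuration (see [read_sim_config()]) or a
#'   [sim_config()] object.
#' @param outdir Output directory.
#' @return The file manifest, invisibly.
#' @examples
#' \donttest{
#' dir <- tempfile()
#' kd_simulate(sim_config(n_genes = 150, n_tfs = 8, n_knockdowns = 3,
#'                        seed = 1), dir)
#' }
#' @export
kd_simulate <- function(config, outdir) {
  cfg <- if (inherits(config, "kd_sim_config")) config else
    read_sim_config(config)
  study <- simulate_study(cfg)
  write_fixtures(study, outdir)
}

#' Analyze a fixture directory and write result tables (pipeline entry point)
#'
#' Runs [analyze_fixtures()] on the contents of `datadir` and writes every
#' result table as TSV under `outdir`, plus a `run_manifest.tsv` with
#' checksums and row counts.
#'
#' @param config YAML config path or [sim_config()] object (supplies the
#'   seed recorded in the manifest; analysis itself is deterministic).
#' @param datadir Fixture directory ([write_fixtures()] layout).
#' @param outdir Output directory.
#' @inheritParams analyze_fixtures
#' @return The `kd_results` list, invisibly.
#' @export
kd_analyze <- function(config, datadir, outdir, fdr = 0.05, window = 10000,
                       inner = 0, k = NULL) {
  cfg <- if (inherits(config, "kd_sim_config")) config else
    read_sim_config(config)
  fx <- read_fixtures(datadir)
  res <- analyze_fixtures(fx, fdr = fdr, window = window, inner = inner,
                          k = k)
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok) abort(paste0("cannot create ", outdir), class = "kdbind_io_error")

  de_tbl <- purrr::map_dfr(res$de, function(d) {
    dplyr::mutate(tidy(d), experiment = attr(d, "experiment"), .before = 1)
  })
  out_files <- list(
    de_results.tsv = de_tbl,
    knockdown_efficiency.tsv = res$efficiency,
    overlap_direct.tsv = res$overlap_direct,
    overlap_downstream.tsv = res$overlap_downstream,
    overlap_distal.tsv = res$overlap_distal,
    state_enrichment.tsv = res$state_enrichment,
    site_features.tsv = res$site_features,
    direction.tsv = res$direction,
    window_sensitivity.tsv = res$window_sensitivity,
    binding_counts.tsv = target_counts(res$assignment),
    qc_rle.tsv = dplyr::bind_rows(raw = res$qc$rle_raw,
                                  adjusted = res$qc$rle_adjusted,
                                  .id = "stage"),
    qc_pca_batch.tsv = dplyr::bind_rows(raw = res$qc$pca_raw$batch_assoc,
                                        adjusted = res$qc$pca_adjusted$batch_assoc,
                                        .id = "stage")
  )
  if (!is.null(res$cooccupancy)) {
    out_files$cooccupancy.tsv <- res$cooccupancy$pairs
  }
  if (!is.null(res$k_choice)) {
    out_files$k_selection.tsv <- res$k_choice$table
  }
  for (nm in names(out_files)) {
    readr::write_tsv(out_files[[nm]], file.path(outdir, nm))
  }
  manifest <- tibble(
    file = names(out_files),
    md5 = unname(tools::md5sum(file.path(outdir, names(out_files)))),
    n_rows = vapply(out_files, nrow, integer(1)),
    seed = cfg$seed, k = res$k
  )
  readr::write_tsv(manifest, file.path(outdir, "run_manifest.tsv"))
  invisible(res)
}
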
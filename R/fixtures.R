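#' Write a simulated study to plain-text fixtures
#'
#' Serializes every input the analysis pipeline consumes, plus the ground
#' truth, as TSV/BED text files:
#'
#' * `expression.tsv`, `detection.tsv`: probe x array matrices (first column
#'   `probe_id`),
#' * `arrays.tsv`: array metadata,
#' * `probes.tsv`: probe annotation flags,
#' * `binding.tsv`: 7-column BED-derived binding records (chrom, start,
#'   end = start + 1, factor, posterior, motif_score, cons_score; 0-based
#'   half-open; footprint records carry a posterior, peak records NA),
#' * `tss.tsv`: candidate TSSs with CAGE scores,
#' * `states.bed`: 4-column chromatin-state BED,
#' * `links.tsv`: distal-element-to-gene links (chrom, start, end, gene,
#'   score),
#' * `truth_experiments.tsv`, `truth_targets.tsv`, `truth_network.tsv`,
#'   `truth_genes.tsv`: ground truth,
#' * `manifest.tsv`: file list with md5 checksums and row counts.
#'
#' @param study A `kd_study` from [simulate_study()].
#' @param outdir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_fixtures <- function(study, outdir) {
  stopifnot(inherits(study, "kd_study"))
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outdir, 2) != 0) {
    abort(paste0("cannot write to directory: ", outdir),
          class = "kdbind_io_error")
  }
  mat <- study$mat
  expr <- dplyr::bind_cols(tibble(probe_id = rownames(mat$values)),
                           as_tibble(mat$values))
  det <- dplyr::bind_cols(tibble(probe_id = rownames(mat$detection_p)),
                          as_tibble(mat$detection_p))
  binding <- dplyr::select(study$genome$events, "chrom", "start", "end",
                           "factor", "posterior", "motif_score", "cons_score")

  files <- list(
    expression.tsv = expr,
    detection.tsv = det,
    arrays.tsv = mat$arrays,
    probes.tsv = study$probe_annotation,
    binding.tsv = binding,
    tss.tsv = study$genome$tss_candidates,
    states.bed = study$genome$states[, c("chrom", "start", "end", "state")],
    links.tsv = study$genome$links,
    truth_experiments.tsv = study$truth$experiments,
    truth_targets.tsv = study$truth$targets,
    truth_network.tsv = as_tibble(study$network),
    truth_genes.tsv = study$genome$genes
  )
  for (nm in names(files)) {
    readr::write_tsv(files[[nm]], file.path(outdir, nm),
                     col_names = !grepl("\\.bed$", nm))
  }
  write_sim_config(study$cfg, file.path(outdir, "config.yaml"))

  written <- c(names(files), "config.yaml")
  manifest <- tibble(
    file = written,
    md5 = unname(tools::md5sum(file.path(outdir, written))),
    n_rows = c(vapply(files, nrow, integer(1)), NA_integer_)
  )
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(manifest)
}

#' Read study fixtures from a directory
#'
#' Inverse of [write_fixtures()]; truth tables are attached when present.
#'
#' @param dir Directory written by [write_fixtures()].
#' @return A list of class `kd_fixtures`: `mat` ([kd_expression()],
#'   probe-level), `probe_annotation`, `binding` (with a `source` column
#'   inferred from the posterior), `tss_candidates`, `states`, `links`,
#'   `cfg` (when config.yaml is present) and `truth` (when truth tables are
#'   present).
#' @export
read_fixtures <- function(dir) {
  need <- c("expression.tsv", "detection.tsv", "arrays.tsv", "probes.tsv",
            "binding.tsv", "tss.tsv", "states.bed", "links.tsv")
  paths <- file.path(dir, need)
  miss <- need[!file.exists(paths)]
  if (length(miss) > 0) {
    abort(paste0("missing fixture file(s): ", paste(miss, collapse = ", ")),
          class = "kdbind_io_error")
  }
  tsv <- function(f, ...) readr::read_tsv(file.path(dir, f),
                                          show_col_types = FALSE, ...)
  expr <- tsv("expression.tsv")
  det <- tsv("detection.tsv")
  arrays <- tsv("arrays.tsv",
                col_types = readr::cols(experiment = readr::col_character()))
  vals <- as.matrix(expr[, -1])
  rownames(vals) <- expr$probe_id
  detm <- as.matrix(det[, -1])
  rownames(detm) <- det$probe_id
  binding <- tsv("binding.tsv")
  if (!all(c("chrom", "start", "end", "factor", "posterior", "motif_score",
             "cons_score") %in% names(binding)) ||
      any(binding$end <= binding$start)) {
    abort("binding.tsv is malformed", class = "kdbind_parse_error")
  }
  binding$source <- ifelse(is.na(binding$posterior), "chip", "dnase")
  states <- readr::read_tsv(file.path(dir, "states.bed"),
                            col_names = c("chrom", "start", "end", "state"),
                            show_col_types = FALSE)
  out <- list(
    mat = kd_expression(vals, detm, arrays),
    probe_annotation = tsv("probes.tsv"),
    binding = binding,
    tss_candidates = tsv("tss.tsv"),
    states = states,
    links = tsv("links.tsv")
  )
  if (file.exists(file.path(dir, "config.yaml"))) {
    out$cfg <- read_sim_config(file.path(dir, "config.yaml"))
  }
  truth_files <- c(experiments = "truth_experiments.tsv",
                   targets = "truth_targets.tsv",
                   network = "truth_network.tsv",
                   genes = "truth_genes.tsv")
  if (all(file.exists(file.path(dir, truth_files)))) {
    out$truth <- lapply(truth_files, tsv)
  }
  structure(out, class = "kd_fixtures")
}

#' Fixture view of an in-memory simulated study
#'
#' Produces the same object [read_fixtures()] would return, without touching
#' the filesystem. Useful for running the analysis pipeline directly on a
#' [simulate_study()] result.
#'
#' @param study A `kd_study`.
#' @return A `kd_fixtures` list.
#' @export
fixtures_from_study <- function(study) {
  stopifnot(inherits(study, "kd_study"))
  ev <- study$genome$events
  structure(list(
    mat = study$mat,
    probe_annotation = study$probe_annotation,
    binding = dplyr::select(ev, "chrom", "start", "end", "factor",
                            "posterior", "motif_score", "cons_score",
                            "source"),
    tss_candidates = study$genome$tss_candidates,
    states = study$genome$states[, c("chrom", "start", "end", "state")],
    links = study$genome$links,
    cfg = study$cfg,
    truth = list(experiments = study$truth$experiments,
                 targets = study$truth$targets,
                 network = as_tibble(study$network),
                 genes = study$genome$genes)
  ), class = "kd_fixtures")
}
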
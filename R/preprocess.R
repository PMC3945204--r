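#' Filter probes by mapping and annotation quality
#'
#' Retains probes that map uniquely to the genome, have no secondary hit at
#' one mismatch, are not on chromosome Y, and overlap no heterozygous SNP;
#' among a gene's surviving probes, only the 3'-most (lowest
#' `three_prime_rank`) is kept, so each retained gene is represented by
#' exactly one probe. Genes whose probes are all disqualified are dropped
#' with a message.
#'
#' @param ann Probe-annotation tibble with columns `probe_id`, `gene_id`,
#'   `maps_uniquely`, `secondary_hit_1mm`, `on_chrY`, `het_snp_overlap`,
#'   `three_prime_rank`.
#' @return Tibble with columns `probe_id`, `gene_id`, one row per retained
#'   gene.
#' @examples
#' ann <- tibble::tibble(
#'   probe_id = c("p1", "p2"), gene_id = c("g1", "g1"),
#'   maps_uniquely = TRUE, secondary_hit_1mm = FALSE, on_chrY = FALSE,
#'   het_snp_overlap = c(FALSE, TRUE), three_prime_rank = c(2L, 1L))
#' filter_probes(ann)  # p2 has a SNP, so the rank-2 probe p1 survives
#' @export
filter_probes <- function(ann) {
  ann <- as_tibble(ann)
  need <- c("probe_id", "gene_id", "maps_uniquely", "secondary_hit_1mm",
            "on_chrY", "het_snp_overlap", "three_prime_rank")
  missing <- setdiff(need, names(ann))
  if (length(missing) > 0) {
    abort(paste0("probe annotation lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "kdbind_consistency_error")
  }
  ok <- ann %>%
    dplyr::filter(.data$maps_uniquely, !.data$secondary_hit_1mm,
                  !.data$on_chrY, !.data$het_snp_overlap) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::slice_min(.data$three_prime_rank, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()
  dropped <- setdiff(unique(ann$gene_id), ok$gene_id)
  if (length(dropped) > 0) {
    inform(sprintf("filter_probes: %d gene(s) lost all probes and were dropped",
                   length(dropped)))
  }
  dplyr::select(ok, "probe_id", "gene_id")
}

#' Restrict an expression object to a probe set and rename rows to genes
#'
#' @param mat A [kd_expression()] object with probe-level rows.
#' @param probes Result of [filter_probes()].
#' @return A [kd_expression()] with one row per gene, rownames = gene ids.
#' @export
apply_probe_filter <- function(mat, probes) {
  stopifnot(inherits(mat, "kd_expression"))
  keep <- intersect(probes$probe_id, rownames(mat$values))
  probes <- probes[match(keep, probes$probe_id), ]
  values <- mat$values[keep, , drop = FALSE]
  rownames(values) <- probes$gene_id
  det <- mat$detection_p
  if (!is.null(det)) {
    det <- det[keep, , drop = FALSE]
    rownames(det) <- probes$gene_id
  }
  kd_expression(values, det, mat$arrays)
}

#' Detection filter: the expressed-gene universe of one experiment
#'
#' A gene is considered expressed in an experiment when its detection
#' p-value is below `threshold` on all of the experiment's knockdown arrays,
#' or on all control arrays.
#'
#' @param mat A [kd_expression()] with a detection-p matrix.
#' @param experiment Experiment id (matching `mat$arrays$experiment`).
#' @param threshold Detection p-value cutoff (default 0.01).
#' @param control_arrays Optional character vector of control array ids; by
#'   default all arrays with condition "CONTROL".
#' @return Character vector of expressed gene ids.
#' @export
detection_filter <- function(mat, experiment, threshold = 0.01,
                             control_arrays = NULL) {
  stopifnot(inherits(mat, "kd_expression"))
  if (is.null(mat$detection_p)) {
    abort("no detection p-values in this expression object",
          class = "kdbind_consistency_error")
  }
  kd_cols <- mat$arrays$array_id[!is.na(mat$arrays$experiment) &
                                   mat$arrays$experiment == experiment]
  if (length(kd_cols) == 0) {
    abort(paste0("unknown experiment: ", experiment),
          class = "kdbind_lookup_error")
  }
  if (is.null(control_arrays)) {
    control_arrays <- mat$arrays$array_id[mat$arrays$condition == "CONTROL"]
  }
  d <- mat$detection_p
  pass_kd <- rowSums(d[, kd_cols, drop = FALSE] < threshold) == length(kd_cols)
  pass_ctl <- rowSums(d[, control_arrays, drop = FALSE] < threshold) ==
    length(control_arrays)
  rownames(d)[pass_kd | pass_ctl]
}

#' Quantile normalization
#'
#' Forces every array (column) to the same empirical distribution: the
#' vector of row-rank means. Ties within a column receive the mean of the
#' quantile values they span. Delegates to
#' [limma::normalizeQuantiles()] with `ties = TRUE`. Idempotent; a
#' single-column input is returned unchanged.
#'
#' @param x Numeric matrix or [kd_expression()].
#' @return Object of the same type with normalized values.
#' @examples
#' quantile_normalize(cbind(a = c(1, 3), b = c(2, 4)))
#' @export
quantile_normalize <- function(x) UseMethod("quantile_normalize")

#' @export
quantile_normalize.default <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) <= 1) return(x)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' @export
quantile_normalize.kd_expression <- function(x) {
  x$values <- quantile_normalize(x$values)
  x
}

#' Select control probes as least-variable probes shared across batches
#'
#' For each batch, ranks candidate probes by the sample variance of their
#' log2 values across that batch's arrays and keeps the `n_per_batch` least
#' variable; the control set is the intersection of the per-batch lists.
#'
#' @param mat A [kd_expression()] (normalized values).
#' @param candidates Optional character vector restricting the probes
#'   considered (e.g. detection-passing genes); default all rows.
#' @param n_per_batch Per-batch list size (default 2000); capped at the
#'   number of candidate probes with a warning.
#' @return A list of class `kd_control_set`: `controls` (the intersection),
#'   `per_batch` (named list of per-batch lists) and `n_per_batch`.
#' @export
select_control_probes <- function(mat, candidates = NULL, n_per_batch = 2000) {
  stopifnot(inherits(mat, "kd_expression"))
  batches <- sort(unique(mat$arrays$batch))
  if (length(batches) < 2) {
    abort("control-probe selection needs at least two batches",
          class = "kdbind_config_error")
  }
  v <- mat$values
  if (!is.null(candidates)) v <- v[rownames(v) %in% candidates, , drop = FALSE]
  if (n_per_batch > nrow(v)) {
    warn(sprintf("n_per_batch (%d) exceeds candidate probes (%d); capped",
                 n_per_batch, nrow(v)))
    n_per_batch <- nrow(v)
  }
  per_batch <- lapply(batches, function(b) {
    cols <- mat$arrays$array_id[mat$arrays$batch == b]
    vv <- apply(v[, cols, drop = FALSE], 1, var)
    names(sort(vv))[seq_len(n_per_batch)]
  })
  names(per_batch) <- paste0("batch", batches)
  controls <- Reduce(intersect, per_batch)
  if (length(controls) == 0) {
    warn("control-probe lists are disjoint across batches: empty control set")
  }
  structure(list(controls = controls, per_batch = per_batch,
                 n_per_batch = n_per_batch),
            class = "kd_control_set")
}

#' Relative log expression (RLE) statistics per array
#'
#' Subtracts each row's median across arrays from every cell and summarizes
#' the deviations per array.
#'
#' @param x Numeric matrix or [kd_expression()].
#' @return Tibble with `array_id`, `rle_median`, `rle_iqr`.
#' @export
rle_stats <- function(x) {
  v <- if (inherits(x, "kd_expression")) x$values else as.matrix(x)
  dev <- v - apply(v, 1, median)
  tibble(
    array_id = colnames(v) %||% paste0("array", seq_len(ncol(v))),
    rle_median = apply(dev, 2, median),
    rle_iqr = apply(dev, 2, IQR)
  )
}

#' Principal-component diagnostics of an array set
#'
#' Principal components of the gene-centered matrix on the array side, the
#' fraction of variance captured by each component, and a one-way
#' location-test (Kruskal-Wallis) association p-value of each of the first
#' ten components with batch.
#'
#' @param x Numeric matrix or [kd_expression()].
#' @param arrays Array metadata (defaults to `x$arrays` for
#'   [kd_expression()] input); must contain `array_id` and `batch`.
#' @return List of class `kd_pca`: `scores` (tibble array_id, batch, PC1..),
#'   `var_frac` (numeric), `batch_assoc` (tibble component, p).
#' @export
pca_diagnostics <- function(x, arrays = NULL) {
  if (inherits(x, "kd_expression")) {
    arrays <- arrays %||% x$arrays
    x <- x$values
  }
  x <- as.matrix(x)
  if (ncol(x) < 3) {
    abort("PCA diagnostics need at least 3 arrays",
          class = "kdbind_config_error")
  }
  xc <- x - rowMeans(x)
  sv <- svd(xc)
  var_frac <- sv$d^2 / sum(sv$d^2)
  scores <- sv$v * rep(sv$d, each = ncol(x))
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  sc <- dplyr::bind_cols(
    tibble(array_id = colnames(x) %||% paste0("array", seq_len(ncol(x)))),
    as_tibble(scores)
  )
  batch_assoc <- NULL
  if (!is.null(arrays) && "batch" %in% names(arrays)) {
    sc <- dplyr::left_join(sc,
                           dplyr::select(arrays, "array_id", "batch"),
                           by = "array_id")
    n_pc <- min(10, ncol(scores))
    batch_assoc <- purrr::map_dfr(seq_len(n_pc), function(i) {
      p <- if (dplyr::n_distinct(sc$batch) < 2) NA_real_ else
        kruskal.test(sc[[paste0("PC", i)]], factor(sc$batch))$p.value
      tibble(component = paste0("PC", i), p = p)
    })
  }
  structure(list(scores = sc, var_frac = var_frac, batch_assoc = batch_assoc),
            class = "kd_pca")
}

#' Average matched control arrays across batches
#'
#' Control arrays carry a control type (their `replicate` field) that is
#' matched across batches; this averages each type across the batches,
#' yielding one control profile per type (six by default). Knockdown arrays
#' are left untouched.
#'
#' @param mat A [kd_expression()].
#' @return A [kd_expression()] whose control columns are replaced by
#'   averaged profiles (batch is set to NA for those columns); detection
#'   p-values for averaged profiles are the per-cell maximum across the
#'   averaged arrays (conservative).
#' @export
average_controls <- function(mat) {
  stopifnot(inherits(mat, "kd_expression"))
  ctl <- mat$arrays$condition == "CONTROL"
  if (!any(ctl)) return(mat)
  ctl_meta <- mat$arrays[ctl, ]
  types <- sort(unique(ctl_meta$replicate))
  avg_vals <- sapply(types, function(t) {
    cols <- ctl_meta$array_id[ctl_meta$replicate == t]
    rowMeans(mat$values[, cols, drop = FALSE])
  })
  colnames(avg_vals) <- paste0("CTRL.avg.t", types)
  avg_det <- NULL
  if (!is.null(mat$detection_p)) {
    avg_det <- sapply(types, function(t) {
      cols <- ctl_meta$array_id[ctl_meta$replicate == t]
      apply(mat$detection_p[, cols, drop = FALSE], 1, max)
    })
    colnames(avg_det) <- colnames(avg_vals)
  }
  kd_cols <- !ctl
  arrays <- dplyr::bind_rows(
    mat$arrays[kd_cols, ],
    tibble(array_id = colnames(avg_vals), batch = NA_integer_,
           condition = "CONTROL", replicate = types,
           experiment = NA_character_)
  )
  values <- cbind(mat$values[, kd_cols, drop = FALSE], avg_vals)
  det <- if (is.null(mat$detection_p)) NULL else
    cbind(mat$detection_p[, kd_cols, drop = FALSE], avg_det)
  kd_expression(values, det, arrays)
}
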
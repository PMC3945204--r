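#' Likelihood-ratio test of knockdown vs control for one gene
#'
#' Compares a fixed-effect linear model with a group term (separate
#' knockdown and control means) to the nested grand-mean model. With
#' Gaussian errors and maximum-likelihood variance estimates the
#' likelihood-ratio statistic is `n * ln(RSS0 / RSS1)` with `n` the total
#' number of observations, `RSS0` the residual sum of squares of the
#' grand-mean model, and `RSS1` that of the two-group model; the p-value is
#' the upper tail of a chi-square with 1 degree of freedom. The log2
#' fold-change is `mean(y_kd) - mean(y_ctl)`.
#'
#' A zero `RSS1` (perfectly fit groups) is degenerate: the statistic is set
#' to `Inf`, the p-value to the smallest representable positive double, and
#' the result flagged.
#'
#' @param y_kd,y_ctl Numeric vectors of log2 expression on the knockdown and
#'   control arrays (each of length >= 2).
#' @param test `"chisq"` (default: the likelihood-ratio statistic against
#'   its asymptotic chi-square reference) or `"f"` (the exact F test of the
#'   same nested pair of Gaussian models; useful for calibration at small
#'   n, where the chi-square reference is anti-conservative).
#' @return A one-row tibble: `log2fc`, `lrt_stat`, `p`, `degenerate`.
#' @examples
#' lrt_gene(c(2, 6), c(1, 3))  # lrt_stat = 4 * log(14/10)
#' @export
lrt_gene <- function(y_kd, y_ctl, test = c("chisq", "f")) {
  if (length(y_kd) < 2 || length(y_ctl) < 2) {
    abort("both groups need at least 2 observations",
          class = "kdbind_config_error")
  }
  res <- de_core(rbind(g = c(y_kd, y_ctl)),
                 seq_along(y_kd), length(y_kd) + seq_along(y_ctl),
                 test = test)
  dplyr::select(res, -"gene")
}

# Vectorized two-group LRT (or exact F) over the rows of a matrix.
de_core <- function(values, kd_cols, ctl_cols, test = c("chisq", "f")) {
  test <- match.arg(test)
  ykd <- values[, kd_cols, drop = FALSE]
  yct <- values[, ctl_cols, drop = FALSE]
  n1 <- ncol(ykd); n0 <- ncol(yct); n <- n1 + n0
  m1 <- rowMeans(ykd); m0 <- rowMeans(yct)
  mg <- (n1 * m1 + n0 * m0) / n
  rss1 <- rowSums((ykd - m1)^2) + rowSums((yct - m0)^2)
  rss0 <- rss1 + n1 * (m1 - mg)^2 + n0 * (m0 - mg)^2
  # rss1 = 0 is degenerate; when rss0 = 0 as well the group term explains
  # nothing (a constant gene) - no evidence, p = 1
  degenerate <- rss1 <= 0
  flat <- degenerate & rss0 <= n * .Machine$double.eps * pmax(m1^2, m0^2, 1)
  if (test == "chisq") {
    stat <- ifelse(degenerate, Inf, n * log(rss0 / rss1))
    p <- ifelse(degenerate, .Machine$double.xmin,
                pchisq(stat, df = 1, lower.tail = FALSE))
  } else {
    stat <- ifelse(degenerate, Inf, (rss0 - rss1) / (rss1 / (n - 2)))
    p <- ifelse(degenerate, .Machine$double.xmin,
                stats::pf(stat, 1, n - 2, lower.tail = FALSE))
  }
  stat[flat] <- 0
  p[flat] <- 1
  tibble(gene = rownames(values) %||% as.character(seq_len(nrow(values))),
         log2fc = unname(m1 - m0), lrt_stat = unname(stat), p = unname(p),
         degenerate = unname(degenerate))
}

#' Differential expression for one knockdown experiment
#'
#' Runs the per-gene likelihood-ratio test ([lrt_gene()]) of the
#' experiment's knockdown arrays against the control profiles, restricted to
#' the experiment's expressed-gene universe, and attaches Storey q-values
#' and effect sizes.
#'
#' The effect size in percent is `(2^|log2fc| - 1) * 100` by default (a
#' symmetric reading on the log scale: a halving and a doubling are both
#' 100%); `effect_def = "fraction"` gives the asymmetric alternative
#' `(1 - 2^-|log2fc|) * 100`.
#'
#' @param mat Adjusted [kd_expression()] whose control arrays have been
#'   pooled (see [average_controls()]); gene-level rows.
#' @param experiment Experiment id present in `mat$arrays$experiment`.
#' @param genes Optional character vector: the expressed-gene universe
#'   (defaults to all rows; typically [detection_filter()] output).
#' @param effect_def `"symmetric"` (default) or `"fraction"`.
#' @param test Reference distribution for the group test; see [lrt_gene()].
#' @return A tibble of class `kd_de` with columns `gene`, `log2fc`,
#'   `lrt_stat`, `p`, `q`, `effect_pct`, `degenerate`; attributes
#'   `experiment`, `target` and `pi0`.
#' @export
de_test <- function(mat, experiment, genes = NULL,
                    effect_def = c("symmetric", "fraction"),
                    test = c("chisq", "f")) {
  stopifnot(inherits(mat, "kd_expression"))
  effect_def <- match.arg(effect_def)
  kd_cols <- mat$arrays$array_id[!is.na(mat$arrays$experiment) &
                                   mat$arrays$experiment == experiment]
  if (length(kd_cols) == 0) {
    abort(paste0("unknown experiment: ", experiment),
          class = "kdbind_lookup_error")
  }
  ctl_cols <- mat$arrays$array_id[mat$arrays$condition == "CONTROL"]
  v <- mat$values
  if (!is.null(genes)) v <- v[rownames(v) %in% genes, , drop = FALSE]
  res <- de_core(v, kd_cols, ctl_cols, test = test)
  qv <- storey_qvalues(res$p, return_pi0 = TRUE)
  pi0 <- attr(qv, "pi0")
  res$q <- as.numeric(qv)
  res$effect_pct <- switch(effect_def,
    symmetric = (2^abs(res$log2fc) - 1) * 100,
    fraction = (1 - 2^(-abs(res$log2fc))) * 100
  )
  target <- unique(mat$arrays$condition[!is.na(mat$arrays$experiment) &
                                          mat$arrays$experiment == experiment])
  structure(res, class = c("kd_de", class(res)),
            experiment = experiment, target = target, pi0 = pi0)
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0` by evaluating
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` on the grid
#' `lambda = 0, 0.05, ..., 0.90`, smoothing with a cubic smoothing spline
#' (df = 3) and taking the fit at `lambda = 0.90`, clamped into
#' `[1/m, 1]`. The q-value of each p-value is
#' `pi0 * min over p_(j) >= p_(i) of p_(j) * m / rank(j)`, capped at 1.
#' With fewer than two p-values `pi0` is fixed at 1.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param lambda Estimation grid for `pi0`.
#' @param pi0 Optional: force a fixed `pi0` instead of estimating it.
#' @param return_pi0 If TRUE, attach the estimated `pi0` as an attribute.
#' @return Numeric vector of q-values (same order as `p`).
#' @examples
#' storey_qvalues(c(0.01, 0.04, 0.03), pi0 = 1)  # 0.03 0.04 0.04
#' @export
storey_qvalues <- function(p, lambda = seq(0, 0.90, by = 0.05), pi0 = NULL,
                           return_pi0 = FALSE) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1]", class = "kdbind_config_error")
  }
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 2) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  }
  o <- order(p)
  q_ord <- pi0 * p[o] * m / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q <- numeric(m)
  q[o] <- pmin(q_ord, 1)
  if (return_pi0) attr(q, "pi0") <- pi0
  q
}

#' Call differentially expressed genes at an FDR threshold
#'
#' @param results A `kd_de` tibble (or any tibble with `gene` and `q`).
#' @param fdr FDR threshold in \[0, 1\].
#' @return Character vector of gene ids with `q <= fdr` (monotone
#'   non-decreasing in `fdr`).
#' @export
call_de <- function(results, fdr = 0.05) {
  if (!is.numeric(fdr) || length(fdr) != 1 || fdr < 0 || fdr > 1) {
    abort("`fdr` must be a single value in [0, 1]",
          class = "kdbind_config_error")
  }
  results$gene[results$q <= fdr]
}

#' Array-based knockdown efficiency
#'
#' The knockdown efficiency implied by the targeted gene's fold-change:
#' `(1 - 2^log2fc) * 100`, clamped to \[0, 100\] with out-of-range estimates
#' flagged.
#'
#' @param results A `kd_de` tibble.
#' @param target Targeted gene id (defaults to the fit's `target` attribute).
#' @return One-row tibble: `target`, `efficiency_pct`, `out_of_range`.
#'   `efficiency_pct` is NA when the target was filtered out of the
#'   experiment's universe.
#' @export
knockdown_efficiency <- function(results, target = NULL) {
  target <- target %||% attr(results, "target")
  row <- results[results$gene == target, ]
  if (nrow(row) == 0) {
    return(tibble(target = target, efficiency_pct = NA_real_,
                  out_of_range = NA))
  }
  eff <- (1 - 2^row$log2fc[1]) * 100
  tibble(target = target,
         efficiency_pct = min(max(eff, 0), 100),
         out_of_range = eff < 0 | eff > 100)
}

#' @rdname de_test
#' @param x A `kd_de` object.
#' @param ... Unused.
#' @export
tidy.kd_de <- function(x, ...) {
  as_tibble(x)[, c("gene", "log2fc", "lrt_stat", "p", "q", "effect_pct")]
}

#' @rdname de_test
#' @param fdr FDR used for the `n_de` count in `glance()`.
#' @export
glance.kd_de <- function(x, fdr = 0.05, ...) {
  de <- call_de(x, fdr)
  tibble(
    experiment = attr(x, "experiment"),
    target = attr(x, "target"),
    n_genes = nrow(x),
    n_de = length(de),
    pi0 = attr(x, "pi0"),
    median_effect_pct = median(x$effect_pct[x$gene %in% de]),
    kd_efficiency_pct = knockdown_efficiency(x)$efficiency_pct
  )
}
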
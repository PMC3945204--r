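#' Fit unwanted-variation factors from control genes
#'
#' Estimates hidden nuisance factors from a set of negative-control genes:
#' the factor scores `W` are the first `k` right (array-side) singular
#' vectors of the row-centered control-gene submatrix, and per-gene loadings
#' are the least-squares regression of each centered gene row on `W`
#' (`W` is orthonormal, so the coefficients are simply `Yc %*% W`).
#'
#' @param mat A [kd_expression()] (normalized values).
#' @param controls A `kd_control_set` from [select_control_probes()], or a
#'   character vector of control gene ids.
#' @param k Number of factors to estimate (`>= 0`).
#' @return List of class `kd_ruv`: `k`, `W` (arrays x k, orthonormal
#'   columns), `loadings` (genes x k), `controls`, `array_ids`.
#' @export
fit_ruv <- function(mat, controls, k) {
  stopifnot(inherits(mat, "kd_expression"), k >= 0)
  ctl <- if (inherits(controls, "kd_control_set")) controls$controls
         else as.character(controls)
  ctl <- intersect(ctl, rownames(mat$values))
  if (k > 0 && length(ctl) == 0) {
    abort("empty control set", class = "kdbind_config_error")
  }
  n_arr <- ncol(mat$values)
  if (k == 0) {
    return(structure(list(k = 0L, W = matrix(0, n_arr, 0),
                          loadings = matrix(0, nrow(mat$values), 0),
                          controls = ctl, array_ids = colnames(mat$values)),
                     class = "kd_ruv"))
  }
  X <- mat$values[ctl, , drop = FALSE]
  Xc <- X - rowMeans(X)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1])
  if (k > rank) {
    abort(sprintf("k = %d exceeds the rank (%d) of the control submatrix",
                  k, rank),
          class = "kdbind_dimension_error")
  }
  W <- sv$v[, seq_len(k), drop = FALSE]
  rownames(W) <- colnames(mat$values)
  Yc <- mat$values - rowMeans(mat$values)
  structure(list(k = as.integer(k), W = W, loadings = Yc %*% W,
                 controls = ctl, array_ids = colnames(mat$values)),
            class = "kd_ruv")
}

#' Remove fitted unwanted-variation factors from an expression matrix
#'
#' Replaces each gene's row by its mean plus the residual of regressing the
#' centered row on the factor scores `W`. Residual rows are orthogonal to
#' every column of `W` (to numerical tolerance) and per-gene means are
#' preserved. With `k = 0` the input is returned unchanged.
#'
#' When `design` is supplied (a group label per array, e.g. the experiment
#' for knockdown arrays and "CONTROL" for controls), the per-gene regression
#' coefficients are estimated after centering within those groups, so that
#' large condition effects - a factor's own knockdown can shift its
#' transcript by several log2 units on a few arrays - cannot leak into the
#' fitted factor component and contaminate other columns. The removed
#' component is still `coef %*% t(W)`; only the coefficient estimate is
#' protected. Without a design the plain regression of the spec'd
#' adjust-the-data scheme is used.
#'
#' @param mat A [kd_expression()] whose arrays match those the factors were
#'   fit on.
#' @param factors A `kd_ruv` object from [fit_ruv()].
#' @param design Optional character vector (one label per array) of
#'   condition groups to protect during coefficient estimation.
#' @return The adjusted [kd_expression()].
#' @export
apply_ruv <- function(mat, factors, design = NULL) {
  stopifnot(inherits(mat, "kd_expression"), inherits(factors, "kd_ruv"))
  if (!identical(colnames(mat$values), factors$array_ids)) {
    abort("arrays of the expression matrix do not match the fitted factors",
          class = "kdbind_consistency_error")
  }
  if (factors$k == 0) return(mat)
  Y <- mat$values
  W <- factors$W
  if (is.null(design)) {
    # W has orthonormal columns, so least-squares coefficients are Yc %*% W;
    # W is orthogonal to the intercept (it comes from a row-centered SVD),
    # so per-gene means are preserved
    Yc <- Y - rowMeans(Y)
    coef <- Yc %*% W
  } else {
    stopifnot(length(design) == ncol(Y))
    # joint-model estimate: residualize W on the design groups, then take
    # the least-squares coefficient of each gene on the residualized scores
    Wr <- W
    for (g in unique(design)) {
      cols <- design == g
      Wr[cols, ] <- sweep(W[cols, , drop = FALSE], 2,
                          colMeans(W[cols, , drop = FALSE]))
    }
    coef <- Y %*% Wr %*% solve(crossprod(Wr))
  }
  out <- Y - coef %*% t(W)
  dimnames(out) <- dimnames(mat$values)
  mat$values <- out
  mat
}

#' Choose the number of unwanted factors to remove
#'
#' Scans a grid of candidate `k` and computes, for each:
#' (a) the number of genes differentially expressed (FDR `fdr`) between the
#' control arrays of different batches (summed over batch pairs) - a measure
#' of residual batch signal that should reach zero. This comparison is
#' computed on the control arrays alone (factors fit and regressed on the
#' control-array submatrix), so that the large knockdown effects on other
#' arrays cannot leak into a control-vs-control null check through the
#' per-gene factor regressions;
#' (b) the number of differentially expressed genes shared between
#' knockdown experiments repeated across batches (summed over repeated
#' conditions) - a measure of biological signal that adjustment should not
#' destroy; and
#' (c) the mean correlation of `-log10 p` between repeated experiments.
#'
#' The selected `k` is the smallest value with (a) = 0 that maximizes (b);
#' when no `k` achieves (a) = 0, the `k` minimizing (a) (then maximizing (b),
#' then smallest) is returned with a warning. The diagnostic DE counts use
#' the exact F version of the group test ([lrt_gene()] with `test = "f"`):
#' criterion (a) is a null comparison at small n, where the asymptotic
#' chi-square reference would sprinkle false positives over every `k` and
#' (a) would never reach zero.
#'
#' @param mat Normalized, unadjusted [kd_expression()].
#' @param controls Control set (see [fit_ruv()]).
#' @param k_grid Integer grid of candidate `k` (default 0:10).
#' @param fdr FDR threshold for the diagnostic DE counts.
#' @return List of class `kd_k_choice`: `k` (selected), `table` (one row per
#'   candidate `k` with `n_de_controls`, `n_de_common`, `p_cor`).
#' @export
choose_k <- function(mat, controls, k_grid = 0:10, fdr = 0.05) {
  stopifnot(inherits(mat, "kd_expression"))
  if (length(k_grid) == 0) {
    abort("empty k grid", class = "kdbind_config_error")
  }
  arrays <- mat$arrays
  batches <- sort(unique(arrays$batch))
  ctl_cols <- split(arrays$array_id[arrays$condition == "CONTROL"],
                    arrays$batch[arrays$condition == "CONTROL"])
  repeated <- arrays %>%
    dplyr::filter(.data$condition != "CONTROL") %>%
    dplyr::distinct(.data$condition, .data$experiment) %>%
    dplyr::count(.data$condition) %>%
    dplyr::filter(.data$n > 1) %>%
    dplyr::pull(.data$condition)
  if (length(repeated) == 0) {
    abort("choose_k needs at least one knockdown repeated across batches",
          class = "kdbind_config_error")
  }
  max_k <- ncol(mat$values) - 1L
  k_grid <- sort(unique(as.integer(k_grid[k_grid <= max_k])))

  batch_pairs <- if (length(ctl_cols) >= 2) combn(names(ctl_cols), 2,
                                                  simplify = FALSE) else list()

  ctl_ids <- arrays$array_id[arrays$condition == "CONTROL"]
  ctl_mat <- kd_expression(mat$values[, ctl_ids, drop = FALSE],
                           arrays = arrays[arrays$condition == "CONTROL", ])
  protect <- ifelse(arrays$condition == "CONTROL", "CONTROL",
                    arrays$experiment)

  # removing k components absorbs ~k/(n_arrays - 1) of every gene's residual
  # variance, silently inflating downstream F statistics; the diagnostics
  # deflate the statistic accordingly so the replication count does not creep
  # upward with k for purely mechanical reasons
  df_deflate <- function(de, k, n_arr, n_obs) {
    scale <- max(0, (n_arr - 1 - k)) / (n_arr - 1)
    de$p <- stats::pf(de$lrt_stat * scale, 1, n_obs - 2, lower.tail = FALSE)
    de$p[de$degenerate & de$lrt_stat == 0] <- 1
    de$p <- pmax(de$p, .Machine$double.xmin)
    de
  }

  eval_k <- function(k) {
    adj <- apply_ruv(mat, fit_ruv(mat, controls, k), design = protect)
    k_ctl <- min(k, ncol(ctl_mat$values) - 2L)
    ctl_adj <- apply_ruv(ctl_mat, fit_ruv(ctl_mat, controls, k_ctl))
    n_ctl <- ncol(ctl_mat$values)
    n_ctl_de <- sum(vapply(batch_pairs, function(pr) {
      de <- de_core(ctl_adj$values, ctl_cols[[pr[1]]], ctl_cols[[pr[2]]],
                    test = "f")
      de <- df_deflate(de, k_ctl, n_ctl,
                       length(ctl_cols[[pr[1]]]) + length(ctl_cols[[pr[2]]]))
      sum(storey_qvalues(de$p) <= fdr)
    }, numeric(1)))
    common <- 0
    cors <- numeric(0)
    for (cond in repeated) {
      exps <- unique(arrays$experiment[!is.na(arrays$experiment) &
                                         arrays$condition == cond])
      res <- lapply(exps, function(e) {
        kd <- arrays$array_id[!is.na(arrays$experiment) &
                                arrays$experiment == e]
        b <- unique(arrays$batch[arrays$array_id %in% kd])
        ctl_own <- arrays$array_id[arrays$condition == "CONTROL" &
                                     arrays$batch %in% b]
        de <- de_core(adj$values, kd, ctl_own, test = "f")
        de <- df_deflate(de, k, ncol(mat$values),
                         length(kd) + length(ctl_own))
        de$q <- storey_qvalues(de$p)
        de
      })
      for (pair in combn(seq_along(res), 2, simplify = FALSE)) {
        d1 <- res[[pair[1]]]; d2 <- res[[pair[2]]]
        common <- common + length(intersect(d1$gene[d1$q <= fdr],
                                            d2$gene[d2$q <= fdr]))
        cors <- c(cors, cor(-log10(d1$p), -log10(d2$p)))
      }
    }
    tibble(k = k, n_de_controls = n_ctl_de, n_de_common = common,
           p_cor = mean(cors))
  }

  tab <- purrr::map_dfr(k_grid, eval_k)
  cand <- tab[tab$n_de_controls == 0, ]
  if (nrow(cand) == 0) {
    warn("no k removed all between-batch control DE; using the best available")
    cand <- tab[tab$n_de_controls == min(tab$n_de_controls), ]
  }
  # replication counts within one Poisson standard error (or a quarter, for
  # large counts - extra removal still mechanically inflates the count a
  # little) of the maximum are treated as tied, and ties go to the smallest
  # k (remove fewer components)
  b_max <- max(cand$n_de_common)
  cand <- cand[cand$n_de_common >= b_max - max(sqrt(b_max), 0.25 * b_max), ]
  structure(list(k = min(cand$k), table = tab), class = "kd_k_choice")
}

#' @export
print.kd_k_choice <- function(x, ...) {
  cat(sprintf("<kd_k_choice> selected k = %d\n", x$k))
  print(x$table)
  invisible(x)
}
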
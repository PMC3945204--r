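#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by full hypergeometric enumeration conditional on the
#' margins: the sum of the probabilities of all tables no more probable than
#' the observed one (with the customary 1e-7 relative tolerance for
#' floating-point ties). The reported odds ratio is the sample odds ratio
#' `(a d)/(b c)`, with a 0.5 continuity correction on all cells when any
#' cell is zero; the correction never affects the p-value. A table with a
#' zero margin carries no information: p = 1 and the odds ratio is NA.
#'
#' @param table A 2x2 matrix (or something coercible) of non-negative
#'   integer counts.
#' @return One-row tibble: `odds_ratio`, `p`.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2))  # p = 2/252
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("cells must be non-negative integers", class = "kdbind_config_error")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c_ + d
  r1 <- a + b; c1 <- a + c_
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    return(tibble(odds_ratio = NA_real_, p = 1))
  }
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  support <- lo:hi
  dens <- dhyper(support, c1, n - c1, r1)
  p <- sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
  or <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  tibble(odds_ratio = or, p = min(p, 1))
}

#' Relative enrichment of a 2x2 overlap table
#'
#' Observed overlap divided by the overlap expected under independence:
#' `a N / ((a + b)(a + c))`. Symmetric in the two margins (invariant to
#' transposition); NA when either margin is zero.
#'
#' @param table A 2x2 matrix of counts with the overlap in cell \[1,1\].
#' @return A single number.
#' @export
relative_enrichment <- function(table) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2, 2)))
  a <- tab[1, 1]
  n <- sum(tab)
  r1 <- a + tab[1, 2]; c1 <- a + tab[2, 1]
  if (r1 == 0 || c1 == 0) return(NA_real_)
  a * n / (r1 * c1)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test. The default `"auto"` method enumerates the exact
#' permutation distribution of the rank sum when both groups have at most 8
#' observations and otherwise uses the normal approximation with tie
#' correction and a 0.5 continuity correction. The two-sided exact p-value
#' is the probability of a rank sum at least as far from its null mean as
#' the observed one.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return One-row tibble: `statistic` (rank sum of `x`), `shift`
#'   (median(x) - median(y)), `p`, `method`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))  # exact p = 2/6
#' @export
rank_sum_test <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    return(tibble(statistic = NA_real_, shift = NA_real_, p = NA_real_,
                  method = "empty"))
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  shift <- median(x) - median(y)
  if (method == "auto") method <- if (n1 <= 8 && n2 <= 8) "exact" else "normal"

  if (method == "exact") {
    combos <- combn(n, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
  }
  tibble(statistic = w, shift = shift, p = p, method = method)
}
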
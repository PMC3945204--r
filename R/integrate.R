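#' Classify functional binding for one knockdown experiment
#'
#' A gene is *bound* when the assignment contains at least one event for a
#' relevant factor within the window; it is *differentially expressed* when
#' its q-value is at or below `fdr`; binding is *functional* when both hold.
#' The relevant factor set is either the siRNA-targeted factor alone
#' (`mode = "direct"`) or the targeted factor plus every factor with binding
#' data that is itself differentially expressed in the experiment
#' (`mode = "downstream"`). The universe is the experiment's expressed
#' genes, i.e. the rows of the DE table.
#'
#' @param assignment A `kd_assignment` (all factors).
#' @param de A `kd_de` table for the experiment.
#' @param fdr FDR threshold for the DE flag.
#' @param mode `"direct"` or `"downstream"`.
#' @param target Targeted factor (default: the DE fit's `target` attribute).
#' @return A list of class `kd_functional`: `calls` (tibble gene, bound, de,
#'   functional), `overlap` (one-row tibble: n_expressed, n_bound, n_de,
#'   n_overlap, frac_bound_de, frac_de_bound, odds_ratio, fisher_p,
#'   rel_enrichment), `relevant_factors`, `experiment`, `mode`, `fdr`.
#'   NULL (with a message) when `mode = "direct"` and the targeted factor
#'   has no binding data.
#' @export
classify_functional <- function(assignment, de, fdr = 0.05,
                                mode = c("direct", "downstream"),
                                target = NULL) {
  mode <- match.arg(mode)
  target <- target %||% attr(de, "target")
  assignment <- as_tibble(assignment)
  have_map <- unique(assignment$factor)
  de_genes <- call_de(de, fdr)
  relevant <- if (mode == "direct") {
    if (!target %in% have_map) {
      inform(sprintf("no binding data for targeted factor %s; skipped", target))
      return(NULL)
    }
    target
  } else {
    union(intersect(target, have_map), intersect(de_genes, have_map))
  }
  bound_genes <- unique(assignment$gene[assignment$factor %in% relevant])
  calls <- tibble(
    gene = de$gene,
    bound = de$gene %in% bound_genes,
    de = de$gene %in% de_genes
  )
  calls$functional <- calls$bound & calls$de
  structure(
    list(calls = calls, overlap = overlap_table(calls),
         relevant_factors = relevant,
         experiment = attr(de, "experiment"), mode = mode, fdr = fdr),
    class = "kd_functional"
  )
}

#' Overlap summary of bound vs differentially expressed genes
#'
#' @param calls Tibble with logical columns `bound` and `de` over the
#'   expressed-gene universe.
#' @return One-row tibble with the 2x2 counts and derived quantities;
#'   `frac_bound_de` is the fraction of bound genes that are DE,
#'   `frac_de_bound` the fraction of DE genes that are bound (NA when the
#'   corresponding margin is empty).
#' @export
overlap_table <- function(calls) {
  a <- sum(calls$bound & calls$de)
  b <- sum(calls$bound & !calls$de)
  c_ <- sum(!calls$bound & calls$de)
  d <- sum(!calls$bound & !calls$de)
  tab <- matrix(c(a, c_, b, d), 2)
  fe <- fisher_exact(tab)
  tibble(
    n_expressed = nrow(calls),
    n_bound = a + b,
    n_de = a + c_,
    n_overlap = a,
    frac_bound_de = if (a + b > 0) a / (a + b) else NA_real_,
    frac_de_bound = if (a + c_ > 0) a / (a + c_) else NA_real_,
    odds_ratio = fe$odds_ratio,
    fisher_p = fe$p,
    rel_enrichment = relative_enrichment(tab)
  )
}

#' Chromatin-state enrichment of functional binding
#'
#' For each chromatin state, tests whether binding events of the relevant
#' factors that fall in that state are enriched around differentially
#' expressed genes: a Fisher's exact test on the 2x2 table (event in state?)
#' x (assigned gene DE?), with Benjamini-Hochberg adjustment across the
#' states present in the experiment. The unit is the binding event; an event
#' assigned to several genes counts as DE when any of them is.
#'
#' @param assignment A `kd_assignment` carrying a `state` column (see
#'   [annotate_site_state()]).
#' @param functional A `kd_functional` from [classify_functional()], or a
#'   list of them (events are then pooled across experiments, each event
#'   inheriting DE status from its own experiment).
#' @return Tibble: `state`, `n_de`, `n_not_de`, `odds_ratio`, `p`, `p_adj`,
#'   `direction` ("enriched"/"depleted").
#' @export
state_enrichment <- function(assignment, functional) {
  if (inherits(functional, "kd_functional")) functional <- list(functional)
  ev <- purrr::map_dfr(functional, function(fc) {
    de_genes <- fc$calls$gene[fc$calls$de]
    x <- as_tibble(assignment) %>%
      dplyr::filter(.data$factor %in% fc$relevant_factors,
                    .data$gene %in% fc$calls$gene) %>%
      dplyr::group_by(.data$factor, .data$chrom, .data$midpoint) %>%
      dplyr::summarise(state = .data$state[1],
                       event_de = any(.data$gene %in% de_genes),
                       .groups = "drop")
    x$experiment <- fc$experiment
    x
  })
  if (nrow(ev) == 0) {
    return(tibble(state = character(), n_de = integer(),
                  n_not_de = integer(), odds_ratio = double(), p = double(),
                  p_adj = double(), direction = character()))
  }
  out <- purrr::map_dfr(sort(unique(ev$state)), function(s) {
    in_s <- ev$state == s
    tab <- matrix(c(sum(in_s & ev$event_de), sum(!in_s & ev$event_de),
                    sum(in_s & !ev$event_de), sum(!in_s & !ev$event_de)), 2)
    fe <- fisher_exact(tab)
    tibble(state = s, n_de = tab[1, 1], n_not_de = tab[1, 2],
           odds_ratio = fe$odds_ratio, p = fe$p)
  })
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$direction <- dplyr::if_else(is.na(out$odds_ratio) | out$odds_ratio >= 1,
                                  "enriched", "depleted")
  out
}

#' Compare a binding feature between functional and non-functional targets
#'
#' Rank-sum comparison ([rank_sum_test()]) of a feature between binding near
#' functionally bound genes (bound and DE) and binding near non-functionally
#' bound genes (bound, not DE). Per-event features (`motif_score`,
#' `cons_score`, `distance`) compare event values (motif and conservation
#' exist only for footprint-derived events); per-gene features compare the
#' number of binding events (`n_sites`) or distinct bound factors
#' (`n_factors`) per bound gene.
#'
#' @param assignment A `kd_assignment`.
#' @param functional A `kd_functional`, or a list of them to pool across
#'   experiments.
#' @param feature One of `"motif_score"`, `"cons_score"`, `"distance"`,
#'   `"n_sites"`, `"n_factors"`.
#' @return One-row tibble: `feature`, `n_functional`, `n_nonfunctional`,
#'   `statistic`, `shift`, `p`.
#' @export
compare_site_features <- function(assignment, functional,
                                  feature = c("motif_score", "cons_score",
                                              "distance", "n_sites",
                                              "n_factors")) {
  feature <- match.arg(feature)
  if (inherits(functional, "kd_functional")) functional <- list(functional)

  grp <- purrr::map_dfr(functional, function(fc) {
    x <- as_tibble(assignment) %>%
      dplyr::filter(.data$factor %in% fc$relevant_factors,
                    .data$gene %in% fc$calls$gene)
    de_genes <- fc$calls$gene[fc$calls$de]
    if (feature %in% c("n_sites", "n_factors")) {
      x %>%
        dplyr::group_by(.data$gene) %>%
        dplyr::summarise(value = if (feature == "n_sites") dplyr::n() else
                           dplyr::n_distinct(.data$factor),
                         .groups = "drop") %>%
        dplyr::mutate(functional = .data$gene %in% de_genes)
    } else {
      tibble(value = x[[feature]], functional = x$gene %in% de_genes)
    }
  })
  grp <- grp[!is.na(grp$value), ]
  f <- grp$value[grp$functional]
  nf <- grp$value[!grp$functional]
  if (length(f) == 0 || length(nf) == 0) {
    return(tibble(feature = feature, n_functional = length(f),
                  n_nonfunctional = length(nf), statistic = NA_real_,
                  shift = NA_real_, p = NA_real_))
  }
  rs <- rank_sum_test(f, nf)
  tibble(feature = feature, n_functional = length(f),
         n_nonfunctional = length(nf), statistic = rs$statistic,
         shift = rs$shift, p = rs$p)
}

#' Co-occupancy enrichment binned by shared differentially expressed factors
#'
#' For every unordered pair of knockdown experiments, computes the Jaccard
#' fraction of differentially expressed factors in common and the relative
#' enrichment of the 2x2 table (gene DE in both experiments?) x (gene bound
#' by at least one factor DE in both?) over the genes expressed in both
#' experiments. Pairs with an empty DE-factor intersection carry no
#' co-occupancy signal and are excluded (but counted). Pairs are binned into
#' quintiles of the shared fraction.
#'
#' @param de_list Named list of `kd_de` tables, one per experiment.
#' @param assignment A `kd_assignment` over all factors.
#' @param fdr FDR threshold.
#' @param n_bins Number of shared-fraction bins (default 5).
#' @return List of class `kd_cooccupancy`: `pairs` (tibble exp1, exp2,
#'   shared_frac, enrichment, bin), `n_excluded`.
#' @export
cooccupancy_enrichment <- function(de_list, assignment, fdr = 0.05,
                                   n_bins = 5) {
  if (length(de_list) < 2) {
    abort("need at least two experiments", class = "kdbind_config_error")
  }
  assignment <- as_tibble(assignment)
  have_map <- unique(assignment$factor)
  info <- lapply(de_list, function(de) {
    de_genes <- call_de(de, fdr)
    list(genes = de$gene, de = de_genes,
         de_tfs = intersect(de_genes, have_map))
  })
  combos <- combn(seq_along(de_list), 2, simplify = FALSE)
  n_excluded <- 0L
  pairs <- purrr::map_dfr(combos, function(pr) {
    i <- info[[pr[1]]]; j <- info[[pr[2]]]
    uni <- union(i$de_tfs, j$de_tfs)
    int <- intersect(i$de_tfs, j$de_tfs)
    shared <- if (length(uni) == 0) 0 else length(int) / length(uni)
    if (length(int) == 0) {
      n_excluded <<- n_excluded + 1L
      return(NULL)
    }
    genes <- intersect(i$genes, j$genes)
    de_both <- genes %in% i$de & genes %in% j$de
    bound <- genes %in%
      unique(assignment$gene[assignment$factor %in% int])
    tab <- matrix(c(sum(de_both & bound), sum(!de_both & bound),
                    sum(de_both & !bound), sum(!de_both & !bound)), 2)
    tibble(exp1 = names(de_list)[pr[1]], exp2 = names(de_list)[pr[2]],
           shared_frac = shared, enrichment = relative_enrichment(tab))
  })
  if (nrow(pairs) > 0) {
    br <- unique(quantile(pairs$shared_frac, probs = seq(0, 1,
                                                         length.out = n_bins + 1)))
    pairs$bin <- if (length(br) > 1) {
      as.integer(cut(pairs$shared_frac, breaks = br, include.lowest = TRUE))
    } else 1L
  }
  structure(list(pairs = pairs, n_excluded = n_excluded),
            class = "kd_cooccupancy")
}

#' Direction of expression change among putative direct targets
#'
#' @param functional A `kd_functional`.
#' @param de The matching `kd_de` table.
#' @return One-row tibble: `experiment`, `n_functional`,
#'   `frac_up_functional` (fraction of bound-and-DE genes with positive
#'   log2 fold-change; NA when there are none), `n_de`, `frac_up_de` (same
#'   over all DE genes).
#' @export
direction_of_effect <- function(functional, de) {
  lfc <- setNames(de$log2fc, de$gene)
  fun_genes <- functional$calls$gene[functional$calls$functional]
  de_genes <- functional$calls$gene[functional$calls$de]
  tibble(
    experiment = functional$experiment,
    n_functional = length(fun_genes),
    frac_up_functional = if (length(fun_genes) == 0) NA_real_ else
      mean(lfc[fun_genes] > 0),
    n_de = length(de_genes),
    frac_up_de = if (length(de_genes) == 0) NA_real_ else
      mean(lfc[de_genes] > 0)
  )
}

#' Sensitivity of the functional-binding fraction to the TSS window
#'
#' Recomputes the direct-binding overlap for a grid of window sizes plus the
#' promoter-excluded annulus, reporting per experiment the fraction of bound
#' genes that are differentially expressed.
#'
#' @param events Unified binding events.
#' @param tss Reference TSS table.
#' @param de_list Named list of `kd_de` tables.
#' @param windows Window half-widths in bp.
#' @param annulus Length-2 numeric `c(inner, outer)` for the
#'   promoter-excluded configuration, or NULL to skip.
#' @param fdr FDR threshold.
#' @param mode Relevant-factor mode passed to [classify_functional()].
#' @return Tibble: `window_label`, `window`, `inner`, `experiment`,
#'   `n_bound`, `n_overlap`, `frac_bound_de`.
#' @export
window_sensitivity <- function(events, tss, de_list,
                               windows = c(1, 2, 5, 10, 15, 20) * 1000,
                               annulus = c(1000, 10000), fdr = 0.05,
                               mode = "direct") {
  cfgs <- tibble(window = windows, inner = 0)
  if (!is.null(annulus)) {
    cfgs <- dplyr::bind_rows(cfgs,
                             tibble(window = annulus[2], inner = annulus[1]))
  }
  purrr::map_dfr(seq_len(nrow(cfgs)), function(i) {
    w <- cfgs$window[i]; inner <- cfgs$inner[i]
    asg <- assign_targets_window(events, tss, window = w, inner = inner)
    purrr::map_dfr(names(de_list), function(e) {
      fc <- classify_functional(asg, de_list[[e]], fdr = fdr, mode = mode)
      if (is.null(fc)) return(NULL)
      tibble(
        window_label = if (inner > 0)
          sprintf("%g-%g kb", inner / 1000, w / 1000)
        else sprintf("%g kb", w / 1000),
        window = w, inner = inner, experiment = e,
        n_bound = fc$overlap$n_bound, n_overlap = fc$overlap$n_overlap,
        frac_bound_de = fc$overlap$frac_bound_de
      )
    })
  })
}
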
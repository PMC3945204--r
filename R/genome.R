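#' Chromatin-state labels used on the synthetic chromosome
#'
#' Twelve merged state labels in the style of genome-wide chromatin
#' segmentations (two strong-enhancer, weak-enhancer and repetitive
#' sub-states each collapsed into one label).
#'
#' @export
chromatin_states <- function() {
  c("active_promoter", "weak_promoter", "poised_promoter",
    "strong_enhancer", "weak_enhancer", "insulator",
    "txn_transition", "txn_elongation", "weak_txn",
    "repressed", "heterochromatin", "repetitive")
}

# Background sampling probabilities for non-promoter tiles. The synthetic
# chromosome only represents the +/-10 kb neighbourhoods of expressed genes,
# i.e. active chromatin, where enhancer states are common.
state_background_probs <- function() {
  c(weak_promoter = 0.05, poised_promoter = 0.04,
    strong_enhancer = 0.22, weak_enhancer = 0.10, insulator = 0.06,
    txn_transition = 0.05, txn_elongation = 0.11, weak_txn = 0.12,
    repressed = 0.09, heterochromatin = 0.11, repetitive = 0.05)
}

#' Generate the synthetic genome annotation and binding maps
#'
#' Lays out one synthetic chromosome with one gene locus per
#' `cfg$gene_spacing` bp, candidate TSSs with CAGE-like scores, a complete
#' non-overlapping tiling of chromatin-state segments (+/-1 kb around each
#' true TSS is "active_promoter"; other tiles are drawn from a fixed
#' background distribution), and per-factor binding events.
#'
#' Binding events are placed within +/-10 kb of an assigned gene's true TSS
#' by sampling a chromatin-state segment with probability proportional to its
#' overlap width, multiplied by `promoter_affinity` for the promoter tile
#' (all sites, so decoy binding concentrates at promoters) and by
#' `enhancer_enrichment` for strong-enhancer tiles at functional sites only.
#' Every functional edge of the network receives at least one event near its
#' target's TSS that survives the footprint posterior filter. Each factor
#' additionally receives decoy events at genes it does not regulate, so the
#' expected fraction of bound genes that are true targets equals
#' `functional_fraction`. Motif scores at functional sites are shifted by
#' `motif_shift`, conservation by `cons_shift` (default 0).
#'
#' @param cfg A [sim_config()] object.
#' @param net A [generate_network()] result built from the same config.
#' @return A list of class `kd_genome` with elements `chrom`, `genes`
#'   (gene, locus_start, locus_end, strand, tss_true), `tss_candidates`
#'   (gene, chrom, strand, position, cage_score), `states` (chrom, start,
#'   end, state; 0-based half-open, tiling the chromosome), `events`
#'   (factor, chrom, start, end, source, posterior, motif_score, cons_score,
#'   plus truth columns target_gene and functional) and `links`
#'   (chrom, start, end, gene, score).
#' @export
generate_annotation <- function(cfg, net) {
  cfg <- validate_sim_config(cfg)
  stopifnot(inherits(net, "kd_network"))
  genes <- gene_ids(cfg$n_genes)
  if (!all(net$target %in% genes) || !all(net$tf %in% genes)) {
    abort("network references genes outside the configured genome",
          class = "kdbind_consistency_error")
  }

  withr::local_seed(stage_seed(cfg, "annotation"))
  chrom <- "chrS"
  spacing <- cfg$gene_spacing

  gene_tbl <- tibble(
    gene = genes,
    locus_start = (seq_along(genes) - 1) * spacing,
    locus_end = seq_along(genes) * spacing,
    strand = sample(c("+", "-"), length(genes), replace = TRUE)
  )
  gene_tbl$tss_true <- round(gene_tbl$locus_start + spacing / 2 +
                               runif(nrow(gene_tbl), -2000, 2000))

  n_cand <- sample(1:3, nrow(gene_tbl), replace = TRUE)
  idx <- rep(seq_len(nrow(gene_tbl)), n_cand)
  first <- !duplicated(idx)
  offset <- ifelse(first, 0L,
                   sample(500:1500, length(idx), replace = TRUE) *
                     sample(c(-1L, 1L), length(idx), replace = TRUE))
  score <- runif(length(idx), 1, 100)
  # the true TSS (first candidate of each gene) carries the top CAGE score
  score <- unlist(lapply(split(score, idx), sort, decreasing = TRUE),
                  use.names = FALSE)
  tss_candidates <- tibble(
    gene = gene_tbl$gene[idx], chrom = chrom,
    strand = gene_tbl$strand[idx],
    position = gene_tbl$tss_true[idx] + offset,
    cage_score = score
  )

  states <- tile_states(gene_tbl, chrom)
  events <- place_binding_events(cfg, net, gene_tbl, states, chrom)
  links <- make_distal_links(gene_tbl, chrom)

  structure(
    list(chrom = chrom, genes = gene_tbl, tss_candidates = tss_candidates,
         states = states, events = events, links = links),
    class = "kd_genome"
  )
}

# Tile each locus without gaps or overlaps: random-width background tiles up
# to the promoter, a fixed active_promoter tile at tss +/- 1 kb, then random
# tiles to the end of the locus.
tile_states <- function(gene_tbl, chrom) {
  bg <- state_background_probs()
  region_breaks <- function(from, to) {
    if (to <= from) return(NULL)
    n_max <- ceiling((to - from) / 800) + 1
    widths <- round(runif(n_max, 800, 3000))
    breaks <- from + cumsum(widths)
    c(from, breaks[breaks < to], to)
  }
  n <- nrow(gene_tbl)
  starts <- vector("list", n)
  ends <- vector("list", n)
  promoter <- vector("list", n)
  for (i in seq_len(n)) {
    tss <- gene_tbl$tss_true[i]
    b1 <- region_breaks(gene_tbl$locus_start[i], tss - 1000)
    b2 <- region_breaks(tss + 1000, gene_tbl$locus_end[i])
    s <- c(b1[-length(b1)], tss - 1000, b2[-length(b2)])
    e <- c(b1[-1], tss + 1000, b2[-1])
    starts[[i]] <- s
    ends[[i]] <- e
    promoter[[i]] <- s == tss - 1000
  }
  start <- unlist(starts)
  end <- unlist(ends)
  prom <- unlist(promoter)
  state <- sample(names(bg), length(start), replace = TRUE, prob = bg)
  state[prom] <- "active_promoter"
  tibble(chrom = chrom, start = start, end = end, state = state)
}

# Sample n event positions within +/-10 kb of a gene's TSS, weighting state
# segments by width x promoter_affinity (promoter tile) x enh_mult
# (strong-enhancer tiles).
sample_positions <- function(n, tss, segs, promoter_affinity, enh_mult) {
  lo <- tss - 10000
  hi <- tss + 10000
  ov <- segs[segs$end > lo & segs$start < hi, ]
  s <- pmax(ov$start, lo)
  e <- pmin(ov$end, hi)
  w <- (e - s) *
    ifelse(ov$state == "active_promoter", promoter_affinity, 1) *
    ifelse(ov$state == "strong_enhancer", enh_mult, 1)
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  floor(s[idx] + runif(n) * (e[idx] - s[idx]))
}

place_binding_events <- function(cfg, net, gene_tbl, states, chrom) {
  tss_of <- setNames(gene_tbl$tss_true, gene_tbl$gene)
  seg_by_locus <- split(states, findInterval(states$start,
                                             gene_tbl$locus_start))
  locus_of <- setNames(seq_len(nrow(gene_tbl)), gene_tbl$gene)
  ff <- cfg$functional_fraction

  one_factor <- function(tf, edges) {
    func_targets <- edges$target[edges$functional]
    n_edges <- nrow(edges)
    n_decoy <- max(0L, n_edges - length(func_targets))
    # decoy binding is placed independently of the regulatory network
    # (functional targets excluded only because they already carry sites)
    decoy_pool <- setdiff(gene_tbl$gene, c(func_targets, tf))
    decoys <- sample(decoy_pool, min(n_decoy, length(decoy_pool)))

    bound <- tibble(
      gene = c(func_targets, decoys),
      functional = rep(c(TRUE, FALSE), c(length(func_targets), length(decoys)))
    )
    if (nrow(bound) == 0) return(NULL)
    # functional regulatory regions harbour more binding sites than decoy
    # ones
    bound$n_ev <- 1L + rpois(nrow(bound),
                             ifelse(bound$functional, 1.2, 0.3))

    # per-gene positions (segment weights differ per gene), then one
    # event-level table for the whole factor
    pos <- vector("list", nrow(bound))
    for (i in seq_len(nrow(bound))) {
      g <- bound$gene[i]
      pos[[i]] <- sample_positions(
        bound$n_ev[i], tss_of[[g]], seg_by_locus[[locus_of[[g]]]],
        cfg$promoter_affinity,
        if (bound$functional[i]) cfg$enhancer_enrichment else 1
      )
    }
    idx <- rep(seq_len(nrow(bound)), bound$n_ev)
    n <- length(idx)
    fun <- bound$functional[idx]
    first <- !duplicated(idx)
    pos <- unlist(pos)
    src <- sample(c("chip", "dnase"), n, replace = TRUE)
    post <- ifelse(src == "dnase", runif(n, 0.9, 1), NA_real_)
    # the first event of a functional target is the construction guarantee:
    # it must survive the posterior > 0.95 filter
    guar <- fun & first & src == "dnase"
    post[guar] <- runif(sum(guar), 0.9501, 1)
    motif <- ifelse(src == "dnase",
                    rnorm(n, cfg$motif_mean, cfg$motif_sd) +
                      fun * cfg$motif_shift,
                    NA_real_)
    cons <- ifelse(src == "dnase",
                   pmin(1, rbeta(n, 2, 5) + fun * cfg$cons_shift),
                   NA_real_)
    tibble(factor = tf, chrom = chrom, start = pos, end = pos + 1L,
           source = src, posterior = post, motif_score = motif,
           cons_score = cons, target_gene = bound$gene[idx],
           functional = fun)
  }

  net %>%
    dplyr::group_by(.data$tf) %>%
    dplyr::group_split() %>%
    purrr::map_dfr(~ one_factor(.x$tf[1], .x))
}

# Distal regulatory elements linked to genes (cross-tissue-correlation style
# links): one promoter-proximal element per gene plus two distal elements
# within the +/-10 kb window; a random 10% of distal elements are linked to
# the neighbouring gene as well.
make_distal_links <- function(gene_tbl, chrom) {
  n <- nrow(gene_tbl)
  idx <- rep(seq_len(n), each = 3)
  distal <- rep(c(FALSE, TRUE, TRUE), n)
  m <- length(idx)
  offset <- ifelse(distal,
                   sample(1500:8000, m, replace = TRUE) *
                     sample(c(-1, 1), m, replace = TRUE),
                   -500)
  width <- ifelse(distal, round(runif(m, 1000, 2000)), 1000)
  out <- tibble(
    chrom = chrom,
    start = gene_tbl$tss_true[idx] + offset,
    end = gene_tbl$tss_true[idx] + offset + width,
    gene = gene_tbl$gene[idx],
    score = runif(m, 0.7, 1)
  )
  # a random tenth of distal elements is linked to the neighbouring gene too
  extra <- out[distal & runif(m) < 0.1 & idx < n, ]
  if (nrow(extra) > 0) {
    extra$gene <- gene_tbl$gene[match(extra$gene, gene_tbl$gene) + 1]
    out <- dplyr::bind_rows(out, extra)
  }
  out
}

#' @export
print.kd_genome <- function(x, ...) {
  cat("<kd_genome>\n")
  cat(sprintf("  %s: %d genes, %d state segments, %d binding events, %d links\n",
              x$chrom, nrow(x$genes), nrow(x$states), nrow(x$events),
              nrow(x$links)))
  invisible(x)
}
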
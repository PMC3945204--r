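#' Generate a ground-truth regulatory network
#'
#' Draws a signed TF-to-target network. Every transcription factor receives a
#' Poisson-distributed set of target genes; each edge carries a sign (+1: the
#' target goes up when the factor is knocked down, i.e. the factor represses
#' it; -1: the target goes down) and an effect magnitude in log2 units.
#' Magnitudes are drawn as `log2(1 + x)` with `x` exponential with median
#' `median_effect_pct/100`, so the median absolute percent change in
#' expression among true targets matches the configured effect size exactly
#' in distribution. An edge is flagged `functional` with probability
#' `functional_fraction`; functional edges are the ones the annotation
#' generator supports with binding events near the target's TSS.
#'
#' Factors are grouped into co-regulatory modules (`module_size` factors per
#' module); a fraction `within_module_frac` of each factor's targets is
#' drawn from a module-specific target pool that also contains the module's
#' other factors, so factors of one module regulate overlapping target sets
#' and each other - the structure behind co-occupancy of functional binding.
#'
#' Knocked-down factors are guaranteed to have at least one up- and one
#' down-signed target. Self-edges are never drawn: the only direct effect of
#' a factor on its own transcript is the knockdown itself.
#'
#' @param cfg A [sim_config()] object.
#' @return A tibble of class `kd_network` with columns `tf`, `target`,
#'   `sign`, `effect` (log2 magnitude, > 0), `functional`; attributes
#'   `tf_list` (all TF gene ids) and `kd_tfs` (knocked-down factors).
#' @examples
#' net <- generate_network(sim_config(n_genes = 300, n_tfs = 12,
#'                                    n_knockdowns = 4, seed = 7))
#' dplyr::count(net, tf)
#' @export
generate_network <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  genes <- gene_ids(cfg$n_genes)
  tf_list <- genes[seq_len(cfg$n_tfs)]
  kd_tfs <- tf_list[seq_len(cfg$n_knockdowns)]

  withr::local_seed(stage_seed(cfg, "network"))
  rate <- log(2) / (cfg$median_effect_pct / 100)

  # co-regulatory modules: a shared target pool per module, containing the
  # module's factors themselves
  module_of <- setNames(
    rep(seq_len(ceiling(cfg$n_tfs / cfg$module_size)),
        each = cfg$module_size)[seq_len(cfg$n_tfs)],
    tf_list
  )
  # pools only slightly larger than the out-degree: module-mates then share
  # most of their pool targets while pools of different modules stay distinct
  pool_size <- max(20L, round(1.2 * cfg$mean_out_degree))
  # TF transcripts are controlled by their module co-members only (core
  # regulatory circuitry); pools otherwise draw from non-TF genes
  non_tf <- setdiff(genes, tf_list)
  pools <- lapply(split(tf_list, module_of), function(tfs) {
    union(tfs, sample(non_tf, min(pool_size, length(non_tf))))
  })

  edges <- purrr::map_dfr(tf_list, function(tf) {
    deg <- max(2L, rpois(1, cfg$mean_out_degree))
    deg <- min(deg, cfg$n_genes - 1L)
    # factors of one module regulate each other (the module's defining
    # feature) and share a target pool
    fellows <- setdiff(tf_list[module_of == module_of[[tf]]], tf)
    fellows <- fellows[runif(length(fellows)) <
                         0.85 * cfg$within_module_frac / 0.7]
    pool <- setdiff(pools[[module_of[[tf]]]], c(tf, fellows))
    n_pool <- max(0L, min(round(cfg$within_module_frac * deg) -
                            length(fellows), length(pool)))
    targets <- c(fellows, sample(pool, n_pool))
    rest <- setdiff(non_tf, targets)
    targets <- c(targets,
                 sample(rest, max(0L, min(deg - length(targets),
                                          length(rest)))))
    sign <- ifelse(rbinom(length(targets), 1, 0.5) == 1, 1L, -1L)
    # knocked-down factors must show both directions of effect
    if (tf %in% kd_tfs && length(unique(sign)) == 1L) {
      sign[1] <- -sign[1]
    }
    tibble(
      tf = tf,
      target = targets,
      sign = sign,
      effect = log2(1 + rexp(length(targets), rate = rate)),
      functional = rbinom(length(targets), 1, cfg$functional_fraction) == 1
    )
  })

  structure(edges,
            class = c("kd_network", class(tibble())),
            tf_list = tf_list, kd_tfs = kd_tfs, modules = module_of)
}

gene_ids <- function(n) sprintf("G%05d", seq_len(n))
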
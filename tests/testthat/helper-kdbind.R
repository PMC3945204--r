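# Shared fixtures and wrappers for the test suite. All data is generated in
# code; sizes are kept small so the full suite stays fast.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

tiny_cfg <- function(..., seed = 42) {
  sim_config(n_genes = 200, n_tfs = 8, n_knockdowns = 3, mean_out_degree = 25,
             seed = seed, ...)
}

small_cfg <- function(..., seed = 7) {
  sim_config(n_genes = 500, n_tfs = 15, n_knockdowns = 6, seed = seed, ...)
}

# a tiny expression object with explicit batch structure, for unit tests
toy_expression <- function(n_genes = 50, n_batches = 3, per_batch = 4,
                           seed = 1) {
  withr::local_seed(seed)
  n_arr <- n_batches * per_batch
  arrays <- tibble::tibble(
    array_id = paste0("a", seq_len(n_arr)),
    batch = rep(seq_len(n_batches), each = per_batch),
    condition = "CONTROL",
    replicate = rep(seq_len(per_batch), n_batches),
    experiment = NA_character_
  )
  values <- matrix(rnorm(n_genes * n_arr, 8, 1), n_genes,
                   dimnames = list(paste0("g", seq_len(n_genes)),
                                   arrays$array_id))
  kd_expression(values, arrays = arrays)
}

# brute-force oracles used by several files
oracle_window <- function(events, tss, window, inner = 0) {
  out <- list()
  for (i in seq_len(nrow(events))) {
    for (j in seq_len(nrow(tss))) {
      if (events$chrom[i] != tss$chrom[j]) next
      d <- abs(events$midpoint[i] - tss$position[j])
      if (d <= window && (inner == 0 || d > inner)) {
        out[[length(out) + 1]] <- data.frame(
          gene = tss$gene[j], factor = events$factor[i],
          midpoint = events$midpoint[i], distance = d
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(), factor = character(),
                      midpoint = integer(), distance = numeric()))
  }
  do.call(rbind, out)
}

oracle_distal <- function(events, links) {
  out <- list()
  for (i in seq_len(nrow(events))) {
    for (j in seq_len(nrow(links))) {
      if (events$chrom[i] != links$chrom[j]) next
      m <- events$midpoint[i]
      if (m >= links$start[j] && m < links$end[j]) {
        out[[length(out) + 1]] <- data.frame(
          gene = links$gene[j], factor = events$factor[i], midpoint = m
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(), factor = character(),
                      midpoint = integer()))
  }
  do.call(rbind, out)
}

oracle_state <- function(events, states) {
  vapply(seq_len(nrow(events)), function(i) {
    hit <- which(states$chrom == events$chrom[i] &
                   states$start <= events$midpoint[i] &
                   events$midpoint[i] < states$end)
    if (length(hit) == 0) "unannotated" else states$state[hit[1]]
  }, character(1))
}

sort_pairs <- function(df) {
  out <- data.frame(gene = as.character(df$gene),
                    factor = as.character(df$factor),
                    midpoint = as.numeric(df$midpoint))
  if ("distance" %in% names(df)) out$distance <- as.numeric(df$distance)
  out <- out[order(out$gene, out$factor, out$midpoint), ]
  rownames(out) <- NULL
  out
}
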
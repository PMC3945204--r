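mk_de <- function(genes, de_genes, lfc = NULL, experiment = "E1",
                  target = "F1") {
  q <- ifelse(genes %in% de_genes, 0.01, 0.5)
  if (is.null(lfc)) lfc <- rep(1, length(genes))
  structure(tibble::tibble(gene = genes, log2fc = lfc, q = q),
            experiment = experiment, target = target,
            class = c("kd_de", class(tibble::tibble())))
}

mk_assignment <- function(df) {
  if (!"chrom" %in% names(df)) df$chrom <- "chr1"
  for (col in c("source", "posterior", "motif_score", "cons_score",
                "distance")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  structure(tibble::as_tibble(df),
            class = c("kd_assignment", class(tibble::tibble())),
            window = 10000, inner = 0)
}

test_that("functional classification counts the toy overlap correctly", {
  genes <- paste0("g", 1:10)
  # 4 bound (g1..g4), 3 DE (g1, g2, g5), 2 overlapping
  asg <- mk_assignment(tibble::tibble(
    gene = c("g1", "g2", "g3", "g4"), factor = "F1",
    midpoint = c(100, 200, 300, 400)
  ))
  de <- mk_de(genes, c("g1", "g2", "g5"))
  fc <- classify_functional(asg, de, fdr = 0.05, mode = "direct")
  expect_equal(fc$overlap$n_expressed, 10)
  expect_equal(fc$overlap$n_bound, 4)
  expect_equal(fc$overlap$n_de, 3)
  expect_equal(fc$overlap$n_overlap, 2)
  expect_equal(fc$overlap$frac_bound_de, 0.5)
  expect_equal(fc$overlap$frac_de_bound, 2 / 3)
  expect_true(all(fc$calls$functional == (fc$calls$bound & fc$calls$de)))

  # no DE genes: frac_bound_de = 0, frac_de_bound undefined
  none <- classify_functional(asg, mk_de(genes, character(0)), mode = "direct")
  expect_equal(none$overlap$frac_bound_de, 0)
  expect_true(is.na(none$overlap$frac_de_bound))

  # direct mode without a binding map for the target: skipped with a message
  expect_message(
    out <- classify_functional(asg, mk_de(genes, "g1", target = "F9"),
                               mode = "direct"),
    "no binding data"
  )
  expect_null(out)
})

test_that("downstream mode adds binding maps of DE factors", {
  genes <- c(paste0("g", 1:8), "F2")
  asg <- mk_assignment(tibble::tibble(
    gene = c("g1", "g2", "g3"), factor = c("F1", "F2", "F2"),
    midpoint = c(100, 200, 300)
  ))
  de <- mk_de(genes, c("F2", "g3"))
  direct <- classify_functional(asg, de, mode = "direct")
  down <- classify_functional(asg, de, mode = "downstream")
  expect_equal(direct$relevant_factors, "F1")
  expect_setequal(down$relevant_factors, c("F1", "F2"))
  expect_equal(direct$overlap$n_bound, 1)
  expect_equal(down$overlap$n_bound, 3)
})

test_that("overlap identities hold: overlap = frac * margin on both sides", {
  withr::local_seed(31)
  for (i in 1:20) {
    calls <- tibble::tibble(bound = runif(50) < 0.4, de = runif(50) < 0.3)
    ov <- overlap_table(calls)
    expect_equal(ov$frac_bound_de * ov$n_bound, ov$n_overlap,
                 tolerance = 1e-12)
    expect_equal(ov$frac_de_bound * ov$n_de, ov$n_overlap, tolerance = 1e-12)
    expect_lte(ov$n_overlap, min(ov$n_bound, ov$n_de))
  }
})

test_that("state enrichment tables match a hand count with hand-stepped BH", {
  # 12 events in 3 states; gene DE status fixed by construction
  asg <- mk_assignment(tibble::tibble(
    gene = paste0("g", c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6)),
    factor = "F1",
    midpoint = 1:12 * 10,
    state = c("strong_enhancer", "strong_enhancer", "strong_enhancer",
              "strong_enhancer", "active_promoter", "active_promoter",
              "active_promoter", "active_promoter", "weak_txn", "weak_txn",
              "weak_txn", "weak_txn")
  ))
  de <- mk_de(paste0("g", 1:6), c("g1", "g2"))
  fc <- classify_functional(asg, de, mode = "direct")
  se <- state_enrichment(asg, fc)
  expect_equal(nrow(se), 3)
  enh <- se[se$state == "strong_enhancer", ]
  # hand count: 4 enhancer events all DE; 8 other events none DE
  expect_equal(enh$n_de, 4)
  expect_equal(enh$n_not_de, 0)
  expect_equal(enh$p, fisher_exact(matrix(c(4, 0, 0, 8), 2))$p)
  # BH by the step-up formula
  o <- order(se$p)
  bh <- pmin(1, rev(cummin(rev(se$p[o] * 3 / seq_len(3)))))
  expect_equal(se$p_adj[o], bh)
  expect_true(all(se$p_adj >= se$p))
})

test_that("no-contrast state layouts give odds ratio 1 and p 1", {
  asg <- mk_assignment(tibble::tibble(
    gene = paste0("g", 1:4), factor = "F1", midpoint = 1:4 * 10,
    state = "weak_txn"
  ))
  de <- mk_de(paste0("g", 1:4), c("g1", "g2"))
  se <- state_enrichment(asg, classify_functional(asg, de, mode = "direct"))
  expect_equal(se$p, 1)
})

test_that("site-feature comparisons split events by the DE status of their gene", {
  asg <- mk_assignment(tibble::tibble(
    gene = rep(c("g1", "g2", "g3", "g4"), each = 2),
    factor = "F1", midpoint = 1:8,
    motif_score = c(5, 6, 7, 8, 1, 2, 3, 4),
    distance = c(100, 200, 300, 400, 500, 600, 700, 800)
  ))
  de <- mk_de(paste0("g", 1:4), c("g1", "g2"))
  fc <- classify_functional(asg, de, mode = "direct")
  mo <- compare_site_features(asg, fc, "motif_score")
  expect_equal(mo$n_functional, 4)
  expect_equal(mo$n_nonfunctional, 4)
  expect_gt(mo$shift, 0)
  expect_equal(mo$p, rank_sum_test(c(5, 6, 7, 8), c(1, 2, 3, 4))$p)

  ns <- compare_site_features(asg, fc, "n_sites")
  expect_equal(ns$n_functional, 2)   # per-gene unit
  nf <- compare_site_features(asg, fc, "n_factors")
  expect_equal(nf$shift, 0)          # every gene bound by exactly one factor

  no_nf <- classify_functional(asg, mk_de(paste0("g", 1:4), paste0("g", 1:4)),
                               mode = "direct")
  expect_true(is.na(compare_site_features(asg, no_nf, "motif_score")$p))
})

test_that("co-occupancy pairs use Jaccard sharing and exclude empty intersections", {
  genes <- c(paste0("g", 1:10), "F1", "F2", "F3")
  asg <- mk_assignment(tibble::tibble(
    gene = c("g1", "g2", "g3", "g4"), factor = c("F2", "F2", "F3", "F3"),
    midpoint = 1:4 * 100
  ))
  de <- list(
    E1 = mk_de(genes, c("F2", "g1", "g2"), experiment = "E1", target = "TA"),
    E2 = mk_de(genes, c("F2", "g1", "g5"), experiment = "E2", target = "TB"),
    E3 = mk_de(genes, c("F3", "g9"), experiment = "E3", target = "TC")
  )
  co <- cooccupancy_enrichment(de, asg, fdr = 0.05)
  p12 <- co$pairs[co$pairs$exp1 == "E1" & co$pairs$exp2 == "E2", ]
  expect_equal(p12$shared_frac, 1)      # identical DE-factor sets {F2}
  # E1/E3 and E2/E3 share no DE factors -> excluded but counted
  expect_equal(co$n_excluded, 2)
  expect_equal(nrow(co$pairs), 1)
  expect_error(cooccupancy_enrichment(de[1], asg),
               class = "kdbind_config_error")
})

test_that("direction of effect counts up-regulated functional targets", {
  genes <- paste0("g", 1:5)
  asg <- mk_assignment(tibble::tibble(
    gene = c("g1", "g2", "g3"), factor = "F1", midpoint = 1:3 * 10
  ))
  de <- mk_de(genes, c("g1", "g2", "g3", "g4"),
              lfc = c(1, -1, 2, -3, 1))
  fc <- classify_functional(asg, de, mode = "direct")
  d <- direction_of_effect(fc, de)
  expect_equal(d$n_functional, 3)
  expect_equal(d$frac_up_functional, 2 / 3)
  expect_equal(d$frac_up_de, 2 / 4)

  all_down <- mk_de(genes, c("g1", "g2"), lfc = rep(-1, 5))
  fc2 <- classify_functional(asg, all_down, mode = "direct")
  expect_equal(direction_of_effect(fc2, all_down)$frac_up_functional, 0)

  none <- mk_de(genes, character(0))
  fc3 <- classify_functional(asg, none, mode = "direct")
  expect_true(is.na(direction_of_effect(fc3, none)$frac_up_functional))
})

test_that("window sensitivity saturates once all binding is inside the window", {
  tss <- tibble::tibble(gene = paste0("g", 1:6), chrom = "chr1", strand = "+",
                        position = (1:6) * 100000, cage_score = 1)
  # all events within 2 kb of their gene's TSS
  ev <- tibble::tibble(
    factor = "F1", chrom = "chr1",
    midpoint = tss$position[1:4] + c(500, -1500, 1800, 900),
    source = "chip", posterior = NA_real_, motif_score = NA_real_,
    cons_score = NA_real_
  )
  de <- list(E1 = mk_de(tss$gene, c("g1", "g5")))
  ws <- window_sensitivity(ev, tss, de, windows = c(2, 5, 10, 20) * 1000,
                           annulus = NULL)
  expect_true(all(diff(ws$n_bound) >= 0))      # widening never shrinks bound
  expect_equal(length(unique(ws$frac_bound_de)), 1)  # saturated at >= 2 kb
  ws2 <- window_sensitivity(ev, tss, de, windows = 10000,
                            annulus = c(1000, 10000))
  ann <- ws2[ws2$inner == 1000, ]
  expect_equal(ann$n_bound, 2)   # the 500 bp and 900 bp events are excluded
})
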
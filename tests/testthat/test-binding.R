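test_that("reference TSS selection takes the CAGE maximum with midpoint ties", {
  one <- tibble::tibble(gene = "g", chrom = "chr1", strand = "+",
                        position = c(100, 400, 900), cage_score = c(5, 9, 2))
  expect_equal(select_reference_tss(one)$position, 400)

  tie <- tibble::tibble(gene = "g", chrom = "chr1", strand = "-",
                        position = c(100, 201), cage_score = c(7, 7))
  got <- select_reference_tss(tie)
  expect_equal(got$position, 150)
  expect_equal(got$strand, "-")

  bad <- tibble::tibble(gene = "g", chrom = c("chr1", "chr2"), strand = "+",
                        position = c(1, 2), cage_score = c(1, 2))
  expect_error(select_reference_tss(bad), class = "kdbind_consistency_error")
})

test_that("reference TSS selection matches a brute-force oracle", {
  withr::local_seed(4)
  for (i in 1:300) {
    n <- sample(1:5, 1)
    cand <- tibble::tibble(
      gene = "g", chrom = "chr1", strand = sample(c("+", "-"), 1),
      position = sample(1000:2000, n),
      cage_score = sample(1:6, n, replace = TRUE)  # ties likely
    )
    got <- select_reference_tss(cand)$position
    top <- cand$position[cand$cage_score == max(cand$cage_score)]
    want <- if (length(top) == 1) top else floor((min(top) + max(top)) / 2)
    expect_identical(as.numeric(got), as.numeric(want))
  }
})

test_that("event unification filters posteriors strictly and reduces midpoints", {
  dnase <- tibble::tibble(
    factor = "F1", chrom = "chr1",
    start = c(100, 300, 500), end = c(200, 400, 600),
    posterior = c(0.95, 0.951, 0.99),
    motif_score = 1:3, cons_score = c(0.1, 0.2, 0.3)
  )
  ev <- unify_binding_events(dnase_sites = dnase)
  expect_equal(nrow(ev), 2)                # 0.95 excluded (strict >)
  expect_equal(ev$midpoint, c(350, 550))

  peaks <- tibble::tibble(factor = c("F1", "F2"), chrom = "chr1",
                          start = c(100, 100), end = c(200, 201))
  expect_equal(unify_binding_events(chip_peaks = peaks)$midpoint,
               c(150, 150))
  # duplicate (factor, chrom, midpoint) collapses after union
  dup <- tibble::tibble(factor = "F1", chrom = "chr1",
                        start = c(100, 100), end = c(200, 201))
  expect_equal(nrow(unify_binding_events(chip_peaks = dup)), 1)

  both <- unify_binding_events(
    chip_peaks = tibble::tibble(factor = "F1", chrom = "chr1",
                                start = 100, end = 200),
    dnase_sites = dnase
  )
  expect_equal(nrow(both), 3)
  # idempotence: unify of an already-unified set is the identity
  again <- unify_binding_events(chip_peaks = both[both$source == "chip", ],
                                dnase_sites = both[both$source == "dnase", ])
  expect_equal(again, both)

  expect_error(unify_binding_events(
    chip_peaks = tibble::tibble(factor = "F", chrom = "c",
                                start = 10, end = 10)),
    class = "kdbind_parse_error")
  empty <- unify_binding_events()
  expect_equal(nrow(empty), 0)
})

test_that("window assignment uses an inclusive boundary and inner exclusion", {
  tss <- tibble::tibble(gene = "g", chrom = "chr1", strand = "+",
                        position = 50000, cage_score = 1)
  ev <- tibble::tibble(factor = "F1", chrom = "chr1",
                       midpoint = c(60000, 60001, 49200), source = "chip",
                       posterior = NA_real_, motif_score = NA_real_,
                       cons_score = NA_real_)
  a <- assign_targets_window(ev, tss, window = 10000)
  expect_setequal(a$midpoint, c(60000, 49200))   # 60001 is out (inclusive <=)
  a2 <- assign_targets_window(ev, tss, window = 10000, inner = 1000)
  expect_equal(a2$midpoint, 60000)               # distance 800 excluded
  expect_error(assign_targets_window(ev, tss, window = 0),
               class = "kdbind_config_error")
  counts <- target_counts(a)
  expect_equal(counts$n, 2)
})

test_that("window, distal and state assignment match quadratic oracles", {
  withr::local_seed(12)
  n_ev <- 500
  tss <- tibble::tibble(
    gene = paste0("g", 1:40),
    chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
    strand = "+",
    position = sample(1:200000, 40), cage_score = 1
  )
  ev <- tibble::tibble(
    factor = sample(c("F1", "F2", "F3"), n_ev, replace = TRUE),
    chrom = sample(c("chr1", "chr2"), n_ev, replace = TRUE),
    midpoint = sample(1:200000, n_ev, replace = TRUE),
    source = "chip", posterior = NA_real_, motif_score = NA_real_,
    cons_score = NA_real_
  )
  for (w in c(5000, 10000)) {
    got <- assign_targets_window(ev, tss, window = w)
    want <- oracle_window(ev, tss, w)
    expect_equal(nrow(got), nrow(want))
    expect_equal(sort_pairs(as.data.frame(got[, c("gene", "factor",
                                                  "midpoint", "distance")])),
                 sort_pairs(want))
  }
  gotin <- assign_targets_window(ev, tss, window = 10000, inner = 1000)
  expect_equal(nrow(gotin), nrow(oracle_window(ev, tss, 10000, 1000)))

  links <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
    start = sample(1:195000, 60)
  )
  links$end <- links$start + sample(500:4000, 60, replace = TRUE)
  links$gene <- sample(tss$gene, 60, replace = TRUE)
  links$score <- runif(60)
  gd <- assign_targets_distal(ev, links)
  wd <- oracle_distal(ev, links)
  expect_equal(nrow(gd), nrow(wd))
  expect_equal(sort_pairs(as.data.frame(gd[, c("gene", "factor", "midpoint")])),
               sort_pairs(wd))

  breaks <- sort(sample(1:199999, 80))
  states <- tibble::tibble(
    chrom = "chr1",
    start = c(0, breaks), end = c(breaks, 200001),
    state = sample(chromatin_states(), 81, replace = TRUE)
  )
  got_st <- quiet(annotate_site_state(ev, states))$state
  want_st <- oracle_state(ev, states)
  # chr2 events fall outside the chr1 tiling
  expect_equal(got_st, want_st)
})

test_that("distal assignment honours half-open intervals and multi-gene links", {
  ev <- tibble::tibble(factor = "F1", chrom = "chr1",
                       midpoint = c(100, 200), source = "chip",
                       posterior = NA_real_, motif_score = NA_real_,
                       cons_score = NA_real_)
  links <- tibble::tibble(chrom = "chr1", start = c(50, 50),
                          end = c(200, 200), gene = c("gA", "gB"),
                          score = 0.9)
  got <- assign_targets_distal(ev, links)
  # midpoint 200 == element end -> outside (half-open); 100 hits both genes
  expect_equal(nrow(got), 2)
  expect_setequal(got$gene, c("gA", "gB"))
  expect_true(all(got$midpoint == 100))
  expect_error(assign_targets_distal(ev, tibble::tibble(
    chrom = "chr1", start = 5, end = 5, gene = "g", score = 1)),
    class = "kdbind_parse_error")
})

test_that("state labels respect half-open segment boundaries", {
  states <- tibble::tibble(chrom = "chr1", start = c(0, 100, 200),
                           end = c(100, 200, 300),
                           state = c("s1", "s2", "s3"))
  ev <- tibble::tibble(chrom = "chr1", midpoint = c(100, 199, 200, 500))
  got <- quiet(annotate_site_state(ev, states))
  expect_equal(got$state, c("s2", "s2", "s3", "unannotated"))
})

test_that("TSS distances transform on the kb scale with the 0.001 offset", {
  asg <- tibble::tibble(distance = c(0, 1000, 10000))
  kb <- site_distance_to_tss(asg)
  expect_equal(kb$log_distance[1], -3)
  expect_equal(kb$log_distance[2], log10(1.001))
  expect_equal(round(kb$log_distance[2], 6), 0.000434)
  bp <- site_distance_to_tss(asg, scale = "bp")
  expect_equal(bp$log_distance[2], log10(1000.001))
  # absolute distances are strand-free by construction
  tssp <- tibble::tibble(gene = "g", chrom = "c", strand = "+",
                         position = 1000, cage_score = 1)
  tssm <- dplyr::mutate(tssp, strand = "-")
  ev <- tibble::tibble(factor = "F", chrom = "c", midpoint = 1800,
                       source = "chip", posterior = NA_real_,
                       motif_score = NA_real_, cons_score = NA_real_)
  expect_equal(assign_targets_window(ev, tssp, 10000)$distance,
               assign_targets_window(ev, tssm, 10000)$distance)
})
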
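test_that("probe filtering applies every exclusion rule and keeps 3'-most probes", {
  ann <- tibble::tibble(
    probe_id = paste0("p", 1:6),
    gene_id = c("g1", "g1", "g2", "g3", "g3", "g4"),
    maps_uniquely = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    secondary_hit_1mm = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    on_chrY = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    het_snp_overlap = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    three_prime_rank = c(1L, 2L, 1L, 1L, 2L, 1L)
  )
  # hand-walk: p1 chrY-excluded -> g1 keeps p2; g2's only probe has a SNP ->
  # dropped; g3 keeps rank-1 p4; g4's probe maps non-uniquely -> dropped
  expect_message(out <- filter_probes(ann), "2 gene")
  expect_equal(out$probe_id, c("p2", "p4"))
  expect_equal(out$gene_id, c("g1", "g3"))

  two <- tibble::tibble(
    probe_id = c("a", "b"), gene_id = "g",
    maps_uniquely = TRUE, secondary_hit_1mm = FALSE, on_chrY = FALSE,
    het_snp_overlap = c(TRUE, FALSE), three_prime_rank = c(1L, 2L)
  )
  expect_equal(filter_probes(two)$probe_id, "b")
  expect_error(filter_probes(ann[, -3]), class = "kdbind_consistency_error")
})

test_that("detection filter keeps genes expressed in all knockdowns or all controls", {
  det <- rbind(
    g1 = c(0.005, 0.005, 0.005, rep(0.5, 6)),   # all KD pass
    g2 = c(0.02, 0.005, 0.005, rep(0.005, 6)),  # all controls pass
    g3 = c(0.02, 0.005, 0.005, 0.02, rep(0.005, 5)),  # neither arm complete
    g4 = rep(0.005, 9),                          # both arms pass
    g5 = rep(0.5, 9)                             # nothing passes
  )
  arrays <- tibble::tibble(
    array_id = paste0("a", 1:9),
    batch = 1L,
    condition = c(rep("TF1", 3), rep("CONTROL", 6)),
    replicate = c(1:3, 1:6),
    experiment = c(rep("TF1.b1", 3), rep(NA, 6))
  )
  mat <- kd_expression(matrix(8, 5, 9, dimnames = list(rownames(det),
                                                       arrays$array_id)),
                       det, arrays)
  got <- detection_filter(mat, "TF1.b1")
  # brute-force evaluation of the rule over the toy table
  want <- rownames(det)[apply(det[, 1:3] < 0.01, 1, all) |
                          apply(det[, 4:9] < 0.01, 1, all)]
  expect_setequal(got, want)
  expect_setequal(got, c("g1", "g2", "g4"))
  expect_error(detection_filter(mat, "nope"), class = "kdbind_lookup_error")
})

test_that("quantile normalization equalizes columns with rank-mean values", {
  expect_equal(quantile_normalize(cbind(c(1, 3), c(2, 4))),
               cbind(c(1.5, 3.5), c(1.5, 3.5)))
  # ties share the mean of the quantiles they span
  expect_equal(quantile_normalize(cbind(c(5, 5), c(2, 4))),
               cbind(c(4, 4), c(3.5, 4.5)))
  same <- matrix(c(1, 2, 3), 3, 4)
  expect_equal(quantile_normalize(same), same)
  one <- matrix(rnorm(5), 5, 1)
  expect_identical(quantile_normalize(one), one)
})

test_that("quantile normalization is idempotent and equalizes distributions", {
  withr::local_seed(11)
  x <- matrix(rnorm(600, sd = 3), 100, 6)
  q1 <- quantile_normalize(x)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  for (j in 2:ncol(q1)) {
    expect_equal(sort(q1[, j]), sort(q1[, 1]), tolerance = 1e-12)
  }
})

test_that("control probes are the least-variable intersection across batches", {
  # three batches of 2 arrays; 5 probes with hand-set within-batch spreads
  arrays <- tibble::tibble(
    array_id = paste0("a", 1:6), batch = rep(1:3, each = 2),
    condition = "CONTROL", replicate = rep(1:2, 3),
    experiment = NA_character_
  )
  base <- matrix(0, 5, 6, dimnames = list(paste0("g", 1:5), arrays$array_id))
  # g1, g2 flat everywhere; g3 variable in batch 1; g4 in batch 2; g5 in batch 3
  base["g3", 1:2] <- c(-2, 2)
  base["g4", 3:4] <- c(-2, 2)
  base["g5", 5:6] <- c(-2, 2)
  jitter <- matrix(seq(0, 0.29, by = 0.01), 5, 6) * 0.01
  mat <- kd_expression(base + jitter, arrays = arrays)
  cs <- select_control_probes(mat, n_per_batch = 4)
  expect_s3_class(cs, "kd_control_set")
  expect_setequal(cs$controls, c("g1", "g2"))
  expect_true(all(vapply(cs$per_batch, length, integer(1)) == 4))
  expect_true(all(cs$controls %in% Reduce(intersect, cs$per_batch)))

  expect_warning(select_control_probes(mat, n_per_batch = 50), "capped")
  # disjoint least-variable lists -> empty set with a warning
  disj <- base
  disj["g1", 1:2] <- c(-3, 3)
  disj["g2", 3:4] <- c(-3, 3)
  disj["g3", ] <- 0
  disj["g4", ] <- 0
  disj["g5", 5:6] <- c(-3, 3)
  disj <- disj + matrix(rnorm(30, sd = 1e-4), 5, 6)
  mat2 <- kd_expression(disj, arrays = arrays)
  got <- withr::with_seed(1, select_control_probes(mat2, n_per_batch = 4))
  expect_true(length(got$controls) < 5)
})

test_that("control-probe selection is depleted of true knockdown targets", {
  hits <- vapply(1:5, function(s) {
    cfg <- sim_config(n_genes = 400, n_tfs = 12, n_knockdowns = 5, seed = s)
    study <- simulate_study(cfg)
    mat <- quiet(apply_probe_filter(study$mat,
                                    filter_probes(study$probe_annotation)))
    mat <- quantile_normalize(mat)
    cs <- quiet(select_control_probes(mat, n_per_batch = 100))
    targets <- unique(study$truth$targets$gene)
    n_univ <- nrow(mat$values)
    n_t <- sum(targets %in% rownames(mat$values))
    overlap <- length(intersect(cs$controls, targets))
    # lower-tail hypergeometric: controls contain fewer targets than chance
    phyper(overlap, n_t, n_univ - n_t, length(cs$controls))
  }, numeric(1))
  expect_gte(sum(hits < 0.01), 4)
})

test_that("RLE statistics match their definition", {
  const <- matrix(5, 10, 4, dimnames = list(NULL, paste0("a", 1:4)))
  rs <- rle_stats(const)
  expect_true(all(rs$rle_median == 0))
  expect_true(all(rs$rle_iqr == 0))

  # one array shifted by +1 from otherwise identical arrays: its deviation
  # median is exactly +1
  withr::local_seed(2)
  v <- rnorm(50, 8)
  shifted <- cbind(a1 = v, a2 = v + 1, a3 = v, a4 = v)
  rs2 <- rle_stats(shifted)
  expect_equal(unname(rs2$rle_median), c(0, 1, 0, 0))

  x6 <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("a", 1:6)))
  rs3 <- rle_stats(x6)
  dev <- x6 - apply(x6, 1, median)
  expect_equal(rs3$rle_median, apply(dev, 2, median))
  expect_equal(rs3$rle_iqr, apply(dev, 2, IQR))
})

test_that("PCA diagnostics report variance fractions and batch associations", {
  mat <- toy_expression()
  pca <- pca_diagnostics(mat)
  expect_equal(sum(pca$var_frac), 1, tolerance = 1e-10)
  expect_true(all(c("PC1", "PC2") %in% names(pca$scores)))
  expect_equal(nrow(pca$batch_assoc), 10)
  expect_error(pca_diagnostics(matrix(1:4, 2, 2)),
               class = "kdbind_config_error")
})

test_that("control averaging pools matched control types across batches", {
  cfg <- tiny_cfg()
  sim <- simulate_expression(cfg, generate_network(cfg))
  avg <- average_controls(sim$mat)
  ctl_before <- sim$mat$arrays$array_id[sim$mat$arrays$condition == "CONTROL"]
  ctl_after <- avg$arrays$array_id[avg$arrays$condition == "CONTROL"]
  expect_equal(length(ctl_after), cfg$controls_per_batch)
  expect_equal(ncol(avg$values),
               ncol(sim$mat$values) - length(ctl_before) + length(ctl_after))
  # profile 1 is the mean of the type-1 control arrays across batches
  t1 <- grep("\\.t1$", ctl_before, value = TRUE)
  expect_equal(avg$values[, "CTRL.avg.t1"],
               rowMeans(sim$mat$values[, t1]))
})
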
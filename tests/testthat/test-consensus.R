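test_that("perfectly separated blocks give exact consensus and the planted k", {
  x <- block_matrix(4, samples_per = 10)
  run <- consensus_cluster(x, k_range = 2:8, reps = 80, seed = 3)
  truth <- rep(1:4, each = 10)
  C <- run$consensus[["4"]]
  within <- outer(truth, truth, "==")
  expect_true(all(C[within] == 1))
  expect_true(all(C[!within] == 0))
  expect_equal(as.integer(run$chosen_k), 4L)
  expect_equal(partition_overlap(run$partition, truth), 1)

  # a different seed gives the same partition in the perfect-structure limit
  run2 <- consensus_cluster(x, k_range = 2:8, reps = 80, seed = 99)
  expect_equal(partition_overlap(run$partition, run2$partition), 1)

  two <- consensus_cluster(block_matrix(2, 10), k_range = 2:8, reps = 80, seed = 3)
  expect_equal(as.integer(two$chosen_k), 2L)
})

test_that("consensus matrices are symmetric, unit-diagonal, in [0,1], and seeded runs reproduce", {
  set.seed(12)
  x <- named_matrix(rbinom(40 * 30, 1, 0.3), 40, 30)
  r1 <- consensus_cluster(x, k_range = 2:4, reps = 40, seed = 5)
  r2 <- consensus_cluster(x, k_range = 2:4, reps = 40, seed = 5)
  for (C in r1$consensus) {
    expect_equal(C, t(C))
    expect_true(all(diag(C) == 1))
    expect_true(all(C >= 0 & C <= 1))
  }
  expect_identical(r1$consensus, r2$consensus)
  expect_identical(r1$partition, r2$partition)
})

test_that("consensus clustering validates its configuration", {
  x <- named_matrix(rbinom(100, 1, 0.5), 10, 10)
  expect_error(consensus_cluster(x, k_range = 2:10), class = "gdtec_config_error")
  expect_error(consensus_cluster(x, k_range = 2:4, method = "kmeans",
                                 distance = "binary"),
               class = "gdtec_config_error")
  expect_error(consensus_cluster(x, k_range = 2:4, subsample_fraction = 0),
               class = "gdtec_config_error")
})

test_that("select_k flags a flat delta-area curve as degenerate", {
  fake <- structure(list(
    k_range = 2:6,
    delta_area = data.frame(k = 2:6, area = rep(0.05, 5),
                            rel_delta = c(0.05, 0.01, 0.01, 0.01, 0.01)),
    config = list(elbow_threshold = 0.1)), class = "consensus_run")
  k <- select_k(fake)
  expect_equal(as.integer(k), 2L)
  expect_true(isTRUE(attr(k, "degenerate")))
})

test_that("planted-subtype cohorts are recovered with high agreement", {
  fx <- fused_fixture(seed = 201)
  run <- consensus_cluster(fx$fused$matrix, k_range = 2:6, reps = 150, seed = 1)
  expect_equal(as.integer(run$chosen_k), 4L)
  expect_gte(truth_ari(run$partition, fx$cohort), 0.9)
})

test_that("partition overlap equals the brute-force matching oracle", {
  expect_equal(partition_overlap(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(partition_overlap(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1)
  p <- setNames(c(1, 2, 1, 2), paste0("s", 1:4))
  q <- setNames(c(2, 1, 2, 1), paste0("s", c(2, 1, 4, 3)))
  expect_equal(partition_overlap(p, q), 1)  # name alignment + relabeling

  set.seed(77)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    p1 <- sample(1:3, n, replace = TRUE)
    p2 <- sample(1:3, n, replace = TRUE)
    expect_equal(partition_overlap(p1, p2), overlap_oracle(p1, p2))
    expect_equal(partition_overlap(p1, p2), partition_overlap(p2, p1))
    # any single matched pair of clusters is attainable, so the largest
    # contingency cell is a lower bound
    expect_gte(partition_overlap(p1, p2), max(table(p1, p2)) / n - 1e-12)
  }
  expect_error(partition_overlap(setNames(1:2, c("a", "b")),
                                 setNames(1:2, c("a", "c"))),
               class = "gdtec_alignment_error")
})

test_that("matrix overlap is Jaccard on 1-cells with the all-zero convention", {
  m <- named_matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(matrix_overlap(m, m), 1)
  d <- named_matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(matrix_overlap(m, d), 0)
  z <- named_matrix(0, 2, 2)
  expect_equal(matrix_overlap(z, z), 1)
  set.seed(8)
  for (i in 1:10) {
    a <- matrix(rbinom(100, 1, 0.4), 10, 10)
    b <- matrix(rbinom(100, 1, 0.4), 10, 10)
    both <- 0; either <- 0
    for (r in 1:10) for (cc in 1:10) {
      both <- both + (a[r, cc] == 1 && b[r, cc] == 1)
      either <- either + (a[r, cc] == 1 || b[r, cc] == 1)
    }
    expect_equal(matrix_overlap(a, b), both / either)
    expect_equal(matrix_overlap(a, b), matrix_overlap(b, a))
  }
  expect_error(matrix_overlap(m, named_matrix(0, 3, 2)),
               class = "gdtec_alignment_error")
})

test_that("widening the LFC band only removes driven cells (nesting)", {
  fx <- fused_fixture(seed = 55)
  co <- fx$cohort
  post_cnv <- collapse_cnv(co$cnv_calls)
  build <- function(band) {
    rna <- discretize_lfc(fx$lfc, band[1], band[2])
    fuse_gdtec(cnv_rna_consistency(post_cnv, rna),
               snv_rna_consistency(co$mutation, absolutize(rna)))
  }
  narrow <- build(c(-1, 1))
  mid <- build(c(-1.2, 1.2))
  wide <- build(c(-3, 3))
  expect_true(all(narrow[mid == 1] == 1))   # mid 1-cells subset of narrow's
  expect_true(all(mid[wide == 1] == 1))
  o_mid <- matrix_overlap(narrow, mid)
  o_wide <- matrix_overlap(narrow, wide)
  expect_lt(o_mid, 1)
  expect_gt(o_mid, o_wide)
})

test_that("robustness battery reports full agreement for identical configs and high agreement for separated cohorts", {
  fx <- fused_fixture(seed = 90, n_samples = 120,
                      expression_noise_sd = 0.15)
  co <- fx$cohort
  cfg <- list(method = "pam", distance = "binary")
  rep1 <- robustness_battery(co$mutation, collapse_cnv(co$cnv_calls), fx$lfc,
                             configs = list(cfg, cfg), k_range = 2:5,
                             reps = 30, seed = 2)
  expect_equal(rep1$summary_fraction, 1)
  expect_true(all(rep1$partition_overlap == 1))

  configs <- list(list(method = "pam", distance = "binary"),
                  list(method = "hclust-average", distance = "binary"),
                  list(method = "pam", distance = "manhattan"),
                  list(method = "kmeans", distance = "euclidean"))
  rep2 <- robustness_battery(co$mutation, collapse_cnv(co$cnv_calls), fx$lfc,
                             lfc_thresholds = list(c(-1, 1), c(-1.2, 1.2), c(-3, 3)),
                             multilevel_bands = list(c(1, 2, 3)),
                             configs = configs, k_range = 2:5, reps = 40,
                             seed = 3, overlap_cutoff = 0.8)
  expect_true(all(rep2$partition_overlap >= 0.9))
  expect_equal(rep2$summary_fraction, 1)
  mo <- rep2$matrix_overlap
  expect_equal(mo, t(mo))
  expect_gt(mo["lfc(-1,1)", "lfc(-1.2,1.2)"], mo["lfc(-1,1)", "lfc(-3,3)"])
  expect_output(print(rep2), "configuration pairs")
})
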
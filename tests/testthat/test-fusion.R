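# Brute-force oracle for the full fusion over a raw (cnv, rna, snv) triple:
# concordant copy-number/expression change, mutation with any expression
# change, and suppression when both mechanisms mark the same cell.
fusion_oracle <- function(cnv, rna, snv) {
  cnv_driven <- (cnv == 1 && rna == 1) || (cnv == -1 && rna == -1)
  snv_driven <- snv == 1 && abs(rna) == 1
  as.numeric(xor(cnv_driven, snv_driven))
}

test_that("consistency matrices match the sum-then-mark rules exhaustively", {
  combos <- expand.grid(cnv = c(-1, 0, 1), rna = c(-1, 0, 1))
  cnv <- named_matrix(combos$cnv, 1, 9)
  rna <- named_matrix(combos$rna, 1, 9)
  got <- cnv_rna_consistency(cnv, rna)
  want <- as.numeric(abs(combos$cnv + combos$rna) == 2)
  expect_identical(as.vector(got), want)
  expect_equal(got[1, combos$cnv == 1 & combos$rna == 1], 1)
  expect_equal(got[1, combos$cnv == -1 & combos$rna == -1], 1)
  expect_equal(got[1, combos$cnv == 1 & combos$rna == -1], 0)
  expect_equal(got[1, combos$cnv == 1 & combos$rna == 0], 0)

  combos2 <- expand.grid(snv = c(0, 1), rna2 = c(0, 1))
  snv <- named_matrix(combos2$snv, 1, 4)
  rna2 <- named_matrix(combos2$rna2, 1, 4)
  got2 <- snv_rna_consistency(snv, rna2)
  expect_identical(as.vector(got2), as.numeric(combos2$snv & combos2$rna2))
})

test_that("fusion is exclusive-or: simultaneous driving is zeroed", {
  combos <- expand.grid(a = c(0, 1), b = c(0, 1))
  a <- named_matrix(combos$a, 1, 4)
  b <- named_matrix(combos$b, 1, 4)
  got <- fuse_gdtec(a, b)
  expect_identical(as.vector(got), as.numeric(xor(combos$a, combos$b)))
  expect_equal(got[1, combos$a == 1 & combos$b == 1], 0)
})

test_that("composed pipeline equals the brute-force oracle on all 18 raw combos", {
  combos <- expand.grid(cnv = c(-1, 0, 1), rna = c(-1, 0, 1), snv = c(0, 1))
  cnv <- named_matrix(combos$cnv, 1, 18)
  rna <- named_matrix(combos$rna, 1, 18)
  snv <- named_matrix(combos$snv, 1, 18)
  fused <- fuse_gdtec(cnv_rna_consistency(cnv, rna),
                      snv_rna_consistency(snv, absolutize(rna)))
  want <- mapply(fusion_oracle, combos$cnv, combos$rna, combos$snv)
  expect_identical(as.vector(fused), unname(want))
  # no driven expression without an expression change
  expect_true(all(combos$rna[fused[1, ] == 1] != 0))
})

test_that("sparsity filter removes at strictly more than the zero bound", {
  m <- named_matrix(0, 3, 100)
  m[1, 1:39] <- 1   # 61 zeros -> removed
  m[2, 1:40] <- 1   # 60 zeros -> retained
  m[3, ] <- 1
  f <- filter_sparse_genes(m, 0.6)
  expect_setequal(f$retained_genes, c("g2", "g3"))
  expect_equal(f$removed_genes, "g1")

  ones <- named_matrix(1, 5, 10)
  expect_length(filter_sparse_genes(ones)$removed_genes, 0)

  set.seed(17)
  for (i in 1:5) {
    r <- named_matrix(rbinom(400, 1, runif(1, 0.2, 0.6)), 20, 20)
    f2 <- filter_sparse_genes(r, 0.6)
    want <- rownames(r)[vapply(seq_len(20), function(g)
      sum(r[g, ] == 0) / 20 <= 0.6, logical(1))]
    expect_identical(f2$retained_genes, want)
    # a gene with >= 40% ones can never be removed at the 60% bound
    dense <- rownames(r)[rowMeans(r) >= 0.4]
    expect_true(all(dense %in% f2$retained_genes))
  }
  expect_error(filter_sparse_genes(m, 0), class = "gdtec_config_error")
})

test_that("gdtec() composes, filters and summarises", {
  fx <- fused_fixture(seed = 7)
  g <- fx$fused
  expect_s3_class(g, "gdtec")
  expect_identical(rownames(g$matrix), g$retained_genes)
  expect_true(all(g$matrix %in% c(0, 1)))
  expect_true(all(rowMeans(g$matrix == 0) <= g$filter_fraction))
  expect_identical(sort(c(g$retained_genes, g$removed_genes)),
                   rownames(g$fused))
  expect_output(print(g), "GDTEC fusion matrix")
  expect_output(print(summary(g)), "double marks zeroed")
})

test_that("proportion screen selects by the hi/lo bounds and matches counting", {
  set.seed(23)
  m <- named_matrix(rbinom(600, 1, 0.4), 20, 30)
  groups <- factor(rep(c("mix", "rest"), c(12, 18)), levels = c("mix", "rest"))
  rep_ <- screen_gdtec_proportion(m, groups, hi = 0.7, lo = 0.3)
  for (i in seq_len(nrow(rep_))) {
    pa <- mean(m[i, 1:12]); pb <- mean(m[i, 13:30])
    expect_equal(rep_$prop_a[i], pa)
    expect_equal(rep_$prop_b[i], pb)
    expect_equal(rep_$selected[i], pa >= 0.7 && pb <= 0.3)
  }
  # explicit boundary cases
  m2 <- named_matrix(0, 2, 20)
  m2[1, 1:10] <- c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0)  # 0.8 in A
  m2[1, 11:12] <- 1                               # 0.2 in B
  m2[2, ] <- rep(c(1, 0), 10)                     # 0.5 / 0.5
  r2 <- screen_gdtec_proportion(m2, factor(rep(c("a", "b"), each = 10)))
  expect_identical(r2$selected, c(TRUE, FALSE))
  # sample-order invariance
  perm <- sample(30)
  rp <- screen_gdtec_proportion(m[, perm], groups[perm])
  expect_equal(rp$prop_a, rep_$prop_a)
  expect_equal(rp$selected, rep_$selected)
})

test_that("differential screen: planted shift found, null controlled, BH correct", {
  set.seed(31)
  n <- 50
  vals <- named_matrix(rnorm(40 * 2 * n, sd = 0.3), 40, 2 * n)
  vals[1, 1:n] <- vals[1, 1:n] + 2.0
  groups <- factor(rep(c("a", "b"), each = n))
  rep_ <- differential_genes(vals, groups)
  expect_true(rep_$selected[1])
  expect_equal(rep_$logfc[1], 2, tolerance = 0.2)

  # label shuffle of one matrix: null behaviour over repeated shuffles
  set.seed(32)
  base <- named_matrix(rnorm(40 * 2 * n), 40, 2 * n)
  hits <- vapply(1:10, function(i) {
    g <- sample(groups)
    sum(differential_genes(base, g)$selected)
  }, numeric(1))
  expect_lte(mean(hits), 0.05 * 40)

  # BH adjustment equals the step-up oracle
  hand_bh <- function(p) {
    m <- length(p); o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(p[o] * m / rank(p)[o]))
    adj[order(o)]
  }
  expect_equal(rep_$fdr, hand_bh(rep_$p), tolerance = 1e-12)
  expect_equal(hand_bh(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))

  # constant gene never selected
  cvals <- vals; cvals[2, ] <- 3
  r2 <- differential_genes(cvals, groups)
  expect_equal(r2$p[2], 1)
  expect_false(r2$selected[2])
})

test_that("Spearman screen matches a rank-then-Pearson oracle", {
  set.seed(41)
  expr <- named_matrix(rnorm(12 * 25), 12, 25)
  expr[2, ] <- expr[1, ]            # identical
  expr[3, ] <- -expr[1, ]           # reversed
  expr[4, ] <- 5                    # constant
  pairs <- cbind(paste0("g", c(1, 1, 1, 5, 7, 9)),
                 paste0("g", c(2, 3, 4, 6, 8, 10)))
  rep_ <- correlate_pairs(expr, pairs)
  expect_equal(rep_$rho[1], 1)
  expect_true(rep_$selected[1])
  expect_equal(rep_$rho[2], -1)
  expect_false(rep_$selected[2])
  expect_true(rep_$constant[3])
  expect_false(rep_$selected[3])
  for (i in c(4, 5, 6)) {
    want <- cor(rank(expr[pairs[i, 1], ]), rank(expr[pairs[i, 2], ]))
    expect_equal(rep_$rho[i], want, tolerance = 1e-12)
  }
  expect_error(correlate_pairs(expr, cbind("g1", "nope")),
               class = "gdtec_lookup_error")
})
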
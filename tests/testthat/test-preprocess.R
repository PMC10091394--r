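test_that("compute_lfc matches its definition entrywise", {
  tumor <- named_matrix(8, 1, 1, genes = "g1")
  normal <- named_matrix(c(1, 3), 1, 2, genes = "g1")
  expect_equal(compute_lfc(tumor, normal, pseudocount = 0)[1, 1], 2)

  # tumor equal to the reference everywhere -> all zero
  set.seed(3)
  norm <- named_matrix(rexp(40, 0.1), 8, 5)
  tum <- matrix(rowMeans(norm), 8, 4, dimnames = list(rownames(norm),
                                                      paste0("t", 1:4)))
  expect_true(all(abs(compute_lfc(tum, norm, pseudocount = 0)) < 1e-12))

  # random matrices against a per-entry loop oracle
  tum2 <- named_matrix(rexp(200, 0.05), 20, 10)
  norm2 <- named_matrix(rexp(120, 0.05), 20, 6, genes = rownames(tum2))
  got <- compute_lfc(tum2, norm2, pseudocount = 1)
  for (i in seq_len(nrow(tum2))) for (j in seq_len(ncol(tum2))) {
    want <- log2((tum2[i, j] + 1) / (mean(norm2[i, ]) + 1))
    expect_equal(got[i, j], want, tolerance = 1e-12)
  }
})

test_that("compute_lfc contract errors: missing gene, zero reference", {
  tum <- named_matrix(1:4, 2, 2, genes = c("a", "b"))
  norm <- named_matrix(1:2, 1, 2, genes = "a")
  expect_error(compute_lfc(tum, norm), class = "gdtec_alignment_error")
  norm0 <- named_matrix(c(0, 1, 0, 1), 2, 2, genes = c("a", "b"))
  err <- expect_error(compute_lfc(tum, norm0, pseudocount = 0),
                      class = "gdtec_domain_error")
  expect_match(conditionMessage(err), "a")
})

test_that("LFC is invariant to common positive scaling at pseudocount 0", {
  set.seed(9)
  tum <- named_matrix(rexp(60, 0.1), 10, 6)
  norm <- named_matrix(rexp(40, 0.1), 10, 4, genes = rownames(tum))
  l1 <- compute_lfc(tum, norm, pseudocount = 0)
  l2 <- compute_lfc(tum * 7.3, norm * 7.3, pseudocount = 0)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("binary LFC discretization matches brute force, including boundaries", {
  vals <- seq(-30, 30) / 10  # exact +-1 on the grid
  lfc <- named_matrix(vals, length(vals), 1)
  got <- discretize_lfc(lfc, -1, 1)
  want <- vapply(vals, function(x) if (x >= 1) 1 else if (x <= -1) -1 else 0,
                 numeric(1))
  expect_identical(as.vector(got), want)
  expect_identical(got[vals == 1], 1)
  expect_identical(got[vals == -1], -1)
  expect_identical(got[vals == 0.9], 0)

  # spec triple and all-zero identity
  trip <- named_matrix(c(2, -1.5, 0.5), 1, 3)
  expect_identical(as.vector(discretize_lfc(trip)), c(1, -1, 0))
  z <- named_matrix(0, 4, 4)
  expect_identical(discretize_lfc(z), z)
  expect_error(discretize_lfc(z, 1, -1), class = "gdtec_config_error")
})

test_that("discretization is monotone in the LFC value", {
  set.seed(5)
  x <- named_matrix(rnorm(100, sd = 2), 10, 10)
  d1 <- discretize_lfc(x)
  d2 <- discretize_lfc(x + abs(rnorm(100)))
  expect_true(all(d2 >= d1))
})

test_that("multi-level scoring matches a linear band scan; single band reduces to binary", {
  lfc <- named_matrix(c(2.5, -3.2, 0.9, 1, -1, 0), 1, 6)
  got <- discretize_lfc_multilevel(lfc, bands = c(1, 2, 3))
  expect_identical(as.vector(got), c(2, -3, 0, 1, -1, 0))

  set.seed(21)
  x <- named_matrix(rnorm(200, sd = 2.5), 20, 10)
  bands <- c(0.5, 1.4, 2.2, 3.1)
  got2 <- discretize_lfc_multilevel(x, bands, scores = c(1, 2, 5, 9))
  scan <- function(v) {
    s <- 0
    for (b in seq_along(bands)) if (abs(v) >= bands[b]) s <- c(1, 2, 5, 9)[b]
    sign(v) * s
  }
  expect_identical(as.vector(got2), vapply(as.vector(x), scan, numeric(1)))

  # one band at the binary threshold, scores clamped to 1
  single <- discretize_lfc_multilevel(x, bands = 1, scores = 1)
  expect_identical(single, discretize_lfc(x, -1, 1))

  expect_error(discretize_lfc_multilevel(x, bands = numeric(0)),
               class = "gdtec_config_error")
  expect_error(discretize_lfc_multilevel(x, bands = c(2, 1)),
               class = "gdtec_config_error")
})

test_that("mutation binarization filters silent records and ignores duplicates", {
  genes <- c("TP53", "F11R"); samples <- c("S1", "S2")
  one <- data.frame(sample_id = "S1", gene_id = "TP53",
                    variant_classification = "Missense_Mutation")
  m <- binarize_mutations(one, genes, samples)
  expect_equal(sum(m), 1)
  expect_equal(m["TP53", "S1"], 1)

  sil <- data.frame(sample_id = "S1", gene_id = "TP53",
                    variant_classification = "Silent")
  expect_equal(sum(binarize_mutations(sil, genes, samples)), 0)
  expect_equal(sum(binarize_mutations(sil, genes, samples,
                                      nonsilent_only = FALSE)), 1)

  dup <- one[rep(1, 5), ]
  expect_identical(binarize_mutations(dup, genes, samples), m)
})

test_that("random mutation sets match a membership oracle; outsiders counted", {
  set.seed(13)
  genes <- paste0("G", 1:10); samples <- paste0("S", 1:8)
  tab <- data.frame(
    sample_id = paste0("S", sample(1:10, 60, replace = TRUE)),
    gene_id = paste0("G", sample(1:12, 60, replace = TRUE)),
    variant_classification = sample(known_variant_classes, 60, replace = TRUE),
    stringsAsFactors = FALSE)
  got <- binarize_mutations(tab, genes, samples)
  qualifying <- !(tab$variant_classification %in% silent_variant_classes)
  for (g in genes) for (s in samples) {
    want <- any(qualifying & tab$gene_id == g & tab$sample_id == s)
    expect_equal(got[g, s] == 1, want)
  }
  inside <- tab$gene_id %in% genes & tab$sample_id %in% samples
  expect_equal(attr(got, "dropped_records"),
               sum(!inside[qualifying]))
})

test_that("CNV collapse implements sign and deep-only modes", {
  calls <- named_matrix(c(-2, -1, 0, 1, 2), 1, 5)
  expect_identical(as.vector(collapse_cnv(calls, "sign")), c(-1, -1, 0, 1, 1))
  expect_identical(as.vector(collapse_cnv(calls, "deep-only")), c(-1, 0, 0, 0, 1))
  set.seed(2)
  r <- named_matrix(sample(-2:2, 80, replace = TRUE), 8, 10)
  expect_identical(collapse_cnv(r, "sign"), sign(r))
  expect_identical(collapse_cnv(r, "deep-only"), sign(r) * (abs(r) == 2))
  expect_error(collapse_cnv(named_matrix(0.5, 1, 1)), class = "gdtec_domain_error")
})

test_that("absolutize is elementwise absolute value on ternary input", {
  t3 <- named_matrix(c(-1, 0, 1), 1, 3)
  expect_identical(as.vector(absolutize(t3)), c(1, 0, 1))
  z <- named_matrix(0, 3, 3)
  expect_identical(absolutize(z), z)
  set.seed(4)
  r <- named_matrix(sample(c(-1, 0, 1), 50, replace = TRUE), 5, 10)
  expect_identical(absolutize(r), abs(r))
  expect_error(absolutize(named_matrix(2, 1, 1)), class = "gdtec_domain_error")
})
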
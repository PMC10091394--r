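#' @name fusion
#' @title GDTEC fusion arithmetic and feature screens
#' @description The core fusion: two consistency matrices (copy number with
#'   expression change; mutation with any expression change) combined by an
#'   exclusive-or into the binary genome-driven transcriptome expression
#'   (GDTEC) matrix, followed by a sparsity filter, plus the screening rules
#'   used to derive subtype-specific feature lists from it.
NULL

#' Copy-number / expression-change consistency matrix
#'
#' The ternary layers are summed; sums of +-2 (both layers +1 or both -1,
#' i.e. a concordant change) are marked 1, everything else 0: expression is
#' considered driven by copy number only when the directions agree.
#'
#' @param post_cnv,post_rnaseq Ternary matrices with identical shape and
#'   gene/sample order.
#' @return Binary matrix.
#' @export
cnv_rna_consistency <- function(post_cnv, post_rnaseq) {
  validate_gene_matrix(post_cnv, "ternary", "post-CNV")
  validate_gene_matrix(post_rnaseq, "ternary", "post-RNAseq")
  gd_assert_same_shape(post_cnv, post_rnaseq, "post-CNV and post-RNAseq")
  1 * (abs(post_cnv + post_rnaseq) == 2)
}

#' Mutation / expression-change consistency matrix
#'
#' The binary mutation layer and the absolute expression-change layer are
#' summed; sums of 2 (both present) are marked 1: expression is considered
#' driven by mutation only when the gene is both mutated and differentially
#' expressed in that patient.
#'
#' @param post_snv,post2_rnaseq Binary matrices with identical shape and
#'   gene/sample order.
#' @return Binary matrix.
#' @export
snv_rna_consistency <- function(post_snv, post2_rnaseq) {
  validate_gene_matrix(post_snv, "binary", "post-SNV")
  validate_gene_matrix(post2_rnaseq, "binary", "post2-RNAseq")
  gd_assert_same_shape(post_snv, post2_rnaseq, "post-SNV and post2-RNAseq")
  post_snv * post2_rnaseq
}

#' Fuse the two consistency matrices into the GDTEC matrix
#'
#' The consistency matrices are summed and sums of 2 are marked 0 (an
#' exclusive-or): a cell is genome-driven when exactly one of the two
#' genomic mechanisms is consistent with the expression change, on the
#' rationale that simultaneous driving by both mechanisms is rare and a
#' double mark more likely reflects noise.
#'
#' @param cnv_rna,snv_rna Binary matrices with identical shape and order.
#' @return Binary GDTEC matrix.
#' @export
fuse_gdtec <- function(cnv_rna, snv_rna) {
  validate_gene_matrix(cnv_rna, "binary", "CNV-RNAseq consistency")
  validate_gene_matrix(snv_rna, "binary", "SNV-RNAseq consistency")
  gd_assert_same_shape(cnv_rna, snv_rna, "consistency matrices")
  1 * (cnv_rna + snv_rna == 1)
}

#' Remove genes whose GDTEC row is mostly zero
#'
#' A gene is removed when it is 0 in strictly more than
#' `max_zero_fraction` of the samples (the default 0.6 reads "more than 60
#' percent" literally: exactly 60 percent zeros is retained).
#'
#' @param gdtec_matrix Binary GDTEC matrix.
#' @param max_zero_fraction Retention bound on the per-gene zero fraction.
#' @return A list with `matrix` (retained rows), `retained_genes`,
#'   `removed_genes` and `filter_fraction`.
#' @export
filter_sparse_genes <- function(gdtec_matrix, max_zero_fraction = 0.6) {
  validate_gene_matrix(gdtec_matrix, "binary", "GDTEC matrix")
  if (!(max_zero_fraction > 0 && max_zero_fraction <= 1)) {
    gd_stop("gdtec_config_error", "max_zero_fraction must be in (0, 1]")
  }
  if (ncol(gdtec_matrix) == 0L) {
    gd_stop("gdtec_degenerate_error", "GDTEC matrix has zero samples")
  }
  zero_frac <- rowMeans(gdtec_matrix == 0)
  keep <- zero_frac <= max_zero_fraction
  list(matrix = gdtec_matrix[keep, , drop = FALSE],
       retained_genes = rownames(gdtec_matrix)[keep],
       removed_genes = rownames(gdtec_matrix)[!keep],
       filter_fraction = max_zero_fraction)
}

#' Build the GDTEC matrix from the three discretized layers
#'
#' Composes [cnv_rna_consistency()], [snv_rna_consistency()] (via
#' [absolutize()]) and [fuse_gdtec()], then applies the sparsity filter.
#'
#' @param post_snv Binary mutation layer.
#' @param post_cnv Ternary copy-number layer.
#' @param post_rnaseq Ternary expression-change layer.
#' @param max_zero_fraction Sparsity filter bound; see [filter_sparse_genes()].
#' @return An object of class `"gdtec"`: a list with the filtered binary
#'   `matrix`, the unfiltered `fused` matrix, the two consistency matrices
#'   (`cnv_rna`, `snv_rna`), `retained_genes`, `removed_genes` and
#'   `filter_fraction`.
#' @examples
#' genes <- c("TP53", "F11R"); samples <- c("S1", "S2")
#' snv <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(genes, samples))
#' cnv <- matrix(c(0, 1, 0, -1), 2, 2, dimnames = list(genes, samples))
#' rna <- matrix(c(1, 1, 0, -1), 2, 2, dimnames = list(genes, samples))
#' gdtec(snv, cnv, rna)$matrix
#' @export
gdtec <- function(post_snv, post_cnv, post_rnaseq, max_zero_fraction = 0.6) {
  cnv_rna <- cnv_rna_consistency(post_cnv, post_rnaseq)
  snv_rna <- snv_rna_consistency(post_snv, absolutize(post_rnaseq))
  fused <- fuse_gdtec(cnv_rna, snv_rna)
  filt <- filter_sparse_genes(fused, max_zero_fraction)
  structure(list(matrix = filt$matrix, fused = fused,
                 cnv_rna = cnv_rna, snv_rna = snv_rna,
                 retained_genes = filt$retained_genes,
                 removed_genes = filt$removed_genes,
                 filter_fraction = filt$filter_fraction),
            class = "gdtec")
}

#' @export
print.gdtec <- function(x, ...) {
  cat(sprintf("GDTEC fusion matrix: %d genes x %d samples (%d genes removed by the %.0f%% sparsity filter)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$removed_genes),
              100 * x$filter_fraction))
  cat(sprintf("driven cells: %d (%.1f%% of retained cells)\n",
              sum(x$matrix), 100 * mean(x$matrix)))
  invisible(x)
}

#' @export
summary.gdtec <- function(object, ...) {
  per_sample <- colSums(object$matrix)
  structure(list(
    n_genes = nrow(object$matrix),
    n_samples = ncol(object$matrix),
    removed_genes = length(object$removed_genes),
    driven_per_sample = summary(per_sample),
    cnv_driven = sum(object$cnv_rna),
    snv_driven = sum(object$snv_rna),
    both_suppressed = sum(object$cnv_rna + object$snv_rna == 2)
  ), class = "summary.gdtec")
}

#' @export
print.summary.gdtec <- function(x, ...) {
  cat(sprintf("GDTEC: %d genes x %d samples (%d filtered out)\n",
              x$n_genes, x$n_samples, x$removed_genes))
  cat(sprintf("CNV-driven cells %d, SNV-driven cells %d, double marks zeroed %d\n",
              x$cnv_driven, x$snv_driven, x$both_suppressed))
  cat("GDTEC genes per sample:\n")
  print(x$driven_per_sample)
  invisible(x)
}

.check_two_groups <- function(groups, samples) {
  groups <- as.factor(groups)
  if (length(groups) != length(samples)) {
    gd_stop("gdtec_alignment_error", "group labels must cover every sample")
  }
  if (nlevels(droplevels(groups)) != 2L) {
    gd_stop("gdtec_config_error", "exactly two non-empty groups are required")
  }
  droplevels(groups)
}

#' Screen genes by GDTEC proportion contrast between two groups
#'
#' A gene is selected when the fraction of GDTEC-expressing patients is at
#' least `hi` in the first group and at most `lo` in the second; the
#' defaults (0.7 / 0.3) are the subtype-specific screening bounds used for
#' ligand/receptor candidates, applicable to any gene list.
#'
#' @param gdtec_matrix Binary matrix (rows = genes), or a `"gdtec"` object.
#' @param groups Two-level factor over the samples; the first level is the
#'   high-proportion group.
#' @param hi,lo Proportion bounds.
#' @return Data frame with per-gene proportions and a `selected` flag;
#'   thresholds in attributes.
#' @export
screen_gdtec_proportion <- function(gdtec_matrix, groups, hi = 0.7, lo = 0.3) {
  if (inherits(gdtec_matrix, "gdtec")) gdtec_matrix <- gdtec_matrix$matrix
  validate_gene_matrix(gdtec_matrix, "binary", "GDTEC matrix")
  groups <- .check_two_groups(groups, colnames(gdtec_matrix))
  ga <- levels(groups)[1]; gb <- levels(groups)[2]
  pa <- rowMeans(gdtec_matrix[, groups == ga, drop = FALSE])
  pb <- rowMeans(gdtec_matrix[, groups == gb, drop = FALSE])
  out <- data.frame(gene_id = rownames(gdtec_matrix),
                    prop_a = pa, prop_b = pb,
                    selected = pa >= hi & pb <= lo,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(hi = hi, lo = lo)
  attr(out, "groups") <- c(a = ga, b = gb)
  out
}

#' Two-group differential screen on a real-valued matrix
#'
#' Per gene: effect = difference of group means (first minus second level)
#' on the log2 scale of the supplied values, a two-sample location test
#' (Welch's t by default, Wilcoxon optionally), Benjamini-Hochberg
#' adjustment across genes, and selection at `|effect| >= min_abs_logfc`
#' and adjusted p `< max_fdr`. A gene constant in both groups gets p = 1
#' and is never selected.
#'
#' @param values Real gene-by-sample matrix on the log2 scale.
#' @param groups Two-level factor over the samples.
#' @param min_abs_logfc,max_fdr Selection thresholds (defaults 0.58 / 0.05).
#' @param test `"welch"` or `"wilcoxon"`.
#' @return Data frame with `logfc`, `p`, `fdr` and `selected` per gene.
#' @export
differential_genes <- function(values, groups, min_abs_logfc = 0.58,
                               max_fdr = 0.05, test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  validate_gene_matrix(values, "real", "expression matrix")
  groups <- .check_two_groups(groups, colnames(values))
  a <- values[, groups == levels(groups)[1], drop = FALSE]
  b <- values[, groups == levels(groups)[2], drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) {
    gd_stop("gdtec_config_error", "each group needs >= 2 samples")
  }
  logfc <- rowMeans(a) - rowMeans(b)
  p <- vapply(seq_len(nrow(values)), function(i) {
    xa <- a[i, ]; xb <- b[i, ]
    if (sd(xa) == 0 && sd(xb) == 0) return(if (mean(xa) == mean(xb)) 1 else 0)
    tryCatch({
      if (test == "welch") t.test(xa, xb)$p.value
      else wilcox.test(xa, xb, exact = FALSE)$p.value
    }, error = function(e) 1)
  }, numeric(1))
  fdr <- p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(values), logfc = logfc, p = p, fdr = fdr,
             selected = abs(logfc) >= min_abs_logfc & fdr < max_fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman-correlation screen over gene pairs
#'
#' For each (gene A, gene B) pair, Spearman's rho across samples with its
#' p-value; a pair is selected when `rho >= min_rho` and `p < max_p`. Ties
#' receive average ranks; p-values are exact below 10 samples (when there
#' are no ties) and use the t approximation otherwise. Pairs involving a
#' constant gene are flagged and never selected.
#'
#' @param expr Real gene-by-sample expression matrix.
#' @param pairs Two-column matrix or data.frame of gene IDs.
#' @param min_rho,max_p Selection thresholds (defaults 0.2 / 0.05).
#' @return Data frame with `rho`, `p`, `constant` flag and `selected`.
#' @export
correlate_pairs <- function(expr, pairs, min_rho = 0.2, max_p = 0.05) {
  validate_gene_matrix(expr, "real", "expression matrix")
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) gd_stop("gdtec_config_error", "pairs must have two columns")
  if (ncol(expr) < 3L) gd_stop("gdtec_config_error", "need >= 3 samples")
  missing_genes <- setdiff(unique(c(pairs)), rownames(expr))
  if (length(missing_genes)) {
    gd_stop("gdtec_lookup_error", "gene(s) absent from expression matrix: %s",
            paste(head(missing_genes, 3), collapse = ", "))
  }
  n <- ncol(expr)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    xa <- expr[pairs[i, 1], ]; xb <- expr[pairs[i, 2], ]
    if (sd(xa) == 0 || sd(xb) == 0) {
      return(data.frame(rho = NA_real_, p = NA_real_, constant = TRUE))
    }
    ct <- suppressWarnings(
      cor.test(xa, xb, method = "spearman", exact = n < 10))
    data.frame(rho = unname(ct$estimate), p = ct$p.value, constant = FALSE)
  })
  res <- do.call(rbind, res)
  data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2], res,
             selected = !res$constant & res$rho >= min_rho & res$p < max_p,
             row.names = NULL, stringsAsFactors = FALSE)
}
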
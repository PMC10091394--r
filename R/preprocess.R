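#' @name preprocess
#' @title Discretized omics layers
#' @description Builds the three per-gene, per-patient discretized layers the
#'   fusion consumes: binary mutation status (post-SNV), ternary copy-number
#'   direction (post-CNV) and ternary expression change via log2 fold change
#'   against a pooled normal reference (post-RNAseq), plus the multi-level
#'   scored variant and the absolute-value transform (post2-RNAseq).
NULL

#' Log2 fold change of tumor expression against the pooled normal reference
#'
#' Each entry is `log2((tumor + pseudocount) / (mean(normal) + pseudocount))`
#' where the reference is the per-gene mean over all normal samples. A
#' pseudocount (default 1 on the abundance scale) guards against zero
#' references in FPKM-like data.
#'
#' @param tumor,normal Real gene-by-sample matrices sharing gene IDs
#'   (every tumor gene must be present in `normal`).
#' @param pseudocount Non-negative real added to tumor values and to the
#'   normal reference mean before the log ratio.
#' @return Matrix of log2 fold changes with the shape of `tumor`, carrying
#'   attributes `pseudocount` and `reference` (a description string).
#' @export
compute_lfc <- function(tumor, normal, pseudocount = 1) {
  gd_assert_matrix(tumor, "tumor")
  gd_assert_matrix(normal, "normal")
  if (pseudocount < 0) gd_stop("gdtec_config_error", "pseudocount must be >= 0")
  if (ncol(normal) < 1L) gd_stop("gdtec_config_error", "normal needs >= 1 sample")
  missing_genes <- setdiff(rownames(tumor), rownames(normal))
  if (length(missing_genes)) {
    gd_stop("gdtec_alignment_error",
            "gene(s) present in tumor but absent in normal: %s",
            paste(head(missing_genes, 3), collapse = ", "))
  }
  ref <- rowMeans(normal[rownames(tumor), , drop = FALSE]) + pseudocount
  if (any(ref == 0)) {
    gd_stop("gdtec_domain_error",
            "zero reference mean with pseudocount 0 for gene '%s'",
            rownames(tumor)[which(ref == 0)[1]])
  }
  lfc <- log2(sweep(tumor + pseudocount, 1, ref, "/"))
  attr(lfc, "pseudocount") <- pseudocount
  attr(lfc, "reference") <- sprintf("per-gene mean over %d normal samples", ncol(normal))
  lfc
}

#' Threshold a log-fold-change matrix into a ternary expression-change layer
#'
#' Values inside the open interval `(low, high)` are normal expression (0);
#' `lfc >= high` is up-regulation (1) and `lfc <= low` down-regulation (-1).
#' A fold change exactly at a threshold counts as abnormal.
#'
#' @param lfc Real matrix of log2 fold changes.
#' @param low,high Band edges, `low < high`; default band `(-1, 1)`.
#' @return Ternary matrix in \{-1, 0, 1\}.
#' @export
discretize_lfc <- function(lfc, low = -1, high = 1) {
  if (!(low < high)) gd_stop("gdtec_config_error", "low must be < high")
  out <- matrix(0, nrow(lfc), ncol(lfc), dimnames = dimnames(lfc))
  out[lfc >= high] <- 1
  out[lfc <= low] <- -1
  out
}

#' Multi-level score assignment from log fold changes
#'
#' Assigns `sign(lfc) * score` of the highest band whose lower bound is
#' `<= |lfc|`, and 0 below the first band. With the default bands
#' (scores 1, 2, 3 at |LFC| >= 1, 2, 3) this generalizes the ternary layer
#' to a graded one.
#'
#' @param lfc Real matrix of log2 fold changes.
#' @param bands Strictly increasing non-negative lower bounds on `|lfc|`.
#' @param scores Positive integer score per band (defaults to `1:length(bands)`).
#' @return Integer-valued matrix of signed scores.
#' @export
discretize_lfc_multilevel <- function(lfc, bands = c(1, 2, 3),
                                      scores = seq_along(bands)) {
  if (length(bands) == 0L) gd_stop("gdtec_config_error", "band list is empty")
  if (length(bands) != length(scores)) {
    gd_stop("gdtec_config_error", "bands and scores must have equal length")
  }
  if (any(diff(bands) <= 0)) {
    gd_stop("gdtec_config_error", "bands must be strictly increasing")
  }
  if (any(scores <= 0) || any(scores != round(scores))) {
    gd_stop("gdtec_config_error", "scores must be positive integers")
  }
  idx <- findInterval(abs(lfc), bands)
  val <- ifelse(idx == 0, 0, scores[pmax(idx, 1)])
  out <- sign(lfc) * val
  dim(out) <- dim(lfc)
  dimnames(out) <- dimnames(lfc)
  out
}

#' Binary mutation layer from a mutation table
#'
#' Entry (gene, sample) is 1 when at least one qualifying mutation record
#' exists. With `nonsilent_only = TRUE` (the default), records whose
#' classification is in [silent_variant_classes] do not qualify. Records for
#' genes/samples outside the supplied universes are dropped and counted.
#'
#' @param muts Mutation table from [read_mutation_table()].
#' @param genes,samples Character vectors defining the matrix universe.
#' @param nonsilent_only Drop silent/non-coding records?
#' @return Binary gene-by-sample matrix; attribute `dropped_records` counts
#'   the records outside the universes.
#' @export
binarize_mutations <- function(muts, genes, samples, nonsilent_only = TRUE) {
  keep <- rep(TRUE, nrow(muts))
  if (nonsilent_only) {
    keep <- !(muts$variant_classification %in% silent_variant_classes)
  }
  m <- muts[keep, , drop = FALSE]
  inside <- m$gene_id %in% genes & m$sample_id %in% samples
  dropped <- sum(!inside)
  m <- m[inside, , drop = FALSE]
  out <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
  if (nrow(m)) out[cbind(m$gene_id, m$sample_id)] <- 1
  attr(out, "dropped_records") <- dropped
  out
}

#' Collapse GISTIC-style integer copy-number calls to a ternary layer
#'
#' `mode = "sign"` (default) keeps the direction of any gain/loss;
#' `mode = "deep-only"` keeps only deep events (`|call| == 2`).
#'
#' @param calls Integer gene-by-sample matrix, typically in \{-2..2\}.
#' @param mode `"sign"` or `"deep-only"`.
#' @return Ternary matrix in \{-1, 0, 1\}.
#' @export
collapse_cnv <- function(calls, mode = c("sign", "deep-only")) {
  mode <- match.arg(mode)
  validate_gene_matrix(calls, "integer", what = "CNV calls")
  out <- if (mode == "sign") sign(calls) else sign(calls) * (abs(calls) == 2)
  dimnames(out) <- dimnames(calls)
  out
}

#' Absolute-value transform of a ternary layer
#'
#' Marks -1 as 1 so that both expression directions count as an expression
#' change; applied to the post-RNAseq layer this yields the post2-RNAseq
#' layer consumed by the mutation-consistency rule.
#'
#' @param x Ternary matrix in \{-1, 0, 1\}.
#' @return Binary matrix in \{0, 1\}.
#' @export
absolutize <- function(x) {
  validate_gene_matrix(x, "ternary", what = "ternary layer")
  abs(x)
}
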
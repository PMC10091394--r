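#' @name omics_io
#' @title Tabular omics input/output and cross-layer alignment
#' @description Readers and writers for the plain TSV formats the pipeline
#'   touches: MAF-style mutation tables, gene-by-sample matrices (UCSC
#'   Xena / GEO series-matrix convention: gene rows, sample columns, tab
#'   separated, header row of sample IDs) and clinical tables. Gene identity
#'   is the symbol string as given; no aliasing or remapping is performed.
NULL

#' Variant-classification vocabulary
#'
#' Controlled vocabulary for MAF `Variant_Classification` values and the
#' subset conventionally treated as silent (non-coding / synonymous), which
#' [binarize_mutations()] excludes when `nonsilent_only = TRUE`.
#'
#' @format Character vectors.
#' @export
known_variant_classes <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site", "Targeted_Region",
  "Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR", "RNA"
)

#' @rdname known_variant_classes
#' @export
silent_variant_classes <- c(
  "Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR", "RNA"
)

.domain_check <- function(values, value_domain) {
  switch(value_domain,
    real = !is.finite(values),
    ternary = !(values %in% c(-1, 0, 1)),
    binary = !(values %in% c(0, 1)),
    integer = !is.finite(values) | values != round(values),
    gd_stop("gdtec_config_error", "unknown value domain '%s'", value_domain)
  )
}

#' Validate a gene-by-sample matrix against a declared value domain
#'
#' @param mat Numeric matrix, genes as rows, samples as columns, both named.
#' @param value_domain One of `"real"`, `"ternary"` (-1/0/1), `"binary"`
#'   (0/1) or `"integer"` (GISTIC-style integer calls).
#' @param what Label used in error messages.
#' @return The matrix, invisibly. Errors name the offending gene/sample
#'   coordinate for domain violations and reject duplicated IDs.
#' @export
validate_gene_matrix <- function(mat, value_domain = "real", what = "matrix") {
  gd_assert_matrix(mat, what)
  if (anyDuplicated(rownames(mat))) {
    gd_stop("gdtec_format_error", "%s has duplicated gene IDs (e.g. '%s')",
            what, rownames(mat)[duplicated(rownames(mat))][1])
  }
  if (anyDuplicated(colnames(mat))) {
    gd_stop("gdtec_format_error", "%s has duplicated sample IDs (e.g. '%s')",
            what, colnames(mat)[duplicated(colnames(mat))][1])
  }
  bad <- array(.domain_check(mat, value_domain), dim(mat))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    gd_stop("gdtec_domain_error",
            "%s value %s at gene '%s', sample '%s' outside declared domain '%s'",
            what, format(mat[idx[1], idx[2]]), rownames(mat)[idx[1]],
            colnames(mat)[idx[2]], value_domain)
  }
  invisible(mat)
}

#' Read a gene-by-sample matrix from TSV
#'
#' Expects gene rows and sample columns with a header row of sample IDs; the
#' first column holds gene IDs.
#'
#' @inheritParams validate_gene_matrix
#' @param path Path to a TSV file.
#' @return A validated numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path, value_domain = "real") {
  if (!file.exists(path)) gd_stop("gdtec_format_error", "file not found: %s", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    gd_stop("gdtec_empty_error", "matrix file %s has no data", path)
  }
  genes <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  validate_gene_matrix(mat, value_domain, what = basename(path))
  mat
}

#' Write a gene-by-sample matrix as TSV
#'
#' @param mat Named numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  gd_assert_matrix(mat)
  # %.17g keeps doubles exact under the write/read round trip
  chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat),
                dimnames = dimnames(mat))
  df <- data.frame(gene_id = rownames(mat), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a somatic mutation table
#'
#' Supports minimal MAF (columns `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Variant_Classification`) and a long TSV with columns `sample_id`,
#' `gene_id`, `variant_classification`. Classifications outside the
#' documented vocabulary are preserved but recorded in the
#' `"unknown_classes"` attribute.
#'
#' @param path Path to a TSV/MAF file.
#' @param format `"maf"` or `"long"`.
#' @return A data.frame with columns `sample_id`, `gene_id`,
#'   `variant_classification`.
#' @export
read_mutation_table <- function(path, format = c("maf", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) gd_stop("gdtec_format_error", "file not found: %s", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  need <- if (format == "maf") {
    c(gene_id = "Hugo_Symbol", sample_id = "Tumor_Sample_Barcode",
      variant_classification = "Variant_Classification")
  } else {
    c(gene_id = "gene_id", sample_id = "sample_id",
      variant_classification = "variant_classification")
  }
  missing_cols <- setdiff(need, colnames(raw))
  if (length(missing_cols)) {
    gd_stop("gdtec_format_error", "mutation table %s is missing column(s): %s",
            path, paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    gd_stop("gdtec_empty_error", "mutation table %s has no records", path)
  }
  tab <- data.frame(
    sample_id = as.character(raw[[need[["sample_id"]]]]),
    gene_id = as.character(raw[[need[["gene_id"]]]]),
    variant_classification = as.character(raw[[need[["variant_classification"]]]]),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(tab$sample_id)) || any(!nzchar(tab$gene_id))) {
    gd_stop("gdtec_format_error", "mutation table %s has empty sample or gene IDs", path)
  }
  attr(tab, "unknown_classes") <-
    setdiff(unique(tab$variant_classification), known_variant_classes)
  tab
}

#' Write a mutation table
#'
#' @param tab Data frame as returned by [read_mutation_table()].
#' @param path Output path.
#' @param format `"maf"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(tab, path, format = c("maf", "long")) {
  format <- match.arg(format)
  out <- if (format == "maf") {
    data.frame(Hugo_Symbol = tab$gene_id,
               Tumor_Sample_Barcode = tab$sample_id,
               Variant_Classification = tab$variant_classification,
               stringsAsFactors = FALSE)
  } else {
    tab[, c("sample_id", "gene_id", "variant_classification")]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Requires columns `sample_id`, `os_time` (days, non-negative) and
#' `os_event` (0 = censored, 1 = death); additional columns are carried
#' through as covariates. One row per sample.
#'
#' @param path Path to a TSV file.
#' @return A data.frame.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) gd_stop("gdtec_format_error", "file not found: %s", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("sample_id", "os_time", "os_event")
  missing_cols <- setdiff(need, colnames(raw))
  if (length(missing_cols)) {
    gd_stop("gdtec_format_error", "clinical table %s is missing column(s): %s",
            path, paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$sample_id)) {
    gd_stop("gdtec_format_error", "clinical table %s has duplicated sample IDs", path)
  }
  if (any(!is.finite(raw$os_time)) || any(raw$os_time < 0)) {
    gd_stop("gdtec_domain_error", "os_time must be non-negative and finite")
  }
  if (!all(raw$os_event %in% c(0, 1))) {
    gd_stop("gdtec_domain_error", "os_event must be 0 or 1")
  }
  raw
}

#' Align omics layers (and optionally a clinical table) on shared IDs
#'
#' Restricts every layer to the intersection of gene IDs and sample IDs,
#' in lexicographic order (so alignment is reproducible and idempotent),
#' and reports the IDs dropped from each layer. Matching is on the ID
#' strings as provided.
#'
#' @param layers Named list of gene-by-sample matrices (at least two).
#' @param clinical Optional clinical data.frame with a `sample_id` column;
#'   its samples join the intersection.
#' @return A list with elements `layers` (aligned matrices), `clinical`
#'   (aligned or NULL), `genes`, `samples` and `dropped` (per-layer lists of
#'   dropped gene/sample IDs).
#' @export
align_layers <- function(layers, clinical = NULL) {
  if (!is.list(layers) || length(layers) < 2L) {
    gd_stop("gdtec_config_error", "align_layers needs at least two layers")
  }
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    names(layers) <- paste0("layer", seq_along(layers))
  }
  for (nm in names(layers)) gd_assert_matrix(layers[[nm]], nm)
  genes <- sort(Reduce(intersect, lapply(layers, rownames)))
  samples <- Reduce(intersect, lapply(layers, colnames))
  if (!is.null(clinical)) samples <- intersect(samples, clinical$sample_id)
  samples <- sort(samples)
  if (length(genes) == 0L || length(samples) == 0L) {
    gd_stop("gdtec_alignment_error",
            "empty gene or sample intersection across layers")
  }
  dropped <- lapply(layers, function(m) {
    list(genes = setdiff(rownames(m), genes),
         samples = setdiff(colnames(m), samples))
  })
  aligned <- lapply(layers, function(m) m[genes, samples, drop = FALSE])
  clin <- NULL
  if (!is.null(clinical)) {
    clin <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
    rownames(clin) <- NULL
    dropped$clinical <- list(samples = setdiff(clinical$sample_id, samples))
  }
  list(layers = aligned, clinical = clin, genes = genes, samples = samples,
       dropped = dropped)
}
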
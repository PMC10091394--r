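#' @name synthetic
#' @title Synthetic multi-omics cohorts with planted structure
#' @description Generates aligned mutation, copy-number, tumor-expression and
#'   normal-expression layers plus a clinical table, with known subtype
#'   labels, driven-gene signatures and survival effects, so that every
#'   pipeline stage can be tested end to end without external cohorts.
NULL

#' Specification of a synthetic cohort
#'
#' Defaults describe the reference study conditions used throughout the
#' package's tests: 200 tumor samples, 80 genes, 4 equally sized subtypes,
#' in-signature event probability 0.8 against a 0.05 background, an even
#' copy-number/mutation mechanism mix, |LFC| effect 2 with log2-scale noise
#' sd 0.3, and 20 percent censoring.
#'
#' By default the driven-gene signature is organized in pair blocks: each
#' block of genes is driven in a *pair* of subtypes, every subtype owning a
#' unique combination of blocks. This emulates signature sharing across
#' subtypes seen in real fused matrices and keeps the expected per-gene
#' zero fraction (about 0.58 under the defaults) below the pipeline's 60
#' percent sparsity cutoff; a one-subtype-per-gene design would push every
#' driven gene past the cutoff and leave nothing to cluster.
#'
#' @param n_samples,n_genes,n_subtypes Cohort dimensions.
#' @param subtype_proportions Simplex vector of subtype sizes.
#' @param driven_gene_sets Optional list (one element per subtype) of gene
#'   indices driven in that subtype; NULL builds the default pair-block
#'   design.
#' @param p_driven_in,p_driven_out Event probability for a driven gene in
#'   its subtype(s) versus background (must satisfy in > out).
#' @param cnv_vs_snv_mix Probability a planted event is copy-number-type
#'   rather than mutation-type.
#' @param lfc_effect Mean |log2 fold change| of a planted event.
#' @param expression_noise_sd Log2-scale expression noise sd.
#' @param baseline_log_hazard Per-subtype log hazard (events/day) of the
#'   exponential survival baseline.
#' @param gene_log_hazard Named vector of per-gene log-hazard effects,
#'   applied when the sample carries a planted event in that gene; NULL
#'   plants effects 0.7 and 0.5 on the first two genes of the last
#'   signature block.
#' @param censoring_rate Target censoring fraction in \[0, 1), achieved
#'   exactly in expectation by per-sample exponential censoring with rate
#'   `censoring_rate/(1 - censoring_rate)` times the sample's event rate.
#' @param n_normals Number of normal expression samples.
#' @param allow_cooccurrence Plant copy-number and mutation events in the
#'   same cell (default FALSE: mutually exclusive, so the fusion's
#'   exclusive-or loses no planted event in the noiseless limit).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_samples = 200, n_genes = 80, n_subtypes = 4,
                           subtype_proportions = rep(1 / n_subtypes, n_subtypes),
                           driven_gene_sets = NULL,
                           p_driven_in = 0.8, p_driven_out = 0.05,
                           cnv_vs_snv_mix = 0.5, lfc_effect = 2,
                           expression_noise_sd = 0.3,
                           baseline_log_hazard = seq(-7.6, -6.4,
                                                     length.out = n_subtypes),
                           gene_log_hazard = NULL,
                           censoring_rate = 0.2, n_normals = 20,
                           allow_cooccurrence = FALSE, seed = 1L) {
  if (n_subtypes < 2L) gd_stop("gdtec_spec_error", "need >= 2 subtypes")
  if (abs(sum(subtype_proportions) - 1) > 1e-8 || any(subtype_proportions <= 0)) {
    gd_stop("gdtec_spec_error", "subtype proportions must be positive and sum to 1")
  }
  probs <- c(p_driven_in, p_driven_out, cnv_vs_snv_mix)
  if (any(probs < 0 | probs > 1)) {
    gd_stop("gdtec_spec_error", "probabilities must lie in [0, 1]")
  }
  if (!(p_driven_in > p_driven_out)) {
    gd_stop("gdtec_spec_error", "p_driven_in must exceed p_driven_out")
  }
  if (censoring_rate < 0 || censoring_rate >= 1) {
    gd_stop("gdtec_spec_error", "censoring_rate must be in [0, 1)")
  }
  if (length(baseline_log_hazard) != n_subtypes) {
    gd_stop("gdtec_spec_error", "one baseline log hazard per subtype required")
  }
  blocks <- NULL
  if (is.null(driven_gene_sets)) {
    pairs <- utils::combn(n_subtypes, 2)
    n_blocks <- ncol(pairs)
    block_size <- floor(0.9 * n_genes / n_blocks)
    if (block_size < 1L) {
      gd_stop("gdtec_spec_error",
              "too few genes (%d) for %d signature blocks", n_genes, n_blocks)
    }
    blocks <- lapply(seq_len(n_blocks), function(b) {
      ((b - 1) * block_size + 1):(b * block_size)
    })
    driven_gene_sets <- lapply(seq_len(n_subtypes), function(t) {
      sort(unlist(blocks[which(pairs[1, ] == t | pairs[2, ] == t)]))
    })
  }
  if (length(driven_gene_sets) != n_subtypes ||
      any(unlist(driven_gene_sets) > n_genes) ||
      any(unlist(driven_gene_sets) < 1)) {
    gd_stop("gdtec_spec_error", "driven gene sets must index 1..n_genes, one set per subtype")
  }
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  if (is.null(gene_log_hazard)) {
    risk_genes <- if (!is.null(blocks)) {
      gene_ids[blocks[[length(blocks)]][1:2]]
    } else {
      gene_ids[driven_gene_sets[[n_subtypes]][1:2]]
    }
    gene_log_hazard <- setNames(c(0.7, 0.5), risk_genes)
  }
  if (!all(names(gene_log_hazard) %in% gene_ids)) {
    gd_stop("gdtec_spec_error", "gene_log_hazard names must be cohort gene IDs")
  }
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_subtypes = n_subtypes,
                 subtype_proportions = subtype_proportions,
                 driven_gene_sets = driven_gene_sets,
                 p_driven_in = p_driven_in, p_driven_out = p_driven_out,
                 cnv_vs_snv_mix = cnv_vs_snv_mix, lfc_effect = lfc_effect,
                 expression_noise_sd = expression_noise_sd,
                 baseline_log_hazard = baseline_log_hazard,
                 gene_log_hazard = gene_log_hazard,
                 censoring_rate = censoring_rate, n_normals = n_normals,
                 allow_cooccurrence = allow_cooccurrence,
                 seed = as.integer(seed), gene_ids = gene_ids),
            class = "synthetic_spec")
}

#' Generate a synthetic multi-omics cohort
#'
#' For each sample of subtype t and gene g, a driven event is planted with
#' probability `p_driven_in` (g in t's signature) or `p_driven_out`
#' (background). An event is copy-number-type (concordant +-2 call and
#' expression shift of +-`lfc_effect`) or mutation-type (mutation flag and
#' a shift of random sign) per `cnv_vs_snv_mix`, never both unless
#' co-occurrence is enabled. Tumor expression is
#' `baseline * 2^(shift + noise)` over a shared per-gene lognormal
#' baseline; normals carry noise only. Survival is exponential with log
#' hazard `baseline_log_hazard[subtype] + sum(gene effects * event
#' indicators)`, censored independently at the target rate.
#'
#' @param spec A [synthetic_spec()] object.
#' @return An object of class `"synthetic_cohort"`: binary `mutation`,
#'   integer `cnv_calls`, real `expr_tumor` and `expr_normal` matrices, a
#'   `clinical` data.frame (`sample_id`, `os_time`, `os_event`), and
#'   `truth` (subtype labels, driven gene sets by ID, the planted event
#'   matrix, per-sample log hazards).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    gd_stop("gdtec_spec_error", "generate_cohort expects a synthetic_spec")
  }
  n <- spec$n_samples; g <- spec$n_genes
  gene_ids <- spec$gene_ids
  sample_ids <- sprintf("S%03d", seq_len(n))
  normal_ids <- sprintf("N%03d", seq_len(spec$n_normals))
  with_seed(spec$seed, {
    counts <- diff(round(cumsum(c(0, spec$subtype_proportions)) * n))
    counts[spec$n_subtypes] <- n - sum(counts[-spec$n_subtypes])
    subtype <- sample(rep(seq_len(spec$n_subtypes), counts))
    p_mat <- matrix(spec$p_driven_out, g, n)
    for (t in seq_len(spec$n_subtypes)) {
      p_mat[spec$driven_gene_sets[[t]], subtype == t] <- spec$p_driven_in
    }
    events <- matrix(runif(g * n) < p_mat, g, n)
    is_cnv <- matrix(runif(g * n) < spec$cnv_vs_snv_mix, g, n) & events
    is_snv <- events & !is_cnv
    if (spec$allow_cooccurrence) {
      both <- events & matrix(runif(g * n) < 0.25, g, n)
      is_cnv <- is_cnv | both
      is_snv <- is_snv | both
    }
    ev_sign <- matrix(sample(c(-1, 1), g * n, replace = TRUE), g, n)
    cnv_calls <- ifelse(is_cnv, 2 * ev_sign, 0)
    mutation <- 1 * is_snv
    shift <- ifelse(events, spec$lfc_effect * ev_sign, 0)
    baseline <- exp(rnorm(g, mean = 5, sd = 1))
    noise_t <- matrix(rnorm(g * n, sd = spec$expression_noise_sd), g, n)
    expr_tumor <- baseline * 2^(shift + noise_t)
    noise_n <- matrix(rnorm(g * spec$n_normals, sd = spec$expression_noise_sd),
                      g, spec$n_normals)
    expr_normal <- baseline * 2^noise_n
    eff <- rep(0, g)
    eff[match(names(spec$gene_log_hazard), gene_ids)] <- spec$gene_log_hazard
    log_hazard <- spec$baseline_log_hazard[subtype] +
      as.numeric(crossprod(events, eff))
    lambda <- exp(log_hazard)
    t_event <- rexp(n, rate = lambda)
    if (spec$censoring_rate > 0) {
      mu <- spec$censoring_rate / (1 - spec$censoring_rate) * lambda
      t_cens <- rexp(n, rate = mu)
    } else {
      t_cens <- rep(Inf, n)
    }
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)
    dimnames(cnv_calls) <- dimnames(mutation) <- dimnames(expr_tumor) <-
      list(gene_ids, sample_ids)
    dimnames(expr_normal) <- list(gene_ids, normal_ids)
    storage.mode(events) <- "double"
    dimnames(events) <- list(gene_ids, sample_ids)
    structure(list(
      mutation = mutation, cnv_calls = cnv_calls,
      expr_tumor = expr_tumor, expr_normal = expr_normal,
      clinical = data.frame(sample_id = sample_ids, os_time = os_time,
                            os_event = os_event, stringsAsFactors = FALSE),
      truth = list(
        subtype = setNames(subtype, sample_ids),
        driven_gene_sets = lapply(spec$driven_gene_sets, function(i) gene_ids[i]),
        events = events,
        gene_log_hazard = spec$gene_log_hazard,
        log_hazard = setNames(log_hazard, sample_ids)),
      spec = spec), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes x %d tumors (%d normals), %d subtypes, seed %d\n",
              x$spec$n_genes, x$spec$n_samples, x$spec$n_normals,
              x$spec$n_subtypes, x$spec$seed))
  cat(sprintf("events planted: %d cells (%.1f%%); censoring %.0f%% target, %.0f%% realized\n",
              sum(x$truth$events), 100 * mean(x$truth$events),
              100 * x$spec$censoring_rate, 100 * mean(1 - x$clinical$os_event)))
  invisible(x)
}

#' Adjusted Rand index of a partition against the planted subtypes
#'
#' @param partition Cluster labels, named by sample ID when not in cohort
#'   order.
#' @param cohort A `"synthetic_cohort"` object.
#' @return The adjusted Rand index (1 = identical up to relabeling,
#'   approximately 0 at chance).
#' @export
truth_ari <- function(partition, cohort) {
  truth <- cohort$truth$subtype
  if (!is.null(names(partition))) {
    if (!setequal(names(partition), names(truth))) {
      gd_stop("gdtec_alignment_error", "partition does not cover the cohort samples")
    }
    partition <- partition[names(truth)]
  } else if (length(partition) != length(truth)) {
    gd_stop("gdtec_alignment_error", "partition length differs from cohort size")
  }
  mclust::adjustedRandIndex(as.vector(partition), as.vector(truth))
}

#' Write a cohort's five input files plus ground truth to a directory
#'
#' Emits exactly the formats the readers consume: a long-format mutation
#' TSV, three matrix TSVs, a clinical TSV and a `truth.json` sidecar.
#'
#' @param cohort A `"synthetic_cohort"` object.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  muts <- which(cohort$mutation == 1, arr.ind = TRUE)
  mut_tab <- data.frame(
    sample_id = colnames(cohort$mutation)[muts[, 2]],
    gene_id = rownames(cohort$mutation)[muts[, 1]],
    variant_classification = "Missense_Mutation",
    stringsAsFactors = FALSE)
  mut_tab <- mut_tab[order(mut_tab$sample_id, mut_tab$gene_id), , drop = FALSE]
  paths <- c(snv = file.path(dir, "mutations.tsv"),
             cnv = file.path(dir, "cnv_calls.tsv"),
             expr_tumor = file.path(dir, "expr_tumor.tsv"),
             expr_normal = file.path(dir, "expr_normal.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.json"))
  write_mutation_table(mut_tab, paths[["snv"]], format = "long")
  write_matrix(cohort$cnv_calls, paths[["cnv"]])
  write_matrix(cohort$expr_tumor, paths[["expr_tumor"]])
  write_matrix(cohort$expr_normal, paths[["expr_normal"]])
  write.table(cohort$clinical, paths[["clinical"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(subtype = as.list(cohort$truth$subtype),
         driven_gene_sets = cohort$truth$driven_gene_sets,
         gene_log_hazard = as.list(cohort$truth$gene_log_hazard)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
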
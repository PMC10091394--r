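#' @name consensus
#' @title Resampling consensus clustering and robustness metrics
#' @description Subsampling-based consensus clustering of a gene-by-sample
#'   matrix: each repetition subsamples the patients, clusters the subsample
#'   at every k with the configured base method and distance, and
#'   accumulates, for every sample pair, the fraction of co-sampled runs in
#'   which the pair co-clustered. The empirical CDFs of the per-k consensus
#'   values and their delta-area curve drive k selection at the inflection
#'   point. Overlap metrics compare partitions (optimal-matching accuracy)
#'   and binary matrices (Jaccard on 1-cells), and a robustness battery
#'   sweeps LFC thresholds, scoring schemes and clustering configurations.
NULL

.gd_methods <- c("pam", "kmeans", "hclust-average", "hclust-complete", "hclust-ward")
.gd_distances <- c("binary", "euclidean", "manhattan", "pearson")

# Sample-by-sample distance over rows of xt (samples x genes). "binary" is
# the asymmetric binary (Jaccard) distance of stats::dist, matching the
# conventional meaning of a binary distance in clustering stacks.
.gd_dist <- function(xt, distance) {
  d <- switch(distance,
    binary = dist(xt, method = "binary"),
    euclidean = dist(xt, method = "euclidean"),
    manhattan = dist(xt, method = "manhattan"),
    pearson = as.dist(1 - suppressWarnings(cor(t(xt)))))
  d[is.na(d)] <- 2  # constant rows under pearson: maximal dissimilarity
  d
}

.hclust_method <- function(method) {
  switch(method, "hclust-average" = "average", "hclust-complete" = "complete",
         "hclust-ward" = "ward.D2")
}

# Cluster one subsample at every k. Returns a named list of integer label
# vectors, or signals an error (caller retries the repetition).
.cluster_all_k <- function(xt, k_range, method, distance) {
  out <- vector("list", length(k_range))
  if (method == "kmeans") {
    for (i in seq_along(k_range)) {
      out[[i]] <- kmeans(xt, centers = k_range[i], nstart = 3,
                         iter.max = 50)$cluster
    }
  } else {
    d <- .gd_dist(xt, distance)
    if (startsWith(method, "hclust")) {
      tree <- hclust(d, method = .hclust_method(method))
      for (i in seq_along(k_range)) out[[i]] <- cutree(tree, k_range[i])
    } else {
      for (i in seq_along(k_range)) {
        out[[i]] <- cluster::pam(d, k_range[i], cluster.only = TRUE,
                                 pamonce = 5)
      }
    }
  }
  out
}

# Area under the empirical CDF of consensus values on [0, 1].
.ecdf_area <- function(v) {
  if (length(v) == 0L) return(0)
  s <- sort(v)
  sum(diff(c(s, 1)) * seq_along(s) / length(s))
}

#' Consensus clustering of samples by resampling
#'
#' @param x Numeric gene-by-sample matrix; the columns (samples) are
#'   clustered.
#' @param k_range Integer vector of cluster numbers to evaluate (default
#'   2..10; at least three values are needed for k selection).
#' @param reps Number of subsampling repetitions (default 1000).
#' @param subsample_fraction Fraction of samples drawn (without
#'   replacement) per repetition (default 0.8).
#' @param method Base clustering method: `"pam"` (default), `"kmeans"`,
#'   `"hclust-average"`, `"hclust-complete"` or `"hclust-ward"`.
#' @param distance `"binary"` (Jaccard; the default, matching pam-binary),
#'   `"euclidean"`, `"manhattan"` or `"pearson"` (1 - correlation).
#'   `kmeans` admits only `"euclidean"`.
#' @param seed Master seed; repetition r reseeds deterministically at
#'   `seed + r` (a counter scheme), so runs are bit-reproducible.
#' @param elbow_threshold Relative delta-area cutoff for k selection
#'   (default 0.1); see [select_k()].
#' @param final_method Clustering of `1 - consensus` that yields the final
#'   partition at the chosen k: `"hclust"` (average linkage, default) or
#'   `"pam"`.
#' @return An object of class `"consensus_run"`: per-k consensus matrices
#'   (symmetric, unit diagonal, entries in \[0, 1\]), the CDF areas and
#'   delta-area curve, `chosen_k`, the named `partition` at `chosen_k`, all
#'   per-k partitions (`partitions`), and the configuration.
#' @export
consensus_cluster <- function(x, k_range = 2:10, reps = 1000,
                              subsample_fraction = 0.8,
                              method = "pam", distance = "binary",
                              seed = 1L, elbow_threshold = 0.1,
                              final_method = c("hclust", "pam")) {
  method <- match.arg(method, .gd_methods)
  distance <- match.arg(distance, .gd_distances)
  final_method <- match.arg(final_method)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("S", seq_len(ncol(x)))
  n <- ncol(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 1L || min(k_range) < 2L || max(k_range) > n - 1L) {
    gd_stop("gdtec_config_error",
            "k_range must lie within [2, %d] for %d samples", n - 1L, n)
  }
  if (reps < 1L) gd_stop("gdtec_config_error", "reps must be >= 1")
  if (!(subsample_fraction > 0 && subsample_fraction <= 1)) {
    gd_stop("gdtec_config_error", "subsample_fraction must be in (0, 1]")
  }
  if (method == "kmeans" && distance != "euclidean") {
    gd_stop("gdtec_config_error", "kmeans admits only the euclidean distance")
  }
  m <- max(2L, as.integer(floor(subsample_fraction * n)))
  if (m <= max(k_range)) {
    gd_stop("gdtec_config_error",
            "subsample size %d cannot support k = %d", m, max(k_range))
  }
  xt <- t(x)
  conn <- lapply(k_range, function(k) matrix(0, n, n))
  samp <- matrix(0, n, n)
  seed <- as.integer(seed) %% 100000000L
  for (r in seq_len(reps)) {
    labs <- NULL
    for (attempt in 0:4) {
      set.seed(seed + r + attempt * 1000003L)
      idx <- sort(sample.int(n, m))
      labs <- tryCatch(
        .cluster_all_k(xt[idx, , drop = FALSE], k_range, method, distance),
        error = function(e) NULL)
      if (!is.null(labs)) break
      warning(sprintf("repetition %d retried: degenerate subsample", r))
    }
    if (is.null(labs)) next
    samp[idx, idx] <- samp[idx, idx] + 1
    for (i in seq_along(k_range)) {
      co <- outer(labs[[i]], labs[[i]], "==")
      conn[[i]][idx, idx] <- conn[[i]][idx, idx] + co
    }
  }
  consensus <- lapply(conn, function(M) {
    C <- matrix(0, n, n)
    pos <- samp > 0
    C[pos] <- M[pos] / samp[pos]
    diag(C) <- 1
    dimnames(C) <- list(colnames(x), colnames(x))
    C
  })
  names(consensus) <- as.character(k_range)
  areas <- vapply(consensus, function(C) .ecdf_area(C[upper.tri(C)]), numeric(1))
  rel <- numeric(length(areas))
  rel[1] <- areas[1]
  if (length(areas) > 1) {
    for (i in 2:length(areas)) {
      rel[i] <- if (areas[i - 1] > 0) (areas[i] - areas[i - 1]) / areas[i - 1]
                else areas[i]
    }
  }
  rel <- pmax(rel, 0)
  delta_area <- data.frame(k = k_range, area = unname(areas), rel_delta = rel)
  run <- structure(list(consensus = consensus, k_range = k_range,
                        delta_area = delta_area,
                        config = list(method = method, distance = distance,
                                      reps = reps,
                                      subsample_fraction = subsample_fraction,
                                      seed = seed,
                                      elbow_threshold = elbow_threshold,
                                      final_method = final_method)),
                   class = "consensus_run")
  run$chosen_k <- select_k(run)
  run$partitions <- lapply(seq_along(k_range), function(i) {
    .partition_from_consensus(consensus[[i]], k_range[i], final_method)
  })
  names(run$partitions) <- as.character(k_range)
  run$partition <- run$partitions[[as.character(run$chosen_k)]]
  run
}

.partition_from_consensus <- function(C, k, final_method) {
  d <- as.dist(1 - C)
  labels <- if (final_method == "pam") {
    cluster::pam(d, k, cluster.only = TRUE, pamonce = 5)
  } else {
    cutree(hclust(d, method = "average"), k)
  }
  setNames(as.integer(labels), rownames(C))
}

#' Select the number of clusters at the delta-area inflection
#'
#' Computes the relative increase in the area under the consensus-value CDF
#' as k grows and locates the inflection: the point past which the relative
#' delta-area collapses. Among the candidate values whose relative
#' delta-area exceeds the elbow threshold, the chosen k is the one with the
#' largest drop ratio `rel_delta(k) / rel_delta(k + 1)` (larger ties win).
#' The drop ratio separates a true inflection from the small, roughly
#' constant area gains that forced extra splits produce at every k, which a
#' plain cutoff on the gain itself does not do reliably. A flat curve (no k
#' above the threshold) returns the smallest k with attribute
#' `degenerate = TRUE`.
#'
#' @param run A `"consensus_run"` object.
#' @param elbow_threshold Override of the run's configured threshold.
#' @return Integer k.
#' @export
select_k <- function(run, elbow_threshold = NULL) {
  if (!inherits(run, "consensus_run")) {
    gd_stop("gdtec_config_error", "select_k expects a consensus_run")
  }
  if (length(run$k_range) < 3L) {
    gd_stop("gdtec_config_error", "k selection needs >= 3 evaluated values of k")
  }
  thr <- elbow_threshold %||% run$config$elbow_threshold
  rel <- run$delta_area$rel_delta
  if (all(rel <= thr)) {
    k <- min(run$k_range)
    attr(k, "degenerate") <- TRUE
    return(k)
  }
  # Candidate inflection points: gains that are non-negligible relative to
  # the curve's largest gain (an absolute cutoff would miss true k when its
  # gain sits just under it, and keep artifact gains just over it).
  cand <- which(rel > thr * max(rel))
  eps <- 1e-9
  ratio <- rel / pmax(c(rel[-1], eps), eps)  # drop ratio toward the next k
  ratio[length(ratio)] <- 0                  # the largest k has no successor
  scored <- ratio[cand] + seq_along(cand) * eps  # larger k wins exact ties
  best <- if (all(ratio[cand] <= 0)) max(cand) else cand[which.max(scored)]
  run$k_range[best]
}

#' @export
print.consensus_run <- function(x, ...) {
  cat(sprintf("Consensus clustering (%s/%s, %d reps, %.0f%% subsampling)\n",
              x$config$method, x$config$distance, x$config$reps,
              100 * x$config$subsample_fraction))
  cat(sprintf("k evaluated: %s; chosen k = %d\n",
              paste(x$k_range, collapse = ", "), x$chosen_k))
  cat("cluster sizes at chosen k:\n")
  print(table(x$partition))
  invisible(x)
}

#' @export
summary.consensus_run <- function(object, ...) {
  cat(sprintf("chosen k = %d (elbow threshold %.2f)\n",
              object$chosen_k, object$config$elbow_threshold))
  print(object$delta_area, row.names = FALSE)
  invisible(object$delta_area)
}

#' @export
plot.consensus_run <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  grid <- seq(0, 1, length.out = 101)
  first <- TRUE
  for (i in seq_along(x$k_range)) {
    v <- x$consensus[[i]][upper.tri(x$consensus[[i]])]
    cdf <- vapply(grid, function(t) mean(v <= t), numeric(1))
    if (first) {
      plot(grid, cdf, type = "l", col = i, xlab = "consensus index",
           ylab = "CDF", main = "Consensus CDFs", ylim = c(0, 1))
      first <- FALSE
    } else lines(grid, cdf, col = i)
  }
  legend("bottomright", legend = paste0("k=", x$k_range),
         col = seq_along(x$k_range), lty = 1, cex = 0.8)
  plot(x$delta_area$k, x$delta_area$rel_delta, type = "b",
       xlab = "k", ylab = "relative delta area", main = "Delta-area curve")
  abline(h = x$config$elbow_threshold, lty = 2)
  invisible(x)
}

#' Overlap ratio between two partitions of the same samples
#'
#' The maximum fraction of samples placed in matched clusters over all
#' one-to-one matchings of the cluster labels (the assignment-problem
#' optimum on the contingency table). Symmetric, invariant to label
#' permutation, equal to 1 exactly when the partitions coincide up to
#' relabeling, and bounded below by the largest cluster fraction.
#'
#' @param p1,p2 Label vectors over the same samples; when both are named
#'   they are aligned by name.
#' @return A number in \[0, 1\].
#' @export
partition_overlap <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) {
      gd_stop("gdtec_alignment_error", "partitions cover different sample sets")
    }
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    gd_stop("gdtec_alignment_error", "partitions have different lengths")
  }
  n <- length(p1)
  C <- table(as.character(p1), as.character(p2))
  assignment_max(C) / n
}

#' Jaccard overlap of the 1-cells of two binary matrices
#'
#' `|both 1| / |either 1|`, defined as 1 when both matrices are all zero
#' (identical emptiness). The informative GDTEC events are the 1s, so
#' simple matching (dominated by shared 0s) is deliberately not used.
#'
#' @param m1,m2 Binary matrices of identical shape.
#' @return A number in \[0, 1\].
#' @export
matrix_overlap <- function(m1, m2) {
  if (!identical(dim(m1), dim(m2))) {
    gd_stop("gdtec_alignment_error", "matrices differ in shape")
  }
  both <- sum(m1 == 1 & m2 == 1)
  either <- sum(m1 == 1 | m2 == 1)
  if (either == 0) return(1)
  both / either
}

#' Robustness battery: LFC thresholds, scoring schemes, clustering grid
#'
#' Rebuilds the (unfiltered) fused matrix for every LFC threshold band and
#' every multi-level scoring scheme, fills the matrix-overlap table across
#' those variants, reruns consensus clustering of the reference GDTEC
#' matrix (first threshold, sparsity-filtered) under every clustering
#' configuration, fills the pairwise partition-overlap table, and reports
#' the fraction of configuration pairs whose overlap reaches
#' `overlap_cutoff`.
#'
#' A multi-level scheme enters the fusion through the sign of its scores
#' (the fusion arithmetic is defined on ternary input); its clustering
#' input carries the score magnitude on driven cells.
#'
#' @param post_snv Binary mutation layer.
#' @param post_cnv Ternary copy-number layer.
#' @param lfc Real log2-fold-change matrix (from [compute_lfc()]).
#' @param lfc_thresholds List of `c(low, high)` bands (default just
#'   `c(-1, 1)`).
#' @param multilevel_bands Optional list of band vectors for
#'   [discretize_lfc_multilevel()] variants.
#' @param configs List of `list(method=, distance=)` clustering
#'   configurations; defaults to the full valid method-by-distance grid.
#' @param k_range,reps,subsample_fraction,seed Consensus parameters
#'   (smaller `reps` default than [consensus_cluster()] because the battery
#'   multiplies runs).
#' @param max_zero_fraction Sparsity filter for the reference matrix.
#' @param overlap_cutoff Agreement cutoff summarized over configuration
#'   pairs (default 0.8).
#' @param compare_k Force a common k when comparing partitions; by default
#'   each run's chosen k is used.
#' @return An object of class `"robustness_report"` with `matrix_overlap`
#'   and `partition_overlap` tables, per-config chosen k, and
#'   `summary_fraction`.
#' @export
robustness_battery <- function(post_snv, post_cnv, lfc,
                               lfc_thresholds = list(c(-1, 1)),
                               multilevel_bands = NULL,
                               configs = NULL,
                               k_range = 2:6, reps = 100,
                               subsample_fraction = 0.8, seed = 1L,
                               max_zero_fraction = 0.6,
                               overlap_cutoff = 0.8, compare_k = NULL) {
  if (is.null(configs)) {
    configs <- list()
    for (mth in .gd_methods) for (dst in .gd_distances) {
      if (mth == "kmeans" && dst != "euclidean") next
      configs[[length(configs) + 1L]] <- list(method = mth, distance = dst)
    }
  }
  if (length(lfc_thresholds) + length(multilevel_bands) < 2L &&
      length(configs) < 2L) {
    gd_stop("gdtec_config_error",
            "battery needs >= 2 thresholds/schemes or >= 2 configurations")
  }
  variants <- list()
  for (t in lfc_thresholds) {
    rna <- discretize_lfc(lfc, t[1], t[2])
    fused <- fuse_gdtec(cnv_rna_consistency(post_cnv, rna),
                        snv_rna_consistency(post_snv, absolutize(rna)))
    variants[[sprintf("lfc(%g,%g)", t[1], t[2])]] <- fused
  }
  for (b in multilevel_bands) {
    scored <- discretize_lfc_multilevel(lfc, b)
    rna <- sign(scored)
    fused <- fuse_gdtec(cnv_rna_consistency(post_cnv, rna),
                        snv_rna_consistency(post_snv, absolutize(rna)))
    variants[[sprintf("ml(%s)", paste(b, collapse = ","))]] <- fused * abs(scored)
  }
  nv <- length(variants)
  mo <- matrix(1, nv, nv, dimnames = list(names(variants), names(variants)))
  if (nv > 1) {
    for (i in 1:(nv - 1)) for (j in (i + 1):nv) {
      mo[i, j] <- mo[j, i] <- matrix_overlap(1 * (variants[[i]] != 0),
                                             1 * (variants[[j]] != 0))
    }
  }
  ref <- filter_sparse_genes(1 * (variants[[1]] != 0), max_zero_fraction)$matrix
  if (nrow(ref) == 0L) {
    gd_stop("gdtec_degenerate_error", "sparsity filter removed every gene")
  }
  runs <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    runs[[i]] <- consensus_cluster(ref, k_range = k_range, reps = reps,
                                   subsample_fraction = subsample_fraction,
                                   method = cfg$method, distance = cfg$distance,
                                   seed = seed + i)
  }
  cfg_names <- vapply(configs, function(cfg)
    paste(cfg$method, cfg$distance, sep = "/"), character(1))
  parts <- lapply(runs, function(r) {
    if (is.null(compare_k)) r$partition
    else r$partitions[[as.character(compare_k)]]
  })
  nc <- length(configs)
  po <- matrix(1, nc, nc, dimnames = list(cfg_names, cfg_names))
  if (nc > 1) {
    for (i in 1:(nc - 1)) for (j in (i + 1):nc) {
      po[i, j] <- po[j, i] <- partition_overlap(parts[[i]], parts[[j]])
    }
  }
  pair_vals <- po[upper.tri(po)]
  summary_fraction <- if (length(pair_vals)) mean(pair_vals >= overlap_cutoff) else 1
  structure(list(matrix_overlap = mo, partition_overlap = po,
                 chosen_k = setNames(vapply(runs, function(r) as.integer(r$chosen_k),
                                            integer(1)), cfg_names),
                 summary_fraction = summary_fraction,
                 overlap_cutoff = overlap_cutoff,
                 configs = cfg_names, variants = names(variants)),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("Robustness battery: %d matrix variants, %d clustering configurations\n",
              length(x$variants), length(x$configs)))
  cat(sprintf("%.1f%% of configuration pairs reach partition overlap >= %.2f\n",
              100 * x$summary_fraction, x$overlap_cutoff))
  cat("chosen k per configuration:\n")
  print(x$chosen_k)
  invisible(x)
}
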
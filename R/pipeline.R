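#' @name pipeline
#' @title Pipeline orchestration
#' @description Runs the full method from one configuration: obtain inputs
#'   (simulation or files), build the discretized layers, fuse them into the
#'   GDTEC matrix, cluster, model survival on fused features of the
#'   worst-prognosis cluster, and train a subtype classifier. Every stage's
#'   outputs land under one run directory with fixed names, together with a
#'   JSON manifest; one master seed fans out to per-stage seeds by a fixed
#'   counter, so reruns are byte-identical.
NULL

.default_config <- function() {
  list(
    simulate = TRUE,
    sim = list(),             # overrides forwarded to synthetic_spec()
    inputs = NULL,            # list(snv=, snv_format=, cnv=, expr_tumor=, expr_normal=, clinical=)
    output_dir = NULL,
    seed = 1L,
    pseudocount = 1,
    lfc_low = -1, lfc_high = 1,
    cnv_mode = "sign",
    nonsilent_only = TRUE,
    max_zero_fraction = 0.6,
    cluster = list(method = "pam", distance = "binary", k_min = 2L, k_max = 6L,
                   reps = 250L, subsample_fraction = 0.8, elbow_threshold = 0.1),
    survival = list(max_features = 2L, hi = 0.7, lo = 0.3),
    classifier = list(train_fraction = 0.7, ntree = 500L)
  )
}

.merge_config <- function(config) {
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    gd_stop("gdtec_config_error", "unknown configuration key(s): %s",
            paste(unknown, collapse = ", "))
  }
  for (nm in c("cluster", "survival", "classifier", "inputs")) {
    bad <- setdiff(names(config[[nm]]),
                   names(defaults[[nm]]) %||%
                     c("snv", "snv_format", "cnv", "expr_tumor",
                       "expr_normal", "clinical"))
    if (length(bad)) {
      gd_stop("gdtec_config_error", "unknown key(s) under '%s': %s",
              nm, paste(bad, collapse = ", "))
    }
  }
  modifyList(defaults, config)
}

.validate_config <- function(cfg) {
  if (is.null(cfg$output_dir)) gd_stop("gdtec_config_error", "output_dir is required")
  if (is.null(cfg$seed)) gd_stop("gdtec_config_error", "seed is required")
  if (!(cfg$lfc_low < cfg$lfc_high)) {
    gd_stop("gdtec_config_error", "lfc_low must be < lfc_high")
  }
  if (cfg$cluster$k_min < 2L || cfg$cluster$k_max < cfg$cluster$k_min) {
    gd_stop("gdtec_config_error", "invalid cluster k range")
  }
  if (!isTRUE(cfg$simulate)) {
    need <- c("snv", "cnv", "expr_tumor", "expr_normal", "clinical")
    missing_in <- setdiff(need, names(cfg$inputs))
    if (length(missing_in)) {
      gd_stop("gdtec_config_error", "inputs missing: %s",
              paste(missing_in, collapse = ", "))
    }
    for (p in unlist(cfg$inputs[need])) {
      if (!file.exists(p)) gd_stop("gdtec_config_error", "input file not found: %s", p)
    }
  }
  n <- if (isTRUE(cfg$simulate)) cfg$sim$n_samples %||% 200L else NULL
  if (!is.null(n) && cfg$cluster$k_max > n - 1L) {
    gd_stop("gdtec_config_error", "cluster k_max exceeds the sample count")
  }
  invisible(cfg)
}

#' Run the full pipeline from one configuration
#'
#' @param config A named list or the path of a YAML file. Recognized keys
#'   (all optional except `output_dir`): `simulate` (default TRUE), `sim`
#'   (overrides for [synthetic_spec()]), `inputs` (file paths: `snv`,
#'   `snv_format`, `cnv`, `expr_tumor`, `expr_normal`, `clinical`), `seed`,
#'   `pseudocount`, `lfc_low`/`lfc_high`, `cnv_mode`, `nonsilent_only`,
#'   `max_zero_fraction`, and sublists `cluster`, `survival`, `classifier`.
#'   Unknown keys are errors.
#' @param output_dir Overrides `config$output_dir`.
#' @return The run manifest (also written as `manifest.json`), invisibly
#'   carrying the in-memory stage results in attribute `"results"`. On a
#'   stage failure the manifest records the failing stage and downstream
#'   stages are skipped.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  .validate_config(cfg)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  manifest <- list(package = "gdtec",
                   version = as.character(utils::packageVersion("gdtec")),
                   seed = seed, parameters = cfg, stages = list())
  results <- list()
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      failed <<- TRUE
    } else {
      manifest$stages[[name]] <<- list(status = "completed",
                                       outputs = res$outputs %||% character(0))
      results[[name]] <<- res
    }
    invisible(NULL)
  }

  run_stage("inputs", function() {
    if (isTRUE(cfg$simulate)) {
      spec <- do.call(synthetic_spec, modifyList(list(seed = seed + 1L), cfg$sim))
      cohort <- generate_cohort(spec)
      paths <- write_cohort(cohort, file.path(out, "inputs"))
      list(cohort = cohort, snv = cohort$mutation,
           cnv_calls = cohort$cnv_calls, expr_tumor = cohort$expr_tumor,
           expr_normal = cohort$expr_normal, clinical = cohort$clinical,
           outputs = unname(paths))
    } else {
      muts <- read_mutation_table(cfg$inputs$snv,
                                  format = cfg$inputs$snv_format %||% "maf")
      cnv <- read_matrix(cfg$inputs$cnv, "integer")
      expr_tumor <- read_matrix(cfg$inputs$expr_tumor, "real")
      expr_normal <- read_matrix(cfg$inputs$expr_normal, "real")
      clinical <- read_clinical_table(cfg$inputs$clinical)
      al <- align_layers(list(cnv = cnv, expr_tumor = expr_tumor),
                         clinical = clinical)
      snv <- binarize_mutations(muts, al$genes, al$samples,
                                nonsilent_only = cfg$nonsilent_only)
      list(snv = snv, cnv_calls = al$layers$cnv,
           expr_tumor = al$layers$expr_tumor,
           expr_normal = expr_normal[intersect(al$genes, rownames(expr_normal)),
                                     , drop = FALSE],
           clinical = al$clinical, outputs = character(0))
    }
  })

  run_stage("preprocess", function() {
    inp <- results$inputs
    lfc <- compute_lfc(inp$expr_tumor, inp$expr_normal,
                       pseudocount = cfg$pseudocount)
    post_rnaseq <- discretize_lfc(lfc, cfg$lfc_low, cfg$lfc_high)
    post_cnv <- collapse_cnv(inp$cnv_calls, mode = cfg$cnv_mode)
    post_snv <- inp$snv
    files <- c(file.path(out, "post_snv.tsv"), file.path(out, "post_cnv.tsv"),
               file.path(out, "post_rnaseq.tsv"),
               file.path(out, "post2_rnaseq.tsv"))
    write_matrix(post_snv, files[1])
    write_matrix(post_cnv, files[2])
    write_matrix(post_rnaseq, files[3])
    write_matrix(absolutize(post_rnaseq), files[4])
    list(lfc = lfc, post_snv = post_snv, post_cnv = post_cnv,
         post_rnaseq = post_rnaseq, outputs = files)
  })

  run_stage("fuse", function() {
    pp <- results$preprocess
    fused <- gdtec(pp$post_snv, pp$post_cnv, pp$post_rnaseq,
                   max_zero_fraction = cfg$max_zero_fraction)
    if (nrow(fused$matrix) == 0L) {
      gd_stop("gdtec_degenerate_error", "sparsity filter removed every gene")
    }
    f <- file.path(out, "gdtec.tsv")
    write_matrix(fused$matrix, f)
    list(fused = fused, outputs = f)
  })

  run_stage("cluster", function() {
    cc <- cfg$cluster
    run <- consensus_cluster(results$fuse$fused$matrix,
                             k_range = cc$k_min:cc$k_max, reps = cc$reps,
                             subsample_fraction = cc$subsample_fraction,
                             method = cc$method, distance = cc$distance,
                             seed = seed + 2L,
                             elbow_threshold = cc$elbow_threshold)
    f1 <- file.path(out, "partition.tsv")
    write.table(data.frame(sample_id = names(run$partition),
                           cluster = as.integer(run$partition)),
                f1, sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- file.path(out, "delta_area.tsv")
    write.table(run$delta_area, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    f3 <- file.path(out, "cluster_summary.json")
    jsonlite::write_json(list(chosen_k = as.integer(run$chosen_k),
                              method = cc$method, distance = cc$distance),
                         f3, auto_unbox = TRUE)
    list(run = run, outputs = c(f1, f2, f3))
  })

  run_stage("survival", function() {
    clin <- results$inputs$clinical
    run <- results$cluster$run
    mat <- results$fuse$fused$matrix
    part <- run$partition[clin$sample_id]
    km <- km_logrank(clin$os_time, clin$os_event, part)
    # worst-prognosis cluster: smallest restricted-mean survival
    rmeans <- summary(km$fit, rmean = max(clin$os_time))$table[, "rmean"]
    worst <- as.integer(sub(".*group=", "", names(which.min(rmeans))))
    groups <- factor(ifelse(part == worst, "worst", "rest"),
                     levels = c("worst", "rest"))
    screen <- screen_gdtec_proportion(mat, groups,
                                      hi = cfg$survival$hi, lo = cfg$survival$lo)
    cand <- screen$gene_id[screen$selected]
    if (length(cand) < 2L) {
      cand <- screen$gene_id[order(-(screen$prop_a - screen$prop_b))]
    }
    cand <- head(cand, max(2L, cfg$survival$max_features))
    uni <- cox_fit(clin$os_time, clin$os_event,
                   as.data.frame(t(mat[cand, clin$sample_id, drop = FALSE])),
                   mode = "univariate")
    top <- uni$table$feature[order(uni$table$p)][seq_len(
      min(cfg$survival$max_features, nrow(uni$table)))]
    multi <- cox_fit(clin$os_time, clin$os_event,
                     as.data.frame(t(mat[top, clin$sample_id, drop = FALSE])),
                     mode = "multivariate")
    risk_groups <- risk_stratify(multi)
    km_risk <- km_logrank(clin$os_time, clin$os_event, risk_groups)
    counts <- count_group(mat[, clin$sample_id, drop = FALSE], top[1:2])
    f1 <- file.path(out, "cox_coefficients.tsv")
    write.table(multi$table, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- file.path(out, "risk_scores.tsv")
    write.table(data.frame(sample_id = names(multi$risk),
                           risk = unname(multi$risk),
                           group = as.character(risk_groups[names(multi$risk)]),
                           gdtec_count = unname(counts[names(multi$risk)])),
                f2, sep = "\t", quote = FALSE, row.names = FALSE)
    f3 <- file.path(out, "survival_summary.json")
    jsonlite::write_json(list(subtype_logrank_p = km$p,
                              risk_logrank_p = km_risk$p,
                              worst_cluster = worst,
                              risk_genes = top),
                         f3, auto_unbox = TRUE, digits = NA)
    list(km = km, worst = worst, cox_uni = uni, cox_multi = multi,
         risk_groups = risk_groups, km_risk = km_risk,
         outputs = c(f1, f2, f3))
  })

  run_stage("classify", function() {
    mat <- results$fuse$fused$matrix
    worst <- results$survival$worst
    part <- results$cluster$run$partition
    labels <- factor(ifelse(part == worst, "Mix_Sub", "non-Mix_Sub"),
                     levels = c("non-Mix_Sub", "Mix_Sub"))
    fit <- train_rf(t(mat), labels,
                    train_fraction = cfg$classifier$train_fraction,
                    ntree = cfg$classifier$ntree, seed = seed + 3L)
    f1 <- file.path(out, "classifier_predictions.tsv")
    write.table(fit$test, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- file.path(out, "classifier_importance.tsv")
    write.table(data.frame(feature = names(fit$importance),
                           mean_decrease_gini = unname(fit$importance)),
                f2, sep = "\t", quote = FALSE, row.names = FALSE)
    list(fit = fit, outputs = c(f1, f2))
  })

  all_outputs <- unlist(lapply(manifest$stages, function(s) s$outputs),
                        use.names = FALSE)
  manifest$digests <- as.list(tools::md5sum(all_outputs[file.exists(all_outputs)]))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  attr(manifest, "results") <- results
  invisible(manifest)
}
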
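#' @name survival_ops
#' @title Survival analysis on fused features
#' @description Kaplan-Meier estimation with log-rank tests across groups,
#'   univariate/multivariate Cox proportional-hazards fits on GDTEC or
#'   expression-derived features, median risk stratification, and the
#'   two-gene event-count grouping.
NULL

#' Kaplan-Meier curves and log-rank test across groups
#'
#' @param time Non-negative survival times (days).
#' @param event Event indicators (1 = death, 0 = censored).
#' @param group Group labels (>= 2 non-empty groups).
#' @return An object of class `"gdtec_km"`: the `survfit` object, the
#'   log-rank chi-square, its degrees of freedom and p-value. With no
#'   events at all the statistic is undefined and the result is flagged
#'   (`flag = "all-censored"`, p = NA).
#' @export
km_logrank <- function(time, event, group) {
  if (any(time < 0) || any(!is.finite(time))) {
    gd_stop("gdtec_domain_error", "survival times must be non-negative and finite")
  }
  if (!all(event %in% c(0, 1))) {
    gd_stop("gdtec_domain_error", "event indicators must be 0 or 1")
  }
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) {
    gd_stop("gdtec_config_error", "log-rank needs >= 2 non-empty groups")
  }
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(Surv(time, event) ~ group, data = df)
  if (sum(event) == 0) {
    return(structure(list(fit = fit, chisq = NA_real_, df = nlevels(group) - 1L,
                          p = NA_real_, flag = "all-censored"),
                     class = "gdtec_km"))
  }
  sd <- survival::survdiff(Surv(time, event) ~ group, data = df)
  p <- pchisq(sd$chisq, df = nlevels(group) - 1L, lower.tail = FALSE)
  structure(list(fit = fit, chisq = unname(sd$chisq),
                 df = nlevels(group) - 1L, p = p, flag = NULL,
                 n = table(group)),
            class = "gdtec_km")
}

#' @export
print.gdtec_km <- function(x, ...) {
  if (!is.null(x$flag)) {
    cat(sprintf("Kaplan-Meier: %s -- log-rank statistic undefined\n", x$flag))
  } else {
    cat(sprintf("Log-rank: chi-square = %.4g on %d df, p = %.4g\n",
                x$chisq, x$df, x$p))
  }
  invisible(x)
}

#' Cox proportional-hazards fit on named features
#'
#' Partial-likelihood maximization with Efron's ties method by default.
#' `mode = "multivariate"` fits all features jointly and records per-sample
#' risk scores (the linear predictor, used for ordering only);
#' `mode = "univariate"` fits each feature separately and reports one row
#' per feature.
#'
#' @param time,event Survival times and event indicators.
#' @param features Data frame or matrix, samples as rows, one column per
#'   covariate (GDTEC indicators, fold changes, ...).
#' @param mode `"multivariate"` (default) or `"univariate"`.
#' @param ties Ties method passed to [survival::coxph()] (default
#'   `"efron"`).
#' @return An object of class `"gdtec_cox"`: a coefficient `table` with
#'   log-hazard, hazard ratio, 95 percent Wald confidence bounds and
#'   p-values; `risk` (multivariate linear predictor, or NULL); flags for
#'   non-convergence or separation.
#' @export
cox_fit <- function(time, event, features, mode = c("multivariate", "univariate"),
                    ties = "efron") {
  mode <- match.arg(mode)
  features <- as.data.frame(features)
  if (is.null(colnames(features))) {
    gd_stop("gdtec_config_error", "features must be named columns")
  }
  if (nrow(features) != length(time)) {
    gd_stop("gdtec_alignment_error", "features and survival data differ in length")
  }
  for (nm in colnames(features)) {
    if (length(unique(features[[nm]])) < 2L) {
      gd_stop("gdtec_degenerate_error", "feature '%s' is constant", nm)
    }
  }
  if (mode == "multivariate" && sum(event) < ncol(features)) {
    gd_stop("gdtec_degenerate_error",
            "fewer events (%d) than covariates (%d)", sum(event), ncol(features))
  }
  fit_one <- function(cols) {
    df <- cbind(data.frame(.time = time, .event = event), features[, cols, drop = FALSE])
    flags <- character(0)
    fit <- withCallingHandlers(
      survival::coxph(Surv(.time, .event) ~ ., data = df, ties = ties,
                      control = survival::coxph.control(iter.max = 50)),
      warning = function(w) {
        flags <<- c(flags, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (any(abs(coef(fit)) > 15)) flags <- c(flags, "possible complete separation")
    s <- summary(fit)
    tab <- data.frame(
      feature = rownames(s$coefficients),
      coef = s$coefficients[, "coef"],
      hr = s$conf.int[, "exp(coef)"],
      hr_lower = s$conf.int[, "lower .95"],
      hr_upper = s$conf.int[, "upper .95"],
      z = s$coefficients[, "z"],
      p = s$coefficients[, "Pr(>|z|)"],
      row.names = NULL, stringsAsFactors = FALSE)
    list(fit = fit, table = tab, flags = flags)
  }
  if (mode == "multivariate") {
    res <- fit_one(colnames(features))
    risk <- unname(res$fit$linear.predictors)
    names(risk) <- rownames(features)
    structure(list(table = res$table, risk = risk, mode = mode, ties = ties,
                   n = length(time), events = sum(event),
                   flags = res$flags, fits = list(res$fit)),
              class = "gdtec_cox")
  } else {
    pieces <- lapply(colnames(features), function(nm) fit_one(nm))
    tab <- do.call(rbind, lapply(pieces, `[[`, "table"))
    structure(list(table = tab, risk = NULL, mode = mode, ties = ties,
                   n = length(time), events = sum(event),
                   flags = unlist(lapply(pieces, `[[`, "flags")),
                   fits = lapply(pieces, `[[`, "fit")),
              class = "gdtec_cox")
  }
}

#' @export
print.gdtec_cox <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s, ties = %s): n = %d, events = %d\n",
              x$mode, x$ties, x$n, x$events))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, digits = 4)
  print(tab, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(unique(x$flags), collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.gdtec_cox <- function(object, ...) {
  setNames(object$table$coef, object$table$feature)
}

#' @export
predict.gdtec_cox <- function(object, newdata, ...) {
  if (object$mode != "multivariate") {
    gd_stop("gdtec_config_error", "prediction requires a multivariate fit")
  }
  as.numeric(predict(object$fits[[1]], newdata = as.data.frame(newdata),
                     type = "lp"))
}

#' Split samples into low/high risk at the median risk score
#'
#' Scores strictly above the median are high risk; scores at or below it
#' (including median ties) are low risk, which keeps the split
#' deterministic.
#'
#' @param x A multivariate `"gdtec_cox"` fit or a numeric vector of risk
#'   scores.
#' @return Named factor with levels `low`, `high`. Constant scores raise a
#'   degenerate-split error.
#' @export
risk_stratify <- function(x) {
  scores <- if (inherits(x, "gdtec_cox")) {
    if (is.null(x$risk)) gd_stop("gdtec_config_error", "fit carries no risk scores")
    x$risk
  } else setNames(as.numeric(x), names(x))
  if (length(unique(scores)) < 2L) {
    gd_stop("gdtec_degenerate_error", "risk scores are constant; no median split")
  }
  med <- median(scores)
  out <- factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
  names(out) <- names(scores)
  out
}

#' Group samples by how many of two risk genes are flagged
#'
#' Counts, per sample, how many of the two genes carry a 1 in the supplied
#' binary matrix (GDTEC indicators or abnormal-expression flags), yielding
#' the 0/1/2 grouping used for two-gene survival comparisons.
#'
#' @param flag_matrix Binary gene-by-sample matrix.
#' @param genes Character vector of exactly two gene IDs.
#' @return Named integer vector of counts in \{0, 1, 2\}.
#' @export
count_group <- function(flag_matrix, genes) {
  if (length(genes) != 2L) gd_stop("gdtec_config_error", "exactly two genes required")
  missing_genes <- setdiff(genes, rownames(flag_matrix))
  if (length(missing_genes)) {
    gd_stop("gdtec_lookup_error", "gene(s) not in matrix: %s",
            paste(missing_genes, collapse = ", "))
  }
  counts <- colSums(flag_matrix[genes, , drop = FALSE] != 0)
  setNames(as.integer(counts), colnames(flag_matrix))
}

#' Abnormal-expression flags from log fold changes
#'
#' Flags a cell when its discretized fold change is nonzero in either
#' direction, using the same band as the main pipeline by default.
#'
#' @param lfc Real matrix of log2 fold changes.
#' @param low,high Band edges passed to [discretize_lfc()].
#' @return Binary matrix of abnormal-expression flags.
#' @export
abnormal_flags <- function(lfc, low = -1, high = 1) {
  1 * (discretize_lfc(lfc, low, high) != 0)
}
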
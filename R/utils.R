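`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers/tests can distinguish contract violations:
# gdtec_format_error, gdtec_domain_error, gdtec_alignment_error,
# gdtec_config_error, gdtec_degenerate_error, gdtec_empty_error,
# gdtec_lookup_error, gdtec_spec_error.
gd_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "gdtec_error")))
}

gd_assert_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    gd_stop("gdtec_format_error", "%s must be a numeric matrix", what)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    gd_stop("gdtec_format_error", "%s must have gene rownames and sample colnames", what)
  }
  invisible(x)
}

gd_assert_same_shape <- function(a, b, what = "matrices") {
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b))) {
    gd_stop("gdtec_alignment_error",
            "%s must share shape and gene/sample order", what)
  }
  invisible(NULL)
}

# Run code with a deterministic RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Maximum-weight one-to-one matching on a (small) contingency table via
# bitmask dynamic programming over the smaller label set; rows may stay
# unmatched when cluster counts differ.
assignment_max <- function(C) {
  C <- unclass(as.matrix(C))
  if (nrow(C) > ncol(C)) C <- t(C)
  r <- nrow(C)
  cc <- ncol(C)
  if (cc > 16L) {
    gd_stop("gdtec_config_error",
            "partition matching supports at most 16 clusters (got %d)", cc)
  }
  nmask <- bitwShiftL(1L, cc)
  dp <- numeric(nmask)
  for (i in seq_len(r)) {
    ndp <- dp
    for (mask in seq_len(nmask - 1L)) {
      best <- dp[mask + 1L]
      for (j in seq_len(cc)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) != 0L) {
          cand <- dp[mask - bit + 1L] + C[i, j]
          if (cand > best) best <- cand
        }
      }
      if (best > ndp[mask + 1L]) ndp[mask + 1L] <- best
    }
    dp <- ndp
  }
  max(dp)
}
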
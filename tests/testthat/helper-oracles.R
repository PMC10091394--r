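# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (loops, enumeration, closed forms) and never call the
# code paths they check.

# k perfectly separated binary blocks: identical rows within a block,
# orthogonal between blocks.
block_matrix <- function(k, samples_per = 10, genes_per = 10) {
  m <- matrix(0, k * genes_per, k * samples_per)
  for (i in seq_len(k)) {
    m[((i - 1) * genes_per + 1):(i * genes_per),
      ((i - 1) * samples_per + 1):(i * samples_per)] <- 1
  }
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  m
}

named_matrix <- function(values, nrow, ncol, genes = NULL, samples = NULL) {
  matrix(values, nrow, ncol,
         dimnames = list(genes %||% paste0("g", seq_len(nrow)),
                         samples %||% paste0("s", seq_len(ncol))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All permutations of a vector (small n only).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Brute-force partition overlap: maximum matched fraction over every
# injective mapping of p1's cluster labels onto p2's (padded with dummies).
overlap_oracle <- function(p1, p2) {
  l1 <- unique(p1)
  l2 <- unique(p2)
  width <- max(length(l1), length(l2))
  padded <- c(as.character(l2), paste0(".dummy", seq_len(width)))[seq_len(width)]
  best <- 0
  for (perm in all_perms(padded)) {
    mapping <- setNames(perm[seq_along(l1)], as.character(l1))
    acc <- mean(mapping[as.character(p1)] == as.character(p2))
    best <- max(best, acc)
  }
  best
}

# Adjusted Rand index by explicit pair counting.
ari_oracle <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  total <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / total
  maxidx <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxidx == expected) return(ifelse(s11 == maxidx, 1, 0))
  (s11 - expected) / (maxidx - expected)
}

# Two-group log-rank chi-square by observed-vs-expected tabulation.
logrank2_oracle <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (tj in times) {
    at_risk <- time >= tj
    nj <- sum(at_risk)
    n1j <- sum(at_risk & group == g1)
    dj <- sum(time == tj & event == 1)
    d1j <- sum(time == tj & event == 1 & group == g1)
    O1 <- O1 + d1j
    E1 <- E1 + dj * n1j / nj
    if (nj > 1) {
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  (O1 - E1)^2 / V
}

# AUC as exhaustive pairwise concordance (ties count one half).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Default small cohort + fused matrix used by several suites.
fused_fixture <- function(seed = 7, ...) {
  co <- generate_cohort(synthetic_spec(seed = seed, ...))
  lfc <- compute_lfc(co$expr_tumor, co$expr_normal)
  fused <- gdtec(co$mutation, collapse_cnv(co$cnv_calls), discretize_lfc(lfc))
  list(cohort = co, lfc = lfc, fused = fused)
}
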
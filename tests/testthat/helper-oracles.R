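## Independent oracles and small fixtures used across the suite. The
## oracles recompute quantities from first principles and never share code
## with the implementation paths they check.

## Brute-force scorer: recomputes a window's normalized score directly
## from the count matrix, independent of the package's scoring path.
oracle_score <- function(window, counts, background = rep(0.25, 4),
                         pseudocount = sqrt(colSums(counts))) {
  bases <- c("A", "C", "G", "T")
  L <- ncol(counts)
  idx <- match(strsplit(window, "")[[1]], bases)
  n <- colSums(counts)
  raw <- 0; smin <- 0; smax <- 0
  for (i in seq_len(L)) {
    p <- (counts[, i] + pseudocount[i] * background) / (n[i] + pseudocount[i])
    w <- log2(p / background)
    d <- sum(ifelse(p > 0, p * log2(p / background), 0))
    raw <- raw + d * w[idx[i]]
    smin <- smin + d * min(w)
    smax <- smax + d * max(w)
  }
  if (smax == smin) return(1)
  (raw - smin) / (smax - smin)
}

## All 4^L windows of length L as strings.
all_windows <- function(L) {
  bases <- c("A", "C", "G", "T")
  do.call(paste0, expand.grid(rep(list(bases), L))[, L:1, drop = FALSE])
}

## Brute-force Benjamini-Hochberg: direct definition with the cumulative
## minimum taken explicitly.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## Brute-force one-sided Fisher p: explicit hypergeometric tail sum over
## binomial coefficients.
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  js <- a:min(m, k)
  js <- js[k - js <= n & k - js >= 0]
  sum(exp(lchoose(m, js) + lchoose(n, k - js) - lchoose(m + n, k)))
}

## Exhaustive CFS: evaluates every non-empty subset, returning the best
## merit (ties toward smaller subsets, then lexicographic order).
oracle_cfs_exhaustive <- function(features, labels) {
  p <- ncol(features)
  best <- list(subset = integer(0), merit = 0)
  for (mask in 1:(2^p - 1)) {
    subset <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    m <- cfs_merit(subset, features, labels)
    if (m > best$merit + 1e-10) best <- list(subset = subset, merit = m)
  }
  best
}

## Hand-built aligned region: 5 species, optionally perturbed.
toy_region <- function(ref = "TTACGTGTTAGGCCAATT",
                       species = c("human", "chimp", "dog", "cow", "mouse"),
                       edits = list(), start = 1000L) {
  rows <- setNames(rep(ref, length(species)), species)
  for (sp in names(edits)) {
    s <- strsplit(rows[[sp]], "")[[1]]
    for (e in edits[[sp]]) s[e$at] <- e$to
    rows[[sp]] <- paste(s, collapse = "")
  }
  aligned_region("toy", "chr1", start, start + nchar(gsub("-", "", ref)),
                 rows)
}

## Tiny deterministic PWM whose consensus is ACGT.
acgt_pwm <- function(id = "ACGT1") {
  counts <- matrix(c(10, 0, 0, 0,
                     0, 10, 0, 0,
                     0, 0, 10, 0,
                     0, 0, 0, 10), nrow = 4)
  pwm(counts, id = id)
}
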
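## MATCH-style threshold calibration: minFN (low stringency), minFP (high
## stringency) and minSum (intermediate). All thresholds are on the
## normalized score scale in [0, 1].

#' Sample sequences from a PWM's corrected probabilities
#'
#' Each position is drawn independently from the corrected column
#' probabilities \eqn{p(\cdot, i)} — the distribution the scorer models.
#'
#' @param x a [pwm] object.
#' @param n number of sequences.
#' @return integer matrix (n x L) of encoded bases.
#' @keywords internal
sample_pwm_codes <- function(x, n) {
  L <- ncol(x$probs)
  m <- matrix(0L, nrow = n, ncol = L)
  for (i in seq_len(L))
    m[, i] <- sample.int(4L, n, replace = TRUE, prob = x$probs[, i])
  m
}

## Normalized scores of a matrix of fixed-length windows (one per row).
score_sample <- function(x, codes_matrix) {
  L <- ncol(codes_matrix)
  w <- x$weights * rep(x$ic, each = 4L)
  raw <- numeric(nrow(codes_matrix))
  bad <- logical(nrow(codes_matrix))
  for (i in seq_len(L)) {
    contrib <- w[cbind(codes_matrix[, i], i)]
    miss <- is.na(contrib) | contrib == -Inf
    bad <- bad | miss
    contrib[miss] <- 0
    raw <- raw + contrib
  }
  rng <- x$s_max - x$s_min
  norm <- if (rng > 0) (raw - x$s_min) / rng else rep(1, length(raw))
  norm[bad] <- 0
  pmin(pmax(norm, 0), 1)
}

#' Generate a synthetic i.i.d. background corpus
#'
#' Stand-in for a coding-sequence corpus during minFP calibration; base
#' composition is controlled by the GC content (default 52%, coding-like).
#'
#' @param length_bp corpus length in base pairs.
#' @param gc GC fraction in (0, 1).
#' @return a single DNA string.
#' @export
random_corpus <- function(length_bp, gc = 0.52) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, length_bp, replace = TRUE, prob = p), collapse = "")
}

corpus_scores <- function(x, corpus, both_strands = FALSE) {
  if (inherits(corpus, "DNAStringSet")) corpus <- as.character(corpus)
  stopifnot(is.character(corpus))
  sc <- unlist(lapply(corpus, function(s) {
    codes <- encode_dna(s)
    out <- score_codes(codes, x)
    if (both_strands) out <- c(out, score_codes(revcomp_codes(codes), x))
    out
  }), use.names = FALSE)
  if (length(sc) == 0L)
    stop("corpus is shorter than one PWM window")
  sc
}

#' minFN threshold: detect a stated fraction of true sites
#'
#' Samples `n_samples` sequences position-wise from the matrix
#' probabilities and returns the empirical threshold whose achieved
#' detection (fraction of the sample scoring at or above it) is closest to
#' `detect_fraction` (default 90%). Candidate thresholds are the distinct
#' observed scores, so tied score values — common for short or highly
#' discrete matrices — cannot force the detection far to one side; exact
#' `detect_fraction` detection is achieved whenever the score distribution
#' is continuous.
#'
#' @param x a [pwm] object.
#' @param n_samples sample size (>= 100).
#' @param detect_fraction fraction of true sites to detect, in (0, 1).
#' @param seed integer seed; calibration is reproducible bit-for-bit.
#' @param scores optionally, precomputed normalized scores of the
#'   calibration sample (internal reuse).
#' @return the threshold, with attribute `detection` giving the achieved
#'   detection fraction on the calibration sample.
#' @export
calibrate_minFN <- function(x, n_samples = 10000L, detect_fraction = 0.90,
                            seed = 1L, scores = NULL) {
  stopifnot(inherits(x, "pwm"), n_samples >= 100,
            detect_fraction > 0, detect_fraction < 1)
  if (is.null(scores)) {
    if (!is.null(seed)) set.seed(seed)
    scores <- score_sample(x, sample_pwm_codes(x, n_samples))
  }
  n_samples <- length(scores)
  s <- sort(scores)
  u <- unique(s)
  det <- (n_samples - findInterval(u - 1e-15, s)) / n_samples
  ## closest achievable detection; ties resolved toward higher detection
  ## (the FN-minimizing side)
  best <- which(abs(det - detect_fraction) ==
                  min(abs(det - detect_fraction)))
  thr <- u[best[1L]]
  structure(thr, detection = det[best[1L]])
}

#' minFP threshold: at most one hit per 10000 bp of background corpus
#'
#' Scans every window of the corpus and returns the smallest normalized
#' score threshold whose hit rate (windows scoring at or above it, per
#' scanned bp) does not exceed `target_rate`. Candidate thresholds are the
#' observed window scores plus 1.0.
#'
#' @param x a [pwm] object.
#' @param corpus character vector of DNA strings (or a `DNAStringSet`); a
#'   stand-in for coding sequence, e.g. [random_corpus()].
#' @param target_rate maximum hits per bp (default 1/10000).
#' @param both_strands scan both strands; must match the scan-time policy.
#' @return the threshold, with attributes `rate` (achieved hits/bp),
#'   `corpus_bp`, and `saturated` (TRUE when even a threshold of 1.0 cannot
#'   reach the target rate).
#' @param scores optionally, precomputed corpus window scores (internal
#'   reuse).
#' @export
calibrate_minFP <- function(x, corpus, target_rate = 1e-4,
                            both_strands = FALSE, scores = NULL) {
  stopifnot(inherits(x, "pwm"), target_rate > 0)
  if (inherits(corpus, "DNAStringSet")) corpus <- as.character(corpus)
  sc <- if (is.null(scores)) corpus_scores(x, corpus, both_strands)
    else scores
  total_bp <- sum(nchar(corpus))
  allowed <- floor(target_rate * total_bp)
  cand <- sort(unique(sc))
  ## hits at threshold t = number of scores >= t (monotone non-increasing)
  n_ge <- length(sc) - findInterval(cand - 1e-15, sort(sc))
  ok <- which(n_ge <= allowed)
  if (length(ok)) {
    thr <- cand[ok[1L]]
    structure(thr, rate = n_ge[ok[1L]] / total_bp, corpus_bp = total_bp,
              saturated = FALSE)
  } else if (sum(sc >= 1) <= allowed) {
    structure(1.0, rate = sum(sc >= 1) / total_bp, corpus_bp = total_bp,
              saturated = FALSE)
  } else {
    warning("PWM '", x$id, "': even threshold 1.0 exceeds the target rate")
    structure(1.0, rate = sum(sc >= 1) / total_bp, corpus_bp = total_bp,
              saturated = TRUE)
  }
}

#' minSum threshold: minimize false negatives plus false positives
#'
#' Evaluates an even grid of thresholds between minFN and minFP. The false
#' negative rate at `t` is the fraction of matrix-sampled sequences scoring
#' below `t`; the false positive rate is the corpus hit rate at `t`
#' normalized by the hit rate at minFN (clipped to \[0, 1\], so the two
#' terms are commensurable). Returns the grid argmin of their sum, lowest
#' threshold on ties.
#'
#' @inheritParams calibrate_minFP
#' @param n_samples matrix sample size for the FN term.
#' @param grid number of grid points (>= 2).
#' @param seed integer seed.
#' @param minFN,minFP optionally supply precomputed endpoint thresholds.
#' @param sample_scores,corpus_scores optionally, precomputed normalized
#'   scores of the matrix sample / corpus windows (internal reuse).
#' @return the threshold.
#' @export
calibrate_minSum <- function(x, corpus, n_samples = 10000L, grid = 100L,
                             seed = 1L, minFN = NULL, minFP = NULL,
                             target_rate = 1e-4, both_strands = FALSE,
                             detect_fraction = 0.90, sample_scores = NULL,
                             corpus_scores = NULL) {
  stopifnot(grid >= 2L)
  if (is.null(minFN))
    minFN <- calibrate_minFN(x, n_samples, detect_fraction, seed = seed,
                             scores = sample_scores)
  if (is.null(minFP))
    minFP <- calibrate_minFP(x, corpus, target_rate, both_strands,
                             scores = corpus_scores)
  lo <- as.numeric(minFN); hi <- as.numeric(minFP)
  if (hi <= lo) return(as.numeric(hi))
  if (is.null(sample_scores)) {
    if (!is.null(seed)) set.seed(seed + 1L)
    sample_scores <- score_sample(x, sample_pwm_codes(x, n_samples))
  }
  csc <- if (is.null(corpus_scores))
    corpus_scores(x, corpus, both_strands)
  else corpus_scores
  ts <- seq(lo, hi, length.out = grid)
  fn <- vapply(ts, function(t) mean(sample_scores < t), 0)
  rate0 <- max(mean(csc >= lo), .Machine$double.eps)
  fp <- vapply(ts, function(t) min(mean(csc >= t) / rate0, 1), 0)
  ts[which.min(fn + fp)]
}

#' Calibrate all three MATCH thresholds for a set of PWMs
#'
#' @param pwms list of [pwm] objects.
#' @param corpus background corpus for the FP terms; generated with
#'   [random_corpus()] (1 Mbp, 52% GC) when not supplied.
#' @param n_samples,detect_fraction,target_rate,grid,both_strands,seed see
#'   the individual calibration functions.
#' @return a `threshold_set` data.frame with columns `pwm_id`, `minFN`,
#'   `minSum`, `minFP`, `detection`, `fp_rate`, `corpus_bp`, `seed`; the
#'   invariant `minFN <= minSum <= minFP` holds row-wise.
#' @export
calibrate_thresholds <- function(pwms, corpus = NULL, n_samples = 10000L,
                                 detect_fraction = 0.90, target_rate = 1e-4,
                                 grid = 100L, both_strands = FALSE,
                                 seed = 1L) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.null(corpus)) {
    set.seed(seed)
    corpus <- random_corpus(1e6)
  }
  rows <- lapply(pwms, function(p) {
    set.seed(seed)
    ss <- score_sample(p, sample_pwm_codes(p, n_samples))
    cs <- corpus_scores(p, corpus, both_strands)
    fn <- calibrate_minFN(p, n_samples, detect_fraction, seed = seed,
                          scores = ss)
    fp <- calibrate_minFP(p, corpus, target_rate, both_strands,
                          scores = cs)
    ms <- calibrate_minSum(p, corpus, n_samples, grid, seed = seed,
                           minFN = fn, minFP = fp,
                           target_rate = target_rate,
                           both_strands = both_strands,
                           detect_fraction = detect_fraction,
                           sample_scores = ss, corpus_scores = cs)
    data.frame(pwm_id = p$id, minFN = as.numeric(fn), minSum = ms,
               minFP = as.numeric(fp),
               detection = attr(fn, "detection"),
               fp_rate = attr(fp, "rate"),
               corpus_bp = attr(fp, "corpus_bp"), seed = seed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("threshold_set", "data.frame")
  out
}

#' Persist / load calibrated thresholds
#'
#' @param x a `threshold_set` data.frame.
#' @param path TSV file.
#' @return `path` invisibly; `read_thresholds` returns the table.
#' @export
write_thresholds <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("threshold_set", "data.frame")
  out
}

## Look up the threshold of one PWM at a given stringency.
threshold_for <- function(thresholds, pwm_id,
                          stringency = c("minSum", "minFN", "minFP")) {
  stringency <- match.arg(stringency)
  i <- match(pwm_id, thresholds$pwm_id)
  if (is.na(i))
    stop("no calibrated threshold for PWM '", pwm_id, "'")
  thresholds[[stringency]][i]
}
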
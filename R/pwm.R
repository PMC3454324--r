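#' @importFrom stats quantile rnorm runif rbinom setNames median mad density
#'   pnorm pt pchisq p.adjust fisher.test wilcox.test chisq.test var sd
#' @importFrom utils read.delim write.table head tail
NULL

BASES <- c("A", "C", "G", "T")

## Integer encoding used by every scanner: A=1 C=2 G=3 T=4, anything else NA.
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], BASES)
  m
}

decode_dna <- function(codes) paste(BASES[codes], collapse = "")

revcomp_codes <- function(codes) rev(5L - codes)

#' Construct a position weight matrix model
#'
#' Builds the motif model used throughout the package from a raw count
#' matrix: corrected (pseudocounted) probabilities, log-odds weights,
#' per-position information content (relative entropy versus the background,
#' in bits), and the high-information mask used by the conservation filter.
#'
#' The corrected probability of base \eqn{b} at position \eqn{i} is
#' \deqn{p(b,i) = (f(b,i) + c \cdot p(b)) / (N_i + c)}
#' where \eqn{f(b,i)} are raw counts, \eqn{N_i} the column total and
#' \eqn{c} the pseudocount weight (default \eqn{\sqrt{N_i}}, distributed by
#' the background). Weights are \eqn{W(b,i) = \log_2 p(b,i)/p(b)} and the
#' information content is \eqn{D_i = \sum_b p(b,i) \log_2 p(b,i)/p(b)}.
#'
#' @param counts 4 x L integer matrix of base counts (rows A, C, G, T).
#' @param id,name identifiers carried through scans and reports.
#' @param background probability vector over A,C,G,T; must sum to 1.
#' @param pseudocount pseudocount weight \eqn{c}: a non-negative number, or
#'   `"sqrt"` for the per-column default \eqn{\sqrt{N_i}}.
#' @param ic_fraction positions with \eqn{D_i \ge} `ic_fraction` times the
#'   maximal achievable information content are masked as high-information
#'   (default 0.60).
#' @return An object of class `pwm`.
#' @export
pwm <- function(counts, id = "PWM", name = id,
                background = rep(0.25, 4),
                pseudocount = "sqrt", ic_fraction = 0.60) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop("counts must have 4 rows (A, C, G, T)")
  if (any(is.na(counts)) || any(counts < 0))
    stop("PWM '", id, "': counts must be non-negative and non-missing")
  rownames(counts) <- BASES
  background <- check_background(background)
  n_sites <- colSums(counts)
  if (any(n_sites <= 0))
    stop("PWM '", id, "': every column must have a positive site count")
  cvec <- if (identical(pseudocount, "sqrt")) sqrt(n_sites) else {
    stopifnot(is.numeric(pseudocount), all(pseudocount >= 0))
    rep_len(pseudocount, ncol(counts))
  }
  probs <- sweep(counts, 2L, n_sites + cvec, "/") +
    outer(background, cvec / (n_sites + cvec))
  weights <- log2(probs / background)     # -Inf allowed when c = 0
  ic <- information_from_probs(probs, background)
  d_max <- log2(1 / min(background))      # maximal achievable rel. entropy
  obj <- list(
    id = id, name = name, counts = counts, n_sites = n_sites,
    background = background, pseudocount = cvec,
    probs = probs, weights = weights, ic = ic,
    ic_fraction = ic_fraction, ic_max = d_max,
    ic_mask = ic / d_max >= ic_fraction
  )
  ## score bounds over finite weights; zero-probability bases are hard
  ## mismatches handled at scan time
  wfin <- weights
  wfin[!is.finite(wfin)] <- NA
  obj$s_min <- sum(ic * apply(wfin, 2L, min, na.rm = TRUE))
  obj$s_max <- sum(ic * apply(wfin, 2L, max, na.rm = TRUE))
  class(obj) <- "pwm"
  obj
}

check_background <- function(background) {
  stopifnot(is.numeric(background), length(background) == 4L)
  if (abs(sum(background) - 1) > 1e-6)
    stop("background probabilities must sum to 1")
  if (any(background <= 0))
    stop("background probabilities must be positive")
  names(background) <- BASES
  background
}

information_from_probs <- function(probs, background) {
  term <- probs * log2(probs / background)
  term[probs == 0] <- 0
  colSums(term)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (%s): %d positions, total IC %.2f bits\n",
              x$id, x$name, ncol(x$counts), sum(x$ic)))
  cat("consensus:", decode_dna(apply(x$probs, 2L, which.max)), "\n")
  invisible(x)
}

#' @export
length.pwm <- function(x) ncol(x$counts)

#' Corrected base probabilities for one matrix column
#'
#' @param counts_column base-count vector (A, C, G, T).
#' @param N column total; defaults to `sum(counts_column)`.
#' @param background base probabilities summing to 1.
#' @param pseudocount_weight non-negative pseudocount weight \eqn{c}.
#' @return probability vector \eqn{(f(b,i) + c p(b)) / (N + c)}.
#' @export
corrected_probability <- function(counts_column, N = sum(counts_column),
                                  background = rep(0.25, 4),
                                  pseudocount_weight = sqrt(N)) {
  background <- check_background(background)
  if (!is.numeric(N) || N <= 0) stop("N must be positive")
  stopifnot(pseudocount_weight >= 0)
  p <- (counts_column + pseudocount_weight * background) /
    (N + pseudocount_weight)
  setNames(as.numeric(p), BASES)
}

#' Log-odds weight matrix of a PWM
#'
#' @param x a [pwm] object.
#' @return the 4 x L matrix \eqn{W(b,i) = \log_2 p(b,i)/p(b)}; entries are
#'   `-Inf` where a zero-pseudocount column has a zero probability.
#' @export
log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  x$weights
}

#' Per-position information content (Stormo), in bits
#'
#' Relative entropy of the corrected column probabilities versus the
#' background; non-negative, zero iff the column equals the background, and
#' at most `log2(1/min(background))` (2 bits under a uniform background).
#'
#' @param x a [pwm] object.
#' @return numeric vector of length L.
#' @export
information_content <- function(x) {
  stopifnot(inherits(x, "pwm"))
  x$ic
}

## Vectorized scoring over every window of an encoded sequence.
## Returns normalized scores (length n - L + 1); windows containing
## non-ACGT characters score 0. Zero-probability bases (possible with c = 0)
## are hard mismatches that also send a window to 0.
score_codes <- function(codes, x) {
  L <- ncol(x$counts)
  n <- length(codes)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  raw <- numeric(nw)
  bad <- logical(nw)
  w <- x$weights * rep(x$ic, each = 4L)   # IC-weighted contributions
  for (i in seq_len(L)) {
    b <- codes[i:(i + nw - 1L)]
    contrib <- w[cbind(b, i)]
    miss <- is.na(contrib) | contrib == -Inf
    bad <- bad | miss
    contrib[miss] <- 0
    raw <- raw + contrib
  }
  rng <- x$s_max - x$s_min
  norm <- if (rng > 0) (raw - x$s_min) / rng else rep(1, nw)
  norm[bad] <- 0
  pmin(pmax(norm, 0), 1)
}

#' Score one window against a PWM
#'
#' The raw score is the information-content-weighted sum of log-odds
#' weights, \eqn{S = \sum_i D_i W(b_i, i)}; it is normalized by subtracting
#' the minimum attainable score and dividing by the score range, so the
#' per-position argmax sequence scores 1 and the argmin sequence 0. Windows
#' containing `N` are unscannable: they score 0 and are flagged.
#'
#' @param window DNA string of the PWM's length (characters A/C/G/T/N).
#' @param x a [pwm] object.
#' @return list with `sequence`, `raw_score`, `normalized_score`,
#'   `unscannable`.
#' @export
score_window <- function(window, x) {
  stopifnot(inherits(x, "pwm"))
  codes <- encode_dna(window)
  L <- ncol(x$counts)
  if (length(codes) != L)
    stop("window length ", length(codes), " does not match PWM length ", L)
  unscannable <- anyNA(codes)
  raw <- if (unscannable) NA_real_ else {
    contrib <- x$weights[cbind(codes, seq_len(L))] * x$ic
    if (any(contrib == -Inf)) unscannable <- TRUE
    sum(contrib)
  }
  norm <- score_codes(codes, x)
  list(sequence = toupper(window), raw_score = raw,
       normalized_score = norm, unscannable = unscannable)
}

#' Parse a JASPAR PFM document
#'
#' Reads ">ID name" records with four base rows (optionally labelled
#' `A [ ... ]` as in the 2010 release, or bare whitespace-separated counts
#' in A/C/G/T order).
#'
#' @param text path to a PFM file, or the document as a character vector.
#' @param ... passed to [pwm()] (background, pseudocount, ic_fraction).
#' @return list of [pwm] objects, named by matrix id, in file order.
#' @export
parse_jaspar <- function(text, ...) {
  lines <- as_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no JASPAR records found")
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[k]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    id <- toks[1L]
    name <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else id
    body <- lines[(starts[k] + 1L):ends[k]]
    if (length(body) != 4L)
      stop("JASPAR record '", id, "': expected 4 base rows, found ",
           length(body))
    rows <- lapply(body, parse_jaspar_row, id = id)
    labels <- vapply(rows, `[[`, "", "base")
    mat <- do.call(rbind, lapply(rows, `[[`, "counts"))
    if (all(labels %in% BASES) && !anyDuplicated(labels)) {
      mat <- mat[match(BASES, labels), , drop = FALSE]
    }
    if (length(unique(vapply(rows, function(r) length(r$counts), 0L))) != 1L)
      stop("JASPAR record '", id, "': rows have unequal lengths")
    if (any(mat < 0))
      stop("JASPAR record '", id, "': negative counts")
    out[[k]] <- pwm(mat, id = id, name = name, ...)
  }
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

parse_jaspar_row <- function(line, id) {
  line <- trimws(line)
  base <- NA_character_
  m <- regmatches(line,
                  regexec("^([ACGTacgt])\\s*[\\[:]?(.*)$", line,
                          perl = TRUE))[[1]]
  if (length(m) == 3L && grepl("[^0-9. \\]]", m[3]) == FALSE) {
    base <- toupper(m[2]); line <- m[3]
  }
  line <- gsub("[][]", " ", line)
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  counts <- suppressWarnings(as.numeric(toks))
  if (anyNA(counts))
    stop("JASPAR record '", id, "': malformed count row '", line, "'")
  list(base = base, counts = counts)
}

#' Parse a TRANSFAC flat-file matrix document
#'
#' Records are delimited by `//`, identified by their `AC` line (`ID` line
#' used as the name when present), and carry numbered position rows
#' `01 .. NN` with A C G T counts; the trailing consensus column is
#' ignored.
#'
#' @param text path to a matrix file, or the document as a character vector.
#' @param ... passed to [pwm()].
#' @return list of [pwm] objects named by accession; empty document gives an
#'   empty list.
#' @export
parse_transfac <- function(text, ...) {
  lines <- as_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  terms <- grep("^//", lines)
  if (length(terms) == 0L || max(terms) < length(lines))
    stop("TRANSFAC document: missing '//' record terminator")
  rec_start <- c(1L, head(terms, -1L) + 1L)
  out <- list()
  for (k in seq_along(terms)) {
    body <- lines[rec_start[k]:(terms[k] - 1L)]
    if (length(body) == 0L) next
    ac <- sub("^AC\\s+", "", grep("^AC\\s", body, value = TRUE))
    id <- if (length(ac)) trimws(ac[1L]) else stop("TRANSFAC record without AC line")
    idl <- sub("^ID\\s+", "", grep("^ID\\s", body, value = TRUE))
    name <- if (length(idl)) trimws(idl[1L]) else id
    ## base order from the P0/PO header when present
    order_bases <- BASES
    p0 <- grep("^P[0O]\\s", body, value = TRUE)
    if (length(p0)) {
      toks <- toupper(strsplit(trimws(p0[1L]), "\\s+")[[1]][-1L])
      if (all(BASES %in% toks)) order_bases <- toks[toks %in% BASES]
    }
    rows <- grep("^[0-9]{2}\\s", body, value = TRUE)
    if (length(rows) == 0L)
      stop("TRANSFAC record '", id, "': no position rows")
    mat <- sapply(rows, function(r) {
      toks <- strsplit(trimws(r), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(toks[2:5]))
      if (anyNA(vals))
        stop("TRANSFAC record '", id, "': non-numeric counts in row '",
             r, "'")
      vals
    })
    rownames(mat) <- order_bases
    mat <- mat[BASES, , drop = FALSE]
    out[[id]] <- pwm(mat, id = id, name = name, ...)
  }
  out
}

as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}

#' Write weights and information content of PWMs as TSV
#'
#' @param pwms list of [pwm] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pwm_tsv <- function(pwms, path) {
  rows <- do.call(rbind, lapply(pwms, function(p) {
    L <- ncol(p$counts)
    data.frame(pwm_id = p$id, position = seq_len(L),
               A = p$weights["A", ], C = p$weights["C", ],
               G = p$weights["G", ], T = p$weights["T", ],
               ic = p$ic, ic_mask = p$ic_mask)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
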
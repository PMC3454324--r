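## Per-PWM enrichment (Fisher's exact test) and correlation-based feature
## selection (CFS) under repeated stratified cross-validation.

#' Fisher enrichment of conserved hits in core vs background regions
#'
#' For each PWM column of the presence matrix, the 2x2 table
#' (core-with-hit a, core-without b, background-with c, background-without
#' d) is tested with Fisher's exact test, one-sided "greater" by default
#' (overrepresentation in the core set). Significance is declared at
#' p < 0.05 with no multiple-testing correction; a BH-adjusted column is
#' reported alongside for transparency.
#'
#' @param presence binary matrix (regions x PWMs) from [presence_matrix()].
#' @param labels vector with values `"core"` / `"background"`, one per
#'   region.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param alpha significance level (default 0.05).
#' @return data.frame (`pwm_id`, `a`, `b`, `c`, `d`, `odds_ratio`, `p`,
#'   `adj_p`, `significant`), sorted by p.
#' @export
fisher_enrichment <- function(presence, labels,
                              alternative = c("greater", "two.sided"),
                              alpha = 0.05) {
  alternative <- match.arg(alternative)
  labels <- as.character(labels)
  stopifnot(nrow(presence) == length(labels),
            all(labels %in% c("core", "background")))
  if (!any(labels == "core") || !any(labels == "background"))
    stop("both 'core' and 'background' labels must be present")
  core <- labels == "core"
  rows <- lapply(seq_len(ncol(presence)), function(j) {
    v <- presence[, j] != 0
    a <- sum(v & core); b <- sum(!v & core)
    cc <- sum(v & !core); d <- sum(!v & !core)
    if (a + cc == 0L || b + d == 0L) {       # constant column
      p <- 1; or <- NA_real_
    } else {
      p <- if (alternative == "greater")
        fisher_p_greater(a, b, cc, d)
      else
        fisher.test(matrix(c(a, b, cc, d), nrow = 2),
                    alternative = "two.sided")$p.value
      or <- (a * d) / (b * cc)
      if (is.nan(or)) or <- NA_real_
    }
    data.frame(pwm_id = colnames(presence)[j], a = a, b = b, c = cc, d = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## One-sided (greater) Fisher exact p: the hypergeometric upper tail
## P(X >= a) with X ~ Hypergeom(core = a+b, background = c+d, hits = a+c).
## Vectorized over table entries.
fisher_p_greater <- function(a, b, cc, d) {
  stats::phyper(a - 1, a + b, cc + d, a + cc, lower.tail = FALSE)
}

## Symmetrical uncertainty between two discrete vectors:
## SU = 2 I(X;Y) / (H(X) + H(Y)), zero when both entropies vanish.
symmetrical_uncertainty <- function(x, y) {
  su_codes(as_codes(x), as_codes(y))
}

as_codes <- function(x) as.integer(factor(x))

su_codes <- function(xi, yi) {
  n <- length(xi)
  kx <- max(xi); ky <- max(yi)
  hx <- plugin_entropy(tabulate(xi, kx), n)
  hy <- plugin_entropy(tabulate(yi, ky), n)
  if (hx + hy == 0) return(0)
  hxy <- plugin_entropy(tabulate(xi + kx * (yi - 1L), kx * ky), n)
  su <- 2 * (hx + hy - hxy) / (hx + hy)
  min(max(su, 0), 1)
}

plugin_entropy <- function(counts, n) {
  p <- as.numeric(counts) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

## Cache feature-class and pairwise feature SU for one training split.
su_cache <- function(features, labels) {
  p <- ncol(features)
  cols <- lapply(seq_len(p), function(j) as_codes(features[, j]))
  lab <- as_codes(labels)
  rcf <- vapply(cols, su_codes, 0, yi = lab)
  rff <- matrix(0, p, p)
  if (p >= 2L)
    for (i in seq_len(p - 1L))
      for (j in (i + 1L):p)
        rff[i, j] <- rff[j, i] <- su_codes(cols[[i]], cols[[j]])
  list(rcf = rcf, rff = rff)
}

merit_from_cache <- function(subset, cache) {
  k <- length(subset)
  if (k == 0L) return(0)
  rcf_bar <- mean(cache$rcf[subset])
  rff_bar <- if (k > 1L) {
    sub <- cache$rff[subset, subset, drop = FALSE]
    sum(sub) / (k * (k - 1L))
  } else 0
  denom <- sqrt(k + k * (k - 1L) * rff_bar)
  if (denom == 0) return(0)
  k * rcf_bar / denom
}

#' CFS merit of a feature subset
#'
#' \deqn{Merit = k \bar{r}_{cf} / \sqrt{k + k (k-1) \bar{r}_{ff}}}
#' where \eqn{\bar{r}_{cf}} is the mean feature-class correlation and
#' \eqn{\bar{r}_{ff}} the mean pairwise feature correlation, both measured
#' as symmetrical uncertainty on the discrete variables. High merit
#' rewards class-relevant, mutually non-redundant subsets.
#'
#' @param subset integer vector of feature (column) indices.
#' @param features matrix of discrete features.
#' @param labels class vector.
#' @return the merit value.
#' @export
cfs_merit <- function(subset, features, labels) {
  stopifnot(length(subset) >= 1L)
  cache <- su_cache(features[, subset, drop = FALSE], labels)
  merit_from_cache(seq_along(subset), cache)
}

#' Best-first CFS subset selection
#'
#' Forward best-first search over feature subsets maximizing the CFS
#' merit, stopping after `patience` consecutive node expansions that fail
#' to improve the best merit. Ties are broken deterministically toward
#' the lowest feature index; features carrying no information (all-zero
#' merit) leave the selection empty.
#'
#' @param features matrix of discrete features (columns).
#' @param labels class vector.
#' @param patience non-improving expansions tolerated (default 5).
#' @return sorted integer vector of selected feature indices.
#' @export
cfs_select <- function(features, labels, patience = 5L) {
  stopifnot(ncol(features) >= 1L)
  cache <- su_cache(features, labels)
  cfs_select_cached(cache, ncol(features), patience)
}

cfs_select_cached <- function(cache, p, patience = 5L) {
  best_subset <- integer(0)
  best_merit <- 0
  eps <- 1e-10
  open <- list(list(subset = integer(0), merit = 0))
  seen <- new.env(hash = TRUE)
  assign("s", TRUE, envir = seen)
  stall <- 0L
  while (length(open) > 0L && stall < patience) {
    merits <- vapply(open, `[[`, 0, "merit")
    i <- which.max(merits)   # FIFO among equals: which.max takes first
    node <- open[[i]]
    open[[i]] <- NULL
    improved <- FALSE
    for (f in setdiff(seq_len(p), node$subset)) {
      child <- sort(c(node$subset, f))
      key <- paste0("s", paste(child, collapse = ","))
      if (exists(key, envir = seen, inherits = FALSE)) next
      assign(key, TRUE, envir = seen)
      m <- merit_from_cache(child, cache)
      open[[length(open) + 1L]] <- list(subset = child, merit = m)
      if (m > best_merit + eps) {
        best_merit <- m
        best_subset <- child
        improved <- TRUE
      }
    }
    stall <- if (improved) 0L else stall + 1L
  }
  best_subset
}

#' Selection counts under repeated stratified cross-validation
#'
#' Runs CFS selection on the training split of each fold of a stratified
#' k-fold cross-validation, repeated `iterations` times with reshuffled
#' folds, and counts how many folds chose each feature — from 0 (never
#' chosen) to `folds * iterations` (every fold of every iteration).
#'
#' @param features matrix of discrete features; column names are carried
#'   into the result.
#' @param labels class vector (both classes must have at least `folds`
#'   members, otherwise folds are reduced with a warning).
#' @param folds folds per iteration (default 10).
#' @param iterations iterations (default 10).
#' @param seed integer seed for the fold assignments.
#' @param patience passed to [cfs_select()].
#' @return data.frame (`pwm_id`, `times_chosen`), sorted by count.
#' @export
cfs_cross_validate <- function(features, labels, folds = 10L,
                               iterations = 10L, seed = 1L,
                               patience = 5L) {
  labels <- as.character(labels)
  classes <- unique(labels)
  min_class <- min(table(labels))
  if (min_class < folds) {
    warning("smallest class has ", min_class, " members; reducing folds")
    folds <- max(2L, min_class)
  }
  p <- ncol(features)
  counts <- integer(p)
  set.seed(seed)
  for (it in seq_len(iterations)) {
    fold_id <- integer(length(labels))
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    for (f in seq_len(folds)) {
      train <- fold_id != f
      cache <- su_cache(features[train, , drop = FALSE], labels[train])
      sel <- cfs_select_cached(cache, p, patience)
      counts[sel] <- counts[sel] + 1L
    }
  }
  ids <- colnames(features)
  if (is.null(ids)) ids <- paste0("f", seq_len(p))
  out <- data.frame(pwm_id = ids, times_chosen = counts,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$times_chosen), , drop = FALSE]
  rownames(out) <- NULL
  out
}
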
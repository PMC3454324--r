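## Tiling-array ChIP region calling: normalization, per-probe shrinkage
## t statistics with BH correction, sliding-window quantile smoothing,
## null-distribution thresholding and enriched-region assembly.

#' Construct a tiling probe track
#'
#' @param probes data.frame with `probe_id`, `chrom`, `start`, `end`
#'   (0-based half-open), sorted internally by (chrom, start).
#' @param ratios numeric matrix of per-replicate log-ratios, one row per
#'   probe (NAs allowed).
#' @return an object of class `probe_track`.
#' @export
probe_track <- function(probes, ratios) {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "chrom", "start", "end") %in% names(probes)),
            nrow(probes) == nrow(ratios), ncol(ratios) >= 1L)
  ord <- order(probes$chrom, probes$start)
  probes <- probes[ord, , drop = FALSE]
  ratios <- as.matrix(ratios)[ord, , drop = FALSE]
  rownames(probes) <- NULL
  structure(list(probes = probes, ratios = ratios,
                 smoothed = NULL, pvalue = NULL, adj_pvalue = NULL),
            class = "probe_track")
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf("probe_track: %d probes, %d replicates%s%s\n",
              nrow(x$probes), ncol(x$ratios),
              if (!is.null(x$smoothed)) ", smoothed" else "",
              if (!is.null(x$adj_pvalue)) ", p-values" else ""))
  invisible(x)
}

#' Read / write probe tables
#'
#' TSV with columns `probe_id`, `chrom`, `start`, `end`, then one column
#' per replicate; empty cells are missing values.
#'
#' @param path TSV file.
#' @return a [probe_track].
#' @export
read_probe_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  reps <- setdiff(names(d), c("probe_id", "chrom", "start", "end"))
  probe_track(d[c("probe_id", "chrom", "start", "end")],
              as.matrix(d[reps]))
}

#' @rdname read_probe_table
#' @param track a [probe_track].
#' @export
write_probe_table <- function(track, path) {
  out <- cbind(track$probes, as.data.frame(track$ratios))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize replicate log-ratio columns
#'
#' `glog` (default) applies the variance-stabilizing transform
#' `asinh(x / s_r)` with `s_r` the replicate's median absolute deviation,
#' then median-centers each replicate; a constant replicate is centered
#' only, with a warning. `quantile` maps all replicates onto their common
#' quantile profile; `none` is the identity.
#'
#' @param track a [probe_track].
#' @param method `"glog"`, `"quantile"` or `"none"`.
#' @return the track with transformed `ratios`.
#' @export
normalize_track <- function(track, method = c("glog", "quantile", "none")) {
  method <- match.arg(method)
  if (method == "none") return(track)
  r <- track$ratios
  if (method == "glog") {
    for (j in seq_len(ncol(r))) {
      s <- mad(r[, j], na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        warning("replicate ", j, " is constant; centering only")
        r[, j] <- r[, j] - median(r[, j], na.rm = TRUE)
      } else {
        v <- asinh(r[, j] / s)
        r[, j] <- v - median(v, na.rm = TRUE)
      }
    }
  } else {
    r <- limma::normalizeQuantiles(r)
  }
  track$ratios <- r
  track
}

## Method-of-moments estimate of the variance-shrinkage prior: sample
## variances are modelled as s^2 ~ s0^2 * F(d, d0); d0 solves
## var(s2)/mean(s2)^2 = 2 (d + d0 - 2) / (d (d0 - 4)).
estimate_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2)]
  if (length(s2) < 3L) return(list(d0 = Inf, s02 = mean(s2)))
  m <- mean(s2); v <- var(s2)
  r <- v / m^2
  denom <- r * d - 2
  if (!is.finite(denom) || denom <= 0)
    return(list(d0 = Inf, s02 = m))
  d0 <- (2 * d - 4 + 4 * r * d) / denom
  if (!is.finite(d0) || d0 <= 4.01)      # moments invalid below 4 df
    return(list(d0 = 4.01, s02 = m * (4.01 - 2) / 4.01))
  list(d0 = d0, s02 = m * (d0 - 2) / d0)
}

#' Per-probe statistics: shrinkage t-test of log-ratios against zero
#'
#' One-sample t statistics on the replicate log-ratios of each probe. With
#' `shrink = TRUE` per-probe variances are shrunk toward a grand prior
#' variance `s0^2` with prior degrees of freedom `d0`, both estimated by a
#' method of moments across probes; the posterior variance is
#' `(d0 s0^2 + d s^2) / (d0 + d)` and p-values are two-sided from a t
#' distribution with `d0 + d` degrees of freedom. Benjamini-Hochberg
#' adjustment is applied across probes. Probes with fewer than 2 non-null
#' replicates get p = 1 and are flagged.
#'
#' @param track a [probe_track].
#' @param shrink moderate the variances (default TRUE).
#' @return the track with `pvalue`, `adj_pvalue`, `tstat` and `flagged`.
#' @export
probe_statistics <- function(track, shrink = TRUE) {
  r <- track$ratios
  k <- rowSums(!is.na(r))
  mu <- rowMeans(r, na.rm = TRUE)
  s2 <- apply(r, 1L, var, na.rm = TRUE)
  d <- k - 1L
  ok <- k >= 2L
  p <- rep(1, nrow(r))
  tstat <- rep(0, nrow(r))
  if (any(ok)) {
    if (shrink) {
      prior <- estimate_prior(s2[ok], d = median(d[ok]))
      d0 <- min(prior$d0, 1e6)
      s2t <- (d0 * prior$s02 + d * s2) / (d0 + d)
      df <- d0 + d
    } else {
      s2t <- s2
      df <- d
    }
    se <- sqrt(s2t / k)
    t0 <- ifelse(se > 0, mu / se, ifelse(mu == 0, 0, sign(mu) * Inf))
    p[ok] <- 2 * pt(abs(t0[ok]), df = df[ok], lower.tail = FALSE)
    tstat[ok] <- t0[ok]
  }
  track$tstat <- tstat
  track$pvalue <- p
  track$adj_pvalue <- p.adjust(p, method = "BH")
  track$flagged <- !ok
  track
}

#' Sliding-window quantile smoothing of the replicate-mean signal
#'
#' For each probe, the smoothed level is the `quant` quantile (linear
#' interpolation) of the replicate-mean log-ratios of all probes whose
#' interval midpoint lies within `winHalfSize` bp of its own midpoint on
#' the same chromosome; an isolated probe keeps its own value.
#'
#' @param track a [probe_track].
#' @param winHalfSize window half-width in bp (default 100).
#' @param quant quantile level (default 0.75).
#' @return the track with a `smoothed` vector.
#' @export
smooth_signal <- function(track, winHalfSize = 100L, quant = 0.75) {
  level <- rowMeans(track$ratios, na.rm = TRUE)
  centers <- (track$probes$start + track$probes$end) %/% 2
  sm <- numeric(length(level))
  for (ch in unique(track$probes$chrom)) {
    idx <- which(track$probes$chrom == ch)
    cc <- centers[idx]          # sorted within chromosome
    lo <- findInterval(cc - winHalfSize - 0.5, cc) + 1L
    hi <- findInterval(cc + winHalfSize, cc)
    for (j in seq_along(idx)) {
      vals <- level[idx[lo[j]:hi[j]]]
      sm[idx[j]] <- quantile(vals, quant, na.rm = TRUE, names = FALSE)
    }
  }
  track$smoothed <- sm
  track
}

#' Null upper bound for the smoothed signal
#'
#' Estimates the null distribution of smoothed levels by reflecting the
#' left (sub-mode) tail around the mode, under the assumption that bound
#' probes inflate only the right tail; the threshold is the `q` quantile
#' of that symmetric null. `method = "empirical"` falls back to the plain
#' empirical quantile.
#'
#' @param track a smoothed [probe_track].
#' @param q quantile level (default 0.99).
#' @param method `"reflect"` (default) or `"empirical"`.
#' @return the threshold level.
#' @export
null_threshold <- function(track, q = 0.99,
                           method = c("reflect", "empirical")) {
  method <- match.arg(method)
  v <- track$smoothed
  if (is.null(v)) stop("smooth the track first (smooth_signal)")
  v <- v[is.finite(v)]
  if (length(unique(v)) == 1L) {
    warning("all smoothed values identical")
    return(v[1L])
  }
  if (method == "empirical")
    return(quantile(v, q, names = FALSE))
  dd <- density(v)
  mode <- dd$x[which.max(dd$y)]
  left <- v[v <= mode]
  null <- c(left, 2 * mode - left)
  quantile(null, q, names = FALSE)
}

#' Call ChIP-enriched regions on the smoothed signal
#'
#' Maximal runs of probes with smoothed level above the threshold, where
#' consecutive above-threshold probe midpoints are at most `distCutOff`
#' apart. A run becomes a region when it has at least `minProbesInRow`
#' probes, harbours at least one probe with BH-adjusted p below `p_gate`,
#' and is adequately covered: the run plus flanking probes within
#' `distCutOff` of its boundaries must total at least `min_total_probes`.
#' Regions are ranked by best adjusted p, then by maximum smoothed level.
#'
#' @param track a [probe_track] with `smoothed` and `adj_pvalue`.
#' @param threshold smoothed-level threshold, e.g. [null_threshold()].
#' @param distCutOff maximum probe spacing within a region, bp (default
#'   200).
#' @param minProbesInRow minimum probes per region (default 4).
#' @param p_gate FDR gate on the best probe (default 0.02).
#' @param min_total_probes minimum probes counting run plus flanks
#'   (default 8).
#' @return data.frame of regions (`chrom`, `start`, `end`, `n_probes`,
#'   `n_total`, `best_adj_p`, `max_smoothed`, `rank`), sorted by rank.
#' @export
call_regions <- function(track, threshold, distCutOff = 200L,
                         minProbesInRow = 4L, p_gate = 0.02,
                         min_total_probes = 8L) {
  stopifnot(!is.null(track$smoothed), !is.null(track$adj_pvalue))
  centers <- (track$probes$start + track$probes$end) %/% 2
  out <- list()
  for (ch in unique(track$probes$chrom)) {
    idx <- which(track$probes$chrom == ch)
    above <- idx[track$smoothed[idx] > threshold]
    if (length(above) == 0L) next
    gaps <- diff(centers[above])
    runs <- cumsum(c(1L, as.integer(gaps > distCutOff)))
    for (g in split(above, runs)) {
      if (length(g) < minProbesInRow) next
      best_p <- min(track$adj_pvalue[g])
      if (!(best_p < p_gate)) next
      rstart <- min(track$probes$start[g])
      rend <- max(track$probes$end[g])
      lo_c <- min(centers[g]); hi_c <- max(centers[g])
      flank <- setdiff(idx[centers[idx] >= lo_c - distCutOff &
                           centers[idx] <= hi_c + distCutOff], g)
      n_total <- length(g) + length(flank)
      if (n_total < min_total_probes) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = rstart, end = rend,
        n_probes = length(g), n_total = n_total,
        best_adj_p = best_p, max_smoothed = max(track$smoothed[g]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      n_total = integer(0), best_adj_p = numeric(0),
                      max_smoothed = numeric(0), rank = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$best_adj_p, -res$max_smoothed), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}
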
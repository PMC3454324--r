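## Aligned regions and conservation-filtered motif scanning.

#' Construct an aligned region
#'
#' A genomic interval with per-species gapped sequences (reference species
#' first) and a map from reference positions to alignment columns.
#'
#' @param region_id region identifier.
#' @param chrom,start,end 0-based half-open reference coordinates.
#' @param species_rows named character vector of gapped sequences of equal
#'   length; the first entry is the reference species.
#' @return an object of class `aligned_region` with fields `ref_seq`
#'   (degapped reference) and `colmap` (1-based alignment column of each
#'   reference position).
#' @export
aligned_region <- function(region_id, chrom, start, end, species_rows) {
  stopifnot(length(species_rows) >= 1L, !is.null(names(species_rows)))
  species_rows <- toupper(species_rows)
  widths <- nchar(species_rows)
  if (length(unique(widths)) != 1L)
    stop("region '", region_id, "': species rows have unequal lengths")
  ref_chars <- strsplit(species_rows[[1L]], "", fixed = TRUE)[[1]]
  colmap <- which(ref_chars != "-")
  if (length(colmap) == 0L)
    stop("region '", region_id, "': reference row is all gaps")
  ref_seq <- paste(ref_chars[colmap], collapse = "")
  if (!missing(end) && !is.null(end) && end - start != length(colmap))
    stop("region '", region_id, "': reference degapped length ",
         length(colmap), " does not match end - start = ", end - start)
  structure(list(region_id = region_id, chrom = chrom,
                 start = start, end = start + length(colmap),
                 species = names(species_rows),
                 rows = species_rows, ref_seq = ref_seq, colmap = colmap),
            class = "aligned_region")
}

#' @export
print.aligned_region <- function(x, ...) {
  cat(sprintf("aligned_region '%s' %s:%d-%d, %d species (%s reference)\n",
              x$region_id, x$chrom, x$start, x$end, length(x$species),
              x$species[1L]))
  invisible(x)
}

#' Read aligned regions from a multi-FASTA file
#'
#' Each record header is `>species region_id chrom:start-end`; consecutive
#' records sharing a region_id form one alignment, reference species first.
#'
#' @param path FASTA file (gapped sequences allowed).
#' @return a list of [aligned_region] objects, named by region id.
#' @export
read_aligned_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  hdr <- strsplit(names(seqs), "\\s+")
  species <- vapply(hdr, `[`, "", 1L)
  rid <- vapply(hdr, function(h) if (length(h) >= 2L) h[2L] else NA_character_, "")
  loc <- vapply(hdr, function(h) if (length(h) >= 3L) h[3L] else NA_character_, "")
  if (anyNA(rid)) stop("aligned FASTA headers must carry 'species region_id chrom:start-end'")
  groups <- split(seq_along(seqs), factor(rid, levels = unique(rid)))
  out <- lapply(groups, function(idx) {
    if (length(idx) < 2L)
      stop("region '", rid[idx[1L]], "': need at least 2 species rows")
    m <- regmatches(loc[idx[1L]],
                    regexec("^(.+):([0-9]+)-([0-9]+)$", loc[idx[1L]]))[[1]]
    if (length(m) != 4L)
      stop("region '", rid[idx[1L]], "': malformed location '", loc[idx[1L]], "'")
    rows <- setNames(as.character(seqs[idx]), species[idx])
    aligned_region(rid[idx[1L]], m[2L], as.integer(m[3L]), as.integer(m[4L]),
                   rows)
  })
  names(out) <- names(groups)
  out
}

#' Write aligned regions as multi-FASTA
#'
#' @param regions list of [aligned_region] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(regions, path) {
  if (inherits(regions, "aligned_region")) regions <- list(regions)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in regions) {
    for (s in r$species) {
      writeLines(sprintf(">%s %s %s:%d-%d", s, r$region_id, r$chrom,
                         r$start, r$end), con)
      writeLines(r$rows[[s]], con)
    }
  }
  invisible(path)
}

#' Find RCGTG consensus motifs (hypoxia response elements)
#'
#' Reports every occurrence of RCGTG (R = A or G) on the reference strand
#' and, when `both_strands`, of its reverse complement CACGY on the minus
#' strand; HREs are orientation-independent. Overlapping occurrences are
#' all reported.
#'
#' @param region an [aligned_region].
#' @param both_strands also search the minus strand (default TRUE).
#' @return a motif-hit data.frame (`region_id`, `pwm_id = "RCGTG"`,
#'   `offset` 0-based reference-relative, `strand`, `width`,
#'   `normalized_score = 1`, `conserved = NA`).
#' @export
find_rcgtg <- function(region, both_strands = TRUE) {
  seq <- region$ref_seq
  plus <- rcgtg_offsets(seq, "(?=[AG]CGTG)")
  hits <- data.frame(region_id = character(0), pwm_id = character(0),
                     offset = integer(0), strand = character(0),
                     width = integer(0), normalized_score = numeric(0),
                     conserved = logical(0))
  add <- function(off, strand) {
    if (length(off) == 0L) return(NULL)
    data.frame(region_id = region$region_id, pwm_id = "RCGTG",
               offset = off, strand = strand, width = 5L,
               normalized_score = 1, conserved = NA)
  }
  out <- list(add(plus, "+"))
  if (both_strands)
    out <- c(out, list(add(rcgtg_offsets(seq, "(?=CACG[CT])"), "-")))
  out <- do.call(rbind, c(list(hits), out))
  rownames(out) <- NULL
  out
}

rcgtg_offsets <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Cross-species conservation of a motif occurrence
#'
#' A hit is conserved when at least `min_species` species (counting the
#' reference) carry a base identical to the reference at every masked
#' position of the motif, and all `required_species` are among them. Gaps
#' and N count as mismatches. For the RCGTG consensus every position is
#' checked; for PWM hits the mask is the matrix's high-information mask
#' (information content over the 60% cutoff).
#'
#' @param region an [aligned_region].
#' @param offset 0-based reference-relative motif start.
#' @param width motif width.
#' @param ic_mask logical vector of length `width` selecting the positions
#'   that must be identical, or NULL to check all positions.
#' @param min_species minimum number of matching species, reference
#'   included (default 4).
#' @param required_species species that must match; defaults to the
#'   reference plus `"mouse"`. A required species absent from the alignment
#'   makes the hit non-conserved (not an error).
#' @return logical.
#' @export
is_conserved <- function(region, offset, width, ic_mask = NULL,
                         min_species = 4L, required_species = NULL) {
  if (is.null(required_species))
    required_species <- c(region$species[1L], "mouse")
  if (is.null(ic_mask)) ic_mask <- rep(TRUE, width)
  stopifnot(length(ic_mask) == width)
  if (offset < 0 || offset + width > region$end - region$start)
    stop("motif at offset ", offset, " lies outside region '",
         region$region_id, "'")
  pos <- which(ic_mask)
  if (length(pos) == 0L) pos <- seq_len(width)  # vacuous mask: check all
  cols <- region$colmap[offset + pos]
  ref_bases <- substring(region$rows[[1L]], cols, cols)
  matches <- vapply(region$species, function(sp) {
    b <- substring(region$rows[[sp]], cols, cols)
    all(b == ref_bases & b %in% BASES)
  }, NA)
  matching <- region$species[matches]
  sum(matches) >= min_species && all(required_species %in% matching)
}

#' Scan an aligned region with a PWM
#'
#' Splits the reference sequence into overlapping windows of the matrix
#' length, keeps windows with normalized score at or above the threshold,
#' and annotates each with its conservation status under the PWM's
#' high-information mask (hits failing conservation are retained with
#' `conserved = FALSE`). By default only the reference strand is scanned;
#' minus-strand conservation is evaluated on the same alignment columns.
#'
#' @param region an [aligned_region].
#' @param x a [pwm] object.
#' @param threshold normalized score threshold in \[0, 1\].
#' @param both_strands also scan the reverse complement.
#' @param min_species,required_species passed to [is_conserved()].
#' @return a motif-hit data.frame; empty when the region is shorter than
#'   the matrix.
#' @export
scan_region <- function(region, x, threshold, both_strands = FALSE,
                        min_species = 4L, required_species = NULL) {
  stopifnot(inherits(x, "pwm"), threshold >= 0, threshold <= 1)
  codes <- encode_dna(region$ref_seq)
  L <- ncol(x$counts)
  res <- list()
  sc <- score_codes(codes, x)
  keep <- which(sc >= threshold)
  if (length(keep))
    res[["+"]] <- data.frame(region_id = region$region_id, pwm_id = x$id,
                             offset = keep - 1L, strand = "+", width = L,
                             normalized_score = sc[keep])
  if (both_strands) {
    scm <- rev(score_codes(revcomp_codes(codes), x))
    keep <- which(scm >= threshold)
    if (length(keep))
      res[["-"]] <- data.frame(region_id = region$region_id, pwm_id = x$id,
                               offset = keep - 1L, strand = "-", width = L,
                               normalized_score = scm[keep])
  }
  if (length(res) == 0L)
    return(data.frame(region_id = character(0), pwm_id = character(0),
                      offset = integer(0), strand = character(0),
                      width = integer(0), normalized_score = numeric(0),
                      conserved = logical(0)))
  out <- do.call(rbind, res)
  mask <- x$ic_mask
  ## minus-strand hits use the reversed mask on reference columns
  out$conserved <- vapply(seq_len(nrow(out)), function(i) {
    m <- if (out$strand[i] == "-") rev(mask) else mask
    is_conserved(region, out$offset[i], L, m, min_species, required_species)
  }, NA)
  rownames(out) <- NULL
  out[order(out$offset), , drop = FALSE]
}

#' Per-region presence/absence matrix of conserved PWM hits
#'
#' A cell is 1 when the region carries at least one conserved hit of the
#' PWM at the chosen stringency threshold, otherwise 0.
#'
#' @param regions list of [aligned_region] objects.
#' @param pwms list of [pwm] objects.
#' @param thresholds a `threshold_set` from [calibrate_thresholds()]
#'   covering every PWM.
#' @param stringency one of `"minFN"`, `"minSum"`, `"minFP"`.
#' @param both_strands,min_species,required_species scan policy, as in
#'   [scan_region()].
#' @return binary integer matrix, rows = regions, columns = PWM ids.
#' @export
presence_matrix <- function(regions, pwms, thresholds,
                            stringency = c("minSum", "minFN", "minFP"),
                            both_strands = FALSE, min_species = 4L,
                            required_species = NULL) {
  stringency <- match.arg(stringency)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  thr <- vapply(pwms, function(p)
    threshold_for(thresholds, p$id, stringency), 0)
  mat <- matrix(0L, nrow = length(regions), ncol = length(pwms),
                dimnames = list(vapply(regions, `[[`, "", "region_id"),
                                vapply(pwms, `[[`, "", "id")))
  for (r in seq_along(regions)) {
    region <- regions[[r]]
    codes <- encode_dna(region$ref_seq)
    for (k in seq_along(pwms)) {
      x <- pwms[[k]]
      L <- ncol(x$counts)
      if (length(codes) < L) next
      cand <- score_codes(codes, x)
      idx <- which(cand >= thr[k])
      strands <- rep("+", length(idx))
      if (both_strands) {
        scm <- rev(score_codes(revcomp_codes(codes), x))
        idxm <- which(scm >= thr[k])
        ord <- order(c(-cand[idx], -scm[idxm]))
        strands <- c(strands, rep("-", length(idxm)))[ord]
        idx <- c(idx, idxm)[ord]
      } else if (length(idx)) {
        ord <- order(-cand[idx])
        idx <- idx[ord]
      }
      for (j in seq_along(idx)) {   # best-scoring first, short-circuit
        m <- if (strands[j] == "-") rev(x$ic_mask) else x$ic_mask
        if (is_conserved(region, idx[j] - 1L, L, m, min_species,
                         required_species)) {
          mat[r, k] <- 1L
          break
        }
      }
    }
  }
  mat
}

#' Write motif hits as BED6
#'
#' Scores are `1000 * normalized_score`, the BED convention.
#'
#' @param hits a motif-hit data.frame with genomic coordinates (columns
#'   `chrom`, `start` added by the caller or derived from a region).
#' @param region the [aligned_region] the hits came from (supplies
#'   coordinates when `hits` has none).
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, region = NULL) {
  if (!is.null(region)) {
    hits$chrom <- region$chrom
    hits$start <- region$start + hits$offset
  }
  bed <- data.frame(chrom = hits$chrom, start = hits$start,
                    end = hits$start + hits$width,
                    name = paste(hits$region_id, hits$pwm_id, sep = "|"),
                    score = round(1000 * hits$normalized_score),
                    strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
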
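## Core and background HRE region sets: cross-study overlap, conserved
## HBS identification, phastCons-style extension, induction filtering,
## location annotation and matched background sampling.

regions_to_granges <- function(x) {
  if (inherits(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
  extra <- setdiff(names(x), c("chrom", "start", "end"))
  if (length(extra))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(x[extra])
  gr
}

granges_to_regions <- function(gr) {
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  mc <- S4Vectors::mcols(gr)
  if (ncol(mc)) out <- cbind(out, as.data.frame(mc))
  rownames(out) <- NULL
  out
}

#' Read / write BED interval files
#'
#' Plain BED on disk; 0-based half-open internally.
#'
#' @param path BED file.
#' @return `read_bed`: a data.frame with `chrom`, `start`, `end` and any
#'   name/score/strand columns present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  granges_to_regions(gr)
}

#' @rdname read_bed
#' @param x data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optional `name`, `score`, `strand` columns.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  ## BED columns are positional: fill gaps up to the last present column
  want <- c("chrom", "start", "end", "name", "score", "strand")
  upto <- max(match(cols, want))
  out <- x[want[seq_len(upto)][want[seq_len(upto)] %in% names(x)]]
  if (upto >= 4 && is.null(x$name)) out$name <- "."
  if (upto >= 5 && is.null(x$score)) out$score <- 0
  out <- out[intersect(want, names(out))]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Cross-study overlap: binding regions supported by several studies
#'
#' Walks the studies in the given order; a candidate region is kept when it
#' overlaps (by at least 1 bp) regions in at least `min_studies` studies,
#' counting its own. Candidates overlapping an already-kept region from an
#' earlier study are collapsed onto it, so `min_studies = 1` returns the
#' union with study-order precedence.
#'
#' @param binding_sets named list (study -> region data.frame with `chrom`,
#'   `start`, `end`, 0-based half-open).
#' @param min_studies minimum number of supporting studies (default 2).
#' @return region data.frame with a `support` column.
#' @export
overlap_core <- function(binding_sets, min_studies = 2L) {
  stopifnot(length(binding_sets) >= 1L)
  grl <- lapply(binding_sets, regions_to_granges)
  ## shared seqlevels so cross-study overlap and concatenation are silent
  lvls <- unique(unlist(lapply(grl, GenomeInfoDb::seqlevels)))
  grl <- lapply(grl, function(g) {
    GenomeInfoDb::seqlevels(g) <- lvls
    g
  })
  kept <- NULL
  rows <- list()
  for (s in seq_along(grl)) {
    gr <- grl[[s]]
    if (length(gr) == 0L) next
    support <- rowSums(matrix(vapply(grl, function(other)
      IRanges::overlapsAny(gr, other), logical(length(gr))),
      nrow = length(gr)))
    pass <- support >= min_studies
    if (!is.null(kept)) pass <- pass & !IRanges::overlapsAny(gr, kept)
    if (any(pass)) {
      sel <- gr[pass]
      df <- granges_to_regions(sel)
      df$study <- names(binding_sets)[s]
      df$support <- support[pass]
      rows[[length(rows) + 1L]] <- df
      kept <- if (is.null(kept)) sel else c(kept, sel)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), study = character(0),
                      support = integer(0)))
  out <- do.call(rbind, lapply(rows, function(d)
    d[c("chrom", "start", "end", "study", "support")]))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Evolutionarily conserved HIF binding sites in a region
#'
#' RCGTG occurrences that fall wholly inside a conserved element and pass
#' the cross-species conservation filter (all five positions checked).
#'
#' @param region an [aligned_region].
#' @param elements conserved-element intervals (data.frame `chrom`,
#'   `start`, `end`, 0-based half-open), e.g. a phastCons-style track.
#' @param min_species,required_species passed to [is_conserved()].
#' @param both_strands search both strands (default TRUE).
#' @return motif-hit data.frame with genomic `chrom`/`start`/`end` columns.
#' @export
conserved_hbs <- function(region, elements, min_species = 4L,
                          required_species = NULL, both_strands = TRUE) {
  hits <- find_rcgtg(region, both_strands = both_strands)
  if (nrow(hits) == 0L) return(hits)
  hits$chrom <- region$chrom
  hits$start <- region$start + hits$offset
  hits$end <- hits$start + hits$width
  inside <- rep(FALSE, nrow(hits))
  if (!is.null(elements) && nrow(elements)) {
    el <- elements[elements$chrom == region$chrom, , drop = FALSE]
    if (nrow(el))
      inside <- vapply(seq_len(nrow(hits)), function(i)
        any(hits$start[i] >= el$start & hits$end[i] <= el$end), NA)
  }
  hits <- hits[inside, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  hits$conserved <- vapply(seq_len(nrow(hits)), function(i)
    is_conserved(region, hits$offset[i], hits$width[i], NULL,
                 min_species, required_species), NA)
  out <- hits[hits$conserved, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extend an HBS into an HIF binding region over conserved sequence
#'
#' Grows the interval symmetrically in `step`-bp increments while the
#' fraction of the whole candidate span covered by conserved elements
#' stays above `min_coverage`, stopping at `max_span`. The result always
#' contains the seed HBS; with no element overlap at all the HBS itself is
#' returned.
#'
#' @param hbs one row of a genomic hit table (needs `chrom`, `start`,
#'   `end`), or a list with those fields.
#' @param elements conserved-element intervals (data.frame).
#' @param min_coverage minimum covered fraction (default 0.5, i.e. the
#'   ">50% presence" rule).
#' @param step growth increment per side, bp (default 10).
#' @param max_span maximum region span, bp (default 2000).
#' @return list with `chrom`, `start`, `end`, `coverage`.
#' @export
extend_region <- function(hbs, elements, min_coverage = 0.5, step = 10L,
                          max_span = 2000L) {
  chrom <- hbs$chrom; lo <- hbs$start; hi <- hbs$end
  el <- if (is.null(elements) || nrow(elements) == 0L)
    data.frame(start = integer(0), end = integer(0))
  else elements[elements$chrom == chrom, c("start", "end"), drop = FALSE]
  coverage <- function(a, b) {
    if (nrow(el) == 0L) return(0)
    cov <- sum(pmax(0, pmin(el$end, b) - pmax(el$start, a)))
    cov / (b - a)
  }
  repeat {
    cand <- c(lo - step, hi + step)
    if (cand[2] - cand[1] > max_span) break
    if (coverage(cand[1], cand[2]) <= min_coverage) break
    lo <- cand[1]; hi <- cand[2]
  }
  list(chrom = chrom, start = lo, end = hi, coverage = coverage(lo, hi))
}

#' Keep regions whose gene is robustly induced by hypoxia
#'
#' @param regions region data.frame carrying a `gene_id` column.
#' @param meta_calls data.frame (`gene_id`, `combined_p`, `adj_p`) from
#'   [combine_datasets()].
#' @param max_fdr FDR-adjusted p-value gate (default 0.02).
#' @return the retained regions; regions whose gene is absent from
#'   `meta_calls` are dropped with a warning.
#' @export
filter_by_induction <- function(regions, meta_calls, max_fdr = 0.02) {
  stopifnot("gene_id" %in% names(regions))
  i <- match(regions$gene_id, meta_calls$gene_id)
  if (anyNA(i))
    warning(sum(is.na(i)), " region(s) dropped: gene not in meta-analysis (",
            paste(unique(regions$gene_id[is.na(i)])[1:min(3, sum(is.na(i)))],
                  collapse = ", "), " ...)")
  keep <- !is.na(i) & meta_calls$adj_p[i] <= max_fdr
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate the genomic location class of a region
#'
#' Promoter when the region midpoint lies within `promoter_bp` upstream of
#' a TSS (through the TSS); otherwise the class of the overlapped feature
#' with precedence promoter > 5'UTR > intron > 3'UTR; regions overlapping
#' nothing fall back to the nearest TSS's promoter class (logged).
#'
#' @param region list or one-row data.frame with `chrom`, `start`, `end`.
#' @param gene_model data.frame (`chrom`, `start`, `end`, `gene_id`,
#'   `strand`, `feature`) with feature in tss/utr5/intron/utr3; tss rows
#'   are 1-bp intervals at the transcription start.
#' @param promoter_bp promoter window upstream of the TSS (default 2000).
#' @return list with `location_class` (promoter/UTR5/intron/UTR3) and
#'   `gene_id`.
#' @export
annotate_location <- function(region, gene_model, promoter_bp = 2000L) {
  mid <- (region$start + region$end) %/% 2
  gm <- gene_model[gene_model$chrom == region$chrom, , drop = FALSE]
  tss <- gm[gm$feature == "tss", , drop = FALSE]
  if (nrow(tss)) {
    up <- ifelse(tss$strand == "-",
                 mid >= tss$start & mid < tss$start + promoter_bp,
                 mid >= tss$start - promoter_bp & mid <= tss$start)
    if (any(up)) {
      g <- tss$gene_id[which(up)[1L]]
      return(list(location_class = "promoter", gene_id = g))
    }
  }
  for (cls in c("utr5", "intron", "utr3")) {
    f <- gm[gm$feature == cls & gm$start <= mid & mid < gm$end, , drop = FALSE]
    if (nrow(f))
      return(list(location_class = c(utr5 = "UTR5", intron = "intron",
                                     utr3 = "UTR3")[[cls]],
                  gene_id = f$gene_id[1L]))
  }
  if (nrow(tss) == 0L)
    stop("gene model has no TSS on ", region$chrom)
  j <- which.min(abs(tss$start - mid))
  message("region at ", region$chrom, ":", region$start,
          " overlaps no feature; assigned to nearest-gene promoter")
  list(location_class = "promoter", gene_id = tss$gene_id[j])
}

#' Build the matched background region set
#'
#' Candidates qualify when, in every expression dataset, every probe of
#' their gene has a mean log-fold value within `tolerance_sd` standard
#' deviations of that dataset's global mean (genes not modulated by
#' hypoxia). From the qualifying pool, a seeded sample is drawn without
#' replacement whose genomic-location-class proportions match the core
#' set's; classes short of candidates contribute everything they have,
#' with a warning. Genes present in the core set are excluded. A GC
#' summary of both sets is attached for base-composition reporting.
#'
#' @param candidates candidate region data.frame with `gene_id` and
#'   `location_class` columns (and optionally `gc`).
#' @param fold_tables list (one per dataset) of data.frames (`gene_id`,
#'   `probe_id`, `fold`) of per-probe mean log-fold values.
#' @param core the core region data.frame (needs `gene_id`,
#'   `location_class`, optionally `gc`).
#' @param tolerance_sd half-width of the acceptance band in SD units
#'   (default 0.25).
#' @param size target background size (default 3500, capped at the
#'   eligible pool).
#' @param seed integer seed for the stratified sample.
#' @return background region data.frame labelled `background`, with a
#'   `matching_report` attribute (class counts and GC summaries).
#' @export
build_background <- function(candidates, fold_tables, core,
                             tolerance_sd = 0.25, size = 3500L, seed = 1L) {
  stopifnot(all(c("gene_id", "location_class") %in% names(candidates)))
  eligible_gene <- function(g) {
    for (tab in fold_tables) {
      mu <- mean(tab$fold, na.rm = TRUE)
      sdv <- sd(tab$fold, na.rm = TRUE)
      probes <- tab$fold[tab$gene_id == g]
      if (length(probes) == 0L) next
      if (any(abs(probes - mu) >= tolerance_sd * sdv, na.rm = TRUE))
        return(FALSE)
    }
    TRUE
  }
  genes <- unique(candidates$gene_id)
  ok_genes <- genes[vapply(genes, eligible_gene, NA)]
  ok_genes <- setdiff(ok_genes, unique(core$gene_id))
  pool <- candidates[candidates$gene_id %in% ok_genes, , drop = FALSE]
  core_tab <- table(core$location_class)
  props <- core_tab / sum(core_tab)
  size <- min(size, nrow(pool))
  want <- round(props * size)
  set.seed(seed)
  picked <- list()
  for (cls in names(want)) {
    idx <- which(pool$location_class == cls)
    k <- want[[cls]]
    if (length(idx) < k) {
      warning("background class '", cls, "': only ", length(idx),
              " candidates for a target of ", k)
      k <- length(idx)
    }
    picked[[cls]] <- idx[sample.int(length(idx), k)]
  }
  out <- pool[sort(unlist(picked)), , drop = FALSE]
  out$label <- "background"
  rownames(out) <- NULL
  report <- list(
    core_classes = as.data.frame(core_tab),
    background_classes = as.data.frame(table(out$location_class)),
    core_gc = if ("gc" %in% names(core)) summary(core$gc) else NULL,
    background_gc = if ("gc" %in% names(out)) summary(out$gc) else NULL)
  attr(out, "matching_report") <- report
  out
}
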
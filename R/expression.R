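## Per-dataset induction and basal-expression calls, cross-dataset
## combination, and the basal-expression association analyses.

#' Construct an expression dataset
#'
#' @param dataset_id identifier.
#' @param probes data.frame with `probe_id`, `gene_id`.
#' @param norm,hyp numeric matrices of normoxic / hypoxic replicate raw
#'   signals (one row per probe; NAs are null measurements).
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, probes, norm, hyp) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probes)),
            nrow(probes) >= 1L,
            nrow(norm) == nrow(probes), nrow(hyp) == nrow(probes),
            ncol(norm) >= 1L, ncol(hyp) >= 1L)
  structure(list(dataset_id = dataset_id, probes = probes,
                 norm = as.matrix(norm), hyp = as.matrix(hyp)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset '%s': %d probes, %d+%d replicates\n",
              x$dataset_id, nrow(x$probes), ncol(x$norm), ncol(x$hyp)))
  invisible(x)
}

#' Read / write expression datasets as TSV
#'
#' Columns: `probe_id`, `gene_id`, `norm_r1..rk`, `hyp_r1..rk`; empty
#' cells are null signals.
#'
#' @param path TSV file.
#' @param dataset_id identifier (defaults to the file name).
#' @return an [expression_dataset].
#' @export
read_expression_tsv <- function(path, dataset_id = basename(path)) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  nc <- grep("^norm_", names(d)); hc <- grep("^hyp_", names(d))
  expression_dataset(dataset_id, d[c("probe_id", "gene_id")],
                     as.matrix(d[nc]), as.matrix(d[hc]))
}

#' @rdname read_expression_tsv
#' @param ds an [expression_dataset].
#' @export
write_expression_tsv <- function(ds, path) {
  norm <- as.data.frame(ds$norm); hyp <- as.data.frame(ds$hyp)
  names(norm) <- paste0("norm_r", seq_len(ncol(norm)))
  names(hyp) <- paste0("hyp_r", seq_len(ncol(hyp)))
  write.table(cbind(ds$probes[c("probe_id", "gene_id")], norm, hyp),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average replicate signals with the null-majority rule
#'
#' Mean of the non-null values, unless half or more of the replicates are
#' null, in which case the average is null.
#'
#' @param signals numeric vector with NAs for null measurements.
#' @return scalar mean, or NA.
#' @export
average_replicates <- function(signals) {
  stopifnot(length(signals) >= 1L)
  if (mean(is.na(signals)) >= 0.5) return(NA_real_)
  mean(signals, na.rm = TRUE)
}

row_average <- function(m) apply(m, 1L, average_replicates)

#' Call hypoxic induction within one dataset
#'
#' Per probe, the log2 ratio of averaged hypoxic over normoxic signal. A
#' probe is induced when its log-ratio exceeds the dataset mean log-ratio
#' by `sd_factor` standard deviations (mean and SD over all non-null
#' log-ratios), or when its normoxic average is null while the hypoxic one
#' is not. Basal expression is significant iff the normoxic average is
#' non-null.
#'
#' @param ds an [expression_dataset].
#' @param sd_factor induction stringency in SD units (default 2.6).
#' @return data.frame (`probe_id`, `gene_id`, `basal` =
#'   "significant"/"null", `induced`, `log_ratio`), one row per probe.
#' @export
call_induction <- function(ds, sd_factor = 2.6) {
  norm <- row_average(ds$norm)
  hyp <- row_average(ds$hyp)
  lr <- ifelse(!is.na(norm) & !is.na(hyp) & norm > 0 & hyp > 0,
               log2(hyp / norm), NA_real_)
  if (all(is.na(lr)))
    warning("dataset '", ds$dataset_id, "': all log-ratios are null")
  mu <- mean(lr, na.rm = TRUE)
  sdv <- sd(lr, na.rm = TRUE)
  cutoff <- mu + sd_factor * sdv
  induced <- (!is.na(lr) & lr > cutoff) | (is.na(norm) & !is.na(hyp))
  data.frame(probe_id = ds$probes$probe_id, gene_id = ds$probes$gene_id,
             basal = ifelse(is.na(norm), "null", "significant"),
             induced = induced, log_ratio = lr,
             stringsAsFactors = FALSE)
}

#' Combine induction evidence across datasets
#'
#' Per gene and dataset, the evidence is the standardized log-ratio
#' \eqn{z = (LR - \bar{LR}) / SD} of the gene's best probe (zero where the
#' log-ratio is null). Evidence is combined across datasets by Stouffer's
#' method (default), \eqn{Z = \sum z / \sqrt{k}} with a one-sided p-value,
#' or Fisher's method on the per-dataset one-sided p-values;
#' Benjamini-Hochberg adjustment is applied over genes.
#'
#' @param calls named list (dataset -> data.frame from [call_induction()]).
#' @param method `"stouffer"` (default) or `"fisher"`.
#' @return data.frame (`gene_id`, `z`, `combined_p`, `adj_p`,
#'   `n_datasets`), sorted by combined p.
#' @export
combine_datasets <- function(calls, method = c("stouffer", "fisher")) {
  method <- match.arg(method)
  stopifnot(length(calls) >= 1L)
  per_ds <- lapply(calls, function(d) {
    mu <- mean(d$log_ratio, na.rm = TRUE)
    sdv <- sd(d$log_ratio, na.rm = TRUE)
    z <- ifelse(is.na(d$log_ratio), 0, (d$log_ratio - mu) / sdv)
    ## best probe per gene
    tapply(z, d$gene_id, max)
  })
  genes <- unique(unlist(lapply(per_ds, names), use.names = FALSE))
  zmat <- vapply(per_ds, function(v) v[genes], numeric(length(genes)))
  zmat <- matrix(zmat, nrow = length(genes),
                 dimnames = list(genes, names(calls)))
  k <- rowSums(!is.na(zmat))
  if (any(k == 0L)) { zmat <- zmat[k > 0L, , drop = FALSE]; k <- k[k > 0L] }
  if (method == "stouffer") {
    Z <- rowSums(zmat, na.rm = TRUE) / sqrt(k)
    p <- pnorm(Z, lower.tail = FALSE)
  } else {
    pmat <- pnorm(zmat, lower.tail = FALSE)
    X <- rowSums(-2 * log(pmat), na.rm = TRUE)
    p <- pchisq(X, df = 2 * k, lower.tail = FALSE)
    Z <- qnorm_safe(p)
  }
  out <- data.frame(gene_id = rownames(zmat), z = Z, combined_p = p,
                    adj_p = p.adjust(p, method = "BH"), n_datasets = k,
                    stringsAsFactors = FALSE)
  out <- out[order(out$combined_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

qnorm_safe <- function(p) stats::qnorm(pmin(pmax(p, 1e-300), 1), lower.tail = FALSE)

#' Association of basal expression and HBS presence with hypoxic induction
#'
#' For each dataset, the percentage of target genes induced by hypoxia is
#' compared between the basal-significant and basal-null strata; the two
#' per-dataset percentages are compared across datasets with a paired
#' Wilcoxon signed-rank test, and the pooled 2x2 (basal x induced) table
#' with an uncorrected chi-square test. When `hbs_genes` is given, the
#' four-way classification of basal-significant genes by conserved-HBS
#' presence and induction is reported per dataset (percentages summing to
#' 100).
#'
#' @param calls named list of [call_induction()] tables.
#' @param target_genes genes to stratify (default: all genes).
#' @param hbs_genes genes carrying a conserved HBS, or NULL.
#' @return list with `per_dataset`, `wilcoxon_p`, `chisq_stat`, `chisq_p`,
#'   `pooled` (the 2x2 table) and `fourway` (or NULL).
#' @export
basal_association <- function(calls, target_genes = NULL, hbs_genes = NULL) {
  stopifnot(length(calls) >= 2L)
  per <- lapply(names(calls), function(nm) {
    d <- calls[[nm]]
    if (!is.null(target_genes)) d <- d[d$gene_id %in% target_genes, ]
    sig <- d[d$basal == "significant", ]
    nul <- d[d$basal == "null", ]
    data.frame(dataset = nm,
               pct_induced_basal = 100 * mean(sig$induced),
               pct_induced_null = 100 * mean(nul$induced),
               n_basal = nrow(sig), n_null = nrow(nul))
  })
  per <- do.call(rbind, per)
  usable <- per$n_basal > 0 & per$n_null > 0
  if (!all(usable))
    message(sum(!usable), " dataset(s) excluded from the paired test ",
            "(empty stratum)")
  diffs <- per$pct_induced_basal[usable] - per$pct_induced_null[usable]
  wp <- if (sum(usable) < 2) NA_real_
  else if (all(abs(diffs) < 1e-12)) 1   # no signal in any dataset
  else suppressWarnings(wilcox.test(per$pct_induced_basal[usable],
                                    per$pct_induced_null[usable],
                                    paired = TRUE))$p.value
  pooled <- matrix(0, 2, 2, dimnames = list(basal = c("significant", "null"),
                                            induced = c("yes", "no")))
  for (d in calls) {
    if (!is.null(target_genes)) d <- d[d$gene_id %in% target_genes, ]
    pooled["significant", "yes"] <- pooled["significant", "yes"] +
      sum(d$basal == "significant" & d$induced)
    pooled["significant", "no"] <- pooled["significant", "no"] +
      sum(d$basal == "significant" & !d$induced)
    pooled["null", "yes"] <- pooled["null", "yes"] +
      sum(d$basal == "null" & d$induced)
    pooled["null", "no"] <- pooled["null", "no"] +
      sum(d$basal == "null" & !d$induced)
  }
  cs <- suppressWarnings(chisq.test(pooled, correct = FALSE))
  fourway <- NULL
  if (!is.null(hbs_genes)) {
    fourway <- do.call(rbind, lapply(names(calls), function(nm) {
      d <- calls[[nm]]
      d <- d[d$basal == "significant", ]
      hbs <- d$gene_id %in% hbs_genes
      n <- nrow(d)
      data.frame(dataset = nm,
                 NoHBS_notInduced = 100 * sum(!hbs & !d$induced) / n,
                 NoHBS_Induced = 100 * sum(!hbs & d$induced) / n,
                 HBS_notInduced = 100 * sum(hbs & !d$induced) / n,
                 HBS_Induced = 100 * sum(hbs & d$induced) / n)
    }))
  }
  list(per_dataset = per, wilcoxon_p = wp,
       chisq_stat = unname(cs$statistic), chisq_p = cs$p.value,
       pooled = pooled, fourway = fourway)
}
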
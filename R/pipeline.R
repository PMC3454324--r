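## Pipeline orchestration: simulate inputs, run stages, report. A thin
## command-line wrapper over these functions ships in inst/cli/hrescan.

#' Read / write a pipeline configuration
#'
#' YAML with per-stage sections; missing fields fall back to the
#' [sim_config()] and stage defaults (the printed parameters of the
#' method: 2.6 SD induction, 60% IC mask, winHalfSize 100, quant 0.75,
#' distCutOff 200, minProbesInRow 4, FDR gates 0.02, 0.99 null quantile,
#' 0.25 SD background band, Fisher alpha 0.05, 90% detection, 1 hit per
#' 10000 bp).
#'
#' @param path YAML file.
#' @return a `sim_config`-compatible list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(sim_config, raw)
}

#' @rdname read_config
#' @param config a [sim_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

manifest_entry <- function(outdir, stage, t0, outputs, config) {
  list(stage = stage,
       elapsed_s = round(as.numeric(Sys.time()) - t0, 2),
       outputs = outputs,
       digests = as.list(tools::md5sum(file.path(outdir, outputs))),
       seed = config$seed,
       version = as.character(utils::packageVersion("hrescan")))
}

write_manifest <- function(outdir, entries, config) {
  jsonlite::write_json(
    list(config = unclass(config), stages = entries),
    file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Generate a complete synthetic dataset directory
#'
#' Writes aligned regions (multi-FASTA), conserved elements and region
#' tables (BED/TSV), a tiling probe table, expression TSVs, the truth
#' files, and a run manifest with input digests.
#'
#' @param config a [sim_config()] or path to a YAML config.
#' @param outdir output directory (created).
#' @return `outdir`, invisibly.
#' @export
cmd_simulate <- function(config = sim_config(), outdir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  aln <- gen_alignment_set(config)
  write_aligned_fasta(aln$core, file.path(outdir, "core.aln.fa"))
  write_aligned_fasta(aln$background, file.path(outdir, "background.aln.fa"))
  write_bed(aln$elements, file.path(outdir, "conserved_elements.bed"))
  write.table(aln$regions, file.path(outdir, "regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(aln$truth, file.path(outdir, "truth_motifs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  til <- gen_tiling_experiment(config)
  write_probe_table(til$track, file.path(outdir, "tiling_probes.tsv"))
  write_bed(til$truth, file.path(outdir, "truth_bound_regions.bed"))
  ex <- gen_expression_datasets(config)
  for (ds in ex$datasets)
    write_expression_tsv(ds, file.path(outdir,
                                       paste0("expr_", ds$dataset_id, ".tsv")))
  writeLines(ex$induced_genes, file.path(outdir, "truth_induced_genes.txt"))
  outputs <- list.files(outdir, pattern = "\\.(fa|bed|tsv|txt)$")
  write_manifest(outdir, list(manifest_entry(outdir, "simulate", t0,
                                             outputs, config)), config)
  invisible(outdir)
}

#' Run analysis stages on a simulated dataset directory
#'
#' Stages: `calibrate` (MATCH thresholds for the planted PWM and its
#' decoys), `scan` (conservation-filtered presence matrix),
#' `call-regions` (tiling-array enriched regions), `expression`
#' (induction calls and cross-dataset combination), `enrich` (Fisher
#' enrichment and CFS selection counts). Each stage writes its outputs
#' plus a manifest entry; missing upstream outputs raise an error naming
#' the producing stage.
#'
#' The `build-sets` stage locates the conserved HBS of every simulated
#' region, extends it over the conserved element into an HIF binding
#' region, and writes `core.bed` / `background.bed`.
#'
#' @param outdir a directory produced by [cmd_simulate()].
#' @param stages subset of stages, in order (default: all).
#' @param config the [sim_config()] used for simulation (or YAML path).
#' @param stringency presence-matrix stringency (default `"minSum"`).
#' @return `outdir`, invisibly.
#' @export
cmd_run <- function(outdir,
                    stages = c("calibrate", "scan", "build-sets",
                               "call-regions", "expression", "enrich"),
                    config = sim_config(),
                    stringency = "minSum") {
  if (is.character(config)) config <- read_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  need <- function(f, producer) {
    p <- file.path(outdir, f)
    if (!file.exists(p))
      stop("missing '", f, "': run the '", producer, "' stage first")
    p
  }
  entries <- list()
  planted <- tgacgtca_pwm()
  pwms <- c(list(planted),
            gen_decoy_pwms(planted, config$n_decoys, seed = config$seed))
  if ("calibrate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    thr <- calibrate_thresholds(pwms, seed = config$seed)
    write_thresholds(thr, file.path(outdir, "thresholds.tsv"))
    entries <- c(entries, list(manifest_entry(outdir, "calibrate", t0,
                                              "thresholds.tsv", config)))
  }
  if ("scan" %in% stages) {
    t0 <- as.numeric(Sys.time())
    thr <- read_thresholds(need("thresholds.tsv", "calibrate"))
    core <- read_aligned_fasta(need("core.aln.fa", "simulate"))
    bg <- read_aligned_fasta(need("background.aln.fa", "simulate"))
    pm <- presence_matrix(c(core, bg), pwms, thr, stringency = stringency)
    labels <- rep(c("core", "background"), c(length(core), length(bg)))
    out <- data.frame(region_id = rownames(pm), label = labels,
                      as.data.frame(pm), check.names = FALSE)
    write.table(out, file.path(outdir, "presence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    entries <- c(entries, list(manifest_entry(outdir, "scan", t0,
                                              "presence.tsv", config)))
  }
  if ("build-sets" %in% stages) {
    t0 <- as.numeric(Sys.time())
    elements <- read_bed(need("conserved_elements.bed", "simulate"))
    for (set in c("core", "background")) {
      regs <- read_aligned_fasta(need(paste0(set, ".aln.fa"), "simulate"))
      rows <- lapply(regs, function(r) {
        hbs <- conserved_hbs(r, elements)
        if (nrow(hbs) == 0L) return(NULL)
        ext <- extend_region(hbs[1L, ], elements)
        data.frame(chrom = ext$chrom, start = ext$start, end = ext$end,
                   name = r$region_id)
      })
      write_bed(do.call(rbind, rows), file.path(outdir,
                                                paste0(set, ".bed")))
    }
    entries <- c(entries, list(manifest_entry(
      outdir, "build-sets", t0, c("core.bed", "background.bed"), config)))
  }
  if ("call-regions" %in% stages) {
    t0 <- as.numeric(Sys.time())
    track <- read_probe_table(need("tiling_probes.tsv", "simulate"))
    track <- probe_statistics(track)
    track <- smooth_signal(track)
    regions <- call_regions(track, null_threshold(track))
    write.table(regions, file.path(outdir, "chip_regions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    entries <- c(entries, list(manifest_entry(outdir, "call-regions", t0,
                                              "chip_regions.tsv", config)))
  }
  if ("expression" %in% stages) {
    t0 <- as.numeric(Sys.time())
    files <- list.files(outdir, pattern = "^expr_.*\\.tsv$",
                        full.names = TRUE)
    if (length(files) == 0L)
      stop("missing 'expr_*.tsv': run the 'simulate' stage first")
    calls <- lapply(files, function(f) call_induction(read_expression_tsv(f)))
    names(calls) <- sub("^expr_(.*)\\.tsv$", "\\1", basename(files))
    combined <- combine_datasets(calls)
    write.table(combined, file.path(outdir, "meta_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    entries <- c(entries, list(manifest_entry(outdir, "expression", t0,
                                              "meta_calls.tsv", config)))
  }
  if ("enrich" %in% stages) {
    t0 <- as.numeric(Sys.time())
    pres <- read.delim(need("presence.tsv", "scan"), check.names = FALSE)
    labels <- pres$label
    mat <- as.matrix(pres[setdiff(names(pres), c("region_id", "label"))])
    enr <- fisher_enrichment(mat, labels)
    write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sel <- cfs_cross_validate(mat, labels, seed = config$seed)
    write.table(sel, file.path(outdir, "selection.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    entries <- c(entries, list(manifest_entry(
      outdir, "enrich", t0, c("enrichment.tsv", "selection.tsv"), config)))
  }
  prev <- file.path(outdir, "manifest.json")
  if (file.exists(prev)) {
    old <- jsonlite::read_json(prev)
    entries <- c(old$stages, entries)
  }
  write_manifest(outdir, entries, config)
  invisible(outdir)
}

#' Summarize a completed run
#'
#' @param outdir a run directory.
#' @return list with `enrichment` and `selection` tables (the Fisher and
#'   CFS reports), `chip_regions`, `meta_calls` and `stages` — whatever
#'   the completed stages produced; also written as `report.json`.
#' @export
cmd_report <- function(outdir) {
  grab <- function(f) {
    p <- file.path(outdir, f)
    if (file.exists(p)) read.delim(p, check.names = FALSE) else NULL
  }
  man <- file.path(outdir, "manifest.json")
  stages <- if (file.exists(man))
    vapply(jsonlite::read_json(man)$stages, `[[`, "", "stage")
  else character(0)
  if (length(stages) == 0L)
    message("no completed stages in ", outdir)
  rep <- list(stages = stages,
              enrichment = grab("enrichment.tsv"),
              selection = grab("selection.tsv"),
              chip_regions = grab("chip_regions.tsv"),
              meta_calls = grab("meta_calls.tsv"))
  jsonlite::write_json(rep, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(rep)
}
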
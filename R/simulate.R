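## Synthetic-data generators: every input the pipeline consumes, with
## known ground truth, reproducible bit-for-bit under a seed.

#' Simulation configuration
#'
#' Bundles the defaults of all generators: 120 core versus 3500 background
#' regions of 400 bp across five mammalian species, a high-information
#' TGACGTCA-like cooperating motif planted (conserved) in 30% of core and
#' 10% of background regions, tiling tracks of 80 bp-spaced probes with
#' four replicates, and expression datasets with 5% hypoxia-induced genes.
#'
#' @param seed master seed.
#' @param n_core,n_background region counts.
#' @param species species names, reference first (default human, chimp,
#'   dog, cow, mouse).
#' @param region_length region length in bp.
#' @param gc reference base composition.
#' @param core_rate,background_rate planting rates of the cooperating
#'   motif per region class.
#' @param conserved_fraction fraction of planted instances that are
#'   conserved across species (non-conserved copies get their mouse row
#'   scrambled over the motif).
#' @param conservation_noise per-species substitution rate outside planted
#'   and conserved positions.
#' @param n_decoys number of IC-matched column-shuffled decoy PWMs.
#' @param tiling list: `n_probes`, `spacing`, `probe_width`,
#'   `n_replicates`, `noise_sd`, `effect` (added log-ratio in bound
#'   regions), `n_regions`, `region_probes`.
#' @param expression list: `n_genes`, `n_datasets`, `n_replicates`,
#'   `frac_induced`, `effect_sd` (induction effect in SD units of the
#'   log-ratio distribution), `lr_sd`, `null_frac`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_core = 120L, n_background = 3500L,
                       species = c("human", "chimp", "dog", "cow", "mouse"),
                       region_length = 400L, gc = 0.42,
                       core_rate = 0.30, background_rate = 0.10,
                       conserved_fraction = 1.0,
                       conservation_noise = 0.15, n_decoys = 10L,
                       tiling = list(), expression = list()) {
  til <- utils::modifyList(list(n_probes = 2000L, spacing = 80L,
                                probe_width = 50L, n_replicates = 4L,
                                noise_sd = 0.25, effect = 0.75,
                                n_regions = 20L, region_probes = 5L),
                           tiling)
  expr <- utils::modifyList(list(n_genes = 2000L, n_datasets = 5L,
                                 n_replicates = 2L, frac_induced = 0.05,
                                 effect_sd = 4, lr_sd = 0.5,
                                 null_frac = 0.05),
                            expression)
  structure(list(seed = seed, n_core = n_core, n_background = n_background,
                 species = species, region_length = region_length, gc = gc,
                 core_rate = core_rate, background_rate = background_rate,
                 conserved_fraction = conserved_fraction,
                 conservation_noise = conservation_noise,
                 n_decoys = n_decoys, tiling = til, expression = expr),
            class = "sim_config")
}

#' The default planted cooperating motif (TGACGTCA-like)
#'
#' A high-information 8-mer position weight matrix centred on the
#' TGACGTCA palindrome (the CRE/AP1-family consensus), used as the
#' positive-control cooperating motif in synthetic region sets.
#'
#' @param id matrix id.
#' @param ... passed to [pwm()].
#' @return a [pwm].
#' @export
tgacgtca_pwm <- function(id = "PL0001_TGACGTCA", ...) {
  consensus <- c("T", "G", "A", "C", "G", "T", "C", "A")
  strength <- c(95L, 97L, 93L, 99L, 97L, 94L, 96L, 93L)  # mixed column IC
  counts <- sapply(seq_along(consensus), function(i) {
    col <- rep((100L - strength[i]) %/% 3L, 4)
    col[match(consensus[i], BASES)] <- 0L
    col[match(consensus[i], BASES)] <- 100L - sum(col)
    col
  })
  rownames(counts) <- BASES
  colnames(counts) <- NULL
  pwm(counts, id = id, name = "TGACGTCA", ...)
}

#' Generate a PWM with a target information-content profile
#'
#' Per column, mixes a random consensus base with the uniform distribution
#' and solves the mixing weight by bisection so that the column's raw
#' relative entropy (counts without pseudocount, so the full 0-2 bit range
#' is reachable) lands within 0.1 bits of the target; unreachable targets
#' get the best effort and a warning.
#'
#' @param length motif length.
#' @param ic_profile target bits per position, each in \[0, 2\]; recycled.
#' @param seed integer seed.
#' @param n_sites site count backing each column (default 100).
#' @param id matrix id.
#' @return a [pwm].
#' @export
gen_pwm <- function(length, ic_profile, seed = 1L, n_sites = 100L,
                    id = sprintf("SYN%04d", seed)) {
  stopifnot(all(ic_profile >= 0), all(ic_profile <= 2))
  set.seed(seed)
  ic_profile <- rep_len(ic_profile, length)
  counts <- matrix(0L, 4, length)
  col_ic <- function(cnt) {
    probs <- cnt / sum(cnt)
    sum(ifelse(probs > 0, probs * log2(probs / 0.25), 0))
  }
  for (i in seq_len(length)) {
    b <- sample.int(4L, 1L)
    make <- function(w) {
      p <- rep((1 - w) / 4, 4)
      p[b] <- p[b] + w
      cnt <- floor(p * n_sites)
      cnt[b] <- cnt[b] + n_sites - sum(cnt)
      cnt
    }
    lo <- 0; hi <- 1
    for (iter in 1:40) {
      mid <- (lo + hi) / 2
      if (col_ic(make(mid)) < ic_profile[i]) lo <- mid else hi <- mid
    }
    ## the floor-rounded mixing family has gaps near the consensus end;
    ## near-consensus columns fill them
    cands <- list(make(hi), make(lo))
    other <- if (b == 1L) 2L else 1L
    for (k in 0:5) {
      cnt <- rep(0L, 4); cnt[b] <- n_sites - k; cnt[other] <- k
      cands[[length(cands) + 1L]] <- cnt
    }
    dev <- vapply(cands, function(cc) abs(col_ic(cc) - ic_profile[i]), 0)
    cand <- cands[[which.min(dev)]]
    if (min(dev) > 0.1 + 1e-9)
      warning("column ", i, ": target ", ic_profile[i],
              " bits unreachable; achieved ", round(col_ic(cand), 3))
    counts[, i] <- cand
  }
  pwm(counts, id = id)
}

#' IC-matched decoy PWMs by column shuffling
#'
#' @param x the planted [pwm].
#' @param n number of decoys.
#' @param seed integer seed.
#' @return list of [pwm] objects with shuffled column order and shuffled
#'   base identity per column (information profile preserved).
#' @export
gen_decoy_pwms <- function(x, n, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    counts <- x$counts[, sample(ncol(x$counts)), drop = FALSE]
    for (i in seq_len(ncol(counts)))
      counts[, i] <- counts[sample(4L), i]
    rownames(counts) <- BASES
    pwm(counts, id = sprintf("DECOY%03d", k),
        name = sprintf("decoy %d of %s", k, x$id),
        background = x$background, ic_fraction = x$ic_fraction)
  })
}

sample_seq_codes <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample.int(4L, n, replace = TRUE, prob = p)
}

mutate_codes <- function(codes, rate, protect) {
  hit <- which(runif(length(codes)) < rate & !protect)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    codes[hit] <- ((codes[hit] - 1L + shift) %% 4L) + 1L
  }
  codes
}

#' Generate aligned core and background region sets with planted motifs
#'
#' Every region carries a central conserved RCGTG inside a generated
#' conserved element. The cooperating motif is planted (an instance
#' sampled from its corrected probabilities) at the class-specific rate;
#' conserved instances are protected from cross-species noise, while
#' non-conserved instances get the mouse row scrambled over the motif.
#' Non-reference species are mutated at `conservation_noise` everywhere
#' else.
#'
#' @param config a [sim_config()].
#' @param planted the cooperating [pwm] (default [tgacgtca_pwm()]).
#' @return list with `core` and `background` (lists of [aligned_region]),
#'   `elements` (conserved-element BED data.frame), `truth` (planted
#'   instances: region, class, pwm, offset, conserved) and `regions`
#'   (per-region metadata incl. the central HBS offset).
#' @export
gen_alignment_set <- function(config = sim_config(),
                              planted = tgacgtca_pwm()) {
  set.seed(config$seed)
  len <- config$region_length
  L <- ncol(planted$counts)
  n_all <- config$n_core + config$n_background
  labels <- rep(c("core", "background"),
                c(config$n_core, config$n_background))
  rates <- ifelse(labels == "core", config$core_rate,
                  config$background_rate)
  regions <- vector("list", n_all)
  truth <- list()
  meta <- list()
  elements <- list()
  center_off <- len %/% 2 - 2L          # central RCGTG start
  el_half <- 75L
  for (r in seq_len(n_all)) {
    rid <- sprintf("%s_%05d", labels[r], r)
    gstart <- (r - 1L) * 10000L
    ref <- sample_seq_codes(len, config$gc)
    protect <- logical(len)
    ## central HRE, conserved in all species by construction
    hre <- c(match(sample(c("A", "G"), 1L), BASES),
             match(c("C", "G", "T", "G"), BASES))
    ref[center_off + 1:5] <- hre
    protect[center_off + 1:5] <- TRUE
    plant <- runif(1) < rates[r]
    plant_off <- NA_integer_
    plant_conserved <- NA
    if (plant) {
      ## offset clear of the central HRE
      repeat {
        plant_off <- sample.int(len - L + 1L, 1L) - 1L
        if (plant_off + L <= center_off || plant_off >= center_off + 5L)
          break
      }
      inst <- vapply(seq_len(L), function(i)
        sample.int(4L, 1L, prob = planted$probs[, i]), 0L)
      ref[plant_off + seq_len(L)] <- inst
      plant_conserved <- runif(1) < config$conserved_fraction
      if (plant_conserved) protect[plant_off + seq_len(L)] <- TRUE
      truth[[length(truth) + 1L]] <- data.frame(
        region_id = rid, label = labels[r], pwm_id = planted$id,
        offset = plant_off, conserved = plant_conserved)
    }
    rows <- setNames(vector("list", length(config$species)),
                     config$species)
    rows[[1L]] <- ref
    for (s in config$species[-1L]) {
      cs <- mutate_codes(ref, config$conservation_noise, protect)
      if (s == "mouse" && isFALSE(plant_conserved)) {
        ## scramble the mouse row over the motif so conservation fails
        span <- plant_off + seq_len(L)
        cs[span] <- ((ref[span] - 1L +
                        sample.int(3L, L, replace = TRUE)) %% 4L) + 1L
      }
      rows[[s]] <- cs
    }
    rows <- vapply(rows, decode_dna, "")
    regions[[r]] <- aligned_region(rid, "chrSyn", gstart, gstart + len,
                                   rows)
    elements[[r]] <- data.frame(
      chrom = "chrSyn",
      start = gstart + center_off + 2L - el_half,
      end = gstart + center_off + 3L + el_half)
    meta[[r]] <- data.frame(region_id = rid, label = labels[r],
                            chrom = "chrSyn", start = gstart,
                            end = gstart + len,
                            hbs_offset = center_off,
                            gc = mean(ref %in% c(2L, 3L)))
  }
  list(core = regions[labels == "core"],
       background = regions[labels == "background"],
       elements = do.call(rbind, elements),
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(region_id = character(0), label = character(0),
                    pwm_id = character(0), offset = integer(0),
                    conserved = logical(0)),
       regions = do.call(rbind, meta))
}

#' Generate a replicated tiling-array experiment with planted bound regions
#'
#' Probes at fixed spacing along one chromosome; baseline log-ratios are
#' N(0, noise_sd) in every replicate, and probes inside planted regions
#' get `effect` added in all replicates.
#'
#' @param config a [sim_config()]; see the `tiling` element.
#' @return list with `track` (a [probe_track]) and `truth` (planted-region
#'   BED data.frame).
#' @export
gen_tiling_experiment <- function(config = sim_config()) {
  set.seed(config$seed + 1L)
  t <- config$tiling
  starts <- (seq_len(t$n_probes) - 1L) * t$spacing
  probes <- data.frame(probe_id = sprintf("P%06d", seq_len(t$n_probes)),
                       chrom = "chrSyn", start = starts,
                       end = starts + t$probe_width)
  ratios <- matrix(rnorm(t$n_probes * t$n_replicates, sd = t$noise_sd),
                   nrow = t$n_probes)
  ## non-adjacent probe blocks for the bound regions
  block_starts <- sort(sample.int(t$n_probes %/% (2L * t$region_probes),
                                  t$n_regions)) *
    (2L * t$region_probes) - t$region_probes + 1L
  bound <- logical(t$n_probes)
  truth <- list()
  for (b in block_starts) {
    sel <- b:(b + t$region_probes - 1L)
    bound[sel] <- TRUE
    ratios[sel, ] <- ratios[sel, ] + t$effect
    truth[[length(truth) + 1L]] <- data.frame(
      chrom = "chrSyn", start = probes$start[min(sel)],
      end = probes$end[max(sel)], n_probes = length(sel))
  }
  list(track = probe_track(probes, ratios),
       truth = do.call(rbind, truth), bound = bound)
}

#' Generate expression datasets with planted hypoxia-induced genes
#'
#' Normoxic signals are log-normal; the log2 hypoxia/normoxia ratio is
#' N(0, lr_sd) for unaffected genes and shifted by `effect_sd * lr_sd` for
#' the planted induced fraction (the same genes in every dataset). A
#' `null_frac` of measurements is nulled at random.
#'
#' @param config a [sim_config()]; see the `expression` element.
#' @return list with `datasets` (list of [expression_dataset]) and
#'   `induced_genes` (character vector of planted gene ids).
#' @export
gen_expression_datasets <- function(config = sim_config()) {
  set.seed(config$seed + 2L)
  e <- config$expression
  genes <- sprintf("G%05d", seq_len(e$n_genes))
  n_induced <- round(e$frac_induced * e$n_genes)
  induced <- if (n_induced > 0) sample(genes, n_induced) else character(0)
  datasets <- lapply(seq_len(e$n_datasets), function(d) {
    base <- 2^rnorm(e$n_genes, mean = 8, sd = 1.5)
    lr <- rnorm(e$n_genes, sd = e$lr_sd) +
      ifelse(genes %in% induced, e$effect_sd * e$lr_sd, 0)
    norm <- matrix(base, e$n_genes, e$n_replicates) *
      2^matrix(rnorm(e$n_genes * e$n_replicates, sd = 0.1), e$n_genes)
    hyp <- matrix(base * 2^lr, e$n_genes, e$n_replicates) *
      2^matrix(rnorm(e$n_genes * e$n_replicates, sd = 0.1), e$n_genes)
    if (e$null_frac > 0) {
      norm[runif(length(norm)) < e$null_frac] <- NA
      hyp[runif(length(hyp)) < e$null_frac] <- NA
    }
    expression_dataset(sprintf("DS%02d", d),
                       data.frame(probe_id = paste0(genes, "_at"),
                                  gene_id = genes),
                       norm, hyp)
  })
  names(datasets) <- vapply(datasets, `[[`, "", "dataset_id")
  list(datasets = datasets, induced_genes = induced)
}
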
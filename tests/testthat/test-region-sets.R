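test_that("cross-study overlap keeps regions supported by enough studies", {
  s1 <- data.frame(chrom = "chr1", start = c(100, 500), end = c(200, 600))
  s2 <- data.frame(chrom = "chr1", start = 100, end = 200)
  s3 <- data.frame(chrom = "chr1", start = 900, end = 950)
  s4 <- data.frame(chrom = "chr2", start = 100, end = 200)
  core <- overlap_core(list(a = s1, b = s2, c = s3, d = s4),
                       min_studies = 2)
  expect_equal(nrow(core), 1L)
  expect_equal(core$start, 100)
  expect_equal(core$support, 2L)

  ## min_studies = 1 returns the (precedence-collapsed) union
  uni <- overlap_core(list(a = s1, b = s2, c = s3, d = s4),
                      min_studies = 1)
  expect_equal(nrow(uni), 4L)  # 100-200 collapsed onto study a

  expect_equal(nrow(overlap_core(list(a = s1[0, ], b = s2[0, ]))), 0L)
})

test_that("overlap support equals a brute-force interval intersection", {
  set.seed(13)
  mk <- function(n) {
    st <- sample.int(5000, n)
    data.frame(chrom = "chr1", start = st, end = st + sample(20:80, n,
                                                             replace = TRUE))
  }
  studies <- list(a = mk(40), b = mk(40), c = mk(40), d = mk(40))
  core <- overlap_core(studies, min_studies = 2)
  brute_support <- function(row) {
    sum(vapply(studies, function(s)
      any(s$start < row$end & row$start < s$end), NA))
  }
  for (i in seq_len(nrow(core)))
    expect_equal(core$support[i], brute_support(core[i, ]))
  ## every kept region overlaps >= 2 studies; a dropped candidate from the
  ## reference study overlaps < 2 or a kept region
  ref <- studies$a
  for (i in seq_len(nrow(ref))) {
    supp <- brute_support(ref[i, ])
    in_core <- any(core$study == "a" & core$start == ref$start[i])
    if (supp < 2) expect_false(in_core)
  }
})

test_that("conserved HBS requires element containment and conservation", {
  r <- toy_region("TTACGTGTTACGTGAA", start = 1000L)   # HREs at 2 and 10
  el <- data.frame(chrom = "chr1", start = 1000, end = 1009)
  hbs <- conserved_hbs(r, el, both_strands = FALSE)
  expect_equal(hbs$offset, 2L)                 # second motif outside

  ## 1 bp short of containment drops the motif
  el2 <- data.frame(chrom = "chr1", start = 1003, end = 1007)
  expect_equal(nrow(conserved_hbs(r, el2, both_strands = FALSE)), 0L)

  expect_equal(nrow(conserved_hbs(r, el[0, ], both_strands = FALSE)), 0L)

  ## conservation still applies inside elements
  rbad <- toy_region("TTACGTGTTACGTGAA",
                     edits = list(mouse = list(list(at = 4, to = "A"))),
                     start = 1000L)
  expect_equal(nrow(conserved_hbs(rbad, el, both_strands = FALSE)), 0L)
})

test_that("region extension follows the whole-span coverage rule", {
  hbs <- list(chrom = "chr1", start = 1000, end = 1005)
  ## centered inside a 300 bp element: growth continues while span
  ## coverage stays above 1/2, i.e. to just under twice the element width
  el <- data.frame(chrom = "chr1", start = 850, end = 1150)
  ext <- extend_region(hbs, el)
  expect_lte(ext$start, 850)
  expect_gte(ext$end, 1150)
  expect_gt(ext$coverage, 0.5)
  expect_lte(ext$end - ext$start, 600 + 20)
  ## one more symmetric step would drop coverage to <= 1/2
  expect_lte(300 / (ext$end - ext$start + 20), 0.5 + 0.017)

  ## no element overlap: the HBS itself comes back
  ext0 <- extend_region(hbs, el[0, ])
  expect_equal(c(ext0$start, ext0$end), c(1000, 1005))

  ## two elements separated by a gap equal to their combined length:
  ## extension halts before bridging the gap
  el2 <- data.frame(chrom = "chr1", start = c(900, 1300), end = c(1100, 1500))
  ext2 <- extend_region(list(chrom = "chr1", start = 995, end = 1000), el2)
  expect_lte(ext2$end, 1300)

  ## the seed HBS is always contained and max_span is respected
  big <- data.frame(chrom = "chr1", start = 0, end = 10000)
  ext3 <- extend_region(hbs, big, max_span = 500)
  expect_lte(ext3$end - ext3$start, 500)
  expect_lte(ext3$start, 1000); expect_gte(ext3$end, 1005)
})

test_that("induction filtering keeps genes under the FDR gate", {
  regions <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                        end = c(50, 150, 250),
                        gene_id = c("g1", "g2", "g3"))
  meta <- data.frame(gene_id = c("g1", "g2"), combined_p = c(0.001, 0.02),
                     adj_p = c(0.01, 0.05))
  expect_warning(kept <- filter_by_induction(regions, meta), "dropped")
  expect_equal(kept$gene_id, "g1")
  expect_warning(none <- filter_by_induction(regions, meta[0, ]), "dropped")
  expect_equal(nrow(none), 0L)
})

test_that("location annotation applies the promoter window and precedence", {
  gm <- data.frame(
    chrom = "chr1",
    start = c(5000, 5000, 5200, 6000, 9000),
    end = c(5001, 5200, 6000, 6400, 9001),
    gene_id = "g1",
    strand = "+",
    feature = c("tss", "utr5", "intron", "utr3", "tss"))
  gm$gene_id[5] <- "g2"

  expect_equal(annotate_location(list(chrom = "chr1", start = 4400,
                                      end = 4600), gm)$location_class,
               "promoter")
  expect_equal(annotate_location(list(chrom = "chr1", start = 5300,
                                      end = 5400), gm)$location_class,
               "intron")
  ## straddling the utr5/intron boundary resolves to UTR5 by precedence
  expect_equal(annotate_location(list(chrom = "chr1", start = 5100,
                                      end = 5250), gm)$location_class,
               "UTR5")
  expect_equal(annotate_location(list(chrom = "chr1", start = 6100,
                                      end = 6200), gm)$location_class,
               "UTR3")
  ## orphan region falls back to the nearest TSS promoter
  expect_message(far <- annotate_location(list(chrom = "chr1",
                                               start = 20000, end = 20100),
                                          gm), "nearest")
  expect_equal(far$gene_id, "g2")
})

test_that("background matching reproduces core location proportions", {
  set.seed(19)
  n <- 1000
  candidates <- data.frame(
    chrom = "chr1", start = seq_len(n) * 100,
    end = seq_len(n) * 100 + 50,
    gene_id = paste0("bg", seq_len(n)),
    location_class = sample(c("promoter", "intron"), n, replace = TRUE))
  core <- data.frame(gene_id = paste0("core", 1:40),
                     location_class = rep(c("promoter", "intron"),
                                          c(20, 20)))
  ## candidate probes sit at the global mean; a spread population of other
  ## probes sets the global SD so the 0.25 SD band accepts the candidates
  folds <- lapply(1:3, function(d)
    data.frame(gene_id = c(candidates$gene_id, paste0("other", 1:400)),
               probe_id = paste0("p", seq_len(n + 400)),
               fold = c(rnorm(n, sd = 0.02), rnorm(400, sd = 1))))
  bg <- build_background(candidates, folds, core, size = 100, seed = 7)
  tab <- table(bg$location_class)
  expect_equal(unname(tab[["promoter"]]), 50)
  expect_equal(unname(tab[["intron"]]), 50)
  expect_equal(attr(bg, "matching_report")$core_classes$Freq, c(20, 20))
})

test_that("a single out-of-band probe vetoes a background gene", {
  candidates <- data.frame(chrom = "chr1", start = c(0, 100),
                           end = c(50, 150),
                           gene_id = c("gA", "gB"),
                           location_class = "promoter")
  ## gA centered, gB +3 SD in dataset 2
  mk <- function(foldA, foldB) {
    data.frame(gene_id = c("gA", "gB", paste0("x", 1:200)),
               probe_id = paste0("p", 1:202),
               fold = c(foldA, foldB, rnorm(200)))
  }
  set.seed(3)
  folds <- list(mk(0, 0), mk(0, 3))
  core <- data.frame(gene_id = "c1", location_class = "promoter")
  bg <- build_background(candidates, folds, core, size = 2, seed = 1)
  expect_true("gA" %in% bg$gene_id)
  expect_false("gB" %in% bg$gene_id)
})

test_that("BED round trip preserves intervals", {
  x <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 100L),
                  end = c(50L, 160L), name = c("a", "b"),
                  score = c(0, 500), strand = c("+", "-"))
  f <- tempfile(fileext = ".bed")
  write_bed(x, f)
  back <- read_bed(f)
  expect_equal(back$start, x$start)
  expect_equal(back$end, x$end)
  expect_equal(back$name, x$name)
})
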
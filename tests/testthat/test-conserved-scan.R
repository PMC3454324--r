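test_that("aligned FASTA round trip preserves rows and coordinates", {
  r <- toy_region()
  f <- tempfile(fileext = ".fa")
  write_aligned_fasta(r, f)
  back <- read_aligned_fasta(f)[[1]]
  expect_equal(back$rows, r$rows)
  expect_equal(back$start, r$start)
  expect_equal(back$species[1], "human")
})

test_that("reference gaps drive the position-to-column map", {
  gapless <- aligned_region("g", "chr1", 0, 10,
                            c(human = "ACGTACGTAC", mouse = "ACGTACGTAC"))
  expect_equal(gapless$colmap, 1:10)

  gapped <- aligned_region("g2", "chr1", 0, 4,
                           c(human = "AC-GT", mouse = "ACAGT"))
  expect_equal(gapped$colmap, c(1, 2, 4, 5))
  expect_equal(gapped$ref_seq, "ACGT")

  expect_error(aligned_region("bad", "chr1", 0, 3,
                              c(human = "ACG", mouse = "AC")), "unequal")
  expect_error(aligned_region("bad2", "chr1", 0, 0,
                              c(human = "---", mouse = "ACG")), "all gaps")
})

test_that("RCGTG finder honors the R ambiguity and both strands", {
  r <- toy_region("TTACGTGTT")
  h <- find_rcgtg(r, both_strands = FALSE)
  expect_equal(h$offset, 2L)
  expect_equal(h$strand, "+")

  expect_equal(find_rcgtg(toy_region("TTGCGTGTT"),
                          both_strands = FALSE)$offset, 2L)
  expect_equal(nrow(find_rcgtg(toy_region("TTCCGTGTT"),
                               both_strands = FALSE)), 0L)

  ## CACGY on the minus strand
  rev <- find_rcgtg(toy_region("TTCACGCTT"))
  expect_equal(rev$strand, "-")
  expect_equal(rev$offset, 2L)
})

test_that("conservation requires mouse plus enough identical species", {
  r <- toy_region("TTACGTGTT")          # 5 identical species
  expect_true(is_conserved(r, 2, 5))

  ## mouse gap at a checked position fails despite 4 other matches
  rg <- toy_region("TTACGTGTT",
                   edits = list(mouse = list(list(at = 4, to = "-"))))
  expect_false(is_conserved(rg, 2, 5))

  ## a missing required species is FALSE, not an error
  r3 <- aligned_region("x", "chr1", 0, 9,
                       c(human = "TTACGTGTT", chimp = "TTACGTGTT",
                         dog = "TTACGTGTT", cow = "TTACGTGTT"))
  expect_false(is_conserved(r3, 2, 5))
  expect_true(is_conserved(r3, 2, 5, required_species = "human"))

  ## raising min_species never adds conserved hits
  r4 <- toy_region("TTACGTGTT",
                   edits = list(cow = list(list(at = 3, to = "T")),
                                dog = list(list(at = 5, to = "A"))))
  cons <- vapply(2:5, function(k) is_conserved(r4, 2, 5, min_species = k),
                 NA)
  expect_false(is.unsorted(rev(cons)))  # monotone TRUE..FALSE
})

test_that("the information mask restricts which columns must align", {
  ## species differ everywhere except position 3 of the motif
  edits <- list(mouse = list(list(at = 3, to = "G")),
                cow = list(list(at = 7, to = "A")))
  r <- toy_region("TTACGTGTT", edits = edits)
  mask_all <- rep(TRUE, 5)
  mask_pos3 <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  expect_false(is_conserved(r, 2, 5, mask_all))
  expect_true(is_conserved(r, 2, 5, mask_pos3))
})

test_that("region scanning recovers a planted consensus and obeys bounds", {
  set.seed(31)
  x <- gen_pwm(8, rep(1.8, 8), seed = 31)
  consensus <- paste(c("A", "C", "G", "T")[apply(x$probs, 2, which.max)],
                     collapse = "")
  bg <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
              collapse = "")
  seqs <- paste0(substr(bg, 1, 20), consensus, substr(bg, 29, 60))
  r <- toy_region(seqs)
  hits <- scan_region(r, x, threshold = 0.95)
  expect_true(20L %in% hits$offset)
  expect_true(all(hits$conserved))      # identical species rows

  ## threshold 0 keeps every window
  h0 <- scan_region(r, x, threshold = 0)
  expect_equal(nrow(h0), nchar(seqs) - 8 + 1)

  ## all-N region is unscannable
  rn <- toy_region(strrep("N", 30))
  expect_equal(nrow(scan_region(rn, x, threshold = 0.1)), 0L)

  ## region shorter than the matrix
  expect_equal(nrow(scan_region(toy_region("ACGT"), x, 0)), 0L)
})

test_that("hit sets are nested across stringencies", {
  set.seed(17)
  x <- gen_pwm(7, runif(7, 0.6, 1.8), seed = 17)
  corpus <- random_corpus(5e4)
  thr <- calibrate_thresholds(list(x), corpus, n_samples = 1500, seed = 3)
  r <- toy_region(random_corpus(300))
  h_fn <- scan_region(r, x, thr$minFN)$offset
  h_ms <- scan_region(r, x, thr$minSum)$offset
  h_fp <- scan_region(r, x, thr$minFP)$offset
  expect_true(all(h_fp %in% h_ms))
  expect_true(all(h_ms %in% h_fn))
})

test_that("presence matrix flags conserved hits and is stringency-monotone", {
  set.seed(23)
  x <- gen_pwm(8, rep(1.8, 8), seed = 23)
  consensus <- paste(c("A", "C", "G", "T")[apply(x$probs, 2, which.max)],
                     collapse = "")
  flank <- random_corpus(40)
  seqs <- paste0(substr(flank, 1, 15), consensus, substr(flank, 24, 40))
  conserved_region <- toy_region(seqs)
  ## scramble the mouse row over the motif
  scr <- chartr("ACGT", "GTAC", consensus)
  rows <- conserved_region$rows
  substr(rows[["mouse"]], 16, 23) <- scr
  broken_region <- aligned_region("broken", "chr1", 1000,
                                  1000 + nchar(seqs), rows)

  corpus <- random_corpus(5e4)
  thr <- calibrate_thresholds(list(x), corpus, n_samples = 1500, seed = 9)
  pm <- presence_matrix(list(conserved_region, broken_region), list(x),
                        thr, stringency = "minSum")
  expect_equal(unname(pm[1, 1]), 1L)
  expect_equal(unname(pm[2, 1]), 0L)

  ## raising stringency never turns 0 into 1
  for (rgn in list(conserved_region, broken_region)) {
    v <- vapply(c("minFN", "minSum", "minFP"), function(s)
      presence_matrix(list(rgn), list(x), thr, stringency = s)[1, 1], 0L)
    expect_false(is.unsorted(rev(v)))
  }

  ## vacuous PWM list
  pm0 <- presence_matrix(list(conserved_region), list(), thr)
  expect_equal(ncol(pm0), 0L)

  ## missing threshold errors by name
  thr2 <- thr; thr2$pwm_id <- "other"
  expect_error(presence_matrix(list(conserved_region), list(x), thr2),
               x$id)
})

test_that("presence matches a brute-force window rescan on short regions", {
  set.seed(41)
  x <- gen_pwm(6, runif(6, 0.8, 1.8), seed = 41)
  corpus <- random_corpus(4e4)
  thr <- calibrate_thresholds(list(x), corpus, n_samples = 1200, seed = 2)
  regions <- lapply(1:5, function(i) {
    r <- toy_region(random_corpus(80), start = i * 1000L)
    r$region_id <- paste0("r", i)
    r
  })
  pm <- presence_matrix(regions, list(x), thr, stringency = "minFN")
  ## oracle: rescan every window with the independent scorer; windows
  ## within float-rounding distance of the threshold are indeterminate
  t0 <- thr$minFN
  oracle_any <- function(r, t) {
    seqs <- r$ref_seq
    n <- nchar(seqs)
    any(vapply(seq_len(n - 5), function(o) {
      w <- substr(seqs, o, o + 5)
      oracle_score(w, x$counts) >= t &&
        is_conserved(r, o - 1, 6, x$ic_mask)
    }, NA))
  }
  must_hit <- vapply(regions, oracle_any, NA, t = t0 + 1e-9)
  may_hit <- vapply(regions, oracle_any, NA, t = t0 - 1e-9)
  got <- unname(pm[, 1] == 1L)
  expect_true(all(got[must_hit]))
  expect_true(all(!got[!may_hit]))
})
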
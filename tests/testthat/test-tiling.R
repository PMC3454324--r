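mk_track <- function(n = 50, spacing = 80, reps = 4, sd = 0.25,
                     seed = 1) {
  set.seed(seed)
  starts <- (seq_len(n) - 1L) * spacing
  probe_track(data.frame(probe_id = paste0("p", seq_len(n)),
                         chrom = "chrT", start = starts,
                         end = starts + 50L),
              matrix(rnorm(n * reps, sd = sd), n))
}

test_that("normalization contracts: identity, centering, rank-preservation", {
  tr <- mk_track()
  expect_identical(normalize_track(tr, "none")$ratios, tr$ratios)

  g <- normalize_track(tr, "glog")
  expect_equal(unname(apply(g$ratios, 2, median)), rep(0, 4),
               tolerance = 1e-12)

  ## scaled copies become rank-identical after quantile normalization
  tr2 <- tr
  tr2$ratios[, 2] <- 3 * tr2$ratios[, 1]
  q <- normalize_track(tr2, "quantile")
  expect_equal(rank(q$ratios[, 1]), rank(q$ratios[, 2]))
  expect_equal(sort(q$ratios[, 1]), sort(q$ratios[, 2]))

  trc <- tr
  trc$ratios[, 1] <- 5
  expect_warning(normalize_track(trc, "glog"), "constant")
})

test_that("probe statistics: zero probes, flags, and the BH adjustment", {
  tr <- mk_track(n = 20)
  tr$ratios[1, ] <- 0
  tr$ratios[2, ] <- c(1, NA, NA, NA)   # one usable replicate
  st <- probe_statistics(tr)
  expect_equal(st$pvalue[1], 1)
  expect_equal(st$tstat[1], 0)
  expect_true(st$flagged[2])
  expect_equal(st$pvalue[2], 1)
  expect_true(all(st$adj_pvalue >= st$pvalue - 1e-15))

  ## BH equals the brute-force oracle, including the worked example
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(6)
  p <- runif(500)^2
  expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  st2 <- probe_statistics(mk_track(n = 200, seed = 8))
  expect_equal(st2$adj_pvalue, oracle_bh(st2$pvalue), tolerance = 1e-12)
})

test_that("equal-variance probes make shrinkage match the plain t statistic", {
  set.seed(4)
  n <- 100
  base <- rnorm(4)
  base <- (base - mean(base)) / sd(base)      # mean 0, var exactly 1
  r <- t(sapply(seq_len(n), function(i) i / 50 + 0.3 * base))
  tr <- probe_track(data.frame(probe_id = paste0("p", 1:n), chrom = "c",
                               start = (1:n) * 80L, end = (1:n) * 80L + 50L),
                    r)
  sh <- probe_statistics(tr, shrink = TRUE)
  pl <- probe_statistics(tr, shrink = FALSE)
  expect_equal(sh$tstat, pl$tstat, tolerance = 1e-6)
})

test_that("window quantile smoothing follows the stated conventions", {
  ## three probes inside one window, values 1,2,3 -> 0.75-quantile 2.5
  tr <- probe_track(data.frame(probe_id = c("a", "b", "c"), chrom = "c",
                               start = c(0, 80, 160), end = c(50, 130, 210)),
                    cbind(c(1, 2, 3)))
  sm <- smooth_signal(tr, winHalfSize = 100, quant = 0.75)
  expect_equal(sm$smoothed[2], 2.5)

  ## isolated probe keeps its own value
  tr2 <- probe_track(data.frame(probe_id = c("a", "b"), chrom = "c",
                                start = c(0, 5000), end = c(50, 5050)),
                     cbind(c(1.5, -2)))
  sm2 <- smooth_signal(tr2)
  expect_equal(sm2$smoothed, c(1.5, -2))

  ## constant track is invariant
  tr3 <- mk_track(n = 30)
  tr3$ratios[] <- 0.7
  expect_equal(unique(smooth_signal(tr3)$smoothed), 0.7)
})

test_that("null threshold resists planted positive signal", {
  set.seed(10)
  tr <- mk_track(n = 2000, sd = 0.2)
  tr <- smooth_signal(tr)
  t_null <- null_threshold(tr, 0.99)
  emp <- quantile(tr$smoothed, 0.99, names = FALSE)
  expect_equal(t_null, emp, tolerance = 0.05)

  ## bound probes inflate the right tail but barely move the threshold
  tr2 <- tr
  tr2$smoothed[1:100] <- tr2$smoothed[1:100] + 2
  t_poll <- null_threshold(tr2, 0.99)
  expect_lt(abs(t_poll - t_null), 0.05)
  ## whereas the naive empirical quantile jumps
  expect_gt(quantile(tr2$smoothed, 0.99, names = FALSE) - emp, 1)

  ## q = 0.5 lands near the mode
  expect_lt(abs(null_threshold(tr, 0.5)), 0.05)
})

test_that("region calling enforces run length, spacing, gates and ranks", {
  n <- 40
  starts <- (seq_len(n) - 1L) * 80L
  tr <- probe_track(data.frame(probe_id = paste0("p", 1:n), chrom = "c",
                               start = starts, end = starts + 50L),
                    matrix(0, n, 4))
  tr$smoothed <- rep(0, n)
  tr$adj_pvalue <- rep(1, n)

  ## 4 consecutive probes above threshold, one significant -> one region
  tr1 <- tr
  tr1$smoothed[10:13] <- 1
  tr1$adj_pvalue[11] <- 0.001
  r1 <- call_regions(tr1, threshold = 0.5)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$n_probes, 4L)
  expect_gte(r1$n_total, 8L)

  ## 3 consecutive -> nothing
  tr2 <- tr
  tr2$smoothed[10:12] <- 1
  tr2$adj_pvalue[10] <- 0.001
  expect_equal(nrow(call_regions(tr2, threshold = 0.5)), 0L)

  ## without a significant probe -> nothing
  tr3 <- tr
  tr3$smoothed[10:13] <- 1
  expect_equal(nrow(call_regions(tr3, threshold = 0.5)), 0L)

  ## a 250 bp gap splits the run into two candidates
  st <- c((0:3) * 80L, 240L + 250L + (0:3) * 80L)
  tg <- probe_track(data.frame(probe_id = paste0("g", 1:8), chrom = "c",
                               start = st, end = st + 50L),
                    matrix(0, 8, 2))
  tg$smoothed <- rep(1, 8)
  tg$adj_pvalue <- rep(0.001, 8)
  rg <- call_regions(tg, threshold = 0.5, min_total_probes = 4)
  expect_equal(nrow(rg), 2L)
  expect_true(all(rg$n_probes == 4L))

  ## ranking: best adjusted p first
  tr4 <- tr
  tr4$smoothed[c(5:8, 20:23)] <- 1
  tr4$adj_pvalue[6] <- 0.01
  tr4$adj_pvalue[21] <- 0.0001
  r4 <- call_regions(tr4, threshold = 0.5)
  expect_equal(r4$rank, 1:2)
  expect_equal(r4$best_adj_p, c(1e-4, 1e-2))
})

test_that("lowering the threshold only grows the called regions", {
  set.seed(15)
  sim <- gen_tiling_experiment(sim_config(seed = 15,
                                          tiling = list(n_probes = 600,
                                                        n_regions = 6)))
  tr <- probe_statistics(sim$track)
  tr <- smooth_signal(tr)
  hi <- call_regions(tr, threshold = 0.5)
  lo <- call_regions(tr, threshold = 0.3)
  ## every hi region is covered by some lo region
  for (i in seq_len(nrow(hi))) {
    covered <- any(lo$start <= hi$start[i] & lo$end >= hi$end[i])
    expect_true(covered)
  }
})

test_that("probe tables survive the TSV round trip", {
  tr <- mk_track(n = 10)
  f <- tempfile(fileext = ".tsv")
  write_probe_table(tr, f)
  back <- read_probe_table(f)
  expect_equal(back$probes$start, tr$probes$start)
  expect_equal(unname(back$ratios), unname(tr$ratios), tolerance = 1e-12)
})
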
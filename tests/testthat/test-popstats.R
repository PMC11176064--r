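test_that("window pi matches the hand value and the pairwise oracle", {
  # one site, two diploids 0/0 and 1/1: c_ref = 2, c_alt = 2, n = 4
  gm <- make_gm(matrix(c(0L, 2L), 2, 1), pos = 50L)
  pw <- pi_windows(gm, sample_ids(gm), window = 100000,
                   chrom_lengths = c(chr1 = 100000))
  expect_equal(pw$pi, (8 / 12) / 100000)
  expect_equal(pi_site_oracle(c(0L, 2L)), 8 / 12)

  # monomorphic window
  gm0 <- make_gm(matrix(0L, 3, 4))
  pw0 <- pi_windows(gm0, sample_ids(gm0), chrom_lengths = c(chr1 = 100000))
  expect_equal(pw0$pi, 0)

  # 50 random sites with missingness vs brute-force pairwise enumeration
  set.seed(21)
  g <- random_geno(8, 50, p = 0.4, miss = 0.1)
  gm50 <- make_gm(g, pos = sort(sample.int(90000, 50)))
  pw50 <- pi_windows(gm50, rownames(g), window = 100000,
                     chrom_lengths = c(chr1 = 100000))
  oracle <- sum(vapply(seq_len(50), function(j) pi_site_oracle(g[, j]),
                       numeric(1))) / 100000
  expect_equal(pw50$pi, oracle, tolerance = 1e-12)

  expect_error(pi_windows(gm, "s01"), ">= 2 samples")
})

test_that("pi is invariant to ref/alt label swap", {
  set.seed(3)
  g <- random_geno(6, 30, p = 0.5, miss = 0.05)
  gm <- make_gm(g)
  flipped <- make_gm(2L - g)
  expect_equal(pi_windows(gm, rownames(g), chrom_lengths = c(chr1 = 5000))$pi,
               pi_windows(flipped, rownames(g), chrom_lengths = c(chr1 = 5000))$pi)
})

test_that("genome-wide mean pi is the unweighted window mean", {
  expect_equal(mean_window_stat(c(2e-3, 0)), 1e-3)
  expect_equal(mean_window_stat(c(4e-3)), 4e-3)
  set.seed(4)
  v <- runif(20)
  expect_equal(mean_window_stat(v), mean_window_stat(sample(v)))
  expect_true(is.na(mean_window_stat(c(NA_real_, NA_real_))))
})

test_that("per-site FST behaves at fixation and under no differentiation", {
  gm <- make_gm(rbind(matrix(0L, 10, 1), matrix(2L, 10, 1)))
  a <- sample_ids(gm)[1:10]; b <- sample_ids(gm)[11:20]
  expect_equal(fst_site(gm, a, b), 1)

  # identical genotype vectors in both groups: ratio <= 0.05 for n = 50
  set.seed(12)
  half <- random_geno(50, 40, p = 0.4)
  gm2 <- make_gm(rbind(half, `rownames<-`(half, sprintf("t%02d", 1:50))))
  ratios <- fst_site(gm2, rownames(half), sprintf("t%02d", 1:50))
  expect_true(all(ratios[!is.na(ratios)] <= 0.05))

  # monomorphic across both groups: skipped, not an error
  gm3 <- make_gm(matrix(0L, 6, 1))
  expect_true(is.na(fst_site(gm3, sample_ids(gm3)[1:3], sample_ids(gm3)[4:6])))
})

test_that("FST components match an independent transcription of the equations", {
  set.seed(77)
  for (rep in 1:4) {
    g <- rbind(random_geno(6, 50, p = runif(1, 0.2, 0.7), miss = 0.05),
               `rownames<-`(random_geno(6, 50, p = runif(1, 0.2, 0.7)),
                            sprintf("t%02d", 1:6)))
    gm <- make_gm(g)
    comp <- fst_components(gm, sprintf("s%02d", 1:6), sprintf("t%02d", 1:6))
    for (j in seq_len(50)) {
      if (!comp$usable[j]) next
      oracle <- wc_oracle_site(list(gm$geno[1:6, j], gm$geno[7:12, j]))
      expect_equal(comp$a[j], unname(oracle["a"]), tolerance = 1e-12)
      expect_equal(comp$d[j], unname(oracle["d"]), tolerance = 1e-12)
    }
  }
})

test_that("FST is symmetric under group swap and bounded by one", {
  set.seed(31)
  g <- rbind(random_geno(8, 60, p = 0.3),
             `rownames<-`(random_geno(8, 60, p = 0.7), sprintf("t%02d", 1:8)))
  gm <- make_gm(g)
  ab <- fst_site(gm, sprintf("s%02d", 1:8), sprintf("t%02d", 1:8))
  ba <- fst_site(gm, sprintf("t%02d", 1:8), sprintf("s%02d", 1:8))
  expect_equal(ab, ba)
  expect_true(all(ab[!is.na(ab)] <= 1 + 1e-12))
})

test_that("windowed FST is the ratio of sums over the window's sites", {
  set.seed(55)
  g <- rbind(random_geno(6, 80, p = 0.3),
             `rownames<-`(random_geno(6, 80, p = 0.6), sprintf("t%02d", 1:6)))
  gm <- make_gm(g, pos = sort(sample.int(30000, 80)))
  a <- sprintf("s%02d", 1:6); b <- sprintf("t%02d", 1:6)
  win <- fst_windows(gm, a, b, window = 10000, step = 5000,
                     chrom_lengths = c(chr1 = 30000))
  comp <- fst_components(gm, a, b)
  for (i in seq_len(nrow(win))) {
    idx <- which(gm$sites$pos >= win$start[i] & gm$sites$pos <= win$end[i] &
                   comp$usable)
    if (!length(idx)) {
      expect_true(is.na(win$fst[i]))
    } else {
      expect_equal(win$fst[i], sum(comp$a[idx]) / sum(comp$d[idx]),
                   tolerance = 1e-12)
      expect_equal(win$n_sites[i], length(idx))
    }
  }
  # splitting a window's sites into sub-lists and re-merging is invariant
  idx <- which(gm$sites$pos <= 10000 & comp$usable)
  split_sum <- sum(comp$a[idx[idx %% 2 == 0]]) + sum(comp$a[idx[idx %% 2 == 1]])
  expect_equal(sum(comp$a[idx]), split_sum)

  # a planted fully fixed block gives a window value of 1
  gfix <- rbind(matrix(0L, 6, 20), matrix(2L, 6, 20))
  rownames(gfix) <- c(a, b)
  gmfix <- make_gm(gfix, pos = seq(100, 2000, by = 100))
  wfix <- fst_windows(gmfix, a, b, 2000, 1000, chrom_lengths = c(chr1 = 2000))
  expect_equal(wfix$fst[1], 1)
})

test_that("LD decay bins composite r2 by pair distance", {
  # two perfectly co-varying sites 250 bp apart -> bin [200,300) has r2 = 1
  g <- cbind(c(0L, 1L, 2L, 0L, 2L, 1L), c(0L, 1L, 2L, 0L, 2L, 1L))
  rownames(g) <- sprintf("s%02d", 1:6)
  gm <- make_gm(g, pos = c(100L, 350L))
  bins <- ld_decay(gm, rownames(g), max_dist = 1000, bin = 100)
  expect_equal(bins$mean_r2[bins$bin_start == 200], 1)
  expect_equal(bins$n_pairs[bins$bin_start == 200], 1)
  expect_equal(sum(bins$n_pairs), 1)

  # dosage flip at either site leaves r2 unchanged
  g2 <- cbind(g[, 1], 2L - g[, 2])
  gm2 <- make_gm(g2, pos = c(100L, 350L))
  bins2 <- ld_decay(gm2, rownames(g), max_dist = 1000, bin = 100)
  expect_equal(bins2$mean_r2[bins2$bin_start == 200], 1)

  # zero-variance site: pair skipped
  g3 <- cbind(g[, 1], rep(1L, 6))
  bins3 <- ld_decay(make_gm(g3, pos = c(100L, 350L)), rownames(g),
                    max_dist = 1000, bin = 100)
  expect_equal(sum(bins3$n_pairs), 0)
})

test_that("independent sites in a large cohort show near-zero mean r2", {
  set.seed(99)
  g <- random_geno(2000, 20, p = 0.5)
  gm <- make_gm(g, pos = sort(sample.int(900, 20)) )
  bins <- ld_decay(gm, rownames(g), max_dist = 1000, bin = 100)
  expect_lt(stats::weighted.mean(bins$mean_r2, bins$n_pairs, na.rm = TRUE), 0.01)
})

test_that("half-decay distance interpolates to the half-maximum crossing", {
  bins <- data.frame(bin_start = c(0, 100), mean_r2 = c(0.8, 0.4),
                     n_pairs = c(10L, 10L))
  expect_equal(half_decay_distance(bins), 150)

  flat <- data.frame(bin_start = seq(0, 900, 100), mean_r2 = 0.5,
                     n_pairs = 5L)
  expect_true(is.na(half_decay_distance(flat)))

  empty <- data.frame(bin_start = 0, mean_r2 = NA_real_, n_pairs = 0L)
  expect_error(half_decay_distance(empty), "empty")

  # exponential curve m(d) = 0.8 exp(-d / tau): crossing within one bin width
  tau <- 20000
  d <- seq(0, 100000 - 100, by = 100)
  curve <- data.frame(bin_start = d,
                      mean_r2 = 0.8 * exp(-(d + 50) / tau), n_pairs = 1L)
  expect_lt(abs(half_decay_distance(curve) - tau * log(2)), 100)
})
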
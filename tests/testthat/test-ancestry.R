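test_that("consensus is the modal call with the documented tie-break", {
  gm <- make_gm(cbind(c(0L, 0L, 2L),     # majority 0/0
                      c(0L, 2L, NA),     # tie -> smaller dosage
                      c(NA, NA, NA),     # all missing
                      c(1L, 1L, 2L)))    # majority het
  cons <- build_consensus(gm, sample_ids(gm))
  expect_equal(cons$consensus, c(0L, 0L, NA, 1L))
  expect_equal(cons$support, c(2L, 1L, 0L, 2L))
  expect_equal(cons$n_called, c(3L, 2L, 0L, 3L))
  expect_error(build_consensus(gm, character(0)), "empty group")
})

test_that("identity windows apply the shared-SNP and similarity thresholds", {
  # 10 comparable sites in one 5-kb tile
  donor_calls <- list(
    all_match = rep(0L, 10),
    nine_match = c(rep(0L, 9), 2L),
    four_sites = c(rep(0L, 4), rep(NA, 6)))
  for (case in names(donor_calls)) {
    geno <- rbind(matrix(0L, 3, 10), donor_calls[[case]])
    rownames(geno) <- c("a", "b", "c", "donor")
    gm <- make_gm(geno, pos = seq(100L, 4600L, by = 500L))
    cons <- build_consensus(gm, c("a", "b", "c"))
    iw <- identity_windows(gm, "donor", cons,
                           chrom_lengths = c(chr1 = 5000))
    expect_equal(nrow(iw), 1)
    if (case == "all_match") {
      expect_equal(iw$similarity, 1.0)
      expect_true(iw$pass)
    } else if (case == "nine_match") {
      expect_equal(iw$similarity, 0.9)
      expect_false(iw$pass)          # similarity must exceed 0.96
    } else {
      expect_equal(iw$shared_snps, 4L)
      expect_false(iw$pass)          # needs at least five shared SNPs
    }
  }
})

test_that("similarity is invariant to ref/alt label swap", {
  set.seed(17)
  geno <- rbind(random_geno(4, 40, p = 0.4), donor = rbinom(40, 2, 0.4))
  gm <- make_gm(geno, pos = sort(sample.int(20000, 40)))
  gm_fl <- make_gm(2L - geno, pos = gm$sites$pos)
  cons <- build_consensus(gm, rownames(geno)[1:4])
  # relabelling ref/alt flips the consensus dosage along with every call
  cons_fl <- cons
  cons_fl$consensus <- 2L - cons$consensus
  iw <- identity_windows(gm, "donor", cons, chrom_lengths = c(chr1 = 20000))
  iw_fl <- identity_windows(gm_fl, "donor", cons_fl,
                            chrom_lengths = c(chr1 = 20000))
  expect_equal(iw$similarity, iw_fl$similarity)
  expect_equal(iw$shared_snps, iw_fl$shared_snps)
})

test_that("a single-sample group is identical to itself in every full tile", {
  set.seed(19)
  geno <- rbind(solo = rbinom(60, 2, 0.5))
  gm <- make_gm(geno, pos = sort(sample.int(15000, 60)))
  cons <- build_consensus(gm, "solo")
  iw <- identity_windows(gm, "solo", cons, chrom_lengths = c(chr1 = 15000))
  full <- iw$shared_snps >= 5
  expect_true(all(iw$similarity[full] == 1))
  expect_true(all(iw$pass[full]))
})

test_that("identical regions are maximal runs of passing tiles", {
  win <- data.frame(chrom = "chr1",
                    start = seq(1L, by = 5000L, length.out = 6),
                    end = seq(5000L, by = 5000L, length.out = 6),
                    shared_snps = 10L, matches = 10L, similarity = 1,
                    pass = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  reg <- call_identical_regions(win)
  expect_equal(nrow(reg), 3)
  expect_equal(reg$start, c(1L, 15001L, 25001L))
  expect_equal(reg$end, c(10000L, 20000L, 30000L))

  # random pass vectors match the brute-force run-length oracle
  set.seed(29)
  for (rep in 1:10) {
    pass <- runif(40) < 0.4
    win2 <- data.frame(chrom = "chr1",
                       start = seq(1L, by = 5000L, length.out = 40),
                       end = seq(5000L, by = 5000L, length.out = 40),
                       shared_snps = 10L, matches = 10L, similarity = 1,
                       pass = pass)
    reg2 <- call_identical_regions(win2)
    oracle <- rle_regions_oracle(win2$start, win2$end, pass)
    if (is.null(oracle)) {
      expect_equal(nrow(reg2), 0)
    } else {
      expect_equal(cbind(reg2$start, reg2$end), unname(oracle))
    }
  }
})

test_that("contribution summary reports fraction and length histogram", {
  reg <- data.frame(chrom = "chr1", start = 1L, end = 5000L, n_windows = 1L)
  cs <- contribution_summary(reg, 100000)
  expect_equal(cs$fraction, 0.05)
  expect_equal(cs$n_regions, 1L)
  expect_equal(cs$hist$count, 1L)

  empty <- reg[0, ]
  cs0 <- contribution_summary(empty, 100000)
  expect_equal(cs0$fraction, 0)
  expect_equal(nrow(cs0$hist), 0)
  expect_error(contribution_summary(reg, 0), "positive")
})

test_that("planted identical tracts are recovered at high recall and precision", {
  sim <- simulate_groups(11, chrom_lengths = c(chr1 = 1000000), snp_per_kb = 30,
                         group_sizes = c(Curdless = 20, GreenCurd = 10,
                                         WhiteCurd = 10, Wild = 2),
                         drift = c(Curdless = 0.05, GreenCurd = 0.08,
                                   WhiteCurd = 0.12, Wild = 0.3))
  tr_starts <- c(100000, 250000, 400000, 550000, 700000, 850000) + 1
  tracts <- data.frame(chrom = "chr1", start = tr_starts,
                       end = tr_starts + 49999, donor = "Wild_01")
  planted <- plant_introgressions(sim$matrix, tracts,
                                  group_samples(sim$groups, "Curdless"),
                                  noise = 0.02, seed = 12)
  cons <- build_consensus(planted$matrix, group_samples(sim$groups, "Curdless"))
  iw <- identity_windows(planted$matrix, "Wild_01", cons,
                         chrom_lengths = c(chr1 = 1000000))
  reg <- call_identical_regions(iw)
  called <- logical(1000000)
  for (i in seq_len(nrow(reg))) called[reg$start[i]:reg$end[i]] <- TRUE
  truth <- logical(1000000)
  for (i in seq_len(nrow(tracts))) truth[tracts$start[i]:tracts$end[i]] <- TRUE
  recall <- sum(called & truth) / sum(truth)
  precision <- sum(called & truth) / sum(called)
  expect_gte(recall, 0.90)
  expect_gte(precision, 0.90)
  # total recovered length within one tile of the planted total
  cs <- contribution_summary(reg, 1000000)
  expect_lte(abs(sum(reg$end - reg$start + 1) - sum(truth)), 2 * 5000)
})
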
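test_that("the toy genome is deterministic and its CDS translate cleanly", {
  d1 <- withr::local_tempdir()
  toy1 <- make_toy_genome(1)
  toy2 <- make_toy_genome(1)
  f1 <- file.path(d1, "a.fa"); g1 <- file.path(d1, "a.gff3")
  f2 <- file.path(d1, "b.fa"); g2 <- file.path(d1, "b.gff3")
  write_toy_genome(toy1, f1, g1)
  write_toy_genome(toy2, f2, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))

  # every CDS translates without internal stops and ends in a stop
  cds <- toy1$annotation[toy1$annotation$type == "CDS"]
  txs <- unique(as.character(unlist(cds$Parent)))
  for (tx in txs) {
    feats <- cds[as.character(unlist(cds$Parent)) == tx]
    feats <- feats[order(GenomicRanges::start(feats))]
    chrom <- as.character(GenomicRanges::seqnames(feats))[1]
    spliced <- paste(vapply(seq_along(feats), function(k)
      as.character(Biostrings::subseq(toy1$genome[[chrom]],
                                      GenomicRanges::start(feats)[k],
                                      GenomicRanges::end(feats)[k])),
      character(1)), collapse = "")
    dna <- Biostrings::DNAString(spliced)
    if (as.character(GenomicRanges::strand(feats))[1] == "-")
      dna <- Biostrings::reverseComplement(dna)
    prot <- as.character(Biostrings::translate(dna))
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)), label = tx)
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_equal(substr(prot, 1, 1), "M")
  }
  # both strands represented
  genes <- toy1$annotation[toy1$annotation$type == "gene"]
  expect_gte(sum(as.character(GenomicRanges::strand(genes)) == "-"), 1)
})

test_that("group simulation is seed-reproducible with controllable divergence", {
  s1 <- simulate_groups(5, chrom_lengths = c(chr1 = 2000000))
  s2 <- simulate_groups(5, chrom_lengths = c(chr1 = 2000000))
  expect_identical(s1$matrix$geno, s2$matrix$geno)
  expect_identical(s1$matrix$sites, s2$matrix$sites)

  # zero drift, no blocks: windowed FST stays near zero
  flat <- simulate_groups(6, chrom_lengths = c(chr1 = 2000000),
                          group_sizes = c(A = 20, B = 20),
                          drift = c(A = 0, B = 0))
  fw <- fst_windows(flat$matrix, group_samples(flat$groups, "A"),
                    group_samples(flat$groups, "B"), 100000, 10000,
                    chrom_lengths = c(chr1 = 2000000))
  expect_lt(mean(fw$fst, na.rm = TRUE), 0.02)

  # planted block with gap 0.8: windowed FST well above background
  blocks <- data.frame(chrom = "chr1", start = 500001, end = 800000,
                       group_a = "A", group_b = "B", gap = 0.8)
  hot <- simulate_groups(6, chrom_lengths = c(chr1 = 2000000),
                         group_sizes = c(A = 20, B = 20),
                         drift = c(A = 0, B = 0), sweep_blocks = blocks)
  fw2 <- fst_windows(hot$matrix, group_samples(hot$groups, "A"),
                     group_samples(hot$groups, "B"), 100000, 10000,
                     chrom_lengths = c(chr1 = 2000000))
  inblk <- fw2$start >= 500001 & fw2$end <= 800000
  expect_gt(mean(fw2$fst[inblk], na.rm = TRUE), 0.3)
})

test_that("introgression planting controls tract similarity", {
  sim <- simulate_groups(9, chrom_lengths = c(chr1 = 200000), snp_per_kb = 10,
                         group_sizes = c(A = 10, Wild = 1),
                         drift = c(A = 0.05, Wild = 0.3))
  tracts <- data.frame(chrom = "chr1", start = 50001, end = 100000,
                       donor = "Wild_01")
  # zero noise: tract windows are perfectly identical
  p0 <- plant_introgressions(sim$matrix, tracts, group_samples(sim$groups, "A"),
                             noise = 0, seed = 10)
  cons <- build_consensus(p0$matrix, group_samples(sim$groups, "A"))
  iw <- identity_windows(p0$matrix, "Wild_01", cons,
                         chrom_lengths = c(chr1 = 200000))
  tract_w <- iw$start >= 50001 & iw$end <= 100000
  expect_true(all(iw$similarity[tract_w] == 1))

  # 2% noise: mean similarity near the binomial expectation
  p2 <- plant_introgressions(sim$matrix, tracts, group_samples(sim$groups, "A"),
                             noise = 0.02, seed = 10)
  cons2 <- build_consensus(p2$matrix, group_samples(sim$groups, "A"))
  iw2 <- identity_windows(p2$matrix, "Wild_01", cons2,
                          chrom_lengths = c(chr1 = 200000))
  expect_lt(abs(mean(iw2$similarity[tract_w]) - 0.98), 0.015)

  # empty tract list leaves the matrix unchanged
  p_none <- plant_introgressions(sim$matrix, tracts[0, ],
                                 group_samples(sim$groups, "A"),
                                 noise = 0.02, seed = 10)
  expect_identical(p_none$matrix$geno, sim$matrix$geno)

  # overlapping tracts for one donor are rejected
  bad <- data.frame(chrom = "chr1", start = c(1, 25000), end = c(30000, 60000),
                    donor = "Wild_01")
  expect_error(plant_introgressions(sim$matrix, bad,
                                    group_samples(sim$groups, "A"),
                                    seed = 10), "overlapping")
})

test_that("F2 bulk simulation is reproducible and polarized at the causal site", {
  f1 <- simulate_f2_bulks(13)
  f2 <- simulate_f2_bulks(13)
  expect_identical(f1$counts, f2$counts)

  at <- f1$counts$chrom == f1$truth$causal_chrom &
    f1$counts$pos == f1$truth$causal_pos
  expect_equal(f1$counts$hb_a[at] / (f1$counts$hb_a[at] + f1$counts$hb_b[at]), 1)
  expect_equal(f1$counts$lb_a[at] / (f1$counts$lb_a[at] + f1$counts$lb_b[at]), 0)
})

test_that("ground truth round-trips through JSON", {
  truth <- list(seed = 5, noise = 0.02,
                tracts = data.frame(chrom = "chr1", start = c(1L, 100L),
                                    end = c(50L, 200L), donor = "W",
                                    stringsAsFactors = FALSE))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$seed, truth$seed)
  expect_equal(back$noise, truth$noise)
  expect_equal(as.data.frame(back$tracts), truth$tracts)
})
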
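# Independent oracles. Each one recomputes a statistic by brute force or by
# a direct scalar transcription of the defining equations, on a code path
# disjoint from the package implementation.

# Weir-Cockerham (1984) variance components for one site, written for a
# general number r of populations with explicit scalar sums.
wc_oracle_site <- function(dos_list) {
  pops <- lapply(dos_list, function(g) g[!is.na(g)])
  r <- length(pops)
  n <- vapply(pops, length, numeric(1))
  p <- vapply(pops, function(g) sum(g) / (2 * length(g)), numeric(1))
  h <- vapply(pops, function(g) mean(g == 1), numeric(1))
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, d = a + b + cc)
}

# Per-site mean pairwise difference by enumerating every pair of sampled
# alleles (haploid draws) at the site.
pi_site_oracle <- function(dos) {
  alleles <- unlist(lapply(dos[!is.na(dos)], function(d) c(rep(1L, d), rep(0L, 2L - d))))
  n <- length(alleles)
  if (n < 2) return(0)
  diff_sum <- 0L
  n_pairs <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    diff_sum <- diff_sum + (alleles[i] != alleles[j])
    n_pairs <- n_pairs + 1L
  }
  diff_sum / n_pairs
}

# Exhaustive mutate-and-translate degeneracy for one transcript: mutate each
# CDS position to all four bases, retranslate the full spliced CDS, and
# count the bases preserving the protein.
degeneracy_oracle <- function(genome, ann, tx_id) {
  parents <- vapply(as.list(ann$Parent), function(p) {
    p <- as.character(p)
    if (length(p) && nzchar(p[1])) p[1] else NA_character_
  }, character(1))
  cds <- ann[ann$type == "CDS" & !is.na(parents) & parents == tx_id]
  cds <- cds[order(GenomicRanges::start(cds))]
  chrom <- as.character(GenomicRanges::seqnames(cds))[1]
  minus <- as.character(GenomicRanges::strand(cds))[1] == "-"
  pos_fwd <- unlist(lapply(seq_along(cds), function(k)
    GenomicRanges::start(cds)[k]:GenomicRanges::end(cds)[k]))
  chrseq <- strsplit(as.character(genome[[chrom]]), "")[[1]]
  spliced_ref <- chrseq[pos_fwd]
  bases <- c("A", "C", "G", "T")
  # every single-base mutant of the spliced CDS, translated in one batch
  muts <- character(4L * length(pos_fwd))
  k <- 0L
  for (i in seq_along(pos_fwd)) for (b in bases) {
    mut <- spliced_ref
    mut[i] <- b
    k <- k + 1L
    muts[k] <- paste(mut, collapse = "")
  }
  dset <- Biostrings::DNAStringSet(c(paste(spliced_ref, collapse = ""), muts))
  if (minus) dset <- Biostrings::reverseComplement(dset)
  prots <- as.character(Biostrings::translate(dset, if.fuzzy.codon = "X",
                                              no.init.codon = TRUE))
  same <- colSums(matrix(prots[-1] == prots[1], nrow = 4L))
  out <- data.frame(pos = pos_fwd,
                    degeneracy = ifelse(same == 1L, 0L, same))
  out[order(out$pos), ]
}

# Brute-force run-length scan over a pass/fail tile vector.
rle_regions_oracle <- function(starts, ends, pass) {
  out <- list()
  i <- 1
  while (i <= length(pass)) {
    if (pass[i]) {
      j <- i
      while (j < length(pass) && pass[j + 1]) j <- j + 1
      out[[length(out) + 1]] <- c(starts[i], ends[j])
      i <- j + 1
    } else i <- i + 1
  }
  do.call(rbind, out)
}
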
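# Seeded generators for every fixture the pipeline consumes: a toy genome
# with coding genes on both strands, structured multi-group genotypes with
# planted divergent blocks, donor accessions carrying planted identical
# tracts, and F2 bulk read counts with one causal locus. Every generator is
# a pure function of its arguments plus the seed.

random_codons <- function(n) {
  code <- Biostrings::GENETIC_CODE
  non_stop <- names(code)[code != "*"]
  sample(non_stop, n, replace = TRUE)
}

#' Generate a toy genome with annotated coding genes
#'
#' Random chromosome sequences carrying single- and two-exon protein-coding
#' genes on both strands, with valid phases, an ATG start, no internal stop
#' codons, and a terminal stop. Deterministic for a given seed.
#'
#' @param seed RNG seed.
#' @param chrom_lengths named chromosome lengths in bp (each >= 10 kb).
#' @param gene_every mean spacing between gene starts in bp.
#' @param codon_range range of CDS lengths in codons (including start and
#'   stop).
#' @param two_exon_frac fraction of genes split into two CDS features by an
#'   intron (exercises non-zero phases).
#' @return list with `genome` (a `DNAStringSet`) and `annotation` (a
#'   `GRanges` with gene/mRNA/CDS features).
#' @export
make_toy_genome <- function(seed, chrom_lengths = c(chrA = 30000, chrB = 20000),
                            gene_every = 1500, codon_range = c(30, 100),
                            two_exon_frac = 0.3) {
  stopifnot(all(chrom_lengths >= 10000))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- list()
  feats <- list()
  gene_i <- 0L
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    chrseq <- sample(bases, len, replace = TRUE)
    cursor <- sample(100:400, 1)
    while (TRUE) {
      n_cod <- sample(codon_range[1]:codon_range[2], 1)
      cds <- paste0("ATG",
                    paste(random_codons(n_cod - 2L), collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1))
      L <- nchar(cds)
      two_exon <- stats::runif(1) < two_exon_frac
      ilen <- if (two_exon) sample(60:200, 1) else 0L
      span <- L + ilen
      a <- cursor
      b <- a + span - 1L
      if (b > len - 200L) break
      gene_i <- gene_i + 1L
      gid <- sprintf("gene%03d", gene_i)
      minus <- stats::runif(1) < 0.5
      len1 <- if (two_exon) sample(4:(L - 4L), 1) else L
      sense <- if (two_exon)
        paste0(substr(cds, 1, len1),
               paste(sample(bases, ilen, replace = TRUE), collapse = ""),
               substr(cds, len1 + 1L, L))
      else cds
      placed <- if (minus)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(sense)))
      else sense
      chrseq[a:b] <- strsplit(placed, "")[[1]]
      strand <- if (minus) "-" else "+"
      phase2 <- (3L - len1 %% 3L) %% 3L
      if (two_exon) {
        if (minus) {
          cds_coords <- data.frame(start = c(b - len1 + 1L, a),
                                   end = c(b, a + (L - len1) - 1L),
                                   phase = c(0L, phase2))
        } else {
          cds_coords <- data.frame(start = c(a, a + len1 + ilen),
                                   end = c(a + len1 - 1L, b),
                                   phase = c(0L, phase2))
        }
      } else {
        cds_coords <- data.frame(start = a, end = b, phase = 0L)
      }
      feats[[length(feats) + 1L]] <- data.frame(
        chrom = ch, start = c(a, a, cds_coords$start),
        end = c(b, b, cds_coords$end),
        strand = strand,
        type = c("gene", "mRNA", rep("CDS", nrow(cds_coords))),
        phase = c(NA, NA, cds_coords$phase),
        id = c(gid, paste0(gid, ".t1"),
               paste0(gid, ".t1.cds", seq_len(nrow(cds_coords)))),
        parent = c(NA, gid, rep(paste0(gid, ".t1"), nrow(cds_coords))),
        stringsAsFactors = FALSE)
      cursor <- b + sample(200:max(201, gene_every), 1)
      if (cursor > len - 500L) break
    }
    seqs[[ch]] <- paste(chrseq, collapse = "")
  }
  fdf <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(fdf$chrom,
                               IRanges::IRanges(fdf$start, fdf$end),
                               strand = fdf$strand)
  gr$type <- fdf$type
  gr$ID <- fdf$id
  gr$Parent <- ifelse(is.na(fdf$parent), "", fdf$parent)
  gr$phase <- fdf$phase
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  GenomeInfoDb::seqlengths(gr) <- chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  list(genome = genome, annotation = gr)
}

#' Write a toy genome to FASTA and GFF3
#'
#' @param toy list from [make_toy_genome()].
#' @param fasta_path,gff_path output paths.
#' @return invisibly, the two paths.
#' @export
write_toy_genome <- function(toy, fasta_path, gff_path) {
  Biostrings::writeXStringSet(toy$genome, fasta_path)
  ann <- toy$annotation
  # top-level features carry no Parent
  ann$Parent <- IRanges::CharacterList(lapply(ann$Parent, function(p)
    if (identical(p, "")) character(0) else p))
  rtracklayer::export(ann, gff_path, format = "gff3")
  invisible(c(fasta_path, gff_path))
}

#' Simulate a structured multi-group genotype cohort
#'
#' Per site, an ancestral allele frequency is drawn uniformly on
#' (0.05, 0.95); each group's frequency is a normal perturbation of it,
#' scaled by the group's drift parameter and truncated to `[0, 1]`, so the
#' groups form a nested cline of increasing differentiation. Inside a
#' planted sweep block, the designated group pair is pushed apart to a
#' configured allele-frequency gap. Diploid genotypes are binomial draws
#' from the group frequency, and calls are masked missing uniformly at
#' random.
#'
#' @param seed RNG seed.
#' @param chrom_lengths named chromosome lengths in bp.
#' @param snp_per_kb SNP density (default 1 per kb).
#' @param group_sizes named integer vector of samples per group.
#' @param drift named numeric vector (same names): per-group
#'   frequency-perturbation standard deviation.
#' @param sweep_blocks optional data.frame (`chrom`, `start`, `end`,
#'   `group_a`, `group_b`, `gap`) of planted divergent blocks.
#' @param missing_rate uniform missing-call probability (default 0.03).
#' @return list with `matrix` (a `genotype_matrix`), `groups` (named
#'   sample -> label vector) and `truth` (sweep blocks, per-site group
#'   frequencies, seed).
#' @export
simulate_groups <- function(seed,
                            chrom_lengths = c(chr1 = 10000000),
                            snp_per_kb = 1,
                            group_sizes = c(Curdless = 20, GreenCurd = 20,
                                            WhiteCurd = 20),
                            drift = c(Curdless = 0.05, GreenCurd = 0.08,
                                      WhiteCurd = 0.12),
                            sweep_blocks = NULL,
                            missing_rate = 0.03) {
  stopifnot(length(group_sizes) >= 2,
            all(names(group_sizes) %in% names(drift)))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  sites <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    n <- max(1L, round(chrom_lengths[[ch]] / 1000 * snp_per_kb))
    data.frame(chrom = ch,
               pos = sort(sample.int(chrom_lengths[[ch]], n)),
               stringsAsFactors = FALSE)
  }))
  n_sites <- nrow(sites)
  sites$ref <- sample(bases, n_sites, replace = TRUE)
  sites$alt <- vapply(sites$ref, function(r) sample(setdiff(bases, r), 1), "")
  p0 <- stats::runif(n_sites, 0.05, 0.95)
  freqs <- sapply(names(group_sizes), function(g)
    pmin(pmax(p0 + stats::rnorm(n_sites, 0, drift[[g]]), 0), 1))
  if (!is.null(sweep_blocks)) {
    for (i in seq_len(nrow(sweep_blocks))) {
      blk <- sweep_blocks[i, ]
      idx <- sites$chrom == blk$chrom & sites$pos >= blk$start &
        sites$pos <= blk$end
      freqs[idx, blk$group_a] <- 0.5 + blk$gap / 2
      freqs[idx, blk$group_b] <- 0.5 - blk$gap / 2
    }
  }
  geno <- NULL
  ids <- character(0)
  labels <- character(0)
  for (g in names(group_sizes)) {
    ng <- group_sizes[[g]]
    gm <- matrix(stats::rbinom(ng * n_sites, 2, rep(freqs[, g], each = ng)),
                 nrow = ng)
    geno <- rbind(geno, gm)
    ids <- c(ids, sprintf("%s_%02d", g, seq_len(ng)))
    labels <- c(labels, rep(g, ng))
  }
  if (missing_rate > 0)
    geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
  rownames(geno) <- ids
  list(matrix = genotype_matrix(geno, sites),
       groups = stats::setNames(labels, ids),
       truth = list(seed = seed,
                    sweep_blocks = sweep_blocks,
                    chrom_lengths = as.list(chrom_lengths),
                    freqs = as.data.frame(freqs)))
}

#' Plant donor-identical introgression tracts
#'
#' Inside each tract the donor sample's calls are overwritten with the
#' recipient group's consensus genotype, then flipped to a different call
#' state with probability `noise` per site — emulating nearly identical
#' shared segments between a wild donor and a crop group's ancestral
#' genotype.
#'
#' @param matrix a `genotype_matrix` containing the donor samples.
#' @param tracts data.frame (`chrom`, `start`, `end`, `donor`); tracts of
#'   one donor must not overlap.
#' @param recipient_samples sample ids whose consensus is copied.
#' @param noise per-site flip probability (default 0.02).
#' @param seed RNG seed.
#' @return list with `matrix` (modified) and `truth` (tracts, noise, seed).
#' @export
plant_introgressions <- function(matrix, tracts, recipient_samples,
                                 noise = 0.02, seed) {
  set.seed(seed)
  for (d in unique(tracts$donor)) {
    tr <- tracts[tracts$donor == d, , drop = FALSE]
    for (ch in unique(tr$chrom)) {
      trc <- tr[tr$chrom == ch, , drop = FALSE]
      trc <- trc[order(trc$start), , drop = FALSE]
      if (nrow(trc) > 1 && any(trc$start[-1] <= trc$end[-nrow(trc)]))
        stop("overlapping tracts for donor ", d)
    }
  }
  cons <- build_consensus(matrix, recipient_samples)
  for (i in seq_len(nrow(tracts))) {
    tr <- tracts[i, ]
    idx <- which(matrix$sites$chrom == tr$chrom &
                   matrix$sites$pos >= tr$start & matrix$sites$pos <= tr$end)
    calls <- cons$consensus[idx]
    flip <- stats::runif(length(idx)) < noise & !is.na(calls)
    calls[flip] <- (calls[flip] + sample(1:2, sum(flip), replace = TRUE)) %% 3L
    matrix$geno[tr$donor, idx] <- calls
  }
  list(matrix = matrix,
       truth = list(seed = seed, noise = noise, tracts = tracts))
}

haldane_r <- function(dist_bp, cm_per_mb) {
  morgans <- dist_bp * cm_per_mb / 100 / 1e6
  0.5 * (1 - exp(-2 * morgans))
}

#' Simulate F2 bulk read counts with one causal locus
#'
#' High and low bulks of `bulk_size` F2 individuals are fixed for the
#' parent-A and parent-B allele at the causal locus respectively. At every
#' other site, each of the bulk's `2 * bulk_size` gametes carries the
#' causal-locus-linked parental allele unless a recombination occurred, at
#' the Haldane recombination fraction for the map distance to the causal
#' locus (sites on other chromosomes segregate freely, r = 0.5). Reads are
#' binomial at the configured depth. One recombination-free chromosome-scale
#' simplification: sites are independent given the causal genotype.
#'
#' @param seed RNG seed.
#' @param chrom_lengths named chromosome lengths in bp (first carries the
#'   causal locus unless `causal_chrom` says otherwise).
#' @param snp_per_kb SNP density (default 0.2 per kb).
#' @param causal_chrom,causal_pos causal-locus location.
#' @param bulk_size individuals per bulk (default 20).
#' @param depth read depth per bulk per site (default 50).
#' @param cm_per_mb genetic-map rate (default 5 cM/Mb).
#' @return list with `counts` (data.frame `chrom`, `pos`, `hb_a`, `hb_b`,
#'   `lb_a`, `lb_b`) and `truth` (causal locus, per-site recombination
#'   fraction, design).
#' @export
simulate_f2_bulks <- function(seed,
                              chrom_lengths = c(chr1 = 10000000,
                                                chr2 = 5000000),
                              snp_per_kb = 0.2,
                              causal_chrom = names(chrom_lengths)[1],
                              causal_pos = 5000000,
                              bulk_size = 20, depth = 50, cm_per_mb = 5) {
  stopifnot(causal_chrom %in% names(chrom_lengths),
            causal_pos >= 1, causal_pos <= chrom_lengths[[causal_chrom]])
  set.seed(seed)
  sites <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    n <- max(1L, round(chrom_lengths[[ch]] / 1000 * snp_per_kb))
    pos <- sort(sample.int(chrom_lengths[[ch]], n))
    if (ch == causal_chrom && !causal_pos %in% pos)
      pos <- sort(c(pos, causal_pos))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  r <- ifelse(sites$chrom == causal_chrom,
              haldane_r(abs(sites$pos - causal_pos), cm_per_mb), 0.5)
  n_al <- 2L * bulk_size
  n <- nrow(sites)
  freq_high <- stats::rbinom(n, n_al, 1 - r) / n_al  # parent-A allele
  freq_low <- stats::rbinom(n, n_al, r) / n_al
  hb_a <- stats::rbinom(n, depth, freq_high)
  lb_a <- stats::rbinom(n, depth, freq_low)
  counts <- data.frame(chrom = sites$chrom, pos = sites$pos,
                       hb_a = hb_a, hb_b = depth - hb_a,
                       lb_a = lb_a, lb_b = depth - lb_a,
                       stringsAsFactors = FALSE)
  list(counts = counts,
       truth = list(seed = seed, causal_chrom = causal_chrom,
                    causal_pos = causal_pos, bulk_size = bulk_size,
                    depth = depth, cm_per_mb = cm_per_mb,
                    chrom_lengths = as.list(chrom_lengths),
                    recomb_fraction = r))
}

#' Write / read ground truth as JSON
#'
#' @param truth a ground-truth list from a generator.
#' @param path JSON path.
#' @return the path (write) or the list (read).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a sample-to-group table as TSV
#' @param groups named vector (sample -> label).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_groups_tsv <- function(groups, path) {
  utils::write.table(data.frame(sample = names(groups), group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write / read a bulk-counts table as TSV
#' @param counts data.frame (`chrom`, `pos`, `hb_a`, `hb_b`, `lb_a`, `lb_b`).
#' @param path TSV path.
#' @return the path (write) or the data.frame (read).
#' @export
write_bulk_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bulk_counts
#' @export
read_bulk_counts <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
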
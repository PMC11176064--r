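# Fourfold-degenerate site classification from genome + annotation, and the
# neutral-SNP filter (4d sites, MAF > 0.05, missing rate < 20%).

# Degeneracy of every codon x codon-position under the standard genetic
# code: number of bases at that position preserving the amino acid, with
# nondegenerate positions coded 0 (field convention 0/2/3/4-fold).
codon_degeneracy_table <- function() {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  tab <- matrix(NA_integer_, nrow = 64, ncol = 3,
                dimnames = list(names(code), NULL))
  for (codon in names(code)) {
    cs <- strsplit(codon, "")[[1]]
    for (p in 1:3) {
      variants <- vapply(bases, function(b) {
        v <- cs; v[p] <- b; paste(v, collapse = "")
      }, character(1))
      n_same <- sum(code[variants] == code[codon])
      tab[codon, p] <- if (n_same == 1L) 0L else n_same
    }
  }
  tab
}

read_genome <- function(genome) {
  if (is.character(genome)) Biostrings::readDNAStringSet(genome) else genome
}

read_annotation <- function(annotation) {
  if (is.character(annotation)) rtracklayer::import(annotation) else annotation
}

# CDS features grouped per transcript, in translation order.
cds_by_transcript <- function(ann) {
  cds <- ann[ann$type == "CDS"]
  if (length(cds) == 0L) stop("annotation contains no CDS features")
  parent <- as.character(unlist(cds$Parent %||% cds$ID))
  split(cds, parent)
}

#' Classify coding-site degeneracy from genome and annotation
#'
#' Walks every CDS, translates in the annotated frame, and assigns each
#' coding base its degeneracy class under the standard genetic code (0-, 2-,
#' 3- or 4-fold: the number of bases at that codon position encoding the
#' same amino acid). Minus-strand genes are classified on the reverse
#' complement and mapped back to forward coordinates. Genes whose spliced
#' CDS length is not a multiple of three after phase adjustment, or that
#' contain an internal stop codon, are skipped with a warning. Positions
#' claimed by several transcripts with disagreeing degeneracy are marked
#' conflicted.
#'
#' @param genome a `DNAStringSet` or path to a FASTA file.
#' @param annotation a `GRanges` (as from `rtracklayer::import`) or path to
#'   a GFF3 file; CDS features need strand and phase, and a `Parent` (or
#'   `ID`) to group them by transcript.
#' @return data.frame with columns `chrom`, `pos` (forward-strand, 1-based),
#'   `degeneracy` (0/2/3/4; `NA` where conflicted), `conflicted` (logical),
#'   `gene` (transcript id of the first claimant), `codon_pos` (1-3).
#' @export
classify_degeneracy <- function(genome, annotation) {
  genome <- read_genome(genome)
  ann <- read_annotation(annotation)
  tab <- codon_degeneracy_table()
  groups <- cds_by_transcript(ann)
  res <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    tx <- names(groups)[i]
    cds <- groups[[i]]
    chrom <- as.character(GenomicRanges::seqnames(cds))[1]
    if (!chrom %in% names(genome))
      stop("CDS of ", tx, " references absent contig ", chrom)
    minus <- as.character(GenomicRanges::strand(cds))[1] == "-"
    cds <- cds[order(GenomicRanges::start(cds))]
    spliced_fwd <- paste(vapply(seq_along(cds), function(k)
      as.character(Biostrings::subseq(genome[[chrom]],
                                      GenomicRanges::start(cds)[k],
                                      GenomicRanges::end(cds)[k])),
      character(1)), collapse = "")
    pos_fwd <- unlist(lapply(seq_along(cds), function(k)
      GenomicRanges::start(cds)[k]:GenomicRanges::end(cds)[k]))
    if (minus) {
      cseq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(spliced_fwd)))
      gpos <- rev(pos_fwd)
      cds <- cds[order(GenomicRanges::start(cds), decreasing = TRUE)]
    } else {
      cseq <- spliced_fwd
      gpos <- pos_fwd
    }
    phase <- suppressWarnings(as.integer(as.character(cds$phase[1] %||% 0L)))
    if (is.na(phase)) phase <- 0L
    if (phase > 0L) {
      cseq <- substring(cseq, phase + 1L)
      gpos <- gpos[-seq_len(phase)]
    }
    n <- nchar(cseq)
    if (n %% 3L != 0L) {
      warning("CDS of ", tx, " not a multiple of 3 after phase; skipped")
      next
    }
    codons <- substring(cseq, seq(1, n, 3), seq(3, n, 3))
    aas <- Biostrings::GENETIC_CODE[codons]
    if (any(aas[-length(aas)] == "*", na.rm = TRUE)) {
      warning("internal stop codon in ", tx, "; skipped")
      next
    }
    deg <- as.vector(t(tab[codons, , drop = FALSE]))
    res[[i]] <- data.frame(chrom = chrom, pos = gpos, degeneracy = deg,
                           gene = tx, codon_pos = rep.int(1:3, n / 3L),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no classifiable CDS")
  key <- paste(out$chrom, out$pos)
  agree <- tapply(out$degeneracy, key, function(d) length(unique(d)) == 1L)
  first <- !duplicated(key)
  out <- out[first, , drop = FALSE]
  out$conflicted <- !agree[paste(out$chrom, out$pos)]
  out$degeneracy[out$conflicted] <- NA_integer_
  out <- out[order(match(out$chrom, unique(out$chrom)), out$pos), ]
  rownames(out) <- NULL
  out
}

#' Minor-allele frequency and missing rate per site
#'
#' MAF is computed on non-missing alleles only.
#'
#' @param x a `genotype_matrix`.
#' @return data.frame with columns `maf`, `missing_rate`, `n_called`.
#' @export
site_frequencies <- function(x) {
  g <- x$geno
  n_called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  data.frame(maf = pmin(p_alt, 1 - p_alt),
             missing_rate = 1 - n_called / nrow(g),
             n_called = n_called)
}

#' Select SNPs at fourfold-degenerate sites
#'
#' Retains sites that are 4-fold degenerate (and not conflicted), with minor
#' allele frequency strictly greater than `maf_min` (computed on non-missing
#' alleles) and a missing-call fraction strictly below `missing_max` — the
#' standard neutral-SNP proxy set for population-structure work.
#'
#' @param matrix a `genotype_matrix`.
#' @param classes classification table from [classify_degeneracy()].
#' @param maf_min minimum minor allele frequency (strict `>`); default 0.05.
#' @param missing_max maximum missing fraction (strict `<`); default 0.20.
#' @return a `genotype_matrix` with the same samples and the retained subset
#'   of sites.
#' @export
select_4d_snps <- function(matrix, classes, maf_min = 0.05, missing_max = 0.20) {
  four <- classes[!classes$conflicted & classes$degeneracy == 4L, , drop = FALSE]
  key4 <- paste(four$chrom, four$pos)
  skey <- paste(matrix$sites$chrom, matrix$sites$pos)
  fr <- site_frequencies(matrix)
  keep <- skey %in% key4 & !is.na(fr$maf) & fr$maf > maf_min &
    fr$missing_rate < missing_max
  if (!any(keep)) stop("no sites pass the 4d-SNP filter")
  subset_matrix(matrix, site_idx = which(keep))
}

#' Write a site-classification table as TSV
#' @param classes table from [classify_degeneracy()].
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @return the path, invisibly.
#' @export
write_site_classes <- function(classes, path, seed = NULL) {
  write_tsv_with_header(classes, path, seed)
}
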
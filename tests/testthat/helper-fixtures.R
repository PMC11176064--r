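# Shared fixture builders for the test suite. All fixtures are generated in
# code; nothing is read from disk except files the tests themselves write.

# Tiny genotype matrix from a samples x sites dosage matrix.
make_gm <- function(geno, chrom = "chr1", pos = NULL, ref = NULL, alt = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("s%02d", seq_len(nrow(geno)))
  ns <- ncol(geno)
  sites <- data.frame(
    chrom = rep_len(chrom, ns),
    pos = pos %||% (seq_len(ns) * 100L),
    ref = ref %||% rep_len("A", ns),
    alt = alt %||% rep_len("G", ns),
    stringsAsFactors = FALSE)
  genotype_matrix(geno, sites)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random dosage matrix with optional missingness.
random_geno <- function(n_samples, n_sites, p = 0.3, miss = 0) {
  g <- matrix(rbinom(n_samples * n_sites, 2, p), n_samples)
  if (miss > 0) g[runif(length(g)) < miss] <- NA_integer_
  rownames(g) <- sprintf("s%02d", seq_len(n_samples))
  g
}

# Plain-text VCF writer used to craft hand-made inputs (indels,
# multiallelics, odd GT strings) independent of the package's own emitter.
write_raw_vcf <- function(path, samples, records) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=1000000>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  writeLines(records, con)
  invisible(path)
}
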
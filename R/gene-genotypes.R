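# Gene-body genotype strings, representative genotypes, discrimination
# capacity, the protein-homology hit filter, and qPCR relative expression.

#' Gene-body genotype strings
#'
#' SNP calls within a gene span are concatenated, in genomic order, into one
#' string per sample ("0" hom ref, "1" het, "2" hom alt, "." missing,
#' joined by "-") — the sample's gene-body genotype.
#'
#' @param matrix a `genotype_matrix`.
#' @param chrom,start,end gene span (1-based inclusive).
#' @param samples sample ids (default: all).
#' @return data.frame: `sample`, `genotype`, `n_snps`, `completeness`
#'   (fraction of non-missing calls; `NA` when the gene has no SNP, in which
#'   case `genotype` is the empty string).
#' @export
gene_genotype_strings <- function(matrix, chrom, start, end, samples = NULL) {
  stopifnot(start <= end)
  samples <- samples %||% sample_ids(matrix)
  idx <- which(matrix$sites$chrom == chrom &
                 matrix$sites$pos >= start & matrix$sites$pos <= end)
  if (!length(idx))
    return(data.frame(sample = samples, genotype = "", n_snps = 0L,
                      completeness = NA_real_, stringsAsFactors = FALSE))
  g <- matrix$geno[samples, idx, drop = FALSE]
  sym <- matrix(".", nrow(g), ncol(g))
  ok <- !is.na(g)
  sym[ok] <- as.character(g[ok])
  data.frame(sample = samples,
             genotype = apply(sym, 1, paste, collapse = "-"),
             n_snps = length(idx),
             completeness = rowMeans(ok),
             stringsAsFactors = FALSE)
}

#' Representative (most abundant) genotype of a group
#'
#' The modal genotype string; ties are broken toward the lexicographically
#' smallest string.
#'
#' @param strings character vector of genotype strings (non-empty).
#' @return the representative string.
#' @export
representative_genotype <- function(strings) {
  if (!length(strings)) stop("empty group")
  tab <- table(strings)
  min(names(tab)[tab == max(tab)])
}

#' Discrimination capacity of a gene within a group
#'
#' The number of distinct gene-body genotype strings divided by the number
#' of individuals in the group — a within-group haplotype-diversity
#' statistic bounded by `1/n` (all identical) and 1 (all distinct). Strings
#' containing the missing symbol count as their own genotypes.
#'
#' @param strings character vector of genotype strings (non-empty).
#' @return value in `(0, 1]`.
#' @export
discrimination_capacity <- function(strings) {
  if (!length(strings)) stop("empty group")
  length(unique(strings)) / length(strings)
}

#' Read tabular protein-alignment hits
#'
#' Expects the standard 12-column tabular alignment format followed by the
#' query and subject sequence lengths (columns 13 and 14, as produced with
#' `-outfmt "6 std qlen slen"`).
#'
#' @param path tab-separated hits file (no header).
#' @return data.frame with the standard columns plus `qcov` and `scov`
#'   (aligned fraction of query and subject).
#' @export
read_homology_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "qlen", "slen")
  df <- utils::read.table(path, sep = "\t", header = FALSE, col.names = cols,
                          stringsAsFactors = FALSE)
  if (any(is.na(df$qlen)) || any(is.na(df$slen)))
    stop("hit rows missing query/subject length")
  df$qcov <- (df$qend - df$qstart + 1) / df$qlen
  df$scov <- (abs(df$send - df$sstart) + 1) / df$slen
  df
}

#' Filter homology hits for the candidate-gene panel
#'
#' Retains hits with mutual coverage strictly above `min_coverage` (both
#' query and subject), percent identity strictly above `min_identity`, and a
#' mismatch rate — mismatches over the aligned span — strictly below
#' `max_mismatch_rate`.
#'
#' @param hits data.frame from [read_homology_hits()] (needs `qcov`, `scov`,
#'   `pident`, `mismatch`, `length`).
#' @param min_coverage mutual-coverage threshold, strict `>` (default 0.70).
#' @param min_identity identity threshold in percent, strict `>` (default 75).
#' @param max_mismatch_rate mismatch-rate threshold, strict `<` (default 0.25).
#' @return the retained subset of `hits`.
#' @export
filter_homology <- function(hits, min_coverage = 0.70, min_identity = 75,
                            max_mismatch_rate = 0.25) {
  need <- c("qcov", "scov", "pident", "mismatch", "length")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hits lack column(s): ", paste(miss, collapse = ", "))
  keep <- pmin(hits$qcov, hits$scov) > min_coverage &
    hits$pident > min_identity &
    hits$mismatch / hits$length < max_mismatch_rate
  hits[keep, , drop = FALSE]
}

#' qPCR relative expression
#'
#' Relative expression in arbitrary units from cycle-threshold values
#' against an internal control gene: `2^-(ct_target - ct_control) * 1000`.
#'
#' @param ct_target CT of the target gene.
#' @param ct_control CT of the control (reference) gene.
#' @return relative expression (arbitrary units); vectorized.
#' @export
relative_expression <- function(ct_target, ct_control) {
  stopifnot(is.finite(ct_target), is.finite(ct_control))
  2^(-(ct_target - ct_control)) * 1000
}
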
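#' Construct a genotype matrix
#'
#' The central container of the package: diploid genotype calls for a set of
#' samples at biallelic SNP sites. Calls are stored as alternate-allele
#' dosage: 0 (hom ref), 1 (het), 2 (hom alt), `NA` (missing). Missing is a
#' first-class state and is never imputed.
#'
#' @param geno integer matrix, samples x sites, values in `{0,1,2,NA}`;
#'   rownames are sample identifiers.
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt` (single bases, A/C/G/T, ref != alt). Sites are sorted by
#'   (chromosome, position) on construction; chromosome order is first
#'   appearance. Positions must be unique per chromosome.
#' @return an object of class `genotype_matrix` with elements `geno` and
#'   `sites`.
#' @export
genotype_matrix <- function(geno, sites) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            ncol(geno) == nrow(sites),
            !is.null(rownames(geno)))
  if (anyDuplicated(rownames(geno)))
    stop("duplicate sample ids")
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype calls must be 0, 1, 2 or NA")
  bases <- c("A", "C", "G", "T")
  if (!all(sites$ref %in% bases) || !all(sites$alt %in% bases))
    stop("ref/alt alleles must be single bases A/C/G/T")
  if (any(sites$ref == sites$alt))
    stop("ref and alt allele identical at some site")
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stop("duplicate positions within a chromosome")
  rownames(sites) <- NULL
  structure(list(geno = geno, sites = sites), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d biallelic SNP sites on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$sites$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Sample identifiers of a genotype matrix
#' @param x a `genotype_matrix`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) rownames(x$geno)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param samples character vector of sample ids (default: all).
#' @param site_idx integer indices into the (sorted) site list (default: all).
#' @return a `genotype_matrix`.
#' @export
subset_matrix <- function(x, samples = NULL, site_idx = NULL) {
  samples <- samples %||% rownames(x$geno)
  site_idx <- site_idx %||% seq_len(ncol(x$geno))
  miss <- setdiff(samples, rownames(x$geno))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  genotype_matrix(x$geno[samples, site_idx, drop = FALSE],
                  x$sites[site_idx, , drop = FALSE])
}

gt_to_dosage <- function(gt) {
  # unphased reading: phase separators ignored
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  out[gt %in% "0/0"] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt %in% "1/1"] <- 2L
  out
}

#' Load genotypes from a VCF file
#'
#' Reads a VCF with GT fields into a [genotype_matrix()]. Only biallelic SNP
#' records (single-base REF and ALT, both A/C/G/T) are admitted; multiallelic
#' records and indels are dropped at load and the drop count is reported.
#' Phase separators are ignored; any GT other than 0/0, 0/1, 1/0 or 1/1 is
#' treated as missing.
#'
#' @param vcf_path path to a VCF (optionally gzipped).
#' @param verbose report the number of dropped records via `message()`.
#' @return a `genotype_matrix`; the number of dropped records is attached as
#'   attribute `n_dropped`.
#' @export
load_genotypes <- function(vcf_path, verbose = TRUE) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no variant records in ", vcf_path)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw) || ncol(gt_raw) == 0L) stop("VCF has no sample genotypes: ", vcf_path)
  bases <- c("A", "C", "G", "T")
  keep <- fix$REF %in% bases & fix$ALT %in% bases
  n_dropped <- sum(!keep)
  if (verbose && n_dropped > 0)
    message(n_dropped, " record(s) dropped (multiallelic or non-SNP)")
  if (!any(keep)) stop("zero biallelic SNP sites after filtering: ", vcf_path)
  sites <- data.frame(chrom = fix$CHROM[keep],
                      pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      stringsAsFactors = FALSE)
  dos <- apply(gt_raw[keep, , drop = FALSE], 2, gt_to_dosage)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1, dimnames = list(NULL, colnames(gt_raw)))
  gm <- genotype_matrix(t(dos), sites)
  attr(gm, "n_dropped") <- n_dropped
  gm
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a plain-text VCFv4.2 file with contig headers (in chromosome
#' appearance order) and unphased GT genotypes; the inverse of
#' [load_genotypes()] for files produced by this package.
#'
#' @param x a `genotype_matrix`.
#' @param path output path.
#' @param chrom_lengths optional named lengths for the contig headers;
#'   defaults to the maximum site position per chromosome.
#' @return the path, invisibly.
#' @export
write_genotypes_vcf <- function(x, path, chrom_lengths = NULL) {
  chroms <- unique(x$sites$chrom)
  lens <- chrom_lengths %||% infer_chrom_lengths(x$sites)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chroms, as.integer(lens[chroms])),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(x$geno)), collapse = "\t"), con)
  gtchar <- c("0/0", "0/1", "1/1")
  body <- matrix("./.", nrow(x$geno), ncol(x$geno))
  ok <- !is.na(x$geno)
  body[ok] <- gtchar[x$geno[ok] + 1L]
  per_site <- apply(body, 2, paste, collapse = "\t")
  lines <- paste(x$sites$chrom, x$sites$pos, ".", x$sites$ref, x$sites$alt,
                 ".", "PASS", ".", "GT", per_site, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Load a sample-to-group assignment table
#'
#' @param tsv_path two-column tab-separated file: sample_id, group (no
#'   header, or header `sample`/`group`).
#' @param matrix a `genotype_matrix`; every listed sample must be present.
#' @return named character vector mapping sample id to group label.
#' @export
load_groups <- function(tsv_path, matrix) {
  df <- utils::read.table(tsv_path, sep = "\t", header = FALSE,
                          col.names = c("sample", "group"),
                          colClasses = "character")
  if (nrow(df) && df$sample[1] %in% c("sample", "sample_id"))
    df <- df[-1, , drop = FALSE]
  dup <- duplicated(df$sample)
  if (any(dup))
    stop("duplicate sample row(s) in group table: ",
         paste(which(dup), collapse = ", "))
  unknown <- setdiff(df$sample, sample_ids(matrix))
  if (length(unknown))
    stop("group table names sample(s) absent from the genotype matrix: ",
         paste(unknown, collapse = ", "))
  stats::setNames(df$group, df$sample)
}

#' Samples belonging to one group
#' @param groups named vector from [load_groups()] (sample -> label).
#' @param label group label.
#' @return character vector of sample ids.
#' @export
group_samples <- function(groups, label) names(groups)[groups == label]

#' Write genomic regions as BED
#'
#' Internally all coordinates are 1-based inclusive; BED output uses the
#' 0-based half-open convention (start-1, end). The region label goes in
#' column 4.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` and
#'   optionally `label`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  stopifnot(all(regions$start <= regions$end))
  lab <- if ("label" %in% names(regions)) regions$label else "."
  lines <- sprintf("%s\t%d\t%d\t%s", regions$chrom,
                   as.integer(regions$start) - 1L, as.integer(regions$end),
                   lab)
  writeLines(lines[seq_len(nrow(regions))], path)
  invisible(path)
}

#' Read a BED file into 1-based inclusive regions
#' @param path BED path (3+ columns; column 4, if present, becomes `label`).
#' @return data.frame with columns `chrom`, `start`, `end`, `label`.
#' @export
read_regions_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      stringsAsFactors = FALSE))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  data.frame(chrom = df[[1]],
             start = as.integer(df[[2]]) + 1L,
             end = as.integer(df[[3]]),
             label = if (ncol(df) >= 4) df[[4]] else ".",
             stringsAsFactors = FALSE)
}
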
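# Top-percentile selection of windowed FST, two-stage merging into highly
# diverged regions, and gene annotation of the result.

#' Select top-percentile windows
#'
#' The threshold is the empirical top-`q` cut by nearest rank: the
#' `ceiling(q * N)`-th largest defined window value. All windows with a
#' value greater than or equal to the threshold are selected, so ties at the
#' threshold are all included. With `q = 0` only the maximum-tied windows
#' are selected.
#'
#' @param stats window data.frame with a `fst` (or last) statistic column.
#' @param q upper tail fraction (default 0.05, the top 5%).
#' @return list with `selected` (the selected rows of `stats`), `threshold`
#'   and `n_defined`.
#' @export
top_percentile_select <- function(stats, q = 0.05) {
  v <- if ("fst" %in% names(stats)) stats$fst else stats[[ncol(stats)]]
  def <- which(!is.na(v))
  if (!length(def)) stop("no defined window values")
  if (length(def) < 20)
    warning("fewer than 20 defined windows; top-percentile threshold is degenerate")
  k <- max(1L, ceiling(q * length(def)))
  thr <- sort(v[def], decreasing = TRUE)[k]
  sel <- def[v[def] >= thr]
  list(selected = stats[sel, , drop = FALSE], threshold = thr,
       n_defined = length(def))
}

#' Merge selected windows into diverged regions
#'
#' Two-stage merging: neighbouring (overlapping or bookended) selected
#' windows are first merged into fragments; fragments are then merged into
#' one region when the gap between them (`next start - prev end - 1`) is
#' strictly less than `bridge` bp. Regions never span chromosomes.
#'
#' @param selected data.frame of selected windows (`chrom`, `start`, `end`).
#' @param bridge maximum bridged gap in bp, exclusive (default 100 kb).
#' @return data.frame of regions: `chrom`, `start`, `end`, `label`.
#' @export
merge_to_regions <- function(selected, bridge = 100000) {
  if (nrow(selected) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      stringsAsFactors = FALSE))
  gr <- regions_to_granges(selected)
  frags <- GenomicRanges::reduce(gr)                       # stage 1: neighbours
  regions <- GenomicRanges::reduce(frags, min.gapwidth = bridge)  # stage 2: gap < bridge
  regions <- GenomicRanges::sort(regions)
  out <- granges_to_regions(regions)
  out$label <- sprintf("region_%03d", seq_len(nrow(out)))
  out
}

#' Genes overlapping regions
#'
#' A gene is assigned to a region when its span overlaps it by at least one
#' bp.
#'
#' @param regions data.frame of regions (`chrom`, `start`, `end`, optional
#'   `label`).
#' @param annotation a `GRanges` or GFF3 path; features with
#'   `type == "gene"` are used (all features if none are typed "gene").
#' @return data.frame: `region` (label or index), `chrom`, `start`, `end`,
#'   `gene`.
#' @export
genes_in_regions <- function(regions, annotation) {
  ann <- read_annotation(annotation)
  genes <- ann[ann$type == "gene"]
  if (length(genes) == 0L) genes <- ann
  rg <- regions_to_granges(regions)
  hits <- GenomicRanges::findOverlaps(rg, genes, minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  lab <- if ("label" %in% names(regions)) regions$label else as.character(seq_len(nrow(regions)))
  data.frame(region = lab[qi],
             chrom = regions$chrom[qi],
             start = regions$start[qi],
             end = regions$end[qi],
             gene = as.character(genes$ID %||% genes$Name)[si],
             stringsAsFactors = FALSE)
}

#' Discrimination-capacity profile of genes in diverged regions
#'
#' For every gene overlapping the regions and every group, computes the
#' gene-body genotype discrimination capacity (distinct genotype strings /
#' group size; see [discrimination_capacity()]) in long format. Genes with
#' no SNP in the genotype matrix get `NA` capacity.
#'
#' @param regions data.frame of regions.
#' @param matrix a `genotype_matrix`.
#' @param groups named vector (sample -> group label).
#' @param annotation a `GRanges` or GFF3 path with gene spans.
#' @return data.frame: `region`, `gene`, `group`, `n`, `n_distinct`,
#'   `capacity`, `representative`.
#' @export
discrimination_profile <- function(regions, matrix, groups, annotation) {
  ann <- read_annotation(annotation)
  gmap <- genes_in_regions(regions, annotation = ann)
  genes <- ann[ann$type == "gene"]
  if (length(genes) == 0L) genes <- ann
  gid <- as.character(genes$ID %||% genes$Name)
  out <- list()
  for (i in seq_len(nrow(gmap))) {
    k <- match(gmap$gene[i], gid)
    span <- c(GenomicRanges::start(genes)[k], GenomicRanges::end(genes)[k])
    chrom <- as.character(GenomicRanges::seqnames(genes))[k]
    for (lab in unique(groups)) {
      sams <- group_samples(groups, lab)
      strs <- gene_genotype_strings(matrix, chrom, span[1], span[2], sams)
      has_snps <- nrow(strs) > 0 && nchar(strs$genotype[1]) > 0
      out[[length(out) + 1L]] <- data.frame(
        region = gmap$region[i], gene = gmap$gene[i], group = lab,
        n = length(sams),
        n_distinct = if (has_snps) length(unique(strs$genotype)) else NA_integer_,
        capacity = if (has_snps) discrimination_capacity(strs$genotype) else NA_real_,
        representative = if (has_snps) representative_genotype(strs$genotype) else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(region = character(), gene = character(),
                      group = character(), n = integer(),
                      n_distinct = integer(), capacity = numeric(),
                      representative = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
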
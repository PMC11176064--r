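# Consensus-genotype reconstruction and identity-window (IBS) painting of
# donor accessions against a group's inferred ancestral genotype.

#' Consensus genotype of a group
#'
#' Per site, the modal genotype call (hom ref / het / hom alt) over the
#' group's non-missing calls; ties are broken toward the call with the
#' smaller alternate-allele dosage (hom ref < het < hom alt). Sites where
#' every group member is missing get a missing consensus.
#'
#' @param matrix a `genotype_matrix`.
#' @param samples sample ids of the group (non-empty).
#' @return data.frame aligned with `matrix$sites`: `chrom`, `pos`,
#'   `consensus` (0/1/2/`NA`), `support` (count of the modal call),
#'   `n_called`.
#' @export
build_consensus <- function(matrix, samples) {
  if (!length(samples)) stop("empty group")
  g <- group_dosage(matrix, samples)
  counts <- rbind(colSums(g == 0L, na.rm = TRUE),
                  colSums(g == 1L, na.rm = TRUE),
                  colSums(g == 2L, na.rm = TRUE))
  n_called <- colSums(counts)
  # which.max returns the first maximum: dosage order implements the tie-break
  mode_idx <- apply(counts, 2, which.max)
  consensus <- as.integer(mode_idx) - 1L
  support <- counts[cbind(mode_idx, seq_len(ncol(counts)))]
  consensus[n_called == 0L] <- NA_integer_
  data.frame(chrom = matrix$sites$chrom, pos = matrix$sites$pos,
             consensus = consensus, support = as.integer(support),
             n_called = as.integer(n_called), stringsAsFactors = FALSE)
}

#' Identity windows between a donor and a consensus genotype
#'
#' Tiles each chromosome with consecutive non-overlapping windows from
#' position 1 and, per window, counts the shared SNPs (donor call and
#' consensus both non-missing) and the matches (identical call state).
#' A window passes when it has at least `min_shared` shared SNPs and a
#' similarity (matches / shared) strictly greater than `min_similarity` —
#' the operational definition of a candidate identical ("syntenic") region.
#'
#' @param matrix a `genotype_matrix`.
#' @param donor donor sample id.
#' @param consensus data.frame from [build_consensus()] on the same matrix.
#' @param window window width in bp (default 5 kb).
#' @param min_shared minimum shared SNPs per window (default 5).
#' @param min_similarity similarity threshold, strict `>` (default 0.96).
#' @param chrom_lengths optional named chromosome lengths.
#' @return data.frame: `chrom`, `start`, `end`, `shared_snps`, `matches`,
#'   `similarity`, `pass`.
#' @export
identity_windows <- function(matrix, donor, consensus, window = 5000,
                             min_shared = 5, min_similarity = 0.96,
                             chrom_lengths = NULL) {
  d <- as.integer(matrix$geno[donor, ])
  stopifnot(nrow(consensus) == ncol(matrix$geno))
  comp <- !is.na(d) & !is.na(consensus$consensus)
  match_v <- as.numeric(comp & d == consensus$consensus)
  lens <- chrom_lengths %||% infer_chrom_lengths(matrix$sites)
  win <- tile_windows(lens, window)
  rng <- window_site_ranges(win, matrix$sites)
  win$shared_snps <- as.integer(range_sums(as.numeric(comp), rng))
  win$matches <- as.integer(range_sums(match_v, rng))
  win$similarity <- ifelse(win$shared_snps > 0,
                           win$matches / win$shared_snps, NA_real_)
  win$pass <- win$shared_snps >= min_shared &
    !is.na(win$similarity) & win$similarity > min_similarity
  win
}

#' Merge passing identity windows into identical regions
#'
#' Maximal runs of consecutive passing tiles (per chromosome) are merged;
#' region lengths are therefore multiples of the tile width, except where
#' the final tile is truncated at a chromosome end.
#'
#' @param windows data.frame from [identity_windows()].
#' @return data.frame of regions: `chrom`, `start`, `end`, `n_windows`.
#' @export
call_identical_regions <- function(windows) {
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    r <- rle(w$pass)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    for (k in keep) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = w$start[starts[k]], end = w$end[ends[k]],
        n_windows = r$lengths[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Per-donor genome contribution and fragment-length histogram
#'
#' @param regions data.frame of identical regions for one donor.
#' @param genome_length total genome length in bp (> 0).
#' @param bin histogram bin width in bp (default 5 kb).
#' @return list: `fraction` (summed region length / genome length),
#'   `n_regions`, `mean_length`, `hist` (data.frame `bin_start`, `count`).
#' @export
contribution_summary <- function(regions, genome_length, bin = 5000) {
  if (genome_length <= 0) stop("genome length must be positive")
  if (nrow(regions) == 0)
    return(list(fraction = 0, n_regions = 0L, mean_length = NA_real_,
                hist = data.frame(bin_start = integer(), count = integer())))
  lens <- regions$end - regions$start + 1
  bins <- (ceiling(lens / bin) - 1L) * bin
  tab <- table(bins)
  list(fraction = sum(lens) / genome_length,
       n_regions = nrow(regions),
       mean_length = mean(lens),
       hist = data.frame(bin_start = as.integer(names(tab)),
                         count = as.integer(tab)))
}
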
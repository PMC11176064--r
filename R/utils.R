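# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Tile chromosomes with non-overlapping windows
#'
#' Windows are anchored at position 1 of each chromosome; the last window is
#' truncated at the chromosome end. Coordinates are 1-based inclusive.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param window window width in bp.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
tile_windows <- function(chrom_lengths, window) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)), window >= 1)
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, len, by = window)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window - 1, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sliding windows over chromosomes
#'
#' Windows start at position 1 and advance by `step`; every window that
#' starts within the chromosome is emitted, with its end truncated at the
#' chromosome end.
#'
#' @inheritParams tile_windows
#' @param step step size in bp; `window` must be a multiple of `step`.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
sliding_windows <- function(chrom_lengths, window, step) {
  stopifnot(window >= step, window %% step == 0)
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, max(1, len - step + 1), by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window - 1, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Chromosome lengths implied by the sites of a genotype matrix (max position
# per chromosome), used when no FASTA/contig lengths are supplied.
infer_chrom_lengths <- function(sites) {
  tapply(sites$pos, factor(sites$chrom, levels = unique(sites$chrom)), max)
}

# data.frame(chrom,start,end[,label]) <-> GRanges
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start, regions$end))
}

granges_to_regions <- function(gr, label = NA_character_) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             label = label,
             stringsAsFactors = FALSE)
}

# For each window row, the range of site indices (sites sorted by chrom,pos)
# falling inside; returns matrix with columns lo, hi (hi < lo => empty).
window_site_ranges <- function(windows, sites) {
  lo <- integer(nrow(windows)); hi <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    widx <- which(windows$chrom == ch)
    sidx <- which(sites$chrom == ch)
    pos <- sites$pos[sidx]
    lo[widx] <- sidx[1L] - 1L + findInterval(windows$start[widx] - 0.5, pos) + 1L
    hi[widx] <- sidx[1L] - 1L + findInterval(windows$end[widx] + 0.5, pos)
    if (length(sidx) == 0L) { lo[widx] <- 1L; hi[widx] <- 0L }
  }
  cbind(lo = lo, hi = hi)
}

# Sum v over each [lo,hi] index range via cumulative sums (NA treated as 0).
range_sums <- function(v, ranges) {
  v[is.na(v)] <- 0
  cs <- c(0, cumsum(v))
  cs[ranges[, "hi"] + 1L] - cs[ranges[, "lo"]]
}

write_tsv_with_header <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("curdscan"))
  seedtxt <- if (is.null(seed)) "" else paste0(" seed=", seed)
  writeLines(sprintf("# curdscan %s%s", ver, seedtxt), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
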
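# QTL-seq style bulked-segregant analysis: SNP index, delta SNP index,
# sliding-window means, and simulation-based confidence bands under the
# no-QTL null.

#' SNP index of one bulk
#'
#' Fraction of reads carrying the parent-A allele; undefined (`NA`) below
#' the minimum depth.
#'
#' @param reads_a,reads_b read counts supporting the parent-A and parent-B
#'   alleles (vectorized).
#' @param min_depth minimum total depth (default 8).
#' @return values in `[0, 1]` or `NA`.
#' @export
snp_index <- function(reads_a, reads_b, min_depth = 8) {
  tot <- reads_a + reads_b
  ifelse(tot >= min_depth, reads_a / tot, NA_real_)
}

#' Delta SNP index per site
#'
#' `snp_index(bulk 1) - snp_index(bulk 2)` on parent-A-polarized read
#' counts; sites where either bulk index is undefined are `NA`.
#'
#' @param counts data.frame with columns `chrom`, `pos`, `hb_a`, `hb_b`
#'   (bulk-1 reads for parent-A and parent-B alleles), `lb_a`, `lb_b`
#'   (bulk 2).
#' @param min_depth per-bulk minimum depth (default 8).
#' @return `counts` with added columns `index1`, `index2`, `delta`, `depth`
#'   (mean of the two bulk depths).
#' @export
delta_snp_index <- function(counts, min_depth = 8) {
  counts$index1 <- snp_index(counts$hb_a, counts$hb_b, min_depth)
  counts$index2 <- snp_index(counts$lb_a, counts$lb_b, min_depth)
  counts$delta <- counts$index1 - counts$index2
  counts$depth <- (counts$hb_a + counts$hb_b + counts$lb_a + counts$lb_b) / 2
  counts
}

#' Sliding-window mean delta SNP index
#'
#' Per sliding window, the unweighted mean of the defined per-site delta
#' values; the per-window mean depth is carried along for confidence-band
#' lookup.
#'
#' @param sites data.frame from [delta_snp_index()] (sorted by chrom, pos).
#' @param window window width in bp (default 1,000 kb).
#' @param step step size in bp (default 10 kb).
#' @param chrom_lengths optional named chromosome lengths.
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `depth`,
#'   `mean_delta`.
#' @export
windowed_delta <- function(sites, window = 1000000, step = 10000,
                           chrom_lengths = NULL) {
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  lens <- chrom_lengths %||% infer_chrom_lengths(sites)
  win <- sliding_windows(lens, window, step)
  rng <- window_site_ranges(win, sites)
  def <- !is.na(sites$delta)
  n <- range_sums(as.numeric(def), rng)
  win$n_sites <- as.integer(n)
  win$depth <- ifelse(n > 0, range_sums(ifelse(def, sites$depth, 0), rng) / n,
                      NA_real_)
  win$mean_delta <- ifelse(n > 0,
                           range_sums(ifelse(def, sites$delta, 0), rng) / n,
                           NA_real_)
  win
}

#' Simulate the no-QTL null band of the delta SNP index
#'
#' Under the null hypothesis of no QTL, each bulk of `bulk_size` F2
#' individuals draws genotypes AA/Aa/aa with probabilities 1/4, 1/2, 1/4;
#' the bulk allele frequency is `(2 nAA + nAa) / (2 bulk_size)` and read
#' counts follow `Binomial(depth, p)`. The band is the empirical
#' (lower, upper) quantile pair of `index1 - index2` at the requested
#' confidence.
#'
#' @param depth read depth per bulk (vectorized over a depth grid).
#' @param bulk_size individuals per bulk (default 20).
#' @param replicates simulation replicates (default 10,000).
#' @param confidence two-sided confidence level (default 0.95).
#' @param seed RNG seed (mandatory for reproducible bands).
#' @return data.frame: `depth`, `lower`, `upper`, `replicates`, `bulk_size`.
#' @export
simulate_null_band <- function(depth, bulk_size = 20, replicates = 10000,
                               confidence = 0.95, seed) {
  stopifnot(all(depth >= 1))
  if (replicates < 100) warning("fewer than 100 replicates; band is noisy")
  set.seed(seed)
  alpha <- (1 - confidence) / 2
  out <- lapply(depth, function(dp) {
    draw_index <- function() {
      geno <- stats::rmultinom(replicates, bulk_size, c(1, 2, 1) / 4)
      p <- (2 * geno[1, ] + geno[2, ]) / (2 * bulk_size)
      stats::rbinom(replicates, dp, p) / dp
    }
    delta <- draw_index() - draw_index()
    q <- stats::quantile(delta, c(alpha, 1 - alpha), names = FALSE, type = 1)
    data.frame(depth = dp, lower = q[1], upper = q[2],
               replicates = replicates, bulk_size = bulk_size)
  })
  do.call(rbind, out)
}

#' Null-band grid over a range of depths
#'
#' @param depths depth grid (default 10, 20, ..., 100).
#' @inheritParams simulate_null_band
#' @return data.frame as from [simulate_null_band()], one row per depth.
#' @export
null_band_grid <- function(depths = seq(10, 100, by = 10), bulk_size = 20,
                           replicates = 10000, confidence = 0.95, seed) {
  simulate_null_band(depths, bulk_size, replicates, confidence, seed)
}

#' Call candidate QTL regions from windowed delta SNP index
#'
#' Each window's mean delta is compared against the null band simulated for
#' the nearest depth on the band grid; maximal runs of consecutive
#' exceeding windows are merged (union of their spans) into candidate
#' regions.
#'
#' @param winstats data.frame from [windowed_delta()].
#' @param bands data.frame from [null_band_grid()].
#' @return data.frame of regions: `chrom`, `start`, `end`, `peak_delta`.
#' @export
call_candidate_regions <- function(winstats, bands) {
  def <- !is.na(winstats$mean_delta) & !is.na(winstats$depth)
  bi <- vapply(winstats$depth, function(dp)
    if (is.na(dp)) NA_integer_ else which.min(abs(bands$depth - dp)),
    integer(1))
  exceed <- def & (winstats$mean_delta > bands$upper[bi] |
                     winstats$mean_delta < bands$lower[bi])
  exceed[is.na(exceed)] <- FALSE
  if (!any(exceed))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_delta = numeric(),
                      stringsAsFactors = FALSE))
  sel <- winstats[exceed, , drop = FALSE]
  gr <- GenomicRanges::reduce(regions_to_granges(sel))
  out <- granges_to_regions(gr)
  out$label <- NULL
  ov <- GenomicRanges::findOverlaps(gr, regions_to_granges(sel))
  out$peak_delta <- vapply(seq_along(gr), function(i) {
    v <- sel$mean_delta[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]
    v[which.max(abs(v))]
  }, numeric(1))
  out
}
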
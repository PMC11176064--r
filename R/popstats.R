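# Windowed nucleotide diversity, Weir-Cockerham FST, and LD decay.

group_dosage <- function(matrix, samples) {
  miss <- setdiff(samples, sample_ids(matrix))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  matrix$geno[samples, , drop = FALSE]
}

#' Nucleotide diversity in physical windows
#'
#' Per non-overlapping window (tiled from position 1), pi is the sum over
#' variant sites of the unbiased per-site heterozygosity
#' `2 * c_ref * c_alt / (n * (n - 1))` — `c_ref`, `c_alt` the non-missing
#' allele counts in the group and `n = c_ref + c_alt` — divided by the
#' window length in bp. Sites with fewer than two called alleles contribute
#' nothing.
#'
#' @param matrix a `genotype_matrix`.
#' @param samples sample ids of the group (>= 2 samples).
#' @param window window width in bp (default 100 kb).
#' @param chrom_lengths optional named chromosome lengths; defaults to the
#'   maximum site position per chromosome.
#' @return data.frame (one row per window): `chrom`, `start`, `end`,
#'   `n_sites`, `pi`.
#' @export
pi_windows <- function(matrix, samples, window = 100000, chrom_lengths = NULL) {
  if (length(samples) < 2) stop("pi requires a group of >= 2 samples")
  g <- group_dosage(matrix, samples)
  n_called <- colSums(!is.na(g))
  c_alt <- colSums(g, na.rm = TRUE)
  n <- 2 * n_called
  c_ref <- n - c_alt
  term <- ifelse(n >= 2, 2 * c_ref * c_alt / (n * (n - 1)), 0)
  lens <- chrom_lengths %||% infer_chrom_lengths(matrix$sites)
  win <- tile_windows(lens, window)
  rng <- window_site_ranges(win, matrix$sites)
  win$n_sites <- as.integer(rng[, "hi"] - rng[, "lo"] + 1L)
  win$pi <- range_sums(term, rng) / (win$end - win$start + 1)
  win
}

#' Genome-wide average of defined window values
#'
#' The unweighted mean over windows with a defined statistic, the convention
#' used for per-group genome-wide pi and FST summaries.
#'
#' @param stats a window data.frame whose last column holds the statistic,
#'   or a numeric vector of window values.
#' @return the mean over non-`NA` values; `NA` if none are defined.
#' @export
mean_window_stat <- function(stats) {
  v <- if (is.data.frame(stats)) stats[[ncol(stats)]] else stats
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' Genome-wide mean nucleotide diversity
#'
#' Convenience wrapper: [pi_windows()] followed by [mean_window_stat()].
#'
#' @inheritParams pi_windows
#' @return scalar mean pi per bp.
#' @export
mean_pi <- function(matrix, samples, window = 100000, chrom_lengths = NULL) {
  mean_window_stat(pi_windows(matrix, samples, window, chrom_lengths))
}

#' Per-site Weir-Cockerham variance components
#'
#' For every site, the among-population variance component `a` and the total
#' `a + b + c` of the Weir-Cockerham (1984) two-level model for two
#' populations, computed from per-group sample sizes, allele frequencies and
#' observed heterozygote proportions. A site is unusable (components `NA`)
#' when either group has no called genotype, when the mean sample size does
#' not exceed one, or when both groups are monomorphic for the same allele.
#'
#' @param matrix a `genotype_matrix`.
#' @param samples_a,samples_b sample ids of the two groups.
#' @return data.frame with per-site columns `a`, `d` (= a + b + c) and
#'   `usable`.
#' @export
fst_components <- function(matrix, samples_a, samples_b) {
  ga <- group_dosage(matrix, samples_a)
  gb <- group_dosage(matrix, samples_b)
  n1 <- colSums(!is.na(ga)); n2 <- colSums(!is.na(gb))
  p1 <- colSums(ga, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(gb, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(ga == 1L, na.rm = TRUE) / n1
  h2 <- colSums(gb == 1L, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar  # r - 1 = 1
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  usable <- n1 >= 1 & n2 >= 1 & nbar > 1 &
    !(s2 == 0 & (pbar == 0 | pbar == 1))
  data.frame(a = ifelse(usable, a, NA_real_),
             d = ifelse(usable, a + b + cc, NA_real_),
             usable = usable)
}

#' Per-site FST between two groups
#'
#' The Weir-Cockerham ratio `a / (a + b + c)`; can be negative in small
#' samples. Unusable sites (see [fst_components()]) are `NA`.
#'
#' @inheritParams fst_components
#' @return numeric vector, one value per site.
#' @export
fst_site <- function(matrix, samples_a, samples_b) {
  comp <- fst_components(matrix, samples_a, samples_b)
  ifelse(comp$usable & comp$d != 0, comp$a / comp$d, NA_real_)
}

#' Windowed FST (sliding windows, ratio of sums)
#'
#' FST per sliding window is the weighted "ratio of sums"
#' `sum(a) / sum(a + b + c)` over the usable sites in the window; windows
#' with no usable site are `NA`. Negative window values are reported as
#' computed.
#'
#' @inheritParams fst_components
#' @param window window width in bp.
#' @param step step size in bp; `window` must be a multiple of `step`.
#' @param chrom_lengths optional named chromosome lengths.
#' @return data.frame: `chrom`, `start`, `end`, `n_sites`, `fst`.
#' @export
fst_windows <- function(matrix, samples_a, samples_b, window = 100000,
                        step = 10000, chrom_lengths = NULL) {
  comp <- fst_components(matrix, samples_a, samples_b)
  lens <- chrom_lengths %||% infer_chrom_lengths(matrix$sites)
  win <- sliding_windows(lens, window, step)
  rng <- window_site_ranges(win, matrix$sites)
  num <- range_sums(ifelse(comp$usable, comp$a, 0), rng)
  den <- range_sums(ifelse(comp$usable, comp$d, 0), rng)
  win$n_sites <- as.integer(range_sums(as.numeric(comp$usable), rng))
  win$fst <- ifelse(win$n_sites > 0 & den != 0, num / den, NA_real_)
  win
}

#' LD decay: binned mean r-squared against physical distance
#'
#' For every intra-chromosomal SNP pair separated by at most `max_dist`,
#' r-squared is the squared Pearson correlation of genotype dosage (0/1/2)
#' over samples called at both sites (composite LD; no phasing). Pairs are
#' averaged into distance bins of `bin` bp covering `(0, max_dist]`; a pair
#' at distance d falls in the bin with lower edge `bin * (ceiling(d/bin)-1)`.
#' Pairs with a zero-variance dosage at either site, or fewer than
#' `min_samples` jointly called samples, are skipped.
#'
#' @param matrix a `genotype_matrix`.
#' @param samples sample ids of the group (>= 4).
#' @param max_dist maximum pair separation in bp (default 1,000 kb).
#' @param bin bin width in bp (default 100).
#' @param min_samples minimum jointly non-missing samples per pair.
#' @return data.frame: `bin_start` (lower edge, bp), `mean_r2` (`NA` for
#'   empty bins), `n_pairs`.
#' @export
ld_decay <- function(matrix, samples, max_dist = 1000000, bin = 100,
                     min_samples = 4) {
  if (length(samples) < 4) stop("LD decay requires >= 4 samples")
  n_bins <- as.integer(ceiling(max_dist / bin))
  sum_r2 <- numeric(n_bins)
  n_pairs <- integer(n_bins)
  for (ch in unique(matrix$sites$chrom)) {
    idx <- which(matrix$sites$chrom == ch)
    if (length(idx) < 2) next
    g <- matrix$geno[samples, idx, drop = FALSE]
    pos <- matrix$sites$pos[idx]
    r2 <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))^2
    n_ok <- crossprod(!is.na(g))
    dmat <- abs(outer(pos, pos, "-"))
    keep <- upper.tri(dmat) & dmat <= max_dist & dmat > 0 &
      n_ok >= min_samples & !is.na(r2)
    d <- dmat[keep]
    v <- r2[keep]
    if (!length(d)) next
    b <- ceiling(d / bin)
    sums <- tapply(v, b, sum)
    cnts <- tapply(v, b, length)
    bi <- as.integer(names(sums))
    sum_r2[bi] <- sum_r2[bi] + sums
    n_pairs[bi] <- n_pairs[bi] + cnts
  }
  data.frame(bin_start = (seq_len(n_bins) - 1L) * bin,
             mean_r2 = ifelse(n_pairs > 0, sum_r2 / n_pairs, NA_real_),
             n_pairs = n_pairs)
}

#' Half-maximum distance of an LD decay curve
#'
#' Finds the maximum bin mean `m*`, then the smallest distance at which the
#' binned mean r-squared first drops to `m*/2`, linearly interpolating
#' between bin centers. Returns `NA` if the curve never reaches half its
#' maximum.
#'
#' @param bins data.frame from [ld_decay()].
#' @return distance in bp, or `NA` if undefined.
#' @export
half_decay_distance <- function(bins) {
  def <- !is.na(bins$mean_r2)
  if (!any(def)) stop("all LD bins are empty")
  width <- if (nrow(bins) > 1) bins$bin_start[2] - bins$bin_start[1] else 100
  centers <- bins$bin_start[def] + width / 2
  m <- bins$mean_r2[def]
  target <- max(m) / 2
  below <- which(m <= target)
  if (!length(below)) return(NA_real_)
  j <- below[1]
  if (j == 1 || m[j] == target) return(centers[j])
  # linear interpolation between the bracketing bin centers
  x0 <- centers[j - 1]; x1 <- centers[j]
  y0 <- m[j - 1]; y1 <- m[j]
  x0 + (y0 - target) / (y0 - y1) * (x1 - x0)
}

#' Write window statistics as TSV
#' @param stats window data.frame (`chrom`, `start`, `end`, ...).
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @return the path, invisibly.
#' @export
write_window_stats <- function(stats, path, seed = NULL) {
  write_tsv_with_header(stats, path, seed)
}
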
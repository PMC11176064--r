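---
title: "Methods and design notes for curdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for curdscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it computes,
the conventions it fixes where the field leaves choices open, and what its
synthetic cohorts do and do not establish about real data.

## The data model

Genotypes live in a `genotype_matrix`: diploid calls at biallelic SNP sites
coded as alternate-allele dosage 0/1/2 with `NA` for missing. Multiallelic
records and indels are dropped at VCF load (the count is reported) because
every downstream statistic is defined on biallelic SNPs; phase separators
are ignored because nothing here uses phase; missing is a first-class state
and is never imputed — filters act on missing *rates*, not on imputed
values. Sites are kept sorted by (chromosome, position) with chromosome
order fixed by first appearance, which makes every windowed computation
deterministic. Coordinates are 1-based inclusive everywhere except BED
emission (0-based half-open), and a round-trip property test pins that
convention.

## Nucleotide diversity

Per site the unbiased heterozygosity is `2 c_ref c_alt / (n (n-1))` with
`c_ref`, `c_alt` the called allele counts in the group and `n` their sum;
window π divides the site sum by the window length in bp (so invariant
sites contribute zero, as they must when only SNPs are stored). Windows
are non-overlapping 100-kb tiles anchored at position 1 of each
chromosome; the genome-wide value is the unweighted mean over windows —
the convention used when per-clade diversity levels are compared. The
last tile of a chromosome is truncated and divided by its true length.

## F_ST

Per-site variance components follow the Weir–Cockerham (1984) two-level
model for two populations, computed from sample sizes, allele frequencies
and observed heterozygote proportions. Windowed F_ST is the weighted
ratio of sums Σa / Σ(a+b+c) over the usable sites in a sliding window.
One estimator family is used for both the 50-kb/5-kb divergence windows
and the 100-kb/10-kb scan: divergence scans built on VCFtools and on
variance-component packages are both WC-family, the downstream threshold
is rank-based (top 5%), and a single coherent estimator keeps window
ranks comparable. Sites where both groups are monomorphic for the same
allele are skipped (no information about differentiation); sites with a
single called diploid per group are skipped because the small-sample
correction divides by `n̄ − 1`. Negative per-window values — expected
under weak differentiation with finite samples — are reported as
computed, never clipped, to preserve ranking fidelity.

## The divergence scan

The scan threshold is the nearest-rank top-5% cut: the `ceiling(0.05 N)`-th
largest defined window value, with all threshold ties included.
Nearest-rank was chosen over interpolated quantiles because it is exact
under ties and makes the selected count `ceiling(0.05 N)` plus ties — a
testable identity. Merging is two-stage: overlapping or bookended selected
windows become fragments (sliding windows overlap by construction, so
"neighbouring" is read as "touching"); fragments merge into one region
when the gap between them is strictly less than 100 kb. Both stages run
on interval algebra (`GenomicRanges::reduce`), and regions never span
chromosomes. The top-5% cut is applied genome-wide, not per chromosome —
with a whole-genome scan the per-chromosome alternative would make
thresholds depend on chromosome length. Genes overlap a region with ≥ 1 bp.

Note what a top-percentile selection implies: 5% of windows are selected
*by construction*, so a genome with one true sweep still yields a handful
of background regions from the tail of the drift distribution. The planted
-block recovery test therefore asserts that exactly one final region
contains the block midpoint, not that only one region exists.

## Consensus genotypes and identity windows

A group's pseudo-ancestral consensus is the per-site modal genotype call
over non-missing calls, ties broken toward the smaller alternate dosage
(hom-ref < het < hom-alt) for determinism; all-missing sites have missing
consensus. Donor-vs-consensus identity is evaluated in consecutive
non-overlapping 5-kb tiles from position 1 — the "consecutive windows"
reading, which also keeps called region lengths on a 5-kb grid, matching
how identical-region lengths are reported. A tile passes with at least 5
shared SNPs (both calls non-missing) and similarity strictly above 0.96;
similarity is strict state identity, so a donor het against a consensus
hom counts as a mismatch. Counting partial allele sharing at het sites
would be a defensible alternative; strict matching was chosen because the
comparison is defined per SNP site on genotype states, and the choice is
isolated in one comparison so it can be revisited. Passing runs merge into
identical regions; per donor, the genome fraction is the summed region
length over the genome length, with a 5-kb fragment-length histogram.

## Gene-body genotypes and discrimination capacity

Gene-body genotype strings concatenate the dosage codes of the SNPs inside
the gene span in genomic order, with "." for missing. The representative
genotype is the modal string (lexicographic tie-break); discrimination
capacity is the number of distinct strings divided by group size, bounded
by 1/n and 1. Strings containing missing symbols count as distinct
genotypes — an upper bound on capacity; collapsing them onto compatible
complete strings would require an imputation model the package
deliberately avoids. The homology filter retains hits with mutual
coverage > 0.70, identity > 75 and mismatches over the alignment length
< 0.25; "mismatch rate over the aligned span" is the natural reading of a
mismatches/coverage ratio, and the denominator choice is isolated in one
predicate. All thresholds here and above are strict inequalities, exactly
as worded in the conventions they encode.

## Fourfold-degenerate sites

Degeneracy is classified per CDS base under the standard genetic code
(nuclear plant genes): the number of bases at that codon position
preserving the amino acid, with nondegenerate positions written 0-fold.
Minus-strand genes are classified on the reverse complement and mapped
back to forward coordinates; phases are honoured (the test genomes
include two-exon genes with non-zero phases); genes with frame-breaking
lengths or internal stops are skipped with a warning. Positions claimed
by overlapping transcripts with disagreeing degeneracy are marked
conflicted and excluded from 4d sets — the conservative choice for a
neutrality proxy. The 4d-SNP filter keeps 4-fold, non-conflicted sites
with MAF > 0.05 (computed on non-missing alleles) and missing rate < 0.20.
The classifier is validated against an exhaustive mutate-every-base-and-
retranslate oracle, which pins both the genetic-code table and the
coordinate mapping.

## LD decay

r² is the squared Pearson correlation of genotype dosage over samples
called at both sites (composite LD) — the deterministic choice for
unphased data, avoiding EM haplotype estimation. All intra-chromosomal
pairs within 1000 kb are averaged into 100-bp distance bins; pairs with a
zero-variance dosage or fewer than 4 jointly called samples are skipped.
The half-maximum distance takes the maximum bin mean m*, then linearly
interpolates between bin centers to the first crossing of m*/2,
returning undefined if the curve never reaches it. The all-pairs
computation is quadratic in sites per chromosome and is intended for the
package's toy scales; subset sites before calling it on dense data.

## Bulked-segregant analysis

Per bulk, the SNP index is the fraction of reads carrying the parent-A
allele, undefined below a depth floor (default 8 reads — the upstream
conventions filter on base/mapping quality > 30 but set no depth floor,
and an index computed from a handful of reads is noise). Δ(SNP index) is
bulk-1 minus bulk-2 on parent-A-polarized counts; windows are 1,000-kb /
10-kb sliding means, unweighted across sites (the common convention;
depth already gates per-site inclusion). The null band simulates, per
replicate and bulk independently, 20 F2 genotypes at probabilities
(¼, ½, ¼), the bulk allele frequency (2n_AA + n_Aa)/40, binomial reads at
the observed depth, and takes empirical 2.5/97.5% quantiles of Δ over
10,000 replicates on a depth grid of 10–100×; observed windows look up
the nearest grid depth. Candidate regions are maximal runs of windows
whose mean Δ exceeds the depth-matched band. Because the bulk allele
count is a sum of independent gamete draws, the simulation draws it
binomially — distributionally identical to looping individuals, and fast
enough that bands are always recomputed rather than cached.

## The synthetic cohorts

The generator is frequency-based rather than coalescent: per site an
ancestral frequency ~ U(0.05, 0.95), per-group truncated-normal
perturbations scaled by a drift parameter, binomial diploid draws, 3%
uniform missingness. This gives direct control over the quantities the
pipeline measures — allele-frequency gaps (0.8 in planted sweep blocks,
yielding windowed F_ST far above a drift background), identical tracts
(donor calls copied from the recipient consensus, flipped with 2% noise),
and an F2 design (bulks of 20, 50× depth, Haldane recombination at
5 cM/Mb around one causal locus, an unlinked chromosome as the null).
Default cohort sizes (20 per group), SNP densities (1/kb for 10-Mb scan
chromosomes; 30/kb for the 1-Mb identity-painting chromosome, the
realistic density for this kind of resequencing cohort) and the planted
feature sizes (300-kb sweep block, 50-kb tracts) are fixed once as the
package's study conditions. Problem sizes in the tests (10-Mb scan
chromosome, 1-Mb painting chromosome, 10,000 null-band replicates) were
chosen as the smallest scales at which the planted effects are
unambiguous.

What the passing tests show: the estimators agree with independent
transcriptions and brute-force enumerations to 1e-12; the region calling
logic is bit-exact at its thresholds; planted features of realistic
effect size are recovered. What they do not show: behaviour under real
LD structure (sites are independent given frequencies — there is no
recombination map in the cohort generator), under systematic missingness
or genotyping error, or under the reference-bias and mapping artefacts of
real resequencing. The BSA simplification (site-wise independence given
the causal genotype) overstates the smoothness of real Δ profiles.

## Degenerate inputs and numerical conventions

Empty matrices, all-missing sites, monomorphic windows, zero-SNP genes,
empty region lists and empty LD bins all have defined behaviour (explicit
errors or `NA`/empty results) and are covered by tests. Window statistics
report `n_sites` so undefined windows are distinguishable from zero-valued
ones. All quantile computations are type-1 (inverse empirical CDF) for
determinism; every simulation takes an explicit seed; pipeline outputs
are written atomically (temp-then-rename) with a header naming the
package version and seed.

## Known limitations

- The LD module holds a per-chromosome site×site correlation matrix;
  it is quadratic in memory and intended for subsets, not whole dense
  chromosomes.
- Windowed F_ST uses one estimator family; mean-of-ratios alternatives
  will rank windows slightly differently near the selection threshold.
- Identity painting compares one donor at a time to a single consensus;
  it does not model mosaic ancestry or compute f-statistics.
- The BSA module expects pre-polarized counts (parent-A vs parent-B
  reads); it does not call or polarize variants from alignments.
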
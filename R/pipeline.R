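# Staged pipeline driver: classify-sites -> popstats -> sweep-scan ->
# ancestry -> gene-genotypes -> bsa, configured from a YAML file, plus a
# one-shot seeded demo that simulates every fixture and runs all stages.

default_config <- function() {
  list(
    pi_window = 100000,            # pi per 100-kb window
    fst_div_window = 50000,        # group-divergence FST: 50-kb / 5-kb
    fst_div_step = 5000,
    fst_scan_window = 100000,      # divergence scan: 100-kb / 10-kb
    fst_scan_step = 10000,
    top_fraction = 0.05,           # top 5% of scan windows
    merge_bridge = 100000,         # fragments merged when gap < 100 kb
    identity_window = 5000,        # 5-kb identity tiles
    identity_min_shared = 5,       # >= 5 shared SNPs
    identity_min_similarity = 0.96, # similarity > 96%
    maf_min = 0.05,                # 4d-SNP filter: MAF > 0.05
    missing_max = 0.20,            # missing rate < 20%
    ld_max_dist = 1000000,         # LD pairs within 1000 kb
    ld_bin = 100,                  # 100-bp distance bins
    bsa_window = 1000000,          # BSA: 1,000-kb window / 10-kb step
    bsa_step = 10000,
    bsa_min_depth = 8,
    bulk_size = 20,                # individuals per bulk
    band_replicates = 10000,
    band_confidence = 0.95,
    band_depths = seq(10, 100, by = 10)
  )
}

write_atomic <- function(write_fn, path) {
  tmp <- paste0(path, ".tmp")
  write_fn(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' Executes the stages in dependency order (classify-sites, popstats,
#' sweep-scan, ancestry, gene-genotypes, bsa), reading inputs and thresholds
#' from a YAML configuration (or an equivalent named list). Every threshold
#' defaults to the study convention (see `vignette("curdscan-methods")`);
#' outputs are TSV/BED files carrying a header comment naming the package
#' version and seed, written atomically (temp-then-rename).
#'
#' Recognized configuration keys: `vcf`, `groups_tsv`, `fasta`, `gff`,
#' `bulk_counts_tsv`, `out_dir`, `seed`, `stages` (subset of the six stage
#' names), the group labels `pi_groups`, `fst_pair` (length 2),
#' `ancestry_group`, `donors`, and every threshold listed above.
#'
#' @param config path to a YAML file, or a named list.
#' @return invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  for (key in c("vcf", "groups_tsv", "out_dir", "seed"))
    if (is.null(cfg[[key]]))
      stop("config field missing: ", key)
  stages <- cfg$stages %||% c("classify-sites", "popstats", "sweep-scan",
                              "ancestry", "gene-genotypes", "bsa")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  res <- list()

  mat <- load_genotypes(cfg$vcf)
  groups <- load_groups(cfg$groups_tsv, mat)
  seed <- cfg$seed
  lens <- NULL
  if (!is.null(cfg$fasta)) {
    genome <- read_genome(cfg$fasta)
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
  }

  if ("classify-sites" %in% stages) {
    if (is.null(cfg$fasta) || is.null(cfg$gff))
      stop("config field missing: fasta/gff (required by classify-sites)")
    classes <- classify_degeneracy(cfg$fasta, cfg$gff)
    write_atomic(function(p) write_site_classes(classes, p, seed),
                 out("site_classes.tsv"))
    res$classes <- classes
  }

  if ("popstats" %in% stages) {
    multi <- names(which(table(groups) >= 2))
    for (lab in (cfg$pi_groups %||% unique(groups)[unique(groups) %in% multi])) {
      pw <- pi_windows(mat, group_samples(groups, lab), cfg$pi_window, lens)
      write_atomic(function(p) write_window_stats(pw, p, seed),
                   out(sprintf("pi_%s.tsv", lab)))
      res$pi[[lab]] <- pw
    }
    pair <- cfg$fst_pair %||% utils::head(unique(groups), 2)
    fw <- fst_windows(mat, group_samples(groups, pair[1]),
                      group_samples(groups, pair[2]),
                      cfg$fst_div_window, cfg$fst_div_step, lens)
    write_atomic(function(p) write_window_stats(fw, p, seed),
                 out("fst_divergence.tsv"))
    res$fst_divergence <- fw
  }

  if ("sweep-scan" %in% stages) {
    pair <- cfg$fst_pair %||% utils::head(unique(groups), 2)
    scan <- fst_windows(mat, group_samples(groups, pair[1]),
                        group_samples(groups, pair[2]),
                        cfg$fst_scan_window, cfg$fst_scan_step, lens)
    sel <- top_percentile_select(scan, cfg$top_fraction)
    regions <- merge_to_regions(sel$selected, cfg$merge_bridge)
    write_atomic(function(p) write_window_stats(scan, p, seed),
                 out("fst_scan.tsv"))
    write_atomic(function(p) write_regions_bed(regions, p),
                 out("diverged_regions.bed"))
    if (!is.null(cfg$gff)) {
      gmap <- genes_in_regions(regions, cfg$gff)
      write_atomic(function(p) write_tsv_with_header(gmap, p, seed),
                   out("region_genes.tsv"))
      res$region_genes <- gmap
    }
    res$scan <- scan; res$scan_threshold <- sel$threshold
    res$diverged_regions <- regions
  }

  if ("ancestry" %in% stages) {
    lab <- cfg$ancestry_group %||% unique(groups)[1]
    donors <- cfg$donors %||% character(0)
    cons <- build_consensus(mat, group_samples(groups, lab))
    glen <- sum(lens %||% infer_chrom_lengths(mat$sites))
    contrib <- list()
    for (d in donors) {
      iw <- identity_windows(mat, d, cons, cfg$identity_window,
                             cfg$identity_min_shared,
                             cfg$identity_min_similarity, lens)
      reg <- call_identical_regions(iw)
      reg$label <- rep(d, nrow(reg))
      write_atomic(function(p) write_regions_bed(
        reg[, c("chrom", "start", "end", "label")], p),
        out(sprintf("identical_regions_%s.bed", d)))
      cs <- contribution_summary(reg, glen)
      contrib[[d]] <- data.frame(donor = d, group = lab,
                                 fraction = cs$fraction,
                                 n_regions = cs$n_regions,
                                 mean_len = cs$mean_length)
      res$identity[[d]] <- iw
    }
    if (length(contrib))
      write_atomic(function(p)
        write_tsv_with_header(do.call(rbind, contrib), p, seed),
        out("donor_contribution.tsv"))
    res$consensus <- cons
    res$contribution <- if (length(contrib)) do.call(rbind, contrib) else NULL
  }

  if ("gene-genotypes" %in% stages && !is.null(cfg$gff) &&
      !is.null(res$diverged_regions) && nrow(res$diverged_regions) > 0) {
    prof <- discrimination_profile(res$diverged_regions, mat, groups, cfg$gff)
    write_atomic(function(p) write_tsv_with_header(prof, p, seed),
                 out("discrimination_profile.tsv"))
    res$discrimination <- prof
  }

  if ("bsa" %in% stages && !is.null(cfg$bulk_counts_tsv)) {
    counts <- read_bulk_counts(cfg$bulk_counts_tsv)
    sites <- delta_snp_index(counts, cfg$bsa_min_depth)
    win <- windowed_delta(sites, cfg$bsa_window, cfg$bsa_step)
    bands <- null_band_grid(cfg$band_depths, cfg$bulk_size,
                            cfg$band_replicates, cfg$band_confidence,
                            seed = seed)
    cand <- call_candidate_regions(win, bands)
    bi <- vapply(win$depth, function(dp)
      if (is.na(dp)) NA_integer_ else which.min(abs(bands$depth - dp)),
      integer(1))
    track <- cbind(win, lower = bands$lower[bi], upper = bands$upper[bi])
    write_atomic(function(p) write_tsv_with_header(track, p, seed),
                 out("bsa_windows.tsv"))
    cand$label <- rep("bsa_candidate", nrow(cand))
    write_atomic(function(p) write_regions_bed(
      cand[, c("chrom", "start", "end", "label")], p),
      out("bsa_candidate_regions.bed"))
    res$bsa_windows <- win; res$bsa_bands <- bands
    res$bsa_regions <- cand
  }

  invisible(res)
}

#' One-shot demo: simulate all fixtures and run every stage
#'
#' Generates a seeded toy cohort — toy genome, three-group genotypes with a
#' planted divergent block, a wild donor with planted identical tracts, and
#' F2 bulk counts with one causal locus — writes the fixtures and ground
#' truth under `out_dir`, then runs the full pipeline on them.
#'
#' @param out_dir output directory.
#' @param seed RNG seed (default 42).
#' @return invisibly, the pipeline result list plus `$truth`.
#' @export
run_demo <- function(out_dir, seed = 42) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fix <- file.path(out_dir, "fixtures")
  dir.create(fix, showWarnings = FALSE)
  toy <- make_toy_genome(seed, chrom_lengths = c(chrA = 30000, chrB = 20000))
  write_toy_genome(toy, file.path(fix, "toy_genome.fa"),
                   file.path(fix, "toy_genome.gff3"))
  blocks <- data.frame(chrom = "chr1", start = 4000001, end = 4300000,
                       group_a = "Curdless", group_b = "WhiteCurd", gap = 0.8)
  sim <- simulate_groups(seed, chrom_lengths = c(chr1 = 10000000),
                         sweep_blocks = blocks)
  wild <- matrix(stats::rbinom(2 * ncol(sim$matrix$geno), 2, 0.5),
                 nrow = 2,
                 dimnames = list(c("Wild_01", "Wild_02"), NULL))
  geno <- rbind(sim$matrix$geno, wild)
  mat <- genotype_matrix(geno, sim$matrix$sites)
  groups <- c(sim$groups, Wild_01 = "Wild", Wild_02 = "Wild")
  tracts <- data.frame(chrom = "chr1",
                       start = c(1000001, 7000001),
                       end = c(1050000, 7050000),
                       donor = "Wild_01", stringsAsFactors = FALSE)
  intro <- plant_introgressions(mat, tracts,
                                group_samples(groups, "Curdless"),
                                noise = 0.02, seed = seed + 1)
  mat <- intro$matrix
  write_genotypes_vcf(mat, file.path(fix, "cohort.vcf"),
                      chrom_lengths = c(chr1 = 10000000))
  write_groups_tsv(groups, file.path(fix, "groups.tsv"))
  f2 <- simulate_f2_bulks(seed + 2)
  write_bulk_counts(f2$counts, file.path(fix, "bulk_counts.tsv"))
  truth <- list(groups = sim$truth, introgression = intro$truth,
                f2 = f2$truth)
  write_ground_truth(truth["introgression"], file.path(fix, "ground_truth.json"))
  cfg <- list(vcf = file.path(fix, "cohort.vcf"),
              groups_tsv = file.path(fix, "groups.tsv"),
              fasta = file.path(fix, "toy_genome.fa"),
              gff = file.path(fix, "toy_genome.gff3"),
              bulk_counts_tsv = file.path(fix, "bulk_counts.tsv"),
              out_dir = out_dir, seed = seed,
              fst_pair = c("Curdless", "WhiteCurd"),
              ancestry_group = "Curdless",
              donors = c("Wild_01", "Wild_02"),
              stages = c("popstats", "sweep-scan", "ancestry", "bsa"))
  res <- run_pipeline(cfg)
  res$truth <- truth
  invisible(res)
}
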
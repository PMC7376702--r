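#' Run the full sweep scan on a VCF
#'
#' End-to-end pipeline: read the VCF and population file, compute
#' windowed Fst / pi / pi-ratio, derive thresholds under the policy,
#' flag and merge candidate windows, optionally intersect with gene
#' annotation, and write all outputs into `out_dir`:
#' `windows.tsv`, `sweep_regions.bed`, `gene_hits.tsv` (if annotation
#' given) and `run_metadata.json` (cutoffs, counts, config echo and
#' hash).  Deterministic given identical inputs and configuration.
#'
#' @param vcf Path to the input VCF.
#' @param pops Path to the sample-to-group TSV (or a
#'   [population_assignment()]).
#' @param genes Optional gene annotation path (GFF3/BED) or data.frame
#'   from [read_gene_annotation()].
#' @param out_dir Output directory, created if needed.
#' @param window_bp,step_bp Sliding-window geometry (defaults 10 kb /
#'   5 kb).
#' @param policy A [threshold_policy()].
#' @param max_gap_bp Merge gap for [merge_windows()].
#' @param max_missing Site missingness ceiling for [read_vcf()].
#' @param pi_denominator `"span"` or `"snps"` (see [window_stats()]).
#' @return Invisibly, a list with `windows`, `cutoffs`, `regions`,
#'   `gene_hits` (or `NULL`) and `metadata`.
#' @export
run_scan <- function(vcf, pops, genes = NULL, out_dir,
                     window_bp = 10000, step_bp = 5000,
                     policy = threshold_policy(),
                     max_gap_bp = 0, max_missing = 0.2,
                     pi_denominator = "span") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gm <- read_vcf(vcf, max_missing = max_missing)
  if (!inherits(pops, "population_assignment")) {
    pops <- read_population_file(pops)
  }
  stats <- window_stats(gm, pops, window_bp, step_bp,
                        pi_denominator = pi_denominator)
  # windows with no SNPs carry no information and are dropped from
  # ranking and calling
  ranked <- stats[stats$n_snps > 0, , drop = FALSE]
  cutoffs <- compute_thresholds(ranked, policy)
  flagged <- flag_windows(ranked, cutoffs)
  regions <- merge_windows(flagged, max_gap_bp = max_gap_bp)

  gene_hits <- NULL
  if (!is.null(genes)) {
    if (is.character(genes)) genes <- read_gene_annotation(genes)
    gene_hits <- intersect_genes(regions, genes)
  }

  write_window_stats(stats, file.path(out_dir, "windows.tsv"))
  write_regions_bed(regions, file.path(out_dir, "sweep_regions.bed"))
  if (!is.null(gene_hits)) {
    utils::write.table(gene_hits, file.path(out_dir, "gene_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  config <- list(window_bp = window_bp, step_bp = step_bp,
                 policy = unclass(policy), max_gap_bp = max_gap_bp,
                 max_missing = max_missing,
                 pi_denominator = pi_denominator)
  metadata <- list(
    tool = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    config = config,
    config_hash = config_hash(config),
    cutoffs = cutoffs[c("fst_cutoff", "ratio_low", "ratio_high",
                        "mode", "direction")],
    counts = list(
      sites = n_sites(gm),
      site_exclusions = as.list(attr(gm, "exclusions")),
      windows_total = nrow(stats),
      windows_ranked = nrow(ranked),
      windows_flagged = sum(flagged$flagged),
      regions = nrow(regions),
      genes_hit = if (is.null(gene_hits)) NA_integer_
                  else attr(gene_hits, "n_unique_genes")
    )
  )
  jsonlite::write_json(metadata, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(windows = stats, cutoffs = cutoffs, regions = regions,
                 gene_hits = gene_hits, metadata = metadata))
}

#' LD decay (and optional pruning) from a VCF
#'
#' @param vcf Input VCF path.
#' @param out_dir Output directory; writes `ld_decay.tsv` and, when
#'   `prune = TRUE`, `pruned.vcf` plus `retained_sites.tsv`.
#' @param samples Optional sample subset (ids).
#' @param max_dist_bp,bin_bp Decay-curve range and bin width.
#' @param prune Run [ld_prune()] as well?
#' @param window_snps,step_snps,r2_threshold Pruning parameters
#'   (PLINK-style defaults 50 / 5 / 0.2).
#' @return Invisibly, list with `decay` and (if pruning) `retained`.
#' @export
run_ld <- function(vcf, out_dir, samples = NULL,
                   max_dist_bp = 300000, bin_bp = 1000,
                   prune = FALSE, window_snps = 50, step_snps = 5,
                   r2_threshold = 0.2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gm <- read_vcf(vcf)
  if (max_dist_bp < min_snp_spacing(gm)) {
    warning("max_dist_bp is below the smallest SNP spacing; decay curve will be empty")
  }
  decay <- ld_decay(gm, samples = samples, max_dist_bp = max_dist_bp,
                    bin_bp = bin_bp)
  utils::write.table(decay, file.path(out_dir, "ld_decay.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  retained <- NULL
  if (prune) {
    retained <- ld_prune(gm, window_snps, step_snps, r2_threshold)
    write_vcf(subset_sites(gm, retained), file.path(out_dir, "pruned.vcf"))
    utils::write.table(
      data.frame(chrom = gm$chrom[retained], pos = gm$pos0[retained] + 1L),
      file.path(out_dir, "retained_sites.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(list(decay = decay, retained = retained))
}

min_snp_spacing <- function(gm) {
  sp <- Inf
  for (ch in unique(gm$chrom)) {
    p <- gm$pos0[gm$chrom == ch]
    if (length(p) > 1) sp <- min(sp, min(diff(p)))
  }
  sp
}

#' Distance matrices and NJ tree from a VCF
#'
#' Writes the p-distance and identity-score matrices as TSV and the
#' neighbor-joining tree as Newick; with `bootstrap > 0` also a
#' `support.tsv` of clade bootstrap counts.
#'
#' @param vcf Input VCF path.
#' @param out_dir Output directory.
#' @param bootstrap Number of site-bootstrap replicates (0 = none).
#' @param seed Seed for the bootstrap resampling.
#' @return Invisibly, list with `tree`, `distances`, `support`.
#' @export
run_tree <- function(vcf, out_dir, bootstrap = 0, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gm <- read_vcf(vcf)
  d <- distance_matrix(gm)
  utils::write.table(d, file.path(out_dir, "p_distance.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(1 - d, file.path(out_dir, "identity_score.tsv"),
                     sep = "\t", quote = FALSE)
  support <- NULL
  if (bootstrap > 0) {
    bs <- bootstrap_nj(gm, reps = bootstrap, seed = seed)
    tree <- bs$tree
    support <- bs$support
    utils::write.table(data.frame(node = seq_along(support) +
                                    length(tree$tip.label),
                                  support = support),
                       file.path(out_dir, "support.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tree <- nj_tree(d)
  }
  writeLines(to_newick(tree), file.path(out_dir, "tree.nwk"))
  invisible(list(tree = tree, distances = d, support = support))
}

#' Intersect existing sweep regions with gene annotation
#'
#' @param regions_bed BED file of regions (first four columns used:
#'   chrom, start, end, tail label).
#' @param genes Gene annotation path or data.frame.
#' @param out_dir Output directory; writes `gene_hits.tsv`.
#' @return Invisibly, the gene-hit data.frame.
#' @export
run_annotate <- function(regions_bed, genes, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  first <- tryCatch(readLines(regions_bed, n = 1), error = function(e) character())
  if (!length(first)) {
    regions <- data.frame(chrom = character(), start = integer(),
                          end = integer(), tail = character())
  } else {
    bed <- utils::read.table(regions_bed, sep = "\t", stringsAsFactors = FALSE)
    regions <- data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
                          tail = if (ncol(bed) >= 4) bed[[4]] else ".",
                          stringsAsFactors = FALSE)
  }
  if (is.character(genes)) genes <- read_gene_annotation(genes)
  hits <- intersect_genes(regions, genes)
  utils::write.table(hits, file.path(out_dir, "gene_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(hits)
}

#' Simulate a dataset into a directory
#'
#' Thin wrapper over [simulate_dataset()] accepting loose config
#' arguments.
#'
#' @param out_dir Output directory.
#' @param ... Passed to [simulation_config()].
#' @return Invisibly, the [simulate_dataset()] result.
#' @export
run_simulate <- function(out_dir, ...) {
  simulate_dataset(simulation_config(...), out_dir)
}

# 32-bit FNV-1a over the JSON serialization of a config list; used to
# stamp outputs so reruns with identical settings are identifiable.
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- ((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
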
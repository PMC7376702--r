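#' Configuration for the two-population genotype simulator
#'
#' Defines the simulated study: two groups of diploid samples genotyped
#' at biallelic SNPs scattered along one or more chromosomes.  Ancestral
#' allele frequencies follow a symmetric Beta (U-shaped by default, as
#' in a drift-dominated site-frequency spectrum); group frequencies
#' diverge from the ancestral value under the Balding--Nichols model
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = f_background`.  Inside each
#' sweep interval the group1 frequency is instead pushed towards
#' fixation of the alternate allele so that its expected heterozygosity
#' is `diversity_reduction` times the background expectation, emulating
#' a hard sweep in the selected group.
#'
#' @param seed Integer seed governing every random draw.
#' @param n_per_group Length-2 integer: samples in group1 and group2.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param snp_density Expected SNPs per bp (default 1/500).
#' @param af_beta_shape Shape of the symmetric Beta ancestral-frequency
#'   model (default 0.2; smaller = more U-shaped).
#' @param f_background Balding--Nichols divergence F between the groups
#'   outside sweeps (default 0.05; 0 means identical group frequencies).
#' @param sweeps Data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `diversity_reduction` (target pi fraction
#'   retained in group1) and `fst_target` (intended differentiation
#'   level, recorded and checked for feasibility).
#' @param missing_rate Per-genotype missing-call probability.
#' @param group_labels Length-2 character labels for the groups.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_per_group = c(10, 10),
                              chrom_lengths = c(chr1 = 5e6),
                              snp_density = 1 / 500,
                              af_beta_shape = 0.2,
                              f_background = 0.05,
                              sweeps = data.frame(
                                chrom = "chr1", start = 2450000,
                                end = 2550000,
                                diversity_reduction = 0.1,
                                fst_target = 0.4
                              ),
                              missing_rate = 0.02,
                              group_labels = c("black", "nonblack")) {
  stopifnot(snp_density > 0, af_beta_shape > 0,
            f_background >= 0, f_background < 1,
            missing_rate >= 0, missing_rate <= 1,
            length(n_per_group) == 2, all(n_per_group >= 1),
            !is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  if (!is.null(sweeps) && nrow(sweeps)) {
    stopifnot(all(sweeps$chrom %in% names(chrom_lengths)),
              all(sweeps$start >= 0),
              all(sweeps$end <= chrom_lengths[sweeps$chrom]),
              all(sweeps$start < sweeps$end),
              all(sweeps$diversity_reduction >= 0),
              all(sweeps$diversity_reduction <= 1))
    infeasible <- sweeps$fst_target >= 1 & sweeps$diversity_reduction > 0
    if (any(infeasible)) {
      stop("infeasible sweep: target Fst of 1 requires zero retained diversity")
    }
  }
  structure(list(seed = seed, n_per_group = n_per_group,
                 chrom_lengths = chrom_lengths, snp_density = snp_density,
                 af_beta_shape = af_beta_shape, f_background = f_background,
                 sweeps = sweeps, missing_rate = missing_rate,
                 group_labels = group_labels),
            class = "simulation_config")
}

# Balding-Nichols draw of a descendant population frequency.
bn_draw <- function(p, f) {
  if (f == 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a two-population SNP dataset with known sweeps
#'
#' Generates genotypes under the model described in
#' [simulation_config()], writes a sorted VCF, a sample-to-group TSV, a
#' tiled GFF3 gene annotation (genes every 40 kb, 20 kb long, so some
#' overlap any sweep) and the ground truth (BED + JSON), and returns the
#' file paths together with the truth object.  Output is a deterministic
#' function of the config seed.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with paths `vcf`, `pops`, `genes`,
#'   `truth_bed`, `truth_json` and the `truth` list (sweep intervals
#'   with realized mean Fst and pi ratio, plus the config echo).
#' @export
simulate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n1 <- cfg$n_per_group[1]; n2 <- cfg$n_per_group[2]
  samples <- c(sprintf("%s_%02d", cfg$group_labels[1], seq_len(n1)),
               sprintf("%s_%02d", cfg$group_labels[2], seq_len(n2)))

  sim <- withr_seed(cfg$seed, {
    all_chrom <- character(); all_pos <- integer()
    all_p1 <- numeric(); all_p2 <- numeric(); in_sweep <- logical()
    for (ch in names(cfg$chrom_lengths)) {
      L <- cfg$chrom_lengths[[ch]]
      n_snp <- stats::rpois(1, L * cfg$snp_density)
      pos <- sort(sample.int(L, min(n_snp, L)))  # 1-based, unique
      p_anc <- stats::rbeta(length(pos), cfg$af_beta_shape, cfg$af_beta_shape)
      # keep ancestral frequencies away from exact fixation
      p_anc <- pmin(pmax(p_anc, 1e-3), 1 - 1e-3)
      p1 <- bn_draw(p_anc, cfg$f_background)
      p2 <- bn_draw(p_anc, cfg$f_background)
      sw <- rep(FALSE, length(pos))
      if (!is.null(cfg$sweeps) && nrow(cfg$sweeps)) {
        rows <- which(cfg$sweeps$chrom == ch)
        for (r in rows) {
          hit <- (pos - 1L) >= cfg$sweeps$start[r] & (pos - 1L) < cfg$sweeps$end[r]
          if (!any(hit)) next
          dr <- cfg$sweeps$diversity_reduction[r]
          # expected group1 heterozygosity rescaled to dr times the
          # background value, alternate allele driven towards fixation
          h <- dr * 2 * p_anc[hit] * (1 - p_anc[hit])
          p1[hit] <- (1 + sqrt(pmax(1 - 2 * h, 0))) / 2
          sw <- sw | hit
        }
      }
      all_chrom <- c(all_chrom, rep(ch, length(pos)))
      all_pos <- c(all_pos, pos)
      all_p1 <- c(all_p1, p1); all_p2 <- c(all_p2, p2)
      in_sweep <- c(in_sweep, sw)
    }
    n_site <- length(all_pos)
    d1 <- matrix(stats::rbinom(n1 * n_site, 2, rep(all_p1, each = n1)),
                 nrow = n1)
    d2 <- matrix(stats::rbinom(n2 * n_site, 2, rep(all_p2, each = n2)),
                 nrow = n2)
    dos <- rbind(d1, d2)
    if (cfg$missing_rate > 0) {
      dos[stats::runif(length(dos)) < cfg$missing_rate] <- NA_integer_
    }
    rownames(dos) <- samples
    list(chrom = all_chrom, pos = all_pos, dosage = dos,
         p1 = all_p1, p2 = all_p2, in_sweep = in_sweep)
  })

  # alternating ref/alt bases just to have valid SNP records
  n_site <- length(sim$pos)
  ref <- rep(c("A", "C"), length.out = n_site)
  alt <- rep(c("G", "T"), length.out = n_site)
  gm <- genotype_matrix(sim$dosage, sim$chrom, sim$pos, ref, alt)

  paths <- list(vcf = file.path(dir, "sim.vcf"),
                pops = file.path(dir, "populations.tsv"),
                genes = file.path(dir, "genes.gff3"),
                truth_bed = file.path(dir, "truth.bed"),
                truth_json = file.path(dir, "truth.json"))
  write_vcf(gm, paths$vcf)
  grp <- rep(cfg$group_labels, cfg$n_per_group)
  utils::write.table(data.frame(samples, grp), paths$pops, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tiled_genes(cfg$chrom_lengths, paths$genes)

  truth <- sim_truth(cfg, sim)
  writeLines(paste(truth$intervals$chrom, as.integer(truth$intervals$start),
                   as.integer(truth$intervals$end), "sweep", sep = "\t"),
             paths$truth_bed)
  jsonlite::write_json(
    list(seed = cfg$seed, intervals = truth$intervals,
         config = unclass(cfg)[setdiff(names(cfg), "sweeps")]),
    paths$truth_json, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(paths, list(truth = truth)))
}

# Realized per-interval mean Fst and pi ratio from the simulated
# genotypes (sample frequencies, same estimators as the scan).
sim_truth <- function(cfg, sim) {
  n1 <- cfg$n_per_group[1]
  idx1 <- seq_len(n1)
  idx2 <- seq_len(cfg$n_per_group[2]) + n1
  iv <- if (is.null(cfg$sweeps)) NULL else cfg$sweeps
  realized <- NULL
  if (!is.null(iv) && nrow(iv)) {
    realized <- do.call(rbind, lapply(seq_len(nrow(iv)), function(r) {
      hit <- sim$chrom == iv$chrom[r] &
        (sim$pos - 1L) >= iv$start[r] & (sim$pos - 1L) < iv$end[r]
      d1 <- sim$dosage[idx1, hit, drop = FALSE]
      d2 <- sim$dosage[idx2, hit, drop = FALSE]
      nn1 <- 2 * colSums(!is.na(d1)); nn2 <- 2 * colSums(!is.na(d2))
      q1 <- colSums(d1, na.rm = TRUE) / pmax(nn1, 1)
      q2 <- colSums(d2, na.rm = TRUE) / pmax(nn2, 1)
      fst <- snp_fst(q1, q2)
      h1 <- sum(pi_site_contrib(q1, nn1)); h2 <- sum(pi_site_contrib(q2, nn2))
      data.frame(mean_fst = mean(fst, na.rm = TRUE),
                 pi_ratio = if (h2 > 0) h1 / h2 else NA_real_)
    }))
  }
  intervals <- if (is.null(iv) || !nrow(iv)) {
    data.frame(chrom = character(), start = integer(), end = integer())
  } else {
    cbind(iv[, c("chrom", "start", "end")], realized)
  }
  list(intervals = intervals, seed = cfg$seed)
}

# Uniformly tiled gene models: a 20 kb gene every 40 kb on each
# chromosome, written as GFF3 "gene" features (1-based inclusive).
write_tiled_genes <- function(chrom_lengths, path,
                              gene_bp = 20000, spacing_bp = 40000) {
  lines <- "##gff-version 3"
  g <- 0L
  for (ch in names(chrom_lengths)) {
    starts0 <- as.integer(seq.int(0L, max(0L, chrom_lengths[[ch]] - gene_bp),
                                  by = spacing_bp))
    for (s in starts0) {
      g <- g + 1L
      id <- sprintf("SIMG%05d", g)
      lines <- c(lines, paste(ch, "sweepscan_sim", "gene", s + 1L,
                              s + as.integer(gene_bp), ".", "+", ".",
                              sprintf("ID=%s;Name=%s", id, id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Score sweep recovery against simulation truth
#'
#' Compares called sweep regions with the true simulated intervals:
#' base-pair precision (overlap / called bp), recall (overlap / truth
#' bp) and, per truth interval, the best Jaccard index against any
#' called region; an interval counts as recovered when that Jaccard
#' reaches `jaccard_min`.
#'
#' @param regions Called regions (data.frame with `chrom`, `start`,
#'   `end` in 0-based half-open coordinates).
#' @param truth Truth intervals in the same form (e.g.
#'   `truth$intervals` from [simulate_dataset()]).
#' @param jaccard_min Recovery threshold on the Jaccard index
#'   (default 0.3).
#' @return List with `precision` (`NA` when nothing was called),
#'   `recall`, `n_truth`, `n_recovered` and `jaccard` (per truth
#'   interval).
#' @export
score_recovery <- function(regions, truth, jaccard_min = 0.3) {
  as_gr <- function(df) GenomicRanges::reduce(GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1L, df$end)))
  gt <- as_gr(truth)
  truth_bp <- sum(GenomicRanges::width(gt))
  if (is.null(regions) || !nrow(regions)) {
    return(list(precision = NA_real_, recall = 0,
                n_truth = nrow(truth), n_recovered = 0L,
                jaccard = rep(0, nrow(truth))))
  }
  gc_ <- as_gr(regions)
  called_bp <- sum(GenomicRanges::width(gc_))
  ov <- sum(GenomicRanges::width(GenomicRanges::intersect(gc_, gt)))
  jac <- vapply(seq_len(nrow(truth)), function(r) {
    ti <- GenomicRanges::GRanges(truth$chrom[r],
                                 IRanges::IRanges(truth$start[r] + 1L,
                                                  truth$end[r]))
    best <- 0
    for (k in seq_len(nrow(regions))) {
      ri <- GenomicRanges::GRanges(regions$chrom[k],
                                   IRanges::IRanges(regions$start[k] + 1L,
                                                    regions$end[k]))
      inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ri, ti)))
      uni <- sum(GenomicRanges::width(GenomicRanges::union(ri, ti)))
      if (uni > 0) best <- max(best, inter / uni)
    }
    best
  }, numeric(1))
  list(precision = if (called_bp > 0) ov / called_bp else NA_real_,
       recall = if (truth_bp > 0) ov / truth_bp else NA_real_,
       n_truth = nrow(truth),
       n_recovered = sum(jac >= jaccard_min),
       jaccard = jac)
}
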
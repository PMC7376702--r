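#' Genotype r-squared between two sites
#'
#' Squared Pearson correlation of unphased alternate-allele dosages over
#' pairwise-complete samples (the Rogers--Huff composite measure; no
#' phasing or haplotype EM involved).  Undefined (`NA`) when fewer than
#' two complete samples remain or either site is monomorphic among
#' them.
#'
#' @param x,y Dosage vectors of equal length.
#' @return r^2 in \[0, 1\] or `NA`.
#' @export
genotype_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("dosage vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Linkage-disequilibrium decay curve
#'
#' Scores every same-chromosome site pair separated by at most
#' `max_dist_bp` and bins mean r^2 by pairwise distance.  Distances fall
#' in contiguous bins `[k*bin_bp, (k+1)*bin_bp)`.
#'
#' @param gm A [genotype_matrix()].
#' @param samples Optional sample ids/indices restricting the panel
#'   (e.g. one breed); default all samples.
#' @param max_dist_bp Maximum pair distance in bp (default 300000).
#' @param bin_bp Bin width in bp (default 1000).
#' @return Data.frame `bin_start`, `bin_end`, `mean_r2` (`NA` for empty
#'   bins), `n_pairs`.
#' @export
ld_decay <- function(gm, samples = NULL, max_dist_bp = 300000, bin_bp = 1000) {
  stopifnot(max_dist_bp >= bin_bp, bin_bp >= 1)
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, gm$samples)
    gm <- subset_samples_raw(gm, samples)
  }
  n_bins <- ceiling(max_dist_bp / bin_bp)
  sum_r2 <- numeric(n_bins)
  n_pairs <- integer(n_bins)
  for (ch in unique(gm$chrom)) {
    idx <- which(gm$chrom == ch)
    pos <- gm$pos0[idx]
    for (a in seq_along(idx)) {
      b <- a + 1L
      while (b <= length(idx) && pos[b] - pos[a] <= max_dist_bp) {
        r2 <- genotype_r2(gm$dosage[, idx[a]], gm$dosage[, idx[b]])
        if (!is.na(r2)) {
          bin <- min(floor((pos[b] - pos[a]) / bin_bp) + 1L, n_bins)
          sum_r2[bin] <- sum_r2[bin] + r2
          n_pairs[bin] <- n_pairs[bin] + 1L
        }
        b <- b + 1L
      }
    }
  }
  data.frame(
    bin_start = (seq_len(n_bins) - 1L) * bin_bp,
    bin_end = pmin(seq_len(n_bins) * bin_bp, max_dist_bp),
    mean_r2 = ifelse(n_pairs > 0, sum_r2 / pmax(n_pairs, 1L), NA_real_),
    n_pairs = n_pairs
  )
}

#' Sliding-window LD pruning
#'
#' Greedy PLINK-style `--indep-pairwise` scheme: within each window of
#' `window_snps` consecutive sites, pairs of still-retained sites are
#' examined in position order and whenever r^2 exceeds the threshold one
#' member is removed; the window then slides forward by `step_snps`
#' sites.  The default victim is the downstream (larger-position) site;
#' `victim = "maf"` instead removes the site with the lower minor-allele
#' frequency (ties broken downstream), mimicking PLINK.
#'
#' @param gm A [genotype_matrix()].
#' @param window_snps Window size in SNPs (default 50).
#' @param step_snps Slide in SNPs (default 5); must be < `window_snps`.
#' @param r2_threshold Removal threshold on r^2 (default 0.2, strict
#'   `>`).
#' @param victim `"position"` (default) or `"maf"`.
#' @return Integer vector of retained site indices in position order.
#' @export
ld_prune <- function(gm, window_snps = 50, step_snps = 5,
                     r2_threshold = 0.2, victim = c("position", "maf")) {
  victim <- match.arg(victim)
  stopifnot(window_snps > step_snps, step_snps >= 1, r2_threshold >= 0)
  maf <- NULL
  if (victim == "maf") {
    p <- group_frequencies(gm, seq_len(n_samples(gm)))$freq
    maf <- pmin(p, 1 - p)
  }
  keep <- rep(TRUE, n_sites(gm))
  for (ch in unique(gm$chrom)) {
    idx <- which(gm$chrom == ch)
    s <- 1L
    while (s <= length(idx)) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      repeat {
        changed <- FALSE
        live <- win[keep[win]]
        if (length(live) >= 2) {
          for (a in seq_len(length(live) - 1L)) {
            if (!keep[live[a]]) next
            for (b in (a + 1L):length(live)) {
              if (!keep[live[a]]) break
              if (!keep[live[b]]) next
              r2 <- genotype_r2(gm$dosage[, live[a]], gm$dosage[, live[b]])
              if (!is.na(r2) && r2 > r2_threshold) {
                drop <- if (victim == "position") live[b]
                        else if (maf[live[a]] < maf[live[b]]) live[a]
                        else live[b]
                keep[drop] <- FALSE
                changed <- TRUE
              }
            }
          }
        }
        if (!changed) break
      }
      s <- s + step_snps
    }
  }
  which(keep)
}
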
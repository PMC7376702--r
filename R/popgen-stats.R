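#' Alternate-allele frequency from dosages
#'
#' @param dosages Integer vector of per-sample dosages (0/1/2/NA) at one
#'   site for one group.
#' @return List with `freq` (alternate-allele frequency; `NA` when every
#'   genotype is missing) and `n_chrom` (number of non-missing
#'   chromosomes counted, i.e. twice the called samples).
#' @export
allele_frequency <- function(dosages) {
  ok <- !is.na(dosages)
  n_chrom <- 2L * sum(ok)
  freq <- if (n_chrom == 0) NA_real_ else sum(dosages[ok]) / n_chrom
  list(freq = freq, n_chrom = n_chrom)
}

#' Per-SNP fixation index from two allele frequencies
#'
#' Computes, for the same (alternate) allele at one biallelic SNP,
#' \deqn{F_{ST} = 1 - \frac{p_1(1-p_1) + p_2(1-p_2)}
#'                         {(p_1+p_2)\,[1-(p_1+p_2)/2]},}
#' a Hudson-style two-population estimator built from the group allele
#' frequencies alone.  The statistic is undefined when the site is
#' monomorphic for the same allele in both groups (p1 = p2 = 0 or 1,
#' denominator zero); those sites return `NA` and are excluded from
#' window means.  Algebraically the value equals
#' `(p1 - p2)^2 / ((p1 + p2) * (2 - p1 - p2))`, so it lies in \[0, 1\]
#' whenever defined and equals 1 exactly for a fixed difference.
#'
#' @param p1,p2 Numeric vectors of allele frequencies in group1 and
#'   group2 (recycled to common length).
#' @return Numeric vector of Fst values in \[0, 1\], `NA` where
#'   undefined (including `NA` inputs).
#' @export
snp_fst <- function(p1, p2) {
  n <- max(length(p1), length(p2))
  p1 <- rep_len(as.numeric(p1), n)
  p2 <- rep_len(as.numeric(p2), n)
  bad <- !is.na(p1) & (p1 < 0 | p1 > 1) | !is.na(p2) & (p2 < 0 | p2 > 1)
  if (any(bad)) stop("allele frequencies must lie in [0, 1]")
  s <- p1 + p2
  den <- s * (1 - s / 2)
  num <- p1 * (1 - p1) + p2 * (1 - p2)
  fst <- ifelse(den == 0, NA_real_, 1 - num / den)
  fst
}

# Vectorized per-site group frequencies: alt-allele frequency and
# non-missing chromosome count for the given sample rows.
group_frequencies <- function(gm, idx) {
  d <- gm$dosage[idx, , drop = FALSE]
  n_chrom <- 2L * colSums(!is.na(d))
  freq <- colSums(d, na.rm = TRUE) / n_chrom
  freq[n_chrom == 0] <- NA_real_
  list(freq = unname(freq), n_chrom = unname(n_chrom))
}

# Per-site unbiased heterozygosity contribution to windowed pi:
# 2 p (1-p) * n/(n-1); sites with fewer than two called chromosomes
# contribute 0 (their count is returned for the warning tally).
pi_site_contrib <- function(freq, n_chrom) {
  contrib <- ifelse(is.na(freq) | n_chrom < 2, 0,
                    2 * freq * (1 - freq) * n_chrom / pmax(n_chrom - 1, 1))
  contrib
}

#' Sliding-window layout over a genotype matrix
#'
#' Windows tile each chromosome from coordinate 0 in steps of `step_bp`;
#' a new window starts at every multiple of `step_bp` up to the last SNP
#' position, so each SNP falls in every window whose half-open interval
#' `[start, start + window_bp)` contains its 0-based position.
#' Chromosomes without SNPs yield no windows; windows without SNPs within
#' the tiled range are still emitted (with empty site sets).
#'
#' @param gm A [genotype_matrix()].
#' @param window_bp Window size in bp (default 10000).
#' @param step_bp Step in bp (default 5000); `window_bp >= step_bp >= 1`.
#' @return A list with `windows` (data.frame chrom/start/end) and
#'   `sites` (list of integer site-index vectors, parallel to the rows).
#' @export
window_iter <- function(gm, window_bp = 10000, step_bp = 5000) {
  stopifnot(window_bp >= step_bp, step_bp >= 1)
  chroms <- unique(gm$chrom)
  w_chrom <- character(); w_start <- integer(); sites <- list()
  for (ch in chroms) {
    site_idx <- which(gm$chrom == ch)
    pos <- gm$pos0[site_idx]  # sorted by construction
    starts <- seq.int(0L, max(pos), by = step_bp)
    # half-open [start, start+window); pos is sorted so binary search works
    lo <- findInterval(starts - 1L, pos) + 1L
    hi <- findInterval(starts + window_bp - 1L, pos)
    for (k in seq_along(starts)) {
      w_chrom <- c(w_chrom, ch)
      w_start <- c(w_start, starts[k])
      sites[[length(sites) + 1L]] <-
        if (hi[k] >= lo[k]) site_idx[lo[k]:hi[k]] else integer()
    }
  }
  list(
    windows = data.frame(chrom = w_chrom, start = w_start,
                         end = w_start + as.integer(window_bp),
                         stringsAsFactors = FALSE),
    sites = sites
  )
}

#' Mean per-SNP Fst in a window
#'
#' Arithmetic mean over the computable (non-`NA`) per-SNP values;
#' `NA` when no site in the window has a defined Fst.
#'
#' @param site_fsts Numeric vector of per-SNP Fst values.
#' @return Scalar mean or `NA`.
#' @export
window_fst <- function(site_fsts) {
  v <- site_fsts[!is.na(site_fsts)]
  if (!length(v)) NA_real_ else mean(v)
}

#' Windowed nucleotide diversity for a sample group
#'
#' pi is the sum over SNPs in the window of the unbiased per-site
#' heterozygosity `2 p (1-p) * n/(n-1)` (p the group allele frequency, n
#' the non-missing chromosome count), divided by the window span in bp
#' (default) or by the SNP count.  Monomorphic sites and sites with
#' fewer than two called chromosomes contribute zero.
#'
#' @param gm A [genotype_matrix()].
#' @param samples Sample ids or row indices forming the group.
#' @param chrom,start,end Window in 0-based half-open coordinates.
#' @param denominator `"span"` (per-bp, default) or `"snps"` (per-SNP).
#' @return Scalar pi (0 for an empty window under `"span"`; `NA` under
#'   `"snps"` with no SNPs).
#' @export
window_pi <- function(gm, samples, chrom, start, end,
                      denominator = c("span", "snps")) {
  denominator <- match.arg(denominator)
  if (is.character(samples)) samples <- match(samples, gm$samples)
  in_win <- gm$chrom == chrom & gm$pos0 >= start & gm$pos0 < end
  fr <- group_frequencies(gm, samples)
  total <- sum(pi_site_contrib(fr$freq, fr$n_chrom)[in_win])
  if (denominator == "span") total / (end - start)
  else if (sum(in_win) == 0) NA_real_ else total / sum(in_win)
}

# Cheap row subset that skips revalidation (hot path helper).
subset_samples_raw <- function(gm, idx) {
  gm$dosage <- gm$dosage[idx, , drop = FALSE]
  gm$samples <- gm$samples[idx]
  gm
}

#' Ratio of group nucleotide diversities
#'
#' Oriented group1 / group2 (selected over reference); `NA` when the
#' reference diversity is zero, so that the window is excluded from
#' ratio thresholding.
#'
#' @param pi1,pi2 Non-negative per-bp diversities (vectorized).
#' @return `pi1 / pi2`, `NA` where `pi2 == 0`.
#' @export
pi_ratio <- function(pi1, pi2) {
  if (any(pi1 < 0, na.rm = TRUE) || any(pi2 < 0, na.rm = TRUE)) {
    stop("nucleotide diversity cannot be negative")
  }
  ifelse(!is.na(pi2) & pi2 == 0, NA_real_, pi1 / pi2)
}

#' Windowed Fst, pi and pi-ratio over a genotype matrix
#'
#' The workhorse of the sweep scan: computes per-SNP Fst from the two
#' group allele frequencies and aggregates mean Fst, per-group pi and
#' the pi ratio in sliding windows (defaults 10 kb windows, 5 kb step).
#'
#' @param gm A [genotype_matrix()].
#' @param pops A [population_assignment()].
#' @param window_bp,step_bp Window size and step in bp.
#' @param pi_denominator Passed through to the pi computation: `"span"`
#'   divides by window span in bp, `"snps"` by the window SNP count.
#' @return A data.frame with one row per window: `chrom`, `start`,
#'   `end`, `n_snps`, `n_snps_fst`, `fst_mean`, `pi_group1`,
#'   `pi_group2`, `pi_ratio`.  Attribute `"site_stats"` holds the
#'   per-site frequencies and Fst used.
#' @export
window_stats <- function(gm, pops, window_bp = 10000, step_bp = 5000,
                         pi_denominator = c("span", "snps")) {
  pi_denominator <- match.arg(pi_denominator)
  grp <- align_groups(gm, pops)
  f1 <- group_frequencies(gm, grp$idx1)
  f2 <- group_frequencies(gm, grp$idx2)
  fst <- snp_fst(f1$freq, f2$freq)
  c1 <- pi_site_contrib(f1$freq, f1$n_chrom)
  c2 <- pi_site_contrib(f2$freq, f2$n_chrom)
  low_n <- sum(f1$n_chrom < 2 | f2$n_chrom < 2)
  if (low_n > 0) {
    warning(sprintf("%d site(s) with fewer than 2 called chromosomes in a group contribute 0 to pi", low_n))
  }

  wi <- window_iter(gm, window_bp, step_bp)
  nw <- nrow(wi$windows)
  n_snps <- lengths(wi$sites)
  fst_mean <- pi1 <- pi2 <- numeric(nw)
  n_fst <- integer(nw)
  for (k in seq_len(nw)) {
    idx <- wi$sites[[k]]
    fv <- fst[idx]
    n_fst[k] <- sum(!is.na(fv))
    fst_mean[k] <- window_fst(fv)
    pi1[k] <- sum(c1[idx])
    pi2[k] <- sum(c2[idx])
  }
  if (pi_denominator == "span") {
    span <- wi$windows$end - wi$windows$start
    pi1 <- pi1 / span; pi2 <- pi2 / span
  } else {
    pi1 <- ifelse(n_snps == 0, NA_real_, pi1 / n_snps)
    pi2 <- ifelse(n_snps == 0, NA_real_, pi2 / n_snps)
  }
  out <- data.frame(
    chrom = wi$windows$chrom, start = wi$windows$start,
    end = wi$windows$end, n_snps = n_snps, n_snps_fst = n_fst,
    fst_mean = fst_mean, pi_group1 = pi1, pi_group2 = pi2,
    pi_ratio = pi_ratio(pi1, pi2),
    stringsAsFactors = FALSE
  )
  attr(out, "site_stats") <- data.frame(
    chrom = gm$chrom, pos0 = gm$pos0,
    p1 = f1$freq, n1 = f1$n_chrom, p2 = f2$freq, n2 = f2$n_chrom,
    fst = fst
  )
  out
}
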
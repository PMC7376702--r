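make_stats <- function(fst, ratio, start = NULL, chrom = "chr1") {
  n <- length(fst)
  if (is.null(start)) start <- (seq_len(n) - 1L) * 5000L
  data.frame(chrom = rep_len(chrom, n), start = start, end = start + 10000L,
             n_snps = 5L, n_snps_fst = 5L, fst_mean = fst,
             pi_group1 = ratio * 0.001, pi_group2 = 0.001, pi_ratio = ratio,
             stringsAsFactors = FALSE)
}

test_that("quantile cutoffs use linear interpolation; fixed cutoffs pass through", {
  stats <- make_stats(fst = 0.01 * (1:100), ratio = rep(0.5, 100))
  cut <- compute_thresholds(stats, threshold_policy("quantile"))
  expect_equal(cut$fst_cutoff, 0.9505)  # hand quantile of the 0.01*rank sequence

  cutf <- compute_thresholds(stats, threshold_policy("fixed", fst_value = 0.17))
  expect_equal(cutf$fst_cutoff, 0.17)
  expect_equal(cutf$ratio_low, 0.05)
  expect_equal(cutf$ratio_high, 0.95)

  # identical windows: cutoff equals the shared value, strict > selects none
  same <- make_stats(fst = rep(0.3, 20), ratio = rep(0.5, 20))
  cs <- compute_thresholds(same, threshold_policy("quantile"))
  expect_equal(cs$fst_cutoff, 0.3)
  expect_equal(sum(flag_windows(same, cs)$flagged), 0)

  expect_error(compute_thresholds(make_stats(NA_real_, NA_real_)),
               "no windows")
})

test_that("windows are flagged by the strict dual-threshold rule", {
  cut <- list(fst_cutoff = 0.17, ratio_low = 0.05, ratio_high = 0.95,
              mode = "fixed", direction = "both")
  f <- flag_windows(make_stats(0.30, 0.02), cut)
  expect_true(f$flagged)
  expect_equal(f$tail, "low")
  expect_false(flag_windows(make_stats(0.30, 0.50), cut)$flagged)
  # boundary: strict inequality on both criteria
  expect_false(flag_windows(make_stats(0.17, 0.02), cut)$flagged)
  expect_false(flag_windows(make_stats(0.30, 0.05), cut)$flagged)
  # high tail and direction filter
  fh <- flag_windows(make_stats(0.30, 0.99), cut)
  expect_equal(fh$tail, "high")
  cut$direction <- "low"
  expect_false(flag_windows(make_stats(0.30, 0.99), cut)$flagged)
})

test_that("flagged windows merge into regions by overlap, tail and gap", {
  w <- make_stats(c(0.3, 0.3), c(0.02, 0.02), start = c(0L, 5000L))
  w$tail <- "low"
  r <- merge_windows(w)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(0, 15000))
  expect_equal(r$n_windows, 2)

  w2 <- make_stats(c(0.3, 0.4), c(0.02, 0.01), start = c(0L, 20000L))
  w2$tail <- "low"
  r2 <- merge_windows(w2)
  expect_equal(nrow(r2), 2)
  r3 <- merge_windows(w2, max_gap_bp = 10000)
  expect_equal(nrow(r3), 1)
  expect_equal(c(r3$start, r3$end), c(0, 30000))
  expect_equal(r3$max_fst, 0.4)
  expect_equal(r3$min_ratio, 0.01)

  # different tails never merge
  w4 <- make_stats(c(0.3, 0.3), c(0.02, 0.99), start = c(0L, 5000L))
  w4$tail <- c("low", "high")
  expect_equal(nrow(merge_windows(w4)), 2)
  expect_equal(nrow(merge_windows(w4[0, ])), 0)
})

test_that("region span is exactly the union of its flagged windows", {
  set.seed(21)
  for (rep in 1:5) {
    stats <- make_stats(runif(60), runif(60))
    cut <- compute_thresholds(stats, threshold_policy("quantile",
                                                      fst_quantile = 0.6,
                                                      ratio_quantiles = c(0.3, 0.7)))
    fl <- flag_windows(stats, cut)
    regions <- merge_windows(fl)
    flw <- fl[fl$flagged, ]
    # every flagged window lies inside a region of its tail
    for (k in seq_len(nrow(flw))) {
      expect_true(any(regions$chrom == flw$chrom[k] &
                        regions$tail == flw$tail[k] &
                        regions$start <= flw$start[k] &
                        regions$end >= flw$end[k]))
    }
    # every region bp is covered by >= 1 flagged window
    for (k in seq_len(nrow(regions))) {
      cover <- flw[flw$tail == regions$tail[k] &
                     flw$start >= regions$start[k] &
                     flw$end <= regions$end[k], ]
      pts <- sort(unique(c(cover$start, cover$end)))
      for (m in seq_len(length(pts) - 1)) {
        mid <- (pts[m] + pts[m + 1]) / 2
        expect_true(any(cover$start <= mid & cover$end > mid))
      }
    }
  }
})

test_that("quantile mode flags at most the top tail of ranked windows", {
  set.seed(33)
  stats <- make_stats(runif(200), runif(200))
  cut <- compute_thresholds(stats, threshold_policy("quantile"))
  fl <- flag_windows(stats, cut)
  n_def <- sum(!is.na(stats$fst_mean))
  expect_lte(sum(stats$fst_mean > cut$fst_cutoff, na.rm = TRUE),
             ceiling(0.05 * n_def))
  expect_lte(sum(fl$flagged), ceiling(0.05 * n_def))
})

test_that("gene intersection respects half-open bounds and matches brute force", {
  regions <- data.frame(chrom = "chr1", start = 10000L, end = 15000L,
                        tail = "low", n_windows = 1L, max_fst = 0.5,
                        min_ratio = 0.01, max_ratio = 0.01)
  genes <- data.frame(chrom = "chr1",
                      start = c(12000L, 15000L, 14000L),
                      end = c(13000L, 16000L, 16000L),
                      gene_id = c("inside", "adjacent", "spanning"))
  hits <- intersect_genes(regions, genes)
  expect_setequal(hits$gene_id, c("inside", "spanning"))
  expect_equal(hits$overlap_bp[hits$gene_id == "inside"], 1000)
  expect_equal(hits$overlap_bp[hits$gene_id == "spanning"], 1000)
  expect_equal(attr(hits, "n_unique_genes"), 2L)

  # random fixture vs quadratic all-pairs oracle
  set.seed(9)
  for (rep in 1:5) {
    rs <- sort(sample.int(1e5, 8))
    regions <- data.frame(chrom = sample(c("chr1", "chr2"), 4, TRUE),
                          start = rs[c(1, 3, 5, 7)], end = rs[c(2, 4, 6, 8)],
                          tail = "low", n_windows = 1L, max_fst = 0.5,
                          min_ratio = 0.01, max_ratio = 0.01)
    gs <- matrix(sort(sample.int(1e5, 40)), ncol = 2, byrow = TRUE)
    genes <- data.frame(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                        start = gs[, 1], end = gs[, 2],
                        gene_id = sprintf("g%02d", 1:20))
    hits <- suppressWarnings(intersect_genes(regions, genes))
    brute <- 0L
    for (r in seq_len(nrow(regions))) {
      for (g in seq_len(nrow(genes))) {
        ov <- min(regions$end[r], genes$end[g]) -
          max(regions$start[r], genes$start[g])
        if (regions$chrom[r] == genes$chrom[g] && ov > 0) {
          brute <- brute + 1L
          expect_true(any(hits$gene_id == genes$gene_id[g] &
                            hits$region_start == regions$start[r] &
                            hits$overlap_bp == ov))
        }
      }
    }
    expect_equal(nrow(hits), brute)
  }
})
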
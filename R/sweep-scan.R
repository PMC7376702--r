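#' Dual-threshold policy for sweep calling
#'
#' Candidate sweep windows must exceed the Fst cutoff AND fall in an
#' extreme tail of the pi-ratio distribution.  In `"quantile"` mode the
#' cutoffs are empirical quantiles of the windowed statistics (defaults:
#' top 5% Fst; lower/upper 5% pi-ratio tails).  In `"fixed"` mode the
#' numeric cutoffs are used as given (defaults: Fst > 0.17, pi ratio
#' < 0.05 or > 0.95).  All comparisons are strict.
#'
#' @param mode `"quantile"` or `"fixed"`.
#' @param fst_quantile Quantile for the Fst cutoff (quantile mode).
#' @param ratio_quantiles Length-2 lower/upper tail quantiles for the pi
#'   ratio (quantile mode).
#' @param fst_value Fixed Fst cutoff (fixed mode).
#' @param ratio_low,ratio_high Fixed pi-ratio cutoffs (fixed mode).
#' @param direction Which pi-ratio tail(s) qualify: `"both"`, `"low"`
#'   (diversity reduced in group1) or `"high"`.
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(mode = c("quantile", "fixed"),
                             fst_quantile = 0.95,
                             ratio_quantiles = c(0.05, 0.95),
                             fst_value = 0.17,
                             ratio_low = 0.05, ratio_high = 0.95,
                             direction = c("both", "low", "high")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  stopifnot(fst_quantile > 0, fst_quantile < 1,
            all(ratio_quantiles > 0), all(ratio_quantiles < 1),
            ratio_quantiles[1] < ratio_quantiles[2],
            fst_value >= 0, ratio_low >= 0, ratio_high >= 0)
  structure(list(mode = mode, fst_quantile = fst_quantile,
                 ratio_quantiles = ratio_quantiles, fst_value = fst_value,
                 ratio_low = ratio_low, ratio_high = ratio_high,
                 direction = direction),
            class = "threshold_policy")
}

#' Concrete cutoffs from windowed statistics
#'
#' Quantile-mode cutoffs use the linear-interpolation empirical quantile
#' (R type 7) over windows where the statistic is defined; fixed mode
#' passes the policy values through unchanged.
#'
#' @param stats Window-stats data.frame from [window_stats()].
#' @param policy A [threshold_policy()].
#' @return List with `fst_cutoff`, `ratio_low`, `ratio_high`, the
#'   `mode`/`direction` used and the number of windows each quantile was
#'   taken over.
#' @export
compute_thresholds <- function(stats, policy = threshold_policy()) {
  fst_def <- stats$fst_mean[!is.na(stats$fst_mean)]
  ratio_def <- stats$pi_ratio[!is.na(stats$pi_ratio)]
  if (!length(fst_def) || !length(ratio_def)) {
    stop("no windows with defined fst_mean and pi_ratio; cannot set thresholds")
  }
  if (policy$mode == "quantile") {
    fst_cut <- stats::quantile(fst_def, policy$fst_quantile,
                               type = 7, names = FALSE)
    rq <- stats::quantile(ratio_def, policy$ratio_quantiles,
                          type = 7, names = FALSE)
    ratio_low <- rq[1]; ratio_high <- rq[2]
  } else {
    fst_cut <- policy$fst_value
    ratio_low <- policy$ratio_low
    ratio_high <- policy$ratio_high
  }
  list(fst_cutoff = fst_cut, ratio_low = ratio_low, ratio_high = ratio_high,
       mode = policy$mode, direction = policy$direction,
       n_windows_fst = length(fst_def), n_windows_ratio = length(ratio_def))
}

#' Flag candidate sweep windows
#'
#' A window is flagged iff `fst_mean > fst_cutoff` and its pi ratio lies
#' strictly beyond a qualifying tail cutoff.  Windows with undefined
#' Fst or pi ratio are never flagged.  The low tail (pi ratio below the
#' lower cutoff) marks diversity reduced in group1 — the signature of a
#' sweep selected in that group.
#'
#' @param stats Window-stats data.frame.
#' @param cutoffs From [compute_thresholds()].
#' @return `stats` with added logical `flagged` and character `tail`
#'   (`"low"`, `"high"` or `NA`).
#' @export
flag_windows <- function(stats, cutoffs) {
  fst_ok <- !is.na(stats$fst_mean) & stats$fst_mean > cutoffs$fst_cutoff
  low <- !is.na(stats$pi_ratio) & stats$pi_ratio < cutoffs$ratio_low
  high <- !is.na(stats$pi_ratio) & stats$pi_ratio > cutoffs$ratio_high
  tail_ok <- switch(cutoffs$direction,
                    both = low | high,
                    low = low,
                    high = high)
  stats$flagged <- fst_ok & tail_ok
  stats$tail <- ifelse(stats$flagged & low, "low",
                       ifelse(stats$flagged & high, "high", NA_character_))
  stats
}

#' Merge flagged windows into sweep regions
#'
#' Overlapping or near-adjacent (gap <= `max_gap_bp`) flagged windows on
#' the same chromosome and in the same pi-ratio tail are merged; region
#' summaries aggregate the extreme window statistics.
#'
#' @param flagged Output of [flag_windows()] (only rows with
#'   `flagged == TRUE` are used) or any window-stats subset carrying a
#'   `tail` column.
#' @param max_gap_bp Maximum bp gap bridged when merging (default 0:
#'   only overlapping or book-ended windows merge).
#' @return Data.frame of regions: `chrom`, `start`, `end`, `tail`,
#'   `n_windows`, `max_fst`, `min_ratio`, `max_ratio`, sorted by
#'   (chrom, start).
#' @export
merge_windows <- function(flagged, max_gap_bp = 0) {
  if (!is.null(flagged$flagged)) flagged <- flagged[flagged$flagged, , drop = FALSE]
  cols <- c("chrom", "start", "end", "tail", "n_windows",
            "max_fst", "min_ratio", "max_ratio")
  if (!nrow(flagged)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      tail = character(), n_windows = integer(),
                      max_fst = numeric(), min_ratio = numeric(),
                      max_ratio = numeric(), stringsAsFactors = FALSE)
    return(out[cols])
  }
  flagged <- flagged[order(flagged$chrom, flagged$tail, flagged$start), ]
  regions <- list()
  cur <- NULL
  for (k in seq_len(nrow(flagged))) {
    w <- flagged[k, ]
    if (!is.null(cur) && w$chrom == cur$chrom && w$tail == cur$tail &&
        w$start <= cur$end + max_gap_bp) {
      cur$end <- max(cur$end, w$end)
      cur$n_windows <- cur$n_windows + 1L
      cur$max_fst <- max(cur$max_fst, w$fst_mean)
      cur$min_ratio <- min(cur$min_ratio, w$pi_ratio)
      cur$max_ratio <- max(cur$max_ratio, w$pi_ratio)
    } else {
      if (!is.null(cur)) regions[[length(regions) + 1L]] <- cur
      cur <- list(chrom = w$chrom, start = w$start, end = w$end,
                  tail = w$tail, n_windows = 1L, max_fst = w$fst_mean,
                  min_ratio = w$pi_ratio, max_ratio = w$pi_ratio)
    }
  }
  regions[[length(regions) + 1L]] <- cur
  out <- do.call(rbind, lapply(regions, as.data.frame,
                               stringsAsFactors = FALSE))
  out <- out[order(out$chrom, out$start), cols]
  rownames(out) <- NULL
  out
}

#' Intersect sweep regions with gene annotation
#'
#' Reports every gene overlapping a region by at least 1 bp (half-open
#' coordinates on both sides), with the overlap width.  Chromosome name
#' sets that do not intersect trigger a warning.
#'
#' @param regions Region data.frame from [merge_windows()].
#' @param genes Gene data.frame from [read_gene_annotation()].
#' @return Data.frame with one row per (region, gene) hit, sorted by
#'   region then gene start; attribute `"n_unique_genes"` carries the
#'   distinct overlapped gene count.
#' @export
intersect_genes <- function(regions, genes) {
  empty <- data.frame(chrom = character(), region_start = integer(),
                      region_end = integer(), tail = character(),
                      gene_id = character(), gene_start = integer(),
                      gene_end = integer(), overlap_bp = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(regions) || !nrow(genes)) {
    attr(empty, "n_unique_genes") <- 0L
    return(empty)
  }
  if (!length(intersect(unique(regions$chrom), unique(genes$chrom)))) {
    warning("no chromosome labels shared between regions and gene annotation")
  }
  # 0-based half-open -> 1-based closed for IRanges
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L, regions$end))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_r, gr_g))
  ri <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(gr_r[ri], gr_g[gi])
  out <- data.frame(
    chrom = regions$chrom[ri],
    region_start = regions$start[ri], region_end = regions$end[ri],
    tail = regions$tail[ri],
    gene_id = genes$gene_id[gi],
    gene_start = genes$start[gi], gene_end = genes$end[gi],
    overlap_bp = GenomicRanges::width(ov),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$region_start, out$gene_start), ]
  rownames(out) <- NULL
  attr(out, "n_unique_genes") <- length(unique(out$gene_id))
  out
}
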
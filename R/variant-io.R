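#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF (plain or gzipped) and retains biallelic SNP sites
#' passing the site filters.  Multiallelic sites, indels/non-SNPs and
#' sites exceeding the missingness ceiling are dropped and counted; the
#' counts are attached as the `"exclusions"` attribute of the result.
#' Diploid GT fields are converted to alternate-allele dosage; missing
#' calls (`./.`) become `NA` and are never imputed.
#'
#' @param path Path to a VCF v4.x file with GT fields.
#' @param max_missing Maximum per-site fraction of missing genotypes
#'   (default 0.2); sites above it are excluded.
#' @return A [genotype_matrix()] with attribute `exclusions`, a named
#'   integer vector with counts of `multiallelic`, `non_snp` and
#'   `high_missing` exclusions.
#' @export
read_vcf <- function(path, max_missing = 0.2) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(v@gt) || ncol(v@gt) < 2) {
    stop("VCF has no sample columns: ", path)
  }
  fix <- vcfR::getFIX(v)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  multi <- grepl(",", alt, fixed = TRUE)
  snp <- !multi &
    ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  non_snp <- !multi & !snp

  gt <- vcfR::extract.gt(v, element = "GT")
  # genotype string -> dosage lookup; anything unrecognised is missing
  lut <- c("0/0" = 0L, "0|0" = 0L,
           "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
           "1/1" = 2L, "1|1" = 2L)
  dos <- matrix(lut[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  dos <- t(dos)  # samples x sites

  keep <- !multi & snp
  miss_rate <- colMeans(is.na(dos))
  high_missing <- keep & miss_rate > max_missing
  keep <- keep & !high_missing

  excl <- c(multiallelic = sum(multi),
            non_snp = sum(non_snp),
            high_missing = sum(high_missing))
  if (!any(keep)) stop("no biallelic SNP sites pass the filters in ", path)

  gm <- genotype_matrix(dos[, keep, drop = FALSE],
                        chrom[keep], pos[keep], ref[keep], alt[keep])
  attr(gm, "exclusions") <- excl
  gm
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF v4.2 with GT-only genotype columns; 0-based
#' internal coordinates are converted back to 1-based VCF positions.
#' A `.gz` extension triggers gzip compression.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  ref <- ifelse(is.na(gm$ref), "A", gm$ref)
  alt <- ifelse(is.na(gm$alt), "G", gm$alt)
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_sites(gm), ncol = n_samples(gm))
  d <- t(gm$dosage)
  ok <- !is.na(d)
  gt[ok] <- gt_code[d[ok] + 1L]

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", gm$samples), collapse = "\t")
  )
  body <- paste(gm$chrom, gm$pos0 + 1L, ".", ref, alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a sample-to-group assignment table
#'
#' Expects a two-column (headerless) TSV of `sample_id<TAB>group`.
#'
#' @param path Path to the TSV (gzip tolerated).
#' @param group1,group2 Optional group labels to use as selected /
#'   reference group; see [population_assignment()].
#' @return A [population_assignment()].
#' @export
read_population_file <- function(path, group1 = NULL, group2 = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample", "group"),
                          colClasses = "character")
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in ", path)
  x <- stats::setNames(df$group, df$sample)
  population_assignment(x, group1 = group1, group2 = group2)
}

#' Read gene annotation from GFF3 or BED
#'
#' The format is auto-detected from the file extension (`.gff`, `.gff3`
#' for GFF3; `.bed` for BED; a trailing `.gz` is ignored).  GFF3 rows are
#' restricted to one feature type (default `"gene"`).  All intervals are
#' normalized to 0-based half-open coordinates; records with non-positive
#' width after normalization are rejected with a warning.
#'
#' @param path Annotation file path.
#' @param feature GFF3 feature type to keep (ignored for BED).
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `gene_id`, sorted by (chrom, start).
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  base <- sub("\\.(gz|bgz)$", "", path)
  ext <- tolower(tools::file_ext(base))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == feature]
    ids <- as.character(gr$ID)
    if (!length(ids) || all(is.na(ids))) ids <- as.character(gr$Name)
    ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene", seq_along(gr))
  } else {
    stop("unrecognised annotation extension: ", path)
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    gene_id = ids,
    stringsAsFactors = FALSE
  )
  bad <- df$end <= df$start
  if (any(bad)) {
    warning(sprintf("rejected %d annotation record(s) with end <= start", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write / read windowed statistics as TSV
#'
#' One row per window with chrom, start, end (0-based half-open),
#' n_snps, n_snps_fst, fst_mean, pi_group1, pi_group2 and pi_ratio.
#' Floating-point columns are written at 6 significant digits; rows are
#' ordered by (chrom, start).
#'
#' @param stats A window-stats data.frame from [window_stats()].
#' @param path Output (input) path; gzip by `.gz` extension.
#' @return `path` invisibly for the writer; the data.frame for the
#'   reader.
#' @export
write_window_stats <- function(stats, path) {
  stats <- stats[order(stats$chrom, stats$start), , drop = FALSE]
  out <- stats
  for (col in c("fst_mean", "pi_group1", "pi_group2", "pi_ratio")) {
    out[[col]] <- signif(out[[col]], 6)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_window_stats
#' @export
read_window_stats <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Write sweep regions as BED6
#'
#' Name is the diversity tail label, score is `1000 * max_fst` clamped
#' to \[0, 1000\].
#'
#' @param regions Region data.frame from [merge_windows()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  score <- round(pmin(pmax(1000 * regions$max_fst, 0), 1000))
  lines <- paste(regions$chrom, regions$start, regions$end,
                 regions$tail, score, ".", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
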
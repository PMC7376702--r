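#' Construct a genotype matrix
#'
#' The central container of the package: a samples-by-sites matrix of
#' diploid alternate-allele dosages (0, 1, 2 or `NA` for a missing call)
#' for biallelic SNPs, together with per-site coordinates.  Positions are
#' supplied 1-based (as in VCF) and stored 0-based internally so that all
#' window and interval arithmetic is half-open.
#'
#' @param dosage Integer matrix, samples in rows (rownames are sample
#'   ids), sites in columns.  Values must be 0, 1, 2 or `NA`.
#' @param chrom Character vector of chromosome labels, one per site.
#' @param pos Integer vector of 1-based positions, one per site.  Sites
#'   must be strictly increasing within each chromosome; the constructor
#'   sorts by (chrom, pos) and rejects duplicates.
#' @param ref,alt Optional per-site allele strings.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `samples`, `chrom`, `pos0` (0-based position), `ref`, `alt` and
#'   `dosage`.
#' @export
genotype_matrix <- function(dosage, chrom, pos, ref = NULL, alt = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("sample", seq_len(nrow(dosage)))
  }
  n_sites <- ncol(dosage)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (length(chrom) != n_sites || length(pos) != n_sites) {
    stop("chrom and pos must have one entry per dosage column")
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("dosage values must be 0, 1, 2 or NA")
  }
  if (is.null(ref)) ref <- rep(NA_character_, n_sites)
  if (is.null(alt)) alt <- rep(NA_character_, n_sites)

  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  dosage <- dosage[, ord, drop = FALSE]
  ref <- as.character(ref)[ord]; alt <- as.character(alt)[ord]
  if (anyDuplicated(paste(chrom, pos))) {
    stop("duplicate (chrom, pos) sites are not allowed")
  }
  colnames(dosage) <- paste(chrom, pos, sep = ":")

  structure(
    list(
      samples = rownames(dosage),
      chrom = chrom,
      pos0 = pos - 1L,
      ref = ref,
      alt = alt,
      dosage = dosage
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d biallelic SNP sites on %d chromosome(s)\n",
    n_samples(x), n_sites(x), length(unique(x$chrom))
  ))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotype rate: %.3f\n", miss))
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_sites <- function(gm) length(gm$chrom)

#' Subset a genotype matrix
#'
#' @param gm A `genotype_matrix`.
#' @param sites Integer or logical index over sites.
#' @param samples Integer, logical or character index over samples.
#' @return A new `genotype_matrix`.
#' @export
subset_sites <- function(gm, sites) {
  genotype_matrix(gm$dosage[, sites, drop = FALSE],
                  gm$chrom[sites], gm$pos0[sites] + 1L,
                  gm$ref[sites], gm$alt[sites])
}

#' @rdname subset_sites
#' @export
subset_samples <- function(gm, samples) {
  d <- gm$dosage[samples, , drop = FALSE]
  genotype_matrix(d, gm$chrom, gm$pos0 + 1L, gm$ref, gm$alt)
}

#' Assign samples to two analysis groups
#'
#' A population assignment maps sample ids onto exactly two groups:
#' `group1` is the putatively selected group (e.g. black-skin breeds) and
#' `group2` the reference group.  The pi ratio reported by
#' [window_stats()] is oriented group1 / group2.
#'
#' @param x Named character vector: names are sample ids, values group
#'   labels.
#' @param group1,group2 The two group labels.  Defaults: the first and
#'   second distinct labels in order of appearance.  Samples carrying any
#'   other label are dropped with a warning.
#' @return An object of class `population_assignment` with elements
#'   `labels` (named character vector), `group1`, `group2`.
#' @export
population_assignment <- function(x, group1 = NULL, group2 = NULL) {
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("population assignment requires named sample ids")
  }
  lv <- unique(unname(x))
  if (is.null(group1) && is.null(group2)) {
    if (length(lv) != 2) {
      stop(sprintf(
        "exactly two population groups are required for a sweep scan, got %d (%s)",
        length(lv), paste(lv, collapse = ", ")
      ))
    }
    group1 <- lv[1]; group2 <- lv[2]
  } else {
    if (is.null(group2)) group2 <- setdiff(lv, group1)[1]
    extra <- !(x %in% c(group1, group2))
    if (any(extra)) {
      warning(sprintf("dropping %d sample(s) outside groups '%s'/'%s'",
                      sum(extra), group1, group2))
      x <- x[!extra]
    }
  }
  if (!all(c(group1, group2) %in% x)) {
    stop("each of the two groups must contain at least one sample")
  }
  structure(list(labels = x, group1 = group1, group2 = group2),
            class = "population_assignment")
}

#' @export
print.population_assignment <- function(x, ...) {
  cat(sprintf("<population_assignment> group1 '%s': %d samples; group2 '%s': %d samples\n",
              x$group1, sum(x$labels == x$group1),
              x$group2, sum(x$labels == x$group2)))
  invisible(x)
}

# Resolve sample row indices of the two groups against a genotype matrix.
# Samples present in the matrix but unassigned are reported and excluded;
# assigned samples absent from the matrix are warned about and ignored.
align_groups <- function(gm, pops) {
  stopifnot(inherits(pops, "population_assignment"))
  absent <- setdiff(names(pops$labels), gm$samples)
  if (length(absent)) {
    warning(sprintf("%d assigned sample(s) not in the genotype data: %s",
                    length(absent), paste(absent, collapse = ", ")))
  }
  unassigned <- setdiff(gm$samples, names(pops$labels))
  if (length(unassigned)) {
    message(sprintf("%d sample(s) in the genotype data are unassigned and excluded: %s",
                    length(unassigned), paste(unassigned, collapse = ", ")))
  }
  idx1 <- which(gm$samples %in% names(pops$labels)[pops$labels == pops$group1])
  idx2 <- which(gm$samples %in% names(pops$labels)[pops$labels == pops$group2])
  if (!length(idx1) || !length(idx2)) {
    stop("both population groups must have at least one sample present in the genotype data")
  }
  list(idx1 = idx1, idx2 = idx2)
}
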
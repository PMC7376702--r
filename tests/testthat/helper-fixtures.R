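# Shared fixture builders: everything is generated in code at test time.

# Genotype matrix from a dosage matrix (samples x sites) and positions.
make_gm <- function(dosage, pos, chrom = "chr1", samples = NULL) {
  dosage <- as.matrix(dosage)
  if (!is.null(samples)) rownames(dosage) <- samples
  genotype_matrix(dosage, rep_len(chrom, ncol(dosage)), pos)
}

# Two-group assignment over the rows of a genotype matrix.
make_pops <- function(gm, n1) {
  labs <- c(rep("g1", n1), rep("g2", n_samples(gm) - n1))
  population_assignment(stats::setNames(labs, gm$samples))
}

# A small hand-written VCF exercising multiallelic, indel and missing
# records.  Returns the path.
write_fixture_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tA\tT,C\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1",
    "chr1\t300\t.\tA\tG\t.\tPASS\t.\tGT\t./.\t0/0\t0/1",
    "chr1\t400\t.\tAT\tG\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0",
    "chr1\t500\t.\tC\tT\t.\tPASS\t.\tGT\t1|0\t0|0\t1/1",
    "chr2\t100\t.\tG\tA\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0"
  )
  writeLines(lines, path)
  path
}

# Random genotype matrix with planted LD blocks: within each block the
# later sites copy the first with per-sample copy errors, so nearby
# r^2 is high and decays with the error rate.
make_ld_gm <- function(n_samples = 30, n_sites = 100, block = 10,
                       copy_error = 0.1, seed = 1) {
  set.seed(seed)
  dos <- matrix(0L, n_samples, n_sites)
  pos <- sort(sample.int(n_sites * 100, n_sites))
  for (s in seq_len(n_sites)) {
    if ((s - 1) %% block == 0) {
      p <- runif(1, 0.2, 0.8)
      dos[, s] <- rbinom(n_samples, 2, p)
    } else {
      flip <- runif(n_samples) < copy_error
      dos[, s] <- ifelse(flip, rbinom(n_samples, 2, 0.5), dos[, s - 1])
    }
  }
  make_gm(dos, pos)
}

# Independent re-implementation of the greedy pruning rule, used as the
# oracle for ld_prune: explicit window loop with repeated pair sweeps.
brute_force_prune <- function(gm, window_snps = 50, step_snps = 5,
                              r2_threshold = 0.2) {
  removed <- logical(n_sites(gm))
  for (ch in unique(gm$chrom)) {
    idx <- which(gm$chrom == ch)
    starts <- seq(1L, length(idx), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      repeat {
        alive <- win[!removed[win]]
        hit <- FALSE
        if (length(alive) >= 2) {
          pairs <- utils::combn(alive, 2)
          for (k in seq_len(ncol(pairs))) {
            a <- pairs[1, k]; b <- pairs[2, k]
            if (removed[a] || removed[b]) next
            r2 <- genotype_r2(gm$dosage[, a], gm$dosage[, b])
            if (!is.na(r2) && r2 > r2_threshold) {
              removed[b] <- TRUE
              hit <- TRUE
            }
          }
        }
        if (!hit) break
      }
    }
  }
  which(!removed)
}
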
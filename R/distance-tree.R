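#' Allele-sharing p-distance between two samples
#'
#' Mean over pairwise-complete sites of `|dosage_i - dosage_j| / 2`:
#' 0 for identical genotypes, 1/2 for heterozygote vs homozygote, 1 for
#' opposite homozygotes.  Lies in \[0, 1\].
#'
#' @param gm A [genotype_matrix()].
#' @param i,j Sample ids or row indices.
#' @return Scalar distance.
#' @export
p_distance <- function(gm, i, j) {
  if (is.character(i)) i <- match(i, gm$samples)
  if (is.character(j)) j <- match(j, gm$samples)
  di <- gm$dosage[i, ]; dj <- gm$dosage[j, ]
  ok <- !is.na(di) & !is.na(dj)
  if (!any(ok)) {
    stop(sprintf("no shared non-missing sites between samples '%s' and '%s'",
                 gm$samples[i], gm$samples[j]))
  }
  mean(abs(di[ok] - dj[ok])) / 2
}

#' Pairwise distance matrix over all samples
#'
#' @param gm A [genotype_matrix()].
#' @param method `"p"` for allele-sharing p-distance, `"is"` for the
#'   identity score `1 - p`.
#' @return Symmetric numeric matrix with sample ids as dimnames; zero
#'   (p) or unit (IS) diagonal.
#' @export
distance_matrix <- function(gm, method = c("p", "is")) {
  method <- match.arg(method)
  n <- n_samples(gm)
  m <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- p_distance(gm, i, j)
    }
  }
  if (method == "is") m <- 1 - m
  m
}

#' Whole-genome identity-score matrix
#'
#' IS(i, j) = 1 - p_distance(i, j): the average allele-sharing identity
#' between two individuals.  Unit diagonal.
#'
#' @param gm A [genotype_matrix()].
#' @return Symmetric matrix of identity scores in \[0, 1\].
#' @export
identity_score_matrix <- function(gm) distance_matrix(gm, method = "is")

#' Nei (1972) standard genetic distance between population groups
#'
#' Computed over group allele frequencies at every site:
#' `D = -log(Jxy / sqrt(Jx * Jy))` where the J terms average `p q`
#' products over both alleles of each SNP.
#'
#' @param gm A [genotype_matrix()].
#' @param groups Named character vector sample id -> group label (any
#'   number of groups).
#' @return Symmetric group-by-group distance matrix.
#' @export
nei_distance <- function(gm, groups) {
  groups <- groups[names(groups) %in% gm$samples]
  labs <- unique(unname(groups))
  freqs <- lapply(labs, function(g) {
    idx <- which(gm$samples %in% names(groups)[groups == g])
    group_frequencies(gm, idx)$freq
  })
  names(freqs) <- labs
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (a in seq_along(labs)) {
    for (b in seq_along(labs)) {
      if (b <= a) next
      px <- freqs[[a]]; py <- freqs[[b]]
      ok <- !is.na(px) & !is.na(py)
      jxy <- mean(px[ok] * py[ok] + (1 - px[ok]) * (1 - py[ok]))
      jx <- mean(px[ok]^2 + (1 - px[ok])^2)
      jy <- mean(py[ok]^2 + (1 - py[ok])^2)
      m[a, b] <- m[b, a] <- -log(jxy / sqrt(jx * jy))
    }
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou--Nei agglomeration: repeatedly join the pair
#' minimizing the Q criterion, assign branch lengths by the standard
#' closed form, and reduce the matrix, until three clusters remain and
#' are joined at the final internal node.  On an additive distance
#' matrix the true tree (topology and branch lengths) is recovered
#' exactly.  Negative branch lengths are clamped to zero; the total
#' clamped deficit is recorded in the `"negative_length_deficit"`
#' attribute.
#'
#' @param d Symmetric numeric matrix (or `dist`) of non-negative
#'   distances with zero diagonal; dimnames give the taxon labels.
#' @return An [ape::ape-package] `phylo` tree (unrooted; the root node
#'   is the final trifurcation).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("at least two taxa are required")
  if (!isTRUE(all.equal(d, t(d))) || any(d < 0) || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric and non-negative with zero diagonal")
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  deficit <- 0
  clamp <- function(x) {
    neg <- x < 0
    deficit <<- deficit + sum(-x[neg])
    x[neg] <- 0
    x
  }
  # active clusters as recursive lists: leaf or (children, lens)
  nodes <- lapply(labels, function(l) list(leaf = l))
  D <- d

  if (n == 2) {
    root <- list(children = nodes, lens = clamp(c(D[1, 2] / 2, D[1, 2] / 2)))
  } else {
    while (length(nodes) > 3) {
      m <- length(nodes)
      R <- rowSums(D)
      Q <- (m - 2) * D - outer(R, R, "+")
      diag(Q) <- Inf
      w <- which(Q == min(Q), arr.ind = TRUE)
      ij <- sort(w[1, ])  # deterministic tie-break: first arr.ind hit
      i <- ij[1]; j <- ij[2]
      li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
      lj <- D[i, j] - li
      lens <- clamp(c(li, lj))
      new_node <- list(children = nodes[c(i, j)], lens = lens)
      dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
      keep <- setdiff(seq_len(m), c(i, j))
      D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                  c(dk[keep], 0))
      D <- unname(D2)
      nodes <- c(nodes[keep], list(new_node))
    }
    if (length(nodes) == 3) {
      l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
      l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
      l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
      root <- list(children = nodes, lens = clamp(c(l1, l2, l3)))
    } else {
      # n == 3 at entry handled above; n cannot be < 3 here
      root <- nodes[[1]]
    }
  }
  tr <- rec_to_phylo(root)
  attr(tr, "negative_length_deficit") <- deficit
  tr
}

# Convert the recursive node representation into an ape "phylo" object.
rec_to_phylo <- function(root) {
  count_tips <- function(nd) {
    if (!is.null(nd$leaf)) 1L else sum(vapply(nd$children, count_tips, 1L))
  }
  n_tip <- count_tips(root)
  tips <- character(n_tip)
  next_tip <- 0L
  next_int <- n_tip
  edge_p <- integer(); edge_c <- integer(); edge_l <- numeric()
  assign_node <- function(nd) {
    if (!is.null(nd$leaf)) {
      next_tip <<- next_tip + 1L
      tips[next_tip] <<- nd$leaf
      return(next_tip)
    }
    next_int <<- next_int + 1L
    me <- next_int
    for (k in seq_along(nd$children)) {
      ch <- assign_node(nd$children[[k]])
      edge_p <<- c(edge_p, me)
      edge_c <<- c(edge_c, ch)
      edge_l <<- c(edge_l, nd$lens[k])
    }
    me
  }
  assign_node(root)
  tr <- list(edge = cbind(edge_p, edge_c), edge.length = edge_l,
             tip.label = tips, Nnode = next_int - n_tip)
  class(tr) <- "phylo"
  stats::reorder(tr, "cladewise")
}

# phylo -> recursive node representation (inverse of rec_to_phylo,
# branch lengths kept on the child edges).
phylo_to_rec <- function(tr) {
  n_tip <- length(tr$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  build <- function(node) {
    if (node <= n_tip) return(list(leaf = tr$tip.label[node]))
    rows <- kids[[as.character(node)]]
    list(children = lapply(tr$edge[rows, 2], build),
         lens = tr$edge.length[rows])
  }
  build(root)
}

#' Serialize a tree to Newick with canonical child order
#'
#' Children at every node are ordered by their lexicographically
#' smallest descendant leaf label, so the output string is a
#' deterministic function of the (unordered) tree.
#'
#' @param tree An ape `phylo` with branch lengths.
#' @param digits Significant digits for branch lengths (default 10).
#' @return A single Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, digits = 10) {
  rec <- phylo_to_rec(tree)
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  walk <- function(nd) {
    if (!is.null(nd$leaf)) return(list(key = nd$leaf, str = nd$leaf))
    parts <- lapply(nd$children, walk)
    keys <- vapply(parts, `[[`, "", "key")
    ord <- order(keys, method = "radix")
    strs <- vapply(seq_along(ord), function(k) {
      paste0(parts[[ord[k]]]$str, ":", fmt(nd$lens[ord[k]]))
    }, "")
    list(key = min(keys), str = paste0("(", paste(strs, collapse = ","), ")"))
  }
  paste0(walk(rec)$str, ";")
}

#' Neighbor-joining tree with site-bootstrap support
#'
#' Builds the p-distance NJ tree of all samples, then resamples SNP
#' sites with replacement `reps` times, rebuilds the tree, and computes
#' clade support counts with [ape::prop.clades()].
#'
#' @param gm A [genotype_matrix()].
#' @param reps Number of bootstrap replicates (default 100).
#' @param seed Integer RNG seed for the site resampling.
#' @return List with `tree` (phylo) and `support` (integer counts per
#'   internal node, `NA` for the root).
#' @export
bootstrap_nj <- function(gm, reps = 100, seed = 1) {
  main <- nj_tree(distance_matrix(gm))
  boots <- withr_seed(seed, {
    lapply(seq_len(reps), function(r) {
      idx <- sample.int(n_sites(gm), n_sites(gm), replace = TRUE)
      gmb <- gm
      gmb$dosage <- gm$dosage[, idx, drop = FALSE]
      gmb$chrom <- gm$chrom[idx]  # coordinates unused by distances
      nj_tree(distance_matrix(gmb))
    })
  })
  support <- ape::prop.clades(main, boots, rooted = FALSE)
  list(tree = main, support = support)
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
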
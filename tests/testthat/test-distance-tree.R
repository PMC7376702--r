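# Random tree with comfortably positive branch lengths; its cophenetic
# (leaf-to-leaf path length) matrix is an additive distance matrix, so
# neighbor joining must recover it exactly.
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 1)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

test_that("p-distance is mean allele-sharing dissimilarity over complete sites", {
  gm <- make_gm(rbind(c(0, 1, 2), c(0, 1, 2)), pos = c(10, 20, 30),
                samples = c("a", "b"))
  expect_equal(p_distance(gm, "a", "b"), 0)

  gm2 <- make_gm(rbind(rep(0, 4), rep(2, 4)), pos = c(10, 20, 30, 40))
  expect_equal(p_distance(gm2, 1, 2), 1)

  # |ddiff| of 0, 1, 2 equally represented -> (0 + 0.5 + 1)/3
  gm3 <- make_gm(rbind(c(0, 0, 0), c(0, 1, 2)), pos = c(10, 20, 30))
  expect_equal(p_distance(gm3, 1, 2), 0.5)

  # heterozygote vs homozygote at the only site
  gm4 <- make_gm(rbind(1, 0), pos = 10)
  expect_equal(p_distance(gm4, 1, 2), 0.5)

  # missing-only overlap errors, naming the pair
  gm5 <- make_gm(rbind(c(1, NA), c(NA, 1)), pos = c(10, 20),
                 samples = c("x", "y"))
  expect_error(p_distance(gm5, "x", "y"), "x.*y")
})

test_that("identity score is the elementwise complement of p-distance", {
  set.seed(14)
  gm <- make_gm(matrix(sample(c(0:2, NA), 80, TRUE, prob = c(3, 3, 3, 1)),
                       nrow = 8), pos = sort(sample.int(1e4, 10)))
  d <- distance_matrix(gm)
  is_m <- identity_score_matrix(gm)
  expect_equal(is_m, 1 - d)
  expect_equal(unname(diag(is_m)), rep(1, 8))
  expect_true(isSymmetric(is_m))
})

test_that("Nei distance is zero within a group and positive between diverged groups", {
  set.seed(15)
  p <- runif(300, 0.1, 0.9)
  d1 <- matrix(rbinom(10 * 300, 2, rep(p, each = 10)), nrow = 10)
  d2 <- matrix(rbinom(10 * 300, 2, rep(rev(p), each = 10)), nrow = 10)
  gm <- make_gm(rbind(d1, d1, d2), pos = sort(sample.int(1e6, 300)))
  groups <- setNames(rep(c("a", "b", "c"), each = 10), gm$samples)
  m <- nei_distance(gm, groups)
  expect_lt(m["a", "b"], 0.01)   # same underlying frequencies
  expect_gt(m["a", "c"], m["a", "b"])
})

test_that("neighbor joining recovers additive trees exactly", {
  # 2 taxa: one edge of total length d
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- nj_tree(d2)
  expect_equal(sum(t2$edge.length), 0.4)
  expect_equal(to_newick(t2), "(A:0.2,B:0.2);")

  # hand-built additive 4-taxon distances:
  # ((A:1,B:2):1.5,C:1,D:3) around two internal nodes
  lab <- c("A", "B", "C", "D")
  d4 <- matrix(0, 4, 4, dimnames = list(lab, lab))
  d4["A", "B"] <- d4["B", "A"] <- 3          # 1 + 2
  d4["A", "C"] <- d4["C", "A"] <- 3.5        # 1 + 1.5 + 1
  d4["A", "D"] <- d4["D", "A"] <- 5.5        # 1 + 1.5 + 3
  d4["B", "C"] <- d4["C", "B"] <- 4.5
  d4["B", "D"] <- d4["D", "B"] <- 6.5
  d4["C", "D"] <- d4["D", "C"] <- 4
  t4 <- nj_tree(d4)
  expect_equal(ape::cophenetic.phylo(t4)[lab, lab], d4, tolerance = 1e-12)

  # random 6-taxon additive matrices: exact topology and path lengths
  for (seed in 1:10) {
    ra <- random_additive(6, seed)
    fit <- nj_tree(ra$d)
    expect_equal(ape::dist.topo(ape::unroot(fit), ape::unroot(ra$tree)), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(fit)[rownames(ra$d), colnames(ra$d)] -
                        ra$d)), 1e-9)
  }
})

test_that("NJ topology matches exhaustive least-squares search on 5 taxa", {
  ra <- random_additive(5, seed = 99)
  fit <- nj_tree(ra$d)
  # brute-force oracle: score all 15 unrooted 5-taxon topologies by
  # least-squares branch fitting and take the best
  all_top <- phangorn::allTrees(5, rooted = FALSE,
                                tip.label = rownames(ra$d))
  scores <- vapply(all_top, function(tr) {
    f <- phangorn::nnls.tree(as.dist(ra$d), tr)
    sum((ape::cophenetic.phylo(f)[rownames(ra$d), colnames(ra$d)] - ra$d)^2)
  }, numeric(1))
  best <- all_top[[which.min(scores)]]
  expect_equal(ape::dist.topo(ape::unroot(fit), ape::unroot(best)), 0,
               ignore_attr = TRUE)
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    ra <- random_additive(8, seed + 100)
    d <- ra$d + matrix(runif(64, 0, 0.02), 8)  # mild non-additive noise
    d <- (d + t(d)) / 2; diag(d) <- 0
    mine <- nj_tree(d)
    ref <- ape::nj(d)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
    expect_true(all(mine$edge.length >= 0))
    expect_gte(attr(mine, "negative_length_deficit"), 0)
  }
})

test_that("Newick serialization is canonical and round-trips", {
  ra <- random_additive(6, seed = 7)
  t1 <- nj_tree(ra$d)
  s1 <- to_newick(t1)
  # determinism: identical string on recomputation
  expect_identical(s1, to_newick(nj_tree(ra$d)))
  # taxon input order must not change the canonical string
  perm <- sample(6)
  s2 <- to_newick(nj_tree(ra$d[perm, perm]))
  expect_identical(s1, s2)
  # round trip parses back to an isomorphic tree
  back <- ape::read.tree(text = s1)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(t1)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(back)[t1$tip.label, t1$tip.label],
               ape::cophenetic.phylo(t1)[t1$tip.label, t1$tip.label],
               tolerance = 1e-8)
})

test_that("invalid distance matrices are rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(nj_tree(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2)
  expect_error(nj_tree(neg), "non-negative")
})

test_that("bootstrap support is seeded and sized to the internal nodes", {
  set.seed(16)
  gm <- make_gm(matrix(rbinom(6 * 200, 2, 0.4), nrow = 6),
                pos = sort(sample.int(1e5, 200)),
                samples = letters[1:6])
  b1 <- bootstrap_nj(gm, reps = 20, seed = 5)
  b2 <- bootstrap_nj(gm, reps = 20, seed = 5)
  expect_equal(b1$support, b2$support)
  expect_length(b1$support, b1$tree$Nnode)
  expect_true(all(b1$support[-1] <= 20, na.rm = TRUE))
})
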
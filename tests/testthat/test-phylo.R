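test_that("core distances are length-weighted complements of identity", {
  # two strains, two equal-length core genes at PI 90 and PI 100 -> 5.0
  set.seed(501)
  g1 <- random_aa_string(100)
  g2 <- random_aa_string(100)
  # force exactly 10 substitutions into g1's copy
  chars <- strsplit(g1, "")[[1]]
  pos <- sample(100, 10)
  bg <- names(aa_background())
  for (p in pos) chars[p] <- sample(setdiff(bg, chars[p]), 1)
  g1_b <- paste(chars, collapse = "")

  pA <- toy_proteome("A", c(c1 = g1, c2 = g2))
  pB <- toy_proteome("B", c(d1 = g1_b, d2 = g2))
  hits <- search_all_vs_all(list(pA, pB), k = 4)
  cs <- cluster_orthologs(build_similarity_graph(hits, pan_thresholds()),
                          list(pA, pB))
  d <- core_distance_matrix(cs, list(pA, pB))
  expect_equal(d["A", "B"], 5.0)
  expect_equal(diag(d), c(A = 0, B = 0))

  # identical proteomes: distance zero
  pC <- toy_proteome("C", c(e1 = g1, e2 = g2))
  pD <- toy_proteome("D", c(f1 = g1, f2 = g2))
  h2 <- search_all_vs_all(list(pC, pD), k = 4)
  cs2 <- cluster_orthologs(build_similarity_graph(h2, core_thresholds()),
                           list(pC, pD))
  expect_equal(core_distance_matrix(cs2, list(pC, pD))["C", "D"], 0)
})

test_that("jaccard distances follow the set formula and its geometry", {
  pa <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0))
  d <- jaccard_distance_matrix(pa)
  expect_equal(d["a", "b"], 1 - 1 / 3)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["b", "c"], 1 - 1 / 3)

  disjoint <- rbind(x = c(1, 1, 0, 0), y = c(0, 0, 1, 1))
  expect_equal(jaccard_distance_matrix(disjoint)["x", "y"], 1)

  expect_error(jaccard_distance_matrix(rbind(a = c(0, 0), b = c(1, 0))),
               "all-zero")

  # triangle inequality on random binary matrices
  set.seed(502)
  for (rep in 1:20) {
    m <- matrix(rbinom(6 * 8, 1, 0.5), 6, 8)
    m[, 1] <- 1  # guarantee non-empty profiles
    rownames(m) <- letters[1:6]
    d <- jaccard_distance_matrix(m)
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("three-taxon neighbor joining matches the closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(bl, c(a = 1, b = 1, c = 3))
})

test_that("neighbor joining is exact on additive matrices", {
  set.seed(503)
  for (rep in 1:10) {
    true_tree <- ape::rtree(5, br = function(n) runif(n, 0.5, 2))
    true_tree <- ape::unroot(true_tree)
    d <- cophenetic(true_tree)
    tr <- nj_tree(d)
    expect_equal(sort(tr$tip.label), sort(true_tree$tip.label))
    # path distances reproduced exactly
    expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
    # same unrooted topology
    expect_equal(ape::dist.topo(tr, true_tree)[1], 0, ignore_attr = TRUE)
  }
})

test_that("tree cutting separates well-separated clusters", {
  labs <- sprintf("x%d", 1:6)
  planted <- stats::setNames(rep(1:2, each = 3), labs)
  d <- matrix(10, 6, 6, dimnames = list(labs, labs))
  d[1:3, 1:3] <- 1
  d[4:6, 4:6] <- 1
  diag(d) <- 0
  tr <- nj_tree(d)
  expect_equal(compare_partitions(tree_clades(tr, 2), planted), 1)
})

test_that("newick serialization round-trips the tree", {
  d <- matrix(c(0, 2, 4, 5, 2, 0, 4, 5, 4, 4, 0, 3, 5, 5, 3, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(cophenetic(back)[letters[1:4], letters[1:4]],
               cophenetic(tr)[letters[1:4], letters[1:4]], tolerance = 1e-6)
})

test_that("Rand index matches brute-force pair enumeration", {
  expect_equal(compare_partitions(c(a = 1, b = 1, c = 2),
                                  c(a = 5, b = 5, c = 9)), 1)
  expect_equal(compare_partitions(c(a = 1, b = 2, c = 3),
                                  c(a = 1, b = 1, c = 1)), 0)
  expect_error(compare_partitions(c(a = 1), c(b = 1)), "label sets")

  set.seed(504)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    labs <- letters[1:n]
    p1 <- stats::setNames(sample(1:3, n, TRUE), labs)
    p2 <- stats::setNames(sample(1:3, n, TRUE), labs)
    expect_equal(compare_partitions(p1, p2), oracle_rand(p1, p2))
  }

  # list-of-blocks and clade_partition inputs are accepted
  expect_equal(compare_partitions(list(c("a", "b"), "c"),
                                  c(a = 1, b = 1, c = 2)), 1)
})
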
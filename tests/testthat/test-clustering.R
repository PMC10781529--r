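three_leaf_sim <- function() {
  s <- matrix(c(1, .8, .4,
                .8, 1, .4,
                .4, .4, 1), 3, 3, dimnames = list(c("A", "B", "C"),
                                                  c("A", "B", "C")))
  s
}

test_that("a hand-computed 3-leaf tree has the expected merges", {
  tr <- upgma(three_leaf_sim())
  # d(A,B)=0.2 merges first; C then joins at mean(0.6, 0.6) = 0.6
  expect_equal(tr$height, c(0.2, 0.6))
  expect_equal(sort(tr$labels[-tr$merge[1, ]]), c("A", "B"))
  cp <- cophenetic(tr)
  expect_equal(cp["A", "B"], 0.2)
  expect_equal(cp["A", "C"], 0.6)
  expect_equal(cp["B", "C"], 0.6)
})

test_that("upgma rejects malformed similarity input", {
  s <- three_leaf_sim()
  s[1, 2] <- 0.9                       # break symmetry
  expect_error(upgma(s), "symmetric")
  expect_error(upgma(matrix(1, 1, 1, dimnames = list("A", "A"))),
               "at least 2")
})

test_that("upgma matches the brute-force all-pairs oracle on random matrices", {
  set.seed(41)
  for (trial in 1:100) {
    n <- sample(3:7, 1)
    s <- matrix(0, n, n)
    s[upper.tri(s)] <- runif(n * (n - 1) / 2, 0.1, 0.95)
    s <- s + t(s); diag(s) <- 1
    dimnames(s) <- list(LETTERS[1:n], LETTERS[1:n])
    tr <- upgma(s)
    or <- upgma_oracle(s)
    expect_equal(tr$height, or$heights)
    expect_equal(tree_partitions(tr), or$partitions)
    expect_true(all(diff(tr$height) >= -1e-12))
  }
})

test_that("upgma agrees with hclust average linkage heights", {
  s <- bg_scot_similarity()
  tr <- upgma(s)
  h <- hclust(as.dist(1 - s), method = "average")
  expect_equal(sort(tr$height), sort(h$height))
  # and the hclust bridge preserves the structure
  hb <- as.hclust(tr)
  expect_equal(cophenetic(tr)[h$labels, h$labels][lower.tri(diag(10))],
               as.matrix(stats::cophenetic(hb))[h$labels,
                                                h$labels][lower.tri(diag(10))])
})

test_that("SCoT tree topology follows the printed similarity matrix", {
  tr <- upgma(bg_scot_similarity())
  expect_equal(sort(tr$labels[-tr$merge[1, ]]), c("S5", "S7"))
  expect_equal(tr$height[1], 1 - 0.889, tolerance = 1e-9)
  # verified against the brute-force oracle: the matrix, not the figure
  # prose, determines the topology (see vignette)
  or <- upgma_oracle(bg_scot_similarity())
  expect_equal(tree_partitions(tr), or$partitions)
  expect_equal(cut_clusters(tr, 2),
               list(c("S1", "S10", "S4", "S5", "S6", "S7", "S8", "S9"),
                    c("S2", "S3")))
  expect_true(any(vapply(tree_partitions(tr), identical, logical(1),
                         c("S8", "S9"))))
})

test_that("protein tree clusters the Jaccard-identical cultivars at height zero", {
  tr <- upgma(jaccard_similarity(bg_protein()))
  expect_equal(tree_partitions(tr), upgma_oracle(
    jaccard_similarity(bg_protein()))$partitions)
  # S1,S3,S4,S5,S7,S10 are pairwise identical profiles: first five merges
  # happen at distance 0
  expect_equal(tr$height[1:5], rep(0, 5))
  expect_true(identical(tree_partitions(tr)[[5]],
                        sort(c("S1", "S3", "S4", "S5", "S7", "S10"))))
  # the k=2 cut isolates S8, the most band-poor divergent cultivar
  expect_equal(cut_clusters(tr, 2)[[2]], "S8")
})

test_that("newick export round-trips through ape with heights preserved", {
  skip_if_not_installed("ape")
  for (s in list(three_leaf_sim(), bg_scot_similarity(),
                 jaccard_similarity(bg_protein()))) {
    tr <- upgma(s)
    ph <- ape::read.tree(text = to_newick(tr))
    expect_setequal(ph$tip.label, tr$labels)
    cp_ape <- as.matrix(ape::cophenetic.phylo(ph))[tr$labels, tr$labels]
    expect_equal(cp_ape, cophenetic(tr), tolerance = 1e-8)
    expect_true(ape::is.ultrametric(ph, tol = 1e-8))
  }
})

test_that("newick child order is deterministic and 2-leaf trees are minimal", {
  s2 <- matrix(c(1, .7, .7, 1), 2, 2, dimnames = list(c("B", "A"),
                                                      c("B", "A")))
  expect_equal(to_newick(upgma(s2)), "(A:0.15,B:0.15);")
  expect_identical(to_newick(upgma(bg_scot_similarity())),
                   to_newick(upgma(bg_scot_similarity())))
})

test_that("cophenetic distances are ultrametric and exact on ultrametric input", {
  set.seed(43)
  n <- 6
  s <- matrix(0, n, n)
  s[upper.tri(s)] <- runif(n * (n - 1) / 2, 0.2, 0.9)
  s <- s + t(s); diag(s) <- 1
  dimnames(s) <- list(LETTERS[1:n], LETTERS[1:n])
  tr <- upgma(s)
  cp <- cophenetic(tr)
  # three-point condition: the max of each triple is attained twice
  for (tri in combn(n, 3, simplify = FALSE)) {
    d3 <- sort(c(cp[tri[1], tri[2]], cp[tri[1], tri[3]], cp[tri[2], tri[3]]))
    expect_equal(d3[2], d3[3])
  }
  # UPGMA applied to an ultrametric matrix reproduces it exactly
  s_ultra <- 1 - cp
  diag(s_ultra) <- 1
  expect_equal(cophenetic(upgma(s_ultra)), cp, tolerance = 1e-12)
})

test_that("cut_clusters spans k = 1 to the leaf count", {
  tr <- upgma(bg_scot_similarity())
  expect_equal(cut_clusters(tr, 1), list(sort(paste0("S", 1:10))))
  expect_equal(length(cut_clusters(tr, 10)), 10)
  expect_error(cut_clusters(tr, 0), "between")
  expect_error(cut_clusters(tr, 11), "between")
  # cuts are nested partitions
  for (k in 2:9) {
    parts_k <- cut_clusters(tr, k)
    parts_k1 <- cut_clusters(tr, k + 1)
    for (p in parts_k1)
      expect_true(any(vapply(parts_k, function(q) all(p %in% q),
                             logical(1))))
  }
})
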
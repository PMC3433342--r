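# Distance matrices and neighbor joining.

# path-length matrix between tips of a phylo tree
tree_path_lengths <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d))]
}

test_that("binary p-distance counts differing presence states", {
  pam <- pam_from_counts(c(1, 2, 3), 4)
  d <- binary_p_distance(pam)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  # identical and complementary columns
  presence <- matrix(c(TRUE, TRUE, FALSE,
                       TRUE, TRUE, FALSE,
                       FALSE, FALSE, TRUE), nrow = 3,
                     dimnames = list(c("g1", "g2", "g3"), c("a", "b", "c")))
  d2 <- binary_p_distance(pa_matrix(presence))
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)
  # the published example scale: 26 differing loci of 2,407
  expect_equal(26 / 2407, 0.0108, tolerance = 1e-2)
})

test_that("snp p-distance equals a site-by-site oracle", {
  aln <- list(
    gene1 = c(x = "AAAA", y = "AAAT", z = "AAAA"),
    gene2 = c(x = "CCCC", y = "CCCC", z = "CCNC")
  )
  d <- snp_p_distance(aln)
  # x vs y: 1 mismatch in 8 comparable sites
  expect_equal(d["x", "y"], 1 / 8)
  # x vs z: N site dropped, 0 mismatches in 7
  expect_equal(d["x", "z"], 0)
  # y vs z: 1 mismatch in 7 comparable sites
  expect_equal(d["y", "z"], 1 / 7)

  expect_error(snp_p_distance(list(g = c(x = "AA"), h = c(y = "AA"))),
               "accession set")

  set.seed(61)
  aln2 <- list(g1 = c(a = random_seq(200), b = random_seq(200),
                      c = random_seq(200)))
  d2 <- snp_p_distance(aln2)
  oracle <- function(s1, s2) {
    x <- strsplit(s1, "")[[1]]; y <- strsplit(s2, "")[[1]]
    mean(x != y)
  }
  expect_equal(d2["a", "b"], oracle(aln2$g1[["a"]], aln2$g1[["b"]]))
})

test_that("identical accessions sit at distance zero", {
  aln <- list(g = c(ICE169 = "ACGTACGT", ICE173 = "ACGTACGT",
                    other = "ACGTACGA"))
  d <- snp_p_distance(aln)
  expect_equal(d["ICE169", "ICE173"], 0)
})

test_that("three-taxon NJ uses the closed-form star lengths", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(len["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(len["c"]), (4 + 5 - 3) / 2)
})

test_that("NJ recovers additive trees exactly (n = 4..8)", {
  set.seed(62)
  for (n in 4:8) {
    true_tree <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(true_tree)
    nj <- neighbor_joining(d)
    expect_setequal(nj$tip.label, true_tree$tip.label)
    # path lengths between every leaf pair match the input distances
    got <- tree_path_lengths(nj)
    want <- d[rownames(got), colnames(got)]
    expect_equal(got, want, tolerance = 1e-9)
    # topology identical to the generating tree
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true_tree), nj)), 0)
  }
})

test_that("NJ is deterministic and validates its input", {
  set.seed(63)
  pam <- random_pam(50, 6)
  d <- binary_p_distance(pam)
  t1 <- newick_string(neighbor_joining(d))
  t2 <- newick_string(neighbor_joining(d))
  expect_identical(t1, t2)

  bad <- d
  bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(neighbor_joining(bad), "symmetric")
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("on ultrametric distances NJ matches the single-linkage topology", {
  set.seed(64)
  for (i in 1:5) {
    n <- sample(4:6, 1)
    pts <- matrix(rnorm(n * 2), ncol = 2,
                  dimnames = list(letters[1:n], NULL))
    hc <- stats::hclust(stats::dist(pts), method = "single")
    # ultrametric matrix from the dendrogram (cophenetic heights)
    d <- as.matrix(stats::cophenetic(hc))
    nj <- neighbor_joining(d)
    hc_tree <- ape::as.phylo(hc)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(hc_tree),
                                           ape::unroot(nj))), 0)
  }
})

test_that("tree comparison reports Robinson-Foulds distance", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  t2 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1,e:1);")
  cmp <- compare_trees(t1, t2)
  expect_gt(cmp$rf, 0)
  expect_equal(compare_trees(t1, t1)$rf, 0)
  expect_error(compare_trees(t1, ape::rtree(4)), "leaf sets")
})

test_that("cohort trees carry every accession and finite branch lengths", {
  pip <- default_pipeline()
  expect_setequal(pip$pa_tree$tip.label,
                  colnames(pip$pa_matrix$presence))
  expect_setequal(pip$accession_tree$tip.label,
                  colnames(pip$pa_matrix$presence))
  expect_true(all(is.finite(pip$pa_tree$edge.length)))
  expect_true(all(pip$pa_tree$edge.length >= 0))
  expect_true(all(pip$accession_tree$edge.length >= 0))
})
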
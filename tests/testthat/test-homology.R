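# Gene families by divergence and tandem clusters on chromosomes.

# brute-force maximal-chain oracle: all subsets of the family members on a
# chromosome that satisfy the consecutive-gap chain condition and are not
# extendable.
chain_oracle <- function(ranks, max_gap) {
  stopifnot(length(ranks) <= 15)
  is_chain <- function(r) all(diff(sort(r)) <= max_gap + 1)
  subsets <- unlist(lapply(2:length(ranks), function(sz) {
    utils::combn(ranks, sz, simplify = FALSE)
  }), recursive = FALSE)
  chains <- Filter(is_chain, subsets)
  maximal <- Filter(function(s) {
    !any(vapply(chains, function(t) length(t) > length(s) && all(s %in% t),
                TRUE))
  }, chains)
  lapply(maximal, sort)
}

test_that("pairwise divergence counts substitutions and is symmetric", {
  set.seed(40)
  s <- random_seq(100)
  expect_equal(pairwise_divergence(s, s), 0)
  # 30 substitutions scattered across the interior (a block at a sequence
  # end would be confoundable with excluded terminal gaps)
  mutated <- substitute_at(s, seq(5, 92, by = 3))
  expect_equal(pairwise_divergence(s, mutated), 0.30)
  set.seed(41)
  a <- random_seq(200)
  b <- substitute_at(a, sample(200, 40))
  expect_equal(pairwise_divergence(a, b), pairwise_divergence(b, a))
  expect_error(pairwise_divergence("", a), "empty")
})

test_that("families form by single linkage under strict divergence", {
  set.seed(42)
  base <- random_seq(300)
  a <- base
  p1 <- seq(2, 179, by = 3)             # 60 scattered interior positions
  p2 <- seq(181, 299, by = 2)           # 60 more, disjoint from p1
  b <- substitute_at(base, p1)          # d(a,b) = 0.2
  c <- substitute_at(b, p2)             # d(b,c) = 0.2, d(a,c) = 0.4
  fams <- build_families(c(a = a, b = b, c = c))
  expect_length(fams$families, 1)
  expect_setequal(fams$families[[1]], c("a", "b", "c"))
  expect_length(fams$singletons, 0)

  # three identical genes form one family of three
  fams2 <- build_families(c(x = base, y = base, z = base))
  expect_setequal(fams2$families[[1]], c("x", "y", "z"))

  # all divergences at or above the threshold leave only singletons
  d1 <- random_seq(300)
  d2 <- substitute_at(d1, seq(3, 270, by = 3))  # exactly 0.30: strict <
  fams3 <- build_families(c(p = d1, q = d2, r = random_seq(300)))
  expect_length(fams3$families, 0)
  expect_setequal(fams3$singletons, c("p", "q", "r"))
})

test_that("families and singletons partition the gene set", {
  co <- default_cohort()
  fams <- default_pipeline()$families
  ids <- names(co$reference$genes)
  members <- unlist(fams$families, use.names = FALSE)
  expect_setequal(c(members, fams$singletons), ids)
  expect_equal(anyDuplicated(c(members, fams$singletons)), 0)
})

test_that("planted families are recovered exactly at the 0.3 threshold", {
  co <- default_cohort()
  fams <- default_pipeline()$families
  truth_keys <- sort(vapply(co$truth$families, function(x)
    paste(sort(x), collapse = ","), ""))
  found_keys <- sort(vapply(fams$families, function(x)
    paste(sort(x), collapse = ","), ""))
  expect_equal(unname(found_keys), unname(truth_keys))
})

test_that("cluster detection follows the eight-intervening-gene rule", {
  order_df <- data.frame(gene_id = sprintf("g%02d", 1:40),
                         chromosome = "chr1", rank = 1:40)
  fams <- list(f1 = c("g10", "g14"))      # 3 intervening
  expect_length(detect_clusters(fams, order_df), 1)
  fams2 <- list(f1 = c("g10", "g25"))     # 14 intervening
  expect_length(detect_clusters(fams2, order_df), 0)
  fams3 <- list(f1 = c("g10", "g19", "g28"))  # 8 intervening each: chains
  cl <- detect_clusters(fams3, order_df)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members, c("g10", "g19", "g28"))
  expect_error(detect_clusters(list(f1 = c("g10", "nope")), order_df),
               "missing")
})

test_that("detect_clusters equals the brute-force chain oracle", {
  set.seed(43)
  for (i in 1:25) {
    n_genes <- 15
    n_members <- sample(2:6, 1)
    ranks <- sort(sample(n_genes, n_members))
    ids <- sprintf("g%02d", ranks)
    order_df <- data.frame(gene_id = sprintf("g%02d", 1:n_genes),
                           chromosome = "chr1", rank = 1:n_genes)
    max_gap <- sample(0:8, 1)
    got <- detect_clusters(list(f = ids), order_df, max_gap = max_gap)
    got_ranks <- lapply(got, function(cl) {
      sort(as.integer(sub("g", "", cl$members)))
    })
    want <- chain_oracle(ranks, max_gap)
    key <- function(x) paste(x, collapse = ",")
    expect_setequal(vapply(got_ranks, key, ""), vapply(want, key, ""))
  }
})

test_that("planted tandem clusters are recovered exactly", {
  co <- default_cohort()
  pip <- default_pipeline()
  truth <- sort(vapply(co$truth$clusters, function(x)
    paste(sort(x$members), collapse = ","), ""))
  found <- sort(vapply(pip$clusters, function(x)
    paste(sort(x$members), collapse = ","), ""))
  expect_equal(unname(found), unname(truth))
})

test_that("cluster statistics reproduce the printed proportion arithmetic", {
  expect_equal(round(100 * 746 / 2407, 1), 31.0)
  expect_equal(round(100 * 746 / 1218, 1), 61.2)
  expect_equal(round(100 * 1218 / 2407, 1), 50.6)

  pip <- default_pipeline()
  cs <- pip$cluster_stats
  expect_equal(cs$prop_pa_clustered * cs$n_pa, cs$n_pa_clustered)
  expect_lte(cs$n_pa_clustered, cs$n_pa_in_families)
})
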
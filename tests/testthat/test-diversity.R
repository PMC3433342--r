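# Nucleotide diversity, frequency binning and quadratic covariation.

test_that("nucleotide diversity matches pairwise enumeration", {
  expect_equal(nucleotide_diversity(c("ACGT", "ACGT")), 0)
  expect_equal(nucleotide_diversity(c("AAAA", "AAAT")), 0.25)
  # three sequences: pairwise {0.25, 0.50, 0.25}, mean 1/3
  expect_equal(nucleotide_diversity(c("AAAA", "AAAT", "AATT")), 1 / 3)
  expect_equal(nucleotide_diversity("ACGT"), 0)        # single allele
  expect_equal(nucleotide_diversity(rep("ACGTAC", 7)), 0)
  expect_error(nucleotide_diversity(c("AAA", "AAAA")), "length")
})

test_that("diversity is order-invariant and handles ambiguous sites", {
  set.seed(51)
  seqs <- vapply(1:6, function(i) random_seq(50), "")
  expect_equal(nucleotide_diversity(seqs), nucleotide_diversity(rev(seqs)))
  # an N site is excluded pairwise: AANA vs AAAA has 3 comparable, 0 diffs
  expect_equal(nucleotide_diversity(c("AANA", "AAAA")), 0)
  # AANT vs AAAA: comparable sites A,A,T vs A,A,A -> 1/3
  expect_equal(nucleotide_diversity(c("AANT", "AAAA")), 1 / 3)
  # an all-N allele contributes zero-difference pairs: the pair mean scales
  # by the fraction of informative pairs (3 of 6)
  base <- c("AAAA", "AATA", "TTAA")
  expect_equal(nucleotide_diversity(c(base, "NNNN")),
               nucleotide_diversity(base) * 3 / 6)
})

test_that("binning conserves loci and orders frequencies", {
  loci <- data.frame(gene_id = sprintf("g%04d", 1:2407),
                     absence_count = sample(1:79, 2407, replace = TRUE),
                     pi = runif(2407, 0, 0.02),
                     length = sample(300:3000, 2407, replace = TRUE))
  bins <- bin_by_frequency(loci, n_bins = 29, bin_size = 83, seed = 3)
  expect_length(bins, 29)
  expect_true(all(vapply(bins, function(b) nrow(b$loci), 0) == 83))
  expect_equal(sum(vapply(bins, function(b) nrow(b$loci), 0)), 2407)
  freqs <- vapply(bins, `[[`, 0, "mean_frequency_count")
  expect_true(all(diff(freqs) >= 0))
})

test_that("binning is seed-stable exactly when there are ties", {
  loci <- data.frame(gene_id = letters[1:10], absence_count = 1:10,
                     pi = runif(10))
  b1 <- bin_by_frequency(loci, 2, 5, seed = 1)
  b2 <- bin_by_frequency(loci, 2, 5, seed = 999)
  expect_identical(lapply(b1, function(b) b$loci$gene_id),
                   lapply(b2, function(b) b$loci$gene_id))
  expect_error(bin_by_frequency(loci[1:3, ], 5, 1), "fewer loci")
  expect_error(bin_by_frequency(loci, 2, 6), "exceeds")
})

test_that("remainder loci join the last bin", {
  loci <- data.frame(gene_id = letters[1:11], absence_count = 1:11,
                     pi = runif(11))
  bins <- bin_by_frequency(loci, 2, 5, seed = 1)
  expect_equal(nrow(bins[[1]]$loci), 5)
  expect_equal(nrow(bins[[2]]$loci), 6)
})

test_that("quadratic covariation recovers exact curves and edge cases", {
  f <- seq(0.05, 0.95, length.out = 10)
  bins <- lapply(seq_along(f), function(i) {
    list(bin_index = i, mean_frequency_count = f[i],
         mean_pi = 1 + 2 * f[i] - 2 * f[i]^2)
  })
  fit <- quadratic_covariation(bins, "pi")
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$r, 1)
  expect_equal(fit$beta, c(1, 2, -2), tolerance = 1e-9)
  expect_equal(fit$vertex, 0.5, tolerance = 1e-9)

  flat <- lapply(bins, function(b) { b$mean_pi <- 0.7; b })
  expect_equal(quadratic_covariation(flat, "pi")$r, 0)

  expect_error(quadratic_covariation(bins[1:3], "pi"), "at least 4")
  const_f <- lapply(bins, function(b) { b$mean_frequency_count <- 2; b })
  expect_error(quadratic_covariation(const_f, "pi"), "rank-deficient")
})

test_that("quadratic coefficients match the normal-equations oracle", {
  set.seed(52)
  for (i in 1:10) {
    f <- runif(8)
    y <- runif(8)
    bins <- lapply(1:8, function(j) {
      list(bin_index = j, mean_frequency_count = f[j], mean_pi = y[j])
    })
    fit <- quadratic_covariation(bins, "pi")
    X <- cbind(1, f, f^2)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(fit$beta, as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("covariation report conserves loci and the overall mean", {
  pip <- default_pipeline()
  cv <- pip$covariation
  expect_equal(sum(vapply(cv$bins, function(b) nrow(b$loci), 0)),
               nrow(cv$loci))
  expect_equal(cv$mean_pi, mean(cv$loci$pi))
  expect_true(all(cv$loci$pi >= 0 & cv$loci$pi <= 1))
})

test_that("a flat diversity law rarely yields a significant covariation", {
  # null calibration on cheap synthetic loci (no sequence simulation):
  # per-locus diversity independent of frequency
  set.seed(53)
  n_sig <- 0
  for (s in 1:100) {
    loci <- data.frame(gene_id = sprintf("g%03d", 1:200),
                       absence_count = sample(1:19, 200, replace = TRUE),
                       pi = abs(rnorm(200, 0.008, 0.004)))
    bins <- bin_by_frequency(loci, n_bins = 10, bin_size = 20, seed = s)
    fit <- quadratic_covariation(bins, "pi", n_accessions = 20)
    if (!is.na(fit$p_value) && fit$p_value < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 10)  # not significant in >= 90% of seeds
})

test_that("the planted quadratic diversity law is recovered", {
  pip <- default_pipeline()
  fit <- pip$covariation$fit_pi
  expect_lt(abs(fit$vertex - 0.5), 0.05)
  expect_lt(fit$p_value, 1e-4)
  expect_gt(fit$beta[3], -Inf)
  expect_lt(fit$beta[3], 0)  # concave, as planted
})
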
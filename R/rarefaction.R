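# Random-sampling (rarefaction) model of P/A gene discovery: how many
# distinct absent genes are found among k sampled accessions, the exact
# inclusion-exclusion expectation, the logarithmic curve fit and a
# randomization test for an observed external count.

#' Absent-gene count in one random accession sample
#'
#' Draws `k` accessions uniformly without replacement and counts the genes
#' absent in at least one of them.
#'
#' @param pam A [pa_matrix].
#' @param k Sample size, `1 <= k <=` number of accessions.
#' @return Integer count of distinct absent genes.
#' @export
sample_absent_count <- function(pam, k) {
  n <- ncol(pam$presence)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "]")
  cols <- sample.int(n, k)
  sum(rowSums(!pam$presence[, cols, drop = FALSE]) > 0L)
}

#' Exact expected absent-gene count for a sample of k accessions
#'
#' By inclusion-exclusion over genes, the expected number of distinct absent
#' genes among `k` accessions drawn without replacement from `n` is
#' `sum_g (1 - C(n - m_g, k) / C(n, k))`, where `m_g` is the number of
#' accessions gene `g` is absent in, and `C(n - m, k) = 0` when `k > n - m`.
#'
#' @inheritParams sample_absent_count
#' @return Exact expectation (float).
#' @export
expected_absent_count <- function(pam, k) {
  n <- ncol(pam$presence)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "]")
  m <- pam$absence_count
  p_missed <- ifelse(k > n - m, 0, exp(lchoose(n - m, k) - lchoose(n, k)))
  sum(1 - p_missed)
}

#' Rarefaction curve of absent-gene discovery
#'
#' For every sample size, draws `reps` random accession samples and records
#' the number of distinct absent genes, its mean and a percentile 95%
#' confidence interval. Each replicate draws one random permutation of the
#' accessions and reads the cumulative union of absent genes along it, so
#' each sample size sees exactly the uniform-without-replacement sampling
#' distribution.
#'
#' @param pam A [pa_matrix].
#' @param sizes Integer sample sizes (default `1:n_accessions`).
#' @param reps Replicates per size (default 10000).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return Object of class `rarefaction_result`: list with `sizes`,
#'   `replicate_counts` (matrix reps x sizes), `mean`, `ci_lo`, `ci_hi`
#'   (per size), and the fitted logarithmic coefficients `fit_a`, `fit_b`
#'   (see [fit_log_curve()]).
#' @export
rarefaction_curve <- function(pam, sizes = NULL, reps = 10000L, seed = 1L) {
  n <- ncol(pam$presence)
  sizes <- sizes %||% seq_len(n)
  if (any(sizes < 1L | sizes > n)) stop("sizes must be in [1, ", n, "]")
  if (reps < 2L) stop("need reps >= 2")
  set.seed(seed)
  absent <- !pam$presence
  counts <- matrix(0L, nrow = reps, ncol = length(sizes),
                   dimnames = list(NULL, sizes))
  for (r in seq_len(reps)) {
    perm <- sample.int(n)
    # rank (1..n) of the first sampled accession each gene is absent in
    first <- rep(n + 1L, nrow(absent))
    for (j in seq_len(n)) {
      hit <- absent[, perm[j]] & first > n
      first[hit] <- j
    }
    cum <- cumsum(tabulate(first, nbins = n))
    counts[r, ] <- cum[sizes]
  }
  means <- colMeans(counts)
  ci <- apply(counts, 2L, stats::quantile, probs = c(0.025, 0.975))
  fit <- if (length(unique(sizes)) >= 2L) {
    fit_log_curve(sizes, means)
  } else c(a = NA_real_, b = NA_real_)
  structure(list(sizes = sizes, replicate_counts = counts, mean = means,
                 ci_lo = ci[1L, ], ci_hi = ci[2L, ],
                 fit_a = unname(fit["a"]), fit_b = unname(fit["b"])),
            class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat(sprintf("<rarefaction_result> %d sizes x %d reps; fit y = %.1f ln(x) + %.1f\n",
              length(x$sizes), nrow(x$replicate_counts), x$fit_a, x$fit_b))
  invisible(x)
}

#' Fit a logarithmic discovery curve y = a ln(x) + b
#'
#' Ordinary least squares of the per-size mean counts on the natural log of
#' the sample size.
#'
#' @param sizes Sample sizes (>= 1), at least two distinct values.
#' @param means Mean absent-gene counts per size.
#' @return Named vector `c(a = , b = )`.
#' @export
fit_log_curve <- function(sizes, means) {
  if (length(sizes) != length(means)) stop("sizes and means differ in length")
  if (any(sizes < 1)) stop("sizes must be >= 1")
  if (length(unique(sizes)) < 2L) stop("need at least two distinct sizes")
  fit <- stats::lm(means ~ log(sizes))
  c(a = unname(stats::coef(fit)[2L]), b = unname(stats::coef(fit)[1L]))
}

#' Predict the absent-gene count from a fitted logarithmic curve
#'
#' Evaluates `a * ln(x) + b` and rounds half away from zero to the nearest
#' integer gene count.
#'
#' @param a,b Fitted coefficients.
#' @param x Number of sampled accessions (>= 1).
#' @return Integer predicted count.
#' @export
predict_absent <- function(a, b, x) {
  if (any(x < 1)) stop("x must be >= 1")
  y <- a * log(x) + b
  as.integer(sign(y) * floor(abs(y) + 0.5))
}

#' Randomization test of an observed absent-gene count
#'
#' Two-sided empirical p-value: the fraction of `reps` random samples of
#' size `k` whose absent-gene count deviates from the replicate mean by at
#' least as much as the observed count does, with an add-one correction so
#' p is never exactly 0.
#'
#' @param pam A [pa_matrix].
#' @param k Sample size.
#' @param observed Observed external absent-gene count (>= 0).
#' @param reps Number of replicates (default 10000).
#' @param seed RNG seed.
#' @return p-value in `(0, 1]`.
#' @export
randomization_pvalue <- function(pam, k, observed, reps = 10000L, seed = 1L) {
  if (observed < 0) stop("observed must be >= 0")
  set.seed(seed)
  counts <- replicate(reps, sample_absent_count(pam, k))
  center <- mean(counts)
  (1 + sum(abs(counts - center) >= abs(observed - center))) / (reps + 1)
}
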
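# Nucleotide diversity of present alleles at P/A loci, equal-size frequency
# binning, and the quadratic covariation of absence frequency with diversity
# and gene length.

#' Nucleotide diversity of a set of aligned allele sequences
#'
#' Average over all unordered sequence pairs of the proportion of differing
#' comparable sites. Alleles must be reconstructed against the reference
#' coordinate frame (equal lengths). Sites where either member of a pair has
#' a base outside `{A,C,G,T}` are non-comparable for that pair (pairwise
#' deletion).
#'
#' @param allele_sequences Character vector of equal-length nucleotide
#'   strings; fewer than two sequences give diversity 0.
#' @return Nucleotide diversity (pi) in `[0, 1]`.
#' @export
nucleotide_diversity <- function(allele_sequences) {
  n <- length(allele_sequences)
  if (n < 2L) return(0)
  lens <- nchar(allele_sequences)
  if (length(unique(lens)) > 1L) stop("allele sequences differ in length")
  mat <- do.call(rbind, strsplit(toupper(allele_sequences), "", fixed = TRUE))
  ok <- matrix(mat %in% DNA_BASES, nrow = n)
  if (all(ok)) {
    # no ambiguous sites: count mismatching pairs per site in closed form
    L <- ncol(mat)
    pair_diffs <- 0
    for (b in DNA_BASES) {
      cb <- colSums(mat == b)
      pair_diffs <- pair_diffs + sum(cb * (n - cb))
    }
    return(pair_diffs / 2 / (n * (n - 1) / 2) / L)
  }
  total <- 0
  n_pairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      n_pairs <- n_pairs + 1L
      if (any(comp)) {
        total <- total + mean(mat[i, comp] != mat[j, comp])
      }
    }
  }
  total / n_pairs
}

#' Bin P/A loci into equal-size absence-frequency bins
#'
#' Loci are sorted by absence count, ties shuffled by a seeded RNG, and cut
#' into consecutive blocks of `bin_size`; remainder loci join the last bin.
#'
#' @param loci data.frame with one row per locus; must contain
#'   `absence_count`, and typically `gene_id`, `pi` and `length`.
#' @param n_bins Number of bins (default 29).
#' @param bin_size Loci per bin (default 83); `n_bins * bin_size` must not
#'   exceed the number of loci by construction of the inputs.
#' @param seed Seed for the tie shuffle.
#' @return List of bins; each is a list with `bin_index`, `loci` (the member
#'   rows), `mean_frequency_count` (mean absence count), and the means of
#'   every numeric locus column (`mean_pi`, `mean_length`, ... as present).
#' @export
bin_by_frequency <- function(loci, n_bins = 29L, bin_size = 83L, seed = 1L) {
  n <- nrow(loci)
  if (n < n_bins) stop("fewer loci (", n, ") than bins (", n_bins, ")")
  if (n_bins * bin_size > n) {
    stop("n_bins * bin_size exceeds the number of loci")
  }
  set.seed(seed)
  ord <- order(loci$absence_count, sample.int(n))
  sorted <- loci[ord, , drop = FALSE]
  bin_of <- pmin((seq_len(n) - 1L) %/% bin_size + 1L, n_bins)
  lapply(seq_len(n_bins), function(b) {
    rows <- sorted[bin_of == b, , drop = FALSE]
    out <- list(bin_index = b, loci = rows,
                mean_frequency_count = mean(rows$absence_count))
    for (col in setdiff(names(rows)[vapply(rows, is.numeric, TRUE)],
                        "absence_count")) {
      out[[paste0("mean_", col)]] <- mean(rows[[col]])
    }
    out
  })
}

#' Quadratic covariation of a bin response with absence frequency
#'
#' OLS fit of the per-bin mean response on frequency and squared frequency;
#' the association strength is reported as `r = sqrt(R^2)` of the quadratic
#' fit, with the p-value from the F test of the full model against the
#' intercept-only model.
#'
#' @param bins Output of [bin_by_frequency()], at least 4 bins.
#' @param response `"pi"` or `"length"`: which bin mean to regress.
#' @param n_accessions Number of accessions, used to convert mean absence
#'   counts to frequencies in `[0, 1]`. If `NULL`, mean counts are used as-is.
#' @return List with `beta` (intercept, linear, quadratic), `r`, `r_squared`,
#'   `p_value`, `vertex` (frequency at the fitted extremum, `NA` when the
#'   quadratic term is 0) and the design data.
#' @export
quadratic_covariation <- function(bins, response = c("pi", "length"),
                                  n_accessions = NULL) {
  response <- match.arg(response)
  if (length(bins) < 4L) stop("need at least 4 bins")
  f <- vapply(bins, `[[`, 0, "mean_frequency_count")
  if (!is.null(n_accessions)) f <- f / n_accessions
  y <- vapply(bins, `[[`, 0, paste0("mean_", response))
  if (stats::var(f) == 0) stop("rank-deficient design: constant frequency")
  if (stats::var(y) == 0) {
    return(list(beta = c(y[1L], 0, 0), r = 0, r_squared = 0, p_value = 1,
                vertex = NA_real_, frequency = f, response = y))
  }
  fit <- stats::lm(y ~ f + I(f^2))
  if (anyNA(stats::coef(fit))) stop("rank-deficient quadratic design")
  sm <- suppressWarnings(summary(fit))  # noiseless fits warn harmlessly
  r2 <- sm$r.squared
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  beta <- unname(stats::coef(fit))
  list(beta = beta, r = sqrt(max(r2, 0)), r_squared = r2,
       p_value = unname(p),
       vertex = if (beta[3L] != 0) -beta[2L] / (2 * beta[3L]) else NA_real_,
       frequency = f, response = y)
}

#' Diversity-frequency covariation report for a cohort
#'
#' Computes per-locus nucleotide diversity from the present-allele sequences,
#' bins loci by absence frequency, and fits the quadratic covariation of the
#' bin means for both diversity and gene length.
#'
#' @param pam A [pa_matrix].
#' @param alleles Named list (by gene id) of character vectors: the
#'   present-allele sequences of each P/A locus, reference-frame aligned.
#' @param lengths Optional named numeric vector of gene lengths (bp); by
#'   default the allele length of each locus.
#' @param n_bins,bin_size Binning layout (see [bin_by_frequency()]).
#' @param seed Seed for the binning tie shuffle.
#' @return List with `loci` (per-locus table: `gene_id`, `absence_count`,
#'   `pi`, `length`), `bins`, `fit_pi`, `fit_length` (see
#'   [quadratic_covariation()]), `mean_pi`, and `per_frequency` (bin-free
#'   mean diversity at each distinct absence count).
#' @export
covariation_report <- function(pam, alleles, lengths = NULL, n_bins = 29L,
                               bin_size = 83L, seed = 1L) {
  ids <- intersect(rownames(pam$presence), names(alleles))
  if (length(ids) == 0L) stop("no overlap between matrix genes and alleles")
  pi_vals <- vapply(alleles[ids], nucleotide_diversity, 0)
  len_vals <- if (is.null(lengths)) {
    vapply(alleles[ids], function(a) nchar(a[[1L]]), 0L)
  } else as.numeric(lengths[ids])
  loci <- data.frame(gene_id = ids,
                     absence_count = unname(pam$absence_count[ids]),
                     pi = unname(pi_vals), length = unname(len_vals),
                     row.names = NULL)
  bins <- bin_by_frequency(loci, n_bins = n_bins, bin_size = bin_size,
                           seed = seed)
  n_acc <- ncol(pam$presence)
  per_freq <- stats::aggregate(pi ~ absence_count, data = loci, FUN = mean)
  list(loci = loci, bins = bins,
       fit_pi = quadratic_covariation(bins, "pi", n_accessions = n_acc),
       fit_length = quadratic_covariation(bins, "length",
                                          n_accessions = n_acc),
       mean_pi = mean(loci$pi), per_frequency = per_freq)
}
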
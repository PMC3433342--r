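# 2x2 chi-square enrichment of P/A genes across gene groupings and the
# per-category proportion report.

#' Pearson chi-square test of a 2x2 contingency table
#'
#' No continuity correction: the statistic is the plain Pearson
#' `sum (O - E)^2 / E` with expectations from the table margins,
#' equivalently `(ad - bc)^2 N / (row1 row2 col1 col2)`, with the p-value
#' from the upper tail of the chi-square distribution on 1 degree of
#' freedom. Invariant under transposition of the table.
#'
#' @param a,b,c,d Non-negative cell counts, rows = in-group/not-in-group,
#'   columns = P/A / non-P/A. Alternatively `a` may be a 2x2 matrix.
#' @return List with `statistic`, `df` (always 1) and `p_value`.
#' @export
chi_square_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), nrow = 2L)
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table")
  if (any(tab < 0)) stop("negative cell count")
  rows <- rowSums(tab); cols <- colSums(tab); N <- sum(tab)
  if (any(rows == 0) || any(cols == 0)) stop("zero margin in the 2x2 table")
  E <- outer(rows, cols) / N
  stat <- sum((tab - E)^2 / E)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Functional-category composition and enrichment of P/A genes
#'
#' For every category: how many P/A and reference genes it holds, the P/A
#' proportion within the category, the category's share among P/A genes, and
#' a chi-square enrichment test of the category against its complement.
#' Genes may carry multiple categories (tests are per category, not
#' partition-wise); Benjamini-Hochberg q-values are reported alongside the
#' raw p-values.
#'
#' @param pa_genes Character vector of P/A gene ids.
#' @param all_genes Character vector of all reference gene ids.
#' @param category_map data.frame with columns `gene_id` and `category`
#'   (one row per assignment), e.g. read from a two-column TSV.
#' @return data.frame, one row per category: `category`, `n_pa`, `n_all`,
#'   `prop_pa_in_category` (P/A rate inside the category),
#'   `share_of_pa_genes`, `chi_square`, `p_value`, `q_value`. Categories
#'   whose 2x2 table has a zero margin get `NA` statistics.
#' @export
category_report <- function(pa_genes, all_genes, category_map) {
  stopifnot(all(c("gene_id", "category") %in% names(category_map)))
  cm <- category_map[category_map$gene_id %in% all_genes, , drop = FALSE]
  if (nrow(cm) == 0L) stop("category map covers no reference gene")
  n_pa_tot <- length(pa_genes)
  n_all_tot <- length(all_genes)
  rows <- lapply(split(cm$gene_id, cm$category), function(members) {
    members <- unique(members)
    n_all <- length(members)
    n_pa <- sum(members %in% pa_genes)
    tab <- matrix(c(n_pa, n_pa_tot - n_pa,
                    n_all - n_pa, (n_all_tot - n_pa_tot) - (n_all - n_pa)),
                  nrow = 2L, byrow = TRUE)
    test <- tryCatch(chi_square_2x2(tab),
                     error = function(e) list(statistic = NA_real_,
                                              p_value = NA_real_))
    data.frame(n_pa = n_pa, n_all = n_all,
               prop_pa_in_category = n_pa / n_all,
               share_of_pa_genes = n_pa / n_pa_tot,
               chi_square = test$statistic, p_value = test$p_value)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(category = names(rows)), out)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Share of a gene set within an absence-frequency window
#'
#' Proportion of `gene_set` whose absence count lies in `[lo, hi]`
#' (inclusive bounds).
#'
#' @param pam A [pa_matrix].
#' @param gene_set Character vector of gene ids, all rows of the matrix.
#' @param lo,hi Inclusive absence-count bounds.
#' @return Proportion in `[0, 1]`.
#' @export
frequency_class_share <- function(pam, gene_set, lo, hi) {
  if (length(gene_set) == 0L) stop("empty gene set")
  missing <- setdiff(gene_set, rownames(pam$presence))
  if (length(missing)) stop("gene(s) not in the matrix: ",
                            paste(utils::head(missing, 3L), collapse = ", "))
  m <- pam$absence_count[gene_set]
  mean(m >= lo & m <= hi)
}
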
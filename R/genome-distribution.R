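# Distribution of P/A genes along chromosomes: fixed-width windows,
# per-window P/A proportion, and the centromere-distance profile.

#' Assign genes to fixed-width chromosome windows
#'
#' Window `w` (0-indexed) on a chromosome spans
#' `[w * window_size + 1, (w + 1) * window_size]`; a gene belongs to the
#' window containing its start coordinate.
#'
#' @param genes List of [gene_model] objects or a data.frame with columns
#'   `gene_id`, `chromosome`, `start`.
#' @param chrom_lengths Named integer vector of chromosome lengths; all
#'   windows are enumerated, including gene-free ones.
#' @param window_size Window width in bp (default 1 Mb).
#' @return List with `windows` (data.frame `chrom`, `window`, `start`,
#'   `end`) and `gene_window` (data.frame `gene_id`, `chrom`, `window`).
#' @export
assign_windows <- function(genes, chrom_lengths, window_size = 1e6) {
  tab <- if (is.data.frame(genes)) genes else gene_table(genes)
  stopifnot(all(c("gene_id", "chromosome", "start") %in% names(tab)))
  bad <- !tab$chromosome %in% names(chrom_lengths)
  if (any(bad)) stop("gene on chromosome without a length: ",
                     tab$gene_id[bad][1L])
  if (any(tab$start > chrom_lengths[tab$chromosome])) {
    stop("gene start beyond chromosome length")
  }
  windows <- do.call(rbind, lapply(names(chrom_lengths), function(chr) {
    nw <- ceiling(chrom_lengths[[chr]] / window_size)
    data.frame(chrom = chr, window = seq_len(nw) - 1L,
               start = (seq_len(nw) - 1L) * window_size + 1,
               end = pmin(seq_len(nw) * window_size, chrom_lengths[[chr]]))
  }))
  rownames(windows) <- NULL
  gene_window <- data.frame(gene_id = tab$gene_id, chrom = tab$chromosome,
                            window = as.integer((tab$start - 1) %/% window_size))
  list(windows = windows, gene_window = gene_window,
       window_size = window_size)
}

#' Per-window P/A gene proportion
#'
#' @param assignment Output of [assign_windows()].
#' @param pa_gene_ids Character vector of P/A gene ids.
#' @return The `windows` data.frame extended with `n_total`, `n_pa` and
#'   `proportion` (`NA` for windows with no genes, which are undefined
#'   rather than zero).
#' @export
pa_proportion_per_window <- function(assignment, pa_gene_ids) {
  win <- assignment$windows
  gw <- assignment$gene_window
  key <- function(chrom, window) paste(chrom, window, sep = "@")
  totals <- table(key(gw$chrom, gw$window))
  pa <- table(key(gw$chrom[gw$gene_id %in% pa_gene_ids],
                  gw$window[gw$gene_id %in% pa_gene_ids]))
  wk <- key(win$chrom, win$window)
  win$n_total <- as.integer(ifelse(wk %in% names(totals), totals[wk], 0L))
  win$n_pa <- as.integer(ifelse(wk %in% names(pa), pa[wk], 0L))
  win$proportion <- ifelse(win$n_total > 0L, win$n_pa / win$n_total, NA_real_)
  win
}

#' Centromere-distance profile of the P/A proportion
#'
#' Annotates each window with the distance (Mb) from its midpoint to the
#' nearest edge of its chromosome's centromere (0 when overlapping), and
#' summarizes the covariation of P/A proportion with centromere distance as
#' Spearman rank correlations, per chromosome and pooled.
#'
#' @param window_table Output of [pa_proportion_per_window()].
#' @param centromeres data.frame with columns `chrom`, `start`, `end`: one
#'   centromere interval per chromosome.
#' @return List with `windows` (the table plus `distance_mb`),
#'   `per_chromosome` (data.frame `chrom`, `rho`, `p_value`) and pooled
#'   `rho` / `p_value`. Gene-free windows are excluded from the
#'   correlations.
#' @export
centromere_profile <- function(window_table, centromeres) {
  missing <- setdiff(unique(window_table$chrom), centromeres$chrom)
  if (length(missing)) {
    stop("no centromere given for chromosome(s): ",
         paste(missing, collapse = ", "))
  }
  cen <- centromeres[match(window_table$chrom, centromeres$chrom), ]
  mid <- (window_table$start + window_table$end) / 2
  dist_bp <- pmax(0, pmax(cen$start - mid, mid - cen$end))
  window_table$distance_mb <- dist_bp / 1e6

  sp_cor <- function(df) {
    df <- df[!is.na(df$proportion), , drop = FALSE]
    if (nrow(df) < 3L || stats::var(df$distance_mb) == 0) {
      return(c(rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(df$distance_mb, df$proportion,
                                           method = "spearman",
                                           exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  per_chr <- do.call(rbind, lapply(split(window_table, window_table$chrom),
                                   sp_cor))
  pooled <- sp_cor(window_table)
  list(windows = window_table,
       per_chromosome = data.frame(chrom = rownames(per_chr),
                                   rho = per_chr[, "rho"],
                                   p_value = per_chr[, "p"],
                                   row.names = NULL),
       rho = unname(pooled["rho"]), p_value = unname(pooled["p"]))
}
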
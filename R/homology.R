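# Multi-copy gene families by nucleotide divergence (single linkage over
# pairwise global alignments, with a lossless shared k-mer prefilter), and
# tandem gene clusters on chromosomes.

#' Pairwise nucleotide divergence of two sequences
#'
#' Global alignment with affine gap penalties (Biostrings); divergence is
#' one minus the fraction of identical positions among aligned columns,
#' excluding terminal-gap columns. Symmetric in its arguments.
#'
#' @param seq1,seq2 Nucleotide strings, each at least 30 bp.
#' @return Divergence in `[0, 1]`.
#' @export
pairwise_divergence <- function(seq1, seq2) {
  if (nchar(seq1) < 1L || nchar(seq2) < 1L) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(seq1)), Biostrings::DNAString(toupper(seq2)),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3),
    # stiff gaps: divergence here is substitution-dominated (gene-family
    # classification), and cheap gaps would let the aligner trade mismatch
    # runs for indel excursions
    gapOpening = 10, gapExtension = 4
  )
  a <- seq_to_chars(as.character(Biostrings::alignedPattern(aln)))
  b <- seq_to_chars(as.character(Biostrings::alignedSubject(aln)))
  # drop terminal-gap columns (leading/trailing overhang of either sequence)
  gap <- a == "-" | b == "-"
  inner <- which(!gap)
  keep <- seq(min(inner), max(inner))
  1 - mean(a[keep] == b[keep])
}

# Candidate gene pairs sharing at least min_shared distinct k-mers. At the
# divergence the family threshold targets (< 0.3) true homolog pairs of the
# lengths this package works with share far more than min_shared k-mers, so
# the prefilter does not lose family edges; random pairs almost never pass.
#' @noRd
kmer_candidate_pairs <- function(seqs, k = 13L, min_shared = 2L) {
  ids <- names(seqs)
  kmer_tab <- lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1L) return(character(0))
    unique(substring(s, seq_len(n), seq_len(n) + k - 1L))
  })
  df <- data.frame(kmer = unlist(kmer_tab, use.names = FALSE),
                   gene = rep(seq_along(seqs), lengths(kmer_tab)))
  shared <- split(df$gene, df$kmer)
  shared <- shared[lengths(shared) > 1L]
  if (length(shared) == 0L) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  pairs <- do.call(rbind, lapply(shared, function(g) {
    g <- sort(unique(g))
    if (length(g) < 2L) return(NULL)
    t(utils::combn(g, 2L))
  }))
  key <- paste(pairs[, 1L], pairs[, 2L])
  counts <- table(key)
  keep <- names(counts)[counts >= min_shared]
  parts <- do.call(rbind, strsplit(keep, " ", fixed = TRUE))
  data.frame(i = as.integer(parts[, 1L]), j = as.integer(parts[, 2L]))
}

#' Group genes into families by sequence divergence
#'
#' Builds single-linkage connected components over the graph whose edges are
#' gene pairs with divergence strictly below `max_divergence` (the >= 70%
#' identity homolog criterion at the default). Genes in no edge are
#' singletons. An all-vs-all alignment is avoided by a shared k-mer
#' prefilter; only candidate pairs are aligned.
#'
#' @param genes Named list of [gene_model] objects or named character vector
#'   of CDS sequences.
#' @param max_divergence Family threshold; pairs with divergence
#'   `< max_divergence` are homologs (default 0.3).
#' @param k Prefilter k-mer length (default 13).
#' @param min_shared Minimum shared distinct k-mers for a pair to be aligned
#'   (default 2).
#' @return List with `families` (named list of member-id character vectors,
#'   each of size >= 2) and `singletons` (character vector); together they
#'   partition the input gene ids.
#' @export
build_families <- function(genes, max_divergence = 0.3, k = 13L,
                           min_shared = 2L) {
  seqs <- if (is.character(genes)) genes
          else vapply(genes, `[[`, "", "cds_sequence")
  if (is.null(names(seqs))) {
    names(seqs) <- vapply(genes, `[[`, "", "gene_id")
  }
  n <- length(seqs)
  if (n < 1L) stop("need at least one gene")

  cand <- kmer_candidate_pairs(seqs, k = k, min_shared = min_shared)
  edge <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    d <- pairwise_divergence(seqs[[cand$i[r]]], seqs[[cand$j[r]]])
    edge[r] <- d < max_divergence
  }

  # union-find over divergence edges
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in which(edge)) {
    ri <- find(cand$i[r]); rj <- find(cand$j[r])
    if (ri != rj) parent[ri] <- rj
  }
  comp <- vapply(seq_len(n), find, 0L)
  groups <- split(names(seqs), comp)
  fams <- groups[lengths(groups) > 1L]
  names(fams) <- sprintf("fam%03d", seq_along(fams))
  list(families = fams,
       singletons = unlist(groups[lengths(groups) == 1L], use.names = FALSE))
}

#' Detect tandem gene clusters of family members
#'
#' Within each family and chromosome, members are sorted by their rank in
#' the chromosome's gene order and chained whenever consecutive members have
#' at most `max_gap` intervening genes (rank difference `<= max_gap + 1`).
#' Maximal chains with at least two members are clusters.
#'
#' @param families Named list of member-id character vectors (output of
#'   [build_families()]`$families`).
#' @param gene_order data.frame with columns `gene_id`, `chromosome`, `rank`
#'   (1-based integer position of the gene along its chromosome), e.g. from
#'   [gene_ranks()].
#' @param max_gap Maximum number of intervening genes between consecutive
#'   homologs in a cluster (default 8).
#' @return List of clusters; each is a list with `cluster_id`, `family_id`,
#'   `chromosome`, `members` (ids ordered by rank).
#' @export
detect_clusters <- function(families, gene_order, max_gap = 8L) {
  stopifnot(all(c("gene_id", "chromosome", "rank") %in% names(gene_order)))
  rank_of <- stats::setNames(gene_order$rank, gene_order$gene_id)
  chrom_of <- stats::setNames(gene_order$chromosome, gene_order$gene_id)
  clusters <- list()
  for (fid in names(families)) {
    members <- families[[fid]]
    missing <- members[!members %in% names(rank_of)]
    if (length(missing)) {
      stop("gene(s) missing from the order index: ",
           paste(missing, collapse = ", "))
    }
    for (chr in unique(chrom_of[members])) {
      on_chr <- members[chrom_of[members] == chr]
      if (length(on_chr) < 2L) next
      on_chr <- on_chr[order(rank_of[on_chr])]
      gaps <- diff(rank_of[on_chr])
      chain_id <- cumsum(c(1L, as.integer(gaps > max_gap + 1L)))
      for (chain in split(on_chr, chain_id)) {
        if (length(chain) >= 2L) {
          clusters[[length(clusters) + 1L]] <- list(
            cluster_id = sprintf("clu%03d", length(clusters) + 1L),
            family_id = fid, chromosome = chr, members = unname(chain))
        }
      }
    }
  }
  clusters
}

#' Gene order index for cluster detection
#'
#' Ranks genes 1..n along each chromosome by start coordinate.
#'
#' @param genes List of [gene_model] objects.
#' @return data.frame with columns `gene_id`, `chromosome`, `rank`.
#' @export
gene_ranks <- function(genes) {
  tab <- gene_table(genes)
  tab <- tab[order(tab$chromosome, tab$start), , drop = FALSE]
  tab$rank <- stats::ave(seq_len(nrow(tab)), tab$chromosome,
                         FUN = seq_along)
  tab[, c("gene_id", "chromosome", "rank")]
}

#' Family and cluster composition of the P/A gene set
#'
#' @param pam A [pa_matrix].
#' @param families,clusters Outputs of [build_families()] and
#'   [detect_clusters()] computed over all reference genes.
#' @param all_genes Character vector of all reference gene ids (background).
#' @return List of counts and proportions: P/A genes in multi-copy families
#'   and in clusters, the clustered share among family-member P/A genes, and
#'   the same proportions over all reference genes.
#' @export
cluster_stats <- function(pam, families, clusters, all_genes) {
  pa_genes <- rownames(pam$presence)
  fam_members <- unlist(families$families, use.names = FALSE)
  clu_members <- unlist(lapply(clusters, `[[`, "members"), use.names = FALSE)
  n_pa <- length(pa_genes)
  pa_fam <- sum(pa_genes %in% fam_members)
  pa_clu <- sum(pa_genes %in% clu_members)
  list(
    n_pa = n_pa,
    n_pa_in_families = pa_fam,
    n_pa_clustered = pa_clu,
    prop_pa_in_families = pa_fam / n_pa,
    prop_pa_clustered = pa_clu / n_pa,
    prop_family_pa_clustered = if (pa_fam > 0L) pa_clu / pa_fam else 0,
    n_genes = length(all_genes),
    prop_all_in_families = mean(all_genes %in% fam_members),
    prop_all_clustered = mean(all_genes %in% clu_members)
  )
}
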
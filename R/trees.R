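# Distance matrices on P/A profiles and SNPs, and neighbor-joining tree
# construction (Saitou-Nei, with deterministic tie-breaking and non-negative
# branch lengths).

#' p-distance between accessions on binary P/A profiles
#'
#' `d(i, j)` is the fraction of P/A loci at which the two accessions differ
#' in presence state.
#'
#' @param pam A [pa_matrix] with at least 3 accessions.
#' @return Symmetric numeric matrix with accession ids as dimnames.
#' @export
binary_p_distance <- function(pam) {
  if (nrow(pam$presence) == 0L) stop("matrix has zero loci")
  if (ncol(pam$presence) < 3L) stop("need at least 3 accessions")
  m <- pam$presence * 1L
  d <- as.matrix(stats::dist(t(m), method = "manhattan")) / nrow(m)
  dimnames(d) <- list(colnames(pam$presence), colnames(pam$presence))
  d
}

#' p-distance between accessions on SNPs of non-P/A genes
#'
#' Sites are compared across the concatenation of the per-gene allele
#' alignments; sites where either accession has an ambiguous base are
#' non-comparable for that pair.
#'
#' @param alignments Named list (by gene) of named character vectors: for
#'   each gene, one equal-length allele sequence per accession. Every
#'   accession must appear in every gene.
#' @return Symmetric numeric matrix of pairwise p-distances.
#' @export
snp_p_distance <- function(alignments) {
  if (length(alignments) == 0L) stop("no alignments given")
  acc <- names(alignments[[1L]])
  for (g in names(alignments)) {
    if (!setequal(names(alignments[[g]]), acc)) {
      stop("accession set differs in gene ", g)
    }
  }
  mats <- lapply(alignments, function(a) {
    do.call(rbind, strsplit(toupper(a[acc]), "", fixed = TRUE))
  })
  big <- do.call(cbind, mats)
  ok <- matrix(big %in% DNA_BASES, nrow = length(acc))
  n <- length(acc)
  d <- matrix(0, n, n, dimnames = list(acc, acc))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp)) stop("no comparable sites between ", acc[i],
                           " and ", acc[j])
      d[i, j] <- d[j, i] <- mean(big[i, comp] != big[j, comp])
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Classic Saitou-Nei agglomeration: the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j` is joined at each step, with branch
#' lengths by the standard formulas. Ties in Q are broken by the
#' lexicographically smallest pair of node creation indices, so the result
#' is deterministic. Negative branch lengths are clamped to zero with the
#' deficit moved to the sister branch. The returned tree is unrooted
#' (trifurcating basal node).
#'
#' @param d Symmetric numeric distance matrix with labels as dimnames,
#'   at least 3 taxa.
#' @return An `ape` `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12))) {
    stop("distance matrix is not symmetric")
  }
  labels <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  # node bookkeeping: leaves are nodes 1..n; internal nodes appended
  newick_of <- as.list(labels)
  active <- seq_len(n)
  D <- d
  join_newick <- function(a, b, la, lb) {
    sprintf("(%s:%.12g,%s:%.12g)", newick_of[[a]], la, newick_of[[b]], lb)
  }
  while (length(active) > 3L) {
    r <- length(active)
    Dm <- D[active, active]
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    li <- 0.5 * Dm[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    u <- nrow(D) + 1L
    du <- 0.5 * (D[active[i], active] + D[active[j], active] -
                   D[active[i], active[j]])
    D <- rbind(cbind(D, 0), 0)
    D[u, active] <- du
    D[active, u] <- du
    D[u, u] <- 0
    newick_of[[u]] <- join_newick(active[i], active[j], li, lj)
    active <- c(active[-c(i, j)], u)
  }
  a <- active[1L]; b <- active[2L]; c0 <- active[3L]
  la <- pmax(0, (D[a, b] + D[a, c0] - D[b, c0]) / 2)
  lb <- pmax(0, (D[a, b] + D[b, c0] - D[a, c0]) / 2)
  lc <- pmax(0, (D[a, c0] + D[b, c0] - D[a, b]) / 2)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", newick_of[[a]], la,
                 newick_of[[b]], lb, newick_of[[c0]], lc)
  ape::read.tree(text = txt)
}

#' Robinson-Foulds comparison of two trees
#'
#' Programmatic surrogate for a reconciled-tree display: the topological
#' distance between, e.g., the P/A gene tree and the SNP accession tree.
#'
#' @param tree1,tree2 `phylo` trees on the same leaf set.
#' @return List with `rf` (Robinson-Foulds distance) and `max_rf` (its
#'   maximum `2 (n - 3)` for unrooted binary trees).
#' @export
compare_trees <- function(tree1, tree2) {
  if (!setequal(tree1$tip.label, tree2$tip.label)) {
    stop("trees have different leaf sets")
  }
  rf <- ape::dist.topo(ape::unroot(tree1), ape::unroot(tree2))
  list(rf = as.numeric(rf), max_rf = 2 * (length(tree1$tip.label) - 3))
}
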
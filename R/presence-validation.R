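# Deciding whether a candidate P/A gene is present in an independently
# assembled genome: a seed-and-extend local homology search whose operative
# criterion is cumulative query coverage by sufficiently similar hits.

# Exact k-mer seed positions of a query against one target strand.
# Returns data.frame(qpos, tpos) of seed start coordinates.
#' @noRd
kmer_seeds <- function(query, target, k) {
  nq <- nchar(query) - k + 1L
  if (nq < 1L || nchar(target) < k) {
    return(data.frame(qpos = integer(0), tpos = integer(0)))
  }
  kmers <- substring(query, seq_len(nq), seq_len(nq) + k - 1L)
  keep <- !grepl("[^ACGT]", kmers)
  if (!any(keep)) return(data.frame(qpos = integer(0), tpos = integer(0)))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[keep]))
  hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(target))
  qpos <- rep(which(keep), lengths(Biostrings::startIndex(hits)))
  tpos <- unlist(Biostrings::startIndex(hits), use.names = FALSE)
  data.frame(qpos = as.integer(qpos), tpos = as.integer(tpos))
}

# Hit spans on the query from seeds against one target strand. Seeds are
# grouped by alignment diagonal; merged seed intervals are extended outwards
# base by base while bases match exactly (ungapped), giving maximal exact
# runs. Runs on one diagonal are then chained into a single hit when the
# identity of the chained span still reaches min_identity, so substitution-
# diverged homologs are covered end to end.
#' @noRd
diagonal_hits <- function(query, target, k, min_identity, min_hit) {
  seeds <- kmer_seeds(query, target, k)
  diagonal_spans(seq_to_chars(query), seq_to_chars(target), seeds, k,
                 min_identity, min_hit)
}

# Core of the diagonal extension, working from precomputed seeds and
# character vectors.
#' @noRd
diagonal_spans <- function(qc, tc, seeds, k, min_identity, min_hit) {
  if (nrow(seeds) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  nq <- length(qc); nt <- length(tc)
  extend <- function(qs, qe, diag) {
    while (qs > 1L && qs + diag > 1L && qc[qs - 1L] == tc[qs - 1L + diag]) {
      qs <- qs - 1L
    }
    while (qe < nq && qe + diag < nt && qc[qe + 1L] == tc[qe + 1L + diag]) {
      qe <- qe + 1L
    }
    c(qs, qe)
  }
  by_diag <- split(seeds$qpos, seeds$tpos - seeds$qpos)
  diags <- as.integer(names(by_diag))
  spans <- vector("list", length(by_diag))
  for (di in seq_along(by_diag)) {
    diag <- diags[di]
    qpos <- by_diag[[di]]
    runs <- merge_intervals(qpos, qpos + k - 1L)
    runs <- t(mapply(extend, runs$start, runs$end, MoreArgs = list(diag = diag)))
    if (nrow(runs) > 1L) {
      full <- extend(min(runs[, 1L]), max(runs[, 2L]), diag)
      idx <- full[1L]:full[2L]
      if (mean(qc[idx] == tc[idx + diag]) >= min_identity) {
        runs <- matrix(full, nrow = 1L)
      }
    }
    spans[[di]] <- runs
  }
  spans <- do.call(rbind, spans)
  # chance k-mer matches against megabase-scale targets are ubiquitous;
  # only spans long enough to be significant count as hits
  keep <- spans[, 2L] - spans[, 1L] + 1L >= min_hit
  data.frame(start = spans[keep, 1L], end = spans[keep, 2L])
}

#' Fraction of a query covered by local homology hits in a target genome
#'
#' Seed-and-extend search with exact k-mer seeds on both strands; hits with
#' identity at or above `min_identity` are merged on the query before the
#' covered fraction is computed.
#'
#' @param query Nucleotide string, length >= 30.
#' @param target Target sequence(s): a character vector of chromosome
#'   sequences or a single string.
#' @param min_identity Minimum per-hit identity (default 0.7).
#' @param k Exact seed length (default 11, the classic BLASTN word size).
#' @param min_hit Minimum hit-span length in bp (default 30): shorter spans
#'   are indistinguishable from chance k-mer matches against genome-sized
#'   targets and are discarded, standing in for an alignment significance
#'   cutoff.
#' @return Covered fraction of the query length, in `[0, 1]`.
#' @export
query_coverage <- function(query, target, min_identity = 0.7, k = 11L,
                           min_hit = 30L) {
  query <- toupper(query)
  if (nchar(query) < 30L) stop("query shorter than 30 bp")
  target <- toupper(unlist(target, use.names = FALSE))
  target <- target[nchar(target) > 0L]
  if (length(target) == 0L) {
    warning("empty target genome; reporting zero coverage")
    return(0)
  }
  nq <- nchar(query)
  hits <- do.call(rbind, lapply(target, function(tg) {
    fwd <- diagonal_hits(query, tg, k, min_identity, min_hit)
    rev <- diagonal_hits(revcomp(query), tg, k, min_identity, min_hit)
    # map reverse-strand spans back onto query coordinates
    rev <- data.frame(start = nq - rev$end + 1L, end = nq - rev$start + 1L)
    rbind(fwd, rev)
  }))
  if (nrow(hits) == 0L) return(0)
  merged <- merge_intervals(hits$start, hits$end)
  sum(merged$end - merged$start + 1L) / nchar(query)
}

#' Is a gene present in an assembled genome?
#'
#' `TRUE` when homology hits (see [query_coverage()]) cover strictly more
#' than `min_coverage` of the query length. Lowering `min_coverage` can never
#' flip a presence call to absence.
#'
#' @inheritParams query_coverage
#' @param min_coverage Minimum covered query fraction (default 0.5: a gene
#'   with a counterpart over more than half its length is present).
#' @return Logical presence call, with the covered fraction attached as
#'   attribute `"coverage"`.
#' @export
local_presence <- function(query, target, min_identity = 0.7,
                           min_coverage = 0.5, k = 11L, min_hit = 30L) {
  cov <- query_coverage(query, target, min_identity = min_identity, k = k,
                        min_hit = min_hit)
  structure(cov > min_coverage, coverage = cov)
}

#' Validate candidate P/A genes against independent assembled genomes
#'
#' @param candidates Named list of [gene_model] objects, or a named character
#'   vector of CDS sequences.
#' @param reference_genomes Named list of [accession_genome] objects (their
#'   `sequences` are searched), or a named list of character vectors.
#' @param ... Passed to [local_presence()].
#' @return List with `calls` (logical matrix candidates x genomes),
#'   `n_no_match` (candidates present in no genome) and `n_all_present`
#'   (candidates present in every genome).
#' @export
validate_candidates <- function(candidates, reference_genomes, ...) {
  if (length(reference_genomes) < 1L) stop("need at least one reference genome")
  seqs <- if (is.character(candidates)) as.list(toupper(candidates))
          else lapply(candidates, function(g) toupper(g$cds_sequence))
  ids <- names(seqs) %||% vapply(candidates, `[[`, "", "gene_id")
  targets <- lapply(reference_genomes, function(g) {
    if (inherits(g, "accession_genome")) g$sequences else g
  })
  calls <- matrix(FALSE, nrow = length(seqs), ncol = length(targets),
                  dimnames = list(ids, names(targets)))
  for (j in seq_along(targets)) {
    cov <- batch_query_coverage(seqs, targets[[j]], ...)
    calls[, j] <- cov > attr(cov, "min_coverage")
  }
  list(calls = calls,
       n_no_match = sum(rowSums(calls) == 0L),
       n_all_present = sum(rowSums(calls) == ncol(calls)))
}

# Coverage of many queries against one genome with a single seed scan per
# target strand: all queries' k-mers go into one dictionary, so the target
# is traversed twice (forward and reverse-complement query set) per
# chromosome regardless of the number of queries.
#' @noRd
batch_query_coverage <- function(queries, target, min_identity = 0.7,
                                 min_coverage = 0.5, k = 11L, min_hit = 30L) {
  target <- toupper(unlist(target, use.names = FALSE))
  target <- target[nchar(target) > 0L]
  nqry <- length(queries)
  covered <- lapply(queries, function(q) {
    data.frame(start = integer(0), end = integer(0))
  })
  if (length(target) == 0L) {
    warning("empty target genome; reporting zero coverage")
    out <- rep(0, nqry)
    return(structure(out, min_coverage = min_coverage))
  }
  strands <- list(fwd = queries, rev = lapply(queries, revcomp))
  qchars <- lapply(queries, seq_to_chars)
  rchars <- lapply(strands$rev, seq_to_chars)
  for (tg in target) {
    tc <- seq_to_chars(tg)
    for (strand in names(strands)) {
      qs <- strands[[strand]]
      kmers <- lapply(qs, function(q) {
        n <- nchar(q) - k + 1L
        if (n < 1L) return(character(0))
        km <- substring(q, seq_len(n), seq_len(n) + k - 1L)
        km[grepl("[^ACGT]", km)] <- NA_character_
        km
      })
      qidx <- rep(seq_len(nqry), lengths(kmers))
      qpos <- unlist(lapply(lengths(kmers), seq_len), use.names = FALSE)
      km <- unlist(kmers, use.names = FALSE)
      keep <- !is.na(km)
      if (!any(keep)) next
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(km[keep]))
      hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(tg))
      sidx <- Biostrings::startIndex(hits)
      nh <- lengths(sidx)
      hq <- rep(qidx[keep], nh)
      hp <- rep(qpos[keep], nh)
      tpos <- unlist(sidx, use.names = FALSE)
      for (i in unique(hq)) {
        sel <- hq == i
        seeds <- data.frame(qpos = hp[sel], tpos = tpos[sel])
        chars <- if (strand == "fwd") qchars[[i]] else rchars[[i]]
        spans <- diagonal_spans(chars, tc, seeds, k, min_identity, min_hit)
        if (strand == "rev") {
          nq <- length(chars)
          spans <- data.frame(start = nq - spans$end + 1L,
                              end = nq - spans$start + 1L)
        }
        covered[[i]] <- rbind(covered[[i]], spans)
      }
    }
  }
  out <- vapply(seq_len(nqry), function(i) {
    sp <- covered[[i]]
    if (nrow(sp) == 0L) return(0)
    merged <- merge_intervals(sp$start, sp$end)
    sum(merged$end - merged$start + 1L) / nchar(queries[[i]])
  }, 0)
  structure(out, min_coverage = min_coverage)
}
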
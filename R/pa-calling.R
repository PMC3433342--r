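# Calling absent genes from inaccessible-region masks, assembling the P/A
# matrix and its frequency spectrum, and calling ORF-disrupting variants.

#' Fraction of a gene's CDS covered by inaccessible regions
#'
#' Splice-aware: only bases inside the CDS (exon) intervals count towards
#' either the numerator or the denominator.
#'
#' @param gene A [gene_model].
#' @param mask Normalized mask data.frame (`chrom`, `start`, `end`); a
#'   chromosome with no mask intervals contributes zero overlap.
#' @return Masked fraction of the CDS, in `[0, 1]`.
#' @export
inaccessible_fraction <- function(gene, mask) {
  m <- mask[mask$chrom == gene$chromosome, , drop = FALSE]
  len <- nchar(gene$cds_sequence)
  interval_overlap_bp(gene$cds_intervals, m) / len
}

#' Call a gene absent in one accession
#'
#' A gene is called absent when strictly more than half of its CDS lies in
#' the accession's inaccessible regions; exactly half is still called
#' present.
#'
#' @param gene A [gene_model].
#' @param accession An [accession_genome], or a mask data.frame.
#' @return `TRUE` when the gene is absent in this accession.
#' @export
call_absent <- function(gene, accession) {
  mask <- if (inherits(accession, "accession_genome")) accession$mask
          else accession
  inaccessible_fraction(gene, mask) > 0.5
}

# Vectorized masked-CDS fraction for many genes against one mask.
#' @noRd
masked_cds_fraction <- function(genes, mask) {
  tab <- gene_table(genes)
  frac <- numeric(length(genes))
  for (chr in unique(tab$chromosome)) {
    gi <- which(tab$chromosome == chr)
    m <- mask[mask$chrom == chr, , drop = FALSE]
    if (nrow(m) == 0L) next
    exon_gene <- rep(gi, vapply(genes[gi], function(g) nrow(g$cds_intervals), 0L))
    exons <- do.call(rbind, lapply(genes[gi], `[[`, "cds_intervals"))
    ire <- IRanges::IRanges(start = exons$start, end = exons$end)
    irm <- IRanges::reduce(IRanges::IRanges(start = m$start, end = m$end))
    hits <- IRanges::findOverlaps(ire, irm)
    if (length(hits) == 0L) next
    ov <- IRanges::pintersect(ire[S4Vectors::queryHits(hits)],
                              irm[S4Vectors::subjectHits(hits)])
    bp <- tapply(IRanges::width(ov), exon_gene[S4Vectors::queryHits(hits)], sum)
    frac[as.integer(names(bp))] <- as.numeric(bp)
  }
  frac / tab$cds_length
}

#' Build the presence/absence matrix of a cohort
#'
#' Applies [call_absent()] for every gene in every accession. Genes absent in
#' no accession are not P/A genes and are dropped; genes absent in every
#' accession are unreliable (they may reflect reference-specific insertions)
#' and are reported separately rather than kept in the matrix.
#'
#' @param genes List of [gene_model] objects.
#' @param accessions List of [accession_genome] objects (at least 2).
#' @param drop_all_absent Drop genes absent in all accessions from the matrix
#'   and report them in `discarded_all_absent` (default `TRUE`).
#' @return A [pa_matrix] restricted to P/A genes (absent in at least one but,
#'   when `drop_all_absent`, not all accessions).
#' @export
build_pa_matrix <- function(genes, accessions, drop_all_absent = TRUE) {
  if (length(genes) < 1L) stop("need at least one gene")
  if (length(accessions) < 2L) stop("need at least two accessions")
  acc_ids <- vapply(accessions, `[[`, "", "accession_id")
  if (anyDuplicated(acc_ids)) stop("duplicate accession ids")
  gene_ids <- vapply(genes, `[[`, "", "gene_id")

  absent <- vapply(accessions, function(acc) {
    masked_cds_fraction(genes, acc$mask) > 0.5
  }, logical(length(genes)))
  absent <- matrix(absent, nrow = length(genes),
                   dimnames = list(gene_ids, acc_ids))
  n_abs <- rowSums(absent)
  keep <- n_abs >= 1L
  discarded <- character(0)
  if (drop_all_absent) {
    all_absent <- n_abs == length(accessions)
    discarded <- gene_ids[all_absent]
    keep <- keep & !all_absent
  }
  pa_matrix(!absent[keep, , drop = FALSE], discarded_all_absent = discarded)
}

#' Absence-frequency spectrum
#'
#' Number of P/A genes at each absent-allele frequency (the count of
#' accessions a gene is absent in). Counts sum to the number of P/A genes.
#'
#' @param pam A [pa_matrix].
#' @return data.frame with columns `absence_count` and `n_genes`, ascending.
#' @export
absence_spectrum <- function(pam) {
  tab <- table(pam$absence_count)
  data.frame(absence_count = as.integer(names(tab)),
             n_genes = as.integer(tab))
}

#' Per-accession absence summary
#'
#' @param pam A [pa_matrix].
#' @param n_reference_genes Optional total number of reference genes; when
#'   given, the mean absent count is also expressed as a proportion of it.
#' @return List with `per_accession` (data.frame `accession_id`, `n_absent`),
#'   `mean`, `min`, `max` and (when computable) `proportion_of_reference`.
#' @export
per_accession_summary <- function(pam, n_reference_genes = NULL) {
  n_absent <- colSums(!pam$presence)
  out <- list(
    per_accession = data.frame(accession_id = colnames(pam$presence),
                               n_absent = as.integer(n_absent),
                               row.names = NULL),
    mean = mean(n_absent), min = min(n_absent), max = max(n_absent)
  )
  if (!is.null(n_reference_genes)) {
    out$proportion_of_reference <- mean(n_absent) / n_reference_genes
  }
  out
}

# ---- ORF disruption ----------------------------------------------------------

# Plus-strand spliced CDS of a gene (reverse complement of cds_sequence for
# minus-strand genes).
#' @noRd
plus_spliced <- function(gene) {
  if (gene$strand == "-") revcomp(gene$cds_sequence) else gene$cds_sequence
}

# Map genomic positions to 1-based offsets in the plus-strand spliced CDS;
# NA for positions outside the CDS intervals.
#' @noRd
genomic_to_spliced <- function(gene, pos) {
  iv <- gene$cds_intervals
  widths <- iv$end - iv$start + 1L
  before <- c(0L, cumsum(widths))[seq_len(nrow(iv))]
  out <- rep(NA_integer_, length(pos))
  for (e in seq_len(nrow(iv))) {
    inside <- pos >= iv$start[e] & pos <= iv$end[e]
    out[inside] <- before[e] + (pos[inside] - iv$start[e] + 1L)
  }
  out
}

# Inverse of genomic_to_spliced.
#' @noRd
spliced_to_genomic <- function(gene, offset) {
  iv <- gene$cds_intervals
  widths <- iv$end - iv$start + 1L
  before <- c(0L, cumsum(widths))[seq_len(nrow(iv))]
  out <- rep(NA_integer_, length(offset))
  for (e in seq_len(nrow(iv))) {
    inside <- offset > before[e] & offset <= before[e] + widths[e]
    out[inside] <- iv$start[e] + (offset[inside] - before[e] - 1L)
  }
  out
}

#' Call ORF disruption of one gene in one accession
#'
#' Applies the accession's variants to the gene's CDS and reports whether the
#' edited reading frame is disrupted. A frameshift is called when the net
#' inserted-minus-deleted length within the CDS is not a multiple of 3; a
#' premature stop when translation of the edited CDS reaches a stop codon
#' before its final codon. Both can co-occur.
#'
#' Variants are applied in descending coordinate order so earlier positions
#' stay valid. Variants outside the CDS intervals are ignored; a variant
#' whose reference span crosses a CDS interval boundary, overlaps another
#' variant, or mismatches the reference sequence is an error.
#'
#' @param gene A [gene_model].
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (plus-strand, VCF conventions: indels carry an anchor base).
#' @param accession_id Optional accession label carried into the result.
#' @return One-row data.frame: `gene_id`, `accession_id`, `status` (one of
#'   `intact`, `premature_stop`, `frameshift`, `both`), `frameshift`,
#'   `premature_stop`.
#' @export
call_disruption <- function(gene, variants, accession_id = NA_character_) {
  ps <- plus_spliced(gene)
  v <- variants[variants$chrom == gene$chromosome, , drop = FALSE]
  v <- v[!is.na(genomic_to_spliced(gene, v$pos)), , drop = FALSE]

  net <- 0L
  if (nrow(v)) {
    off <- genomic_to_spliced(gene, v$pos)
    span_end <- genomic_to_spliced(gene, v$pos + nchar(v$ref) - 1L)
    if (any(is.na(span_end) |
            span_end - off != nchar(v$ref) - 1L)) {
      stop("gene ", gene$gene_id,
           ": variant reference span crosses a CDS interval boundary")
    }
    o <- order(off)
    off <- off[o]; v <- v[o, , drop = FALSE]
    ends <- off + nchar(v$ref) - 1L
    if (nrow(v) > 1L && any(off[-1L] <= ends[-nrow(v)])) {
      stop("gene ", gene$gene_id, ": overlapping variants within the CDS")
    }
    obs <- substring(ps, off, ends)
    if (any(obs != toupper(v$ref))) {
      bad <- which(obs != toupper(v$ref))[1L]
      stop("gene ", gene$gene_id, ": variant at ", v$pos[bad],
           " reference allele '", v$ref[bad],
           "' does not match the reference sequence ('", obs[bad], "')")
    }
    for (i in rev(seq_len(nrow(v)))) {
      ps <- paste0(substr(ps, 1L, off[i] - 1L), toupper(v$alt[i]),
                   substr(ps, ends[i] + 1L, nchar(ps)))
    }
    net <- sum(nchar(v$alt) - nchar(v$ref))
  }

  frameshift <- (net %% 3L) != 0L
  oriented <- if (gene$strand == "-") revcomp(ps) else ps
  cods <- codons_of(oriented)
  premature <- length(cods) > 1L &&
    any(cods[-length(cods)] %in% STOP_CODONS)
  status <- if (frameshift && premature) "both"
            else if (frameshift) "frameshift"
            else if (premature) "premature_stop"
            else "intact"
  data.frame(gene_id = gene$gene_id, accession_id = accession_id,
             status = status, frameshift = frameshift,
             premature_stop = premature, row.names = NULL)
}
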
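# Readers/writers for the standard formats the pipeline touches, and the
# domain types every downstream module consumes. Internal coordinates are
# 1-based inclusive (GFF convention); BED input is converted on read.

#' Construct a gene model
#'
#' A gene model carries the representative (longest) CDS of one reference
#' gene: its genomic location, exon structure and spliced, strand-oriented
#' coding sequence.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds_intervals Two-column matrix or data.frame of 1-based inclusive
#'   CDS (exon) intervals, columns `start` and `end`. Intervals must be
#'   sorted and non-overlapping.
#' @param cds_sequence Spliced, strand-oriented nucleotide sequence; its
#'   length must equal the summed interval lengths and be at least 3.
#' @param is_te Logical; `TRUE` for transposable-element genes.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, cds_intervals,
                       cds_sequence, is_te = FALSE) {
  cds_intervals <- as.data.frame(cds_intervals)
  names(cds_intervals)[1:2] <- c("start", "end")
  cds_intervals$start <- as.integer(cds_intervals$start)
  cds_intervals$end <- as.integer(cds_intervals$end)
  if (nrow(cds_intervals) == 0L) stop("gene ", gene_id, ": no CDS intervals")
  if (any(cds_intervals$end < cds_intervals$start)) {
    stop("gene ", gene_id, ": interval end < start")
  }
  if (is.unsorted(cds_intervals$start, strictly = TRUE) ||
      any(cds_intervals$start[-1L] <= cds_intervals$end[-nrow(cds_intervals)])) {
    stop("gene ", gene_id, ": CDS intervals must be sorted and non-overlapping")
  }
  if (!strand %in% c("+", "-")) stop("gene ", gene_id, ": bad strand")
  len <- sum(cds_intervals$end - cds_intervals$start + 1L)
  if (nchar(cds_sequence) != len) {
    stop("gene ", gene_id, ": CDS sequence length (", nchar(cds_sequence),
         ") != summed interval length (", len, ")")
  }
  if (len < 3L) stop("gene ", gene_id, ": CDS shorter than 3 bp")
  structure(
    list(gene_id = gene_id, chromosome = chromosome, strand = strand,
         cds_intervals = cds_intervals,
         cds_sequence = toupper(cds_sequence), is_te = isTRUE(is_te)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d exon(s), CDS %d bp\n",
              x$gene_id, x$chromosome, min(x$cds_intervals$start),
              max(x$cds_intervals$end), x$strand, nrow(x$cds_intervals),
              nchar(x$cds_sequence)))
  invisible(x)
}

#' Summarize a list of gene models as a data frame
#'
#' @param genes List of [gene_model] objects.
#' @return data.frame with one row per gene: `gene_id`, `chromosome`,
#'   `strand`, `start`, `end`, `cds_length`, `is_te`.
#' @export
gene_table <- function(genes) {
  data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chromosome = vapply(genes, `[[`, "", "chromosome"),
    strand = vapply(genes, `[[`, "", "strand"),
    start = vapply(genes, function(g) min(g$cds_intervals$start), 0L),
    end = vapply(genes, function(g) max(g$cds_intervals$end), 0L),
    cds_length = vapply(genes, function(g) nchar(g$cds_sequence), 0L),
    is_te = vapply(genes, `[[`, TRUE, "is_te"),
    row.names = NULL
  )
}

#' Construct an accession genome
#'
#' One cohort member: optionally its per-chromosome consensus sequences, the
#' inaccessible-region mask (normalized on construction) and its variants.
#'
#' @param accession_id Accession identifier.
#' @param sequences Named character vector of chromosome sequences, or `NULL`
#'   when only the mask/variants are known.
#' @param mask data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive); merged per chromosome on construction.
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return An object of class `accession_genome`.
#' @export
accession_genome <- function(accession_id, sequences = NULL,
                             mask = empty_mask(), variants = empty_variants()) {
  mask <- normalize_mask(mask)
  if (!is.null(sequences)) {
    bad <- setdiff(unique(mask$chrom), names(sequences))
    if (length(bad)) {
      stop("accession ", accession_id, ": mask on unknown chromosome(s): ",
           paste(bad, collapse = ", "))
    }
    for (chr in unique(mask$chrom)) {
      if (any(mask$end[mask$chrom == chr] > nchar(sequences[[chr]]))) {
        stop("accession ", accession_id, ": mask interval beyond ", chr)
      }
    }
  }
  structure(list(accession_id = accession_id, sequences = sequences,
                 mask = mask, variants = variants),
            class = "accession_genome")
}

#' @noRd
empty_mask <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0))
}

#' @noRd
empty_variants <- function() {
  data.frame(chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0))
}

#' Normalize an inaccessible-region mask
#'
#' Sorts intervals and merges overlapping or book-ended intervals per
#' chromosome.
#'
#' @param mask data.frame with columns `chrom`, `start`, `end`, 1-based
#'   inclusive.
#' @return data.frame of the same shape, normalized.
#' @export
normalize_mask <- function(mask) {
  if (nrow(mask) == 0L) return(empty_mask())
  stopifnot(all(c("chrom", "start", "end") %in% names(mask)))
  out <- lapply(split(mask, mask$chrom), function(m) {
    merged <- merge_intervals(m$start, m$end)
    data.frame(chrom = m$chrom[1L], start = merged$start, end = merged$end)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Read reference gene models from GFF3 + FASTA
#'
#' Parses a GFF3 annotation against its genome and applies the gene-selection
#' rules used throughout the pipeline: for multi-transcript genes only the
#' transcript with the longest summed CDS is kept; transposable-element genes
#' are excluded; genes whose CDS contains any base outside `{A,C,G,T}`
#' (case-insensitively) are excluded.
#'
#' @param gff3_path Path to a GFF3 file with gene/mRNA/CDS features.
#' @param fasta_path Path to the genome FASTA; every chromosome referenced by
#'   a CDS must be present.
#' @param te_patterns Character vector of patterns; a gene whose feature type
#'   or `biotype` attribute matches any of them is flagged as a
#'   transposable-element gene and excluded.
#' @return Named list of [gene_model] objects (names are gene ids), ordered
#'   by chromosome then start coordinate.
#' @export
read_annotation <- function(gff3_path, fasta_path,
                            te_patterns = "transposable_element") {
  lines <- readLines(gff3_path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    stop("malformed GFF3 line ", which(body)[which(nfield != 9L)[1L]],
         " in ", gff3_path, " (expected 9 tab-separated fields)")
  }

  gff <- rtracklayer::readGFF(gff3_path)
  gff <- as.data.frame(gff)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  is_gene <- grepl("gene", gff$type)
  genes_df <- gff[is_gene, , drop = FALSE]
  if (nrow(genes_df) == 0L) stop("no gene features in ", gff3_path)
  te_flag <- Reduce(`|`, lapply(te_patterns, function(p) {
    hit <- grepl(p, genes_df$type)
    for (col in intersect(c("biotype", "gene_biotype"), names(genes_df))) {
      hit <- hit | (!is.na(genes_df[[col]]) & grepl(p, genes_df[[col]]))
    }
    hit
  }))

  parent_of <- function(df) {
    vapply(df$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  }
  mrna <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  mrna_parent <- parent_of(mrna)
  cds_parent <- parent_of(cds)

  out <- list()
  for (i in seq_len(nrow(genes_df))) {
    gid <- genes_df$ID[i]
    if (te_flag[i]) next
    tx_ids <- mrna$ID[mrna_parent == gid]
    if (length(tx_ids) == 0L) tx_ids <- gid  # CDS attached directly to gene
    tx_cds <- lapply(tx_ids, function(tid) {
      rows <- cds[cds_parent == tid, , drop = FALSE]
      rows[order(rows$start), , drop = FALSE]
    })
    lens <- vapply(tx_cds, function(r) {
      if (nrow(r) == 0L) 0L else sum(r$end - r$start + 1L)
    }, 0L)
    if (max(lens) == 0L) next
    best <- tx_cds[[which.max(lens)]]

    chr <- as.character(best$seqid[1L])
    if (!chr %in% names(genome)) {
      stop("gene ", gid, ": CDS references unknown chromosome '", chr, "'")
    }
    pieces <- substring(as.character(genome[[chr]]), best$start, best$end)
    spliced <- toupper(paste(pieces, collapse = ""))
    if (grepl("[^ACGT]", spliced)) next  # ambiguous bases: gene excluded
    strand <- as.character(genes_df$strand[i])
    seq <- if (strand == "-") revcomp(spliced) else spliced
    out[[gid]] <- gene_model(gid, chr, strand,
                             best[, c("start", "end")], seq)
  }
  tab <- gene_table(out)
  out[order(tab$chromosome, tab$start)]
}

#' Read an inaccessible-region mask from BED
#'
#' BED intervals (0-based, half-open) are converted to 1-based inclusive
#' coordinates and merged when overlapping or adjacent.
#'
#' @param bed_path Path to a 3+ column BED file; an empty file yields an
#'   empty mask.
#' @return Normalized mask data.frame (`chrom`, `start`, `end`).
#' @export
read_mask <- function(bed_path) {
  info <- file.info(bed_path)
  if (is.na(info$size)) stop("no such file: ", bed_path)
  if (info$size == 0L) return(empty_mask())
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED file needs >= 3 columns: ", bed_path)
  start0 <- as.integer(bed[[2L]])
  end0 <- as.integer(bed[[3L]])
  if (any(end0 <= start0)) {
    stop("BED interval with end <= start at line ", which(end0 <= start0)[1L])
  }
  normalize_mask(data.frame(chrom = as.character(bed[[1L]]),
                            start = start0 + 1L, end = end0))
}

#' @noRd
write_bed <- function(mask, path) {
  df <- data.frame(mask$chrom, mask$start - 1L, mask$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read variants from a VCF file
#'
#' @param vcf_path Path to a VCF 4.x file.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`; multi-allelic
#'   records are expanded to one row per alternate allele.
#' @export
read_variants <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_variants())
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(fix)), lengths(alts))
  data.frame(chrom = fix$CHROM[idx], pos = as.integer(fix$POS[idx]),
             ref = fix$REF[idx], alt = unlist(alts))
}

#' @noRd
write_vcf <- function(variants, path, reference_name = "reference") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##reference=", reference_name),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", variants$chrom,
                       variants$pos, variants$ref, variants$alt), con)
  }
  invisible(path)
}

# ---- presence/absence matrix -------------------------------------------------

#' Construct a presence/absence matrix
#'
#' @param presence Logical matrix, genes in rows, accessions in columns, with
#'   dimnames; `TRUE` = present.
#' @param discarded_all_absent Character vector of gene ids that were absent
#'   in every accession and therefore excluded from the matrix.
#' @return Object of class `pa_matrix` with elements `presence`,
#'   `absence_count` (named integer, per gene) and `discarded_all_absent`.
#' @export
pa_matrix <- function(presence, discarded_all_absent = character(0)) {
  stopifnot(is.matrix(presence), is.logical(presence),
            !is.null(rownames(presence)), !is.null(colnames(presence)))
  if (anyDuplicated(rownames(presence))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(presence))) stop("duplicate accession ids")
  counts <- rowSums(!presence)
  storage.mode(counts) <- "integer"
  structure(list(presence = presence,
                 absence_count = counts,
                 discarded_all_absent = discarded_all_absent),
            class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("<pa_matrix> %d P/A genes x %d accessions (%d all-absent genes discarded)\n",
              nrow(x$presence), ncol(x$presence),
              length(x$discarded_all_absent)))
  invisible(x)
}

#' Write / read a presence/absence matrix as TSV
#'
#' The TSV has a header row of accession ids (first column `gene_id`), one
#' row per gene, and cells `1` (present) / `0` (absent). `read_pa_matrix()`
#' is the exact inverse of `write_pa_matrix()`.
#'
#' @param pam A [pa_matrix].
#' @param path Output (or input) TSV path.
#' @return `write_pa_matrix()` returns `path` invisibly; `read_pa_matrix()`
#'   returns a [pa_matrix].
#' @export
write_pa_matrix <- function(pam, path) {
  stopifnot(inherits(pam, "pa_matrix"))
  df <- data.frame(gene_id = rownames(pam$presence),
                   ifelse(pam$presence, 1L, 0L), check.names = FALSE)
  colnames(df) <- c("gene_id", colnames(pam$presence))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pa_matrix
#' @export
read_pa_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in ", path)
  cells <- as.matrix(df[, -1L, drop = FALSE])
  if (!all(cells %in% c(0L, 1L))) stop("P/A matrix cells must be 0 or 1")
  presence <- cells == 1L
  rownames(presence) <- df$gene_id
  pa_matrix(presence)
}

# ---- Newick ------------------------------------------------------------------

#' Serialize a tree to a Newick string or file
#'
#' Leaf labels containing whitespace are single-quoted. Branch lengths are
#' written with 12 significant digits.
#'
#' @param tree An `ape` `phylo` object; every tip must be labelled.
#' @param path Output file path.
#' @return `newick_string()` returns the Newick string; `write_newick()`
#'   writes it to `path` and returns `path` invisibly.
#' @export
newick_string <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (any(is.na(labs) | !nzchar(labs))) stop("tree has an unlabeled leaf")
  quote_lab <- function(x) {
    ifelse(grepl("\\s", x), paste0("'", x, "'"), x)
  }
  ntip <- length(labs)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt_len <- function(i) {
    if (is.null(tree$edge.length)) "" else
      sprintf(":%.12g", tree$edge.length[i])
  }
  build <- function(node) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) return(quote_lab(labs[node]))
    parts <- vapply(rows, function(i) {
      paste0(build(tree$edge[i, 2L]), fmt_len(i))
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(build(ntip + 1L), ";")
}

#' @rdname newick_string
#' @export
write_newick <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(path)
}

#' @noRd
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

# GFF3 writer for gene models (one mRNA per gene); TE genes are written with
# feature type "transposable_element_gene".
#' @noRd
write_gff3 <- function(genes, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", names(chrom_lengths),
                     as.integer(chrom_lengths)), con)
  for (g in genes) {
    gstart <- min(g$cds_intervals$start)
    gend <- max(g$cds_intervals$end)
    gtype <- if (g$is_te) "transposable_element_gene" else "gene"
    tid <- paste0(g$gene_id, ".1")
    writeLines(c(
      sprintf("%s\tpavscape\t%s\t%d\t%d\t.\t%s\t.\tID=%s", g$chromosome,
              gtype, gstart, gend, g$strand, g$gene_id),
      sprintf("%s\tpavscape\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chromosome, gstart, gend, g$strand, tid, g$gene_id),
      sprintf("%s\tpavscape\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s", g$chromosome,
              g$cds_intervals$start, g$cds_intervals$end, g$strand, tid)
    ), con)
  }
  invisible(path)
}
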
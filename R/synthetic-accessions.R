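# Accession-level synthesis: deletion masks from the configured absence
# spectrum, present-allele sequences whose diversity tracks the configured
# law, ORF-disrupting variants, and the truth tables tying it all together.

# Per-site substitution probability giving expected pairwise diversity pi
# under independent per-allele mutation to one fixed alternative base:
# P(two alleles differ at a site) = 2 p (1 - p) = pi.
#' @noRd
pi_to_rate <- function(pi) {
  (1 - sqrt(pmax(0, 1 - 2 * pi))) / 2
}

# Mutate a reference ORF (character vector) at per-site rate p towards the
# per-site alternative bases alt; internal stop codons created by the
# mutations are reverted to the reference codon so reading frames stay
# clean for disruption calling.
#' @noRd
mutate_allele <- function(ref_chars, alt, p) {
  x <- ref_chars
  hit <- which(stats::runif(length(x)) < p)
  x[hit] <- alt[hit]
  n_cod <- length(x) %/% 3L
  if (n_cod > 2L && length(hit)) {
    for (ci in unique((hit - 1L) %/% 3L + 1L)) {
      if (ci > 1L && ci < n_cod) {
        s <- (ci - 1L) * 3L + 1L
        if (chars_to_seq(x[s:(s + 2L)]) %in% STOP_CODONS) {
          x[s:(s + 2L)] <- ref_chars[s:(s + 2L)]
        }
      }
    }
  }
  x
}

#' @noRd
comp_chars <- function(x) chartr("ACGT", "TGCA", x)

# Substitution variants (plus-strand, genomic coordinates) implied by an
# allele that differs from the reference CDS at substitution sites only.
# Alleles are CDS-oriented; positions/bases are mapped through the gene's
# exon structure and strand.
#' @noRd
variants_from_allele <- function(gene, allele_chars, ref_chars) {
  q <- which(allele_chars != ref_chars)
  if (length(q) == 0L) return(empty_variants())
  L <- length(ref_chars)
  if (gene$strand == "-") {
    o <- L - q + 1L
    ref <- comp_chars(ref_chars[q])
    alt <- comp_chars(allele_chars[q])
  } else {
    o <- q
    ref <- ref_chars[q]
    alt <- allele_chars[q]
  }
  pos <- spliced_to_genomic(gene, o)
  ord <- order(pos)
  data.frame(chrom = gene$chromosome, pos = pos[ord],
             ref = ref[ord], alt = alt[ord])
}

# A single-base substitution turning one internal codon of the ORF into a
# stop codon; returns the edited character vector.
#' @noRd
plant_premature_stop <- function(ref_chars) {
  n_cod <- length(ref_chars) %/% 3L
  lo <- 5L
  hi <- n_cod - 4L
  cands <- list()
  for (ci in lo:hi) {
    s <- (ci - 1L) * 3L + 1L
    cod <- ref_chars[s:(s + 2L)]
    two <- paste0(cod[1L], cod[2L])
    tail2 <- paste0(cod[2L], cod[3L])
    if (two %in% c("TA", "TG") && cod[3L] != "A") {
      cands[[length(cands) + 1L]] <- c(s + 2L, "A")
    } else if (tail2 %in% c("AA", "AG", "GA") && cod[1L] != "T") {
      cands[[length(cands) + 1L]] <- c(s, "T")
    }
  }
  if (length(cands) == 0L) stop("no codon mutable to a stop")
  pick <- cands[[sample.int(length(cands), 1L)]]
  x <- ref_chars
  x[as.integer(pick[1L])] <- pick[2L]
  x
}

# A 1-bp deletion variant (VCF anchor convention, plus-strand genomic) in
# the interior of one of the gene's exons.
#' @noRd
plant_frameshift <- function(gene) {
  iv <- gene$cds_intervals
  widths <- iv$end - iv$start + 1L
  e <- which(widths >= 10L)[1L]
  if (is.na(e)) stop("gene ", gene$gene_id, ": no exon wide enough")
  before <- c(0L, cumsum(widths))[e]
  o <- before + widths[e] %/% 2L  # plus-spliced offset, exon interior
  ps <- plus_spliced(gene)
  pos <- spliced_to_genomic(gene, o - 1L)
  data.frame(chrom = gene$chromosome, pos = pos,
             ref = substr(ps, o - 1L, o), alt = substr(ps, o - 1L, o - 1L))
}

#' Generate a full synthetic cohort with truth tables
#'
#' On top of [simulate_reference()], schedules each spectrum-assigned gene
#' for absence in a uniformly drawn accession subset (optionally weighted
#' towards centromere-proximal genes), masks the full CDS of absent genes,
#' plants present-allele SNPs so realized diversity tracks the diversity
#' law, plants background SNPs on non-P/A genes, plants ORF-disrupting
#' variants, and assigns functional categories including one P/A-enriched
#' category. Deterministic given the config seed.
#'
#' @param config A [cohort_config].
#' @return List of class `pav_cohort` with elements `config`, `reference`
#'   (see [simulate_reference()]), `accessions` (named list of
#'   [accession_genome]: masks and variants), `alleles` (per P/A gene, the
#'   present-allele sequences, CDS-oriented, named by accession),
#'   `background_alleles` (per background gene, one allele per accession)
#'   and `truth` (presence matrix, spectrum, families, clusters, per-locus
#'   diversity targets, disruptions, categories, enriched category,
#'   centromeres).
#' @export
simulate_cohort <- function(config) {
  cfg <- config
  ref <- simulate_reference(cfg)
  set.seed(derive_seed(cfg$seed, 2L))
  n_acc <- cfg$n_accessions
  acc_ids <- sprintf("acc%02d", seq_len(n_acc))
  genes <- ref$genes
  gene_ids <- names(genes)
  gt <- gene_table(genes)

  # --- schedule deletions from the spectrum ---
  spectrum <- cfg$spectrum
  n_pa <- sum(spectrum$n_genes)
  weights <- rep(1, length(genes))
  if (isTRUE(cfg$centromere_enrichment)) {
    cen <- ref$centromeres[match(gt$chromosome, ref$centromeres$chrom), ]
    near <- gt$start >= cen$start - cfg$centromere_margin &
      gt$start <= cen$end + cfg$centromere_margin
    weights[near] <- cfg$centromere_weight
  }
  pa_ids <- sample(gene_ids, n_pa, prob = weights)
  m_of <- stats::setNames(sample(rep(spectrum$absence_count,
                                     spectrum$n_genes)), pa_ids)

  presence <- matrix(TRUE, nrow = n_pa, ncol = n_acc,
                     dimnames = list(pa_ids, acc_ids))
  for (gid in pa_ids) {
    presence[gid, sample.int(n_acc, m_of[[gid]])] <- FALSE
  }
  # keep truth rows in reference gene order
  pa_ids <- gene_ids[gene_ids %in% pa_ids]
  presence <- presence[pa_ids, , drop = FALSE]

  # --- masks: the full CDS of every absent gene ---
  mask_rows <- lapply(acc_ids, function(a) {
    absent <- pa_ids[!presence[, a]]
    if (length(absent) == 0L) return(empty_mask())
    do.call(rbind, lapply(genes[absent], function(g) {
      data.frame(chrom = g$chromosome, start = g$cds_intervals$start,
                 end = g$cds_intervals$end)
    }))
  })
  names(mask_rows) <- acc_ids

  # --- present-allele SNPs following the diversity law ---
  law <- cfg$diversity_law
  pi_of <- function(f) law[1L] + law[2L] * f + law[3L] * f^2
  variant_acc <- stats::setNames(vector("list", n_acc), acc_ids)
  add_variants <- function(acc, gene, vdf) {
    if (nrow(vdf)) {
      vdf$gene_id <- gene$gene_id
      variant_acc[[acc]][[length(variant_acc[[acc]]) + 1L]] <<- vdf
    }
  }
  make_alleles <- function(gid, accs, pi_target) {
    g <- genes[[gid]]
    ref_chars <- seq_to_chars(g$cds_sequence)
    alt <- vapply(ref_chars, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    p <- pi_to_rate(pi_target)
    out <- stats::setNames(character(length(accs)), accs)
    for (a in accs) {
      x <- mutate_allele(ref_chars, alt, p)
      add_variants(a, g, variants_from_allele(g, x, ref_chars))
      out[[a]] <- chars_to_seq(x)
    }
    out
  }
  pi_target <- stats::setNames(pi_of(m_of[pa_ids] / n_acc), pa_ids)
  alleles <- stats::setNames(lapply(pa_ids, function(gid) {
    make_alleles(gid, acc_ids[presence[gid, ]], pi_target[[gid]])
  }), pa_ids)

  # --- background SNP genes (accession-tree input) ---
  non_pa <- setdiff(gene_ids, pa_ids)
  bg_ids <- sample(non_pa, min(cfg$n_background_genes, length(non_pa)))
  background_alleles <- stats::setNames(lapply(bg_ids, function(gid) {
    make_alleles(gid, acc_ids, cfg$background_pi)
  }), bg_ids)

  # --- planted ORF disruptions on untouched non-P/A genes ---
  dp <- cfg$disruption_plan
  n_dis <- dp$n_premature_stop + dp$n_frameshift
  eligible <- setdiff(non_pa, bg_ids)
  if (length(eligible) < n_dis) stop("not enough genes for the disruption plan")
  dis_ids <- sample(eligible, n_dis)
  dis_kind <- rep(c("premature_stop", "frameshift"),
                  c(dp$n_premature_stop, dp$n_frameshift))
  dis_acc <- sample(acc_ids, n_dis, replace = TRUE)
  for (i in seq_len(n_dis)) {
    g <- genes[[dis_ids[i]]]
    if (dis_kind[i] == "premature_stop") {
      ref_chars <- seq_to_chars(g$cds_sequence)
      edited <- plant_premature_stop(ref_chars)
      add_variants(dis_acc[i], g, variants_from_allele(g, edited, ref_chars))
    } else {
      vdf <- plant_frameshift(g)
      add_variants(dis_acc[i], g, vdf)
    }
  }
  disruptions <- data.frame(gene_id = dis_ids, accession_id = dis_acc,
                            kind = dis_kind, row.names = NULL)

  # --- functional categories with one planted P/A-enriched category ---
  enr_members <- c(sample(pa_ids, min(cfg$enriched_pa, length(pa_ids))),
                   sample(non_pa, cfg$enriched_size -
                            min(cfg$enriched_pa, length(pa_ids))))
  rest <- setdiff(gene_ids, enr_members)
  categories <- rbind(
    data.frame(gene_id = enr_members, category = cfg$enriched_category),
    data.frame(gene_id = rest,
               category = sample(cfg$categories, length(rest),
                                 replace = TRUE))
  )

  accessions <- stats::setNames(lapply(acc_ids, function(a) {
    v <- if (length(variant_acc[[a]])) {
      do.call(rbind, variant_acc[[a]])
    } else {
      cbind(empty_variants(), data.frame(gene_id = character(0)))
    }
    v <- v[order(v$chrom, v$pos), , drop = FALSE]
    rownames(v) <- NULL
    accession_genome(a, sequences = NULL, mask = mask_rows[[a]], variants = v)
  }), acc_ids)

  structure(list(
    config = cfg, reference = ref, accessions = accessions,
    alleles = alleles, background_alleles = background_alleles,
    truth = list(presence = presence, spectrum = spectrum,
                 families = ref$families, clusters = ref$clusters,
                 pi_target = pi_target, disruptions = disruptions,
                 categories = categories,
                 enriched_category = cfg$enriched_category,
                 centromeres = ref$centromeres,
                 background_genes = bg_ids)
  ), class = "pav_cohort")
}

#' @export
print.pav_cohort <- function(x, ...) {
  cat(sprintf("<pav_cohort> %d genes, %d accessions, %d P/A genes, seed %d\n",
              length(x$reference$genes), length(x$accessions),
              nrow(x$truth$presence), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to standard-format files
#'
#' Emits the reference (FASTA + GFF3, decoy genes included), per-accession
#' masks (BED) and variants (VCF), and the truth tables (TSV).
#'
#' @param cohort A `pav_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- cohort$reference
  write_genome_fasta(ref$genome, file.path(dir, "reference.fa"))
  write_gff3(c(ref$genes, ref$decoys), ref$chrom_lengths,
             file.path(dir, "annotation.gff3"))
  utils::write.table(ref$centromeres, file.path(dir, "centromeres.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  acc_dir <- file.path(dir, "accessions")
  dir.create(acc_dir, showWarnings = FALSE)
  for (a in names(cohort$accessions)) {
    acc <- cohort$accessions[[a]]
    write_bed(acc$mask, file.path(acc_dir, paste0(a, ".mask.bed")))
    write_vcf(acc$variants[, c("chrom", "pos", "ref", "alt")],
              file.path(acc_dir, paste0(a, ".vcf")))
  }
  write_pa_matrix(pa_matrix(cohort$truth$presence),
                  file.path(dir, "truth_pa_matrix.tsv"))
  utils::write.table(cohort$truth$categories,
                     file.path(dir, "categories.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
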
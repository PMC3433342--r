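# Synthetic-cohort generator: a multi-chromosome annotated reference with
# planted gene families and tandem clusters, per-accession deletion masks
# drawn from a configured absence-frequency spectrum, allele sequences whose
# diversity follows a configured function of absence frequency, and
# ORF-disrupting variants -- all with truth tables for downstream recovery
# tests.

#' Cohort configuration
#'
#' Collects every tunable of the synthetic cohort with desk-scale defaults:
#' 2 chromosomes of 2 Mb, 400 genes, 20 accessions, a geometric-decay
#' absence spectrum, and a quadratic diversity law peaking at absence
#' frequency 0.5.
#'
#' @param n_chromosomes,chromosome_length,n_genes,n_accessions Cohort shape.
#' @param orf_codon_range Range (codons) of gene ORF lengths.
#' @param intron_length_range,max_exons Exon/intron structure of genes.
#' @param family_plan List `n_families`, `size`, `divergence`: multi-copy
#'   families planted by mutating a seed ORF.
#' @param cluster_plan List `n_clusters`, `max_intervening`: how many
#'   families are laid out as tandem clusters and the largest number of
#'   intervening genes between consecutive members.
#' @param centromere_fraction Central fraction of each chromosome treated as
#'   centromere.
#' @param centromere_density Relative gene density inside the centromere.
#' @param spectrum data.frame `absence_count`, `n_genes`; default geometric
#'   decay `round(40 * 0.8^(m-1))` over `m = 1 .. n_accessions - 1`.
#'   `absence_count` must stay below `n_accessions` (genes absent everywhere
#'   are not generated) and the counts must not exceed `n_genes` in total.
#' @param centromere_enrichment,centromere_weight,centromere_margin Deleted
#'   genes are sampled with `centromere_weight`-fold preference within
#'   `centromere_margin` bp of a centromere when enrichment is on.
#' @param diversity_law Coefficients `(c0, c1, c2)` of
#'   `pi(f) = c0 + c1 f + c2 f^2`, the target present-allele diversity at
#'   absence frequency `f`; must be non-negative over `[0, 1]`.
#' @param background_pi,n_background_genes Diversity and count of non-P/A
#'   genes carrying SNPs (input for the SNP accession tree).
#' @param disruption_plan List `n_premature_stop`, `n_frameshift`: variants
#'   planted in present alleles of non-P/A genes.
#' @param n_te_decoys,n_ambiguous_decoys Transposable-element genes and
#'   ambiguous-base genes written to the annotation; the annotation reader
#'   must exclude them.
#' @param categories,enriched_category,enriched_size,enriched_pa Functional
#'   category layout: one planted P/A-enriched category plus uniform
#'   background categories.
#' @param n_bins Frequency bins used by the pipeline's covariation stage.
#' @param window_size Chromosome window width (bp) for the distribution
#'   stage; the desk-scale default of 200 kb keeps enough windows per 2 Mb
#'   chromosome for a rank-correlation summary.
#' @param rarefaction_reps Replicates for the pipeline's rarefaction stage.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_chromosomes = 2L, chromosome_length = 2e6,
                          n_genes = 400L, n_accessions = 20L,
                          orf_codon_range = c(100L, 500L),
                          intron_length_range = c(80L, 300L),
                          max_exons = 3L,
                          family_plan = list(n_families = 25L, size = 4L,
                                             divergence = 0.1),
                          cluster_plan = list(n_clusters = 10L,
                                              max_intervening = 2L),
                          centromere_fraction = 0.2,
                          centromere_density = 0.25,
                          spectrum = NULL,
                          centromere_enrichment = TRUE,
                          centromere_weight = 6,
                          centromere_margin = 1e5,
                          diversity_law = c(0, 0.04, -0.04),
                          background_pi = 0.005,
                          n_background_genes = 50L,
                          disruption_plan = list(n_premature_stop = 10L,
                                                 n_frameshift = 10L),
                          n_te_decoys = 4L, n_ambiguous_decoys = 2L,
                          categories = c("membrane", "binding",
                                         "metabolism", "transport"),
                          enriched_category = "stress_response",
                          enriched_size = 30L, enriched_pa = 28L,
                          n_bins = 13L,
                          window_size = 2e5,
                          rarefaction_reps = 10000L,
                          seed = 1L) {
  if (is.null(spectrum)) {
    m <- seq_len(n_accessions - 1L)
    cnt <- round(40 * 0.8^(m - 1L))
    spectrum <- data.frame(absence_count = m[cnt > 0L],
                           n_genes = cnt[cnt > 0L])
  }
  if (any(spectrum$absence_count >= n_accessions)) {
    stop("spectrum includes genes absent in all accessions; disallowed")
  }
  if (sum(spectrum$n_genes) > n_genes) {
    stop("spectrum schedules more deletions than there are genes")
  }
  fgrid <- seq(0, 1, by = 0.01)
  law <- diversity_law[1L] + diversity_law[2L] * fgrid +
    diversity_law[3L] * fgrid^2
  if (any(law < -1e-12)) stop("diversity law negative on [0, 1]")
  structure(mget(names(formals(cohort_config))), class = "cohort_config")
}

#' Read a cohort configuration from YAML
#'
#' Scalar fields map directly onto [cohort_config()] arguments; list-valued
#' fields (`family_plan`, `cluster_plan`, `disruption_plan`, `spectrum`)
#' use the same element names.
#'
#' @param path YAML file path.
#' @return A `cohort_config`.
#' @export
read_pav_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$spectrum)) cfg$spectrum <- as.data.frame(cfg$spectrum)
  if (!is.null(cfg$diversity_law)) {
    cfg$diversity_law <- as.numeric(cfg$diversity_law)
  }
  do.call(cohort_config, cfg)
}

# ---- reference genome --------------------------------------------------------

# Gene start positions along [lo, hi] with depressed density inside the
# centromere: inverse-CDF placement on a piecewise-constant density plus
# jitter, so genes stay comfortably non-overlapping.
#' @noRd
slot_positions <- function(lo, hi, cen_start, cen_end, density, n) {
  segs <- rbind(c(lo, cen_start - 1, 1),
                c(cen_start, cen_end, density),
                c(cen_end + 1, hi, 1))
  segs <- segs[segs[, 2L] >= segs[, 1L], , drop = FALSE]
  w <- (segs[, 2L] - segs[, 1L] + 1) * segs[, 3L]
  cumw <- c(0, cumsum(w))
  targets <- (seq_len(n) - 0.5) / n * sum(w)
  pos <- vapply(targets, function(t) {
    s <- findInterval(t, cumw, rightmost.closed = TRUE)
    s <- min(s, nrow(segs))
    segs[s, 1L] + (t - cumw[s]) / segs[s, 3L]
  }, 0)
  sort(round(pos + stats::runif(n, -1500, 1500)))
}

# Substitute a fraction of positions (keeping start/stop codons) and repair
# any in-frame stop codons the mutations created.
#' @noRd
mutate_orf <- function(orf, rate) {
  x <- seq_to_chars(orf)
  L <- length(x)
  eligible <- 4:(L - 3L)
  hit <- eligible[stats::runif(length(eligible)) < rate]
  for (p in hit) {
    x[p] <- sample(setdiff(DNA_BASES, x[p]), 1L)
  }
  fix_internal_stops(x)
}

# Replace the third base of any internal stop codon with C.
#' @noRd
fix_internal_stops <- function(x) {
  n_cod <- length(x) %/% 3L
  if (n_cod > 2L) {
    for (ci in 2:(n_cod - 1L)) {
      s <- (ci - 1L) * 3L + 1L
      if (chars_to_seq(x[s:(s + 2L)]) %in% STOP_CODONS) x[s + 2L] <- "C"
    }
  }
  chars_to_seq(x)
}

# Exon intervals for a CDS of len bp starting at gstart.
#' @noRd
exon_layout <- function(gstart, len, n_exons, intron_range) {
  if (n_exons == 1L) {
    return(data.frame(start = gstart, end = gstart + len - 1L))
  }
  cuts <- sort(sample(seq(30L, len - 30L), n_exons - 1L))
  widths <- diff(c(0L, cuts, len))
  introns <- sample(seq(intron_range[1L], intron_range[2L]), n_exons - 1L,
                    replace = TRUE)
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  pos <- gstart
  for (e in seq_len(n_exons)) {
    starts[e] <- pos
    ends[e] <- pos + widths[e] - 1L
    pos <- ends[e] + 1L + if (e < n_exons) introns[e] else 0L
  }
  data.frame(start = starts, end = ends)
}

#' Generate the synthetic reference genome and annotation
#'
#' Places genes along each chromosome with depressed density inside the
#' centromere, plants multi-copy families (members mutated from a family
#' seed ORF to the configured divergence) and tandem clusters, and writes
#' each gene's ORF into the chromosome sequence respecting strand and exon
#' structure. Deterministic given the config seed.
#'
#' @param config A [cohort_config].
#' @return List with `genes` (named list of [gene_model], ordered by
#'   chromosome and start), `decoys` (TE and ambiguous-base gene models),
#'   `genome` (named character vector), `centromeres` (data.frame),
#'   `families` (named list of member-id vectors), `clusters` (list of
#'   planted tandem clusters with `family_id`, `chromosome`, `members`),
#'   and `ranks` (gene order index).
#' @export
simulate_reference <- function(config) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, 1L))
  n_chr <- cfg$n_chromosomes
  chr_names <- sprintf("chr%d", seq_len(n_chr))
  chr_len <- stats::setNames(rep(cfg$chromosome_length, n_chr), chr_names)
  cen_half <- cfg$centromere_fraction * cfg$chromosome_length / 2
  centromeres <- data.frame(
    chrom = chr_names,
    start = as.integer(round(cfg$chromosome_length / 2 - cen_half)),
    end = as.integer(round(cfg$chromosome_length / 2 + cen_half))
  )

  per_chr <- diff(round(seq(0, cfg$n_genes, length.out = n_chr + 1L)))
  starts <- vector("list", n_chr)
  for (ci in seq_len(n_chr)) {
    starts[[ci]] <- slot_positions(10001, chr_len[ci] - 3000,
                                   centromeres$start[ci], centromeres$end[ci],
                                   cfg$centromere_density, per_chr[ci])
  }

  # --- assign family members and singletons to chromosome ranks ---
  fp <- cfg$family_plan
  cp <- cfg$cluster_plan
  n_fam_genes <- fp$n_families * fp$size
  if (n_fam_genes > cfg$n_genes) stop("family plan exceeds gene count")
  if (cp$n_clusters > fp$n_families) stop("more clusters than families")
  slot_owner <- lapply(per_chr, function(n) character(n))
  clusters <- list()
  fam_members <- list()
  occupied <- lapply(per_chr, function(n) logical(n))
  gid_counter <- 0L
  next_gid <- function() {
    gid_counter <<- gid_counter + 1L
    sprintf("g%04d", gid_counter)
  }
  place <- function(ci, rank, gid) {
    slot_owner[[ci]][rank] <<- gid
    occupied[[ci]][rank] <<- TRUE
  }
  for (fi in seq_len(fp$n_families)) {
    fam_id <- sprintf("fam_truth%03d", fi)
    ids <- replicate(fp$size, next_gid())
    fam_members[[fam_id]] <- ids
    if (fi <= cp$n_clusters) {
      # tandem cluster: consecutive ranks with small intervening gaps
      repeat {
        ci <- sample.int(n_chr, 1L)
        gaps <- sample(0:cp$max_intervening, fp$size - 1L, replace = TRUE)
        span <- fp$size + sum(gaps)
        r0 <- sample.int(per_chr[ci] - span, 1L)
        ranks <- r0 + cumsum(c(0L, gaps + 1L))
        if (!any(occupied[[ci]][ranks])) break
      }
      for (s in seq_along(ids)) place(ci, ranks[s], ids[s])
      clusters[[length(clusters) + 1L]] <- list(
        family_id = fam_id, chromosome = chr_names[ci], members = ids)
    } else {
      # scattered family: members at least max_gap + 2 ranks apart
      repeat {
        picks <- lapply(ids, function(id) {
          ci <- sample.int(n_chr, 1L)
          c(ci, sample.int(per_chr[ci], 1L))
        })
        mat <- do.call(rbind, picks)
        ok <- !any(occupied_at(occupied, mat)) &&
          !anyDuplicated(paste(mat[, 1L], mat[, 2L]))
        if (ok) {
          for (ci in unique(mat[, 1L])) {
            r <- sort(mat[mat[, 1L] == ci, 2L])
            if (length(r) > 1L && min(diff(r)) < 10L) ok <- FALSE
          }
        }
        if (ok) break
      }
      for (s in seq_along(ids)) place(mat[s, 1L], mat[s, 2L], ids[s])
    }
  }
  for (ci in seq_len(n_chr)) {
    free <- which(!occupied[[ci]])
    for (r in free) place(ci, r, next_gid())
  }

  # --- sequences ---
  orf_len <- function() sample(seq(cfg$orf_codon_range[1L],
                                   cfg$orf_codon_range[2L]), 1L) * 3L
  seqs <- list()
  for (fam_id in names(fam_members)) {
    seed_orf <- random_orf(orf_len() / 3L)
    for (id in fam_members[[fam_id]]) {
      seqs[[id]] <- mutate_orf(seed_orf, fp$divergence)
    }
  }
  all_ids <- unlist(slot_owner, use.names = FALSE)
  for (id in setdiff(all_ids, names(seqs))) {
    seqs[[id]] <- random_orf(orf_len() / 3L)
  }

  # --- genome assembly ---
  genome_chars <- lapply(chr_len, function(L) {
    sample(DNA_BASES, L, replace = TRUE)
  })
  genes <- list()
  for (ci in seq_len(n_chr)) {
    for (r in seq_len(per_chr[ci])) {
      gid <- slot_owner[[ci]][r]
      orf <- seqs[[gid]]
      strand <- sample(c("+", "-"), 1L)
      n_exons <- sample.int(cfg$max_exons, 1L)
      iv <- exon_layout(starts[[ci]][r], nchar(orf), n_exons,
                        cfg$intron_length_range)
      if (max(iv$end) > chr_len[ci]) stop("genes do not fit the chromosome")
      if (r < per_chr[ci] && max(iv$end) >= starts[[ci]][r + 1L]) {
        stop("genes do not fit the chromosome (overlap at rank ", r, ")")
      }
      plus <- if (strand == "-") revcomp(orf) else orf
      plus_chars <- seq_to_chars(plus)
      offset <- 0L
      for (e in seq_len(nrow(iv))) {
        w <- iv$end[e] - iv$start[e] + 1L
        genome_chars[[ci]][iv$start[e]:iv$end[e]] <-
          plus_chars[(offset + 1L):(offset + w)]
        offset <- offset + w
      }
      genes[[gid]] <- gene_model(gid, chr_names[ci], strand, iv, orf)
    }
  }

  # --- decoys: TE genes and ambiguous-base genes in the reserved head ---
  decoys <- list()
  te_per_chr <- distribute_count(cfg$n_te_decoys, n_chr)
  amb_per_chr <- distribute_count(cfg$n_ambiguous_decoys, n_chr)
  for (ci in seq_len(n_chr)) {
    at <- 1000L
    for (i in seq_len(te_per_chr[ci])) {
      orf <- random_orf(60L)
      id <- sprintf("te_%d_%d", ci, i)
      genome_chars[[ci]][at:(at + nchar(orf) - 1L)] <- seq_to_chars(orf)
      decoys[[id]] <- gene_model(id, chr_names[ci], "+",
                                 data.frame(start = at,
                                            end = at + nchar(orf) - 1L),
                                 orf, is_te = TRUE)
      at <- at + nchar(orf) + 500L
    }
    for (i in seq_len(amb_per_chr[ci])) {
      orf <- random_orf(60L)
      x <- seq_to_chars(orf)
      x[sample(10:(length(x) - 10L), 5L)] <- "N"
      id <- sprintf("amb_%d_%d", ci, i)
      genome_chars[[ci]][at:(at + length(x) - 1L)] <- x
      decoys[[id]] <- gene_model(id, chr_names[ci], "+",
                                 data.frame(start = at,
                                            end = at + length(x) - 1L),
                                 chars_to_seq(x))
      at <- at + length(x) + 500L
    }
  }

  genome <- vapply(genome_chars, chars_to_seq, "")
  names(genome) <- chr_names
  genes <- genes[order(gene_table(genes)$chromosome,
                       gene_table(genes)$start)]
  list(genes = genes, decoys = decoys, genome = genome,
       chrom_lengths = chr_len, centromeres = centromeres,
       families = fam_members, clusters = clusters,
       ranks = gene_ranks(genes))
}

#' @noRd
occupied_at <- function(occupied, mat) {
  vapply(seq_len(nrow(mat)), function(i) {
    occupied[[mat[i, 1L]]][mat[i, 2L]]
  }, TRUE)
}

#' @noRd
distribute_count <- function(total, n) {
  base <- total %/% n
  extra <- total %% n
  base + (seq_len(n) <= extra)
}
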
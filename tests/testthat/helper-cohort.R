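# Shared fixtures. The default synthetic cohort and its full pipeline run
# are expensive, so they are built lazily once per test session.

.fixtures <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- simulate_cohort(cohort_config(seed = 1L))
  }
  .fixtures$cohort
}

default_pipeline <- function() {
  if (is.null(.fixtures$pipeline)) {
    .fixtures$pipeline <- run_pav_pipeline(cohort = default_cohort())
  }
  .fixtures$pipeline
}

# A tiny configuration that still exercises every pipeline stage.
small_config <- function(seed = 7L) {
  cohort_config(
    n_chromosomes = 2L, chromosome_length = 6e5, n_genes = 80L,
    n_accessions = 8L,
    family_plan = list(n_families = 4L, size = 3L, divergence = 0.1),
    cluster_plan = list(n_clusters = 2L, max_intervening = 1L),
    spectrum = data.frame(absence_count = c(1L, 2L, 3L, 5L),
                          n_genes = c(10L, 6L, 4L, 4L)),
    n_background_genes = 10L,
    disruption_plan = list(n_premature_stop = 2L, n_frameshift = 2L),
    enriched_size = 8L, enriched_pa = 7L,
    n_bins = 4L, window_size = 1e5, rarefaction_reps = 500L,
    seed = seed
  )
}

# Build a pa_matrix from per-gene absence counts: gene g is absent in the
# first m_g accessions after a fixed per-gene rotation, giving arbitrary
# but deterministic membership.
pam_from_counts <- function(m, n_acc, rotate = TRUE) {
  n_genes <- length(m)
  presence <- matrix(TRUE, n_genes, n_acc,
                     dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                     sprintf("a%02d", seq_len(n_acc))))
  for (g in seq_len(n_genes)) {
    cols <- ((if (rotate) g - 1L else 0L) + seq_len(m[g]) - 1L) %% n_acc + 1L
    presence[g, cols] <- FALSE
  }
  pa_matrix(presence)
}

random_pam <- function(n_genes, n_acc) {
  m <- sample.int(n_acc - 1L, n_genes, replace = TRUE)
  presence <- matrix(TRUE, n_genes, n_acc,
                     dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                     sprintf("a%02d", seq_len(n_acc))))
  for (g in seq_len(n_genes)) {
    presence[g, sample.int(n_acc, m[g])] <- FALSE
  }
  pa_matrix(presence)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Substitute exactly the given positions to a different fixed base.
substitute_at <- function(seq, positions) {
  x <- strsplit(seq, "")[[1]]
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  x[positions] <- swap[x[positions]]
  paste(x, collapse = "")
}

# One hand-built two-exon gene on a small chromosome, for calling tests.
toy_gene <- function(strand = "+", intervals = data.frame(start = c(101, 201),
                                                          end = c(150, 252))) {
  len <- sum(intervals$end - intervals$start + 1)
  n_cod <- len %/% 3
  orf <- paste0("ATG", paste(rep("GGA", n_cod - 2), collapse = ""), "TAA")
  stopifnot(nchar(orf) == len)
  gene_model("toy", "chr1", strand, intervals, orf)
}
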
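# The synthetic-cohort generator and its truth tables.

test_that("configuration validation rejects impossible plans", {
  expect_error(cohort_config(spectrum = data.frame(absence_count = 20,
                                                   n_genes = 5),
                             n_accessions = 20),
               "absent in all")
  expect_error(cohort_config(spectrum = data.frame(absence_count = 1,
                                                   n_genes = 500),
                             n_genes = 400), "more deletions")
  expect_error(cohort_config(diversity_law = c(-0.01, 0, 0)), "negative")
})

test_that("generation is a pure function of the seed", {
  cfg <- small_config(seed = 3L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$reference$genome, c2$reference$genome)
  expect_identical(c1$truth$presence, c2$truth$presence)
  expect_identical(c1$alleles, c2$alleles)
  expect_identical(c1$accessions[[1]]$variants, c2$accessions[[1]]$variants)
  # a different seed changes the cohort
  c3 <- simulate_cohort(small_config(seed = 4L))
  expect_false(identical(c1$reference$genome, c3$reference$genome))
})

test_that("masks cover exactly the CDS of scheduled absences", {
  co <- simulate_cohort(small_config())
  genes <- co$reference$genes
  truth <- co$truth$presence
  for (a in colnames(truth)) {
    mask <- co$accessions[[a]]$mask
    for (gid in rownames(truth)) {
      frac <- inaccessible_fraction(genes[[gid]], mask)
      if (truth[gid, a]) expect_lt(frac, 0.5) else expect_equal(frac, 1)
    }
  }
})

test_that("the realized spectrum equals the configured spectrum", {
  co <- default_cohort()
  pam <- default_pipeline()$pa_matrix
  sp <- absence_spectrum(pam)
  cfg_sp <- co$config$spectrum
  merged <- merge(sp, cfg_sp, by = "absence_count", all = TRUE)
  expect_equal(merged$n_genes.x, merged$n_genes.y)
})

test_that("the called matrix equals the truth matrix exactly", {
  co <- default_cohort()
  pam <- default_pipeline()$pa_matrix
  truth <- co$truth$presence
  expect_identical(dim(pam$presence), dim(truth))
  expect_identical(pam$presence[rownames(truth), colnames(truth)], truth)
})

test_that("variant records match the reference at their positions", {
  co <- simulate_cohort(small_config())
  genome <- co$reference$genome
  for (a in names(co$accessions)[1:3]) {
    v <- co$accessions[[a]]$variants
    if (nrow(v) == 0) next
    obs <- substring(genome[v$chrom], v$pos, v$pos + nchar(v$ref) - 1L)
    expect_equal(unname(obs), v$ref)
  }
})

test_that("realized allele diversity tracks the diversity law", {
  co <- default_cohort()
  pam <- default_pipeline()$pa_matrix
  law <- co$config$diversity_law
  m <- pam$absence_count[names(co$alleles)]
  f <- m / co$config$n_accessions
  target <- law[1] + law[2] * f + law[3] * f^2
  realized <- vapply(co$alleles, nucleotide_diversity, 0)
  # polymorphic loci with >= 2 present alleles track the law on average
  keep <- (co$config$n_accessions - m) >= 2
  expect_equal(mean(realized[keep]), mean(target[keep]), tolerance = 0.15)
  # single-allele loci are monomorphic by definition
  expect_true(all(realized[!keep] == 0))
})

test_that("planted disruptions are recovered exactly by the caller", {
  co <- default_cohort()
  calls <- default_pipeline()$disruptions
  truth <- co$truth$disruptions
  fs_truth <- truth[truth$kind == "frameshift", ]
  ps_truth <- truth[truth$kind == "premature_stop", ]
  fs_called <- calls[calls$frameshift, ]
  ps_called <- calls[calls$premature_stop & !calls$frameshift, ]
  key <- function(df) sort(paste(df$gene_id, df$accession_id))
  expect_equal(key(fs_called), key(fs_truth))
  expect_equal(key(ps_called), key(ps_truth))
  # diversity SNPs never disrupt: every other call is intact
  others <- calls[!(paste(calls$gene_id, calls$accession_id) %in%
                      paste(truth$gene_id, truth$accession_id)), ]
  expect_true(all(others$status == "intact"))
})

test_that("written cohort files are consistent with the in-memory truth", {
  co <- simulate_cohort(small_config())
  dir <- tempfile()
  write_cohort(co, dir)
  # masks round-trip through BED
  a <- names(co$accessions)[1]
  mask <- read_mask(file.path(dir, "accessions", paste0(a, ".mask.bed")))
  expect_equal(mask, co$accessions[[a]]$mask, ignore_attr = TRUE)
  # truth matrix round-trips through TSV
  pam <- read_pa_matrix(file.path(dir, "truth_pa_matrix.tsv"))
  expect_identical(pam$presence, co$truth$presence)
  unlink(dir, recursive = TRUE)
})
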
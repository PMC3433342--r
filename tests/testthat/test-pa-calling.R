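# Absence calling from masks, the P/A matrix, and ORF disruption calls.

# brute-force per-base overlap oracle
masked_fraction_oracle <- function(gene, mask) {
  cds_bases <- unlist(mapply(seq, gene$cds_intervals$start,
                             gene$cds_intervals$end, SIMPLIFY = FALSE))
  m <- mask[mask$chrom == gene$chromosome, , drop = FALSE]
  masked <- unique(unlist(mapply(seq, m$start, m$end, SIMPLIFY = FALSE)))
  mean(cds_bases %in% masked)
}

test_that("inaccessible_fraction counts masked CDS bases splice-aware", {
  g <- gene_model("g", "chr1", "+", data.frame(start = 101, end = 200),
                  random_seq(100))
  m <- data.frame(chrom = "chr1", start = 101, end = 160)
  expect_equal(inaccessible_fraction(g, m), 0.60)

  # mask spanning the intron: only exonic overlap counts
  g2 <- gene_model("g2", "chr1", "+",
                   data.frame(start = c(101, 201), end = c(150, 250)),
                   random_seq(100))
  m2 <- data.frame(chrom = "chr1", start = 140, end = 210)
  expect_equal(inaccessible_fraction(g2, m2), 0.21)
  expect_equal(inaccessible_fraction(g2, m2), masked_fraction_oracle(g2, m2))

  expect_equal(inaccessible_fraction(g, pavscape:::empty_mask()), 0)
  # mask on another chromosome contributes nothing
  expect_equal(inaccessible_fraction(
    g, data.frame(chrom = "chr9", start = 1, end = 1e6)), 0)
})

test_that("fraction agrees with the per-base oracle on random cases", {
  set.seed(11)
  for (i in 1:20) {
    n_ex <- sample(1:4, 1)
    starts <- sort(sample(seq(1, 900, by = 60), n_ex))
    ends <- starts + sample(10:50, n_ex, replace = TRUE)
    len <- sum(ends - starts + 1)
    g <- gene_model("g", "chr1", "+", data.frame(start = starts, end = ends),
                    random_seq(len))
    m <- normalize_mask(data.frame(
      chrom = "chr1", start = s <- sample(1:900, 5),
      end = s + sample(5:80, 5, replace = TRUE)))
    expect_equal(inaccessible_fraction(g, m), masked_fraction_oracle(g, m))
  }
})

test_that("the absence call is strict at exactly half the CDS", {
  g <- gene_model("g", "chr1", "+", data.frame(start = 101, end = 200),
                  random_seq(100))
  expect_true(call_absent(g, data.frame(chrom = "chr1", start = 101,
                                        end = 160)))   # 0.60
  expect_false(call_absent(g, data.frame(chrom = "chr1", start = 101,
                                         end = 150)))  # exactly 0.50
  expect_false(call_absent(g, pavscape:::empty_mask()))  # 0.0
})

test_that("calling is monotone in the mask", {
  set.seed(12)
  g <- gene_model("g", "chr1", "+", data.frame(start = 101, end = 400),
                  random_seq(300))
  m <- data.frame(chrom = "chr1", start = 101, end = 260)
  for (i in 1:10) {
    extra <- data.frame(chrom = "chr1", start = s <- sample(1:500, 3),
                        end = s + sample(10:100, 3, replace = TRUE))
    grown <- normalize_mask(rbind(m, extra))
    expect_gte(inaccessible_fraction(g, grown), inaccessible_fraction(g, m))
    if (call_absent(g, m)) expect_true(call_absent(g, grown))
  }
})

test_that("build_pa_matrix keeps P/A genes and sidelines all-absent genes", {
  genes <- list(
    gene_model("g1", "chr1", "+", data.frame(start = 1, end = 90),
               random_seq(90)),
    gene_model("g2", "chr1", "+", data.frame(start = 101, end = 190),
               random_seq(90)),
    gene_model("g3", "chr1", "+", data.frame(start = 201, end = 290),
               random_seq(90))
  )
  full <- function(g) data.frame(chrom = "chr1", start = g$cds_intervals$start,
                                 end = g$cds_intervals$end)
  acc1 <- accession_genome("a1", mask = rbind(full(genes[[1]]),
                                              full(genes[[3]])))
  acc2 <- accession_genome("a2", mask = full(genes[[3]]))
  pam <- build_pa_matrix(genes, list(acc1, acc2))
  expect_equal(rownames(pam$presence), "g1")  # g2 present everywhere
  expect_equal(pam$discarded_all_absent, "g3")
  expect_equal(unname(pam$absence_count["g1"]), 1)

  expect_error(build_pa_matrix(genes, list(acc1, acc1)), "duplicate")
  expect_error(build_pa_matrix(genes, list(acc1)), "two accessions")
})

test_that("absence counts equal a brute-force recount", {
  co <- default_cohort()
  pam <- default_pipeline()$pa_matrix
  recount <- apply(!pam$presence, 1, sum)
  expect_equal(unname(pam$absence_count), unname(recount))
  col_recount <- apply(!pam$presence, 2, sum)
  expect_equal(unname(colSums(!pam$presence)), unname(col_recount))
})

test_that("absence spectrum conserves the gene count", {
  pam <- pam_from_counts(c(1, 1, 2), 4)
  sp <- absence_spectrum(pam)
  expect_equal(sp$n_genes[sp$absence_count == 1], 2)
  expect_equal(sp$n_genes[sp$absence_count == 2], 1)
  expect_equal(sum(sp$n_genes), nrow(pam$presence))

  pam2 <- default_pipeline()$pa_matrix
  expect_equal(sum(absence_spectrum(pam2)$n_genes), nrow(pam2$presence))
})

test_that("per-accession summary reproduces printed proportion arithmetic", {
  pam <- pam_from_counts(rep(1, 8), 2, rotate = FALSE)
  # first accession absent in all 8, second in none: mean 4
  s <- per_accession_summary(pam)
  expect_equal(s$mean, 4)

  # the cohort-average arithmetic: 444 of 27,004 genes is 1.64%
  expect_equal(round(100 * 444 / 27004, 2), 1.64)
})

test_that("disruption calls classify frameshifts and premature stops", {
  g <- toy_gene()  # ATG GGA ... TAA over two exons, plus strand
  no_v <- pavscape:::empty_variants()
  expect_equal(call_disruption(g, no_v)$status, "intact")

  # 1-bp deletion inside the first exon: frameshift
  del <- data.frame(chrom = "chr1", pos = 110,
                    ref = substr(pavscape:::plus_spliced(g), 10, 11),
                    alt = substr(pavscape:::plus_spliced(g), 10, 10))
  call <- call_disruption(g, del)
  expect_true(call$frameshift)
  expect_true(call$status %in% c("frameshift", "both"))

  # SNP turning codon 5 (GGA, CDS 13..15) into TGA: premature stop.
  # The edited translation is verified against an independent oracle.
  snp <- data.frame(chrom = "chr1", pos = 113, ref = "G", alt = "T")
  call2 <- call_disruption(g, snp)
  expect_equal(call2$status, "premature_stop")
  edited <- g$cds_sequence
  substr(edited, 13, 13) <- "T"
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(edited)))
  first_stop <- regexpr("*", aa, fixed = TRUE)[1]
  expect_lt(first_stop, nchar(aa))  # oracle agrees a stop precedes the end
})

test_that("disruption calling respects strand", {
  # minus-strand gene: genomic slice is the reverse complement of the ORF
  iv <- data.frame(start = 101, end = 202)  # 102 bp, 34 codons
  orf <- paste0("ATG", paste(rep("CAA", 32), collapse = ""), "TAA")
  g <- gene_model("gm", "chr1", "-", iv, orf)
  # plant a stop at codon 10 (CAA -> TAA): CDS position 28, base C -> T.
  # On the plus strand that is position end - 28 + 1 = 175, base G -> A.
  snp <- data.frame(chrom = "chr1", pos = 175, ref = "G", alt = "A")
  expect_equal(call_disruption(g, snp)$status, "premature_stop")
})

test_that("disruption calling validates its variants", {
  g <- toy_gene()
  bad_ref <- data.frame(chrom = "chr1", pos = 113, ref = "T", alt = "C")
  expect_error(call_disruption(g, bad_ref), "does not match")

  overlapping <- data.frame(chrom = "chr1", pos = c(110, 111),
                            ref = c(substr(g$cds_sequence, 10, 12), "G"),
                            alt = c("A", "T"))
  expect_error(call_disruption(g, overlapping), "overlapping|match")

  # a deletion running off the exon end is rejected
  spanning <- data.frame(chrom = "chr1", pos = 149,
                         ref = "AAAA", alt = "A")
  expect_error(call_disruption(g, spanning), "boundary|match")
})
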
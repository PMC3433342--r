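# End-to-end analysis driver: run every stage of the P/A landscape analysis
# on a (synthetic or pre-built) cohort and collect the headline numbers.

#' @noRd
with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full presence/absence analysis pipeline
#'
#' Generates (or accepts) a cohort, calls the P/A matrix from the masks,
#' and runs every downstream stage: absence spectrum and per-accession
#' summary, rarefaction curve with logarithmic fit, gene families and
#' tandem clusters, diversity-frequency covariation, P/A and SNP
#' neighbor-joining trees, chromosomal windows with the centromere profile,
#' functional-category enrichment, ORF-disruption calls, and a presence
#' self-validation spot check. Deterministic given the config seed: every
#' random stage draws from a seed derived from it.
#'
#' @param config A [cohort_config]; its `seed` drives all stages.
#' @param cohort Optionally a pre-built `pav_cohort` (then `config` is taken
#'   from it).
#' @param out_dir Optional output directory; when given, per-stage tables,
#'   both trees (Newick) and a JSON summary are written there.
#' @param write_inputs Also write the cohort itself (FASTA/GFF3/BED/VCF)
#'   under `out_dir/cohort` (default `FALSE`).
#' @return List of class `pav_result` with per-stage results and a `summary`
#'   list of headline numbers.
#' @export
run_pav_pipeline <- function(config = cohort_config(), cohort = NULL,
                             out_dir = NULL, write_inputs = FALSE) {
  if (is.null(cohort)) {
    cohort <- with_stage("simulate", simulate_cohort(config))
  }
  cfg <- cohort$config
  genes <- cohort$reference$genes
  gene_ids <- names(genes)

  pam <- with_stage("call", build_pa_matrix(genes, cohort$accessions))
  spectrum <- absence_spectrum(pam)
  acc_summary <- per_accession_summary(pam, n_reference_genes = length(genes))

  rar <- with_stage("rarefy", rarefaction_curve(
    pam, reps = cfg$rarefaction_reps, seed = derive_seed(cfg$seed, 3L)))
  pred4 <- predict_absent(rar$fit_a, rar$fit_b, 4)
  p_rand <- with_stage("rarefy", randomization_pvalue(
    pam, k = 4L, observed = pred4, reps = 2000L,
    seed = derive_seed(cfg$seed, 4L)))

  fams <- with_stage("families", build_families(genes))
  ranks <- gene_ranks(genes)
  clus <- with_stage("families", detect_clusters(fams$families, ranks))
  cstats <- cluster_stats(pam, fams, clus, gene_ids)

  n_pa <- nrow(pam$presence)
  bin_size <- max(2L, n_pa %/% cfg$n_bins)
  covar <- with_stage("covary", covariation_report(
    pam, cohort$alleles, n_bins = cfg$n_bins, bin_size = bin_size,
    seed = derive_seed(cfg$seed, 5L)))

  pa_tree <- with_stage("tree", neighbor_joining(binary_p_distance(pam)))
  acc_tree <- with_stage("tree", neighbor_joining(
    snp_p_distance(cohort$background_alleles)))
  tree_cmp <- compare_trees(pa_tree, acc_tree)

  win <- with_stage("chromdist", assign_windows(
    genes, cohort$reference$chrom_lengths, window_size = cfg$window_size))
  win_tab <- pa_proportion_per_window(win, rownames(pam$presence))
  cen_prof <- with_stage("chromdist", centromere_profile(
    win_tab, cohort$reference$centromeres))

  enrich <- with_stage("enrich", category_report(
    rownames(pam$presence), gene_ids, cohort$truth$categories))

  disruptions <- with_stage("disrupt", call_cohort_disruptions(
    genes, cohort$accessions))

  set.seed(derive_seed(cfg$seed, 6L))
  check_ids <- sample(rownames(pam$presence), min(10L, n_pa))
  self_val <- with_stage("validate", validate_candidates(
    genes[check_ids], list(reference = cohort$reference$genome)))

  summary <- list(
    n_reference_genes = length(genes),
    n_pa_genes = n_pa,
    n_discarded_all_absent = length(pam$discarded_all_absent),
    mean_absent_per_accession = acc_summary$mean,
    pct_absent_of_reference = 100 * acc_summary$proportion_of_reference,
    fit_a = rar$fit_a, fit_b = rar$fit_b,
    predicted_absent_at_4 = pred4,
    randomization_p_at_4 = p_rand,
    pct_pa_in_families = 100 * cstats$prop_pa_in_families,
    pct_pa_clustered = 100 * cstats$prop_pa_clustered,
    pct_family_pa_clustered = 100 * cstats$prop_family_pa_clustered,
    mean_pi = covar$mean_pi,
    covariation_r = covar$fit_pi$r,
    covariation_p = covar$fit_pi$p_value,
    covariation_vertex = covar$fit_pi$vertex,
    centromere_rho = cen_prof$rho,
    centromere_p = cen_prof$p_value,
    enriched_categories = enrich$category[!is.na(enrich$q_value) &
                                            enrich$q_value < 0.01 &
                                            enrich$prop_pa_in_category >
                                              n_pa / length(genes)],
    n_frameshift = sum(disruptions$frameshift),
    n_premature_stop_only = sum(disruptions$premature_stop &
                                  !disruptions$frameshift),
    tree_rf = tree_cmp$rf,
    self_validation_all_present = self_val$n_all_present ==
      length(check_ids)
  )

  result <- structure(list(
    cohort = cohort, pa_matrix = pam, spectrum = spectrum,
    accession_summary = acc_summary, rarefaction = rar,
    families = fams, clusters = clus, cluster_stats = cstats,
    covariation = covar, pa_tree = pa_tree, accession_tree = acc_tree,
    tree_comparison = tree_cmp, windows = win_tab,
    centromere_profile = cen_prof, enrichment = enrich,
    disruptions = disruptions, self_validation = self_val,
    summary = summary
  ), class = "pav_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pa_matrix(pam, file.path(out_dir, "pa_matrix.tsv"))
    writeLines(pam$discarded_all_absent,
               file.path(out_dir, "all_absent_genes.txt"))
    utils::write.table(spectrum, file.path(out_dir, "spectrum.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    curve <- data.frame(size = rar$sizes, mean = rar$mean,
                        ci_lo = rar$ci_lo, ci_hi = rar$ci_hi)
    utils::write.table(curve, file.path(out_dir, "rarefaction.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fam_df <- data.frame(
      family_id = rep(names(fams$families), lengths(fams$families)),
      gene_id = unlist(fams$families, use.names = FALSE))
    utils::write.table(fam_df, file.path(out_dir, "families.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    clu_df <- do.call(rbind, lapply(clus, function(cl) {
      data.frame(cluster_id = cl$cluster_id, family_id = cl$family_id,
                 chromosome = cl$chromosome,
                 gene_id = cl$members)
    }))
    utils::write.table(clu_df %||% data.frame(),
                       file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(covar$loci, file.path(out_dir, "covariation_loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(win_tab, file.path(out_dir, "windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enrich, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(disruptions, file.path(out_dir, "disruptions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_newick(pa_tree, file.path(out_dir, "pa_tree.nwk"))
    write_newick(acc_tree, file.path(out_dir, "accession_tree.nwk"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (isTRUE(write_inputs)) write_cohort(cohort, file.path(out_dir, "cohort"))
  }
  result
}

#' @export
print.pav_result <- function(x, ...) {
  s <- x$summary
  cat("<pav_result>\n",
      sprintf("  P/A genes: %d of %d reference genes (%d all-absent discarded)\n",
              s$n_pa_genes, s$n_reference_genes, s$n_discarded_all_absent),
      sprintf("  mean absent per accession: %.1f (%.2f%% of reference)\n",
              s$mean_absent_per_accession, s$pct_absent_of_reference),
      sprintf("  rarefaction fit: y = %.1f ln(x) + %.1f\n", s$fit_a, s$fit_b),
      sprintf("  in families: %.1f%%; clustered: %.1f%%\n",
              s$pct_pa_in_families, s$pct_pa_clustered),
      sprintf("  mean pi: %.4f; covariation r = %.2f (p = %.2g)\n",
              s$mean_pi, s$covariation_r, s$covariation_p),
      sprintf("  centromere rho = %.2f (p = %.2g)\n",
              s$centromere_rho, s$centromere_p), sep = "")
  invisible(x)
}

#' Call ORF disruptions across a cohort
#'
#' Groups each accession's variants by gene and applies [call_disruption()].
#'
#' @param genes Named list of [gene_model] objects.
#' @param accessions Named list of [accession_genome] objects whose
#'   `variants` carry a `gene_id` column (as generated by
#'   [simulate_cohort()]); variants without one are assigned to genes by
#'   CDS overlap.
#' @return data.frame of calls for every (gene, accession) pair that has at
#'   least one CDS variant: `gene_id`, `accession_id`, `status`,
#'   `frameshift`, `premature_stop`.
#' @export
call_cohort_disruptions <- function(genes, accessions) {
  rows <- list()
  for (a in names(accessions)) {
    v <- accessions[[a]]$variants
    if (is.null(v) || nrow(v) == 0L) next
    if (!"gene_id" %in% names(v)) {
      v$gene_id <- assign_variant_genes(genes, v)
      v <- v[!is.na(v$gene_id), , drop = FALSE]
    }
    for (gid in unique(v$gene_id)) {
      rows[[length(rows) + 1L]] <- call_disruption(
        genes[[gid]], v[v$gene_id == gid, , drop = FALSE], accession_id = a)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), accession_id = character(0),
                      status = character(0), frameshift = logical(0),
                      premature_stop = logical(0)))
  }
  do.call(rbind, rows)
}

# Gene id whose CDS contains each variant position (NA when none).
#' @noRd
assign_variant_genes <- function(genes, variants) {
  out <- rep(NA_character_, nrow(variants))
  for (g in genes) {
    on_chr <- variants$chrom == g$chromosome
    if (!any(on_chr)) next
    inside <- !is.na(genomic_to_spliced(g, variants$pos))
    out[on_chr & inside] <- g$gene_id
  }
  out
}
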
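# pavscape

Presence/absence (P/A) gene variation analysis for resequenced plant
cohorts.

When a cohort of accessions is resequenced against one reference genome,
each accession carries *inaccessible regions* — intervals with no reliable
base calls, reflecting deletions or missing data. `pavscape` calls a gene
**absent** in an accession when such regions cover strictly more than half
of its coding sequence, assembles the genes × accessions P/A matrix, and
then characterizes the P/A landscape of the cohort:

* the **absence-frequency spectrum** and per-accession absence summaries;
* the **rarefaction curve** — the number of distinct absent genes
  discovered among *k* sampled accessions — with its exact
  inclusion–exclusion expectation
  `E[S_k] = Σ_g (1 − C(n−m_g, k)/C(n, k))`, a logarithmic fit
  `y = a·ln(k) + b`, predictions, and a randomization test for external
  counts;
* **gene families** (single-linkage components at nucleotide divergence
  < 0.3, i.e. ≥ 70 % identity) and **tandem clusters** (family co-members
  with ≤ 8 intervening genes between neighbors);
* **diversity–frequency covariation**: nucleotide diversity π of the
  present alleles per P/A locus, equal-size frequency bins, and a
  quadratic fit of bin means on absence frequency;
* **neighbor-joining trees** on binary P/A profiles and on SNP
  p-distances of non-P/A genes (Saitou–Nei, deterministic tie-breaking,
  non-negative branch lengths);
* the **chromosomal distribution** of P/A genes in fixed windows with a
  centromere-distance profile;
* **functional-category enrichment** by plain Pearson 2×2 chi-square
  (no continuity correction) with BH q-values;
* an **ORF-disruption caller** (premature stops and frameshifts from
  applied variants) and a seed-and-extend **presence validator**
  (coverage of a query by ≥ 70 %-identity hits must exceed 50 %);
* a **synthetic-cohort generator** that plants all of the above —
  families, tandem clusters, an absence spectrum, a quadratic diversity
  law, centromere-proximal deletion excess, disruptions — with truth
  tables, so every stage is validated end to end.

Standard formats in and out: GFF3 + FASTA annotation, BED masks
(0-based, converted on read), VCF variants, TSV matrices, Newick trees.

## A worked example

```r
library(pavscape)
cfg <- cohort_config(seed = 1)   # 2 chromosomes x 2 Mb, 400 genes, 20 accessions
res <- run_pav_pipeline(cfg)
res
```

```
<pav_result>
  P/A genes: 195 of 400 reference genes (0 all-absent discarded)
  mean absent per accession: 45.7 (11.43% of reference)
  rarefaction fit: y = 51.8 ln(x) + 42.3
  in families: 26.7%; clustered: 10.8%
  mean pi: 0.0054; covariation r = 1.00 (p = 7.2e-12)
  centromere rho = -0.76 (p = 8.6e-05)
```

Reading the numbers: all 195 genes scheduled for deletion by the
configured spectrum are recovered (masks are clean at desk scale, so the
called matrix equals the truth matrix exactly). Absent-gene discovery
grows logarithmically with sample size, as in real cohorts. The planted
quadratic diversity law π(f) = 0.04f − 0.04f² is recovered with its
vertex near f = 0.5 (`res$summary$covariation_vertex` ≈ 0.49), the
centromere-proximal deletion excess appears as a significantly negative
rank correlation between window distance-to-centromere and P/A
proportion, and the planted category and all twenty ORF disruptions are
recovered exactly (`res$summary$n_frameshift`,
`res$summary$n_premature_stop_only` are both 10).

`run_pav_pipeline(cfg, out_dir = "pav_out")` additionally writes every
stage's table, both Newick trees and a JSON summary.

See `vignette("pav-analysis")` for the models, parameter defaults and
design choices, including what the synthetic cohort does and does not
emulate.

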
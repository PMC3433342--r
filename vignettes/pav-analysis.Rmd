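---
title: "Presence/absence gene variation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence/absence gene variation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavscape)
```

## The problem

Resequencing a cohort of individuals against one reference genome leaves,
for each individual, genomic intervals with no reliable base calls. These
*inaccessible regions* are either genuine deletions or missing data. When
such regions swallow most of a gene's coding sequence in one accession but
not in others, the gene is a candidate presence/absence (P/A)
polymorphism: a gene carried at a locus by part of a species only. P/A
genes are a major component of plant pan-genomes and are enriched for
rapidly evolving functions such as disease resistance.

`pavscape` implements the full analysis arc: call absent genes from
per-accession masks, then characterize the P/A landscape — its frequency
spectrum, discovery (rarefaction) curve, family and tandem-cluster
structure, the covariation of nucleotide diversity with absence frequency,
P/A and SNP trees, the chromosomal distribution relative to centromeres,
and functional-category enrichment. A fully specified synthetic-cohort
generator with truth tables makes every stage testable end to end.

## The absence call

A gene model carries its representative CDS: for multi-transcript genes
the transcript with the longest summed CDS, with transposable-element
genes and CDS containing ambiguous bases excluded up front. For gene $g$
with CDS length $L_g$ and an accession's normalized mask, the masked
fraction is computed splice-aware: only bases inside CDS intervals count.
The call is

$$\text{absent}(g, a) \iff \frac{\text{masked CDS bp}}{L_g} > \tfrac12 .$$

The inequality is strict: a gene with exactly half its CDS inaccessible is
kept as present. Genes absent in *no* accession are not P/A genes; genes
absent in *every* accession are reported in a sidecar list rather than the
matrix, because that class is dominated by reference-specific insertions
and cannot be distinguished from systematic failure of the mask source.

Absence calling is monotone in the mask (adding intervals can only
increase the masked fraction), which the tests assert as a property.

## Rarefaction: how many absent genes does a sample reveal?

For a P/A matrix over $n$ accessions in which gene $g$ is absent in $m_g$
of them, the number of distinct absent genes among $k$ sampled accessions
has the exact expectation, by inclusion–exclusion,

$$E[S_k] = \sum_g \left(1 - \frac{\binom{n - m_g}{k}}{\binom{n}{k}}\right),$$

which serves as the independent oracle for the Monte-Carlo sampler. The
sampler draws one uniform permutation of the accessions per replicate and
reads the cumulative union of absent genes along it; the first $k$
elements of a uniform permutation are exactly a uniform $k$-subset, so
every sample size sees the correct marginal distribution while one
permutation serves all sizes. Confidence intervals are percentile
intervals (2.5/97.5) across replicates.

The discovery curve is summarized by ordinary least squares of the
per-size mean counts on $\ln k$, $y = a\,\ln k + b$, mirroring the
logarithmic growth such curves show empirically; predictions round half
away from zero to a gene count. An external observed count can be
compared to the sampler by a two-sided randomization p-value, defined
symmetrically about the replicate mean with an add-one correction. The
reference analysis this package follows fitted $y = 480.9 \ln x + 252.6$
on an 80-accession cohort, predicting 919 absent genes at $x = 4$ and
1,669 at $x = 19$; those evaluations are reproduced exactly by
`predict_absent()`.

## Families and tandem clusters

Two genes are homologs when their nucleotide divergence — one minus the
identity over a global affine-gap alignment, terminal gap columns
excluded — is strictly below 0.3 (the ≥70 % identity criterion). Families
are single-linkage connected components of the homolog graph; everything
else is a singleton. Single linkage is the operative reading of "defined
as a family": membership is transitive through intermediate relatives.

All-vs-all alignment is avoided by a shared $k$-mer prefilter
($k = 13$, at least 2 shared distinct $k$-mers). For the divergences the
generator plants (pairwise ≈ 0.19 at the default within-family mutation
rate of 0.1) and CDS of ≥ 300 bp, the expected number of preserved
13-mers per true pair is far above the threshold (≳ 70), so the filter
loses no family edge at test scale, while random pairs pass it with
probability well under $10^{-3}$. Pairs that pass are aligned exactly.

A tandem cluster is a chain of family co-members along one chromosome in
which consecutive members have at most eight intervening genes. The chain
(consecutive-neighbor) reading is used rather than the all-pairs reading,
which would forbid long tandem arrays; maximal chains of two or more
members are reported. `detect_clusters()` is verified against a
brute-force maximal-chain oracle on small chromosomes.

## Diversity–frequency covariation

Nucleotide diversity $\pi$ at a P/A locus is the average over unordered
pairs of present alleles of the proportion of differing comparable sites;
alignment columns with an ambiguous base are dropped pairwise, and loci
with fewer than two present alleles have $\pi = 0$ by definition. Loci
are sorted by absence count (ties shuffled by a seeded RNG, so the layout
is reproducible but unbiased), cut into equal-size bins — 29 bins of 83
loci in the reference analysis; scaled counts for the synthetic cohort —
with remainder loci joining the last bin. Bin-mean diversity (and gene
length) is regressed on absence frequency and its square; the association
is summarized as $r = \sqrt{R^2}$ of the quadratic fit with the F-test
p-value. The reported $r$ is a declared definition: the reference
analysis calls its statistic a "quadratic-like correlation" without
defining it operationally.

## Trees

The accession-level P/A profile tree uses the binary p-distance (fraction
of loci with differing presence state); the accession tree uses the SNP
p-distance over concatenated non-P/A gene alignments with pairwise
deletion of ambiguous sites. Both are built with classic Saitou–Nei
neighbor joining, implemented here so two conventions are explicit:
ties in the $Q$ criterion break to the lexicographically smallest node
pair (bitwise reproducibility), and negative branch lengths are clamped
to zero with the deficit moved to the sister branch. On additive
distances the implementation recovers the generating tree's topology and
path lengths to $10^{-9}$, verified against `ape` oracles. As a
programmatic surrogate for a reconciled-tree display, the two trees are
compared by Robinson–Foulds distance.

## Chromosomal distribution

Chromosomes are cut into fixed windows (1 Mb at reference scale; 200 kb
for the 2 Mb synthetic chromosomes, keeping ≥ 10 windows per chromosome
so a rank correlation is meaningful). A gene belongs to the window
containing its start coordinate. The per-window P/A proportion is
undefined — `NA`, never 0 — for gene-free windows. Centromere proximity
is summarized as the Spearman correlation between window distance to the
nearest centromere edge and P/A proportion, per chromosome and pooled,
rather than a binary near/far call, because no numeric "near" cutoff is
established.

## Enrichment

All 2×2 enrichment tests are plain Pearson chi-square from the table
margins without continuity correction — the convention required to
reproduce the published family-enrichment statistic
($\chi^2 = 281$ on the printed margins; note that the non-P/A total is
$27{,}004 - 2{,}407 = 24{,}597$). Functional categories may overlap, so
category tests are per-category against the complement, with
Benjamini–Hochberg q-values reported alongside raw p-values as a declared
multiple-testing policy.

## The synthetic cohort: what it emulates and what it does not

The generator's defaults define the desk-scale study conditions: 2
chromosomes × 2 Mb, 400 genes, 20 accessions. Genes are random ORFs
(uniform 100–500 codons, 1–3 exons, introns 80–300 bp, random strand)
placed by inverse-CDF sampling from a piecewise-constant density with a
4-fold depression inside the central 20 % of each chromosome (the
centromere). Twenty-five families of four are planted by mutating a seed
ORF at rate 0.1 per site; ten of them are laid out as tandem chains with
at most two intervening genes, the rest scattered with at least nine
intervening genes so they cannot form clusters.

The absence spectrum is geometric decay, $\text{round}(40 \cdot 0.8^{m-1})$
genes absent in $m = 1 \dots 19$ accessions (195 P/A genes of 400; the
decaying shape mirrors the empirical spectra of resequencing cohorts).
Deleted genes are drawn with 6-fold weight within 100 kb of a centromere,
planting the centromere-proximal excess. Masks cover the full CDS of each
scheduled absence, so calling recovers the truth matrix exactly; no
incidental (partial or off-target) masking is simulated.

Present-allele diversity follows $\pi(f) = 0.04 f - 0.04 f^2$ of absence
frequency $f$ — peak $\pi = 0.01$ at $f = 0.5$, matching the magnitude of
plant nuclear diversity. Each present allele mutates each site
independently with probability $p$ where $2p(1-p) = \pi$, towards one
fixed alternative base per site; mutations that would create an in-frame
stop are reverted so diversity SNPs never masquerade as pseudogenizing
variants. Fifty non-P/A genes carry background SNPs at $\pi = 0.005$ and
feed the accession tree. Ten premature-stop SNPs and ten 1-bp frameshift
deletions are planted on present alleles of otherwise untouched non-P/A
genes, one accession each, so disruption recovery is exact by
construction.

What the generator does **not** emulate: read-level error and partial
masking (real inaccessible regions have soft boundaries and false calls —
the reference analysis estimated 25 % of its P/A calls false by PCR),
indel-driven alignment shifts, recombination or coalescent structure
(diversity is planted directly, not evolved), gene-length–frequency
covariation, and insertions relative to the reference. Passing recovery
tests therefore demonstrate correctness of the analysis machinery under
clean masks, not robustness to noisy masks.

## Numerical choices and degenerate inputs

* Internal coordinates are 1-based inclusive; BED is converted on read,
  and masks are normalized (sorted, overlapping/adjacent intervals
  merged) before use.
* The absence boundary is strict (`> 0.5`); exactly half masked is
  present.
* Presence validation replaces a database-size-dependent e-value with
  explicit parameters: exact 11-mer seeds (the classic BLASTN word size),
  ungapped extension, per-hit identity ≥ 0.7, cumulative merged coverage
  > 0.5 of the query, searched on both strands. A 30 bp minimum hit span
  is imposed because chance 11-mer matches are ubiquitous against
  megabase targets — without a significance floor, any query is "covered".
  Same-diagonal exact runs are chained into one hit when the chained span
  still meets the identity threshold, so substitution-diverged homologs
  are covered end to end.
* Variants are applied right-to-left in CDS coordinates so positions stay
  valid; a variant overlapping another, crossing an exon boundary, or
  mismatching the reference is an error rather than silently resolved.
* Quadratic fits with a constant response return $r = 0$ (the F statistic
  is undefined there); constant-frequency designs are an error.
* The rarefaction prediction rounds half away from zero; the
  randomization p-value uses an add-one correction and so is never 0.
* Every random stage takes an explicit seed; the pipeline derives stage
  seeds from the one master seed, so a run is one number away from exact
  reproduction.

## Problem sizes

The shipped tests run the default cohort once (400 genes, 20 accessions,
10,000 rarefaction replicates) and reuse it across test files; oracle
equivalences use exhaustive enumeration at small sizes (subsets to
$n = 10$, chains to 15 genes, additive trees to 8 taxa), and the
unbiasedness suite draws 50 random matrices at 2,000 replicates each.
These sizes were chosen so the whole suite exercises every stage at
full fidelity while staying a desk-scale computation.

## Known limitations

* The absence caller consumes masks; it does not build them from reads,
  and it inherits whatever biases the mask source has.
* `pairwise_divergence` is exact but quadratic in sequence length; family
  construction relies on the k-mer prefilter for scale and is intended
  for gene-sized sequences, not chromosomes.
* The presence validator is a coverage screen, not a general aligner: no
  gapped extension, no e-values, no protein-space search.
* With very few present alleles the per-locus $\pi$ estimate is noisy,
  and loci with one present allele are structurally $\pi = 0$; bin means
  at extreme absence frequencies are correspondingly dampened.

## A worked run

```{r, eval = FALSE}
cfg <- cohort_config(seed = 1)
res <- run_pav_pipeline(cfg, out_dir = "pav_out")
res$summary
```

The summary reports the called P/A gene count (equal to the configured
spectrum total when masks are clean), the mean absent genes per accession,
the fitted rarefaction coefficients, family/cluster percentages, mean
$\pi$ with the quadratic covariation and its vertex, the centromere rank
correlation, enriched categories, and exact disruption recovery counts.
```
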
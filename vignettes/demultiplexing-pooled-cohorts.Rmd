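---
title: "Demultiplexing pooled single-cell cohorts by bulk SNP profile matching"
author: "poolmux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demultiplexing pooled single-cell cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolmux)
```

## The model

A multiplexed single-cell experiment pools cells from $K$ patients. A
genotype-deconvolution tool (Souporcell-style) partitions the barcodes into
$K$ clusters and emits, per cluster, a consensus genotype at the SNP loci it
could call — but the clusters are anonymous. Separately, each patient has a
bulk RNA-seq (or exome) variant-call file. `poolmux` treats both sides as
*genotype profiles*: maps from a biallelic variant key (normalized
chromosome, position, REF, ALT) to an ALT-dosage code $g \in \{0, 1, 2\}$ or
missing. Multi-allelic records are split into one key per ALT and the
genotype recoded against each ALT, so files that order ALTs differently
still harmonize; a leading `chr` prefix is stripped for the same reason.

The matching statistic is the **normalized Hamming distance**. For cluster
$c$ and patient $p$, let $L_{cp}$ be the loci typed in both profiles. Then

$$d(c,p) = \frac{1}{|L_{cp}|}\sum_{\ell \in L_{cp}} \mathbf{1}[g_{c\ell} \ne g_{p\ell}].$$

Normalizing per pair — rather than by a global locus count — keeps a cluster
with heavy missingness from looking artificially close to everyone. Any code
inequality costs 1: a 0-vs-2 disagreement is not more informative than
0-vs-1 for identity matching, though a dosage-weighted variant
(`dosage_weighted = TRUE`, cost $|g_c - g_p|/2$) is exposed for users who
want it.

Clusters are mapped to patients by the **Kuhn–Munkres algorithm**: the
injective assignment minimizing total distance, solved exactly. A global
optimum, rather than per-cluster argmin, guarantees a one-to-one mapping
even when two clusters share a nearest patient; in well-separated cohorts
the two coincide. The per-cluster *margin* (best alternative distance minus
chosen distance) is reported as-is — it can be negative precisely when the
global optimum overrides a row minimum, which is the case users should
audit.

Key assumptions: the pool contains exactly the patients whose bulk profiles
are supplied (extra patients are allowed — unmatched ones are reported;
extra clusters are an error); genotypes are diploid; and cluster consensus
genotypes are conditionally independent noisy observations of one patient's
genotypes.

## Parameters that matter

* `min_support` (default **50** co-typed loci): below this, a (cluster,
  patient) distance is statistically meaningless — with mismatch
  probability around 0.5 between unrelated genomes, 50 loci give a standard
  error of ~0.07, comfortably below the ~0.45 separation between matched and
  unmatched pairs. Invalid pairs are not dropped but costed at `penalty`.
* `penalty` (default **2.0**): a finite cost above the maximum possible
  distance of 1, so an under-supported pairing is chosen only when nothing
  else is injective. Infinity would make the problem unsolvable whenever any
  pair is invalid; the `penalized` flag marks clusters that had to use it.
* `min_qual` (default **20**) and `min_depth` (default **5**): VCF record
  filters. The depth default mirrors a minimum-coverage-5 bulk
  variant-calling setting; records without QUAL or depth information pass.
  Record depth is taken from `INFO/DP`, falling back to the maximum
  per-sample `FORMAT/DP`.
* `snps_only` (default **TRUE**): restrict to single-nucleotide
  substitutions. Indel representation differs enough between callers that
  cross-file indel keys rarely harmonize; they can be kept with
  `--no-snps-only`.
* Whether distances use bulk-restricted loci or all cluster loci is
  controlled by the harmonization mode; the default (union, then per-pair
  co-typed restriction) uses every locus that both sides typed, which is the
  most data per pair.

## The simulator

`simulate_cohort()` emulates the pipeline's inputs with known ground truth:

* per locus an allele frequency $p \sim U(\text{maf\_range})$, default
  $U(0.05, 0.5)$ — common variants, where discriminatory heterozygosity
  lives;
* patient genotypes drawn independently under Hardy–Weinberg equilibrium:
  $P(0) = (1-p)^2$, $P(1) = 2p(1-p)$, $P(2) = p^2$;
* cluster profiles = the (permuted) patient genotypes observed through
  independent per-entry missingness (default 0.5 — single-cell SNP calling
  typically covers roughly half the bulk loci) and symmetric genotype error
  (a typed code is replaced by one of the other two with equal
  probability);
* barcodes allocated uniformly to patients; a `doublet_rate` fraction
  (default 0.05, a typical droplet collision rate) carries two distinct
  patients and appears in `clusters.tsv` with status `doublet`. Doublets do
  not perturb cluster genotypes, matching how deconvolution tools emit
  per-barcode doublet statuses rather than doublet clusters.

Everything is deterministic given `seed`; files are standard VCF v4.2,
Souporcell-format `clusters.tsv`, a reference-label TSV and a ground-truth
JSON, so the simulated data exercises the same readers as real data.

What the simulator does **not** model: linkage disequilibrium (loci are
independent), ambient RNA contamination, coverage that varies by expression
(missingness is uniform, while real single-cell SNP coverage concentrates in
highly expressed 3'UTRs), allele-specific dropout, deconvolution errors that
mix patients *within* a cluster, and doublet genotype mixtures. Passing
tests on simulated cohorts therefore validates the matching and bookkeeping
machinery — harmonization, distance, assignment, propagation, scoring —
under controlled noise, not the behavior of upstream variant callers or
clustering on real tissue.

## Numerical and design choices

* **Determinism everywhere.** Variant keys are totally ordered by (chrom,
  pos, ref, alt); all tables are written in sorted order with fixed column
  sets; identical inputs give byte-identical outputs. The downsampling
  harness derives one RNG substream per (fraction index, replicate) from the
  master seed, so adding fractions does not perturb existing runs.
* **Ties.** The assignment solver resolves equal-cost optima by column scan
  order (deterministic, lowest-index); pool selection and group assignment
  break ties by sample order and warn where a tie was material.
* **Degenerate inputs.** Intersection-mode harmonization with no shared loci,
  single-sample cohorts, clusters with no validly supported patient, more
  clusters than patients, empty assignment tables, and all-tied signed-rank
  comparisons all raise explicit errors or flagged results rather than
  silent output. A downsampling run whose subsample cannot support any pair
  is recorded as failed, not dropped.
* **Pool objective.** "Highest SNP diversity" is operationalized as
  maximizing the *minimum* pairwise discriminatory-locus count: the
  worst-separated pair is what makes demultiplexing fail, so a bottleneck
  criterion protects it. Exhaustive search up to 12 samples, greedy
  (best pair, then argmax-of-min additions) above.
* **Presence of a variant** in cohort evaluation means a typed non-hom-ref
  code: a per-patient variant-call file only has records where an ALT was
  observed, so hom-ref and missing are both "absence" for intersection
  counting. Discriminatory counts, by contrast, use genotype inequality over
  co-typed loci: a locus typed 0 in one patient and 2 in the other
  discriminates the pair even though only one of them "has" the variant.
* **Benchmark definitions.** TP = predicted label equals reference label;
  FP = predictions carrying any label from the reference alphabet, minus
  TP; FN = reference-labeled cells minus TP. `doublet`/`unassigned` are not
  reference labels, so such predictions count only toward FN — a method is
  not penalized twice for abstaining. The assigned-cell count includes
  patient-assigned singlets *and* doublet calls; its denominator is all
  cells seen (predicted or referenced). Zero-difference pairs in the paired
  signed-rank test are dropped and counted, with `p = 1` and a flag when
  every pair ties.
* **Region priority.** A position overlapping several features counts once,
  with priority CDS > 5'UTR > 3'UTR > intron > other > intergenic. Introns
  are derived as gene minus exons when absent from the annotation. These are
  declared conventions — annotation formats differ on whether UTRs are part
  of exons — chosen so the category counts always sum to the locus count.

## Validation scale

The test suite and `scripts/acceptance.R` validate at desk scale: the
assignment solver against a brute-force oracle on 1000 random matrices up to
7×7; exact end-to-end recovery on a noise-free 5-patient, 10,000-locus
cohort; a ≥99/100 recovery rate on 8-patient, 5,000-locus cohorts with 5%
genotype error and 50% missingness; and a 5-fraction × 10-replicate
downsampling harness. These sizes keep the full suite under a minute while
exercising every code path; real cohorts (tens of thousands of SNPs, ~10k
cells) only make the distances better-supported.

## Known limitations

* Patients absent from the bulk reference cannot be detected as "novel" —
  their cluster will be force-assigned to the nearest supplied patient
  (visible as an unusually high per-cluster distance and low margin).
* Monozygotic twins or heavily related patients may fall below any
  distance-based separability; `cohort_diversity` / `select_pool` exist to
  catch this *before* pooling, and `perturb_profiles` simulates it.
* The tool consumes variant calls; it does not validate them. Systematic
  caller disagreements (e.g. different normalization of indels) surface as
  reduced co-typed support rather than being corrected.
* Doublet *detection* is upstream; only the propagation of doublet statuses
  and the overlap comparison of already-called doublet sets are provided.
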
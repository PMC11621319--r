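# poolmux

Genotype-based demultiplexing of pooled single-cell RNA-seq experiments.

## The problem

Pooling cells or nuclei from several patients into one droplet-based
single-cell run cuts costs and batch effects, but the pooled barcodes must be
assigned back to their patients afterwards. Genotype-deconvolution tools
(e.g. Souporcell) cluster barcodes by their SNP profiles without knowing
*which patient* each cluster is: they discriminate, but do not re-assign.
`poolmux` closes that gap. Given per-patient bulk RNA-seq (or exome) variant
calls and the cluster genotypes from deconvolution, it matches every cluster
to its patient and propagates the labels to barcodes. Because deconvolution
may use *all* SNPs observed in the single-cell data — not only those covered
in the bulk reference — this two-step scheme stays robust when few reference
SNPs are available and for rare cell types with distinctive expression.

## The method

For cluster $c$ and patient $p$, genotypes are encoded as ALT-allele dosages
$g \in \{0, 1, 2\}$ over harmonized variant keys (chrom, pos, REF, ALT).
Over the loci typed in both profiles ("co-typed"), the normalized Hamming
distance is

$$d(c, p) = \frac{\#\{\ell : g_{c\ell} \neq g_{p\ell}\}}{\#\{\ell\ \text{co-typed}\}},$$

and the cluster-to-patient map is the injective assignment minimizing
$\sum_c d(c, \sigma(c))$, solved exactly with the Kuhn–Munkres (Hungarian)
algorithm. Pairs supported by fewer than `min_support` co-typed loci enter
only with a last-resort penalty. Reported per-cluster margins (best
alternative minus chosen distance) let users audit clusters whose globally
optimal patient is not their row minimum.

Around this core the package provides:

* **Cohort evaluation** (`cohort_diversity`, `select_pool`): per-patient SNP
  counts, patient-unique variants, exclusive subset intersections
  (upset-style), and the pairwise discriminatory-locus matrix; pool
  selection maximizes the minimum pairwise count (the worst pair is what
  limits demultiplexing).
* **Region stratification** (`annotate_regions`): classify variants into
  CDS / 5'UTR / 3'UTR / intron / intergenic from a BED or minimal GTF
  annotation, with priority CDS > 5'UTR > 3'UTR > intron.
* **Benchmarking** (`precision_recall`, `downsample_experiment`,
  `compare_runs`, `doublet_overlap`): TP/FP/FN scoring against reference
  labels, a bulk-SNP downsampling harness with paired signed-rank
  comparison, and doublet-set overlap/Jaccard tables.
* **Simulation** (`sim_config`, `simulate_cohort`, `perturb_profiles`):
  synthetic cohorts with Hardy–Weinberg patient genotypes, per-cluster
  missingness and genotype error, doublet barcodes, and full ground truth,
  written as standard VCF / clusters.tsv files.

## Worked example

```r
library(poolmux)

cfg <- sim_config(n_patients = 4, n_loci = 3000, n_cells = 500,
                  cluster_missing_rate = 0.5, genotype_error_rate = 0.05,
                  doublet_rate = 0.08, seed = 11)
truth <- simulate_cohort(cfg, dir = "pool")   # writes VCFs + clusters.tsv

dm <- hamming_matrix(truth$clusters, truth$bulk, min_support = 50)
dm
#> <distance_matrix> 4 clusters x 4 patients over 3000 loci
#>   patient1 patient2 patient3 patient4
#> 0    0.531    0.533    0.540    0.053
#> 1    0.044    0.531    0.508    0.520
#> 2    0.517    0.048    0.528    0.520
#> 3    0.519    0.528    0.050    0.541

km <- kuhn_munkres(dm)
km
#> <assignment_result>
#>   cluster  patient distance margin
#> 1       0 patient4   0.0525 0.4785
#> 2       1 patient1   0.0442 0.4640
#> 3       2 patient2   0.0483 0.4690
#> 4       3 patient3   0.0500 0.4691
#> total cost: 0.1950
```

Each cluster sits at distance ~0.05 from its own patient (5% genotype error
was simulated) and ~0.52 from everyone else — margins near 0.47 mean the
assignment is unambiguous. Propagating labels and scoring against the
simulated truth:

```r
assigned <- assign_cells(km, truth$cells[, c("barcode", "status", "cluster")])
precision_recall(setNames(assigned$patient, assigned$barcode),
                 truth$reference, method = "poolmux")
#> <benchmark_result> poolmux: TP=472 FP=0 FN=0 precision=1.0000 recall=1.0000
```

A-priori cohort evaluation for pool design:

```r
rep <- cohort_diversity(truth$bulk)
rep
#> <cohort_report> 4 samples, 2527 variants in union set
#>  per-sample: patient1=1409, patient2=1353, patient3=1372, patient4=1358
#>  unique:     patient1=199, patient2=179, patient3=194, patient4=207
select_pool(rep, 3)
#> [1] "patient1" "patient2" "patient4"   (min pairwise discriminatory: 1515)
```

The same pipeline is scriptable from a shell via the thin CLI installed at
`inst/cli/poolmux` (subcommands `simulate`, `cohort`, `assign`, `bench`,
`version`).

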
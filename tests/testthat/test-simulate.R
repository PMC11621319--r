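test_that("invalid configurations are rejected with the offending fields", {
  expect_error(sim_config(n_patients = 1), "n_patients")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(doublet_rate = 1), "doublet_rate")
  expect_error(sim_config(genotype_error_rate = -0.1, doublet_rate = 2),
               "doublet_rate.*genotype_error_rate|genotype_error_rate.*doublet_rate")
})

test_that("noise-free clusters equal the mapped patients' genotypes", {
  truth <- simulate_cohort(sim_config(n_patients = 4, n_loci = 500,
                                      n_cells = 100,
                                      cluster_missing_rate = 0,
                                      genotype_error_rate = 0, seed = 2))
  for (cl in names(truth$cluster_map)) {
    expect_identical(truth$clusters$codes[, cl],
                     truth$bulk$codes[, truth$cluster_map[[cl]]])
  }
  # ground-truth mapping is a bijection onto the patients
  expect_setequal(unname(truth$cluster_map), truth$bulk$samples)
})

test_that("genotypes follow Hardy-Weinberg at the configured frequency", {
  truth <- simulate_cohort(sim_config(n_patients = 2, n_loci = 10000,
                                      maf_range = c(0.5, 0.5),
                                      n_cells = 10, seed = 4))
  het <- mean(truth$bulk$codes == 1L)
  # E[het] = 2p(1-p) = 0.5 at p = 0.5; 3 binomial standard errors
  se <- sqrt(0.5 * 0.5 / (10000 * 2))
  expect_lt(abs(het - 0.5), 3 * se)
  hom_alt <- mean(truth$bulk$codes == 2L)
  expect_lt(abs(hom_alt - 0.25), 3 * sqrt(0.25 * 0.75 / (10000 * 2)))
})

test_that("doublet counts and missingness follow their binomial rates", {
  truth <- simulate_cohort(sim_config(n_patients = 3, n_loci = 4000,
                                      n_cells = 1000, doublet_rate = 0.1,
                                      cluster_missing_rate = 0.5, seed = 6))
  n_dbl <- length(truth$doublets)
  expect_lt(abs(n_dbl - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  expect_equal(sum(truth$cells$status == "doublet"), n_dbl)
  miss <- mean(is.na(truth$clusters$codes))
  expect_lt(abs(miss - 0.5), 3 * sqrt(0.25 / length(truth$clusters$codes)))
  # doublets never receive their own cluster column
  expect_setequal(colnames(truth$clusters$codes), names(truth$cluster_map))
})

test_that("simulated files are deterministic and re-read losslessly", {
  cfg <- sim_config(n_patients = 3, n_loci = 300, n_cells = 80,
                    cluster_missing_rate = 0.3, genotype_error_rate = 0.1,
                    bulk_missing_rate = 0.05, seed = 12)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  t1 <- simulate_cohort(cfg, dir = d1)
  t2 <- simulate_cohort(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     info = f)
  }
  # bulk VCF round trip recovers the simulated codes exactly
  for (i in seq_along(t1$files$bulk_vcf)) {
    prof <- read_vcf_profiles(t1$files$bulk_vcf[i])
    expect_identical(prof[[1]]$codes, t1$bulk$codes[, prof[[1]]$sample_id])
  }
  # cluster VCF round trip
  cl <- harmonize_loci(read_vcf_profiles(t1$files$cluster_vcf), mode = "union")
  expect_identical(cl$codes[, t1$clusters$samples], t1$clusters$codes)
  # clusters.tsv round trip
  cells <- read_souporcell_clusters(t1$files$clusters_tsv)
  expect_equal(cells$barcode, t1$cells$barcode)
  expect_equal(cells$status, t1$cells$status)
})

test_that("profile perturbation forces the degenerate-pair failure mode", {
  truth <- simulate_cohort(sim_config(n_patients = 4, n_loci = 1000,
                                      n_cells = 50, seed = 30))
  mangled <- perturb_profiles(truth, c("patient1", "patient2"), n_keep = 0)
  rep <- cohort_diversity(mangled$bulk)
  expect_equal(rep$pairwise_discriminatory["patient1", "patient2"], 0L)
  pool <- select_pool(rep, 3)
  expect_length(intersect(c("patient1", "patient2"), pool), 1L)
  # locality: only the overwritten patient's genotypes change
  others <- setdiff(truth$bulk$samples, "patient2")
  expect_identical(mangled$bulk$codes[, others], truth$bulk$codes[, others])
  expect_error(perturb_profiles(truth, c("patient1", "patient1")),
               "distinct")
  expect_error(perturb_profiles(truth, c("patient1", "nope")), "unknown")
})

test_that("partial perturbation leaves a hand-countable distance", {
  truth <- simulate_cohort(sim_config(n_patients = 3, n_loci = 2000,
                                      n_cells = 30, seed = 31))
  mangled <- perturb_profiles(truth, c("patient1", "patient3"), n_keep = 500)
  diff <- sum(mangled$bulk$codes[, "patient1"] !=
                mangled$bulk$codes[, "patient3"])
  dm <- hamming_matrix(
    profile_matrix(mangled$bulk$loci,
                   mangled$bulk$codes[, "patient1", drop = FALSE]),
    profile_matrix(mangled$bulk$loci,
                   mangled$bulk$codes[, "patient3", drop = FALSE]),
    min_support = 1)
  expect_equal(dm$dist["patient1", "patient3"], diff / 2000)
  # kept loci bound the possible differences
  expect_lte(diff, 500)
})

test_that("perturbation leaves other patients' files byte-identical", {
  cfg <- sim_config(n_patients = 3, n_loci = 200, n_cells = 40, seed = 13)
  d1 <- tempfile()
  d2 <- tempfile()
  truth <- simulate_cohort(cfg, dir = d1)
  perturb_profiles(truth, c("patient1", "patient2"), dir = d2)
  for (s in c("patient1", "patient3")) {
    f <- sprintf("bulk_%s.vcf", s)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_false(identical(readLines(file.path(d1, "bulk_patient2.vcf")),
                         readLines(file.path(d2, "bulk_patient2.vcf"))))
})
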
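# Synthetic multiplexed cohorts with full ground truth. The simulator
# emulates the pipeline's inputs end to end: per-patient bulk VCFs with
# Hardy-Weinberg genotypes, a Souporcell-style multi-column cluster VCF
# (patient genotypes observed through per-cluster missingness and genotype
# error), a per-barcode clusters table with doublets, and reference labels.

#' Simulation configuration
#'
#' @param n_patients Number of pooled patients (>= 2). Default 5, a typical
#'   pool size for multiplexed PBMC or solid-tissue experiments.
#' @param n_loci Number of simulated SNP loci. Default 10000, the order of
#'   usable SNPs recovered from bulk RNA-seq of one sample.
#' @param maf_range Minor-allele-frequency bounds; per locus the allele
#'   frequency is drawn uniformly from this interval. Default c(0.05, 0.5)
#'   (common SNPs; rare variants contribute little discriminatory signal).
#' @param n_cells Number of barcodes. Default 1000.
#' @param doublet_rate Fraction of barcodes that are doublets. Default 0.05,
#'   a typical droplet collision rate at standard loading.
#' @param cluster_missing_rate Fraction of loci untyped per cluster profile.
#'   Default 0.5: single-cell SNP calling covers roughly half the bulk loci.
#' @param bulk_missing_rate Fraction of bulk genotypes set missing.
#'   Default 0.
#' @param genotype_error_rate Fraction of typed cluster genotypes replaced
#'   by one of the other two codes (equal probability). Default 0.
#' @param seed RNG seed; every simulated output is deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 5L, n_loci = 10000L,
                       maf_range = c(0.05, 0.5), n_cells = 1000L,
                       doublet_rate = 0.05, cluster_missing_rate = 0.5,
                       bulk_missing_rate = 0, genotype_error_rate = 0,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_loci = as.integer(n_loci),
              maf_range = as.numeric(maf_range),
              n_cells = as.integer(n_cells),
              doublet_rate = as.numeric(doublet_rate),
              cluster_missing_rate = as.numeric(cluster_missing_rate),
              bulk_missing_rate = as.numeric(bulk_missing_rate),
              genotype_error_rate = as.numeric(genotype_error_rate),
              seed = as.integer(seed))
  bad <- character(0)
  if (is.na(cfg$n_patients) || cfg$n_patients < 2L) bad <- c(bad, "n_patients")
  if (is.na(cfg$n_loci) || cfg$n_loci < 1L) bad <- c(bad, "n_loci")
  if (length(cfg$maf_range) != 2L || any(is.na(cfg$maf_range)) ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) bad <- c(bad, "maf_range")
  if (is.na(cfg$n_cells) || cfg$n_cells < 1L) bad <- c(bad, "n_cells")
  for (f in c("doublet_rate", "cluster_missing_rate", "bulk_missing_rate",
              "genotype_error_rate")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] >= 1) bad <- c(bad, f)
  }
  if (is.na(cfg$seed)) bad <- c(bad, "seed")
  if (length(bad)) {
    stop("invalid simulation config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# deterministic 16-mer barcodes in 10x style
make_barcodes <- function(n) {
  bases <- c("A", "C", "G", "T")
  bc <- vapply(seq_len(n), function(i) {
    paste(sample(bases, 16, replace = TRUE), collapse = "")
  }, character(1))
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- vapply(dup, function(i) {
      paste(sample(bases, 16, replace = TRUE), collapse = "")
    }, character(1))
  }
  paste0(bc, "-1")
}

#' Simulate a multiplexed cohort with ground truth
#'
#' Per locus an allele frequency p is drawn from `maf_range`; each patient's
#' genotype is drawn independently under Hardy-Weinberg equilibrium
#' (P(0) = (1-p)^2, P(1) = 2p(1-p), P(2) = p^2). Cluster profiles are the
#' patient genotypes observed through independent missingness and symmetric
#' genotype error; the cluster ids are a random permutation of the patients
#' (the ground-truth mapping). Barcodes are allocated to patients uniformly;
#' doublet barcodes carry two distinct patients and appear in the clusters
#' table with status `doublet` (cluster genotypes are unaffected, as doublet
#' droplets do not form their own genotype cluster).
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, all pipeline input files are
#'   written there (see [write_simulation()]).
#' @return An object of class `sim_truth`: `config`, `bulk`
#'   (`profile_matrix` of patient genotypes as observed in bulk), `clusters`
#'   (`profile_matrix` of cluster profiles), `cells` (barcode table with
#'   true patients), `reference` (named vector: singlet barcode -> true
#'   patient), `cluster_map` (named vector: cluster id -> patient),
#'   `doublets` (barcode set), and `files` (paths, when `dir` was given).
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  np <- config$n_patients
  nl <- config$n_loci
  patients <- sprintf("patient%d", seq_len(np))

  # loci: unique positions on one synthetic chromosome, random REF/ALT pair
  pos <- sort(sample.int(nl * 20L, nl))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nl, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  loci <- variant_keys(rep("1", nl), pos, ref, alt)

  p <- stats::runif(nl, config$maf_range[1], config$maf_range[2])
  probs <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
  geno <- matrix(0L, nl, np, dimnames = list(NULL, patients))
  for (j in seq_len(np)) {
    u <- stats::runif(nl)
    geno[, j] <- (u > probs[, 1]) + (u > probs[, 1] + probs[, 2])
  }

  bulk_codes <- geno
  if (config$bulk_missing_rate > 0) {
    drop <- matrix(stats::runif(nl * np) < config$bulk_missing_rate, nl, np)
    bulk_codes[drop] <- NA_integer_
  }
  bulk <- profile_matrix(loci, bulk_codes)

  # cluster profiles: permuted patients + missingness + symmetric error
  perm <- sample.int(np)
  cluster_ids <- as.character(seq_len(np) - 1L)   # Souporcell-style 0-based
  cluster_map <- stats::setNames(patients[perm], cluster_ids)
  cl_codes <- geno[, perm, drop = FALSE]
  colnames(cl_codes) <- cluster_ids
  if (config$genotype_error_rate > 0) {
    err <- matrix(stats::runif(nl * np) < config$genotype_error_rate, nl, np)
    err <- err & !is.na(cl_codes)
    if (any(err)) {
      shift <- sample.int(2L, sum(err), replace = TRUE)
      cl_codes[err] <- (cl_codes[err] + shift) %% 3L
    }
  }
  if (config$cluster_missing_rate > 0) {
    drop <- matrix(stats::runif(nl * np) < config$cluster_missing_rate, nl, np)
    cl_codes[drop] <- NA_integer_
  }
  clusters <- profile_matrix(loci, cl_codes)

  # barcodes: uniform patient allocation, doublets carry two patients
  nc <- config$n_cells
  barcodes <- make_barcodes(nc)
  is_dbl <- stats::runif(nc) < config$doublet_rate
  pat1 <- sample(patients, nc, replace = TRUE)
  pat2 <- rep(NA_character_, nc)
  if (any(is_dbl)) {
    pat2[is_dbl] <- vapply(pat1[is_dbl], function(q) {
      sample(setdiff(patients, q), 1)
    }, character(1))
  }
  pat_to_cluster <- stats::setNames(names(cluster_map), cluster_map)
  cells <- data.frame(
    barcode = barcodes,
    status = ifelse(is_dbl, "doublet", "singlet"),
    cluster = ifelse(is_dbl,
                     paste(pat_to_cluster[pat1], pat_to_cluster[pat2],
                           sep = "/"),
                     pat_to_cluster[pat1]),
    true_patient = ifelse(is_dbl, paste(pat1, pat2, sep = "/"), pat1),
    stringsAsFactors = FALSE
  )
  reference <- stats::setNames(pat1[!is_dbl], barcodes[!is_dbl])

  truth <- structure(
    list(config = config, bulk = bulk, clusters = clusters, cells = cells,
         reference = reference, cluster_map = cluster_map,
         doublets = barcodes[is_dbl], files = NULL),
    class = "sim_truth"
  )
  if (!is.null(dir)) truth <- write_simulation(truth, dir)
  truth
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("<sim_truth> %d patients, %d loci, %d cells ",
                     "(%d doublets), error %.2f, missing %.2f\n"),
              x$config$n_patients, x$config$n_loci, nrow(x$cells),
              length(x$doublets), x$config$genotype_error_rate,
              x$config$cluster_missing_rate))
  invisible(x)
}

#' Write a simulated cohort's pipeline inputs to disk
#'
#' Emits one bulk VCF per patient (`bulk_<patient>.vcf`), a multi-column
#' cluster VCF (`cluster_genotypes.vcf`), a Souporcell-format `clusters.tsv`
#' (with placeholder log-probability columns), reference labels
#' (`reference_labels.tsv`) and the ground truth as `ground_truth.json`.
#' Output is deterministic: identical truth objects give byte-identical
#' files.
#'
#' @param truth A `sim_truth`.
#' @param dir Output directory (created if needed).
#' @return `truth` with `files` filled in.
#' @export
write_simulation <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()

  bulk <- truth$bulk
  files$bulk_vcf <- character(0)
  for (s in bulk$samples) {
    path <- file.path(dir, sprintf("bulk_%s.vcf", s))
    write_vcf(bulk$loci, bulk$codes[, s, drop = FALSE], path)
    files$bulk_vcf <- c(files$bulk_vcf, path)
  }

  files$cluster_vcf <- file.path(dir, "cluster_genotypes.vcf")
  write_vcf(truth$clusters$loci, truth$clusters$codes, files$cluster_vcf)

  files$clusters_tsv <- file.path(dir, "clusters.tsv")
  cl <- truth$cells
  tab <- data.frame(barcode = cl$barcode, status = cl$status,
                    assignment = cl$cluster,
                    log_prob_singleton = 0, log_prob_doublet = -100,
                    stringsAsFactors = FALSE)
  con <- file(files$clusters_tsv, open = "wb")
  writeLines(paste(names(tab), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(tab, as.character), sep = "\t")), con)
  close(con)

  files$reference_tsv <- file.path(dir, "reference_labels.tsv")
  ref <- data.frame(barcode = names(truth$reference),
                    label = unname(truth$reference))
  con <- file(files$reference_tsv, open = "wb")
  writeLines(paste(names(ref), collapse = "\t"), con)
  writeLines(paste(ref$barcode, ref$label, sep = "\t"), con)
  close(con)

  files$truth_json <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(config = unclass(truth$config),
         cluster_map = as.list(truth$cluster_map),
         doublets = truth$doublets),
    files$truth_json, auto_unbox = TRUE, pretty = TRUE)

  truth$files <- files
  truth
}

#' Degrade a simulated cohort's patient separability
#'
#' Adversarial fixture for insufficient-SNP-heterogeneity failure modes:
#' overwrites one patient's genotypes with a copy of another's, keeping the
#' original genotypes at `n_keep` randomly chosen loci. With `n_keep = 0`
#' the pair becomes genotype-identical (zero discriminatory loci), which
#' pool selection must detect and avoid. Other patients' genotypes are
#' untouched.
#'
#' @param truth A `sim_truth`.
#' @param pair Length-2 vector of distinct patient ids (or indices);
#'   `pair[2]` is overwritten with a copy of `pair[1]`.
#' @param n_keep Number of loci at which `pair[2]` keeps its own genotype
#'   (default 0).
#' @param dir Optional directory to rewrite the files into.
#' @return The modified `sim_truth`. The cluster profile mapped to `pair[2]`
#'   is rebuilt from the perturbed genotypes, preserving its missingness
#'   pattern (genotype error is not re-applied).
#' @export
perturb_profiles <- function(truth, pair, n_keep = 0L, dir = NULL) {
  stopifnot(inherits(truth, "sim_truth"), length(pair) == 2L)
  patients <- truth$bulk$samples
  if (is.numeric(pair)) pair <- patients[pair]
  if (anyNA(match(pair, patients))) {
    stop("unknown patient id(s) in pair", call. = FALSE)
  }
  if (pair[1] == pair[2]) {
    stop("pair must name two distinct patients", call. = FALSE)
  }
  set.seed(truth$config$seed + 1L)
  src <- truth$bulk$codes[, pair[1]]
  dst <- src
  if (n_keep > 0L) {
    keep <- sample.int(length(src), min(n_keep, length(src)))
    dst[keep] <- truth$bulk$codes[keep, pair[2]]
  }
  truth$bulk$codes[, pair[2]] <- dst

  # mirror the perturbation into the cluster profile mapped to pair[2],
  # preserving that cluster's observed missingness pattern
  cl_id <- names(truth$cluster_map)[truth$cluster_map == pair[2]]
  old <- truth$clusters$codes[, cl_id]
  new <- dst
  new[is.na(old)] <- NA_integer_
  truth$clusters$codes[, cl_id] <- new

  if (!is.null(dir)) truth <- write_simulation(truth, dir)
  truth
}
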
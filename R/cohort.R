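# A-priori cohort evaluation: how many SNPs does each patient carry, which
# variants are patient-unique or shared by which subsets, and how many loci
# discriminate each patient pair. Used to pick pools with enough genotype
# diversity before any cells are sequenced.

#' Evaluate cohort SNP diversity
#'
#' A variant is "present" in a sample when its genotype code is 1 or 2
#' (a variant call exists only where an ALT allele was observed); hom-ref
#' and missing are absence. The report gives per-sample variant counts,
#' patient-unique counts, exclusive intersection counts over every realized
#' sample subset (the numbers behind an upset plot), and the pairwise
#' discriminatory-locus matrix: for each sample pair, the number of loci
#' typed in both at which the genotype codes differ.
#'
#' @param matrix_ A `profile_matrix` from union-mode harmonization with
#'   >= 2 samples.
#' @return An object of class `cohort_report` with elements
#'   `per_sample_counts`, `unique_counts`, `exclusive_intersections`
#'   (data.frame `subset`, `count`, subsets as `+`-joined sample ids),
#'   `pairwise_discriminatory` (symmetric matrix, zero diagonal),
#'   `n_union` (size of the union variant set).
#' @export
cohort_diversity <- function(matrix_) {
  stopifnot(inherits(matrix_, "profile_matrix"))
  codes <- matrix_$codes
  samples <- matrix_$samples
  if (length(samples) < 2L) {
    stop("cohort evaluation needs at least two samples", call. = FALSE)
  }
  present <- !is.na(codes) & codes > 0L

  per_sample <- colSums(present)

  in_union <- rowSums(present) > 0L
  pat <- apply(present[in_union, , drop = FALSE], 1, function(r) {
    paste(samples[r], collapse = "+")
  })
  excl <- table(pat)
  exclusive <- data.frame(subset = names(excl),
                          count = as.integer(excl),
                          stringsAsFactors = FALSE)
  exclusive <- exclusive[order(-exclusive$count, exclusive$subset), ,
                         drop = FALSE]
  rownames(exclusive) <- NULL

  uniq <- stats::setNames(integer(length(samples)), samples)
  singleton <- exclusive$subset %in% samples
  uniq[exclusive$subset[singleton]] <- exclusive$count[singleton]

  n <- length(samples)
  disc <- matrix(0L, n, n, dimnames = list(samples, samples))
  typed <- !is.na(codes)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- typed[, i] & typed[, j]
      k <- sum(codes[both, i] != codes[both, j])
      disc[i, j] <- disc[j, i] <- as.integer(k)
    }
  }

  structure(
    list(per_sample_counts = per_sample,
         unique_counts = uniq,
         exclusive_intersections = exclusive,
         pairwise_discriminatory = disc,
         n_union = sum(in_union)),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d samples, %d variants in union set\n",
              length(x$per_sample_counts), x$n_union))
  cat(" per-sample:", paste(names(x$per_sample_counts),
                            x$per_sample_counts, sep = "=", collapse = ", "), "\n")
  cat(" unique:    ", paste(names(x$unique_counts),
                            x$unique_counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Select a maximally diverse pool
#'
#' Chooses `k` samples for pooling so that the minimum pairwise
#' discriminatory-locus count within the pool is maximized (a bottleneck
#' criterion: the worst-separated pair is what limits demultiplexing).
#' Exhaustive search over all subsets for cohorts of up to `exact_limit`
#' samples; above that a greedy scheme seeds with the best pair and
#' repeatedly adds the sample maximizing the minimum count. Ties are broken
#' by sample order, so the result is deterministic.
#'
#' @param report A `cohort_report`.
#' @param k Pool size, `2 <= k <= n samples`.
#' @param exact_limit Cohort size up to which the search is exhaustive
#'   (default 12).
#' @return Character vector of `k` sample ids (in cohort order), with the
#'   achieved bottleneck count in attribute `min_pairwise`.
#' @export
select_pool <- function(report, k, exact_limit = 12L) {
  stopifnot(inherits(report, "cohort_report"))
  disc <- report$pairwise_discriminatory
  n <- nrow(disc)
  if (k < 2L || k > n) {
    stop("k must be between 2 and the number of samples (", n, ")",
         call. = FALSE)
  }
  samples <- rownames(disc)
  if (n <= exact_limit) {
    best <- NULL
    best_val <- -Inf
    subsets <- utils::combn(n, k)
    for (s in seq_len(ncol(subsets))) {
      idx <- subsets[, s]
      val <- min(disc[idx, idx][upper.tri(diag(k))])
      if (val > best_val) {   # strict: keeps the lexicographically first max
        best_val <- val
        best <- idx
      }
    }
  } else {
    off <- disc
    diag(off) <- -Inf
    seed <- which(off == max(off), arr.ind = TRUE)
    seed <- sort(seed[order(seed[, 1], seed[, 2]), , drop = FALSE][1, ])
    best <- as.integer(seed)
    while (length(best) < k) {
      cand <- setdiff(seq_len(n), best)
      gain <- vapply(cand, function(c) min(disc[c, best]), numeric(1))
      best <- sort(c(best, cand[which.max(gain)]))
    }
    best_val <- min(disc[best, best][upper.tri(diag(k))])
  }
  out <- samples[sort(best)]
  attr(out, "min_pairwise") <- best_val
  out
}

#' Write a cohort report to disk
#'
#' Emits three TSVs under `prefix`: `<prefix>_counts.tsv` (per-sample and
#' unique counts), `<prefix>_intersections.tsv` (upset-style long format:
#' subset id, count) and `<prefix>_discriminatory.tsv` (pairwise matrix).
#'
#' @param report A `cohort_report`.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of paths written.
#' @export
write_cohort_report <- function(report, prefix) {
  paths <- paste0(prefix, c("_counts.tsv", "_intersections.tsv",
                            "_discriminatory.tsv"))
  counts <- data.frame(sample = names(report$per_sample_counts),
                       n_variants = unname(report$per_sample_counts),
                       n_unique = unname(report$unique_counts))
  utils::write.table(counts, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$exclusive_intersections, paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  disc <- data.frame(sample = rownames(report$pairwise_discriminatory),
                     report$pairwise_discriminatory, check.names = FALSE)
  utils::write.table(disc, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
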
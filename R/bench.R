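# Benchmarking machinery: precision/recall of per-cell labels against a
# reference, the bulk-SNP downsampling experiment, paired signed-rank
# comparison of configurations, and doublet-set overlap.

#' Precision and recall of per-cell label assignment
#'
#' True positives are cells whose predicted label equals the reference
#' label; false positives are cells predicted with any *valid* reference
#' label value, minus the true positives; false negatives are
#' reference-labeled cells minus the true positives. Predictions of
#' `doublet`/`unassigned` (or labels outside the reference alphabet) are not
#' valid label values: such cells contribute to FN only. Precision is
#' TP/(TP+FP) (NA when nothing was assigned) and recall TP/(TP+FN).
#'
#' @param predicted Named character vector: barcode -> predicted label.
#'   Barcodes may be omitted (unassigned).
#' @param reference Named character vector: barcode -> reference label;
#'   must cover all evaluated barcodes.
#' @param method Optional method name carried into the result.
#' @param assigned_barcodes Optional barcode set counted as "assigned"
#'   (patient-assigned singlets plus doublet calls) for the
#'   `assigned_fraction`; default: predicted barcodes whose label is in the
#'   reference alphabet or is `doublet`. The denominator is the union of
#'   predicted and reference barcodes (all cells seen).
#' @return An object of class `benchmark_result` with `method`, `TP`, `FP`,
#'   `FN`, `precision`, `recall`, `assigned_fraction`.
#' @export
precision_recall <- function(predicted, reference, method = "method",
                             assigned_barcodes = NULL) {
  if (length(reference) == 0L) {
    stop("empty reference labels", call. = FALSE)
  }
  stopifnot(!is.null(names(reference)))
  if (length(predicted) && is.null(names(predicted))) {
    stop("predicted labels must be named by barcode", call. = FALSE)
  }
  alphabet <- unique(reference)
  pred <- predicted[names(predicted) %in% names(reference)]
  valid <- pred[pred %in% alphabet]
  tp <- sum(valid == reference[names(valid)])
  fp <- length(valid) - tp
  fn <- length(reference) - tp
  if (is.null(assigned_barcodes)) {
    assigned_barcodes <- names(predicted)[predicted %in% c(alphabet, "doublet")]
  }
  all_cells <- unique(c(names(predicted), names(reference)))
  structure(
    list(method = method,
         TP = as.integer(tp), FP = as.integer(fp), FN = as.integer(fn),
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = tp / (tp + fn),
         assigned_fraction = length(unique(assigned_barcodes)) /
           length(all_cells)),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "<benchmark_result> %s: TP=%d FP=%d FN=%d precision=%s recall=%.4f\n",
    x$method, x$TP, x$FP, x$FN,
    if (is.na(x$precision)) "NA" else sprintf("%.4f", x$precision),
    x$recall))
  invisible(x)
}

# one deterministic sub-seed per (fraction index, replicate); independent of
# the set of other fractions/replicates present in a call
run_seed <- function(seed, fraction_index, replicate) {
  (as.integer(seed) * 2654435L + fraction_index * 97003L +
     replicate * 101L) %% 2147483647L
}

#' Bulk-SNP downsampling experiment
#'
#' Repeatedly subsamples the bulk loci to a fraction, reruns the full
#' matching pipeline (distance matrix, Kuhn-Munkres, label propagation) and
#' scores it against the reference labels. Mirrors the robustness analysis
#' of demultiplexing performance as fewer reference SNPs are available:
#' each fraction is run `reps` times with loci drawn uniformly without
#' replacement (size = `round(fraction * n_loci)`). Runs whose subsample
#' cannot support any valid pairing are recorded as failed, not dropped.
#'
#' @param bulk `profile_matrix` of patient bulk profiles.
#' @param cluster_profiles `profile_matrix` of cluster profiles.
#' @param cells Barcode table (see [read_souporcell_clusters()]).
#' @param reference Named vector: barcode -> reference label.
#' @param fractions Numeric vector in (0, 1]; default
#'   `c(1, 0.8, 0.6, 0.4, 0.2)`.
#' @param reps Replicates per fraction (default 10).
#' @param seed Master seed; per-run RNG streams are derived from
#'   (seed, fraction index, replicate) so runs are individually
#'   reproducible.
#' @param min_support Passed to [hamming_matrix()].
#' @return A data.frame with one row per run: `fraction`, `replicate`,
#'   `seed`, `n_loci`, `assigned_cells`, `precision`, `recall`,
#'   `mean_margin`, `mapping` (comma-joined cluster->patient pairs), `ok`.
#' @export
downsample_experiment <- function(bulk, cluster_profiles, cells, reference,
                                  fractions = c(1, 0.8, 0.6, 0.4, 0.2),
                                  reps = 10L, seed = 1L, min_support = 50L) {
  stopifnot(inherits(bulk, "profile_matrix"),
            inherits(cluster_profiles, "profile_matrix"))
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  nl <- nrow(bulk$codes)
  out <- vector("list", length(fractions) * reps)
  r <- 0L
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    size <- max(1L, round(f * nl))
    for (rep in seq_len(reps)) {
      r <- r + 1L
      s <- run_seed(seed, fi, rep)
      set.seed(s)
      idx <- sort(sample.int(nl, size))
      sub <- profile_matrix(bulk$loci[idx, , drop = FALSE],
                            bulk$codes[idx, , drop = FALSE])
      res <- tryCatch({
        dm <- hamming_matrix(cluster_profiles, sub, min_support = min_support)
        km <- kuhn_munkres(dm)
        assigned <- assign_cells(km, cells)
        pred <- stats::setNames(assigned$patient, assigned$barcode)
        pr <- precision_recall(pred, reference)
        n_assigned <- sum(assigned$status == "doublet" |
                            (assigned$status == "singlet" &
                               !is.na(assigned$patient)))
        data.frame(
          fraction = f, replicate = rep, seed = s, n_loci = size,
          assigned_cells = n_assigned,
          precision = pr$precision, recall = pr$recall,
          mean_margin = mean(km$margin, na.rm = TRUE),
          mapping = paste(names(km$mapping), km$mapping,
                          sep = ">", collapse = ","),
          ok = TRUE, stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(fraction = f, replicate = rep, seed = s, n_loci = size,
                   assigned_cells = NA_integer_, precision = NA_real_,
                   recall = NA_real_, mean_margin = NA_real_,
                   mapping = NA_character_, ok = FALSE,
                   stringsAsFactors = FALSE)
      })
      out[[r]] <- res
    }
  }
  do.call(rbind, out)
}

#' Paired signed-rank comparison of two metric vectors
#'
#' Two-sided Wilcoxon signed-rank test on per-replicate differences between
#' two configurations, paired by (fraction, replicate). Zero-difference
#' pairs are dropped (the classical convention) and their count reported;
#' when every pair is tied the p-value is reported as 1 with `all_zero`
#' flagged instead of raising an error.
#'
#' @param a,b Equal-length paired metric vectors (>= 5 pairs).
#' @return A list: `statistic` (V), `p_value`, `n_pairs`, `n_dropped`,
#'   `all_zero`.
#' @export
compare_runs <- function(a, b) {
  if (length(a) != length(b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(a) < 5L) stop("need at least 5 pairs", call. = FALSE)
  d <- a - b
  nz <- !is.na(d) & d != 0
  if (!any(nz)) {
    return(list(statistic = NA_real_, p_value = 1, n_pairs = 0L,
                n_dropped = sum(!nz), all_zero = TRUE))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a[nz], b[nz], paired = TRUE, alternative = "two.sided")
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_pairs = sum(nz), n_dropped = sum(!nz), all_zero = FALSE)
}

#' Doublet-call overlap against a reference doublet set
#'
#' For each method, the fraction of reference doublets it recovers
#' (|method ∩ reference| / |reference|), plus the full method-by-method
#' Jaccard table of doublet calls.
#'
#' @param method_doublets Named list: method -> character vector of doublet
#'   barcodes.
#' @param reference_doublets Non-empty character vector of reference doublet
#'   barcodes (e.g. computationally identified doublets).
#' @return A list with `overlap` (named numeric vector per method) and
#'   `jaccard` (methods x methods matrix).
#' @export
doublet_overlap <- function(method_doublets, reference_doublets) {
  if (length(reference_doublets) == 0L) {
    stop("reference doublet set is empty", call. = FALSE)
  }
  stopifnot(is.list(method_doublets), !is.null(names(method_doublets)))
  ref <- unique(reference_doublets)
  sets <- lapply(method_doublets, unique)
  overlap <- vapply(sets, function(s) {
    length(intersect(s, ref)) / length(ref)
  }, numeric(1))
  n <- length(sets)
  jac <- matrix(1, n, n, dimnames = list(names(sets), names(sets)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        u <- length(union(sets[[i]], sets[[j]]))
        jac[i, j] <- jac[j, i] <-
          if (u == 0) 0 else length(intersect(sets[[i]], sets[[j]])) / u
      }
    }
  }
  for (i in seq_len(n)) if (length(sets[[i]]) == 0L) jac[i, i] <- 0
  list(overlap = overlap, jaccard = jac)
}
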
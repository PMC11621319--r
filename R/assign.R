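# Core matching step: normalized Hamming distance between cluster and bulk
# genotype profiles, globally optimal one-to-one assignment, and label
# propagation to barcodes.

#' Normalized Hamming distance between cluster and patient profiles
#'
#' For every (cluster, patient) pair the distance is the fraction of
#' co-typed loci (both genotypes observed) at which the genotype codes
#' differ. Any inequality costs 1 (0 vs 1 counts the same as 0 vs 2);
#' set `dosage_weighted = TRUE` to cost a mismatch by `|code difference|/2`
#' instead. Per-pair normalization by the co-typed count prevents clusters
#' with heavy missingness from looking artificially close. Pairs supported
#' by fewer than `min_support` co-typed loci are flagged invalid (`NA`
#' distance) and only enter the assignment with a last-resort penalty.
#'
#' @param cluster_profiles,bulk_profiles `profile_matrix` objects (or lists
#'   of profiles, harmonized in union mode). They are aligned internally on
#'   the union of their loci.
#' @param min_support Minimum co-typed loci for a pair to be considered
#'   valid (default 50).
#' @param dosage_weighted Use allele-dosage mismatch costs (default `FALSE`).
#' @return An object of class `distance_matrix` with elements `dist`
#'   (clusters x patients, `NA` where invalid), `support` (co-typed locus
#'   counts), `clusters`, `patients`, `min_support`, `n_loci`.
#' @export
hamming_matrix <- function(cluster_profiles, bulk_profiles, min_support = 50,
                           dosage_weighted = FALSE) {
  cm <- harmonize_loci(cluster_profiles)
  bm <- harmonize_loci(bulk_profiles)
  if (!any(cm$loci$key %in% bm$loci$key)) {
    stop("cluster and bulk profiles share no loci", call. = FALSE)
  }
  if (min_support < 1L) stop("min_support must be >= 1", call. = FALSE)
  al <- align_matrices(cm, bm)
  C <- al$a
  B <- al$b
  k <- ncol(C)
  p <- ncol(B)
  d <- matrix(NA_real_, k, p, dimnames = list(colnames(C), colnames(B)))
  support <- matrix(0L, k, p, dimnames = dimnames(d))
  for (i in seq_len(k)) {
    ci <- C[, i]
    typed_c <- !is.na(ci)
    for (j in seq_len(p)) {
      both <- typed_c & !is.na(B[, j])
      n <- sum(both)
      support[i, j] <- n
      if (n >= min_support) {
        if (dosage_weighted) {
          d[i, j] <- sum(abs(ci[both] - B[both, j])) / (2 * n)
        } else {
          d[i, j] <- sum(ci[both] != B[both, j]) / n
        }
      }
    }
  }
  dead <- rowSums(!is.na(d)) == 0L
  if (any(dead)) {
    stop("cluster(s) with no validly supported patient pairing: ",
         paste(colnames(C)[dead], collapse = ", "),
         " (support < ", min_support, " everywhere)", call. = FALSE)
  }
  structure(
    list(dist = d, support = support,
         clusters = colnames(C), patients = colnames(B),
         min_support = as.integer(min_support), n_loci = nrow(al$loci)),
    class = "distance_matrix"
  )
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d clusters x %d patients over %d loci\n",
              length(x$clusters), length(x$patients), x$n_loci))
  print(round(x$dist, 3))
  invisible(x)
}

#' Kuhn-Munkres cluster-to-patient assignment
#'
#' Solves the minimum-total-distance injective mapping of clusters to
#' patients with the Hungarian algorithm. Invalid pairs (insufficient
#' support) are replaced by a finite penalty larger than any valid distance,
#' keeping the problem solvable while making such pairings last-resort.
#' Ties are broken deterministically by index order.
#'
#' The reported per-cluster `margin` is the best alternative distance in the
#' cluster's row minus the chosen distance. Because the algorithm optimizes
#' the total (not each row), a margin can be negative; it is reported as-is
#' so users can audit clusters whose globally optimal patient is not their
#' row minimum.
#'
#' @param dist A `distance_matrix` from [hamming_matrix()], or a plain
#'   numeric matrix of costs (rows = clusters, columns = patients).
#' @param penalty Finite cost substituted for invalid pairs (default 2,
#'   above the maximum possible normalized distance of 1).
#' @return An object of class `assignment_result`: `mapping` (named
#'   character vector cluster -> patient), `per_cluster_distance`, `margin`,
#'   `total_cost`, `unmatched_patients`, and the `penalized` logical vector
#'   marking clusters whose chosen pair was invalid.
#' @export
kuhn_munkres <- function(dist, penalty = 2) {
  if (inherits(dist, "distance_matrix")) {
    d <- dist$dist
  } else {
    d <- as.matrix(dist)
    if (is.null(rownames(d))) rownames(d) <- paste0("c", seq_len(nrow(d)) - 1)
    if (is.null(colnames(d))) colnames(d) <- paste0("p", seq_len(ncol(d)))
  }
  if (nrow(d) > ncol(d)) {
    stop("more clusters than patients; check the pool composition ",
         "(every cluster needs its own patient)", call. = FALSE)
  }
  cost <- d
  cost[is.na(cost)] <- penalty
  sel <- solve_assignment(cost)
  clusters <- rownames(d)
  patients <- colnames(d)
  chosen <- patients[sel]
  names(chosen) <- clusters
  per_dist <- d[cbind(seq_len(nrow(d)), sel)]
  margin <- vapply(seq_len(nrow(d)), function(i) {
    others <- d[i, -sel[i]]
    if (all(is.na(others))) NA_real_ else min(others, na.rm = TRUE) - d[i, sel[i]]
  }, numeric(1))
  names(per_dist) <- names(margin) <- clusters
  structure(
    list(mapping = chosen,
         per_cluster_distance = per_dist,
         margin = margin,
         total_cost = sum(cost[cbind(seq_len(nrow(d)), sel)]),
         unmatched_patients = setdiff(patients, chosen),
         penalized = stats::setNames(is.na(per_dist), clusters)),
    class = "assignment_result"
  )
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("<assignment_result>\n")
  tab <- data.frame(cluster = names(x$mapping), patient = x$mapping,
                    distance = round(x$per_cluster_distance, 4),
                    margin = round(x$margin, 4), row.names = NULL)
  print(tab)
  cat(sprintf("total cost: %.4f", x$total_cost))
  if (length(x$unmatched_patients)) {
    cat("; unmatched patients:", paste(x$unmatched_patients, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Propagate cluster-to-patient labels to barcodes
#'
#' Singlet barcodes receive the patient mapped to their cluster; doublet and
#' unassigned barcodes pass through with a `doublet`/`unassigned` patient
#' field. The row count never changes.
#'
#' @param result An `assignment_result` (or a named cluster -> patient
#'   character vector).
#' @param cells Data.frame with columns `barcode`, `status`, `cluster`
#'   (see [read_souporcell_clusters()]).
#' @return `cells` with a `patient` column added/overwritten.
#' @export
assign_cells <- function(result, cells) {
  mapping <- if (inherits(result, "assignment_result")) result$mapping else result
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  need <- c("barcode", "status", "cluster")
  if (!all(need %in% names(cells))) {
    stop("cells table must have columns barcode, status, cluster",
         call. = FALSE)
  }
  singlet <- cells$status == "singlet"
  unknown <- setdiff(unique(cells$cluster[singlet]), names(mapping))
  if (length(unknown)) {
    stop("singlet cluster(s) absent from the assignment mapping: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cells$patient <- NA_character_
  cells$patient[singlet] <- unname(mapping[cells$cluster[singlet]])
  cells$patient[cells$status == "doublet"] <- "doublet"
  cells$patient[cells$status == "unassigned"] <- "unassigned"
  cells
}

#' Assign clusters to known reference groups
#'
#' When reference labels (e.g. sorted cell populations, cell tags) exist per
#' barcode, clusters can be matched to groups instead of patients: the
#' clusters x groups contingency table of shared singlet barcodes is built
#' and the injective mapping maximizing total overlap is solved with the
#' same Kuhn-Munkres core on negated counts. Ties are resolved by index
#' order and reported with a warning.
#'
#' @param cells Data.frame with `barcode`, `status`, `cluster` columns.
#' @param reference Named character vector: barcode -> group label.
#' @return Named character vector cluster -> group, with the contingency
#'   table in attribute `overlap`.
#' @export
assign_to_groups <- function(cells, reference) {
  stopifnot(is.character(reference), !is.null(names(reference)))
  singlets <- cells[cells$status == "singlet", , drop = FALSE]
  shared <- singlets[singlets$barcode %in% names(reference), , drop = FALSE]
  if (nrow(shared) == 0L) {
    stop("no singlet barcodes shared with the reference labels", call. = FALSE)
  }
  tab <- table(cluster = shared$cluster,
               group = reference[shared$barcode])
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  if (nrow(counts) > ncol(counts)) {
    stop("more clusters than reference groups; injective cluster-to-group ",
         "mapping impossible", call. = FALSE)
  }
  sel <- solve_assignment(-counts)
  mapping <- colnames(counts)[sel]
  names(mapping) <- rownames(counts)
  # a tie: some cluster's chosen overlap equals an unchosen alternative
  tied <- vapply(seq_len(nrow(counts)), function(i) {
    any(counts[i, -sel[i]] == counts[i, sel[i]])
  }, logical(1))
  if (any(tied)) {
    warning("overlap ties for cluster(s) ",
            paste(rownames(counts)[tied], collapse = ", "),
            "; resolved by index order", call. = FALSE)
  }
  attr(mapping, "overlap") <- counts
  mapping
}

#' Write the cluster-to-patient mapping as a TSV
#'
#' Emits one row per cluster: `cluster`, `patient`, `distance`, `margin`,
#' `support` — the table behind a matching heatmap.
#'
#' @param result An `assignment_result`.
#' @param dist The `distance_matrix` the assignment was computed from.
#' @param path Output path.
#' @export
write_mapping_table <- function(result, dist, path) {
  cl <- names(result$mapping)
  tab <- data.frame(
    cluster = cl,
    patient = unname(result$mapping),
    distance = unname(result$per_cluster_distance),
    margin = unname(result$margin),
    support = dist$support[cbind(match(cl, dist$clusters),
                                 match(result$mapping, dist$patients))],
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(tab, as.character), sep = "\t")), con)
  invisible(tab)
}

#' Write a distance matrix as a TSV
#'
#' @param dist A `distance_matrix`.
#' @param path Output path.
#' @export
write_distance_table <- function(dist, path) {
  m <- dist$dist
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("cluster", colnames(m)), collapse = "\t"), con)
  writeLines(paste(rownames(m),
                   apply(m, 1, function(r) paste(r, collapse = "\t")),
                   sep = "\t"), con)
  invisible(m)
}
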
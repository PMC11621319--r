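# VCF reading is delegated to vcfR; this module only turns parsed records
# into genotype profiles: QUAL/DP filtering, multi-allelic splitting, and
# GT -> dosage recoding.

#' Read genotype profiles from a VCF file
#'
#' Reads a VCF (plain or bgzipped) and returns one genotype profile per
#' sample column. Records are filtered on `QUAL` and record-level depth,
#' multi-allelic records are split into one biallelic key per ALT (the GT is
#' recoded against each ALT in turn), and genotypes are encoded as the
#' diploid ALT dosage: 0 (hom-ref), 1 (het), 2 (hom-alt), `NA` (missing,
#' e.g. `./.`). Phasing is ignored (`0|1` equals `0/1`); for non-diploid
#' calls the code is 0 when no ALT copy is present, 2 when all allele copies
#' are the ALT, and 1 otherwise.
#'
#' @param path Path to a VCF v4.x file with GT in FORMAT.
#' @param min_qual Minimum record QUAL; records below are skipped. Records
#'   with missing QUAL (`.`) are kept. Default 20.
#' @param min_depth Minimum record depth; when an `INFO/DP` (or, failing
#'   that, any per-sample `FORMAT/DP`) is present and the record maximum is
#'   below this, the record is skipped. Default 5, mirroring a
#'   `--min-coverage 5` bulk variant-calling setting.
#' @param snps_only Keep only single-nucleotide substitutions (default
#'   `TRUE`); set `FALSE` to retain indel keys.
#' @return A named list of [genotype_profile()] objects, one per VCF sample.
#' @export
read_vcf_profiles <- function(path, min_qual = 20, min_depth = 5,
                              snps_only = TRUE) {
  if (!file.exists(path)) {
    stop("cannot read VCF file: ", path, call. = FALSE)
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) {
    stop("VCF has no sample columns: ", path, call. = FALSE)
  }
  samples <- colnames(gt)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample names in VCF: ", path, call. = FALSE)
  }
  format <- gt[, 1]
  if (any(!grepl("(^|:)GT(:|$)", format))) {
    stop("VCF records without a GT field: ", path, call. = FALSE)
  }

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  keep <- is.na(qual) | qual >= min_qual

  # record-level depth: INFO/DP if present, else max per-sample FORMAT/DP
  info <- fix[, "INFO"]
  info_dp <- rep(NA_real_, nrow(fix))
  has_dp <- !is.na(info) & grepl("(^|;)DP=", info)
  info_dp[has_dp] <- suppressWarnings(as.numeric(
    sub(".*(?:^|;)DP=([0-9.]+).*", "\\1", info[has_dp], perl = TRUE)))
  fmt_fields <- strsplit(format, ":", fixed = TRUE)
  dp_idx <- vapply(fmt_fields, function(f) match("DP", f), integer(1))
  rec_dp <- info_dp
  need_fmt <- is.na(rec_dp) & !is.na(dp_idx)
  if (any(need_fmt)) {
    for (i in which(need_fmt)) {
      vals <- suppressWarnings(as.numeric(vapply(
        strsplit(gt[i, -1], ":", fixed = TRUE),
        function(x) if (length(x) >= dp_idx[i]) x[dp_idx[i]] else NA_character_,
        character(1))))
      rec_dp[i] <- if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
    }
  }
  keep <- keep & (is.na(rec_dp) | rec_dp >= min_depth)
  if (!any(keep)) {
    stop("no VCF records pass the QUAL/DP filters: ", path, call. = FALSE)
  }

  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, -1, drop = FALSE]
  fmt_fields <- fmt_fields[keep]
  gt_idx <- vapply(fmt_fields, function(f) match("GT", f), integer(1))

  gt_strings <- matrix(NA_character_, nrow(gt), ncol(gt))
  for (i in seq_len(nrow(gt))) {
    gt_strings[i, ] <- vapply(strsplit(gt[i, ], ":", fixed = TRUE),
                              function(x) x[gt_idx[i]], character(1))
  }

  # split multi-allelic records: one key per ALT, GT recoded per ALT
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- rep.int(seq_len(nrow(fix)), n_alt)
  alt_rank <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  alt_vec <- unlist(alts, use.names = FALSE)

  loci <- variant_keys(fix[rec, "CHROM"], fix[rec, "POS"],
                       fix[rec, "REF"], alt_vec)
  if (snps_only) {
    snp <- nchar(loci$ref) == 1L & nchar(loci$alt) == 1L
    loci <- loci[snp, , drop = FALSE]
    rec <- rec[snp]
    alt_rank <- alt_rank[snp]
  }
  if (anyDuplicated(loci$key)) {
    dup <- !duplicated(loci$key)
    loci <- loci[dup, , drop = FALSE]
    rec <- rec[dup]
    alt_rank <- alt_rank[dup]
  }
  if (nrow(loci) == 0L) {
    stop("no variant keys left after filtering: ", path, call. = FALSE)
  }

  codes <- matrix(NA_integer_, nrow(loci), length(samples),
                  dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    codes[, j] <- encode_gt(gt_strings[rec, j], alt_rank)
  }
  out <- lapply(samples, function(s) genotype_profile(s, loci, codes[, s]))
  names(out) <- samples
  out
}

# Recode GT strings against a given ALT index (1 = first ALT, ...).
# Returns the ALT dosage 0/1/2 (NA when any allele is uncalled).
encode_gt <- function(gt, alt_index) {
  alleles <- strsplit(gt, "[/|]")
  vapply(seq_along(alleles), function(i) {
    a <- alleles[[i]]
    if (length(a) == 0L || anyNA(a) || any(a == ".") || any(!nzchar(a))) {
      return(NA_integer_)
    }
    ai <- suppressWarnings(as.integer(a))
    if (any(is.na(ai))) return(NA_integer_)
    copies <- sum(ai == alt_index[i])
    if (copies == 0L) 0L else if (copies == length(ai)) 2L else 1L
  }, integer(1))
}

#' Write a per-barcode assignment table
#'
#' Writes the per-cell demultiplexing result as a tab-separated table with
#' columns `barcode`, `status`, `cluster`, `patient` plus any extra metadata
#' columns present. Rows are barcode-sorted, so output is byte-identical
#' across runs on identical input; `NA` cluster/patient fields are written
#' as `none`, and the table round-trips losslessly through
#' [read_assignment_table()].
#'
#' @param cells A cell assignment data.frame (see [assign_cells()]).
#' @param path Output path.
#' @return Invisibly, the normalized table that was written.
#' @export
write_assignment_table <- function(cells, path) {
  if (is.null(cells) || nrow(cells) == 0L) {
    stop("empty assignment table; nothing to write", call. = FALSE)
  }
  req <- c("barcode", "status", "cluster", "patient")
  missing_cols <- setdiff(req, names(cells))
  if (length(missing_cols)) {
    stop("assignment table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cells <- cells[order(cells$barcode, method = "radix"), , drop = FALSE]
  cells <- cells[, c(req, setdiff(names(cells), req)), drop = FALSE]
  out <- cells
  out$cluster <- ifelse(is.na(out$cluster), "none", as.character(out$cluster))
  out$patient <- ifelse(is.na(out$patient), "none", as.character(out$patient))
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("cannot write assignment table to ", path, ": ",
         conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
  writeLines(body, con)
  invisible(cells)
}

#' Read an assignment table written by [write_assignment_table()]
#'
#' @param path Path to the TSV file.
#' @return A data.frame with `NA` restored in the `cluster`/`patient`
#'   columns where `none` was written.
#' @export
read_assignment_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  tab$cluster[tab$cluster == "none"] <- NA_character_
  tab$patient[tab$patient == "none"] <- NA_character_
  tab
}

#' Read a Souporcell-style clusters table
#'
#' Parses a `clusters.tsv`-format file: one row per barcode with columns
#' `barcode`, `status` (singlet/doublet/unassigned) and `assignment` (the
#' cluster id for singlets; a `i/j` pair for doublets). Extra columns such
#' as log-likelihoods are ignored.
#'
#' @param path Path to the clusters table.
#' @return A data.frame with columns `barcode`, `status`, `cluster`
#'   (`NA` for non-singlet rows).
#' @export
read_souporcell_clusters <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  need <- c("barcode", "status", "assignment")
  if (!all(need %in% names(tab))) {
    stop("clusters table must have columns barcode, status, assignment",
         call. = FALSE)
  }
  bad <- setdiff(unique(tab$status), c("singlet", "doublet", "unassigned"))
  if (length(bad)) {
    stop("unknown status values in clusters table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  data.frame(
    barcode = tab$barcode,
    status = tab$status,
    cluster = ifelse(tab$status == "singlet", tab$assignment, NA_character_),
    stringsAsFactors = FALSE
  )
}

# Minimal deterministic VCF v4.2 writer used by the simulator. `codes` is a
# loci x samples integer matrix (NA = ./.). Writes uncompressed text.
write_vcf <- function(loci, codes, path, source = "poolmux") {
  samples <- colnames(codes)
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(codes), ncol(codes))
  typed <- !is.na(codes)
  gt[typed] <- gt_map[as.character(codes[typed])]
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=%s", source),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  body <- paste(loci$chrom, loci$pos, ".", loci$ref, loci$alt, "100",
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
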
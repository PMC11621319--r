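# Genotype codes: diploid ALT-allele dosage.
#   0 = hom-ref, 1 = het (>=1 ALT copy together with another allele),
#   2 = hom-alt, NA = missing (typed locus with an uncallable genotype).

GT_CODES <- c(0L, 1L, 2L)

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix (case-insensitive) so references with and
#' without the prefix (e.g. GRCh38 "chr1" vs "1") interoperate when variant
#' keys are matched across files.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

#' Build variant keys
#'
#' A variant key is the canonical identity of one biallelic REF->ALT pair:
#' normalized chromosome, 1-based position, uppercase REF and ALT alleles.
#' Multi-allelic VCF records are split upstream so each key carries exactly
#' one ALT. Keys are totally ordered by (chrom, pos, ref, alt), which makes
#' every downstream output deterministic.
#'
#' @param chrom,pos,ref,alt Parallel vectors describing the variants.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`, `key`
#'   (the string `chrom:pos:ref:alt`).
#' @export
variant_keys <- function(chrom, pos, ref, alt) {
  chrom <- normalize_chrom(chrom)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("variant positions must be integers >= 1", call. = FALSE)
  }
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    stop("REF and ALT alleles must be non-empty", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("REF and ALT alleles must differ", call. = FALSE)
  }
  data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    key = paste(chrom, pos, ref, alt, sep = ":"),
    stringsAsFactors = FALSE
  )
}

order_keys <- function(loci) {
  order(loci$chrom, loci$pos, loci$ref, loci$alt, method = "radix")
}

#' Construct a genotype profile
#'
#' One sample's (patient's or cluster's) SNP profile: a set of variant keys
#' with a genotype code at each. A locus typed as missing (`NA` code) is
#' distinct from a locus absent from the profile's source file; the former
#' participates in locus harmonization, the latter does not.
#'
#' @param sample_id Sample identifier (unique within any profile collection).
#' @param loci A `variant_keys()` data.frame.
#' @param codes Integer vector of genotype codes (0/1/2/`NA`), parallel to
#'   `loci`.
#' @return An object of class `genotype_profile`.
#' @export
genotype_profile <- function(sample_id, loci, codes) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  codes <- as.integer(codes)
  if (nrow(loci) != length(codes)) {
    stop("loci and codes must have equal length", call. = FALSE)
  }
  if (any(!is.na(codes) & !codes %in% GT_CODES)) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (anyDuplicated(loci$key)) {
    stop("duplicate variant keys in profile '", sample_id, "'", call. = FALSE)
  }
  o <- order_keys(loci)
  structure(
    list(sample_id = sample_id,
         loci = loci[o, , drop = FALSE],
         codes = codes[o]),
    class = "genotype_profile"
  )
}

#' @export
print.genotype_profile <- function(x, ...) {
  n <- length(x$codes)
  cat(sprintf("<genotype_profile> sample '%s': %d loci (%d typed)\n",
              x$sample_id, n, sum(!is.na(x$codes))))
  invisible(x)
}

#' Construct a profile matrix
#'
#' Harmonized loci-by-samples genotype table. Rows are variant keys in
#' canonical order; `NA` entries mark locus/sample pairs that are untyped or
#' missing (the observation mask is `!is.na(codes)`).
#'
#' @param loci A `variant_keys()` data.frame (rows unique).
#' @param codes Integer matrix, `nrow(loci)` x `n samples`, with column
#'   names giving unique sample ids.
#' @return An object of class `profile_matrix`.
#' @export
profile_matrix <- function(loci, codes) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) != nrow(loci)) {
    stop("codes must have one row per locus", call. = FALSE)
  }
  if (is.null(colnames(codes)) || anyDuplicated(colnames(codes))) {
    stop("codes must carry unique sample ids as column names", call. = FALSE)
  }
  if (anyDuplicated(loci$key)) stop("duplicate loci", call. = FALSE)
  if (any(!is.na(codes) & !codes %in% GT_CODES)) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  o <- order_keys(loci)
  structure(
    list(loci = loci[o, , drop = FALSE],
         samples = colnames(codes),
         codes = codes[o, , drop = FALSE]),
    class = "profile_matrix"
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d loci x %d samples (%.1f%% typed)\n",
              nrow(x$codes), ncol(x$codes),
              100 * mean(!is.na(x$codes))))
  cat(" samples:", paste(utils::head(x$samples, 8), collapse = ", "),
      if (length(x$samples) > 8) "..." else "", "\n")
  invisible(x)
}

#' Harmonize loci across genotype profiles
#'
#' Aligns a set of genotype profiles onto a common, sorted locus set.
#' `intersection` keeps only variant keys present (typed or missing) in every
#' profile's source file; `union` keeps all keys and marks untyped
#' locus/sample pairs as missing. Chromosome names are normalized when the
#' keys are built, so "chr1" and "1" collate together.
#'
#' @param profiles List of `genotype_profile` objects (>= 2, unique ids),
#'   or a single `profile_matrix` (returned as-is after validation, so the
#'   operation is idempotent).
#' @param mode `"union"` (default) or `"intersection"`.
#' @return A `profile_matrix`.
#' @export
harmonize_loci <- function(profiles, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (inherits(profiles, "profile_matrix")) return(profiles)
  if (inherits(profiles, "genotype_profile")) profiles <- list(profiles)
  if (length(profiles) < 2L) {
    stop("harmonization needs at least two profiles", call. = FALSE)
  }
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  key_sets <- lapply(profiles, function(p) p$loci$key)
  keys <- if (mode == "intersection") {
    Reduce(intersect, key_sets)
  } else {
    unique(unlist(key_sets, use.names = FALSE))
  }
  if (length(keys) == 0L) {
    stop("no shared loci across profiles (intersection mode)", call. = FALSE)
  }
  all_loci <- do.call(rbind, lapply(profiles, function(p) p$loci))
  loci <- all_loci[!duplicated(all_loci$key), , drop = FALSE]
  loci <- loci[loci$key %in% keys, , drop = FALSE]
  codes <- matrix(NA_integer_, nrow = nrow(loci), ncol = length(profiles),
                  dimnames = list(NULL, ids))
  for (j in seq_along(profiles)) {
    idx <- match(loci$key, profiles[[j]]$loci$key)
    codes[, j] <- profiles[[j]]$codes[idx]
  }
  profile_matrix(loci, codes)
}

#' Split a profile matrix back into genotype profiles
#'
#' Inverse of [harmonize_loci()] up to untyped loci: each sample column
#' becomes a profile over the matrix's full locus set (missing entries keep
#' code `NA`).
#'
#' @param pm A `profile_matrix`.
#' @return Named list of `genotype_profile` objects.
#' @export
profiles_from_matrix <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  out <- lapply(pm$samples, function(s) {
    genotype_profile(s, pm$loci, pm$codes[, s])
  })
  names(out) <- pm$samples
  out
}

# Align two profile matrices onto the union of their loci.
align_matrices <- function(a, b) {
  stopifnot(inherits(a, "profile_matrix"), inherits(b, "profile_matrix"))
  all_loci <- rbind(a$loci, b$loci)
  loci <- all_loci[!duplicated(all_loci$key), , drop = FALSE]
  o <- order_keys(loci)
  loci <- loci[o, , drop = FALSE]
  expand <- function(pm) {
    m <- matrix(NA_integer_, nrow(loci), ncol(pm$codes),
                dimnames = list(NULL, pm$samples))
    idx <- match(pm$loci$key, loci$key)
    m[idx, ] <- pm$codes
    m
  }
  list(loci = loci, a = expand(a), b = expand(b))
}
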
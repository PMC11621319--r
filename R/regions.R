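# Genomic-region stratification of recovered SNPs: where in gene models do
# the usable variants sit (CDS, UTRs, introns, intergenic)? Bulk RNA-seq
# recovers UTR/intronic SNPs that exome capture misses, which matters for
# 3' and single-nucleus assays; these counts quantify that.

REGION_LEVELS <- c("CDS", "UTR5", "UTR3", "intron", "other", "intergenic")

normalize_region_class <- function(x) {
  x <- tolower(gsub("[^a-z0-9']", "", tolower(x)))
  out <- rep("other", length(x))
  out[x %in% c("cds", "codingsequence", "coding")] <- "CDS"
  out[x %in% c("5'utr", "utr5", "fiveprimeutr", "5utr")] <- "UTR5"
  out[x %in% c("3'utr", "utr3", "threeprimeutr", "3utr")] <- "UTR3"
  out[x %in% "intron"] <- "intron"
  out[x %in% c("gene", "transcript")] <- "gene"
  out[x %in% "exon"] <- "exon"
  out
}

#' Read a gene annotation for region stratification
#'
#' Accepts BED (0-based half-open; the 4th/name column carries the feature
#' class) or a minimal GTF subset (features `gene`, `exon`, `CDS`,
#' `five_prime_utr`, `three_prime_utr`; attributes are ignored). All
#' intervals are converted to the package's internal 1-based closed
#' convention and chromosome names are normalized. When the annotation has
#' gene and exon intervals but no explicit introns, introns are derived as
#' gene span minus exon span.
#'
#' @param path Annotation file path.
#' @param format `"bed"` or `"gtf"`; default guessed from the extension.
#' @return A `GRanges` with a `class` metadata column over
#'   `CDS/UTR5/UTR3/intron/other`.
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gtf"
  }
  gr <- rtracklayer::import(path, format = format)
  if (any(GenomicRanges::width(gr) < 1L)) {
    stop("malformed annotation interval (end < start) in ", path,
         call. = FALSE)
  }
  raw_class <- if (format == "bed") {
    if (is.null(gr$name)) stop("BED annotation needs a class in column 4",
                               call. = FALSE)
    gr$name
  } else {
    as.character(gr$type)
  }
  cls <- normalize_region_class(raw_class)
  GenomeInfoDb::seqlevels(gr) <- normalize_chrom(GenomeInfoDb::seqlevels(gr))
  gr$class <- cls

  # derive introns when only gene + exon structure is given
  if (!any(cls == "intron") && any(cls == "gene")) {
    exonic <- gr[cls %in% c("exon", "CDS", "UTR5", "UTR3")]
    if (length(exonic)) {
      introns <- GenomicRanges::setdiff(
        GenomicRanges::reduce(gr[cls == "gene"], ignore.strand = TRUE),
        GenomicRanges::reduce(exonic, ignore.strand = TRUE),
        ignore.strand = TRUE
      )
      if (length(introns)) {
        introns$class <- "intron"
        gr <- c(gr[, "class"], introns)
      } else {
        gr <- gr[, "class"]
      }
    } else {
      gr <- gr[, "class"]
    }
  } else {
    gr <- gr[, "class"]
  }
  gr[gr$class %in% c("CDS", "UTR5", "UTR3", "intron", "other", "gene")]
}

#' Stratify variant loci by genomic region
#'
#' Classifies each variant position into exactly one category with the
#' priority `CDS > 5'UTR > 3'UTR > intron > other > intergenic` when
#' intervals overlap; positions outside every annotated interval are
#' intergenic. Intervals classed `gene` count as `intron` context only via
#' derived introns (see [read_annotation()]); a bare `gene` hit with no
#' finer feature is reported as `other`.
#'
#' @param loci A `variant_keys()` data.frame, a `profile_matrix`, or a
#'   `GRanges` of positions.
#' @param annotation A `GRanges` with a `class` column (see
#'   [read_annotation()]).
#' @return Named integer vector of counts over
#'   `CDS, UTR5, UTR3, intron, other, intergenic`; sums to the number of
#'   input loci.
#' @export
annotate_regions <- function(loci, annotation) {
  if (inherits(loci, "profile_matrix")) loci <- loci$loci
  if (inherits(loci, "GRanges")) {
    pos <- GenomicRanges::GRanges(
      normalize_chrom(as.character(GenomicRanges::seqnames(loci))),
      IRanges::IRanges(GenomicRanges::start(loci),
                       GenomicRanges::start(loci)))
  } else {
    pos <- GenomicRanges::GRanges(
      loci$chrom, IRanges::IRanges(loci$pos, loci$pos))
  }
  stopifnot(inherits(annotation, "GRanges"), !is.null(annotation$class))
  if (any(GenomicRanges::width(annotation) < 1L)) {
    stop("malformed annotation interval (end < start)", call. = FALSE)
  }
  cls <- annotation$class
  cls[cls == "gene"] <- "other"
  prio <- match(cls, REGION_LEVELS)   # lower = higher priority
  hits <- GenomicRanges::findOverlaps(pos, annotation, ignore.strand = TRUE)
  assigned <- rep(NA_integer_, length(pos))
  if (length(hits)) {
    h <- data.frame(q = S4Vectors::queryHits(hits),
                    p = prio[S4Vectors::subjectHits(hits)])
    best <- tapply(h$p, h$q, min)
    assigned[as.integer(names(best))] <- as.integer(best)
  }
  assigned[is.na(assigned)] <- match("intergenic", REGION_LEVELS)
  counts <- tabulate(assigned, nbins = length(REGION_LEVELS))
  stats::setNames(as.integer(counts), REGION_LEVELS)
}
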
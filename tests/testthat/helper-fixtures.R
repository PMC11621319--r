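# Shared fixtures and independent oracles, built in code.

# profile over one synthetic chromosome; pos gives locus identity
mk_profile <- function(id, pos, codes, chrom = "1") {
  genotype_profile(
    id,
    variant_keys(rep(chrom, length(pos)), pos,
                 rep("A", length(pos)), rep("G", length(pos))),
    codes
  )
}

# hand-written VCF fixture
write_vcf_lines <- function(records, samples = "S1",
                            path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, qual, gt, info = ".",
                    format = "GT") {
  paste(chrom, pos, ".", ref, alt, qual, ".", info, format,
        paste(gt, collapse = "\t"), sep = "\t")
}

# independent brute-force oracle for the minimum-cost injective assignment
all_perms <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      rec <- function(v) {
        if (length(v) <= 1L) return(matrix(v, 1))
        do.call(rbind, lapply(seq_along(v), function(i) {
          cbind(v[i], rec(v[-i]))
        }))
      }
      cache[[key]] <<- rec(seq_len(n))
    }
    cache[[key]]
  }
})

brute_min_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  P <- all_perms(n)
  best <- Inf
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    vals <- apply(P, 1, function(p) sum(cost[cbind(seq_len(n), cols[p])]))
    best <- min(best, vals)
  }
  best
}

# brute-force max-min pool oracle
brute_best_pool <- function(disc, k) {
  n <- nrow(disc)
  best_val <- -Inf
  best <- NULL
  for (idx in utils::combn(n, k, simplify = FALSE)) {
    val <- min(disc[idx, idx][upper.tri(diag(k))])
    if (val > best_val) {
      best_val <- val
      best <- idx
    }
  }
  list(pool = rownames(disc)[best], value = best_val)
}

# toy three-feature gene annotation as GRanges
toy_annotation <- function() {
  gr <- GenomicRanges::GRanges(
    "1",
    IRanges::IRanges(
      start = c(100, 201, 1000, 1000, 1400, 2000, 2300),
      end   = c(200, 300, 1500, 1100, 1500, 2500, 2400)
    )
  )
  gr$class <- c("CDS", "UTR3", "gene", "CDS", "UTR3", "gene", "CDS")
  gr
}
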
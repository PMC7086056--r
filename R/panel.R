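#' Microhaplotype panel definition
#'
#' A microhaplotype locus is a short (<150 bp) amplicon containing several
#' SNPs; the phased combination of bases at those SNPs on a single read is a
#' multiallelic marker. A panel bundles, per locus, the reference sequence,
#' the 0-based SNP offsets within it, and the haplotype (allele) strings.
#'
#' @param loci A list of locus definitions; each element is a list with
#'   `locus_id`, `ref_seq` (DNA string), `snp_offsets` (0-based, strictly
#'   increasing positions within `ref_seq`) and `alleles` (character vector
#'   of haplotype strings over A/C/G/T, each of length
#'   `length(snp_offsets)`).
#' @return An object of class `microhap_panel`.
#' @export
microhap_panel <- function(loci) {
  stopifnot(is.list(loci), length(loci) >= 1L)
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate locus_id in panel")
  for (l in loci) {
    off <- l$snp_offsets
    if (length(off) < 1L || is.unsorted(off, strictly = TRUE)) {
      stop(sprintf("locus %s: snp_offsets must be strictly increasing",
                   l$locus_id))
    }
    if (any(off < 0L) || any(off >= nchar(l$ref_seq))) {
      stop(sprintf("locus %s: snp_offsets outside reference", l$locus_id))
    }
    if (length(l$alleles) < 2L) {
      stop(sprintf("locus %s: need >= 2 alleles", l$locus_id))
    }
    if (anyDuplicated(l$alleles)) {
      stop(sprintf("locus %s: allele strings must be unique", l$locus_id))
    }
    if (any(nchar(l$alleles) != length(off))) {
      stop(sprintf("locus %s: allele length != number of SNP offsets",
                   l$locus_id))
    }
    if (any(!grepl("^[ACGT]+$", l$alleles))) {
      stop(sprintf("locus %s: alleles must be over A/C/G/T", l$locus_id))
    }
  }
  names(loci) <- ids
  structure(list(loci = loci), class = "microhap_panel")
}

#' @export
print.microhap_panel <- function(x, ...) {
  na <- vapply(x$loci, function(l) length(l$alleles), integer(1))
  cat(sprintf("microhap_panel: %d loci, %d alleles total (%d-%d per locus)\n",
              length(x$loci), sum(na), min(na), max(na)))
  invisible(x)
}

#' @export
length.microhap_panel <- function(x) length(x$loci)

#' Panel accessors
#'
#' @param panel A `microhap_panel`.
#' @return `panel_locus_ids`: character vector of locus ids;
#'   `panel_alleles`: named list of allele (haplotype) strings per locus.
#' @export
panel_locus_ids <- function(panel) names(panel$loci)

#' @rdname panel_locus_ids
#' @export
panel_alleles <- function(panel) lapply(panel$loci, function(l) l$alleles)

#' Write / read a panel file
#'
#' Tab-separated, one row per locus with columns `locus_id`, `ref_seq`,
#' comma-separated 0-based `snp_offsets`, and comma-separated `alleles`.
#'
#' @param panel A `microhap_panel`.
#' @param path File path.
#' @return `read_panel` returns a `microhap_panel`; `write_panel` returns
#'   `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(
    locus_id = panel_locus_ids(panel),
    ref_seq = vapply(panel$loci, function(l) l$ref_seq, character(1)),
    snp_offsets = vapply(panel$loci,
                         function(l) paste(l$snp_offsets, collapse = ","),
                         character(1)),
    alleles = vapply(panel$loci,
                     function(l) paste(l$alleles, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  loci <- lapply(seq_len(nrow(df)), function(i) {
    list(locus_id = df$locus_id[i],
         ref_seq = df$ref_seq[i],
         snp_offsets = as.integer(strsplit(df$snp_offsets[i], ",")[[1]]),
         alleles = strsplit(df$alleles[i], ",")[[1]])
  })
  microhap_panel(loci)
}

# Draw one random locus definition: reference sequence of `ref_len` bases,
# `n_snps` offsets, and `n_alleles` distinct haplotype strings. The first
# allele is the reference haplotype; the rest are mutated copies.
random_locus <- function(locus_id, n_alleles, ref_len = 100L,
                         n_snps = NULL) {
  bases <- c("A", "C", "G", "T")
  if (is.null(n_snps)) {
    n_snps <- max(2L, ceiling(log2(n_alleles)) + sample.int(2L, 1L) - 1L)
  }
  ref <- paste(sample(bases, ref_len, replace = TRUE), collapse = "")
  off <- sort(sample.int(ref_len, n_snps)) - 1L
  ref_hap <- paste(substring(ref, off + 1L, off + 1L), collapse = "")
  hap_chars <- matrix(rep(strsplit(ref_hap, "")[[1]], n_alleles),
                      nrow = n_alleles, byrow = TRUE)
  haps <- character(n_alleles)
  haps[1L] <- ref_hap
  k <- 2L
  guard <- 0L
  while (k <= n_alleles) {
    guard <- guard + 1L
    if (guard > 1000L) stop("failed to draw distinct haplotypes")
    cand <- hap_chars[1L, ]
    nmut <- sample.int(n_snps, 1L)
    sites <- sample.int(n_snps, nmut)
    for (s in sites) cand[s] <- sample(setdiff(bases, cand[s]), 1L)
    cand_s <- paste(cand, collapse = "")
    if (!cand_s %in% haps[seq_len(k - 1L)]) {
      haps[k] <- cand_s
      k <- k + 1L
    }
  }
  list(locus_id = locus_id, ref_seq = ref, snp_offsets = off,
       alleles = haps)
}
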
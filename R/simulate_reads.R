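#' Simulate merged amplicon reads as SAM (+ target-SNP VCF)
#'
#' For every individual x locus, a total read depth is drawn from the depth
#' law, reads are split between the individual's two true haplotypes with
#' Binomial(1/2), and each read is the full locus reference sequence with
#' the haplotype's bases substituted at the SNP offsets plus independent
#' per-base sequencing errors. Reads are emitted as single-end SAM records
#' aligned to the locus reference (POS 1, all-match CIGAR); read names are
#' `<individual>|<locus>|<serial>`. A VCF 4.2 of the panel's target SNP
#' sites (1-based positions) can be written alongside.
#'
#' @param genotypes A `genotype_table` whose alleles are panel haplotypes.
#' @param panel The `microhap_panel`.
#' @param sam_path Output SAM path.
#' @param vcf_path Optional output VCF path.
#' @param depth_law List: `dist = "nbinom"` with `mu` and `size`
#'   (default mean 50, dispersion 5), or `dist = "fixed"` with `depth`.
#' @param per_base_error Per-base miscall probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Invisibly, a list with the SAM/VCF paths and the number of
#'   reads written.
#' @export
simulate_reads <- function(genotypes, panel, sam_path, vcf_path = NULL,
                           depth_law = list(dist = "nbinom", mu = 50,
                                            size = 5),
                           per_base_error = 0.01, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_table"),
            inherits(panel, "microhap_panel"))
  if (per_base_error < 0 || per_base_error >= 1) {
    stop("`per_base_error` must be in [0, 1)")
  }
  local_seed(seed)
  loci <- gt_loci(genotypes)
  if (!all(loci %in% panel_locus_ids(panel))) {
    stop("genotype loci missing from panel")
  }
  draw_depth <- switch(depth_law$dist,
    nbinom = function(n) stats::rnbinom(n, mu = depth_law$mu,
                                        size = depth_law$size),
    fixed = function(n) rep(as.integer(depth_law$depth), n),
    stop(sprintf("unknown depth distribution %s", depth_law$dist))
  )
  bases <- c("A", "C", "G", "T")
  con <- file(sam_path, "w")
  on.exit(close(con), add = TRUE)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           vapply(loci, function(l) {
             sprintf("@SQ\tSN:%s\tLN:%d", l,
                     nchar(panel$loci[[l]]$ref_seq))
           }, character(1)))
  writeLines(hdr, con)
  n_reads_total <- 0L
  inds <- gt_individuals(genotypes)
  for (j in seq_along(loci)) {
    def <- panel$loci[[loci[j]]]
    len <- nchar(def$ref_seq)
    ref_chars <- strsplit(def$ref_seq, "")[[1]]
    dict <- genotypes$alleles[[loci[j]]]
    ai <- match(dict, def$alleles)
    if (anyNA(ai[unique(c(genotypes$a1[, j], genotypes$a2[, j]))])) {
      stop(sprintf("genotype allele absent from panel at locus %s",
                   loci[j]))
    }
    # pre-build the full-length read sequence of each panel haplotype
    hap_seq <- vapply(def$alleles, function(h) {
      ch <- ref_chars
      ch[def$snp_offsets + 1L] <- strsplit(h, "")[[1]]
      paste(ch, collapse = "")
    }, character(1))
    called <- which(!is.na(genotypes$a1[, j]))
    if (!length(called)) next
    depth <- draw_depth(length(called))
    n1 <- stats::rbinom(length(called), depth, 0.5)
    reads <- character(sum(depth))
    qnames <- character(sum(depth))
    pos <- 0L
    for (k in seq_along(called)) {
      if (depth[k] == 0L) next
      i <- called[k]
      h1 <- hap_seq[ai[genotypes$a1[i, j]]]
      h2 <- hap_seq[ai[genotypes$a2[i, j]]]
      rr <- c(rep(h1, n1[k]), rep(h2, depth[k] - n1[k]))
      idx <- pos + seq_len(depth[k])
      reads[idx] <- rr
      qnames[idx] <- sprintf("%s|%s|%d", inds[i], loci[j],
                             seq_len(depth[k]))
      pos <- pos + depth[k]
    }
    reads <- reads[seq_len(pos)]
    qnames <- qnames[seq_len(pos)]
    if (per_base_error > 0 && pos > 0L) {
      mat <- matrix(unlist(strsplit(reads, "")), nrow = pos, byrow = TRUE)
      err <- matrix(stats::runif(pos * len) < per_base_error, pos, len)
      if (any(err)) {
        # substitute with one of the three other bases, uniformly
        shift <- sample.int(3L, sum(err), replace = TRUE)
        cur <- match(mat[err], bases)
        mat[err] <- bases[((cur - 1L + shift) %% 4L) + 1L]
        reads <- apply(mat, 1, paste, collapse = "")
      }
    }
    if (pos > 0L) {
      qual <- strrep("I", len)
      writeLines(sprintf("%s\t0\t%s\t1\t60\t%dM\t*\t0\t0\t%s\t%s",
                         qnames, loci[j], len, reads, qual), con)
      n_reads_total <- n_reads_total + pos
    }
  }
  if (!is.null(vcf_path)) write_panel_vcf(panel, loci, vcf_path)
  invisible(list(sam = sam_path, vcf = vcf_path, n_reads = n_reads_total))
}

# VCF 4.2 with one record per panel SNP site (1-based POS).
write_panel_vcf <- function(panel, loci, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("##fileformat=VCFv4.2",
               vapply(loci, function(l) {
                 sprintf("##contig=<ID=%s,length=%d>", l,
                         nchar(panel$loci[[l]]$ref_seq))
               }, character(1)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (l in loci) {
    def <- panel$loci[[l]]
    for (s in seq_along(def$snp_offsets)) {
      site_bases <- unique(substring(def$alleles, s, s))
      ref <- substring(def$alleles[1], s, s)
      alt <- setdiff(site_bases, ref)
      writeLines(sprintf("%s\t%d\t%s_%d\t%s\t%s\t.\tPASS\t.",
                         l, def$snp_offsets[s] + 1L, l, s, ref,
                         if (length(alt)) paste(alt, collapse = ",")
                         else "."),
                 con)
    }
  }
  invisible(path)
}
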
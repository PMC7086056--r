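#' Extract per-read microhaplotypes from a SAM file
#'
#' Walks each aligned read's CIGAR to find the read base at every panel SNP
#' offset of its reference locus, preserving within-read phase. Reads that
#' cover all target offsets with aligned (non-gap) bases contribute one
#' haplotype observation; reads with a deletion or clipped/absent base at
#' any offset are discarded and counted. The individual id is taken from
#' the read name up to the first `|`.
#'
#' @param sam_path Path to a SAM file whose reference names are panel locus
#'   ids.
#' @param panel A `microhap_panel`.
#' @param vcf_sites Optional data frame (`locus_id`, `pos` 1-based)
#'   restricting extraction to a subset of the panel's SNP sites, e.g. read
#'   from a VCF with [read_vcf_sites()].
#' @return A `hap_depth_table`: data frame (`individual_id`, `locus_id`,
#'   `haplotype`, `count`) with the number of discarded reads in
#'   `attr(, "n_discarded")`.
#' @export
extract_haplotype_depths <- function(sam_path, panel, vcf_sites = NULL) {
  stopifnot(inherits(panel, "microhap_panel"))
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    out <- data.frame(individual_id = character(0),
                      locus_id = character(0), haplotype = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
    attr(out, "n_discarded") <- 0L
    class(out) <- c("hap_depth_table", "data.frame")
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 11L
  if (any(bad)) stop("malformed SAM record (fewer than 11 fields)")
  qname <- vapply(fields, `[[`, character(1), 1L)
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  rname <- vapply(fields, `[[`, character(1), 3L)
  pos <- as.integer(vapply(fields, `[[`, character(1), 4L))
  cigar <- vapply(fields, `[[`, character(1), 6L)
  seq <- vapply(fields, `[[`, character(1), 10L)
  keep <- rname != "*" & !bitwAnd(flag, 4L)
  qname <- qname[keep]; rname <- rname[keep]; pos <- pos[keep]
  cigar <- cigar[keep]; seq <- seq[keep]
  unknown <- setdiff(unique(rname), panel_locus_ids(panel))
  if (length(unknown)) {
    stop(sprintf("SAM reference %s not in panel", unknown[1]))
  }
  ind <- sub("\\|.*", "", qname)
  offsets <- lapply(panel$loci, function(l) l$snp_offsets)
  if (!is.null(vcf_sites)) {
    offsets <- lapply(stats::setNames(names(offsets), names(offsets)),
                      function(l) {
      keep_pos <- vcf_sites$pos[vcf_sites$locus_id == l] - 1L
      intersect(offsets[[l]], keep_pos)
    })
  }
  n_discarded <- 0L
  res <- list()
  for (l in unique(rname)) {
    sel <- which(rname == l)
    off1 <- offsets[[l]] + 1L # 1-based reference positions
    if (length(off1) == 0L) next
    haps <- character(length(sel))
    simple <- grepl("^[0-9]+M$", cigar[sel])
    # fast path: ungapped all-match alignments
    if (any(simple)) {
      ss <- sel[simple]
      rel <- outer(off1, pos[ss], `-`) + 1L # site x read, read coords
      rl <- nchar(seq[ss])
      okm <- rel >= 1L & sweep(rel, 2, rl, `<=`)
      hv <- matrix("", nrow(rel), ncol(rel))
      for (s in seq_len(nrow(rel))) {
        hv[s, okm[s, ]] <- substring(seq[ss][okm[s, ]], rel[s, okm[s, ]],
                                     rel[s, okm[s, ]])
      }
      full <- colSums(okm) == length(off1)
      haps[simple][full] <- apply(hv[, full, drop = FALSE], 2, paste,
                                  collapse = "")
    }
    for (k in which(!simple)) {
      haps[k] <- cigar_walk_haplotype(seq[sel[k]], cigar[sel[k]],
                                      pos[sel[k]], off1)
    }
    got <- haps != ""
    n_discarded <- n_discarded + sum(!got)
    if (any(got)) {
      tab <- stats::aggregate(
        list(count = rep(1L, sum(got))),
        by = list(individual_id = ind[sel][got], haplotype = haps[got]),
        FUN = sum)
      tab$locus_id <- l
      res[[l]] <- tab[, c("individual_id", "locus_id", "haplotype",
                          "count")]
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(individual_id = character(0), locus_id = character(0),
               haplotype = character(0), count = integer(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_discarded") <- n_discarded
  class(out) <- c("hap_depth_table", "data.frame")
  out
}

# Walk a CIGAR string and return the phased bases at the requested 1-based
# reference positions, or "" if any position is not covered by an aligned
# base (deletion, clip, or outside the read).
cigar_walk_haplotype <- function(seq, cigar, pos, ref_positions) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) == 0L) stop(sprintf("malformed CIGAR %s", cigar))
  lens <- as.integer(sub("[MIDNSHP=X]", "", ops))
  type <- sub("[0-9]+", "", ops)
  ref_at <- pos       # next reference position
  query_at <- 1L      # next query position
  found <- rep(NA_integer_, length(ref_positions))
  for (k in seq_along(ops)) {
    n <- lens[k]
    if (type[k] %in% c("M", "=", "X")) {
      hit <- which(ref_positions >= ref_at & ref_positions < ref_at + n)
      found[hit] <- query_at + (ref_positions[hit] - ref_at)
      ref_at <- ref_at + n
      query_at <- query_at + n
    } else if (type[k] %in% c("I", "S")) {
      query_at <- query_at + n
    } else if (type[k] %in% c("D", "N")) {
      ref_at <- ref_at + n
    } # H, P consume nothing
  }
  if (anyNA(found)) return("")
  paste(substring(seq, found, found), collapse = "")
}

#' Read target SNP sites from a VCF
#'
#' Minimal reader for the site-only VCFs this pipeline consumes: returns
#' the CHROM (locus id) and 1-based POS columns.
#'
#' @param path VCF path.
#' @return Data frame with `locus_id` and `pos`.
#' @export
read_vcf_sites <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(locus_id = character(0), pos = integer(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(locus_id = vapply(parts, `[[`, character(1), 1L),
             pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}

#' Call one locus genotype from haplotype read depths
#'
#' Applies the two read-count filters used for microhaplotype calling: the
#' genotype is missing when total depth is below `min_total_depth`;
#' haplotypes with `count / max(count) >= min_ratio` are retained; one
#' retained haplotype yields a homozygote, two a heterozygote, and more
#' than two a missing call flagged as a contamination anomaly.
#'
#' @param depths Named integer vector, haplotype string -> read count.
#' @param min_total_depth Minimum total depth (default 10).
#' @param min_ratio Minimum depth ratio relative to the deepest haplotype
#'   (default 0.2).
#' @return A list: `alleles` (length-2 character vector or `NULL`),
#'   `missing`, `anomaly`.
#' @export
call_locus_genotype <- function(depths, min_total_depth = 10,
                                min_ratio = 0.2) {
  if (length(depths) == 0L || sum(depths) < min_total_depth) {
    return(list(alleles = NULL, missing = TRUE, anomaly = FALSE))
  }
  if (any(depths < 0)) stop("negative read count")
  retained <- names(depths)[depths / max(depths) >= min_ratio]
  if (length(retained) == 1L) {
    list(alleles = c(retained, retained), missing = FALSE, anomaly = FALSE)
  } else if (length(retained) == 2L) {
    list(alleles = sort(retained), missing = FALSE, anomaly = FALSE)
  } else {
    list(alleles = NULL, missing = TRUE, anomaly = TRUE)
  }
}

#' Call a genotype table from haplotype depths
#'
#' Applies [call_locus_genotype()] to every (individual, locus) cell of a
#' `hap_depth_table`. The allele dictionary is the panel's haplotypes,
#' extended with any called haplotype not in the panel (e.g. real variants
#' absent from the design); anomaly flags are retained for QC.
#'
#' @param hap_depths A `hap_depth_table`.
#' @param panel A `microhap_panel`.
#' @param min_total_depth,min_ratio See [call_locus_genotype()].
#' @return A `genotype_table` covering all panel loci, with an `anomalies`
#'   flag matrix.
#' @export
call_genotypes <- function(hap_depths, panel, min_total_depth = 10,
                           min_ratio = 0.2) {
  loci <- panel_locus_ids(panel)
  inds <- sort(unique(hap_depths$individual_id))
  if (length(inds) == 0L) stop("no individuals in depth table")
  alleles <- panel_alleles(panel)
  a1 <- matrix(NA_integer_, length(inds), length(loci),
               dimnames = list(inds, loci))
  a2 <- a1
  anom <- matrix(FALSE, length(inds), length(loci),
                 dimnames = list(inds, loci))
  sp <- split(hap_depths,
              list(hap_depths$individual_id, hap_depths$locus_id),
              drop = TRUE)
  for (cell in sp) {
    i <- cell$individual_id[1]; l <- cell$locus_id[1]
    call <- call_locus_genotype(
      stats::setNames(cell$count, cell$haplotype),
      min_total_depth, min_ratio)
    anom[i, l] <- call$anomaly
    if (!call$missing) {
      new <- setdiff(call$alleles, alleles[[l]])
      if (length(new)) alleles[[l]] <- c(alleles[[l]], new)
      a1[i, l] <- match(call$alleles[1], alleles[[l]])
      a2[i, l] <- match(call$alleles[2], alleles[[l]])
    }
  }
  meta <- data.frame(individual_id = inds, stringsAsFactors = FALSE)
  genotype_table(a1, a2, alleles, meta, anomalies = anom)
}

#' Individual-level genotype QC
#'
#' Drops individuals with at least `max_missing` missing data (the
#' threshold is inclusive) and individuals whose count of
#' more-than-two-haplotype loci reaches `contamination_locus_threshold`
#' (contamination evidence). When both conditions hold, missingness is
#' reported as the reason.
#'
#' @param gt A `genotype_table` with an `anomalies` matrix (as produced by
#'   [call_genotypes()]); tables without one are treated as anomaly-free.
#' @param max_missing Missingness fraction at or above which an individual
#'   is dropped (default 0.20).
#' @param contamination_locus_threshold Number of anomalous loci at or
#'   above which an individual is dropped (default 3).
#' @return A list: `genotypes` (filtered `genotype_table`), `report`
#'   (per-individual `QCReport` data frame: `individual_id`,
#'   `missing_fraction`, `n_anomalous_loci`, `dropped`, `drop_reason`).
#' @export
apply_individual_qc <- function(gt, max_missing = 0.20,
                                contamination_locus_threshold = 3L) {
  stopifnot(inherits(gt, "genotype_table"))
  if (nrow(gt$a1) == 0L) stop("empty genotype table")
  miss <- gt_missingness(gt)
  n_anom <- if (is.null(gt$anomalies)) rep(0L, nrow(gt$a1)) else
    rowSums(gt$anomalies)
  drop_miss <- miss >= max_missing
  drop_cont <- n_anom >= contamination_locus_threshold
  reason <- ifelse(drop_miss, "missingness",
                   ifelse(drop_cont, "contamination", "none"))
  report <- data.frame(
    individual_id = gt_individuals(gt),
    missing_fraction = unname(miss),
    n_anomalous_loci = unname(n_anom),
    dropped = drop_miss | drop_cont,
    drop_reason = reason,
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  kept <- which(!report$dropped)
  list(genotypes = gt_subset(gt, individuals = kept), report = report)
}
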
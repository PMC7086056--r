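#' Multiallelic diploid genotype table
#'
#' The common container for every analysis stage. Genotypes are stored as a
#' pair of integer matrices (individual x locus) indexing into a per-locus
#' allele dictionary; `NA` encodes a missing call. Genotypes are unordered
#' and canonicalised so `a1 <= a2`.
#'
#' @param a1,a2 Integer matrices (individuals x loci) of allele indices,
#'   `NA` for missing. Row names are individual ids, column names locus ids.
#' @param alleles Named list, one character vector of allele strings per
#'   locus (the allele dictionary indexed by `a1`/`a2`).
#' @param meta Data frame of individual metadata with at least
#'   `individual_id`; optional columns `group`, `cohort_year`, `sex`
#'   (`"M"`, `"F"` or `"unknown"`), `stocking_year`, `stocking_date`,
#'   `habitat`, `true_class`.
#' @param anomalies Optional logical matrix (same shape as `a1`) flagging
#'   loci where more than two haplotypes passed the calling filters
#'   (contamination evidence).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(a1, a2, alleles, meta = NULL, anomalies = NULL) {
  stopifnot(is.matrix(a1), is.matrix(a2), all(dim(a1) == dim(a2)))
  if (nrow(a1) == 0L) {
    # R normalises zero-length dimnames to NULL, so an empty table cannot
    # carry ids; build it directly
    if (is.null(colnames(a1))) colnames(a1) <- colnames(a2) <- names(alleles)
    meta <- if (is.null(meta)) {
      data.frame(individual_id = character(0), stringsAsFactors = FALSE)
    } else {
      meta[integer(0), , drop = FALSE]
    }
    return(structure(list(a1 = a1, a2 = a2,
                          alleles = alleles[colnames(a1)], meta = meta,
                          anomalies = anomalies),
                     class = "genotype_table"))
  }
  if (is.null(rownames(a1))) stop("a1 needs individual ids as row names")
  if (is.null(colnames(a1))) stop("a1 needs locus ids as column names")
  if (!setequal(colnames(a1), names(alleles))) {
    stop("allele dictionary must cover exactly the table's loci")
  }
  alleles <- alleles[colnames(a1)]
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  if (any(is.na(a1) != is.na(a2))) stop("half-missing genotype")
  for (j in seq_len(ncol(a1))) {
    K <- length(alleles[[j]])
    v <- c(a1[, j], a2[, j])
    if (any(!is.na(v) & (v < 1L | v > K))) {
      stop(sprintf("allele index out of range at locus %s", colnames(a1)[j]))
    }
  }
  if (is.null(meta)) {
    meta <- data.frame(individual_id = rownames(a1),
                       stringsAsFactors = FALSE)
  }
  stopifnot(identical(meta$individual_id, rownames(a1)))
  structure(list(a1 = a1, a2 = a2, alleles = alleles, meta = meta,
                 anomalies = anomalies),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x$a1), ncol(x$a1), 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$a1)

#' Genotype-table accessors
#'
#' @param gt A `genotype_table`.
#' @return `gt_individuals`: individual ids; `gt_loci`: locus ids.
#' @export
gt_individuals <- function(gt) rownames(gt$a1)

#' @rdname gt_individuals
#' @export
gt_loci <- function(gt) colnames(gt$a1)

#' Subset a genotype table by individuals and/or loci
#'
#' @param gt A `genotype_table`.
#' @param individuals Character vector of individual ids, or logical/integer
#'   index (default: keep all).
#' @param loci Character vector of locus ids, or index (default: keep all).
#' @return A `genotype_table`.
#' @export
gt_subset <- function(gt, individuals = NULL, loci = NULL) {
  i <- individuals %||% seq_len(nrow(gt$a1))
  j <- loci %||% seq_len(ncol(gt$a1))
  a1 <- gt$a1[i, j, drop = FALSE]
  a2 <- gt$a2[i, j, drop = FALSE]
  an <- if (!is.null(gt$anomalies)) gt$anomalies[i, j, drop = FALSE]
  if (is.null(rownames(a1)) || is.null(colnames(a1))) {
    # R drops dimnames on zero-row subsets; restore them
    ids <- rownames(gt$a1); names(ids) <- ids
    cn <- colnames(gt$a1); names(cn) <- cn
    dn <- list(unname(ids[i]) %||% character(0), unname(cn[j]))
    dimnames(a1) <- dimnames(a2) <- dn
    if (!is.null(an)) dimnames(an) <- dn
  }
  meta <- gt$meta[match(rownames(a1), gt$meta$individual_id), , drop = FALSE]
  rownames(meta) <- NULL
  genotype_table(a1, a2, gt$alleles[colnames(a1)], meta, an)
}

#' Combine genotype tables over individuals
#'
#' Tables must share the same loci; allele dictionaries are merged and
#' indices remapped. Metadata columns are unioned (filled with `NA`).
#'
#' @param ... `genotype_table` objects.
#' @return A `genotype_table`.
#' @export
gt_rbind <- function(...) {
  gts <- list(...)
  if (length(gts) == 1L && is.list(gts[[1]]) &&
      !inherits(gts[[1]], "genotype_table")) {
    gts <- gts[[1]]
  }
  loci <- gt_loci(gts[[1]])
  for (g in gts) stopifnot(identical(gt_loci(g), loci))
  alleles <- stats::setNames(lapply(loci, function(l) {
    unique(unlist(lapply(gts, function(g) g$alleles[[l]])))
  }), loci)
  remap <- function(g) {
    a1 <- g$a1; a2 <- g$a2
    for (j in seq_along(loci)) {
      map <- match(g$alleles[[loci[j]]], alleles[[loci[j]]])
      a1[, j] <- map[g$a1[, j]]
      a2[, j] <- map[g$a2[, j]]
    }
    list(a1 = a1, a2 = a2)
  }
  mapped <- lapply(gts, remap)
  a1 <- do.call(rbind, lapply(mapped, `[[`, "a1"))
  a2 <- do.call(rbind, lapply(mapped, `[[`, "a2"))
  if (anyDuplicated(rownames(a1))) stop("duplicate individual ids")
  cols <- unique(unlist(lapply(gts, function(g) names(g$meta))))
  meta <- do.call(rbind, lapply(gts, function(g) {
    m <- g$meta
    for (cc in setdiff(cols, names(m))) m[[cc]] <- NA
    m[, cols, drop = FALSE]
  }))
  rownames(meta) <- NULL
  an <- NULL
  if (all(vapply(gts, function(g) !is.null(g$anomalies), logical(1)))) {
    an <- do.call(rbind, lapply(gts, `[[`, "anomalies"))
  }
  genotype_table(a1, a2, alleles, meta, an)
}

#' Per-individual missingness
#'
#' @param gt A `genotype_table`.
#' @return Named numeric vector, fraction of loci with a missing call.
#' @export
gt_missingness <- function(gt) rowMeans(is.na(gt$a1))

#' Write / read genotype tables as tidy CSV
#'
#' Long format with columns `individual_id`, `locus_id`, `allele1`,
#' `allele2` (allele strings); a missing genotype has empty allele fields.
#' The literal string `"NA"` is rejected on read to avoid dialect ambiguity.
#' Metadata travels in a separate CSV keyed by `individual_id`.
#'
#' @param gt A `genotype_table`.
#' @param path Genotype CSV path.
#' @param meta_path Optional metadata CSV path.
#' @param alleles Optional allele dictionary (named list per locus) fixing
#'   the allele space on read; defaults to the alleles observed in the file.
#' @return `read_genotypes` returns a `genotype_table`.
#' @export
write_genotypes <- function(gt, path, meta_path = NULL) {
  n <- nrow(gt$a1); L <- ncol(gt$a1)
  al1 <- matrix("", n, L); al2 <- matrix("", n, L)
  for (j in seq_len(L)) {
    dict <- gt$alleles[[j]]
    ok <- !is.na(gt$a1[, j])
    al1[ok, j] <- dict[gt$a1[ok, j]]
    al2[ok, j] <- dict[gt$a2[ok, j]]
  }
  df <- data.frame(
    individual_id = rep(rownames(gt$a1), times = L),
    locus_id = rep(colnames(gt$a1), each = n),
    allele1 = as.vector(al1), allele2 = as.vector(al2),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path)) {
    utils::write.csv(gt$meta, meta_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, meta_path = NULL, alleles = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0))
  need <- c("individual_id", "locus_id", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    stop("genotype CSV must have columns individual_id, locus_id, allele1, allele2")
  }
  if (any(df$allele1 == "NA" | df$allele2 == "NA")) {
    stop("literal \"NA\" found in allele fields; missing calls must be empty")
  }
  inds <- unique(df$individual_id)
  loci <- unique(df$locus_id)
  if (is.null(alleles)) {
    alleles <- lapply(stats::setNames(loci, loci), function(l) {
      v <- c(df$allele1[df$locus_id == l], df$allele2[df$locus_id == l])
      sort(unique(v[v != ""]))
    })
  }
  a1 <- matrix(NA_integer_, length(inds), length(loci),
               dimnames = list(inds, loci))
  a2 <- a1
  ri <- match(df$individual_id, inds)
  ci <- match(df$locus_id, loci)
  for (j in seq_along(loci)) {
    sel <- which(ci == j & df$allele1 != "")
    dict <- alleles[[loci[j]]]
    i1 <- match(df$allele1[sel], dict)
    i2 <- match(df$allele2[sel], dict)
    if (anyNA(i1) || anyNA(i2)) {
      stop(sprintf("allele at locus %s not in dictionary", loci[j]))
    }
    a1[cbind(ri[sel], j)] <- i1
    a2[cbind(ri[sel], j)] <- i2
  }
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    meta <- meta[match(inds, meta$individual_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  genotype_table(a1, a2, alleles, meta)
}
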
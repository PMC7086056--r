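#' Estimate per-population allele frequencies with a pseudocount
#'
#' Frequencies are `(count + pseudocount) / (copies + pseudocount * K)`
#' where `K` is the size of the locus allele dictionary (the union of
#' alleles across all analysed populations), so no allele of the dictionary
#' gets zero frequency and downstream likelihoods are never annihilated by
#' an allele unseen in one reference. Missing genotypes contribute no gene
#' copies.
#'
#' @param gt A `genotype_table`.
#' @param group_col Metadata column defining the populations (default
#'   `"group"`); or pass `groups`, a named list of individual-id vectors.
#' @param groups Optional explicit named list of individual ids.
#' @param pseudocount Added to each allele count (default 0.5).
#' @return An object of class `allele_freq_set`: `alleles` (dictionary),
#'   `freq[[pop]][[locus]]` (numeric vectors aligned to the dictionary) and
#'   `n_copies[[pop]]` (called gene copies per locus).
#' @export
estimate_allele_freqs <- function(gt, group_col = "group", groups = NULL,
                                  pseudocount = 0.5) {
  stopifnot(inherits(gt, "genotype_table"), pseudocount >= 0)
  if (is.null(groups)) {
    if (!group_col %in% names(gt$meta)) {
      stop(sprintf("metadata column `%s` not found", group_col))
    }
    gvec <- gt$meta[[group_col]]
    groups <- split(gt$meta$individual_id, gvec)
  }
  loci <- gt_loci(gt)
  freq <- list(); n_copies <- list()
  for (pop in names(groups)) {
    rows <- match(groups[[pop]], rownames(gt$a1))
    if (anyNA(rows)) stop(sprintf("unknown individuals in group %s", pop))
    f <- list(); nc <- numeric(length(loci))
    any_called <- FALSE
    for (j in seq_along(loci)) {
      K <- length(gt$alleles[[j]])
      cnt <- tabulate(c(gt$a1[rows, j], gt$a2[rows, j]), nbins = K)
      nc[j] <- sum(cnt)
      if (nc[j] > 0) any_called <- TRUE
      f[[j]] <- (cnt + pseudocount) / (sum(cnt) + pseudocount * K)
    }
    if (!any_called) {
      stop(sprintf("group %s has zero called genotypes at every locus", pop))
    }
    names(f) <- loci
    names(nc) <- loci
    freq[[pop]] <- f
    n_copies[[pop]] <- nc
  }
  structure(list(alleles = gt$alleles, freq = freq, n_copies = n_copies),
            class = "allele_freq_set")
}

#' @export
print.allele_freq_set <- function(x, ...) {
  cat(sprintf("allele_freq_set: %d population(s) x %d loci\n",
              length(x$freq), length(x$alleles)))
  invisible(x)
}

#' Diversity summary (Na, Ho, He) per population
#'
#' Mirrors the classic per-population marker summary: `Na` is the mean
#' number of alleles observed per locus, `Ho` the mean over loci of the
#' observed heterozygote fraction among called individuals, and `He` the
#' mean over loci of Nei's unbiased expected heterozygosity
#' `(2n/(2n-1)) * (1 - sum(p^2))` with `n` the called individuals at the
#' locus.
#'
#' @inheritParams estimate_allele_freqs
#' @return A data frame with one row per population (`population`, `n`,
#'   `n_loci`, `Na`, `He`, `Ho`); per-locus detail in
#'   `attr(, "per_locus")`.
#' @export
diversity_summary <- function(gt, group_col = "group", groups = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  if (is.null(groups)) {
    if (!group_col %in% names(gt$meta)) {
      stop(sprintf("metadata column `%s` not found", group_col))
    }
    groups <- split(gt$meta$individual_id, gt$meta[[group_col]])
  }
  loci <- gt_loci(gt)
  out <- NULL; detail <- NULL
  for (pop in names(groups)) {
    rows <- match(groups[[pop]], rownames(gt$a1))
    if (length(rows) == 0L) stop(sprintf("group %s is empty", pop))
    na <- he <- ho <- rep(NA_real_, length(loci))
    for (j in seq_along(loci)) {
      a1 <- gt$a1[rows, j]; a2 <- gt$a2[rows, j]
      called <- !is.na(a1)
      n <- sum(called)
      if (n == 0L) next
      cnt <- tabulate(c(a1[called], a2[called]),
                      nbins = length(gt$alleles[[j]]))
      p <- cnt / (2 * n)
      na[j] <- sum(cnt > 0)
      ho[j] <- mean(a1[called] != a2[called])
      he[j] <- if (n > 0.5) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else NA
    }
    if (all(is.na(na))) stop(sprintf("group %s has no called loci", pop))
    out <- rbind(out, data.frame(
      population = pop, n = length(rows), n_loci = sum(!is.na(na)),
      Na = mean(na, na.rm = TRUE), He = mean(he, na.rm = TRUE),
      Ho = mean(ho, na.rm = TRUE), stringsAsFactors = FALSE))
    detail <- rbind(detail, data.frame(
      population = pop, locus_id = loci, Na = na, He = he, Ho = ho,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  attr(out, "per_locus") <- detail
  out
}

#' Weir-Cockerham differentiation between two populations
#'
#' Multiallelic Weir & Cockerham (1984) theta, computed per allele and per
#' locus from the variance components a (among populations), b (among
#' individuals within populations) and c (within individuals), and combined
#' as a ratio of sums over alleles and loci. Negative per-locus components
#' are kept (not truncated) before summing.
#'
#' @param gt A `genotype_table`.
#' @param pop_a,pop_b Group labels (levels of `group_col`).
#' @param group_col Metadata column with population labels.
#' @return A list of class `fst_result`: `theta` (overall), `per_locus`
#'   (data frame with per-locus theta and components), `populations`.
#' @export
pairwise_fst <- function(gt, pop_a, pop_b, group_col = "group") {
  stopifnot(inherits(gt, "genotype_table"))
  gvec <- gt$meta[[group_col]]
  rows_a <- which(gvec == pop_a)
  rows_b <- which(gvec == pop_b)
  if (length(rows_a) == 0L || length(rows_b) == 0L) {
    stop("both populations must have individuals")
  }
  loci <- gt_loci(gt)
  per <- data.frame(locus_id = loci, a = NA_real_, abc = NA_real_,
                    theta = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(loci)) {
    pops <- lapply(list(rows_a, rows_b), function(rows) {
      a1 <- gt$a1[rows, j]; a2 <- gt$a2[rows, j]
      called <- !is.na(a1)
      K <- length(gt$alleles[[j]])
      ac <- tabulate(c(a1[called], a2[called]), nbins = K)
      het <- numeric(K)
      hrows <- which(called & a1 != a2)
      for (i in hrows) {
        het[a1[i]] <- het[a1[i]] + 1
        het[a2[i]] <- het[a2[i]] + 1
      }
      list(n = sum(called), allele_counts = ac, het_counts = het)
    })
    if (any(vapply(pops, `[[`, numeric(1), "n") < 2)) next
    comp <- wc84_locus(pops)
    per$a[j] <- comp["a"]
    per$abc[j] <- comp["abc"]
    per$theta[j] <- if (comp["abc"] != 0) comp["a"] / comp["abc"] else NA
  }
  usable <- !is.na(per$a)
  if (!any(usable)) {
    stop("no locus has >= 2 called individuals in both populations")
  }
  theta <- sum(per$a[usable]) / sum(per$abc[usable])
  structure(list(theta = theta, per_locus = per,
                 populations = c(pop_a, pop_b)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham theta (%s vs %s): %.4f over %d loci\n",
              x$populations[1], x$populations[2], x$theta,
              sum(!is.na(x$per_locus$theta))))
  invisible(x)
}

#' Principal component analysis of genotypes
#'
#' Builds the one-hot allele dosage matrix (individuals x locus-allele
#' columns, entries 0/1/2), mean-imputes missing entries, column-centres
#' (no scaling) and takes the SVD; scores are left singular vectors times
#' singular values.
#'
#' @param gt A `genotype_table` with >= 2 individuals.
#' @param n_pc Number of components to return.
#' @return A list of class `genotype_pca`: `scores` (individuals x PCs),
#'   `sdev`, `var_explained`.
#' @export
genotype_pca <- function(gt, n_pc = 10L) {
  stopifnot(inherits(gt, "genotype_table"))
  n <- nrow(gt$a1)
  if (n < 2L) stop("need >= 2 individuals")
  if (any(rowSums(!is.na(gt$a1)) == 0L)) {
    stop("all-missing individual in PCA input")
  }
  cols <- list()
  for (j in seq_len(ncol(gt$a1))) {
    K <- length(gt$alleles[[j]])
    d <- matrix(NA_real_, n, K)
    called <- !is.na(gt$a1[, j])
    d[called, ] <- 0
    d[cbind(which(called), gt$a1[called, j])] <-
      d[cbind(which(called), gt$a1[called, j])] + 1
    d[cbind(which(called), gt$a2[called, j])] <-
      d[cbind(which(called), gt$a2[called, j])] + 1
    colnames(d) <- paste(gt_loci(gt)[j], gt$alleles[[j]], sep = ".")
    cols[[j]] <- d
  }
  X <- do.call(cbind, cols)
  mu <- colMeans(X, na.rm = TRUE)
  for (jj in which(colSums(is.na(X)) > 0)) X[is.na(X[, jj]), jj] <- mu[jj]
  X <- sweep(X, 2, colMeans(X))
  n_pc <- min(n_pc, n - 1L, ncol(X))
  sv <- svd(X, nu = n_pc, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pc)], n_pc, n_pc)
  rownames(scores) <- rownames(gt$a1)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  sdev <- sv$d / sqrt(max(1, n - 1))
  structure(list(scores = scores, sdev = sdev,
                 var_explained = sv$d^2 / sum(sv$d^2)),
            class = "genotype_pca")
}

#' Reduce a microhaplotype panel to its most informative SNP per locus
#'
#' For every locus, each SNP offset's marginal base frequencies are obtained
#' by summing haplotype frequencies over the alleles carrying each base at
#' that offset; the offset maximising expected heterozygosity
#' `1 - sum(m^2)`, averaged over the populations in `freqs`, is selected.
#' The returned transform maps microhaplotype genotypes (or frequency sets)
#' to single-site genotypes, so the same classification and kinship
#' machinery runs on the reduced panel.
#'
#' @param panel A `microhap_panel`.
#' @param freqs An `allele_freq_set` covering the panel (typically the two
#'   reference populations).
#' @return A list of class `best_snp_transform` with `offsets` (chosen
#'   0-based offset per locus), `base_maps` (per locus, base carried by each
#'   haplotype allele) and `bases` (per locus base dictionary).
#' @export
panel_to_best_snp <- function(panel, freqs) {
  stopifnot(inherits(panel, "microhap_panel"),
            inherits(freqs, "allele_freq_set"))
  loci <- panel_locus_ids(panel)
  if (!all(loci %in% names(freqs$alleles))) {
    stop("freqs do not cover the panel")
  }
  offsets <- integer(length(loci)); names(offsets) <- loci
  base_maps <- list(); bases <- list()
  for (l in loci) {
    def <- panel$loci[[l]]
    dict <- freqs$alleles[[l]]
    # haplotypes in the freq dictionary but absent from the panel still
    # carry bases; read them from the haplotype string itself
    hap_bases <- function(s) substring(dict, s, s)
    best_he <- -1; best_s <- NA_integer_
    for (s in seq_along(def$snp_offsets)) {
      bs <- hap_bases(s)
      he_pop <- vapply(freqs$freq, function(fp) {
        m <- tapply(fp[[l]], bs, sum)
        1 - sum(m^2)
      }, numeric(1))
      he <- mean(he_pop)
      if (he > best_he + 1e-12) {
        best_he <- he
        best_s <- s
      }
    }
    if (best_he <= 1e-12) {
      stop(sprintf("locus %s has no segregating site", l))
    }
    offsets[l] <- def$snp_offsets[best_s]
    bmap <- hap_bases(best_s)
    bases[[l]] <- sort(unique(bmap))
    base_maps[[l]] <- match(bmap, bases[[l]])
  }
  structure(list(offsets = offsets, base_maps = base_maps, bases = bases),
            class = "best_snp_transform")
}

#' Apply a best-SNP transform to genotypes or frequencies
#'
#' @param transform A `best_snp_transform`.
#' @param gt A `genotype_table` whose allele dictionary matches the one the
#'   transform was built from.
#' @return `best_snp_genotypes`: a `genotype_table` over single-base
#'   alleles; `best_snp_freqs`: an `allele_freq_set` with frequencies
#'   marginalised to the chosen site.
#' @export
best_snp_genotypes <- function(transform, gt) {
  stopifnot(inherits(transform, "best_snp_transform"),
            inherits(gt, "genotype_table"))
  loci <- gt_loci(gt)
  a1 <- gt$a1; a2 <- gt$a2
  for (j in seq_along(loci)) {
    map <- transform$base_maps[[loci[j]]]
    if (length(map) < length(gt$alleles[[j]])) {
      stop("transform does not cover the table's allele dictionary")
    }
    a1[, j] <- map[gt$a1[, j]]
    a2[, j] <- map[gt$a2[, j]]
  }
  genotype_table(a1, a2, transform$bases[loci], gt$meta, gt$anomalies)
}

#' @rdname best_snp_genotypes
#' @param freqs An `allele_freq_set`.
#' @export
best_snp_freqs <- function(transform, freqs) {
  stopifnot(inherits(transform, "best_snp_transform"),
            inherits(freqs, "allele_freq_set"))
  loci <- names(freqs$alleles)
  out_freq <- lapply(freqs$freq, function(fp) {
    stats::setNames(lapply(loci, function(l) {
      map <- transform$base_maps[[l]]
      as.vector(tapply(fp[[l]], map, sum))
    }), loci)
  })
  structure(list(alleles = transform$bases[loci], freq = out_freq,
                 n_copies = freqs$n_copies),
            class = "allele_freq_set")
}
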
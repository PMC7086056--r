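# Shared fixtures, built in code.

# A tiny hand-written panel: two loci, two SNPs each.
tiny_panel <- function() {
  microhap_panel(list(
    list(locus_id = "locA",
         ref_seq = "ACGTACGTACGT",
         snp_offsets = c(2L, 7L),
         alleles = c("AC", "GT")),
    list(locus_id = "locB",
         ref_seq = "TTTTCCCCGGGGAAAA",
         snp_offsets = c(1L, 5L, 10L),
         alleles = c("TCG", "ACG", "ACA"))
  ))
}

# Build a genotype_table directly from a list of per-individual genotypes:
# geno[[ind]][[locus]] = c(a1, a2) indices or NA.
make_gt <- function(geno, alleles, meta_extra = NULL) {
  inds <- names(geno)
  loci <- names(alleles)
  a1 <- matrix(NA_integer_, length(inds), length(loci),
               dimnames = list(inds, loci))
  a2 <- a1
  for (i in seq_along(inds)) {
    for (j in seq_along(loci)) {
      g <- geno[[i]][[loci[j]]]
      if (!is.null(g) && !anyNA(g)) {
        a1[i, j] <- g[1]
        a2[i, j] <- g[2]
      }
    }
  }
  meta <- data.frame(individual_id = inds, stringsAsFactors = FALSE)
  if (!is.null(meta_extra)) meta <- cbind(meta, meta_extra)
  genotype_table(a1, a2, alleles, meta)
}

# Two fixed-difference reference populations over n_loci biallelic loci:
# population A fixed for allele 1, population B fixed for allele 2.
fixed_diff_refs <- function(n_loci = 10L, n_ind = 4L) {
  loci <- sprintf("L%02d", seq_len(n_loci))
  alleles <- stats::setNames(rep(list(c("A", "B")), n_loci), loci)
  mk <- function(allele, prefix) {
    ids <- paste0(prefix, seq_len(n_ind))
    a1 <- matrix(allele, n_ind, n_loci, dimnames = list(ids, loci))
    genotype_table(a1, a1, alleles,
                   data.frame(individual_id = ids,
                              stringsAsFactors = FALSE))
  }
  list(refA = mk(1L, "a"), refB = mk(2L, "b"), alleles = alleles)
}

# A small calibrated-shape model for fast tests.
small_model <- function(n_loci = 25L, seed = 1234L) {
  build_population_model(n_loci = n_loci, seed = seed)
}

# Extract genotype allele strings for comparison.
gt_allele_strings <- function(gt, i, j) {
  if (is.na(gt$a1[i, j])) return(NULL)
  sort(c(gt$alleles[[j]][gt$a1[i, j]], gt$alleles[[j]][gt$a2[i, j]]))
}

# Independent variance-components oracle for Weir-Cockerham theta: classic
# nested ANOVA on per-allele gene-copy indicators (pops / individuals in
# pops / copies in individuals), a route structurally different from the
# package's direct WC84 formulas.
anova_theta <- function(gt, pops, group_col = "group") {
  gvec <- gt$meta[[group_col]]
  asum <- bsum <- csum <- 0
  for (j in seq_len(ncol(gt$a1))) {
    K <- length(gt$alleles[[j]])
    rows <- lapply(pops, function(p) {
      r <- which(gvec == p & !is.na(gt$a1[, j]))
      r
    })
    ni <- lengths(rows)
    if (any(ni < 2)) next
    r <- length(pops)
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    for (al in seq_len(K)) {
      y <- lapply(rows, function(rr) {
        cbind((gt$a1[rr, j] == al) * 1, (gt$a2[rr, j] == al) * 1)
      })
      ybar <- mean(unlist(y))
      if (ybar <= 0 || ybar >= 1) next
      ybar_pop <- vapply(y, mean, numeric(1))
      ybar_ind <- lapply(y, rowMeans)
      ssg <- sum(vapply(seq_along(y), function(p) {
        sum((y[[p]] - ybar_ind[[p]])^2)
      }, numeric(1)))
      ssi <- sum(vapply(seq_along(y), function(p) {
        2 * sum((ybar_ind[[p]] - ybar_pop[p])^2)
      }, numeric(1)))
      ssp <- sum(2 * ni * (ybar_pop - ybar)^2)
      msg <- ssg / sum(ni)
      msi <- ssi / sum(ni - 1)
      msp <- ssp / (r - 1)
      a <- (msp - msi) / (2 * nc)
      b <- (msi - msg) / 2
      cc <- msg
      asum <- asum + a; bsum <- bsum + b; csum <- csum + cc
    }
  }
  asum / (asum + bsum + csum)
}

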
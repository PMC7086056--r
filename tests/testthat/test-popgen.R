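test_that("allele frequency estimation matches the pseudocount formula", {
  alleles <- list(L1 = c("A", "B"))
  gt <- make_gt(list(i1 = list(L1 = c(1, 1)), i2 = list(L1 = c(1, 2))),
                alleles, meta_extra = data.frame(group = c("g", "g")))
  f0 <- estimate_allele_freqs(gt, pseudocount = 0)
  expect_equal(f0$freq$g$L1, c(0.75, 0.25))
  f5 <- estimate_allele_freqs(gt, pseudocount = 0.5)
  expect_equal(f5$freq$g$L1, c(3.5 / 5, 1.5 / 5))

  # all-missing locus: prior only
  gt2 <- make_gt(list(i1 = list(L1 = NA), i2 = list(L1 = NA)),
                 alleles, meta_extra = data.frame(group = c("g", "g")))
  expect_error(estimate_allele_freqs(gt2), "zero called")
  gt3 <- make_gt(list(i1 = list(L1 = NA, L2 = c(1, 1))),
                 list(L1 = c("A", "B"), L2 = c("A", "B")),
                 meta_extra = data.frame(group = "g"))
  f <- estimate_allele_freqs(gt3, pseudocount = 0.5)
  expect_equal(f$freq$g$L1, c(0.5, 0.5))
})

test_that("diversity summary uses unbiased He and is relabel-invariant", {
  alleles <- list(L1 = c("A", "B"), L2 = c("A", "B"))
  gt <- make_gt(list(i1 = list(L1 = c(1, 2), L2 = c(1, 1)),
                     i2 = list(L1 = c(1, 2), L2 = c(1, 1))),
                alleles, meta_extra = data.frame(group = c("g", "g")))
  ds <- diversity_summary(gt)
  per <- attr(ds, "per_locus")
  expect_equal(per$He[per$locus_id == "L1"], (4 / 3) * 0.5)
  expect_equal(per$Ho[per$locus_id == "L1"], 1)
  expect_equal(per$He[per$locus_id == "L2"], 0) # monomorphic
  expect_equal(per$Ho[per$locus_id == "L2"], 0)

  # relabeling alleles leaves He unchanged
  gt_swap <- gt
  gt_swap$a1[, 1] <- 3L - gt$a2[, 1]
  gt_swap$a2[, 1] <- 3L - gt$a1[, 1]
  ds2 <- diversity_summary(gt_swap)
  expect_equal(ds2$He, ds$He)
})

test_that("theta matches the ANOVA oracle and the boundary cases", {
  # fixed alternate alleles -> theta = 1
  fx <- fixed_diff_refs(n_loci = 4, n_ind = 6)
  both <- gt_rbind(fx$refA, fx$refB)
  both$meta$group <- rep(c("A", "B"), each = 6)
  expect_equal(pairwise_fst(both, "A", "B")$theta, 1)

  # two groups from one population -> theta ~ 0
  m <- small_model(n_loci = 40)
  gt <- simulate_reference_genotypes(m, "anadromous", 400, seed = 101)
  gt$meta$group <- rep(c("g1", "g2"), 200)
  expect_lt(abs(pairwise_fst(gt, "g1", "g2")$theta), 0.01)

  # toy table equality with the independent oracle
  withr::with_seed(102, {
    alleles <- list(L1 = c("A", "B", "C"), L2 = c("A", "B"))
    geno <- lapply(1:12, function(i) {
      list(L1 = sort(sample(3, 2, replace = TRUE)),
           L2 = sort(sample(2, 2, replace = TRUE)))
    })
    names(geno) <- paste0("i", 1:12)
    gt2 <- make_gt(geno, alleles,
                   meta_extra = data.frame(group = rep(c("p1", "p2"), 6)))
    ours <- pairwise_fst(gt2, "p1", "p2")$theta
    oracle <- anova_theta(gt2, c("p1", "p2"))
    expect_equal(ours, oracle, tolerance = 1e-12)
    # invariant to population order
    expect_equal(pairwise_fst(gt2, "p2", "p1")$theta, ours)
  })
})

test_that("PCA reproduces an independent eigendecomposition", {
  alleles <- list(L1 = c("A", "B"), L2 = c("A", "B"))
  geno <- list(i1 = list(L1 = c(1, 1), L2 = c(1, 2)),
               i2 = list(L1 = c(1, 1), L2 = c(1, 2)),
               i3 = list(L1 = c(2, 2), L2 = c(2, 2)),
               i4 = list(L1 = c(1, 2), L2 = c(1, 1)))
  gt <- make_gt(geno, alleles)
  pca <- genotype_pca(gt)
  # identical individuals -> identical coordinates
  expect_equal(pca$scores["i1", ], pca$scores["i2", ])
  # oracle: eigendecomposition of the centred dosage covariance
  X <- matrix(0, 4, 4)
  dict <- c("L1.A", "L1.B", "L2.A", "L2.B")
  for (i in 1:4) {
    for (j in 1:2) {
      g <- geno[[i]][[j]]
      X[i, (j - 1) * 2 + g[1]] <- X[i, (j - 1) * 2 + g[1]] + 1
      X[i, (j - 1) * 2 + g[2]] <- X[i, (j - 1) * 2 + g[2]] + 1
    }
  }
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(Xc %*% t(Xc))
  for (k in seq_len(ncol(pca$scores))) {
    if (ev$values[k] < 1e-9) next
    expect_equal(abs(pca$scores[, k]), abs(sqrt(ev$values[k]) *
                                             ev$vectors[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # centring makes a mirror-image pair symmetric about zero on PC1
  expect_equal(sum(pca$scores[, 1]), 0, tolerance = 1e-8)
})

test_that("best-SNP reduction picks the most heterozygous site", {
  # locus with marginal MAFs 0.5 and 0.1 at its two sites
  panel <- microhap_panel(list(list(
    locus_id = "L1", ref_seq = "ACGTACGT", snp_offsets = c(1L, 5L),
    alleles = c("AA", "CA", "CG"))))
  alleles <- list(L1 = c("AA", "CA", "CG"))
  # freqs: site 1 marginal: A 0.5, C 0.5; site 2: A 0.9, G 0.1
  fs <- structure(list(
    alleles = alleles,
    freq = list(p1 = list(L1 = c(0.5, 0.4, 0.1))),
    n_copies = list(p1 = c(L1 = 100))), class = "allele_freq_set")
  tr <- panel_to_best_snp(panel, fs)
  expect_identical(unname(tr$offsets["L1"]), 1L)

  # {AC, AT}: first offset monomorphic, second chosen
  panel2 <- microhap_panel(list(list(
    locus_id = "L1", ref_seq = "ACGTACGT", snp_offsets = c(0L, 4L),
    alleles = c("AC", "AT"))))
  fs2 <- structure(list(
    alleles = list(L1 = c("AC", "AT")),
    freq = list(p1 = list(L1 = c(0.6, 0.4))),
    n_copies = list(p1 = c(L1 = 100))), class = "allele_freq_set")
  tr2 <- panel_to_best_snp(panel2, fs2)
  expect_identical(unname(tr2$offsets["L1"]), 4L)

  # transformed genotypes are at most biallelic
  m <- small_model(n_loci = 15)
  gt <- simulate_reference_genotypes(m, "anadromous", 60, seed = 111)
  gt2 <- simulate_reference_genotypes(m, "landlocked", 60, seed = 112)
  both <- gt_rbind(gt, gt2)
  fr <- estimate_allele_freqs(both)
  tr3 <- panel_to_best_snp(m$panel, fr)
  red <- best_snp_genotypes(tr3, both)
  expect_true(all(lengths(red$alleles) <= 4))
  n_obs <- vapply(seq_len(ncol(red$a1)), function(j) {
    length(unique(stats::na.omit(c(red$a1[, j], red$a2[, j]))))
  }, integer(1))
  expect_true(all(n_obs <= 2 | n_obs <= lengths(both$alleles)))
  # marginalisation never increases allele counts
  expect_true(all(lengths(red$alleles) <= lengths(both$alleles)))
})
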
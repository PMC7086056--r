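test_that("locus genotype calling applies the depth and ratio filters", {
  het <- call_locus_genotype(c(AC = 15, GT = 14))
  expect_false(het$missing)
  expect_identical(het$alleles, c("AC", "GT"))

  shallow <- call_locus_genotype(c(AC = 9))
  expect_true(shallow$missing)
  expect_false(shallow$anomaly)

  # 5/30 < 0.2 -> minor haplotype treated as sequencing error
  hom <- call_locus_genotype(c(AC = 30, GT = 5))
  expect_identical(hom$alleles, c("AC", "AC"))

  contam <- call_locus_genotype(c(AC = 30, GT = 29, TT = 28))
  expect_true(contam$missing)
  expect_true(contam$anomaly)

  zero <- call_locus_genotype(integer(0))
  expect_true(zero$missing)
})

test_that("SAM extraction tallies phased haplotypes and discards gapped reads", {
  p <- tiny_panel()
  sam <- withr::local_tempfile(fileext = ".sam")
  rec <- function(qname, rname, pos, cigar, seq) {
    sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*", qname, rname, pos,
            cigar, seq)
  }
  # locA ref ACGTACGTACGT, offsets 2 and 7 (0-based) -> bases 3 and 8
  lines <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:locA\tLN:12",
    rep(rec("ind1|locA|x", "locA", 1, "12M", "ACGTACGTACGT"), 15),
    rep(rec("ind1|locA|y", "locA", 1, "12M", "ACTTACGGACGT"), 14),
    # deletion spanning offset 7 -> discarded
    rec("ind1|locA|z", "locA", 1, "6M2D4M", "ACGTACACGT"),
    # soft-clipped start shifting coordinates still yields the haplotype
    rec("ind2|locA|w", "locA", 3, "2S10M", "TTGTACGTACGT")
  )
  writeLines(lines, sam)
  hd <- extract_haplotype_depths(sam, p)
  d1 <- hd[hd$individual_id == "ind1", ]
  expect_setequal(d1$haplotype, c("GT", "TG"))
  expect_identical(d1$count[d1$haplotype == "GT"], 15L)
  expect_identical(d1$count[d1$haplotype == "TG"], 14L)
  expect_identical(attr(hd, "n_discarded"), 1L)
  # the clipped read covers ref positions 3..12 -> offsets at bases 3, 8
  d2 <- hd[hd$individual_id == "ind2", ]
  expect_identical(d2$haplotype, "GT")

  expect_error(extract_haplotype_depths(
    {
      bad <- withr::local_tempfile(fileext = ".sam")
      writeLines(c("@SQ\tSN:weird\tLN:5",
                   rec("q", "weird", 1, "5M", "ACGTA")), bad)
      bad
    }, p), "not in panel")
})

test_that("simulated reads round-trip to the exact simulated genotypes", {
  m <- build_population_model(n_loci = 12, seed = 71)
  gt <- simulate_reference_genotypes(m, "landlocked", 12, seed = 72)
  sam <- withr::local_tempfile(fileext = ".sam")
  simulate_reads(gt, m$panel, sam,
                 depth_law = list(dist = "fixed", depth = 25),
                 per_base_error = 0, seed = 73)
  called <- call_genotypes(extract_haplotype_depths(sam, m$panel), m$panel)
  called <- gt_subset(called, individuals = gt_individuals(gt))
  for (i in seq_len(nrow(gt$a1))) {
    for (j in seq_len(ncol(gt$a1))) {
      expect_identical(gt_allele_strings(called, i, j),
                       gt_allele_strings(gt, i, j))
    }
  }
  # heterozygotes show exactly two observed haplotypes with zero error
  hd <- extract_haplotype_depths(sam, m$panel)
  per_cell <- table(paste(hd$individual_id, hd$locus_id))
  expect_true(all(per_cell <= 2))
})

test_that("calling is invariant to read order in the SAM", {
  m <- build_population_model(n_loci = 6, seed = 81)
  gt <- simulate_reference_genotypes(m, "anadromous", 5, seed = 82)
  sam <- withr::local_tempfile(fileext = ".sam")
  simulate_reads(gt, m$panel, sam,
                 depth_law = list(dist = "fixed", depth = 15),
                 per_base_error = 0, seed = 83)
  lines <- readLines(sam)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sam2 <- withr::local_tempfile(fileext = ".sam")
  withr::with_seed(84, writeLines(c(hdr, sample(body)), sam2))
  c1 <- call_genotypes(extract_haplotype_depths(sam, m$panel), m$panel)
  c2 <- call_genotypes(extract_haplotype_depths(sam2, m$panel), m$panel)
  expect_identical(c1$a1, c2$a1)
  expect_identical(c1$a2, c2$a2)
})

test_that("raising thresholds is monotone in missingness and het calls", {
  # error-free reads: with at most two true haplotypes per cell, raising
  # min_ratio can only demote the minor haplotype (with sequencing error a
  # third haplotype can exist, and raising the ratio can rescue a
  # >2-haplotype missing call into a heterozygote)
  m <- build_population_model(n_loci = 10, seed = 91)
  gt <- simulate_reference_genotypes(m, "anadromous", 20, seed = 92)
  sam <- withr::local_tempfile(fileext = ".sam")
  simulate_reads(gt, m$panel, sam,
                 depth_law = list(dist = "nbinom", mu = 15, size = 3),
                 per_base_error = 0, seed = 93)
  hd <- extract_haplotype_depths(sam, m$panel)
  miss <- het <- numeric(0)
  for (dmin in c(5, 10, 20)) {
    cg <- call_genotypes(hd, m$panel, min_total_depth = dmin)
    miss <- c(miss, mean(is.na(cg$a1)))
  }
  expect_true(all(diff(miss) >= 0))
  for (r in c(0.1, 0.2, 0.4)) {
    cg <- call_genotypes(hd, m$panel, min_ratio = r)
    het <- c(het, sum(cg$a1 != cg$a2, na.rm = TRUE))
  }
  expect_true(all(diff(het) <= 0))
})

test_that("individual QC applies the missingness and contamination rules", {
  loci <- sprintf("L%03d", 1:114)
  alleles <- stats::setNames(rep(list(c("A", "B")), 114), loci)
  a1 <- matrix(1L, 3, 114, dimnames = list(c("keep", "drop", "contam"),
                                           loci))
  a2 <- a1
  a1["drop", 1:23] <- NA; a2["drop", 1:23] <- NA   # 23/114 = 20.2%
  a1["keep", 1:22] <- NA; a2["keep", 1:22] <- NA   # 22/114 = 19.3%
  anom <- matrix(FALSE, 3, 114, dimnames = dimnames(a1))
  anom["contam", 1:3] <- TRUE
  gt <- genotype_table(a1, a2, alleles,
                       data.frame(individual_id = rownames(a1),
                                  stringsAsFactors = FALSE),
                       anomalies = anom)
  qc <- apply_individual_qc(gt)
  rep <- qc$report
  expect_false(rep$dropped[rep$individual_id == "keep"])
  expect_identical(rep$drop_reason[rep$individual_id == "drop"],
                   "missingness")
  expect_identical(rep$drop_reason[rep$individual_id == "contam"],
                   "contamination")
  expect_identical(gt_individuals(qc$genotypes), "keep")
  expect_error(apply_individual_qc(gt_subset(gt, individuals = integer(0))),
               "empty")
})
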
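test_that("category likelihoods at a fixed difference are exact", {
  fA <- c(1, 0); fB <- c(0, 1)
  het <- c(1, 2)
  expect_equal(genotype_class_likelihood(het, fA, fB, "F1"), 1)
  expect_equal(genotype_class_likelihood(het, fA, fB, "F2"), 0.5)
  expect_equal(genotype_class_likelihood(het, fA, fB, "PureA"), 0)
  expect_equal(genotype_class_likelihood(het, fA, fB, "BC_A"), 0.5)
  # error mixture pulls towards the mean-frequency HWE draw
  expect_equal(genotype_class_likelihood(het, fA, fB, "PureA",
                                         error_rate = 0.1),
               0.9 * 0 + 0.1 * 2 * 0.5 * 0.5)
})

test_that("the ten-fixed-locus F1 posterior matches the closed form", {
  fx <- fixed_diff_refs(n_loci = 10, n_ind = 5)
  f1 <- simulate_cross(fx$refA, fx$refB, cross_class = "F1",
                       n_offspring = 1, seed = 121)
  post <- classify_individuals(f1, fx$refA, fx$refB, pseudocount = 0)
  expect_equal(post$F1, 1024 / 1027, tolerance = 1e-12)
  expect_identical(post$max_category, "F1")
  expect_equal(post$F2 + post$BC_A + post$BC_B, 3 / 1027,
               tolerance = 1e-12)
})

test_that("posteriors normalise and strong references classify pures", {
  m <- small_model(n_loci = 60)
  refA <- simulate_reference_genotypes(m, "anadromous", 300, seed = 131)
  refB <- simulate_reference_genotypes(m, "landlocked", 150, seed = 132)
  test_ind <- simulate_reference_genotypes(m, "anadromous", 20, seed = 133)
  post <- classify_individuals(test_ind, refA, refB)
  cats <- hybrid_categories()$name
  expect_equal(rowSums(as.matrix(post[, cats])), rep(1, 20),
               tolerance = 1e-9)
  expect_true(mean(post$max_category == "PureA") >= 0.9)
})

test_that("swapping the reference populations swaps the posteriors", {
  m <- small_model(n_loci = 20)
  refA <- simulate_reference_genotypes(m, "anadromous", 100, seed = 141)
  refB <- simulate_reference_genotypes(m, "landlocked", 100, seed = 142)
  ind <- simulate_cross(refA, refB, cross_class = "BC_A",
                        n_offspring = 10, seed = 143)
  p1 <- classify_individuals(ind, refA, refB)
  p2 <- classify_individuals(ind, refB, refA)
  expect_equal(p1$PureA, p2$PureB)
  expect_equal(p1$BC_A, p2$BC_B)
  expect_equal(p1$F1, p2$F1)
  expect_equal(p1$F2, p2$F2)
})

test_that("F1 posterior against fixed differences is monotone in loci", {
  post_f1 <- vapply(c(4, 8, 16), function(L) {
    fx <- fixed_diff_refs(n_loci = L, n_ind = 5)
    f1 <- simulate_cross(fx$refA, fx$refB, cross_class = "F1",
                         n_offspring = 1, seed = 151)
    classify_individuals(f1, fx$refA, fx$refB, pseudocount = 0)$F1
  }, numeric(1))
  expect_true(all(diff(post_f1) > 0))
  expect_gt(post_f1[3], 0.999)
})

test_that("admixture q has the documented boundary behaviour", {
  fx <- fixed_diff_refs(n_loci = 10, n_ind = 5)
  f1 <- simulate_cross(fx$refA, fx$refB, cross_class = "F1",
                       n_offspring = 3, seed = 161)
  q <- estimate_admixture_q(f1, fx$refA, fx$refB, pseudocount = 0)
  expect_equal(q$q, rep(0.5, 3), tolerance = 1e-6)

  pure <- simulate_cross(fx$refA, fx$refB, cross_class = "pureA",
                         n_offspring = 3, seed = 162)
  qp <- estimate_admixture_q(pure, fx$refA, fx$refB, pseudocount = 0)
  expect_equal(qp$q, rep(1, 3))

  # one locus, fA(A) = 0.8, fB(A) = 0.2, genotype {A,A}: likelihood
  # (0.2 + 0.6 q)^2 is increasing in q -> q-hat = 1
  alleles <- list(L1 = c("A", "B"))
  mk_ref <- function(pA, ids) {
    n <- length(ids)
    nA <- round(2 * n * pA)
    al <- c(rep(1L, nA), rep(2L, 2 * n - nA))
    a1 <- matrix(al[seq_len(n)], n, 1, dimnames = list(ids, "L1"))
    a2 <- matrix(al[n + seq_len(n)], n, 1, dimnames = list(ids, "L1"))
    genotype_table(a1, a2, alleles,
                   data.frame(individual_id = ids,
                              stringsAsFactors = FALSE))
  }
  refA <- mk_ref(0.8, paste0("a", 1:5))
  refB <- mk_ref(0.2, paste0("b", 1:5))
  ind <- make_gt(list(x = list(L1 = c(1, 1))), alleles)
  qx <- estimate_admixture_q(ind, refA, refB, pseudocount = 0)
  expect_equal(qx$q, 1)
})

test_that("identical references give chance-level classification", {
  m <- small_model(n_loci = 20)
  ref <- simulate_reference_genotypes(m, "anadromous", 200, seed = 171)
  refA <- gt_subset(ref, individuals = 1:100)
  refB <- gt_subset(ref, individuals = 101:200)
  pc <- power_confusion(refA, refB, n_per_class = 60,
                        include_references = FALSE,
                        estimate_mixing = FALSE, seed = 172)
  # no information: overall accuracy compatible with the 1/6 chance level
  overall <- sum(diag(pc$confusion)) / sum(pc$confusion)
  expect_lt(abs(overall - 1 / 6), 0.08)
})

test_that("mixing-proportion EM recovers a pure-dominated composition", {
  m <- small_model(n_loci = 30)
  refA <- simulate_reference_genotypes(m, "anadromous", 400, seed = 181)
  refB <- simulate_reference_genotypes(m, "landlocked", 150, seed = 182)
  mixed <- gt_rbind(
    simulate_reference_genotypes(m, "anadromous", 180, seed = 183,
                                 id_prefix = "qa"),
    simulate_reference_genotypes(m, "landlocked", 20, seed = 184,
                                 id_prefix = "qb"))
  post <- classify_individuals(mixed, refA, refB, estimate_mixing = TRUE)
  mix <- attr(post, "mixing")
  expect_equal(sum(mix), 1, tolerance = 1e-9)
  expect_gt(mix["PureA"], 0.75)
  expect_gt(mix["PureB"], 0.05)
})

test_that("best-SNP reduction shrinks the F1 / BC_B q-hat separation", {
  m <- small_model(n_loci = 60, seed = 4321)
  refA <- simulate_reference_genotypes(m, "anadromous", 400, seed = 341)
  refB <- simulate_reference_genotypes(m, "landlocked", 150, seed = 342)
  sep_for <- function(ra, rb) {
    f1 <- simulate_cross(ra, rb, "F1", 40, seed = 343)
    bcb <- simulate_cross(ra, rb, "BC_B", 40, seed = 344)
    min(estimate_admixture_q(f1, ra, rb)$q) -
      max(estimate_admixture_q(bcb, ra, rb)$q)
  }
  tr <- panel_to_best_snp(m$panel,
                          estimate_allele_freqs(gt_rbind(refA, refB)))
  sep_full <- sep_for(refA, refB)
  sep_snp <- sep_for(best_snp_genotypes(tr, refA),
                     best_snp_genotypes(tr, refB))
  expect_gt(sep_full, sep_snp)
})
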
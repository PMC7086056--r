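# Brute-force oracle for the pair likelihood: enumerate ordered true
# genotypes, IBD configurations and per-copy error outcomes explicitly.
brute_pair_prob <- function(g1, g2, f, kappa, eps) {
  kappa <- unname(kappa)
  K <- length(f)
  # P(observe unordered o | true ordered (t1, t2)) by enumerating which
  # copies miscall and what they miscall to
  obs_prob <- function(o, t) {
    total <- 0
    for (x in seq_len(K)) {
      for (y in seq_len(K)) {
        p1 <- (1 - eps) * (x == t[1]) + eps * f[x]
        p2 <- (1 - eps) * (y == t[2]) + eps * f[y]
        if (all(sort(c(x, y)) == sort(o))) total <- total + p1 * p2
      }
    }
    total
  }
  total <- 0
  for (a1 in seq_len(K)) for (a2 in seq_len(K)) {
    for (b1 in seq_len(K)) for (b2 in seq_len(K)) {
      pa <- f[a1] * f[a2]
      # k0: independent; k1: one IBD copy (each of the four orderings of
      # which copy is shared, uniformly); k2: both copies IBD
      p_b_k0 <- f[b1] * f[b2]
      p_b_k1 <- 0.25 * ((b1 == a1) * f[b2] + (b1 == a2) * f[b2] +
                          (b2 == a1) * f[b1] + (b2 == a2) * f[b1])
      p_b_k2 <- 0.5 * ((b1 == a1) * (b2 == a2) + (b1 == a2) * (b2 == a1))
      p_joint <- pa * (kappa[1] * p_b_k0 + kappa[2] * p_b_k1 +
                         kappa[3] * p_b_k2)
      total <- total + p_joint * obs_prob(g1, c(a1, a2)) *
        obs_prob(g2, c(b1, b2))
    }
  }
  total
}

test_that("pair log-likelihoods match hand computations", {
  f <- c(0.5, 0.5)
  ll_u <- pair_loglik(c(1, 1), c(1, 1), f, "U")
  ll_po <- pair_loglik(c(1, 1), c(1, 1), f, "PO")
  ll_fs <- pair_loglik(c(1, 1), c(1, 1), f, "FS")
  expect_equal(exp(ll_u), 0.0625)
  expect_equal(exp(ll_po), 0.125)
  expect_equal(ll_po - ll_u, log(2))
  expect_equal(exp(ll_fs), 0.140625)
  expect_equal(ll_fs - ll_u, log(2.25))
})

test_that("pair likelihood equals the brute-force oracle", {
  km <- kinship_model()
  withr::with_seed(191, {
    for (rep in 1:3) {
      K <- sample(2:3, 1)
      f <- as.vector(stats::rmultinom(1, 40, rep(1, K))) + 1
      f <- f / sum(f)
      for (eps in c(0, 0.02)) {
        for (rel in c("U", "PO", "FS", "HS")) {
          kap <- unlist(km[km$name == rel, c("k0", "k1", "k2")])
          for (trial in 1:4) {
            g1 <- sort(sample(K, 2, replace = TRUE))
            g2 <- sort(sample(K, 2, replace = TRUE))
            expect_equal(
              exp(pair_loglik(g1, g2, f, rel, error_rate = eps)),
              brute_pair_prob(g1, g2, f, kap, eps),
              tolerance = 1e-12)
          }
        }
      }
    }
  })
  # multi-locus: sums over loci (3 loci, mixed allele counts)
  withr::with_seed(192, {
    fl <- list(c(0.3, 0.7), c(0.2, 0.5, 0.3), c(0.6, 0.4))
    g1 <- list(c(1, 2), c(2, 3), c(1, 1))
    g2 <- list(c(2, 2), c(1, 3), c(1, 2))
    manual <- sum(vapply(1:3, function(j) {
      pair_loglik(g1[[j]], g2[[j]], fl[[j]], "FS", error_rate = 0.01)
    }, numeric(1)))
    expect_equal(pair_loglik(g1, g2, fl, "FS", error_rate = 0.01), manual)
  })
})

test_that("LLR of unrelated-vs-unrelated is identically zero", {
  m <- small_model(n_loci = 15)
  gt <- simulate_reference_genotypes(m, "anadromous", 30, seed = 201)
  fr <- estimate_allele_freqs(gt, groups = list(p = gt_individuals(gt)))
  s <- simulate_llr_distributions(fr, "U", n_pairs = 200, error_rate = 0,
                                  seed = 202)
  expect_true(all(s$true$lambda == 0))
  s2 <- simulate_llr_distributions(fr, "U", n_pairs = 200,
                                   error_rate = 0.01, seed = 203)
  expect_true(all(s2$true$lambda == 0))
})

test_that("fpr_at_fnr handles the degenerate shapes", {
  sep <- list(true = list(lambda = stats::rnorm(500, 100, 1)),
              unrelated = list(lambda = stats::rnorm(500, -100, 1),
                               weights = NULL))
  expect_equal(fpr_at_fnr(sep)$fpr, 0)
  withr::with_seed(211, {
    x <- stats::rnorm(20000)
    same <- list(true = list(lambda = x),
                 unrelated = list(lambda = x, weights = NULL))
    expect_equal(fpr_at_fnr(same)$fpr, 0.99, tolerance = 0.002)
  })
  expect_error(fpr_at_fnr(sep, fnr = 0), "fnr")
  expect_error(fpr_at_fnr(sep, fnr = 1), "fnr")
})

test_that("PO pairs separate completely at 100 diagnostic loci", {
  fx <- fixed_diff_refs(n_loci = 100)
  # diagnostic biallelic loci at intermediate frequency
  fr <- structure(list(
    alleles = fx$alleles,
    freq = list(p = lapply(fx$alleles, function(a) c(0.5, 0.5))),
    n_copies = list(p = rep(100, length(fx$alleles)))),
    class = "allele_freq_set")
  s <- simulate_llr_distributions(fr, "PO", n_pairs = 400, error_rate = 0,
                                  seed = 221)
  expect_gt(min(s$true$lambda), max(s$unrelated$lambda))
})

test_that("importance sampling agrees with direct Monte Carlo", {
  m <- small_model(n_loci = 8) # weak panel: overlapping distributions
  gt <- simulate_reference_genotypes(m, "anadromous", 100, seed = 231)
  fr <- estimate_allele_freqs(gt, groups = list(p = gt_individuals(gt)))
  dir <- simulate_llr_distributions(fr, "FS", n_pairs = 20000,
                                    error_rate = 0.005, seed = 232)
  is_ <- simulate_llr_distributions(fr, "FS", n_pairs = 20000,
                                    error_rate = 0.005, seed = 233,
                                    importance_sampling = TRUE)
  f_dir <- fpr_at_fnr(dir, fnr = 0.05)
  f_is <- fpr_at_fnr(is_, fnr = 0.05)
  se <- sqrt(f_dir$fpr * (1 - f_dir$fpr) / 20000)
  expect_lt(abs(f_is$fpr - f_dir$fpr), 3 * se + 3 * f_is$fpr /
              sqrt(f_is$effective_sample_size))
  expect_gt(f_is$effective_sample_size, 10)
})

test_that("adding loci never increases the false-positive rate", {
  m <- build_population_model(n_loci = 60, seed = 241)
  gt <- simulate_reference_genotypes(m, "anadromous", 150, seed = 242)
  fr <- estimate_allele_freqs(gt, groups = list(p = gt_individuals(gt)))
  fpr_for <- function(loci_idx) {
    sub <- structure(list(
      alleles = fr$alleles[loci_idx],
      freq = list(p = fr$freq$p[loci_idx]),
      n_copies = list(p = fr$n_copies$p[loci_idx])),
      class = "allele_freq_set")
    s <- simulate_llr_distributions(sub, "HS", n_pairs = 4000,
                                    error_rate = 0.005, seed = 243)
    fpr_at_fnr(s)$fpr
  }
  fprs <- vapply(list(1:10, 1:30, 1:60), fpr_for, numeric(1))
  expect_true(all(diff(fprs) <= 0.01)) # non-increasing up to MC noise
  expect_lt(fprs[3], fprs[1])
})
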
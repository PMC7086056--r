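#' Build a two-ecotype population model by Wright-Fisher drift
#'
#' Constructs a microhaplotype panel and a pair of allele-frequency sets
#' representing an anadromous source population (ancestral) and a landlocked
#' population derived from it by `t` generations of pure drift at effective
#' size `Ne`, emulating isolation above colonial-era dams. Per-locus allele
#' counts are drawn from a shifted binomial on 2..8 and ancestral
#' frequencies from a symmetric Dirichlet; drift is binomial/multinomial
#' resampling of 2*Ne gene copies per generation, so the derived allele
#' support is always a subset of the ancestral support.
#'
#' When `Ne` is `NULL` (the default) a coarse calibration search over
#' `Ne_grid` picks the effective size whose drifted population best matches
#' the emulated landlocked reference sample: mean allelic richness ~2.02
#' alleles/locus and unbiased expected heterozygosity ~0.30 in a
#' 183-diploid sample. The search is seeded and is part of the generator.
#' Under pure drift these two targets pin the between-ecotype
#' differentiation at Weir-Cockerham theta ~0.15; see the methods vignette
#' for why drift-only divergence cannot simultaneously reproduce a lower
#' theta at this heterozygosity contrast.
#'
#' @param n_loci Number of microhaplotype loci (default 114).
#' @param allele_count_law Distribution spec for per-locus allele counts:
#'   a list with `dist = "shifted_binomial"`, `size` and `prob` (counts are
#'   `2 + Binomial(size, prob)` truncated to 2..8), or `dist = "fixed"` with
#'   `k`.
#' @param t Generations of drift isolating the landlocked population
#'   (default 110).
#' @param Ne Effective size of the landlocked population during isolation;
#'   `NULL` triggers the calibration search.
#' @param Ne_grid Candidate effective sizes for the search.
#' @param dirichlet_alpha Symmetric Dirichlet concentration for ancestral
#'   frequencies.
#' @param calib_n Diploid sample sizes (anadromous, landlocked) used by the
#'   calibration search; defaults mirror the study's reference samples.
#' @param seed Integer seed; all randomness in this operation flows from it.
#' @return An object of class `population_model` with elements `panel`,
#'   `ancestral_freqs`, `derived_freqs` (per-locus numeric vectors aligned
#'   with the panel alleles), `t` and `Ne`.
#' @export
build_population_model <- function(n_loci = 114L,
                                   allele_count_law = list(
                                     dist = "shifted_binomial",
                                     size = 6L, prob = 0.36),
                                   t = 110L,
                                   Ne = NULL,
                                   Ne_grid = seq(100L, 180L, by = 10L),
                                   dirichlet_alpha = 0.44,
                                   calib_n = c(2749L, 183L),
                                   seed = NULL) {
  n_loci <- assert_count(n_loci, "n_loci")
  if (t < 0 || t != floor(t)) stop("`t` must be a non-negative integer")
  if (!is.null(Ne) && Ne < 2) stop("`Ne` must be >= 2")
  local_seed(seed)

  K <- draw_allele_counts(allele_count_law, n_loci)
  loci <- lapply(seq_len(n_loci), function(i) {
    random_locus(sprintf("mhap%03d", i), K[i])
  })
  panel <- microhap_panel(loci)
  anc <- lapply(K, function(k) {
    x <- stats::rgamma(k, dirichlet_alpha)
    x / sum(x)
  })
  names(anc) <- panel_locus_ids(panel)

  if (is.null(Ne)) {
    best <- NULL
    for (cand in Ne_grid) {
      der <- wf_drift(anc, t, cand)
      st <- drift_calibration_stats(anc, der, calib_n)
      score <- ((st["na_land"] - 2.02) / 2.02)^2 +
        ((st["he_land"] - 0.30) / 0.30)^2
      if (is.null(best) || score < best$score) {
        best <- list(Ne = cand, derived = der, score = score)
      }
    }
    Ne <- best$Ne
    der <- best$derived
  } else {
    der <- wf_drift(anc, t, Ne)
  }

  structure(list(panel = panel, ancestral_freqs = anc, derived_freqs = der,
                 t = as.integer(t), Ne = as.integer(Ne)),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf(
    "population_model: %d loci, t = %d generations of drift at Ne = %d\n",
    length(x$panel), x$t, x$Ne))
  invisible(x)
}

draw_allele_counts <- function(law, n_loci) {
  if (!is.list(law) || is.null(law$dist)) {
    stop("allele_count_law must be a list with a `dist` element")
  }
  K <- switch(law$dist,
    shifted_binomial = 2L + stats::rbinom(n_loci, law$size, law$prob),
    fixed = rep(as.integer(law$k), n_loci),
    stop(sprintf("unknown allele-count distribution %s", law$dist))
  )
  pmin(pmax(K, 2L), 8L)
}

# Multinomial Wright-Fisher drift of every locus for t generations at
# diploid effective size Ne (2*Ne gene copies resampled per generation).
wf_drift <- function(freqs, t, Ne) {
  if (Ne < 2) stop("`Ne` must be >= 2")
  copies <- 2L * as.integer(Ne)
  lapply(freqs, function(p) {
    for (g in seq_len(t)) {
      p <- as.vector(stats::rmultinom(1L, copies, p)) / copies
    }
    p
  })
}

# Sampled statistics used by the Ne calibration search: mean observed
# alleles per locus and mean unbiased expected heterozygosity in a
# landlocked reference-sized HWE sample (genotype counts drawn
# multinomially over the HWE genotype space).
drift_calibration_stats <- function(anc, der, calib_n) {
  nB <- calib_n[2]
  na_land <- numeric(length(der))
  he_land <- numeric(length(der))
  for (i in seq_along(der)) {
    sB <- hwe_sample_counts(der[[i]], nB)
    p <- sB$allele_counts / (2 * nB)
    na_land[i] <- sum(sB$allele_counts > 0)
    he_land[i] <- (2 * nB / (2 * nB - 1)) * (1 - sum(p^2))
  }
  c(na_land = mean(na_land), he_land = mean(he_land))
}

# Draw n diploids from HWE at one locus; return per-allele counts,
# heterozygote-carrier counts and sample size (see wc84_locus).
hwe_sample_counts <- function(p, n) {
  K <- length(p)
  gs <- geno_space(K)
  gp <- p[gs[, 1]] * p[gs[, 2]] * ifelse(gs[, 1] == gs[, 2], 1, 2)
  cnt <- as.vector(stats::rmultinom(1L, n, gp))
  allele_counts <- numeric(K)
  het_counts <- numeric(K)
  for (g in seq_len(nrow(gs))) {
    a1 <- gs[g, 1]; a2 <- gs[g, 2]
    allele_counts[a1] <- allele_counts[a1] + cnt[g]
    allele_counts[a2] <- allele_counts[a2] + cnt[g]
    if (a1 != a2) {
      het_counts[a1] <- het_counts[a1] + cnt[g]
      het_counts[a2] <- het_counts[a2] + cnt[g]
    }
  }
  list(n = n, allele_counts = allele_counts, het_counts = het_counts)
}

# Weir-Cockerham (1984) variance components at one locus, summed over
# alleles. Input: per-population list(n, allele_counts, het_counts) where
# allele_counts are gene-copy counts and het_counts the number of
# heterozygous individuals carrying each allele. Returns c(a = sum of
# among-population components, abc = sum of a + b + c).
wc84_locus <- function(pops) {
  r <- length(pops)
  ni <- vapply(pops, `[[`, numeric(1), "n")
  if (any(ni < 1) || sum(ni) < 2) return(c(a = 0, abc = 0))
  nbar <- mean(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  K <- length(pops[[1]]$allele_counts)
  asum <- 0; absum <- 0
  for (al in seq_len(K)) {
    pi <- vapply(pops, function(x) x$allele_counts[al] / (2 * x$n),
                 numeric(1))
    hi <- vapply(pops, function(x) x$het_counts[al] / x$n, numeric(1))
    pbar <- sum(ni * pi) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    asum <- asum + a
    absum <- absum + a + b + cc
  }
  c(a = asum, abc = absum)
}
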
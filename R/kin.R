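#' Cotterman coefficients of the standard kin relationships
#'
#' `(k0, k1, k2)` are the probabilities that a pair shares 0, 1 or 2
#' alleles identical by descent at a locus: Unrelated (1,0,0),
#' Parent-Offspring (0,1,0), Full-Sib (1/4,1/2,1/4), Half-Sib (1/2,1/2,0).
#'
#' @return A data frame of class `kinship_model` with columns `name`,
#'   `k0`, `k1`, `k2`.
#' @export
kinship_model <- function() {
  km <- data.frame(
    name = c("U", "PO", "FS", "HS"),
    k0 = c(1, 0, 0.25, 0.5),
    k1 = c(0, 1, 0.50, 0.5),
    k2 = c(0, 0, 0.25, 0.0),
    stringsAsFactors = FALSE
  )
  class(km) <- c("kinship_model", "data.frame")
  km
}

kin_kappa <- function(relationship) {
  km <- kinship_model()
  row <- km[match(relationship, km$name), ]
  if (anyNA(row$k0)) stop(sprintf("unknown relationship %s", relationship))
  c(k0 = row$k0, k1 = row$k1, k2 = row$k2)
}

# --- per-locus probability machinery -------------------------------------
# All pair likelihoods are built from three per-locus objects over the
# unordered genotype space (geno_space order):
#   p_obs  : marginal genotype probabilities, error-convolved
#   J[rel] : joint pair probability matrices, error-convolved
# The per-gene-copy error model: an observed copy equals the true copy with
# probability 1 - eps, else is a fresh draw from the population
# frequencies.

# Allele-level observation matrix: obs_mat[o, t] = P(observe o | true t).
allele_obs_mat <- function(f, eps) {
  K <- length(f)
  (1 - eps) * diag(K) + eps * matrix(f, K, K)
}

# Genotype-level observation matrix M[g_obs, g_true] for unordered
# genotypes, from independent per-copy errors.
geno_obs_mat <- function(f, eps) {
  K <- length(f)
  gs <- geno_space(K)
  G <- nrow(gs)
  if (eps == 0) return(diag(G))
  A <- allele_obs_mat(f, eps)
  M <- matrix(0, G, G)
  for (gt in seq_len(G)) {
    t1 <- gs[gt, 1]; t2 <- gs[gt, 2]
    for (go in seq_len(G)) {
      o1 <- gs[go, 1]; o2 <- gs[go, 2]
      M[go, gt] <- if (o1 == o2) A[o1, t1] * A[o1, t2] else
        A[o1, t1] * A[o2, t2] + A[o2, t1] * A[o1, t2]
    }
  }
  M
}

# HWE genotype probabilities over geno_space.
hwe_geno_probs <- function(f) {
  gs <- geno_space(length(f))
  f[gs[, 1]] * f[gs[, 2]] * ifelse(gs[, 1] == gs[, 2], 1, 2)
}

# P(genotype {x, y} | one transmitted allele t, other drawn from f), as a
# matrix trans[g, t].
transmit_probs <- function(f) {
  K <- length(f)
  gs <- geno_space(K)
  tr <- matrix(0, nrow(gs), K)
  for (t in seq_len(K)) {
    x <- gs[, 1]; y <- gs[, 2]
    tr[, t] <- ifelse(x == y, (x == t) * f[x],
                      (x == t) * f[y] + (y == t) * f[x])
  }
  tr
}

# Joint true-genotype pair matrix under one IBD copy (parent-offspring):
# J[g1, g2] = P(g1) * T(g2 | g1); symmetric.
joint_po <- function(f) {
  gs <- geno_space(length(f))
  P <- hwe_geno_probs(f)
  tr <- transmit_probs(f)
  J <- matrix(0, nrow(gs), nrow(gs))
  for (g1 in seq_len(nrow(gs))) {
    u <- gs[g1, 1]; v <- gs[g1, 2]
    J[g1, ] <- P[g1] * 0.5 * (tr[, u] + tr[, v])
  }
  J
}

# Per-locus lookup tables for a frequency vector: observed-genotype
# marginals and joint matrices for each relationship.
kin_locus_tables <- function(f, eps, relationships = c("PO", "FS", "HS")) {
  P <- hwe_geno_probs(f)
  Jpo <- joint_po(f)
  M <- geno_obs_mat(f, eps)
  p_obs <- as.vector(M %*% P)
  J_U <- outer(P, P)
  joints <- list(U = J_U)
  for (rel in relationships) {
    kap <- kin_kappa(rel)
    J <- kap["k0"] * J_U + kap["k1"] * Jpo + kap["k2"] * diag(P)
    joints[[rel]] <- J
  }
  if (eps > 0) {
    joints <- lapply(joints, function(J) M %*% J %*% t(M))
    # U must stay an exact product so LLR(U vs U) is identically zero
    joints$U <- outer(p_obs, p_obs)
  }
  list(p_obs = p_obs, joints = joints)
}

#' Pairwise kin log-likelihood
#'
#' Log probability of an observed genotype pair under a relationship's
#' Cotterman coefficients: per locus,
#' `P = k0 P(g1) P(g2) + k1 P(g1) T(g2 | g1) + k2 P(g1) [g2 == g1]`,
#' where `T` is the one-IBD-copy transition (one allele transmitted
#' uniformly from `g1`, the other drawn from the frequencies). With
#' `error_rate > 0`, each observed gene copy is correct with probability
#' `1 - error_rate` and otherwise a fresh frequency draw; the error model
#' is convolved into the pair probabilities before mixing. Natural log,
#' summed over loci; a Mendelian exclusion with `error_rate = 0` yields
#' `-Inf`.
#'
#' @param g1,g2 For a single locus: length-2 vectors of allele indices.
#'   For multiple loci: lists of such vectors (NULL elements are skipped as
#'   missing).
#' @param freqs A numeric frequency vector (single locus) or list of
#'   vectors (multi-locus).
#' @param relationship `"U"`, `"PO"`, `"FS"` or `"HS"`.
#' @param error_rate Per-gene-copy error probability.
#' @return Log probability (natural log).
#' @export
pair_loglik <- function(g1, g2, freqs, relationship, error_rate = 0) {
  assert_prob(error_rate, "error_rate")
  if (is.numeric(freqs)) {
    freqs <- list(freqs)
    g1 <- list(g1)
    g2 <- list(g2)
  }
  rel <- match.arg(relationship, c("U", "PO", "FS", "HS"))
  total <- 0
  for (j in seq_along(freqs)) {
    if (is.null(g1[[j]]) || is.null(g2[[j]])) next
    tabs <- kin_locus_tables(freqs[[j]], error_rate,
                             relationships = setdiff(rel, "U"))
    i1 <- geno_index(g1[[j]][1], g1[[j]][2])
    i2 <- geno_index(g2[[j]][1], g2[[j]][2])
    total <- total + log(tabs$joints[[rel]][i1, i2])
  }
  total
}

#' Simulate kin log-likelihood-ratio distributions
#'
#' Draws `n_pairs` genotype pairs under a true relationship and under
#' unrelatedness from population allele frequencies, applies the per-copy
#' genotyping error model to the observed genotypes, and computes each
#' pair's log-likelihood ratio `Lambda = log P(pair | rel) - log
#' P(pair | U)` over all loci. With `importance_sampling = TRUE` the
#' unrelated-tail sample is represented by the pairs drawn under the true
#' relationship carrying raw importance weights `P_U / P_rel =
#' exp(-Lambda)`, which makes vanishing false-positive rates estimable.
#'
#' @param freqs An `allele_freq_set`; `pop` selects the population
#'   (default: first).
#' @param true_rel `"PO"`, `"FS"`, `"HS"` or `"U"`.
#' @param n_pairs Number of pairs per sample.
#' @param error_rate Per-gene-copy genotyping error (default 0.005).
#' @param seed Integer seed.
#' @param importance_sampling Represent the unrelated sample by reweighted
#'   true-relationship pairs.
#' @param pop Population label within `freqs`.
#' @return A list of class `llr_samples`: `true` and `unrelated`, each a
#'   list with `relationship`, `lambda` and optional `weights`;
#'   `effective_sample_size` is attached to a weighted sample.
#' @export
simulate_llr_distributions <- function(freqs, true_rel, n_pairs,
                                       error_rate = 0.005, seed = NULL,
                                       importance_sampling = FALSE,
                                       pop = NULL) {
  stopifnot(inherits(freqs, "allele_freq_set"))
  n_pairs <- assert_count(n_pairs, "n_pairs")
  true_rel <- match.arg(true_rel, c("U", "PO", "FS", "HS"))
  local_seed(seed)
  pop <- pop %||% names(freqs$freq)[1]
  f <- freqs$freq[[pop]]
  if (is.null(f)) stop(sprintf("unknown population %s", pop))
  tabs <- lapply(f, kin_locus_tables, eps = error_rate)
  lam_true <- draw_pairs_lambda(f, tabs, true_rel, n_pairs, error_rate,
                                rel_for_lambda = true_rel)
  out <- list(
    true = list(relationship = true_rel, lambda = lam_true, weights = NULL)
  )
  if (importance_sampling) {
    w <- exp(-lam_true)
    out$unrelated <- list(relationship = "U", lambda = lam_true,
                          weights = w)
    out$unrelated$effective_sample_size <- sum(w)^2 / sum(w^2)
  } else {
    lam_u <- draw_pairs_lambda(f, tabs, "U", n_pairs, error_rate,
                               rel_for_lambda = true_rel)
    out$unrelated <- list(relationship = "U", lambda = lam_u,
                          weights = NULL)
  }
  class(out) <- "llr_samples"
  out
}

# Draw n pairs under `draw_rel` and return Lambda(draw vs U) computed for
# relationship `rel_for_lambda`.
draw_pairs_lambda <- function(f, tabs, draw_rel, n, error_rate,
                              rel_for_lambda) {
  lam <- numeric(n)
  for (j in seq_along(f)) {
    p <- f[[j]]
    K <- length(p)
    draw <- function(m) sample.int(K, m, replace = TRUE, prob = p)
    pick <- function(a, b) ifelse(stats::runif(n) < 0.5, a, b)
    if (draw_rel == "U") {
      g1 <- cbind(draw(n), draw(n))
      g2 <- cbind(draw(n), draw(n))
    } else if (draw_rel == "PO") {
      g1 <- cbind(draw(n), draw(n))
      g2 <- cbind(pick(g1[, 1], g1[, 2]), draw(n))
    } else if (draw_rel == "FS") {
      pa <- cbind(draw(n), draw(n))
      pb <- cbind(draw(n), draw(n))
      g1 <- cbind(pick(pa[, 1], pa[, 2]), pick(pb[, 1], pb[, 2]))
      g2 <- cbind(pick(pa[, 1], pa[, 2]), pick(pb[, 1], pb[, 2]))
    } else { # HS: one shared parent
      ps <- cbind(draw(n), draw(n))
      g1 <- cbind(pick(ps[, 1], ps[, 2]), draw(n))
      g2 <- cbind(pick(ps[, 1], ps[, 2]), draw(n))
    }
    if (error_rate > 0) {
      err <- function(g) {
        e <- matrix(stats::runif(2 * n) < error_rate, n, 2)
        g[e] <- draw(sum(e))
        g
      }
      g1 <- err(g1); g2 <- err(g2)
    }
    i1 <- geno_index(g1[, 1], g1[, 2])
    i2 <- geno_index(g2[, 1], g2[, 2])
    tj <- tabs[[j]]
    lam <- lam + log(tj$joints[[rel_for_lambda]][cbind(i1, i2)]) -
      log(tj$joints$U[cbind(i1, i2)])
  }
  lam
}

#' False-positive rate at a fixed false-negative rate
#'
#' The decision threshold is the `fnr` quantile of the true-relationship
#' log-likelihood-ratio sample (empirical, type 1), so a fraction `fnr` of
#' true pairs falls below it; the false-positive rate is the (importance-
#' weighted, if weights are present) fraction of the unrelated sample at or
#' above the threshold.
#'
#' @param samples An `llr_samples` object (or a list with `true` and
#'   `unrelated` components as documented there).
#' @param fnr Target false-negative rate in (0, 1); default 0.01.
#' @return A list: `fpr`, `threshold`, `fnr`,
#'   `effective_sample_size` (NA for an unweighted sample).
#' @export
fpr_at_fnr <- function(samples, fnr = 0.01) {
  if (!is.numeric(fnr) || fnr <= 0 || fnr >= 1) {
    stop("`fnr` must be in (0, 1)")
  }
  lt <- samples$true$lambda
  lu <- samples$unrelated$lambda
  if (length(lt) == 0L || length(lu) == 0L) stop("empty LLR sample")
  thr <- stats::quantile(lt, probs = fnr, type = 1, names = FALSE)
  w <- samples$unrelated$weights
  if (is.null(w)) {
    fpr <- mean(lu >= thr)
    ess <- NA_real_
  } else {
    fpr <- mean(w * (lu >= thr))
    ess <- samples$unrelated$effective_sample_size %||%
      (sum(w)^2 / sum(w^2))
  }
  list(fpr = fpr, threshold = thr, fnr = fnr,
       effective_sample_size = ess)
}
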
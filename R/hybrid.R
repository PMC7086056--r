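#' The six ancestry categories and their locus-wise ancestry fractions
#'
#' Each category is characterised by the expected fractions `(pi0, pi1,
#' pi2)` of loci at which an individual carries (both copies from
#' population A, one copy from each, both copies from population B):
#' PureA (1,0,0), PureB (0,0,1), F1 (0,1,0), F2 (1/4,1/2,1/4),
#' BC_A (1/2,1/2,0) and BC_B (0,1/2,1/2).
#'
#' @param priors Optional numeric vector of prior category weights (length
#'   6, recycled names as below); default equal priors.
#' @return A data frame of class `hybrid_category_set` with columns
#'   `name`, `pi0`, `pi1`, `pi2`, `prior`.
#' @export
hybrid_categories <- function(priors = NULL) {
  cats <- data.frame(
    name = c("PureA", "PureB", "F1", "F2", "BC_A", "BC_B"),
    pi0 = c(1, 0, 0, 0.25, 0.5, 0),
    pi1 = c(0, 0, 1, 0.50, 0.5, 0.5),
    pi2 = c(0, 1, 0, 0.25, 0.0, 0.5),
    stringsAsFactors = FALSE
  )
  priors <- priors %||% rep(1 / 6, 6)
  if (length(priors) != 6L || any(priors < 0)) {
    stop("priors must be 6 non-negative weights")
  }
  cats$prior <- priors / sum(priors)
  class(cats) <- c("hybrid_category_set", "data.frame")
  cats
}

#' Likelihood of one genotype under an ancestry category
#'
#' For genotype `{a, b}` and per-population frequency vectors `fA`, `fB`,
#' the category likelihood is `pi0*HA + pi1*M + pi2*HB`, where `HA` is the
#' HWE probability under population A, `HB` under population B, and `M`
#' the mixed-ancestry probability `fA(a) fB(b) + fA(b) fB(a)` (or
#' `fA(a) fB(a)` for a homozygote). With `error_rate > 0` the observed
#' genotype is a mixture `(1 - e) * P_true + e * HWE` under the mean of
#' `fA` and `fB`.
#'
#' @param genotype Length-2 vector of allele indices (or names matching
#'   `names(fA)`).
#' @param fA,fB Normalised frequency vectors.
#' @param category Category name (see [hybrid_categories()]) or a row of a
#'   `hybrid_category_set`.
#' @param error_rate Genotype-level error mixture weight in `[0, 1)`.
#' @return A probability.
#' @export
genotype_class_likelihood <- function(genotype, fA, fB, category,
                                      error_rate = 0) {
  assert_prob(error_rate, "error_rate")
  if (is.character(genotype)) genotype <- match(genotype, names(fA))
  a <- genotype[1]; b <- genotype[2]
  if (anyNA(c(a, b)) || a < 1 || b < 1 || a > length(fA) || b > length(fA)) {
    stop("allele outside frequency support")
  }
  if (is.character(category)) {
    cats <- hybrid_categories()
    category <- cats[match(match.arg(category, cats$name), cats$name), ]
  }
  hwe <- function(f) if (a == b) f[a]^2 else 2 * f[a] * f[b]
  M <- if (a == b) fA[a] * fB[a] else fA[a] * fB[b] + fA[b] * fB[a]
  p <- category$pi0 * hwe(fA) + category$pi1 * M + category$pi2 * hwe(fB)
  if (error_rate > 0) {
    p <- (1 - error_rate) * p + error_rate * hwe((fA + fB) / 2)
  }
  unname(p)
}

# Per-locus category likelihood table: rows = unordered genotypes in
# geno_space order, columns = the six categories.
category_locus_table <- function(fA, fB, cats, error_rate) {
  K <- length(fA)
  gs <- geno_space(K)
  het <- gs[, 1] != gs[, 2]
  HA <- fA[gs[, 1]] * fA[gs[, 2]] * ifelse(het, 2, 1)
  HB <- fB[gs[, 1]] * fB[gs[, 2]] * ifelse(het, 2, 1)
  M <- ifelse(het,
              fA[gs[, 1]] * fB[gs[, 2]] + fA[gs[, 2]] * fB[gs[, 1]],
              fA[gs[, 1]] * fB[gs[, 1]])
  tab <- outer(HA, cats$pi0) + outer(M, cats$pi1) + outer(HB, cats$pi2)
  if (error_rate > 0) {
    fm <- (fA + fB) / 2
    Hm <- fm[gs[, 1]] * fm[gs[, 2]] * ifelse(het, 2, 1)
    tab <- (1 - error_rate) * tab + error_rate * Hm
  }
  colnames(tab) <- cats$name
  tab
}

#' Six-category hybrid classification
#'
#' Bayesian posterior over the six ancestry categories for each individual,
#' with plug-in allele frequencies estimated from the two reference tables
#' (pseudocount over the shared allele dictionary, see
#' [estimate_allele_freqs()]). The per-individual posterior is proportional
#' to `prior * prod over called loci` of the category likelihood; missing
#' loci are skipped and the assignment is the arg-max category.
#'
#' When `estimate_mixing = TRUE` the category priors are not fixed but
#' estimated from the classified sample itself by an EM iteration on the
#' mixing proportions (the categories' log-likelihoods are computed once;
#' the priors are updated to the mean posterior until convergence). This
#' mirrors classifying a mixed sample with a model that learns how much of
#' each category the sample contains, and is the protocol used by
#' [power_confusion()] when the reference samples are classified together
#' with the simulated offspring.
#'
#' @param gt Individuals to classify (`genotype_table`).
#' @param refA,refB Reference `genotype_table`s for the two parental
#'   populations (A first, e.g. anadromous).
#' @param categories A `hybrid_category_set`.
#' @param pseudocount Passed to the frequency estimates.
#' @param error_rate Genotype-level error mixture weight.
#' @param estimate_mixing Estimate the category priors from the sample by
#'   EM (default `FALSE`: fixed priors from `categories`).
#' @param max_em_iter,em_tol EM iteration cap and convergence tolerance on
#'   the mixing proportions.
#' @return A data frame of class `class_posterior`: `individual_id`, one
#'   posterior column per category, `max_category`, `max_posterior`,
#'   `n_loci_used`. With `estimate_mixing`, the fitted mixing proportions
#'   are in `attr(, "mixing")`.
#' @export
classify_individuals <- function(gt, refA, refB,
                                 categories = hybrid_categories(),
                                 pseudocount = 0.5, error_rate = 0,
                                 estimate_mixing = FALSE,
                                 max_em_iter = 200L, em_tol = 1e-8) {
  stopifnot(inherits(gt, "genotype_table"))
  if (nrow(refA$a1) == 0L || nrow(refB$a1) == 0L) {
    stop("reference tables must be nonempty")
  }
  al <- align_genotype_tables(list(gt, refA, refB))
  gt <- al$tables[[1]]; refA <- al$tables[[2]]; refB <- al$tables[[3]]
  fset <- two_pop_freqs(refA, refB, pseudocount)
  n <- nrow(gt$a1)
  if (any(rowSums(!is.na(gt$a1)) == 0L)) {
    stop("individual with zero called loci")
  }
  loglik <- matrix(0, n, nrow(categories))
  for (j in seq_len(ncol(gt$a1))) {
    tab <- category_locus_table(fset$fA[[j]], fset$fB[[j]], categories,
                                error_rate)
    called <- which(!is.na(gt$a1[, j]))
    gi <- geno_index(gt$a1[called, j], gt$a2[called, j])
    loglik[called, ] <- loglik[called, ] + log(tab[gi, , drop = FALSE])
  }
  posterior_given_prior <- function(prior) {
    lp <- sweep(loglik, 2, log(prior), `+`)
    lp <- lp - apply(lp, 1, max)
    post <- exp(lp)
    post / rowSums(post)
  }
  prior <- categories$prior
  mixing <- NULL
  if (isTRUE(estimate_mixing)) {
    for (it in seq_len(max_em_iter)) {
      post <- posterior_given_prior(prior)
      new_prior <- colMeans(post)
      if (max(abs(new_prior - prior)) < em_tol) {
        prior <- new_prior
        break
      }
      prior <- new_prior
    }
    mixing <- stats::setNames(prior, categories$name)
  }
  post <- posterior_given_prior(prior)
  colnames(post) <- categories$name
  out <- data.frame(individual_id = rownames(gt$a1), post,
                    stringsAsFactors = FALSE)
  out$max_category <- categories$name[max.col(post, ties.method = "first")]
  out$max_posterior <- apply(post, 1, max)
  out$n_loci_used <- rowSums(!is.na(gt$a1))
  rownames(out) <- NULL
  class(out) <- c("class_posterior", "data.frame")
  if (!is.null(mixing)) attr(out, "mixing") <- mixing
  out
}

# Frequencies of two aligned reference tables as plain per-locus lists.
two_pop_freqs <- function(refA, refB, pseudocount) {
  fA <- estimate_allele_freqs(refA, groups = list(A = gt_individuals(refA)),
                              pseudocount = pseudocount)$freq$A
  fB <- estimate_allele_freqs(refB, groups = list(B = gt_individuals(refB)),
                              pseudocount = pseudocount)$freq$B
  list(fA = fA, fB = fB)
}

#' Supervised two-population admixture proportion
#'
#' Maximum-likelihood point estimate of the proportion `q` of an
#' individual's ancestry from population A, under the standard supervised
#' admixture likelihood: each called gene copy `c` contributes
#' `log(q * fA(c) + (1 - q) * fB(c))`. `q` is found by bounded scalar
#' optimisation on `[0, 1]`; a flat likelihood ties towards 0.5.
#'
#' @inheritParams classify_individuals
#' @return A data frame of class `admixture_estimate`: `individual_id`,
#'   `q`, `loglik`, `n_loci`.
#' @export
estimate_admixture_q <- function(gt, refA, refB, pseudocount = 0.5) {
  stopifnot(inherits(gt, "genotype_table"))
  if (nrow(refA$a1) == 0L || nrow(refB$a1) == 0L) {
    stop("reference tables must be nonempty")
  }
  al <- align_genotype_tables(list(gt, refA, refB))
  gt <- al$tables[[1]]; refA <- al$tables[[2]]; refB <- al$tables[[3]]
  fset <- two_pop_freqs(refA, refB, pseudocount)
  n <- nrow(gt$a1)
  q <- numeric(n); ll <- numeric(n)
  n_loci <- rowSums(!is.na(gt$a1))
  if (any(n_loci == 0L)) stop("individual with zero called loci")
  for (i in seq_len(n)) {
    va <- vb <- numeric(0)
    for (j in seq_len(ncol(gt$a1))) {
      if (is.na(gt$a1[i, j])) next
      idx <- c(gt$a1[i, j], gt$a2[i, j])
      va <- c(va, fset$fA[[j]][idx])
      vb <- c(vb, fset$fB[[j]][idx])
    }
    f <- function(qq) sum(log(qq * va + (1 - qq) * vb))
    opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-9)
    cand_q <- c(0.5, 0, 1, opt$maximum)
    cand_ll <- c(f(0.5), f(0), f(1), opt$objective)
    best <- which.max(cand_ll)
    # prefer 0.5 on exact ties (cand order puts it first)
    best <- which(cand_ll >= cand_ll[best] - 1e-12)[1]
    q[i] <- cand_q[best]
    ll[i] <- cand_ll[best]
  }
  out <- data.frame(individual_id = rownames(gt$a1), q = q, loglik = ll,
                    n_loci = n_loci, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("admixture_estimate", "data.frame")
  out
}

#' Simulation-based power of the six-category classifier
#'
#' Simulates `n_per_class` offspring per ancestry category with
#' [simulate_cross()] from the two reference tables (or from
#' reference-sized samples of a `population_model`), classifies them with
#' [classify_individuals()] and tabulates true against assigned category.
#'
#' The default protocol mirrors how such power runs are done in practice:
#' the simulated offspring are classified together with the reference
#' samples (`include_references = TRUE`) and the category mixing
#' proportions are estimated from that combined sample
#' (`estimate_mixing = TRUE`), so the large pure reference fraction
#' informs the priors just as in a model-based admixture analysis of a
#' real mixed collection. Set both to `FALSE` for a fixed equal-prior
#' assessment of the simulated offspring alone.
#'
#' @param refA A reference `genotype_table` for population A, or a
#'   `population_model` (then reference tables of sizes `ref_sizes` are
#'   drawn from it and `refB` is ignored).
#' @param refB Reference `genotype_table` for population B.
#' @param n_per_class Offspring per category (default 100).
#' @param categories A `hybrid_category_set`.
#' @param pseudocount,error_rate Passed to the classifier.
#' @param ref_sizes Diploid reference sample sizes (A, B) drawn when a
#'   `population_model` is supplied; defaults mirror the study's reference
#'   samples (2,749 anadromous adults, 183 landlocked juveniles).
#' @param include_references Classify the reference individuals alongside
#'   the simulated offspring.
#' @param estimate_mixing Estimate category mixing proportions by EM (see
#'   [classify_individuals()]).
#' @param seed Integer seed.
#' @return A list of class `power_confusion`: `confusion` (6x6 matrix over
#'   the simulated offspring, rows = true class), `accuracy` (per-class
#'   diagonal fraction), `posteriors` (the full `class_posterior`,
#'   references included when classified).
#' @export
power_confusion <- function(refA, refB = NULL, n_per_class = 100L,
                            categories = hybrid_categories(),
                            pseudocount = 0.5, error_rate = 0,
                            ref_sizes = c(2749L, 183L),
                            include_references = TRUE,
                            estimate_mixing = TRUE, seed = NULL) {
  n_per_class <- assert_count(n_per_class, "n_per_class")
  local_seed(seed)
  if (inherits(refA, "population_model")) {
    model <- refA
    refA <- simulate_reference_genotypes(model, "anadromous", ref_sizes[1])
    refB <- simulate_reference_genotypes(model, "landlocked", ref_sizes[2])
  }
  classes <- categories$name
  sims <- lapply(classes, function(cl) {
    s <- simulate_cross(refA, refB, cross_class = map_class_name(cl),
                        n_offspring = n_per_class)
    rownames(s$a1) <- rownames(s$a2) <-
      paste("sim", cl, seq_len(n_per_class), sep = ".")
    s$meta$individual_id <- rownames(s$a1)
    s$meta$true_class <- cl
    s
  })
  sim <- gt_rbind(sims)
  target <- if (include_references) {
    rA <- refA; rB <- refB
    rA$meta$true_class <- "PureA"
    rB$meta$true_class <- "PureB"
    gt_rbind(list(sim, rA, rB))
  } else {
    sim
  }
  post <- classify_individuals(target, refA, refB, categories, pseudocount,
                               error_rate, estimate_mixing = estimate_mixing)
  sim_rows <- match(gt_individuals(sim), post$individual_id)
  truth <- factor(sim$meta$true_class, levels = classes)
  assigned <- factor(post$max_category[sim_rows], levels = classes)
  confusion <- table(true = truth, assigned = assigned)
  accuracy <- diag(confusion) / rowSums(confusion)
  structure(list(confusion = confusion, accuracy = accuracy,
                 posteriors = post, mixing = attr(post, "mixing")),
            class = "power_confusion")
}

# Category names and simulate_cross class labels coincide except the pure
# classes.
map_class_name <- function(cl) {
  switch(cl, PureA = "pureA", PureB = "pureB", cl)
}

#' @export
print.power_confusion <- function(x, ...) {
  cat("classification power (rows = true class):\n")
  print(x$confusion)
  cat("per-class accuracy:\n")
  print(round(x$accuracy, 4))
  invisible(x)
}
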
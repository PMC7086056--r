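#' Simulate reference genotypes under Hardy-Weinberg equilibrium
#'
#' Draws `n` diploid individuals from one population of a
#' [build_population_model()] model; each individual receives two alleles
#' drawn independently from the population's frequency vector at every
#' locus.
#'
#' @param model A `population_model`.
#' @param population `"anadromous"` (ancestral frequencies) or
#'   `"landlocked"` (drifted frequencies).
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed.
#' @param id_prefix Prefix for generated individual ids.
#' @return A `genotype_table` with `group` metadata set to `population`.
#' @export
simulate_reference_genotypes <- function(model, population, n, seed = NULL,
                                         id_prefix = NULL) {
  stopifnot(inherits(model, "population_model"))
  population <- match.arg(population, c("anadromous", "landlocked"))
  n <- assert_count(n, "n")
  local_seed(seed)
  freqs <- switch(population,
                  anadromous = model$ancestral_freqs,
                  landlocked = model$derived_freqs)
  id_prefix <- id_prefix %||% substr(population, 1, 4)
  ids <- sprintf("%s_%05d", id_prefix, seq_len(n))
  loci <- panel_locus_ids(model$panel)
  a1 <- matrix(NA_integer_, n, length(loci), dimnames = list(ids, loci))
  a2 <- a1
  for (j in seq_along(loci)) {
    p <- freqs[[j]]
    a1[, j] <- sample.int(length(p), n, replace = TRUE, prob = p)
    a2[, j] <- sample.int(length(p), n, replace = TRUE, prob = p)
  }
  meta <- data.frame(individual_id = ids, group = population,
                     stringsAsFactors = FALSE)
  genotype_table(a1, a2, panel_alleles(model$panel), meta)
}

#' Simulate offspring of pure and hybrid crosses
#'
#' HYBRIDLAB-style simulation: population allele frequencies are estimated
#' from the two reference genotype tables (plain counts, no pseudocount),
#' virtual parents of the appropriate classes are drawn under HWE, and each
#' offspring receives one gene copy picked uniformly from each parent's two
#' alleles, independently per locus (no linkage). An F2 is F1 x F1 and a
#' backcross is F1 x pure. Fresh virtual parents are drawn for every
#' offspring.
#'
#' @param refA,refB Reference `genotype_table`s for populations A and B
#'   (e.g. anadromous and landlocked), or a two-population
#'   `allele_freq_set` passed as `refA` with `refB = NULL`.
#' @param cross_class One of `"pureA"`, `"pureB"`, `"F1"`, `"F2"`,
#'   `"BC_A"`, `"BC_B"`.
#' @param n_offspring Number of offspring to simulate.
#' @param seed Integer seed.
#' @return A `genotype_table` with `true_class` metadata.
#' @export
simulate_cross <- function(refA, refB = NULL, cross_class, n_offspring,
                           seed = NULL) {
  cross_class <- match.arg(cross_class,
                           c("pureA", "pureB", "F1", "F2", "BC_A", "BC_B"))
  n_offspring <- assert_count(n_offspring, "n_offspring")
  if (inherits(refA, "allele_freq_set")) {
    if (length(refA$freq) != 2L) {
      stop("an allele_freq_set input must contain exactly two populations")
    }
    fA <- refA$freq[[1]]
    fB <- refA$freq[[2]]
    alleles <- refA$alleles
  } else {
    stopifnot(inherits(refA, "genotype_table"),
              inherits(refB, "genotype_table"))
    if (nrow(refA$a1) == 0L || nrow(refB$a1) == 0L) {
      stop("empty reference table")
    }
    ab <- align_genotype_tables(list(refA, refB))
    alleles <- ab$alleles
    fA <- plain_freqs(ab$tables[[1]])
    fB <- plain_freqs(ab$tables[[2]])
  }
  local_seed(seed)
  loci <- names(alleles)
  ids <- sprintf("%s_%05d", cross_class, seq_len(n_offspring))
  a1 <- matrix(NA_integer_, n_offspring, length(loci),
               dimnames = list(ids, loci))
  a2 <- a1
  # A gene copy transmitted by a virtual parent of class c is an A-pop draw
  # with probability pA(c) (independently per copy): pure parents always
  # transmit own-population copies; an F1 parent transmits an A copy with
  # probability 1/2. This is exactly the uniform-pick-from-two-alleles rule
  # with fresh HWE parents.
  copy_probs <- switch(cross_class,
                       pureA = c(1, 1), pureB = c(0, 0),
                       F1 = c(1, 0), F2 = c(0.5, 0.5),
                       BC_A = c(1, 0.5), BC_B = c(0, 0.5))
  for (j in seq_along(loci)) {
    pa <- fA[[j]]; pb <- fB[[j]]
    for (copy in 1:2) {
      fromA <- stats::runif(n_offspring) < copy_probs[copy]
      draws <- integer(n_offspring)
      if (any(fromA)) {
        draws[fromA] <- sample.int(length(pa), sum(fromA), replace = TRUE,
                                   prob = pa)
      }
      if (any(!fromA)) {
        draws[!fromA] <- sample.int(length(pb), sum(!fromA), replace = TRUE,
                                    prob = pb)
      }
      if (copy == 1L) a1[, j] <- draws else a2[, j] <- draws
    }
  }
  meta <- data.frame(individual_id = ids, group = "simulated",
                     true_class = cross_class, stringsAsFactors = FALSE)
  genotype_table(a1, a2, alleles, meta)
}

# Plain (no pseudocount) per-locus allele frequencies of one table; loci
# with zero calls get uniform frequencies.
plain_freqs <- function(gt) {
  lapply(stats::setNames(seq_along(gt$alleles), names(gt$alleles)),
         function(j) {
    K <- length(gt$alleles[[j]])
    cnt <- tabulate(c(gt$a1[, j], gt$a2[, j]), nbins = K)
    if (sum(cnt) == 0) rep(1 / K, K) else cnt / sum(cnt)
  })
}

# Remap a list of genotype tables onto a shared per-locus allele dictionary
# (union of dictionaries, first table's order first).
align_genotype_tables <- function(gts) {
  loci <- gt_loci(gts[[1]])
  for (g in gts) {
    if (!identical(gt_loci(g), loci)) stop("tables must share loci")
  }
  alleles <- stats::setNames(lapply(loci, function(l) {
    unique(unlist(lapply(gts, function(g) g$alleles[[l]])))
  }), loci)
  tables <- lapply(gts, function(g) {
    a1 <- g$a1; a2 <- g$a2
    for (j in seq_along(loci)) {
      map <- match(g$alleles[[loci[j]]], alleles[[loci[j]]])
      a1[, j] <- map[g$a1[, j]]
      a2[, j] <- map[g$a2[, j]]
    }
    genotype_table(a1, a2, alleles, g$meta, g$anomalies)
  })
  list(alleles = alleles, tables = tables)
}

#' Simulate offspring of specific parents by Mendelian transmission
#'
#' Each offspring receives one gene copy picked uniformly from each named
#' parent's two alleles at every locus; loci where a parent's genotype is
#' missing yield a missing offspring call.
#'
#' @param parents A `genotype_table` containing the parents.
#' @param dam_ids,sire_ids Character vectors (recycled against each other)
#'   naming the parent pair of each offspring.
#' @param seed Integer seed.
#' @param id_prefix Prefix for offspring ids.
#' @return A `genotype_table` with `dam_id`/`sire_id` metadata.
#' @export
simulate_offspring <- function(parents, dam_ids, sire_ids, seed = NULL,
                               id_prefix = "off") {
  stopifnot(inherits(parents, "genotype_table"))
  n <- max(length(dam_ids), length(sire_ids))
  dam_ids <- rep_len(dam_ids, n)
  sire_ids <- rep_len(sire_ids, n)
  di <- match(dam_ids, rownames(parents$a1))
  si <- match(sire_ids, rownames(parents$a1))
  if (anyNA(di) || anyNA(si)) stop("unknown parent id")
  local_seed(seed)
  ids <- sprintf("%s_%05d", id_prefix, seq_len(n))
  L <- ncol(parents$a1)
  a1 <- matrix(NA_integer_, n, L,
               dimnames = list(ids, colnames(parents$a1)))
  a2 <- a1
  for (j in seq_len(L)) {
    pick <- function(rows) {
      u <- stats::runif(n) < 0.5
      ifelse(u, parents$a1[rows, j], parents$a2[rows, j])
    }
    a1[, j] <- pick(di)
    a2[, j] <- pick(si)
  }
  meta <- data.frame(individual_id = ids, dam_id = dam_ids,
                     sire_id = sire_ids, stringsAsFactors = FALSE)
  genotype_table(a1, a2, parents$alleles, meta)
}

#' Apply per-gene-copy genotyping error to a table
#'
#' Each called gene copy is replaced, independently with probability
#' `error_rate`, by a random allele drawn from the locus frequencies
#' (estimated from the table itself unless supplied) — the same miscall
#' model the kin and parentage likelihoods assume.
#'
#' @param gt A `genotype_table`.
#' @param error_rate Per-copy miscall probability.
#' @param freqs Optional list of per-locus frequency vectors.
#' @param seed Integer seed.
#' @return A `genotype_table`.
#' @export
apply_genotyping_error <- function(gt, error_rate, freqs = NULL,
                                   seed = NULL) {
  assert_prob(error_rate, "error_rate")
  if (error_rate == 0) return(gt)
  local_seed(seed)
  freqs <- freqs %||% plain_freqs(gt)
  a1 <- gt$a1; a2 <- gt$a2
  n <- nrow(a1)
  for (j in seq_len(ncol(a1))) {
    p <- freqs[[j]]
    for (mat in c("a1", "a2")) {
      m <- get(mat)
      hit <- which(!is.na(m[, j]) & stats::runif(n) < error_rate)
      if (length(hit)) {
        m[hit, j] <- sample.int(length(p), length(hit), replace = TRUE,
                                prob = p)
        assign(mat, m)
      }
    }
  }
  genotype_table(a1, a2, gt$alleles, gt$meta, gt$anomalies)
}
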
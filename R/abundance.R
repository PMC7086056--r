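#' Habitat-stratified seine survey design
#'
#' @param habitats Data frame with `habitat` (e.g. `"pelagic"`,
#'   `"littoral"`) and `area_m2` (> 0).
#' @param sets_per_habitat Number of replicate seine sets per habitat.
#' @param set_area_m2 Area encircled by one set (default 100 m2).
#' @param densities Matrix of true densities (fish / m2), habitats x
#'   classes (row names = habitats, column names = class labels); all
#'   entries >= 0.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(habitats, sets_per_habitat = 3L,
                          set_area_m2 = 100, densities) {
  stopifnot(is.data.frame(habitats),
            all(c("habitat", "area_m2") %in% names(habitats)))
  if (any(habitats$area_m2 <= 0)) stop("habitat areas must be positive")
  if (set_area_m2 <= 0) stop("`set_area_m2` must be positive")
  densities <- as.matrix(densities)
  if (any(densities < 0)) stop("negative density")
  if (!setequal(rownames(densities), habitats$habitat)) {
    stop("density rows must match habitats")
  }
  structure(list(habitats = habitats,
                 sets_per_habitat = as.integer(sets_per_habitat),
                 set_area_m2 = set_area_m2,
                 densities = densities[habitats$habitat, , drop = FALSE]),
            class = "survey_design")
}

#' Simulate a habitat-stratified purse-seine survey
#'
#' Per seine set, the catch is Poisson with mean (total habitat density x
#' set area); the genetically classified subsample's class counts are
#' multinomial with the habitat's class composition. By default the
#' composition follows the design's true densities and every caught fish
#' is classified.
#'
#' @param design A `survey_design`.
#' @param class_composition Optional matrix (habitats x classes) of
#'   composition proportions overriding the density-implied composition;
#'   rows must sum to 1.
#' @param n_classified Optional named vector of per-habitat genetic
#'   subsample sizes; default classifies the whole catch.
#' @param seed Integer seed.
#' @return A `survey_data` list: `sets` (habitat, set_id, area_m2, count),
#'   `composition` (habitat x class counts), `areas` (named vector).
#' @export
simulate_survey <- function(design, class_composition = NULL,
                            n_classified = NULL, seed = NULL) {
  stopifnot(inherits(design, "survey_design"))
  local_seed(seed)
  dens_total <- rowSums(design$densities)
  comp <- class_composition %||%
    sweep(design$densities, 1,
          ifelse(dens_total > 0, dens_total, 1), `/`)
  if (any(abs(rowSums(comp)[dens_total > 0] - 1) > 1e-9)) {
    stop("composition proportions must sum to 1 per habitat")
  }
  habs <- design$habitats$habitat
  sets <- do.call(rbind, lapply(habs, function(h) {
    data.frame(habitat = h, set_id = seq_len(design$sets_per_habitat),
               area_m2 = design$set_area_m2,
               count = stats::rpois(design$sets_per_habitat,
                                    dens_total[h] * design$set_area_m2),
               stringsAsFactors = FALSE)
  }))
  comp_counts <- matrix(0L, length(habs), ncol(design$densities),
                        dimnames = list(habs, colnames(design$densities)))
  for (h in habs) {
    caught <- sum(sets$count[sets$habitat == h])
    n_cl <- if (is.null(n_classified)) caught else
      min(caught, n_classified[[h]])
    if (n_cl > 0 && sum(comp[h, ]) > 0) {
      comp_counts[h, ] <- as.vector(stats::rmultinom(1, n_cl, comp[h, ]))
    }
  }
  structure(list(sets = sets, composition = comp_counts,
                 areas = stats::setNames(design$habitats$area_m2, habs)),
            class = "survey_data")
}

#' Mean seine density in one habitat
#'
#' @param sets Data frame of seine sets (`habitat`, `area_m2`, `count`).
#' @param habitat Habitat label.
#' @return A list: `density` (fish / m2, mean of count/area over sets),
#'   `se` (standard error over sets; `NA` with a `single_set` flag when
#'   only one set exists), `n_sets`.
#' @export
density_estimate <- function(sets, habitat) {
  sel <- sets[sets$habitat == habitat, , drop = FALSE]
  if (nrow(sel) == 0L) stop(sprintf("no sets in habitat %s", habitat))
  d <- sel$count / sel$area_m2
  list(density = mean(d),
       se = if (nrow(sel) > 1L) stats::sd(d) / sqrt(nrow(sel)) else
         NA_real_,
       single_set = nrow(sel) == 1L,
       n_sets = nrow(sel))
}

#' Class-specific abundance by habitat with bootstrap CIs
#'
#' Point estimates are `N[h, c] = density_h x area_h x p[h, c]`, with the
#' composition proportion `p` taken from the genetically classified counts;
#' class totals sum over habitats. Percentile bootstrap CIs resample seine
#' sets with replacement within habitat and redraw composition counts
#' multinomially.
#'
#' @param survey A `survey_data` list (see [simulate_survey()]); any list
#'   with `sets`, `composition` and `areas` of the documented shapes
#'   works.
#' @param n_boot Bootstrap replicates (default 10,000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return A list of class `abundance_estimate`: `by_habitat` (data frame
#'   class x habitat with `estimate`, `lower`, `upper`, `pct_abundance`,
#'   `pct_composition`), `totals` (per class with CI), `method`.
#' @export
class_abundance <- function(survey, n_boot = 10000L, conf = 0.95,
                            seed = NULL) {
  local_seed(seed)
  habs <- rownames(survey$composition)
  classes <- colnames(survey$composition)
  comp_tot <- rowSums(survey$composition)
  if (any(comp_tot == 0)) stop("zero composition total in a habitat")
  point <- matrix(0, length(habs), length(classes),
                  dimnames = list(habs, classes))
  dens <- numeric(length(habs)); names(dens) <- habs
  for (h in habs) {
    dens[h] <- density_estimate(survey$sets, h)$density
    point[h, ] <- dens[h] * survey$areas[h] *
      survey$composition[h, ] / comp_tot[h]
  }
  boot_hab <- array(NA_real_, c(n_boot, length(habs), length(classes)))
  for (b in seq_len(n_boot)) {
    for (hi in seq_along(habs)) {
      h <- habs[hi]
      sel <- survey$sets[survey$sets$habitat == h, , drop = FALSE]
      rs <- sel[sample.int(nrow(sel), replace = TRUE), , drop = FALSE]
      db <- mean(rs$count / rs$area_m2)
      pb <- as.vector(stats::rmultinom(1, comp_tot[h],
                                       survey$composition[h, ] /
                                         comp_tot[h])) / comp_tot[h]
      boot_hab[b, hi, ] <- db * survey$areas[h] * pb
    }
  }
  alpha <- (1 - conf) / 2
  qfun <- function(x) stats::quantile(x, c(alpha, 1 - alpha), names = FALSE)
  by_habitat <- do.call(rbind, lapply(seq_along(classes), function(ci) {
    do.call(rbind, lapply(seq_along(habs), function(hi) {
      qs <- qfun(boot_hab[, hi, ci])
      data.frame(class = classes[ci], habitat = habs[hi],
                 estimate = point[hi, ci], lower = qs[1], upper = qs[2],
                 stringsAsFactors = FALSE)
    }))
  }))
  # percent of each class by habitat: abundance-weighted and
  # composition-only (both emitted; they differ when habitat areas differ)
  class_tot <- colSums(point)
  by_habitat$pct_abundance <- 100 * by_habitat$estimate /
    class_tot[by_habitat$class]
  pc <- sweep(survey$composition, 1, comp_tot, `/`)
  pcn <- sweep(pc, 2, colSums(pc), `/`)
  by_habitat$pct_composition <- 100 *
    pcn[cbind(by_habitat$habitat, by_habitat$class)]
  boot_tot <- apply(boot_hab, c(1, 3), sum)
  totals <- do.call(rbind, lapply(seq_along(classes), function(ci) {
    qs <- qfun(boot_tot[, ci])
    data.frame(class = classes[ci], estimate = class_tot[ci],
               lower = qs[1], upper = qs[2], stringsAsFactors = FALSE)
  }))
  rownames(by_habitat) <- rownames(totals) <- NULL
  structure(list(by_habitat = by_habitat, totals = totals,
                 method = "percentile bootstrap", n_boot = n_boot,
                 conf = conf),
            class = "abundance_estimate")
}

#' Chi-square test of class composition across habitats
#'
#' Pearson chi-square on the habitat x class contingency table, no
#' continuity correction; optionally a Monte-Carlo p-value (useful when
#' expected counts fall below 5).
#'
#' @param composition Matrix of counts, habitats x classes (>= 2 of each).
#' @param monte_carlo Use a simulated p-value.
#' @param B Monte-Carlo replicates.
#' @return A list: `statistic`, `df`, `p_value`, `method`.
#' @export
composition_test <- function(composition, monte_carlo = FALSE, B = 10000L) {
  composition <- as.matrix(composition)
  if (nrow(composition) < 2L || ncol(composition) < 2L) {
    stop("need >= 2 habitats and >= 2 classes")
  }
  if (any(rowSums(composition) == 0) || any(colSums(composition) == 0)) {
    stop("degenerate table: a margin of zeros")
  }
  ct <- suppressWarnings(
    stats::chisq.test(composition, correct = FALSE,
                      simulate.p.value = monte_carlo, B = B))
  list(statistic = unname(ct$statistic),
       df = if (monte_carlo) NA_integer_ else unname(ct$parameter),
       p_value = ct$p.value,
       method = if (monte_carlo) "Pearson chi-square, Monte-Carlo p" else
         "Pearson chi-square")
}
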
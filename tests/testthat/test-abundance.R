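test_that("density estimates are set means with SE over sets", {
  sets <- data.frame(habitat = rep("pelagic", 3), area_m2 = 100,
                     count = c(10, 20, 30))
  d <- density_estimate(sets, "pelagic")
  expect_equal(d$density, 0.2)
  expect_equal(d$se, stats::sd(c(0.1, 0.2, 0.3)) / sqrt(3))
  single <- data.frame(habitat = "littoral", area_m2 = 100, count = 0)
  ds <- density_estimate(single, "littoral")
  expect_equal(ds$density, 0)
  expect_true(is.na(ds$se))
  expect_true(ds$single_set)
  equal <- data.frame(habitat = rep("p", 3), area_m2 = 100, count = 7)
  expect_equal(density_estimate(equal, "p")$se, 0)
  expect_error(density_estimate(sets, "bathyal"), "no sets")
})

test_that("class abundance equals density x area x composition", {
  survey <- list(
    sets = data.frame(habitat = rep("pelagic", 3), area_m2 = 100,
                      count = c(20, 20, 20)),
    composition = matrix(c(10, 10), 1, 2,
                         dimnames = list("pelagic", c("land", "anad"))),
    areas = c(pelagic = 10000))
  est <- class_abundance(survey, n_boot = 200, seed = 281)
  expect_equal(est$by_habitat$estimate, c(1000, 1000))
  expect_equal(est$totals$estimate, c(1000, 1000),
               ignore_attr = TRUE)
  # one-class composition: the other class is 0 with a (0, 0) interval
  survey2 <- survey
  survey2$composition[1, ] <- c(20, 0)
  est2 <- class_abundance(survey2, n_boot = 200, seed = 282)
  anad <- est2$by_habitat[est2$by_habitat$class == "anad", ]
  expect_equal(c(anad$estimate, anad$lower, anad$upper), c(0, 0, 0))
  # linear scaling in area and density
  survey3 <- survey
  survey3$areas <- c(pelagic = 20000)
  est3 <- class_abundance(survey3, n_boot = 50, seed = 283)
  expect_equal(est3$by_habitat$estimate, 2 * est$by_habitat$estimate)
  survey4 <- survey
  survey4$sets$count <- survey4$sets$count * 3
  est4 <- class_abundance(survey4, n_boot = 50, seed = 284)
  expect_equal(est4$by_habitat$estimate, 3 * est$by_habitat$estimate)
})

test_that("abundances sum to density x area and CIs cover the point", {
  design <- survey_design(
    habitats = data.frame(habitat = c("pelagic", "littoral"),
                          area_m2 = c(8e5, 2e5)),
    sets_per_habitat = 3, set_area_m2 = 100,
    densities = matrix(c(0.3, 0.1, 0.05, 0.15), 2, 2,
                       dimnames = list(c("pelagic", "littoral"),
                                       c("land", "anad"))))
  sv <- simulate_survey(design, seed = 291)
  est <- class_abundance(sv, n_boot = 500, seed = 292)
  for (h in c("pelagic", "littoral")) {
    dh <- density_estimate(sv$sets, h)$density
    sel <- est$by_habitat$habitat == h
    expect_equal(sum(est$by_habitat$estimate[sel]), dh * sv$areas[h],
                 ignore_attr = TRUE)
  }
  ok <- with(est$by_habitat, lower <= estimate & estimate <= upper)
  expect_true(all(ok))
  # habitat percentages per class sum to 100
  pct <- tapply(est$by_habitat$pct_abundance, est$by_habitat$class, sum)
  expect_equal(as.numeric(pct), rep(100, 2), tolerance = 0.1)
})

test_that("survey simulation honours densities and composition", {
  design <- survey_design(
    habitats = data.frame(habitat = c("pelagic", "littoral"),
                          area_m2 = c(1e5, 1e5)),
    sets_per_habitat = 200, set_area_m2 = 100,
    densities = matrix(c(0.2, 0, 0, 0), 2, 2,
                       dimnames = list(c("pelagic", "littoral"),
                                       c("c1", "c2"))))
  sv <- simulate_survey(design, seed = 301)
  # zero-density habitat catches nothing
  expect_true(all(sv$sets$count[sv$sets$habitat == "littoral"] == 0))
  # Poisson mean = density x set area = 20
  expect_lt(abs(mean(sv$sets$count[sv$sets$habitat == "pelagic"]) - 20),
            1)
  # degenerate composition puts every classified fish in class 1
  expect_identical(unname(sv$composition["pelagic", "c2"]), 0L)
  expect_error(survey_design(
    habitats = data.frame(habitat = "p", area_m2 = 1),
    densities = matrix(-1, 1, 1, dimnames = list("p", "c1"))),
    "negative density")
})

test_that("composition chi-square matches hand values", {
  same <- matrix(c(10, 10, 5, 5), 2, 2,
                 dimnames = list(c("p", "l"), c("c1", "c2")))
  expect_equal(composition_test(same)$statistic, 0)
  diag2 <- matrix(c(10, 0, 0, 10), 2, 2,
                  dimnames = list(c("p", "l"), c("c1", "c2")))
  ct <- composition_test(diag2)
  expect_equal(ct$statistic, 20)
  expect_identical(unname(ct$df), 1L)
  prop <- matrix(c(30, 3, 10, 1), 2, 2) # proportional rows
  expect_equal(composition_test(prop)$statistic, 0, tolerance = 1e-12)
  expect_error(composition_test(matrix(c(1, 0, 0, 0), 2, 2)),
               "degenerate|margin")
  mc <- composition_test(diag2, monte_carlo = TRUE, B = 500)
  expect_lt(mc$p_value, 0.05)
})

test_that("stratified point estimates are unbiased over replicates", {
  design <- survey_design(
    habitats = data.frame(habitat = c("pelagic", "littoral"),
                          area_m2 = c(9e5, 1.6e5)),
    sets_per_habitat = 3, set_area_m2 = 100,
    densities = matrix(c(0.35, 0.05, 0.08, 0.12), 2, 2,
                       dimnames = list(c("pelagic", "littoral"),
                                       c("land", "anad"))))
  truth <- sweep(design$densities, 1,
                 stats::setNames(design$habitats$area_m2,
                                 design$habitats$habitat)[
                   rownames(design$densities)], `*`)
  truth_tot <- colSums(truth)
  est_tot <- matrix(0, 300, 2)
  withr::with_seed(311, {
    for (b in 1:300) {
      sv <- simulate_survey(design)
      comp_ok <- all(rowSums(sv$composition) > 0)
      if (!comp_ok) next
      dens <- vapply(rownames(sv$composition), function(h)
        density_estimate(sv$sets, h)$density, numeric(1))
      pt <- sweep(sweep(sv$composition, 1, rowSums(sv$composition), `/`),
                  1, dens * sv$areas, `*`)
      est_tot[b, ] <- colSums(pt)
    }
  })
  est_tot <- est_tot[rowSums(est_tot) > 0, ]
  rel_bias <- abs(colMeans(est_tot) - truth_tot) / truth_tot
  expect_true(all(rel_bias < 0.05))
})
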
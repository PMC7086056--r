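#' Parentage LOD score
#'
#' Base-10 log-odds of a parentage hypothesis against unrelatedness. For a
#' single candidate parent the per-locus term is
#' `log10 P(g_o | g_p, f) / P(g_o | f)` with Mendelian transmission of one
#' gene copy and a frequency draw for the other; for a candidate pair both
#' copies are transmitted, one from each parent. With `error_rate > 0` the
#' per-copy miscall model of [pair_loglik()] is convolved in. A Mendelian
#' exclusion at `error_rate = 0` yields `-Inf`.
#'
#' @param offspring,dam,sire Genotypes: length-2 allele-index vectors for a
#'   single locus, or lists of such vectors for multiple loci (`NULL`
#'   entries are treated as missing and skipped). At least one of `dam` /
#'   `sire` must be given.
#' @param freqs A numeric frequency vector or list of vectors.
#' @param error_rate Per-gene-copy error probability.
#' @return LOD score (base 10).
#' @export
parentage_lod <- function(offspring, dam = NULL, sire = NULL, freqs,
                          error_rate = 0) {
  if (is.null(dam) && is.null(sire)) stop("need at least one candidate")
  if (is.numeric(freqs)) {
    freqs <- list(freqs)
    offspring <- list(offspring)
    if (!is.null(dam)) dam <- list(dam)
    if (!is.null(sire)) sire <- list(sire)
  }
  lod <- 0
  for (j in seq_along(freqs)) {
    go <- offspring[[j]]
    if (is.null(go)) next
    f <- freqs[[j]]
    gd <- if (!is.null(dam)) dam[[j]]
    gs <- if (!is.null(sire)) sire[[j]]
    if (is.null(gd) && is.null(gs)) next
    if (!is.null(gd) && !is.null(gs)) {
      tabs <- trio_locus_table(f, error_rate)
      io <- geno_index(go[1], go[2])
      id <- geno_index(gd[1], gd[2])
      is_ <- geno_index(gs[1], gs[2])
      lod <- lod + (log(tabs$J3[io, id, is_]) -
                      log(tabs$p_obs[io] * tabs$p_obs[id] *
                            tabs$p_obs[is_])) / log(10)
    } else {
      gp <- gd %||% gs
      tabs <- kin_locus_tables(f, error_rate, relationships = "PO")
      io <- geno_index(go[1], go[2])
      ip <- geno_index(gp[1], gp[2])
      lod <- lod + (log(tabs$joints$PO[io, ip]) -
                      log(tabs$joints$U[io, ip])) / log(10)
    }
  }
  lod
}

# Trio joint over observed genotypes: J3[g_o, g_d, g_s] with independent
# HWE parents and Mendelian transmission of one copy from each; plus the
# observed marginal p_obs.
trio_locus_table <- function(f, eps) {
  K <- length(f)
  gs <- geno_space(K)
  G <- nrow(gs)
  P <- hwe_geno_probs(f)
  # P(offspring g | parents d, s): average over the 2 x 2 transmissions
  Jt <- array(0, c(G, G, G))
  for (d in seq_len(G)) {
    for (s in seq_len(G)) {
      du <- gs[d, ]; sv <- gs[s, ]
      for (x in 1:2) {
        for (y in 1:2) {
          g <- geno_index(du[x], sv[y])
          Jt[g, d, s] <- Jt[g, d, s] + 0.25
        }
      }
      Jt[, d, s] <- Jt[, d, s] * P[d] * P[s]
    }
  }
  M <- geno_obs_mat(f, eps)
  p_obs <- as.vector(M %*% P)
  if (eps > 0) {
    # convolve each tensor mode with the genotype observation matrix
    mode_mult <- function(A, mode) {
      perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3),
                     `3` = c(3, 1, 2))
      B <- aperm(A, perm)
      B <- M %*% matrix(B, G, G * G)
      dim(B) <- c(G, G, G)
      aperm(B, order(perm))
    }
    Jt <- mode_mult(mode_mult(mode_mult(Jt, 1), 2), 3)
  }
  list(J3 = Jt, p_obs = p_obs)
}

#' Likelihood parentage assignment with constraints and thresholds
#'
#' For every offspring, candidate parents are filtered by the year
#' constraint (stocking year must not postdate the offspring's birth
#' year), single-parent LOD scores are computed against all remaining
#' candidates, and candidate configurations are enumerated: none, each
#' single parent among the top `max_single` candidates, and each
#' (sex-consistent, when the sex constraint is on) pair among those top
#' candidates. Configuration posteriors are prior-weighted normalised
#' likelihoods, with the prior of the "none" configuration derived from
#' `sampled_fraction` (the probability that a true parent is in the
#' candidate set): P(pair sampled) = s^2, P(exactly one) = 2s(1-s),
#' P(none) = (1-s)^2, split evenly over the configurations of each kind.
#' An assignment is accepted only if its posterior exceeds
#' `posterior_threshold` and its LOD exceeds `lod_threshold`; ties break
#' towards "none". Full-sib families are derived from shared accepted
#' parents.
#'
#' @param offspring A `genotype_table`; metadata column `cohort_year` is
#'   used by the year constraint.
#' @param candidates A `genotype_table` of candidate parents; metadata
#'   columns `stocking_year` (year constraint) and `sex` (`"F"`/`"M"`,
#'   sex constraint).
#' @param constraints List with logical `year` and `sex`.
#' @param posterior_threshold,lod_threshold Acceptance thresholds (defaults
#'   0.98 and 10).
#' @param sampled_fraction Prior probability that a true parent is among
#'   the candidates.
#' @param max_single Number of top single candidates searched for pairs.
#' @param freqs Optional `allele_freq_set` for the background frequencies;
#'   default estimated from the candidates (pseudocount 0.5).
#' @param error_rate Per-gene-copy genotyping error (default 0.005).
#' @return A list of class `parentage_result`: `assignments` (data frame
#'   with offspring_id, configuration, dam_id, sire_id, LOD, posterior),
#'   `sibships` (see [sibship_summary()]).
#' @export
assign_parentage <- function(offspring, candidates,
                             constraints = list(year = TRUE, sex = TRUE),
                             posterior_threshold = 0.98,
                             lod_threshold = 10,
                             sampled_fraction = 0.9,
                             max_single = 20L,
                             freqs = NULL,
                             error_rate = 0.005) {
  stopifnot(inherits(offspring, "genotype_table"),
            inherits(candidates, "genotype_table"))
  al <- align_genotype_tables(list(offspring, candidates))
  offspring <- al$tables[[1]]; candidates <- al$tables[[2]]
  if (is.null(freqs)) {
    freqs <- estimate_allele_freqs(
      candidates, groups = list(cand = gt_individuals(candidates)),
      pseudocount = 0.5)
    fvec <- freqs$freq$cand
  } else {
    fvec <- freqs$freq[[1]]
  }
  use_year <- isTRUE(constraints$year)
  use_sex <- isTRUE(constraints$sex)
  if (use_year && (!"stocking_year" %in% names(candidates$meta) ||
                   !"cohort_year" %in% names(offspring$meta))) {
    stop("year constraint needs candidate stocking_year and offspring cohort_year")
  }
  if (use_sex && !"sex" %in% names(candidates$meta)) {
    stop("sex constraint needs candidate sex metadata")
  }
  loci <- gt_loci(offspring)
  tabs <- lapply(fvec, kin_locus_tables, eps = error_rate,
                 relationships = "PO")
  trios <- lapply(fvec, trio_locus_table, eps = error_rate)

  n_off <- nrow(offspring$a1)
  n_cand <- nrow(candidates$a1)
  cand_ids <- gt_individuals(candidates)
  off_ids <- gt_individuals(offspring)

  # single-parent LOD and offspring log-lik under "none", locus by locus
  lod_single <- matrix(0, n_off, n_cand,
                       dimnames = list(off_ids, cand_ids))
  ll_none <- numeric(n_off)
  ll_single_pair_cache <- NULL
  for (j in seq_along(loci)) {
    oi <- geno_index(offspring$a1[, j], offspring$a2[, j])
    ci <- geno_index(candidates$a1[, j], candidates$a2[, j])
    ok_o <- !is.na(oi); ok_c <- !is.na(ci)
    lr <- log(tabs[[j]]$joints$PO) - log(tabs[[j]]$joints$U)
    contrib <- matrix(0, n_off, n_cand)
    contrib[ok_o, ok_c] <- lr[oi[ok_o], ci[ok_c], drop = FALSE]
    lod_single <- lod_single + contrib
    ll_none[ok_o] <- ll_none[ok_o] + log(tabs[[j]]$p_obs[oi[ok_o]])
  }
  lod_single <- lod_single / log(10)

  assignments <- vector("list", n_off)
  for (i in seq_len(n_off)) {
    keep <- rep(TRUE, n_cand)
    if (use_year) {
      keep <- keep & (candidates$meta$stocking_year <=
                        offspring$meta$cohort_year[i])
      keep[is.na(keep)] <- FALSE
    }
    cand_idx <- which(keep)
    res <- list(offspring_id = off_ids[i], configuration = "none",
                dam_id = NA_character_, sire_id = NA_character_,
                LOD = 0, posterior = NA_real_)
    if (length(cand_idx) == 0L) {
      res$posterior <- 1
      assignments[[i]] <- res
      next
    }
    lods <- lod_single[i, cand_idx]
    ord <- cand_idx[order(lods, decreasing = TRUE)]
    top <- ord[seq_len(min(max_single, length(ord)))]
    # configurations: none / single(top) / pairs among top
    pair_idx <- NULL
    if (length(top) >= 2L) {
      pr <- t(utils::combn(top, 2L))
      if (use_sex) {
        sx <- candidates$meta$sex
        ok <- (sx[pr[, 1]] == "F" & sx[pr[, 2]] == "M") |
          (sx[pr[, 1]] == "M" & sx[pr[, 2]] == "F")
        ok[is.na(ok)] <- FALSE
        pr <- pr[ok, , drop = FALSE]
      }
      pair_idx <- pr
    }
    # log-likelihood of the offspring genotype under each configuration
    s <- sampled_fraction
    n_single_cfg <- length(cand_idx)
    n_pair_cfg <- max(1L, choose(length(cand_idx), 2L))
    cfg_ll <- ll_none[i]
    cfg_lprior <- log((1 - s)^2)
    cfg_desc <- list(list(type = "none"))
    for (cidx in top) {
      cfg_ll <- c(cfg_ll, ll_none[i] + lod_single[i, cidx] * log(10))
      cfg_lprior <- c(cfg_lprior, log(2 * s * (1 - s)) - log(n_single_cfg))
      cfg_desc <- c(cfg_desc, list(list(type = "single", p1 = cidx)))
    }
    if (!is.null(pair_idx) && nrow(pair_idx) > 0L) {
      ll_pair <- pair_config_loglik(offspring, i, candidates, pair_idx,
                                    trios)
      cfg_ll <- c(cfg_ll, ll_pair)
      cfg_lprior <- c(cfg_lprior,
                      rep(log(s^2) - log(n_pair_cfg), nrow(pair_idx)))
      for (k in seq_len(nrow(pair_idx))) {
        cfg_desc <- c(cfg_desc, list(list(type = "pair",
                                          p1 = pair_idx[k, 1],
                                          p2 = pair_idx[k, 2])))
      }
    }
    lp <- cfg_ll + cfg_lprior
    lp <- lp - max(lp)
    post <- exp(lp) / sum(exp(lp))
    best <- which(post >= max(post) - 1e-12)[1] # ties toward "none" (first)
    cfg <- cfg_desc[[best]]
    res$posterior <- post[best]
    if (cfg$type == "single") {
      res$LOD <- lod_single[i, cfg$p1]
    } else if (cfg$type == "pair") {
      res$LOD <- (cfg_ll[best] - ll_none[i]) / log(10)
    }
    accepted <- cfg$type != "none" &&
      res$posterior > posterior_threshold && res$LOD > lod_threshold
    if (accepted) {
      res$configuration <- cfg$type
      ids <- cand_ids[c(cfg$p1, cfg$p2)]
      sx <- if ("sex" %in% names(candidates$meta)) {
        candidates$meta$sex[c(cfg$p1, cfg$p2)]
      } else rep(NA_character_, length(ids))
      if (cfg$type == "pair") {
        if (!anyNA(sx) && all(sort(sx) == c("F", "M"))) {
          res$dam_id <- ids[sx == "F"]
          res$sire_id <- ids[sx == "M"]
        } else {
          res$dam_id <- ids[1]; res$sire_id <- ids[2]
        }
      } else {
        if (identical(sx[1], "F")) res$dam_id <- ids[1] else
          res$sire_id <- ids[1]
        if (is.na(sx[1])) res$dam_id <- ids[1]
      }
    }
    assignments[[i]] <- res
  }
  adf <- do.call(rbind, lapply(assignments, function(r) {
    data.frame(r, stringsAsFactors = FALSE)
  }))
  structure(list(assignments = adf, sibships = sibship_summary(adf)),
            class = "parentage_result")
}

# Offspring log-likelihood under each candidate pair, via the trio tables:
# log P(g_o | g_d, g_s) summed over loci = log J3 - log(p_obs_d p_obs_s).
pair_config_loglik <- function(offspring, i, candidates, pair_idx, trios) {
  ll <- numeric(nrow(pair_idx))
  for (j in seq_along(trios)) {
    oi <- geno_index(offspring$a1[i, j], offspring$a2[i, j])
    if (is.na(oi)) next
    c1 <- geno_index(candidates$a1[pair_idx[, 1], j],
                     candidates$a2[pair_idx[, 1], j])
    c2 <- geno_index(candidates$a1[pair_idx[, 2], j],
                     candidates$a2[pair_idx[, 2], j])
    tt <- trios[[j]]
    ok <- !is.na(c1) & !is.na(c2)
    both <- which(ok)
    if (length(both)) {
      ll[both] <- ll[both] +
        log(tt$J3[cbind(oi, c1[both], c2[both])]) -
        log(tt$p_obs[c1[both]]) - log(tt$p_obs[c2[both]])
    }
    # one parent missing at this locus: fall back to the single-parent term
    one1 <- which(!is.na(c1) & is.na(c2))
    one2 <- which(is.na(c1) & !is.na(c2))
    if (length(one1) || length(one2)) {
      for (k in c(one1, one2)) {
        ci <- if (is.na(c2[k])) c1[k] else c2[k]
        po2 <- marg_po_cond(tt, oi, ci)
        ll[k] <- ll[k] + log(po2)
      }
    }
    miss <- which(is.na(c1) & is.na(c2))
    if (length(miss)) ll[miss] <- ll[miss] + log(tt$p_obs[oi])
  }
  ll
}

# P(g_o | one observed parent) from the trio table by marginalising the
# other parent: sum_s J3[o, p, s] / p_obs[p].
marg_po_cond <- function(tt, oi, pi) {
  sum(tt$J3[oi, pi, ]) / tt$p_obs[pi]
}

#' Summarise sibships implied by accepted parentage assignments
#'
#' Offspring sharing an accepted dam-sire pair form a full-sib family;
#' per-parent offspring counts are tabulated by parent id (and sex where
#' known from the dam/sire role).
#'
#' @param assignments The `assignments` data frame of a
#'   `parentage_result`.
#' @return A list: `families` (data frame keyed by dam_id/sire_id with
#'   `size` and comma-separated `offspring`), `family_size_histogram`,
#'   `per_parent` (offspring counts per parent with role).
#' @export
sibship_summary <- function(assignments) {
  acc <- assignments[assignments$configuration == "pair" &
                       !is.na(assignments$dam_id) &
                       !is.na(assignments$sire_id), , drop = FALSE]
  families <- NULL
  if (nrow(acc) > 0L) {
    key <- paste(acc$dam_id, acc$sire_id, sep = "|")
    sp <- split(acc$offspring_id, key)
    families <- data.frame(
      dam_id = sub("\\|.*", "", names(sp)),
      sire_id = sub(".*\\|", "", names(sp)),
      size = lengths(sp),
      offspring = vapply(sp, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE)
    rownames(families) <- NULL
  }
  hist <- if (is.null(families)) integer(0) else table(families$size)
  single <- assignments[assignments$configuration %in% c("single", "pair"),
                        , drop = FALSE]
  pp <- NULL
  if (nrow(single) > 0L) {
    long <- rbind(
      data.frame(parent_id = single$dam_id, role = "dam",
                 stringsAsFactors = FALSE),
      data.frame(parent_id = single$sire_id, role = "sire",
                 stringsAsFactors = FALSE))
    long <- long[!is.na(long$parent_id), , drop = FALSE]
    if (nrow(long) > 0L) {
      tt <- table(long$parent_id)
      pp <- data.frame(parent_id = names(tt),
                       n_offspring = as.integer(tt),
                       role = long$role[match(names(tt), long$parent_id)],
                       stringsAsFactors = FALSE)
      rownames(pp) <- NULL
    }
  }
  list(families = families, family_size_histogram = hist, per_parent = pp)
}

#' Cross-tabulate assigned offspring by parental stocking dates
#'
#' Two-parent assignments are tabulated by the (unordered) pair of
#' stocking dates of dam and sire (upper-triangular date x date counts);
#' single-parent assignments are tallied by the parent's stocking date.
#' Percentages are relative to the total of each tabulation, mirroring the
#' conventional summary of which stocking events produced offspring.
#'
#' @param assignments `assignments` data frame of a `parentage_result`.
#' @param stocking_dates Named character vector mapping candidate ids to
#'   stocking dates (any label; chronological order taken from
#'   `date_levels` or sorted unique values).
#' @param date_levels Optional ordering of the date labels.
#' @return A list: `pair_counts`, `pair_pct` (upper-triangular matrices),
#'   `single_counts`, `single_pct`.
#' @export
stocking_crosstab <- function(assignments, stocking_dates,
                              date_levels = NULL) {
  date_levels <- date_levels %||% sort(unique(unname(stocking_dates)))
  nd <- length(date_levels)
  pair_counts <- matrix(0L, nd, nd,
                        dimnames = list(date_levels, date_levels))
  pairs <- assignments[assignments$configuration == "pair", , drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    d1 <- stocking_dates[[pairs$dam_id[k]]]
    d2 <- stocking_dates[[pairs$sire_id[k]]]
    ij <- sort(match(c(d1, d2), date_levels))
    pair_counts[ij[1], ij[2]] <- pair_counts[ij[1], ij[2]] + 1L
  }
  singles <- assignments[assignments$configuration == "single", ,
                         drop = FALSE]
  sd <- vapply(seq_len(nrow(singles)), function(k) {
    id <- singles$dam_id[k]
    if (is.na(id)) id <- singles$sire_id[k]
    stocking_dates[[id]]
  }, character(1))
  single_counts <- table(factor(sd, levels = date_levels))
  pct <- function(x) {
    tot <- sum(x)
    if (tot == 0) x * 0 else 100 * x / tot
  }
  list(pair_counts = pair_counts, pair_pct = pct(pair_counts),
       single_counts = single_counts, single_pct = pct(single_counts))
}
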
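#!/usr/bin/env Rscript
# Stage 3 — population-genetic characterisation: diversity per group,
# between-ecotype differentiation, PCA of a mixed collection, and the
# best-SNP panel reduction used by the marker-comparison stages.

suppressPackageStartupMessages(library(alewifemix))

out <- "results"
panel <- read_panel(file.path(out, "panel.tsv"))
refA <- read_genotypes(file.path(out, "ref_anadromous.csv"),
                       file.path(out, "ref_anadromous_meta.csv"),
                       alleles = panel_alleles(panel))
refB <- read_genotypes(file.path(out, "ref_landlocked.csv"),
                       file.path(out, "ref_landlocked_meta.csv"),
                       alleles = panel_alleles(panel))
both <- gt_rbind(refA, refB)

ds <- diversity_summary(both)
write.table(ds, file.path(out, "diversity_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
fst <- pairwise_fst(both, "anadromous", "landlocked")
write.table(fst$per_locus, file.path(out, "fst_per_locus.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("overall theta = %.4f", fst$theta))

# PCA of references plus a small simulated hybrid cohort
hyb <- gt_rbind(
  simulate_cross(refA, refB, "F1", 30, seed = 20170841),
  local({
    g <- simulate_cross(refA, refB, "BC_B", 30, seed = 20170842)
    rownames(g$a1) <- rownames(g$a2) <- paste0("bcb", 1:30)
    g$meta$individual_id <- rownames(g$a1); g
  }))
sub <- gt_subset(both, individuals = c(1:200, 2750:2932))
pca_in <- gt_rbind(sub, hyb)
pca <- genotype_pca(pca_in, n_pc = 4)
scores <- data.frame(individual_id = rownames(pca$scores), pca$scores)
write.csv(scores, file.path(out, "pca_scores.csv"), row.names = FALSE)
message(sprintf("PCA: PC1 explains %.1f%% of dosage variance",
                100 * pca$var_explained[1]))
if (requireNamespace("ggplot2", quietly = TRUE)) {
  scores$group <- ifelse(grepl("^anad", scores$individual_id), "anadromous",
                  ifelse(grepl("^land", scores$individual_id), "landlocked",
                  ifelse(grepl("^F1", scores$individual_id), "F1",
                         "landlocked backcross")))
  p <- ggplot2::ggplot(scores,
                       ggplot2::aes(PC1, PC2, colour = group)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(title = "Reference and simulated hybrid juveniles")
  ggplot2::ggsave(file.path(out, "pca_scatter.png"), p,
                  width = 6, height = 4, dpi = 150)
}

# best-SNP reduction
fr <- estimate_allele_freqs(both)
tr <- panel_to_best_snp(panel, fr)
snp_tab <- data.frame(locus_id = names(tr$offsets),
                      best_offset = unname(tr$offsets),
                      n_bases = lengths(tr$bases))
write.table(snp_tab, file.path(out, "best_snp_sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("best-SNP panel: %d loci reduced to single sites (%d biallelic)",
                nrow(snp_tab), sum(snp_tab$n_bases == 2)))
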
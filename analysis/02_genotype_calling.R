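#!/usr/bin/env Rscript
# Stage 2 — amplicon read simulation and microhaplotype calling.
#
# A subsample of landlocked individuals is pushed through the full
# read-level path: merged reads as SAM, phase-preserving haplotype
# extraction, the depth-10 / ratio-0.2 calling filters, and the
# individual-level QC (>= 20% missing data, or > 2 haplotypes at >= 3
# loci). The stage reports concordance between called and true genotypes.

suppressPackageStartupMessages(library(alewifemix))

seed <- 20170830
out <- "results"
panel <- read_panel(file.path(out, "panel.tsv"))
truth_all <- read_genotypes(file.path(out, "ref_landlocked.csv"),
                            file.path(out, "ref_landlocked_meta.csv"),
                            alleles = panel_alleles(panel))
truth <- gt_subset(truth_all, individuals = 1:40)

sam <- file.path(out, "reads.sam")
vcf <- file.path(out, "target_sites.vcf")
info <- simulate_reads(truth, panel, sam, vcf,
                       depth_law = list(dist = "nbinom", mu = 50, size = 5),
                       per_base_error = 0.01, seed = seed)
message(sprintf("wrote %d reads for %d individuals x %d loci",
                info$n_reads, nrow(truth$a1), ncol(truth$a1)))

hd <- extract_haplotype_depths(sam, panel,
                               vcf_sites = read_vcf_sites(vcf))
called <- call_genotypes(hd, panel)
qc <- apply_individual_qc(called)
write.table(qc$report, file.path(out, "qc_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("QC: %d of %d individuals retained",
                sum(!qc$report$dropped), nrow(qc$report)))

kept <- gt_subset(qc$genotypes,
                  individuals = intersect(gt_individuals(qc$genotypes),
                                          gt_individuals(truth)))
conc <- 0; tot <- 0
for (i in gt_individuals(kept)) {
  ti <- match(i, gt_individuals(truth))
  ki <- match(i, gt_individuals(kept))
  for (j in seq_len(ncol(truth$a1))) {
    if (is.na(kept$a1[ki, j])) next
    tot <- tot + 1
    t_alleles <- sort(c(truth$alleles[[j]][truth$a1[ti, j]],
                        truth$alleles[[j]][truth$a2[ti, j]]))
    k_alleles <- sort(c(kept$alleles[[j]][kept$a1[ki, j]],
                        kept$alleles[[j]][kept$a2[ki, j]]))
    conc <- conc + identical(t_alleles, k_alleles)
  }
}
message(sprintf("call concordance with simulated truth: %.2f%% (%d calls)",
                100 * conc / tot, tot))
write_genotypes(qc$genotypes, file.path(out, "called_genotypes.csv"))
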
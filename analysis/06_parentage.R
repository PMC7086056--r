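#!/usr/bin/env Rscript
# Stage 6 — constrained parentage assignment of lake-caught juveniles to
# stocked adults, with sibship summarisation and the stocking-date
# cross-tabulation of assigned offspring.

suppressPackageStartupMessages(library(alewifemix))

out <- "results"
seed <- 20170871
panel <- read_panel(file.path(out, "panel.tsv"))
refA <- read_genotypes(file.path(out, "ref_anadromous.csv"),
                       file.path(out, "ref_anadromous_meta.csv"),
                       alleles = panel_alleles(panel))

# candidate adults: stocked over three dates in 2017, sexed in the field
cand <- gt_subset(refA, individuals = 1:800)
set.seed(seed)
dates <- c("2017-03-30", "2017-04-12", "2017-04-19")
cand$meta$sex <- sample(c("F", "M"), 800, replace = TRUE)
cand$meta$stocking_date <- sample(dates, 800, replace = TRUE)
cand$meta$stocking_year <- 2017

# true families: 60 offspring from sampled dam-sire pairs
dams <- sample(cand$meta$individual_id[cand$meta$sex == "F"], 60)
sires <- sample(cand$meta$individual_id[cand$meta$sex == "M"], 60,
                replace = TRUE) # some sires father several offspring
off <- simulate_offspring(cand, dams, sires, seed = seed + 1)
off$meta$cohort_year <- 2017
off_obs <- apply_genotyping_error(off, 0.005, seed = seed + 2)

cand_obs <- apply_genotyping_error(cand, 0.005, seed = seed + 3)
cand_obs$meta <- cand$meta

res <- assign_parentage(off_obs, cand_obs)
write_run_sidecar(file.path(out, "parentage_assignments.run.json"),
                  stage = "parentage", seed = seed,
                  params = list(posterior_threshold = 0.98,
                                lod_threshold = 10, sampled_fraction = 0.9,
                                error_rate = 0.005,
                                constraints = list(year = TRUE, sex = TRUE)))
a <- res$assignments
write.table(a, file.path(out, "parentage_assignments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
ok <- a$configuration == "pair" &
  ((a$dam_id == dams & a$sire_id == sires) |
     (a$dam_id == sires & a$sire_id == dams))
message(sprintf("recovered %d/60 true parent pairs; %d false pairs",
                sum(ok), sum(a$configuration == "pair") - sum(ok)))

if (!is.null(res$sibships$families)) {
  write.table(res$sibships$families, file.path(out, "sibships.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message("full-sib family size histogram:")
  print(res$sibships$family_size_histogram)
}

ct <- stocking_crosstab(a, stats::setNames(cand$meta$stocking_date,
                                           cand$meta$individual_id),
                        date_levels = dates)
write.table(round(ct$pair_pct, 1),
            file.path(out, "stocking_crosstab_pct.tsv"), sep = "\t",
            quote = FALSE)
message("assigned offspring by parental stocking-date pair (%):")
print(round(ct$pair_pct, 1))
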
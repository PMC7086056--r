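# alewifemix

Genetic analysis of secondary contact between anadromous and landlocked
alewife (*Alosa pseudoharengus*) ecotypes, for fisheries geneticists and
restoration ecologists working with multiallelic microhaplotype panels.

When dams that isolated a landlocked alewife population for ~300 years
(~110 freshwater generations) are bypassed and anadromous adults are
stocked above them, the two ecotypes can interbreed. Tracking that
process requires assigning thousands of juveniles to ancestry
categories — pure anadromous, pure landlocked, F1, F2 and the
reciprocal backcrosses — and to their stocked parents, then converting
habitat-stratified seine catches into class-specific abundances.
`alewifemix` implements the whole chain:

* **Microhaplotype calling** from aligned amplicon reads (SAM):
  phase-preserving CIGAR walks to the panel SNP sites, the depth (10)
  and depth-ratio (0.2) filters, and individual QC (≥ 20% missing
  data, or > 2 haplotypes at ≥ 3 loci).
* **Population genetics**: allelic richness *N*<sub>a</sub>, observed
  and Nei's unbiased expected heterozygosity
  *H*<sub>e</sub> = (2n/(2n−1))(1 − Σp²), multiallelic Weir–Cockerham
  θ (ratio of variance-component sums over alleles and loci), dosage
  PCA, and reduction of each locus to its most informative SNP.
* **Hybrid classification**: six-category Bayesian posteriors with
  per-locus likelihood π₀H_A + π₁M + π₂H_B, plug-in reference
  frequencies, optional EM-estimated category mixing proportions, and
  simulation-based power/confusion assessment; supervised
  two-population admixture proportions *q̂* by bounded maximum
  likelihood.
* **Close-kin power and parentage**: pair log-likelihood ratios
  Λ = log P(pair | k₀,k₁,k₂) − log P(pair | U) with a per-gene-copy
  genotyping-error model, false-positive rate at a false-negative rate
  of 0.01 (importance sampling for tails below 10⁻⁶), and constrained
  parentage (stocking-year and sex), accepting assignments with
  posterior > 0.98 and base-10 LOD > 10, with sibship summaries and
  stocking-date cross-tabulations.
* **Abundance**: habitat-stratified density from replicate 100-m²
  purse-seine sets, class abundance N<sub>h,c</sub> = density ×
  area × composition with percentile-bootstrap CIs, and a composition
  chi-square test.
* **A calibrated synthetic-data generator** (Wright–Fisher drift
  between ecotypes, HYBRIDLAB-style crosses, read simulation, seine
  surveys) so every stage is testable offline; its defaults reproduce
  the reference diversity table (N_a ≈ 4.07/2.02, H_e ≈ 0.47/0.30 for
  anadromous/landlocked reference samples of 2,749/183 diploids).

## Worked example

```r
library(alewifemix)

model <- build_population_model(seed = 42)
model
#> population_model: 114 loci, t = 110 generations of drift at Ne = 130

refA <- simulate_reference_genotypes(model, "anadromous", 2749, seed = 43)
refB <- simulate_reference_genotypes(model, "landlocked", 183, seed = 44)
both <- gt_rbind(refA, refB)
diversity_summary(both)
#>   population    n n_loci       Na        He        Ho
#> 1 anadromous 2749    114 4.131579 0.4422768 0.4420587
#> 2 landlocked  183    114 2.052632 0.2918106 0.2888505
pairwise_fst(both, "anadromous", "landlocked")
#> Weir-Cockerham theta (anadromous vs landlocked): 0.1584 over 114 loci

juv <- simulate_cross(refA, refB, cross_class = "BC_B",
                      n_offspring = 5, seed = 45)
post <- classify_individuals(juv, refA, refB)
round(post[, c("PureB", "BC_B", "F2", "max_posterior")], 3)
#>   PureB  BC_B    F2 max_posterior
#> 1     0 1.000 0.000         1.000
#> 2     0 0.261 0.072         0.667
#> 3     0 0.983 0.007         0.983
#> 4     0 0.997 0.002         0.997
#> 5     0 0.982 0.017         0.982
```

The calibrated model drifts a 114-locus anadromous gene pool for 110
generations at the effective size its built-in search selects (here
N<sub>e</sub> = 130), reproducing the reference samples' allelic
richness (4.13 vs 2.05 alleles/locus) and heterozygosity (0.44 vs
0.29). Five simulated landlocked-backcross juveniles are then
classified against the references: four are confidently recovered as
backcrosses (posterior ≥ 0.98) and one is ambiguous (0.667) — at this
panel's information content a few percent of backcrosses are genuinely
hard to separate from F2s, which is exactly what the power analysis
quantifies.

The `analysis/` directory holds the numbered stage scripts
(`01_simulate.R` … `07_abundance.R`); each reads its inputs from
`results/`, prints a short narrative, and writes its tables back to
`results/`. Run them in order with `Rscript`.

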
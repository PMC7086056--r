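---
title: "Models and methods behind alewifemix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind alewifemix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alewifemix)
```

# The study system this package emulates

Anadromous alewife (*Alosa pseudoharengus*) mature at sea and spawn in
lakes; landlocked populations, isolated above colonial-era dams for
roughly three centuries (on the order of 110 freshwater generations),
complete their life cycle in the lake. When fishway construction and
adult stocking re-establish access, the two ecotypes meet again and can
hybridise. The analytical questions are: can multiallelic microhaplotype
markers (short amplicons carrying several phased SNPs) assign juveniles
to pure and hybrid ancestry categories and to their parents with
near-certainty; and how are the ancestry classes distributed across lake
habitats?

`alewifemix` implements that analysis end to end — haplotype calling
from aligned amplicon reads, six-category hybrid classification,
close-kin log-likelihood power, constrained parentage, and
habitat-stratified abundance — together with a calibrated synthetic-data
generator so every stage is testable without any external download.

# The synthetic-data generator

## Population model

Each of 114 loci receives an allele count $K \sim 2 +
\mathrm{Binomial}(6,\,0.36)$ truncated to $[2,8]$, and ancestral
(anadromous) haplotype frequencies from a symmetric Dirichlet with
concentration $\alpha = 0.44$. The landlocked population is produced by
$t = 110$ generations of Wright–Fisher drift: each generation resamples
$2N_e$ gene copies multinomially, so the derived allele support is
always a subset of the ancestral support and frequencies stay
normalised at every generation.

$N_e$ is not fixed a priori. `build_population_model()` runs a seeded
grid search over $N_e \in \{100, 110, \dots, 180\}$, simulating a
183-diploid landlocked sample at each candidate and choosing the value
minimising the squared relative error to the two landlocked calibration
targets: mean observed alleles per locus $N_a \approx 2.02$ and
unbiased expected heterozygosity $H_e \approx 0.30$. The anadromous
side is calibrated by the $(\textrm{prob},\alpha)$ defaults to
$N_a \approx 4.07$ and $H_e \approx 0.47$ in a 2,749-diploid sample.
These four targets are the diversity table of the emulated reference
samples; over seeded replicates the generator reproduces them within
$\pm 0.2$ alleles/locus and $\pm 0.02$–$0.03$ heterozygosity.

## Why drift-only divergence pins $\theta$ near 0.15

The between-ecotype differentiation implied by these choices is
Weir–Cockerham $\theta \approx 0.15$, noticeably above the $\approx
0.12$ observed between the real ecotypes. This is not a tuning
accident but a structural property of drift-only divergence: with the
ancestral population unchanged, $\theta$ is empirically about $0.43
\times$ the relative heterozygosity loss, so a loss of
$1 - 0.30/0.47 \approx 0.36$ forces $\theta \approx 0.15$. Conversely,
constraining $\theta = 0.12$ would force $N_a^{land} \approx 2.3$ and
$H_e^{land} \approx 0.34$. The real populations' history is evidently
not pure drift from the modern anadromous baseline (the true ancestor
differed from today's source stock, and marker ascertainment shapes the
real panel). We calibrate to allelic richness and heterozygosity — the
quantities that drive classification and kin power — and accept the
inflated $\theta$; the corresponding differentiation check in the
acceptance tests is expected to fail and documents this limit.

## What the generator does and does not emulate

It emulates: multiallelic loci with 2–8 phased haplotypes; HWE
reference samples of the study's sizes; pedigree-structured crosses
(pure, F1, F2, reciprocal backcrosses) with HYBRIDLAB semantics
(virtual parents drawn from estimated frequencies, one gene copy
transmitted uniformly per parent); read-level data (negative-binomial
depth, mean 50, dispersion 5 — chosen to exercise the depth-10 filter;
binomial split of reads between the two haplotypes; independent
per-base errors); and habitat-stratified Poisson seine catches with
multinomial class composition.

It does not emulate: linkage between loci (loci are independent),
private landlocked alleles (impossible under drift-only divergence),
marker ascertainment, chimeric or mis-mapped reads, or juvenile
out-migration before the survey. The ascertainment gap matters: the
real 114 loci were selected from ddRAD data for discriminatory power,
so the real panel separates ancestry classes somewhat better than a
random panel matching the same diversity table. Consequently the
classifier's simulated pure-class accuracy here is 99–100% and the
landlocked-backcross accuracy 95–98%, slightly below the 99% of the
ascertained panel, and the admixture-proportion RMSE across classes is
about 0.055 rather than under 0.05. Passing tests on this generator
demonstrate correctness of the machinery at realistic information
content, not the exact power of the ascertained panel.

# Haplotype calling and QC

`extract_haplotype_depths()` walks each read's CIGAR to the panel's SNP
offsets, keeping per-read phase; reads with a deletion or clip at any
target site are discarded and counted. Calling applies the two
standard microhaplotype filters: a genotype is missing below 10 total
reads; haplotypes with depth ratio (relative to the deepest haplotype)
below 0.2 are treated as sequencing error. One surviving haplotype
calls a homozygote, two a heterozygote, more than two a missing call
flagged as contamination evidence. Individual-level QC drops fish with
$\ge$ 20% missing loci (inclusive, matching the stated rule) or with
contamination flags at $\ge$ 3 loci ("several" is qualitative in the
source protocol; 3 is the configurable default).

A subtlety the tests encode: with sequencing error present, raising the
depth-ratio threshold can *rescue* a three-haplotype cell into a clean
heterozygote, so the intuitive monotonicity of heterozygote calls in
the ratio threshold only holds for error-free data.

# Classification and admixture

The six ancestry categories are characterised by their expected
fractions $(\pi_0, \pi_1, \pi_2)$ of loci with 0, 1 or 2 gene copies of
landlocked origin. Per locus the category likelihood is
$\pi_0 H_A + \pi_1 M + \pi_2 H_B$ with $H_A, H_B$ the HWE probabilities
under each reference and $M$ the mixed-ancestry term; posteriors
multiply across called loci. Reference allele frequencies are plug-in
estimates with a pseudocount of 0.5 spread over the union allele
dictionary, so an allele unseen in one reference cannot annihilate a
likelihood. We use the plug-in rather than Gibbs sampling over
frequencies because the reference samples here are large (hundreds to
thousands of individuals), making frequency uncertainty negligible.

Two prior modes exist. Plain classification uses fixed (default equal)
category priors. Power assessment (`power_confusion()`) classifies the
simulated offspring *together with* the reference samples and estimates
the category mixing proportions from that combined sample by EM — the
protocol a model-based mixture analysis of a real collection uses, and
the one under which pure-class accuracy reaches 100%: the large pure
reference fraction correctly informs the priors. Both modes are
available; the EM mode is the default for power runs.

The supervised admixture proportion $\hat q$ maximises
$\sum_{\text{copies}} \log\!\big(q f_A(c) + (1-q) f_B(c)\big)$ by
bounded scalar optimisation on $[0,1]$; exact ties resolve to 0.5. A
property run shows the best-SNP panel shrinks the $\hat q$ separation
between F1 and landlocked-backcross classes relative to the full
microhaplotypes, the qualitative marker-comparison result.

# Kin likelihoods, power, and parentage

Pair probabilities mix the three identity-by-descent states with
Cotterman coefficients $(k_0,k_1,k_2)$; the one-IBD transition
transmits one allele uniformly from the first genotype and draws the
other from the population frequencies. Genotyping error is modelled
per gene copy: an observed copy is correct with probability
$1-\varepsilon$ (default $\varepsilon = 0.005$) and otherwise a fresh
frequency-weighted draw; the error model is convolved into the
likelihood tables before mixing, and the same model is used to corrupt
simulated data, keeping simulation and inference consistent. All pair
computations go through per-locus lookup tables over the unordered
genotype space, verified against a brute-force enumeration oracle to
$10^{-12}$.

False-positive rates at a fixed false-negative rate (0.01) use the
empirical FNR-quantile of the true-relationship log-likelihood-ratio
sample as threshold. Rates far below direct Monte-Carlo reach
(parent–offspring truly has FPR $\sim 10^{-10}$ on this panel) are
estimated by importance sampling: pairs drawn under the true
relationship carry raw weights $P_U/P_{rel} = e^{-\Lambda}$, reported
together with the effective sample size. Raw (unclipped) weights keep
the estimator unbiased; the ESS can be small for extreme tails, which
is acceptable because those tails only need to be bounded, not
precisely measured.

Parentage enumerates, per offspring, the configurations none / each
single candidate / each sex-consistent pair among the top 20 single
candidates by LOD (base 10, the parentage-literature convention).
Posteriors weight configuration likelihoods by priors derived from the
candidate sampling fraction $s$ (default 0.9): $P(\text{pair}) = s^2$,
$P(\text{one}) = 2s(1-s)$, $P(\text{none}) = (1-s)^2$, split evenly
within each kind. Assignments need posterior $> 0.98$ *and* LOD $> 10$;
ties break conservatively toward "none". The year constraint removes
candidates stocked after the offspring's birth year before any
likelihood is computed, so it can never be violated. This enumeration
replaces a full pedigree MCMC; for a single-generation design (stocked
adults, lake-born juveniles) the enumeration is exact for the question
asked.

# Abundance

Habitat density is the mean of count/area over replicate 100-m² seine
sets; class abundance is density × habitat area × composition
proportion from the genetically classified subsample. Confidence
intervals are percentile bootstrap (resample sets within habitat,
redraw composition multinomially; 10,000 replicates by default) — the
CI method is a package choice and is labelled in the output. Habitat
areas are required inputs; the analysis scripts use a 106-ha lake split
85% pelagic / 15% littoral, a defensible figure for a deep kettle lake
but still a modelling choice. Because percent-by-habitat can be read
two ways, both are emitted: `pct_abundance` (area-weighted, from the
abundance estimates) and `pct_composition` (sample-composition only).
Estimates are "in-lake at survey time"; juveniles that already
out-migrated are out of scope.

# Numerical choices and problem sizes

* All randomness flows through explicit `seed` arguments applied
  locally (the caller's RNG state is restored); derived seeds stay
  below $2^{31}$.
* Log-likelihood sums subtract their maximum before exponentiation;
  exact zeros (fixed frequencies with pseudocount 0) propagate as
  $-\infty$ and behave correctly in posteriors.
* The empirical FNR quantile uses type-1 (inverse-ECDF) quantiles.
* Unit tests run the generator at 6–60 loci; the end-to-end checks use
  the full 114-locus model with the study's reference sizes (2,749 and
  183), 100 simulated offspring per category, $10^4$ pairs per kin
  relationship, 100 offspring against 1,000 candidates for parentage,
  and 10,000 bootstrap replicates for abundance — about half a minute
  in total. These sizes are the package's chosen defaults for a
  desk-scale reproduction; all are arguments.

# Known limitations

* Drift-only divergence cannot reproduce the observed combination of
  heterozygosity contrast and $\theta$ (above), and produces no private
  landlocked alleles.
* Classification power is the Bayes error of the generator's panel:
  a few percent of backcross and F2 individuals are genuinely
  indistinguishable from neighbouring categories at this information
  content.
* Half-sib assignment is underpowered at 114 loci (FPR $\sim 10^{-1}$
  at FNR 0.01) — quantified, and deliberately not used for inference.
* The importance-sampling ESS for extreme tails (PO) is small; treat
  those FPRs as order-of-magnitude bounds.
* Sibship reconstruction is derived from accepted parent assignments
  only; likelihood-based sibling clustering without parents is out of
  scope.
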
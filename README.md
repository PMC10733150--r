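# coalabc

Coalescent simulation and approximate Bayesian computation (ABC) for
inferring the demographic history of structured populations, built around a
five-population sampling design from Indigenous Australian population
genomics: four Australian community samples — Tiwi Islands (`TIW`),
Galiwin'ku (`GAL`), Titjikala (`TIJ`), Yarrabah (`YAR`) — a Highland Papua
New Guinea sample (`PNG`), and a deep outgroup (`OUT`).

The package answers three kinds of question, entirely from simulated data
(cohorts of this kind are access-controlled, so the synthetic-cohort module
reproduces the statistical structure of the design — sample sizes
34/17/7/31/25, biallelic SNVs on unlinked loci, diploid ancestry-mask
missingness — with no individual-level data):

1. **Scenario choice.** Which of seven candidate rooted histories of the
   Australian populations relative to PNG does a dataset support?
   Implemented as rejection ABC over a simulated reference table, with an
   ABC-random-forest classifier for scenario choice, posterior scenario
   probabilities, and Bayes factors for scenario groups (e.g. the
   Tiwi-outgroup family {4,5,6}).
2. **Parameter estimation.** Split times *T* (generations), diploid
   effective sizes *N<sub>e</sub>* (pairwise coalescence rate 1/(2*N<sub>e</sub>*)),
   migration rates *m* (backward lineage-movement probability per
   generation) and admixture-pulse proportions, reported as weighted
   posterior medians with 95% highest-posterior-density intervals.
3. **Cohort statistics.** The surrounding statistic suite: F2/F3/F4 with
   weighted block-jackknife errors (Z-score rules |Z| > 3 for
   non-cladeness, Z < −3 for admixture-F3), Hudson-type unbiased
   F<sub>ST</sub>, Tajima's D, nucleotide diversity, variant-sharing
   classes, minor-allele-count spectra, discovery curves, per-individual
   heterozygosity and rare-allele sharing with ancestry-mask rescaling, and
   ground-truth relative cross-coalescence-rate (rCCR) curves,
   `rCCR = 2λ_cross/(λ_A + λ_B)`, with 0.5/0.9 crossing-time heuristics.

The structured-coalescent simulator (splits, piecewise sizes, migration
bands, pulses; infinite-sites mutation on unlinked loci) is implemented in
C++ and is exact: the test suite checks it against closed forms
(E[T<sub>MRCA</sub>] = 2N, Watterson's E[S], E[π] = 4Nμ) and a
goodness-of-fit test on coalescence waiting times.

## Worked example

Simulate a small cohort under the calibrated best-supported history
(scenario 4: Tiwi as outgroup to the other Australians, AU–PNG split 1,636
generations ≈ 47 ka), then test for shared drift with PNG:

```r
library(coalabc)

model <- scenario4_calibrated()          # calibrated scenario-4 history
ds <- simulate_dataset(model, default_sample_config(10, 10, 7, 10, 10, 5),
                       locus_config(n_loci = 1500, length_bp = 5e4),
                       seed = 1)
ds
#> haplotype_dataset: 1500 loci x 50,000 bp, 52 diploids (6 pops)

# Outgroup F3: Tiwi shares more drift with PNG than inland Titjikala,
# reflecting the calibrated PNG -> northern-Australia migration band
f_statistic(ds, "F3", c("OUT", "PNG", "TIW"))$estimate
#> [1] 0.03389
f_statistic(ds, "F3", c("OUT", "PNG", "TIJ"))$estimate
#> [1] 0.03345
```

A single desk-scale replicate like this one orders the populations
correctly but does not by itself clear the |Z| > 3 significance bar — the
shared-drift excess is a genome-scale signal, and the acceptance
experiments quantify how often the ordering resolves across replicates.

Ground-truth rCCR for a clean two-population split at 1,000 generations,
recovering the split time from the 0.5-crossing heuristic:

```r
m <- simple_model(ne = 1000, split_gen = 1000)
cv <- rccr_between(m, "A", "B", n_pairs = 1e4, seed = 1)
crossing_time(cv, 0.5)
#> [1] 1022.146
crossing_time(cv, 0.9)   # onset of structure: older than full separation
#> [1] 1139.905
```

Scenario choice and parameter estimation against a reference table:

```r
catalog <- scenario_catalog()
cfg <- abc_sim_config()                  # 12 diploids/pop, 800 x 20 kb loci
tab <- generate_reference_table(catalog, 2000, cfg, seed = 101)

obs <- simulate_summary_vector(build_model(catalog[[4]],
                                           scenario4_calibration_params()),
                               cfg$samples, cfg$locus, seed = 7,
                               config = cfg$summary)

forest <- abc_rf_train(tab)
abc_rf_posterior(forest, obs)$probabilities     # scenario probabilities

rej <- abc_reject(tab[tab$scenario_id == 4, ], obs, tolerance = 0.05)
estimate_parameters(rej, scenario_id = 4)       # medians + 95% HPD
```

VCF/popmap/BED input-output (`write_vcf()`, `read_vcf()`,
`write_popmap()`, `write_bed_mask()`) round-trips datasets through
plain-text formats, and `emulate_cohort()` produces the full masked
synthetic cohort in one call.

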
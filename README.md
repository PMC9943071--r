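# ancientdel

Tools for studying **ancient deletion polymorphisms** — human deletions
that have been segregating since before the split, ~700,000 years ago,
between anatomically modern humans (AMHs) and the lineage of Neanderthals
and Denisovans — and for asking whether such trans-species survival
reflects **balancing selection** rather than neutral drift.

The package is aimed at population geneticists who want to reproduce, or
stress-test on synthetic data, every stage of that analysis:

* **Neutral expectation.** A structured-coalescent engine (C++) simulates
  unlinked variants for 216 YRI haploids plus 2 haploids per archaic
  genome under a joint demography (Vindija–Chagyrskaya split 90 ky,
  Altai 130 ky, Denisovan 400 ky, AMH–archaic divergence 700 ky, 29
  y/gen) and measures the proportion of YRI variants (minor allele count
  > 1) whose derived allele is carried by ≥ 1 archaic genome.  An
  island-model variant places structure, with symmetric migrant fraction
  *m*, in the population ancestral to both lineages and scans *m* for the
  largest value that still reproduces an observed sharing level.
* **Read-depth genotyping.** Deletions are called in archaic genomes from
  read intervals via the modified Z-score of window-normalized depth,
  `ModZ_i = (r_i − median(R)) / MAD(R)`, with a conservative call at
  `ModZ < −5`.
* **Classification.** Archaic-shared deletions are partitioned by their
  LD companions (SNVs with haplotypic `r² > 0.9` within 50 kb):
  *recurrent* if no companion accompanies the deletion in any carrier
  genome, *introgressed* if absent from Yoruba with a companion on a
  published S\*-significant haplotype, *ancient* otherwise.
* **Stability, age and scores.** A χ² statistic (squared standardized
  change of the lineage-based allele frequency between 50 and 5 ky BP,
  stratified by present-day frequency; ~χ²₁ under neutrality), plus
  deletion-level age (max / mean over companions) and balancing-selection
  scores (BETAMAX / BETAPRIME) from published per-SNV tables.
* **Enrichment.** Label-permutation tests (add-one corrected, two-sided)
  for exon overlap, GWAS association, 18 phenotype categories, and length
  percentiles.
* **Overdominance signatures.** Forward Wright–Fisher trajectories with
  fitnesses `(1, 1+sh, 1+s)` (equilibrium `h/(2h−1)`), an mssel-style
  structured coalescent conditioned on the trajectory, neutral samples
  conditioned on an intermediate-frequency site, and the classical
  summary-statistic panel (S, θ_W, π, Tajima's D, ZnS, Fay & Wu's H,
  haplotype count and diversity) with a PCA separability report.
* **Synthetic data with planted truth**, so the whole pipeline runs and
  is testable end to end without downloading any cohort.

## Worked example

```r
library(ancientdel)

cfg    <- synth_config(n_deletions = 120, seed = 42)
cohort <- generate_cohort(cfg)
cohort
#> <synth_cohort> 120 deletions, 960 SNVs, 628 haplotypes
#>        ancient human_specific   introgressed      recurrent
#>             12            102              4              2

reads   <- generate_archaic_reads(cohort$deletions, cohort$truth, cfg)
profile <- archaic_depth_profile(reads, cohort$deletions)   # ModZ < -5
calls   <- presence_matrix(profile)
sum(calls$shared)
#> [1] 18

ld  <- cohort_ld_inputs(cohort)
res <- classify_all(cohort$deletions$id, ld$companions_list,
                    calls$presence, ld$archaic_snv_presence,
                    cohort$sstar_snvs, ld$yri_allele_counts)
res$summary
#>         category   n proportion
#> 1 human_specific 102 0.85000000
#> 2      recurrent   2 0.01666667
#> 3   introgressed   4 0.03333333
#> 4        ancient  12 0.10000000
```

All 18 deletions planted as archaic-shared are recovered by the depth
caller, and every planted category label is recovered by the classifier
(agreement 1.0 against the cohort's planted truth).  The neutral
envelope under the realistic constant-size model:

```r
m     <- demographic_model(archaic_sampling_times = "present")
props <- sharing_distribution(m, n_reps = 20, n_loci = 5000, seed = 1)
sprintf("mean %.1f%%, max %.1f%%", 100 * mean(props), 100 * max(props))
#> [1] "mean 7.8%, max 8.6%"
```

i.e. neutral simulations sit far below an observed sharing proportion of
13.7%, which is the excess the downstream selection analyses interrogate.

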
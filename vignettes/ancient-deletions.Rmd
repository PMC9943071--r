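---
title: "Ancient deletion polymorphisms: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancient deletion polymorphisms: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

A human polymorphism whose derived allele is also carried, by common
descent, by Neanderthals or Denisovans must already have been segregating
in the population ancestral to both lineages — it is older than their
divergence, roughly 700,000 years ago.  Polymorphisms that survive that
long are prime candidates for balancing selection.  `ancientdel`
implements the full analytical pipeline around this idea for autosomal
deletion polymorphisms:

1. **Neutral expectation** (`demographic_model()`,
   `sharing_distribution()`, `simulate_structured_ancestry()`,
   `scan_migration()`): how much derived-allele sharing with four
   high-coverage archaic genomes does neutrality predict?
2. **Genotyping deletions in archaic genomes** (`archaic_depth_profile()`
   and friends): read-depth calls from BED read intervals via modified
   Z-scores.
3. **Classification** (`find_companions()`, `classify_shared_deletion()`,
   `classify_all()`): partitioning archaic-shared deletions into
   recurrent, introgressed, and ancient via LD companions.
4. **Trajectory statistics** (`chi2_stability()`, `assign_age_hgd()`,
   `assign_age_mean()`, `assign_beta()`): allele-frequency stability and
   deletion-level age/score assignment from companion tables.
5. **Enrichment** (`intersect_exons()`, `assign_gwas()`,
   `permutation_enrichment()`, `category_enrichment()`,
   `percentile_length_test()`): permutation tests for functional
   relevance and length.
6. **Overdominance signatures** (`simulate_trajectory()`,
   `structured_coalescent_sample()`, `psecoal_sample()`,
   `summary_stats()`, `pca_separation()`): can classical summary
   statistics distinguish heterozygote advantage from neutrality?
7. **Synthetic data** (`synth_config()`, `generate_cohort()`,
   `generate_archaic_reads()`, `generate_annotation_tables()`): seeded
   cohorts with planted truth that make every stage testable without any
   download.

# The coalescent engine

Genealogies are simulated backward in time with an event-driven
structured coalescent written in C++ (piecewise-constant population
sizes, population splits, ancient sampling times, island migration).
Each locus is independent and freely recombining; exactly one mutation is
placed per genealogy with probability proportional to branch length, so
every simulated variant is segregating in the full sample and the
denominator of the sharing proportion (YRI polymorphic with minor allele
count > 1, i.e. both alleles at two or more copies among the 216 YRI
haploids) is exact.  This one-mutation design matches the "independent
variants" framing; it deliberately does not model multiple mutations per
locus or intra-locus recombination.

The default joint demography has 216 YRI haploids plus 2 haploids per
archaic genome; Vindija and Chagyrskaya Neanderthals merge 90 ky ago,
Altai joins 130 ky ago, the Denisovan 400 ky ago (all archaic branches at
diploid size 1,000), and the archaic stem meets the AMH lineage 700 ky
ago.  Generation time is 29 years.  The "realistic constant-size" model
uses AMH Ne = 14,474; piecewise-constant AMH size trajectories are
accepted as config tables (a published variable-Ne curve is not printed
numerically anywhere we can cite, so nothing is hard-coded from a
figure).  Archaic genomes are sampled at ancient times by default
(Altai 120 ky, Chagyrskaya 80 ky, Denisovan 70 ky, Vindija 50 ky);
`archaic_sampling_times = "present"` switches to plain-`ms`-style
present-day sampling, which is what the package's own acceptance checks
use.  The engine is validated in the test suite against msprime — an
independent coalescent implementation — both for a single panmictic
population and for the full five-lineage demography.

# Ancestral structure and the migration scan

The structured-ancestry model splits the population ancestral to AMHs
and archaics into three demes of diploid size 10,000 exchanging a
symmetric per-generation migrant fraction `m` (ms units
`M = 4 * 10000 * m`).  A design question the model description leaves
open is where the ancestral lineages go at the split.  Placing all AMH
ancestors into one deme makes sharing *increase* with `m` (the
high-migration limit behaves like a single population of 30,000), which
contradicts both the direction of the reported threshold and the
observation that ancestral structure inflates intermediate-frequency
variants.  We therefore scatter each AMH ancestral lineage uniformly
across the demes at the split (exactly what repeated `-es` population
splits produce in `ms`), with the archaic stem entering one deme; under
this geometry deep structure yields both a large sharing excess and the
intermediate-frequency SFS distortion, decaying toward the panmictic
value as `m` grows.  The single-deme placement remains available as
`scatter_amh = FALSE`.

`scan_migration()` reports, per its contract, the largest grid `m` whose
simulated sharing still reaches a target.  Because the sharing curve is
flat near the empirically relevant target, that raw readout is dominated
by Monte-Carlo noise; `migration_crossing()` instead fits an isotonic
(monotone non-increasing) curve to the scan table and interpolates the
crossing on the log-`m` scale.  The acceptance script uses a 48-point
log-uniform grid over (2.5e-8, 2.5e-3) with 32,000 variants per point.

# Read-depth genotyping

Reads are counted per candidate window by any-overlap (at least 1 bp,
half-open intervals), normalized by window size, and scored per genome
across all windows with the modified Z-score
`(r - median(R)) / MAD(R)`.  The conventional 0.6745 consistency
constant is *not* applied by default — the conservative calling
threshold of −5 (strict) is calibrated to the unscaled score; a
`scaling_constant` switch restores the textbook definition.  Scores are
computed per genome across all windows (the per-genome score
distribution is the natural reference set); calls are binary, with no
het/hom distinction, and a zero MAD is reported as a degenerate-spread
condition rather than silently producing infinities.

# Classification logic

Only deletions with at least one LD companion (haplotypic r² > 0.9
within 50 kb, distances measured from the nearer breakpoint) can be
vetted, so companion-less deletions are excluded and reported — a
conservative bias toward low-recombination regions.  Precedence is
recurrence first (no companion derived allele in any deletion-carrying
archaic genome), then introgression (zero YRI copies *and* a companion
on a published S*-significant haplotype), then the ancient residual.
"Absent in Yoruba" is read literally as allele count zero.

# Trajectory statistics

`chi2_stability()` estimates past allele frequencies as the fraction of
genealogical lineages carrying the derived allele, takes the change
between 50,000 and 5,000 years before present, keeps variants whose
remaining lineage count at 50 ky exceeds 10% of the present-day sample,
standardizes within deciles of present-day frequency (quantile bins;
granularity configurable), and squares.  Under neutrality the statistic
is approximately chi-squared with one degree of freedom — but only where
the underlying normal approximation is valid.  For rare variants the
lineage counts are small integers and the frequency change concentrates
an atom at zero, so the chi-squared(1) calibration is checked (and
holds, in the test suite) on variants with present-day frequency above
5%, the same pooled-frequency regime in which the enrichment analyses
operate.  A stratum with zero spread yields z = 0 for all members;
strata with fewer than two members are flagged unstandardizable.

Age assignment uses the maximum companion age (a tagging SNV can be
younger, but not older, than the haplotype it tags) or the mean over
companions tagging at r² > 0.9; the score assignment implements BETAMAX
(highest stdb2 among scored companions) and BETAPRIME (among companions
attaining the maximal r², the nearest one, distance ties broken by lower
position).  stdb2 itself is consumed from published per-SNV tables,
never recomputed.

# Enrichment tests

All three permutation tests (functionality, phenotype categories, length
percentiles) share one machinery: shuffle ancient/non-ancient labels,
use the add-one-corrected empirical p-value, and call "more extreme"
two-sidedly (`|difference| >= |observed|`) — the conservative reading
where sidedness is not dictated.  Percentiles interpolate linearly
between order statistics.  The pooled-frequency filter (> 5% across
YRI + CEU + CHB) is applied by the caller via
`filter_pooled_frequency()`, which logs before/after counts.  The
machinery is checked against exhaustive enumeration of all label
placements on small inputs.

# Overdominance simulations

Fitness is parameterized as (1, 1 + sh, 1 + s); with s = 0.005 and
h = 10 the heterozygote fitness is 1.05, the derived homozygote 1.005,
and the deterministic equilibrium is h/(2h−1) = 10/19 ≈ 0.526.
Trajectories are forward Wright–Fisher binomial resampling from a single
copy (diploid N, default 10,000; frequency granularity 1/2N),
conditioned by rejection on segregating at the target age — rejection is
exact and matches the classical trajectory-simulation approach, and the
acceptance rate is always reported because neutral segregation over
40,000 generations is rare (of order 1e-5 to 1e-4).  A frequency-band
post-filter (default 0.44–0.56, bracketing the overdominant equilibrium)
keeps neutral and selected runs comparable at matched focal frequency.

Linked variation is generated by a structured coalescent conditioned on
the trajectory: derived- and ancestral-class lineages coalesce within
class at rates set by the class sizes 2N·x(t) and 2N·(1−x(t)), switch
class at the recombination-driven rate (rho/4N) times the other class's
frequency, and at the allele's origin the derived class collapses into
the ancestral background; past the origin a plain size-N coalescent
finishes the tree.  Mutations fall on branches at rate theta/4N per
generation.  The mssel-style machinery is cross-checked in the tests
against the neutral panmictic limit (frequency pinned near 1, rho = 0,
where expected diversity is theta·x).  The locus-scale parameters theta
and rho are required arguments, not hidden constants; the test suite
and acceptance checks use theta = rho = 10.

`psecoal_sample()` provides the selection-free control: plain coalescent
samples conditioned on containing a site at 22–28 copies out of 50.
`summary_stats()` computes S, Watterson's theta, pi, Tajima's D (with
the standard variance constants, verified against a brute-force oracle),
ZnS (mean pairwise r²), unnormalized Fay and Wu's H (pi − theta_H), the
haplotype count and haplotype diversity; `pca_separation()` standardizes
the panel (undefined entries dropped listwise), projects on principal
components of the correlation structure, and reports per-statistic
rank-sum p-values plus PC1/PC2 overlap.

# The synthetic cohort and what it does not emulate

The generator plants 1000-Genomes-sized samples (YRI 108, CEU 103,
CHB 99 diploids), a category mix defaulting to the empirically observed
partition (88.2% AMH-specific, 1.1% recurrent, 1.9% introgressed, 8.8%
ancient), deletion lengths log-uniform on 0.5–10 kb, LD companions made
by copying the deletion haplotype with a 1% per-haplotype flip rate
(retried, and failing loudly if the r² target is unsatisfiable),
archaic reads at 30x mean depth with 100 bp reads placed uniformly, and
homozygous depth drops (residual fraction 0) at planted deletions.
Coordinates are 0-based half-open internally; VCF emission converts to
1-based.  All randomness flows from one root seed through named
substreams, so regeneration is byte-identical.

Deliberately not emulated: realistic recombination maps and LD decay,
sequencing error, ancient-DNA damage, GC bias, genotype likelihoods, and
multi-allelic or overlapping deletions.  Passing tests on this cohort
demonstrate that the pipeline's logic recovers planted truth under its
own model assumptions — not that the caller or classifier would be
error-free on real archaic BAMs.

# Problem sizes

The shipped checks use desk-scale simulation sizes chosen to keep
Monte-Carlo error well inside every asserted tolerance: 200 replicates
of 5,000 unlinked variants for the neutral sharing envelope; a 48-point
migration grid at 16,000–32,000 variants per point; 5,000 variants for
the chi-squared(1) calibration; 50–60 replicates per scenario and three
seed replicates for the overdominance-vs-neutrality panel; and cohorts
of 40–400 deletions for planted-truth recovery.

# Known limitations

* The sharing curve under ancestral structure is flat near the
  empirical target, so any crossing estimate inherits a few hundredths
  of a log10 unit of uncertainty even after isotonic smoothing.
* The chi-squared(1) null for the stability statistic degrades for rare
  variants (documented above); comparisons between deletion sets should
  use the rank-sum harness rather than nominal chi-squared quantiles.
* One mutation per genealogy means the engine reports sharing
  *proportions*, not per-site diversities; use `summary_stats()` on
  coalescent samples when absolute diversity matters.
* The depth caller assumes roughly uniform coverage; on real data,
  mappability and GC corrections belong upstream of the BED inputs.
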
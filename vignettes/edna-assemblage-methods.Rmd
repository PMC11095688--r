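---
title: "Methods: community analysis of low-volume eDNA samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community analysis of low-volume eDNA samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednaAssemblage)
```

## The analysis problem

Low-volume eDNA sampling detects pelagic animals from the genetic
material they shed into seawater. A survey of this kind yields, per
marker gene (12S rRNA for vertebrates, COI for invertebrates), a table
of denoised amplicon sequence variants (ASVs) by samples, a taxonomy
assignment for each ASV, sample metadata (position, depth, filtered
volume, time, DNA concentration, control status), and — when a trawl
such as a MOCNESS samples the same water — net-based catches for
comparison. Read counts are not comparable abundance across taxa (gene
copy number, shedding rate, primer and PCR biases all differ), so every
community quantity in this package is presence-based.

The pipeline has five analytical stages, each exposed as plain
functions and orchestrated by `run_pipeline()`:
decontamination → standardization → method comparison → depth profiles
→ assemblage clustering. A synthetic-data generator with planted ground
truth closes the loop for testing.

## Decontamination

Filters are applied in a fixed, logged order:

1. **Read threshold** (`drop_low_read_samples`): samples with strictly
   fewer than 1,000 total reads are treated as failed sequencing runs.
   The comparison is strict — a 1,000-read sample stays.
2. **Non-marine blocklist** (`remove_blocklisted_taxa`): taxa that do
   not occur in marine habitats are contamination or misclassification.
   Defaults: terrestrial vertebrate clades plus freshwater
   Cypriniformes for 12S; three non-local bivalve species for COI.
3. **Clade removal** (`remove_clade`): all vertebrates (subphylum
   Vertebrata) are removed from COI, where the 12S marker is the more
   reliable detector.
4. **Control ASVs** (`remove_control_asvs`): any ASV with at least one
   read in a cruise's negative controls is zeroed in that cruise's
   environmental samples (the per-cruise rule; a global mode exists for
   sensitivity analysis). Only ASVs actually flagged here are dropped
   when they vanish; rows zeroed by earlier sample filters are left in
   place, which keeps the whole pipeline idempotent.
5. **Below-detection samples**: environmental samples whose DNA
   concentration fell under the assay floor are excluded, not zeroed;
   the on-disk sentinel is the literal token `BD`. Controls with `BD`
   are retained as controls.

The source material does not pin down whether control-ASV removal
preceded or followed the read threshold; the order above is this
package's canonical choice (the threshold describes sequencing success,
which is logically prior to content filtering), and `steps =` in
`decontamination_config()` lets a user run the other order. Every step
satisfies the conservation identity reads\_in = reads\_out +
reads\_removed (likewise ASVs and samples), which the tests assert.

## Standardization

**Taxonomic groups** are mutually exclusive by construction: an ordered
rule list where the first match wins. Vertebrates are grouped at the
order level except lineages only resolvable within the series
Ovalentaria or Eupercaria (orders incertae sedis), which use the series
name; invertebrates use order, then class, then phylum. ASVs with no
usable lineage map to `"unassigned"` and are excluded from both the
numerator and denominator of proportional occurrence — including a
pseudo-group would distort the method comparison.

**Proportional occurrence** of a group in a sample is the number of
present ASVs (eDNA) or present taxa (trawl) in that group divided by
the total present, so each row sums to 1. Samples are aggregated into
method × zone × depth-bin units by averaging sample rows and
renormalizing (`mode = "pool"` recomputes from pooled presences
instead; averaging is the default because the metric is defined per
sample).

**Zones** follow the trawl sites: a sample joins a zone when it lies
within 1° latitude and 2° longitude of the site. Real zones do not
overlap; synthetic ones may, so ties break deterministically by the
nearest centre under the coordinate-normalized Chebyshev distance, then
by zone id.

**Depth bins** are lower-open/upper-closed, so 200 m falls in 0–200 m
and the deepest group is strictly `>600` m. Three presets mirror the
three uses: comparison (0–200 / >200 m), profile (0–200 / 200–600 /
>600 m, approximating the daytime and nighttime deep scattering
layers), and per-marker mapping bins (0–120 / 121–565 m for 12S,
0–120 / 121–900 m for COI).

**Day/night**: night runs from 90 minutes after sunset to 90 minutes
before sunrise. Sunrise/sunset are metadata inputs, not computed —
solar geometry is out of scope and fixtures control it exactly. The
classifier works on the circular time-of-day phase, so it is invariant
to representing any time ±24 h and handles midnight wraps.

## Community statistics

- **Morisita–Horn** (abundance-weighted, scale-invariant) compares
  proportional-occurrence rows between methods; **binary Jaccard**
  compares species presence sets between samples.
- The **Mantel test** correlates the lower triangles of two distance
  matrices and permutes the second matrix's units; defaults are 999
  permutations and a one-sided upper tail (the conventional ecology
  default), with the observed statistic included in the null set so
  p ≥ 1/(n_perm+1). The default comparison unit is the method × zone ×
  depth-bin aggregate; sample-level input works unchanged.
- **Depth-group tests** stay rank-based throughout. The router checks
  per-group normality (Shapiro–Wilk) and homoscedasticity
  (Brown–Forsythe, i.e., median-centred Levene) at α = 0.05 — the most
  common pairing; the sources leave the choice open. Heteroscedastic
  data go to Welch's ANOVA on global mid-ranks (Welch–Satterthwaite
  df), followed by Games–Howell tests on ranks when significant;
  homoscedastic data go to Kruskal–Wallis with the standard tie
  correction. Normal homoscedastic data also go to Kruskal–Wallis, with
  a note: staying rank-based keeps all outputs invariant to monotone
  transforms of the metric. Games–Howell uses the studentized range
  with q = t√2 and k = number of groups, computed on raw mid-ranks (a
  normal-scores variant was considered and rejected as unstated in the
  source analyses).
- **Species accumulation** supports the random accumulator (mean ± sd
  over random sample orderings) and the exact closed form
  E[S(n)] = Σ_s (1 − C(N−f_s, n)/C(N, n)), which equals the average
  over all orderings and is what the exhaustive-enumeration test
  checks to 1e-12.

## Assemblage clustering

Only ASVs identified to species level enter the presence matrix (so
labels are mutually exclusive), collapsed to species by "any member ASV
present". Mammals and birds are dropped from 12S to focus on
zooplankton, micronekton and forage fishes; species in fewer than three
samples are dropped (strict); only night samples are clustered, to
limit the signature of diel vertical migration.

Ward clustering runs on Jaccard dissimilarities via the Lance–Williams
update in squared-distance (ward.D2-equivalent) form; a `ward_d1`
compatibility variant reproduces the unsquared update because "Ward's
minimum variance" is ambiguous across toolchains. Ties in the minimum
merge distance are broken by the lexicographically smallest member id,
making dendrograms reproducible across platforms. The number of
clusters comes from the elbow rule formalized as the maximum discrete
second difference of the WSS curve (the mean-silhouette curve is
reported alongside); because the visual elbow is a judgment call, the
chosen k is logged and overridable (`cluster$k` in the pipeline
config). Cluster quality uses silhouette widths — singletons and
zero-distance cases get width 0 by convention — and the cohesion rule:
a cluster is retained when its mean width is ≥ 0.1 and strictly fewer
than 15% of its members have negative widths.

Cohesive clusters are summarized by their up-to-10 most frequent
species (ties alphabetical) and mapped as 50% probability-density
contours: a product Gaussian kernel density with per-dimension Scott
bandwidth (n^(−1/6)·sd) on a 256 × 256 grid padded by 3 bandwidths,
thresholded so the highest-density cells capture 50% of the estimated
mass. The enclosed mass is asserted within one grid-cell mass of the
nominal value on every call. Longitude/latitude are treated as planar,
acceptable over the few-degree extent of a regional survey; the KDE is
authored in the package (rather than delegated) so the bandwidth and
mass-capture semantics are exactly these.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with every planted fact recorded in a truth object:

- **Design**: stations with depth-discrete samples on two cruises,
  negative controls per cruise, volumes uniform on 360–1800 mL,
  depth-skewed sampling (about two thirds shallower than 200 m) or
  uniform, and night-biased sampling times with per-date sunrise/sunset
  at 06:00/18:00 UTC.
- **Communities**: K assemblages with spatial centres and log-depth
  niches; stations scatter around the centres and a softened Gaussian
  kernel (kernel sd = 2 × station scatter) converts distance into an
  occurrence probability between `p_out` and `p_in`. An `overlap`
  fraction of each pool is shared across assemblages; optional noise
  samples draw species at random.
- **Reads**: sample totals are negative-binomial (means 24,333 for 12S
  and 31,611 for COI, dispersion 2) with a failure mixture (46% / 21%
  of samples at mean ~300 reads) so the 1,000-read filter removes
  roughly the observed fractions; reads spread over occupied species by
  a symmetric Dirichlet and within species over their ASVs by another —
  so collapsing ASVs to species presence is invariant to multiplicity,
  which is the point of species-level clustering.
- **Multiplicity**: 12S species carry 1 + Poisson ASVs (mean 2.1); COI
  species carry heavy-tailed log-normal counts (the study-scale preset
  uses meanlog 3.5, sdlog 1.3, mean ≈ 78, reproducing the ~8,000
  target-ASV scale from ~100 species).
- **Contamination**: control-shared ASVs with no taxonomic assignment
  (appearing in controls and a fraction of environmental samples),
  non-marine ASVs matching the blocklists, and vertebrate bycatch
  species in COI.
- **DNA concentration**: surface mean 3.6 ng/µl decaying exponentially
  with a 300 m e-folding depth plus Gaussian noise, floored at a 0.05
  ng/µl below-detection threshold — giving the ~10× contrast between
  epipelagic and >600 m samples.
- **Trawls**: nets at fixed depth strata over a subset of stations draw
  Poisson counts from the same latent communities with reduced
  catchability for gelatinous groups, plus a few trawl-exclusive taxa.

Presets: `"paper-like"` (436 samples, 40 stations, 11 controls — the
full survey scale), `"separable-3"` (three well-separated shallow
assemblages, flat depth niches, `p_in` = 0.9, plus 12 noise samples;
the recovery benchmark), and `"null"` (one spatially unstructured
assemblage; the calibration benchmark). What the generator does *not*
emulate: sequence errors, chimeras, PCR amplification, tag jumping, or
spatially autocorrelated noise — so passing recovery tests demonstrates
the pipeline's correctness on data meeting its assumptions, not
robustness to upstream bioinformatic artifacts.

## Numerical choices and problem sizes

Dissimilarities are clamped to [0, 1] against floating-point drift;
permutation p-values include the observed statistic (+1/+1); mid-ranks
are used everywhere ties can arise; sd is the n−1 sample standard
deviation throughout, reported as 0 with a flag for single-species
groups. Tests and the acceptance script run at desk scale: Monte-Carlo
calibrations use 500 replicates (999 permutations each for Mantel),
recovery checks use the `separable-3` preset (~160 environmental
samples per marker), density-region coverage uses 2,000 points, and the
study-scale preset is generated once for design summaries. These sizes
put Monte-Carlo noise well inside the asserted bands (e.g., a ±0.02
band on a 0.05 type-I rate at 500 replicates is ±2 binomial standard
errors).

## Known limitations

- Proportional occurrence treats every ASV presence equally; a species
  split into many ASVs carries more weight at the ASV level, which is
  exactly why clustering collapses to species first.
- The Mantel comparison has few units in a three-zone, two-bin design;
  its power is correspondingly limited, and the null calibration (not
  power) is what the package asserts.
- The elbow rule is a formalization of a visual judgment; with weak
  structure the WSS curve is near-linear and the choice of k is
  genuinely ambiguous — hence the override and the dual curves.
- Density contours assume planar coordinates and a shared bandwidth per
  dimension; they are distribution sketches, not home-range estimates.
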
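---
title: "Consensus genetic maps and kinship-adjusted linkage disequilibrium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus genetic maps and kinship-adjusted linkage disequilibrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conmapLD)
```

conmapLD builds a single consensus linkage map from several
population-specific maps and then uses that map to quantify linkage
disequilibrium (LD) in ways that separate physical linkage from the
spurious correlation injected by family structure or subpopulation
divergence.  The setting it targets is conifer-style genetic mapping:
several full-sib crosses and a haploid megagametophyte population genotyped
at overlapping sets of gene-based markers (SNPs within ESTs, SSRs, RFLPs),
each yielding its own realized map on 12 linkage groups, plus large
association or genomic-selection populations genotyped with the same assay.

This vignette is the package's account of the methods, the choices that
were genuinely open, and what the synthetic validation does and does not
demonstrate.

## Marker informativeness: GIC

Each marker's usefulness for ordering is scored by genotype information
content,

$$\mathrm{GIC} = G_e \times N_\mathrm{indiv}, \qquad
  G_e = 1 \Big/ \sum_j p_j^2,$$

where $p_j$ is the proportion of the $j$-th genotypic class among genotyped
progeny.  $G_e$ is the "effective number of genotype classes": 2 for a
clean 1:1 testcross locus, and strictly smaller as segregation distortion
grows, so GIC falls monotonically with the distortion chi-square at fixed
sample size (a property the test suite asserts).

For loci heterozygous in both parents (hk&times;hk, segregating
1&nbsp;hh:2&nbsp;hk:1&nbsp;kk) $G_e$ is computed from the homozygous
classes only, while $N_\mathrm{indiv}$ still counts all progeny.  Keeping
only hh/kk preserves the inverse relation between GIC and distortion.  An
open point is whether the homozygote proportions should be renormalized
over homozygotes; we renormalize, which caps $G_e$ at 2 and keeps hk&times;hk
loci commensurate with testcross loci.  The alternative (proportions over
all progeny) would let $G_e$ reach 8 and dominate the weighting.

Genes assayed at several SNPs contribute one marker: the one with the
largest cohort-summed GIC (`select_max_gic_per_gene()`, ties to the
smallest marker id).

## Map weights and the merge

Each input map $l$ receives weight
$w_l = \overline{\mathrm{GIC}}_l / \sum_m \overline{\mathrm{GIC}}_m$, where
$\overline{\mathrm{GIC}}_l$ averages cohort-summed GIC over the map's
markers.  Weights therefore favour maps built from many individuals with
clean segregation.

`merge_maps()` is a single deterministic algorithm that combines the two
ideas found in the established merging tools: occurrence-deletion conflict
resolution on a directed order graph, and least-squares consensus
positions.

1. Markers are reduced to gene-level merge keys (`normalize_marker_name()`
   strips the trailing dash-separated SNP-position token).  A key placed on
   different linkage groups by different maps is assigned to the LG holding
   the majority of its weight; the other occurrences are excluded and
   reported.
2. Per linkage group, every adjacent marker pair in every map contributes a
   directed edge carrying the map's weight.  While cycles exist, the set of
   marker *occurrences* (marker, map) of minimum total weight whose
   deletion breaks the cycles is removed.  The search is exact (all
   deletion sets up to size 3, enumerated in order of total weight) when
   the strongly connected component spans at most 12 markers, and greedy
   (repeatedly drop the lowest-weight occurrence) beyond that; each
   conflict records which path was taken.  Deterministic tie-breaks
   (weight, then map name, then marker id) make re-runs identical.
3. The acyclic graph is ordered topologically, ties broken by the
   weight-averaged standardized input position.
4. Consensus positions minimize
   $\sum_l w_l \sum_{(a,b)\ \mathrm{adjacent\ in}\ l} (x_b - x_a - d^{(l)}_{ab})^2$
   subject to monotonicity in consensus order: an unconstrained weighted
   least-squares solve followed, if needed, by pooled-adjacent-violators
   repair, anchored at $x_\mathrm{first} = 0$.  For a pair of markers
   adjacent in every map the solution is the weight-weighted mean of the
   input distances, which the tests check in closed form.

A linkage group present in only one map passes through unchanged (logged).

Because the merge is deterministic, position uncertainty cannot come from
run-to-run variability.  `position_uncertainty()` instead perturbs every
input-map inter-marker distance with multiplicative log-normal noise
(default `noise_sd = 0.1`, 100 replicates), re-merges, and reports the
2.5/97.5 percentile band per marker.  This preserves the replicate-run
interface and yields per-LG and genome-wide mean CI summaries; markers
deleted by conflict resolution in any replicate are flagged rather than
given an interval.

Order agreement between maps is summarized by RMSE on positions
standardized to a 0-100 scale per linkage group (`rmse_order_agreement()`);
raw-cM RMSE is emitted alongside, since published values do not always say
which scale was used.

## Locus quality control

`filter_loci()` applies, in order: Mendelian-error inference against
recorded parental genotypes (a call is an error iff impossible under
transmission; loci with a rate strictly above 5% are dropped, others have
the errors recoded to missing), monoallelic and missing-parent exclusion,
a Pearson chi-square distortion test at $p < 10^{-3}$ over the Mendelian
classes (1:1 for haploid/testcross, 1:2:1 for hk&times;hk; for dosage loci
the expected ratio is derived from the parental dosages when available,
otherwise from the observed class set), and an optional missing-fraction
cut (12.5% is the conventional value for preliminary haploid maps).
Distortion and missingness are assessed after error recoding.

`two_point_diagnostics()` computes, for haploid data, the pairwise
recombination fraction as the raw mismatch fraction (coupling-phase
coding, so a mirrored locus shows RF near 1) and a binomial two-point LOD
at the estimated RF against RF = 0.5 (RF capped into [0.001, 0.999] for
degenerate pairs).  Pairs with RF > 0.60 and LOD > 1.5 are flagged as
suspect linkages, the signature of phase or scoring artifacts.

`select_anchor_loci()` reproduces the fixed-order/start-order curation
step: markers are windowed left-to-right (a window is the maximal run of
markers closer than `min_spacing_cM` to the window's first marker) and the
highest-GIC marker per window is kept; loci conflicting with a reference
order (not on the longest order-concordant subsequence) are excluded
first.  The window convention was chosen to match the worked selection
example exactly, and the tests compare the greedy scan against exhaustive
one-per-window enumeration.

## Marker density along linkage groups

`density_profile()` uses a Gaussian KDE with the normal-reference
bandwidth computed exactly as $bw = (0.9\,s/1.34)\,n^{-1/5}$ from the SD
of marker positions -- deliberately not Silverman's
$\min(s, \mathrm{IQR}/1.34)$ variant.  Density is rescaled to markers per
cM ($\hat f \times n$) and markers per bandwidth ($\hat f \times n \times
bw$).  No boundary reflection is applied; the expected edge deficit is
annotated (flags within one bandwidth of an LG end are marked
boundary-affected) rather than corrected away.

The deviation test compares marker counts against the 95% interval of a
Poisson with mean $\lambda = n/(L/bw)$, bounds taken as the smallest
integers whose CDF reaches $\alpha/2$ and $1-\alpha/2$.  One design
decision was revisited after measurement: testing the KDE-rescaled
markers-per-bandwidth against these bounds is essentially powerless,
because kernel smoothing shrinks the statistic's variance to
$R(K)\lambda \approx 0.28\lambda$, leaving the Poisson bounds roughly
4 standard deviations out (measured flag rate under uniform placement:
0.04%).  The default statistic is therefore the raw count of markers in a
sliding window of width $bw$, which *is* Poisson under uniform placement;
`statistic = "kde"` remains available.  Note that the discrete 95% bounds
are conservative: the attainable false-positive rate equals the exact
exceedance $P(X < \mathrm{lo}) + P(X > \mathrm{hi})$, about 2-4% for
typical $\lambda$, never the nominal 5%.  The acceptance test asserts the
measured rate matches this computable value and stays below $\alpha$.

## Linkage disequilibrium

LD between loci is the squared Pearson correlation of genotype dosages
over pairwise-complete individuals.  Two adjustments remove non-physical
LD:

* **Kinship.**  With $V$ the pedigree additive relationship matrix
  (recursive tabular method: full sibs 0.5, half sibs 0.25), both dosage
  vectors are whitened by $V^{-1/2}$ (symmetric eigendecomposition,
  eigenvalue floor $10^{-8}$), the whitened intercept is projected out
  (the GLS mean), and $r^2$ is the squared cosine of the residuals.  With
  $V = I$ this reduces exactly to the raw $r^2$.
* **Structure.**  Both vectors are replaced by least-squares residuals on
  an intercept plus $K-1$ admixture columns (one column dropped because Q
  rows sum to 1 -- the same singularity that forces a fallback to a larger
  K when a structure matrix is non-invertible), and $r^2$ is computed on
  the residuals.

`ld_pair_table()` classifies pairs as within-gene (excluded from the
among-gene tables), within-LG below 1 cM, within-LG at 1 cM or more
(strictly-below-1 convention, so a pair at exactly 1.0 cM falls in the
extended class), between-LG, or unmapped (kept as an appendix stream, not
in the distance-classed counts).  Counts of pairs with $r^2 > 0.1$ are
tabulated for minimum-MAF strata 0.001/0.1/0.2 (both loci strictly above
the threshold), before and after adjustment; loci with at least 50%
missing calls are excluded.  For tractability the whole-matrix adjusted
computation mean-imputes missing dosages so one whitening or regression
serves all pairs; `adjusted_r_squared()` is the exact per-pair reference,
and the two agree to numerical precision on complete data (tested).

`ld_decay_regression()` is Nadaraya-Watson kernel regression of $r^2$ on
map distance via `stats::ksmooth` (normal kernel, 2 cM default bandwidth,
0.5 cM grid) -- the same smoother conventionally used for such curves.

`extended_ld_critical_value()` addresses the question "how large must a
between-LG $r^2$ be before it is surprising, given the distribution of
$r^2$ among pairs with strong evidence of genuine extended LD?".  A
reference set of order 10^2 values cannot support a direct empirical
quantile at a Bonferroni level like $0.05/558 \approx 9\times10^{-5}$, so
a beta distribution is fitted by the method of moments and its
$1-\alpha/n_\mathrm{tests}$ quantile is reported next to the empirical
maximum.  Method-of-moments sampling error at so extreme a quantile is
substantial (SD ~0.035 at $n = 135$); the reported value should be read
with that in mind, which is why both numbers are returned.

## The synthetic-data generator

The generator provides every input with known truth:

* `simulate_true_map()` -- uniform marker positions per LG, a configurable
  fraction of genes carrying two SNPs (to exercise per-gene selection and
  merge-key collapsing), base allele frequencies uniform on (0.1, 0.9).
* `simulate_founders()` -- Balding-Nichols subpopulation frequencies
  ($\mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$), hard subpopulation
  assignment or Dirichlet-admixed ancestry with per-allele origin draws;
  the true Q matrix is always recorded.  Tests verify the realized
  divergence with a Weir-Cockerham $F_{ST}$ estimator.  Optionally,
  founder haplotypes are mosaics of a finite ancestral haplotype pool
  (template switches at rate $1-e^{-g d/100}$ per interval), which is the
  minimal mechanism producing baseline LD that decays with map distance in
  unrelated samples; the default (independent draws per locus) carries no
  baseline LD at all.
* `simulate_pedigree()` -- single or multi-cohort full-sib crosses,
  circular multi-family designs (parent $i$ &times; parent $i+1$ modulo
  $n$, further rings as needed, progeny split evenly over families), and
  unrelated samples.
* `drop_genotypes()` -- meiosis per linkage group with independent
  Bernoulli recombination at the Kosambi-derived fraction per interval (no
  crossover interference; interference modelling is out of scope), dosage,
  CP, or haploid (single maternal gamete) output, with realized
  haplotype-of-origin tracked for identity-by-descent checks.
* `degrade_genotypes()` -- genotyping error (uniform different legal
  code), missingness, and segregation distortion as viability selection:
  carriers of $k$ disfavoured alleles survive with probability $(1-s)^k$,
  implemented by resampling non-survivors' calls from the
  survival-reweighted class distribution, which reproduces the marginal
  distorted ratios (a haploid locus with $s = 0.5$ segregates 2:1).
* `realize_input_maps()` -- per-population maps as marker subsets (with a
  guaranteed shared quota) whose positions are jittered with Gaussian
  noise and rescaled, then re-sorted, so local order inversions arise
  naturally.

What the generator does *not* emulate: sequence-level artifacts (assay
design, SNP discovery ascertainment), crossover interference, genotyping
error that is correlated across loci or individuals, and real
recombination-rate heterogeneity along chromosomes.  Passing tests
therefore demonstrate algorithmic correctness and the direction and
rough magnitude of the structure/kinship effects, not calibrated
performance on any real assay.

## Default study conditions and problem sizes

The default pipeline configuration (`default_run_config()`) mirrors the
study design at desk scale: two 100 cM linkage groups with 40 genes each
(15% two-SNP genes); two multi-cohort full-sib mapping populations (60+60
and 80 progeny) and one 72-megagametophyte haploid set, the conventional
size for such populations; 1% genotyping error and 2% missingness;
realized maps keeping 85% of markers with 0.75 cM position jitter; a
20-parent/20-family circular pedigree of 200 progeny for kinship-adjusted
LD; and a two-subpopulation ($F = 0.2$) admixed unrelated sample of 120
for structure-adjusted LD.  Merge CIs use 20 replicates in the pipeline
default and tests (the interface default is 100).  These sizes keep the
full pipeline run in a few seconds while leaving every statistical check
well-powered; the acceptance measurements use 100 replicate draws where a
rate is being estimated.

## Numerical choices and degenerate inputs

* Seeds: one run seed; every stage derives an independent stream via
  `derive_seed()` (a fixed integer hash), so stages are independently
  reproducible and outputs byte-identical across reruns.
* Eigenvalue floor $10^{-8}$ in kinship whitening guards singular
  relationship matrices (identical twins / repeated clones).
* Degenerate two-point pairs (RF 0 or 1) are capped into [0.001, 0.999]
  before the LOD.
* hk&times;hk loci with no homozygotes have undefined $G_e$ and are
  flagged, not silently scored.
* Zero-variance loci yield `NA` r-squared with a reason, never 0.
* `position_uncertainty(noise_sd = 0)` returns zero-width intervals, the
  fixed-point sanity check.
* Disconnected order graphs within an LG (maps with no shared markers
  there) are stacked deterministically with a 1 cM gap and logged.

## Known limitations

* The merge is a desk-scale reconstruction of the published two-tool
  protocol, not a reimplementation of either tool; on large, very noisy
  conflict sets the greedy fallback can delete more weight than the
  (intractable) optimum.
* The consensus order is, empirically, about as accurate as the best
  input map -- clearly better than the average input, but not uniformly
  better than the best one, and the tests assert exactly that.
* Structure adjustment assumes the admixture matrix is correct; it is not
  re-estimated here (structure inference is out of scope, the Q matrix is
  an input or simulation truth).
* The adjusted-LD matrix path mean-imputes missing genotypes; with heavy,
  non-random missingness the exact per-pair `adjusted_r_squared()` should
  be preferred.
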
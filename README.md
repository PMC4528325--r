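# conmapLD

Consensus genetic maps and kinship-adjusted linkage disequilibrium.

## The problem

Dense linkage maps for outcrossing trees are assembled from several mapping
populations — full-sib crosses and haploid megagametophyte sets — each of
which yields its own noisy, partially overlapping map of the same 12
linkage groups.  conmapLD merges such maps into a single consensus map and
then uses it to quantify genome-wide linkage disequilibrium (LD) in
association and genomic-selection populations, separating LD that reflects
physical linkage from LD injected by pedigree relationships or
subpopulation structure.  It is aimed at researchers doing linkage mapping,
association genetics, and genomic selection in species where one map per
population is the norm and unrelated reference panels are scarce.

## What it computes

* **Marker informativeness**: genotype information content
  `GIC = G_e × N_indiv`, with `G_e = 1/Σ p_j²` the effective number of
  genotypic classes (homozygote classes only for hk×hk loci).  Used to pick
  one SNP per gene and to weight maps: `w_l = mean(GIC)_l / Σ_m mean(GIC)_m`.
* **Locus QC**: segregation-distortion chi-square (`p < 0.001` drops),
  Mendelian-error inference from parental genotypes (rate > 5% drops,
  otherwise errors recoded to missing), monoallelic/missing-parent
  exclusion, missing-fraction cuts, two-point suspect-linkage diagnostics
  (RF > 0.60 and LOD > 1.5), and spacing/GIC anchor selection.
* **Consensus merging**: a weighted directed order graph over gene-level
  merge keys; order conflicts resolved by deleting the minimum-weight set
  of marker occurrences (exact within small strongly connected components,
  greedy beyond); monotone weighted least-squares consensus positions;
  replicate-perturbation 95% position CIs; standardized order RMSE.
* **Marker density**: Gaussian KDE with bandwidth `0.9·s/1.34·n^(−1/5)`,
  rescaled to markers per cM and per bandwidth, with a Poisson 95% CI test
  for significantly dense or sparse regions.
* **LD**: raw `r²` of genotype dosages, kinship-adjusted `r²` (whitening by
  the inverse square root of the pedigree relationship matrix), and
  structure-adjusted `r²` (regression on admixture proportions), tabulated
  by distance class (within-gene / <1 cM / ≥1 cM / between-LG) and MAF
  stratum, with kernel decay regression and a beta-fit Bonferroni critical
  value for extended LD.
* **Synthetic data**: a gene-dropping simulator (Kosambi recombination
  fractions, Balding–Nichols structure, viability-selection distortion,
  noisy realized maps) generating every pipeline input with known truth.

## Worked example

```r
library(conmapLD)

## three noisy realized maps of the same 2-LG, 80-marker truth
tm   <- simulate_true_map(n_lg = 2, markers_per_lg = 40,
                          lg_length_cM = 100, seed = 101)
maps <- realize_input_maps(tm, c("fullsib", "fullsib2", "haploid"),
                           subsample_fraction = 0.85, order_noise_sd = 0.75,
                           length_scale = 1, shared_quota = 20, seed = 102)

## weights from per-map average GIC
w <- map_weights(c(fullsib = 530, fullsib2 = 339, haploid = 282))
print(w, digits = 3)
#>     map_id avg_gic weight
#> 1  fullsib     530  0.460
#> 2 fullsib2     339  0.295
#> 3  haploid     282  0.245

cm <- merge_maps(maps, w)
cm
#> consensus_map: 80 markers on 2 linkage groups (from 3 input maps)
#> total length: 188.06 cM; order conflicts resolved: 15; markers dropped: 0
summary(cm)
#>       lg n_markers length_cM avg_spacing_cM max_spacing_cM mean_ci_cM
#>        1        40     90.98          2.333          9.090         NA
#>        2        40     97.08          2.489          9.371         NA
#>    Total        80    188.06             NA             NA         NA
#>  Average        40     94.03          2.411          9.231        NaN

## kinship-adjusted LD in a 20-family circular pedigree
ped <- simulate_pedigree("circular_multifamily", n_parents = 20,
                         n_families = 20, n_progeny = 200)
fnd <- simulate_founders(tm, K = 1, F_div = 0, n_per_subpop = 20,
                         seed = 103, ids = paste0("P", 1:20))
gm  <- drop_genotypes(tm, ped, fnd, seed = 104)
A   <- pedigree_relationship_matrix(ped)[gm$individuals, gm$individuals]
ld  <- ld_pair_table(gm, cm, adjustment = "kinship", V = A)
ld
#> ld_table: 3160 locus pairs from 80 loci (adjustment: kinship)
#>  maf_threshold           class n_pairs n_raw_gt pct_raw n_adj_gt pct_adj
#>          0.001 within_LG_lt1cM      23        3   13.04        4   17.39
#>          0.001 within_LG_ge1cM    1537       83    5.40       42    2.73
#>          0.001      between_LG    1600       46    2.88        0    0.00
#>  ...
```

Reading the output: the merge reconciles 15 order conflicts among the three
maps without losing markers, and the consensus spans both linkage groups
with ~2.4 cM average spacing.  In the LD table, the family structure makes
2.9% of *unlinked* (between-LG) pairs look associated (`r² > 0.1`);
whitening by the pedigree relationship matrix removes essentially all of
them, while genuinely linked pairs (<1 cM) keep their signal — the pattern
that motivates adjusting `r²` before interpreting extended LD.

The full pipeline (simulate → QC → GIC/weights → merge → density → LD,
with TSV outputs and a JSON manifest) is one call:

```r
run_pipeline(default_run_config(seed = 1), out_dir = "run1")
```

A thin command-line dispatcher over the same functions is installed at
`inst/scripts/conmap-ld.R`
(`Rscript conmap-ld.R run --config cfg.yaml --out DIR`, plus
`simulate`/`validate`/`qc`/`gic`/`merge`/`density`/`ld` subcommands).

## Documentation

The methods vignette (`vignettes/consensus-map-ld.Rmd`) describes the
model, the tunable parameters and their defaults, the synthetic-data
generator and its limits, and the numerical choices; function-level detail
is in the roxygen help pages.
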
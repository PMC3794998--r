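# sealmix

Population-genetic and movement analyses for multi-site pinniped studies,
built around the question a ringed-seal (*Pusa hispida*) biologist asks of
breeding-site samples: **do these sites exchange migrants, or are they
drifting apart?**  The package serves population geneticists and marine
mammal ecologists who have microsatellite genotypes (GenePop), aligned
mtDNA haplotypes (FASTA) and/or Argos telemetry (CSV) collected at discrete
breeding sites, and want the full chain from raw files to
differentiation/panmixia decisions and seasonal-movement tables — plus
synthetic-data generators that emulate a three-subspecies sampling design
(a large panmictic Arctic group, a migration-connected Baltic satellite,
and a strongly drifted Lake Saimaa isolate) so every stage is testable
without field data.

## What it computes

**Distances.** Tamura–Nei (TN93) sequence distances with a
continuous-gamma rate correction (each term $-k\log w$ becomes
$\alpha k(w^{-1/\alpha}-1)$; defaults $\alpha = 0.25103$ for COI, $0.164$
for the control region); the summed 0–4 single-locus genotype distance
(0 for (ii,ii)/(ij,ij), 1 for (ii,ij)/(ij,ik), 2 for (ij,kl), 3 for
(ii,jk), 4 for (ii,jj)); and the allele-count-difference distance
($2 - |\text{multiset intersection}|$ per locus).

**Diversity.** Observed and Nei-unbiased expected heterozygosity
$\hat H_e = \frac{2n}{2n-1}(1-\sum_k p_k^2)$; Monte-Carlo exact
Hardy–Weinberg tests with a one-sided homozygote-excess p; genotypic-G
linkage tests; Bonferroni-adjusted levels with the loci&times;sites /
pairs&times;sites family conventions; rarefied allelic richness
$\hat A_N$ (individual subsampling, mean &plusmn; SD over replicates) with
a permutation test for richness differences; exact-identity haplotype
frequency tables; and a one-mismatch duplicate-genotype screen.

**Differentiation.** Weir–Cockerham $\hat\theta$ (variance components
a, b, c; multi-locus ratio of sums $\sum a/\sum(a+b+c)$) with
permutation significance; one-level AMOVA on squared pairwise distances
($\Phi_{ST} = \sigma^2_a/(\sigma^2_a+\sigma^2_w)$, permutation p, 16000
permutations by default); average pairwise differences within/between
sites.

**Panmixia.** The Hudson–Boos–Kaplan statistic
$K_{ST} = 1 - K_S/K_T$, where $K_S$ is the sample-size-weighted mean
within-site pairwise distance and $K_T$ the mean over all pairs pooled,
tested against a label-permutation null (5000 permutations, exact
enumeration on small problems) — screened over all site pairs per marker,
with panmictic groups as connected components of the non-rejected pairs.

**Telemetry.** Haversine distances (R = 6371.0088 km); the iterative
&gt;2 m/s speed filter; ice-bound (Dec–May) vs open-water (Jun–Nov)
permutation t-tests on distance from the breeding site; monthly
localization tables; and circadian haulout summaries (per-hour proportion
of days exceeding the daily mid-range of dry time).

## Worked example

```r
library(sealmix)

ds <- study_genotypes(seed = 1)   # emulated 11-site study
ds
#> genotype_dataset: 354 individuals, 9 loci, 11 sites (5 groups)
#>   missing genotypes: 2.4%

weir_cockerham_fst(ds, c("Saimaa", "Tuktoyaktuk"))$theta
#> [1] 0.2680174

sub <- subset_individuals(ds, ds$sites %in% c("Saimaa", "Tuktoyaktuk"))
dm  <- pairwise_genotype_distances(sub, "genotype_smouse_peakall")
kst_permutation_test(dm, sub$sites, n_perm = 5000, seed = 1)
#> K_ST Tuktoyaktuk vs Saimaa (n = 60, 22; genotype_smouse_peakall): K_S = 11.921, K_T = 15.483, K_ST = 0.23007
#>   p = 2e-04 (Monte Carlo, n_perm = 5000)

amova(pairwise_genotype_distances(ds, "allele_count_diff"),
      ds$sites, n_perm = 1000, seed = 1)
#> AMOVA (allele_count_diff): Phi_ST = 0.0870, p = 0.000999 (1000 permutations)
#>     component  df        SS    sigma2   percent
#>   among_sites  10  2970.606  7.020568  8.697866
#>  within_sites 343 25277.527 73.695415 91.302134
```

Read in order: the drifted isolate shows pronounced differentiation from a
large Arctic site ($\hat\theta \approx 0.27$, well above the 0.25
rule-of-thumb for "great" differentiation); the K_ST permutation test
rejects panmixia for that pair at p = 2e-4; and the all-site AMOVA places
~8.7% of the molecular variance among sites — which collapses to ~1.8%
when the isolate is excluded (see `analysis/03_differentiation.R`),
the signature of one diverged population inflating an otherwise panmictic
system.

## The analysis workflow

The numbered drivers under `analysis/` run the emulated study end to end,
writing CSV tables under `results/` (pass a seed as the first argument;
default 1):

```sh
Rscript analysis/01_simulate.R 1        # GenePop + FASTA + telemetry CSVs
Rscript analysis/02_diversity.R 1       # HWE/LD, heterozygosity, rarefaction
Rscript analysis/03_differentiation.R 1 # pairwise theta, AMOVAs
Rscript analysis/04_panmixia.R 1        # K_ST screens, panmictic groups
Rscript analysis/05_telemetry.R 1       # speed filter, seasonal tests, haulout
```

`run_pipeline()` exposes the same orchestration as a single function over
a `run_config()` (inputs or simulation specs, permutation counts, master
seed), writing the stage tables and a manifest.

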
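---
title: "Population structure and seasonal movement of ringed seals: models and methods"
author: "sealmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure and seasonal movement of ringed seals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealmix)
```

## The scientific problem

Ringed seals (*Pusa hispida*) breed on land-fast and pack ice at discrete
sites spread across the Arctic, the Baltic Sea and Lake Saimaa.  Whether
those breeding sites exchange migrants determines how much genetic
variation the species can mobilise against a rapidly changing ice
environment.  Two lines of evidence bear on the question: population
genetics (microsatellite genotypes and mtDNA haplotypes sampled at breeding
sites) and satellite telemetry (seasonal movement and haulout behavior of
tagged seals).  `sealmix` implements both analysis chains as tested,
reusable functions, together with synthetic-data generators that emulate
the sampling structure of such a study, so that every stage can be
exercised and calibrated without access to field data.

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` simulate a full study (`01`), then run diversity (`02`),
differentiation (`03`), panmixia (`04`) and telemetry (`05`) stages over
the simulated files, writing CSV tables under `results/`.  All computation
lives in package functions, so the same code paths are unit-tested and
reusable on real data in the standard formats (GenePop, aligned FASTA,
telemetry CSV).

## Genetic distance metrics

Two pairwise distances feed the differentiation and panmixia machinery.

**TN93 + gamma sequence distance.**  For aligned mtDNA sequences the
Tamura–Nei (1993) distance distinguishes the two transition classes
(A&harr;G at proportion $P_1$, C&harr;T at $P_2$) from transversions ($Q$),
with base frequencies estimated from the two sequences pooled.  Rate
variation across sites is handled with the continuous gamma correction of
shape $\alpha$: each term $-k\log w$ of the plain TN93 formula becomes
$\alpha k (w^{-1/\alpha} - 1)$.  Defaults follow the marker-specific
shapes used for this system, $\alpha = 0.25103$ for COI and
$\alpha = 0.164$ for the control region (`study_mtdna_alpha()`).  A
discrete-category count (K = 4) is sometimes quoted next to these shapes;
that refinement belongs to likelihood phylogenetics, not to the pairwise
closed form, so K is carried as matrix metadata only.  Positions where
either sequence carries `N` or a gap are excluded pairwise; other IUPAC
ambiguity codes are conservatively converted to `N` at construction.
Saturated pairs (a logarithm/power argument reaching zero) raise an error
naming the pair rather than silently capping, because a silent cap would
distort the K_ST statistic; `cap_saturated` substitutes an explicit value
when that behavior is wanted.  The implementation is cross-checked in the
test suite against `ape::dist.dna(model = "TN93", gamma = alpha)` to
1e-10.

**Multiset genotype distances.**  For two diploid single-locus genotypes
compared as unordered allele multisets, the summed single-locus scheme
scores 0 for (ii,ii) or (ij,ij), 1 for (ii,ij) or (ij,ik), 2 for (ij,kl),
3 for (ii,jk) and 4 for (ii,jj), summed over loci where both individuals
are called.  The companion allele-count-difference distance is
$2 - |\text{multiset intersection}|$ per locus; it drives the
microsatellite AMOVA.  Both are true metrics (symmetry, identity,
triangle inequality), property-tested on random genotypes.

## Within-site diversity

Observed heterozygosity is the fraction of heterozygous individuals among
those genotyped; expected heterozygosity uses Nei's unbiased estimator
$\hat H_e = \frac{2n}{2n-1}\left(1 - \sum_k p_k^2\right)$.  A locus is
polymorphic within a site when at least two alleles are observed there —
no frequency threshold, the simplest testable rule.

**Hardy–Weinberg testing** uses a Monte-Carlo exact test: the statistic is
the conditional probability of the genotype array given its allele counts,
and the null is generated by randomly re-pairing the observed allele pool.
This matches the behavior class of the exact tests in the standard
population-genetics programs while remaining fully specified here.  A
one-sided homozygote-excess p-value (heterozygote count as low as or lower
than observed) is reported alongside, because breeding-site data are
conventionally screened for excess homozygosity (null alleles,
inbreeding).  The asymptotic chi-square test was rejected: per-site sample
sizes are small and loci multiallelic, exactly the regime where it fails.
The Monte-Carlo p matches full enumeration at n = 3 in the tests, and its
null rejection rate is calibrated at the 5% level on data simulated under
HWE.  Note the test is conservative when the genotype array's conditional
distribution has few support points (few alleles, small n); the
calibration suite therefore uses a five-allele locus at n = 40.

**Linkage disequilibrium** between two loci within a site is tested with
the genotypic log-likelihood-ratio G for independence of the two-locus
genotype table, with the null generated by permuting one locus's genotypes
among individuals — a genotype-level test that needs no phase information.

**Multiple testing** uses plain Bonferroni correction with the
family-size conventions that reproduce the reporting style of breeding-site
studies: the HWE family is loci &times; sites (9 &times; 11 tests gives an
adjusted level reported as 0.0005 at one significant figure) and the
linkage family is locus pairs &times; sites (36 &times; 11 gives 0.0001).
`bonferroni_alpha()` returns the rounded reporting value with the
unrounded level attached as an attribute; decisions use the unrounded
value.

**Rarefied allelic richness** standardises allele counts to a common
sample size N by repeatedly drawing N individuals without replacement,
counting distinct alleles per locus, and averaging over loci and
replicates ($\hat A_N$, mean &plusmn; SD over replicates; 1000 replicates
by default).  Individuals, not genes, are subsampled, because the
curves are indexed by "number of genotypes in a sample"; missing data are
handled by per-locus renormalisation of the subsample.  At N equal to the
unit's size the value is computed exactly with SD 0.  The test suite
checks the Monte-Carlo mean against the gene-level hypergeometric closed
form $\sum_a \left[1 - \binom{2n-c_a}{2N}/\binom{2n}{2N}\right]$; that
form treats the 2N genes as freely sampled while the estimator samples
them in individual-pairs, so agreement is asserted at 3 Monte-Carlo
standard errors rather than 2.  Differences in $\hat A_N$ between units
are tested by pooling the two units, re-splitting at observed sizes and
recomputing the difference (two-sided).

**Duplicate screening** flags pairs of individuals whose genotypes differ
at no more than one allele across all mutually called loci (per locus:
2 minus the multiset intersection), counting per allele.  In field data
this identifies resampled individuals (shed skin collected twice); the
pipeline removes flagged redundancy before all genetic stages, keeping the
first-seen copy (optionally the copy with fewest missing loci).  One
caveat matters for strongly drifted, low-diversity populations: distinct
individuals can genuinely differ by one allele or none ("shadow" pairs),
so the one-mismatch rule over-flags exactly where diversity is lowest.
Because the synthetic generator emits every individual exactly once, the
acceptance script reports the flag count but analyses the full dataset;
on real data the flags should be reviewed against match probabilities
before removal.

## Between-site structure

**Weir–Cockerham &theta;** estimates F_ST from the 1984 variance
components a (among populations), b (among individuals within
populations) and c (within individuals), computed per allele per locus and
combined as a ratio of sums $\hat\theta = \sum a / \sum (a+b+c)$ — the
standard recommendation, which stabilises low-polymorphism loci relative
to averaging per-locus ratios.  Missing genotypes are dropped per locus.
Negative estimates are reported as computed, never truncated: truncation
is a display choice, and small negative values are informative about
sampling noise near zero.  Significance for a site pair comes from
permuting individuals between the two sites at observed sizes (one-sided:
differentiation inflates &theta;).

**AMOVA** partitions squared pairwise distances into among- and
within-site components (one-level Excoffier–Smouse–Quattro):
$SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2$, within-site sums scaled by
group size, $\sigma^2_w = SS_w/(N-k)$, and
$\sigma^2_a = (MS_{among} - \sigma^2_w)/n_0$ with $n_0$ the standard
unequal-size coefficient; $\Phi_{ST} = \sigma^2_a/(\sigma^2_a+\sigma^2_w)$.
The null permutes individuals among sites at fixed sizes, counting
permuted $\Phi_{ST}$ at least as large as observed; 16000 permutations by
default.  Singleton sites are excluded with a warning (their within-site
degrees of freedom are zero).  When the total variance is zero the result
is flagged degenerate and reported as 0%/100% with p = 1.  Microsatellite
AMOVA consumes allele-count-difference matrices; mtDNA AMOVA consumes
TN93+gamma matrices with the region-specific shape.  The same engine,
fed a brute-force pair-enumeration oracle, is verified component-by-
component in the tests.

## The panmixia test

For a pair of sites, $K_i$ is the mean pairwise distance within site $i$,
$K_S$ the sample-size-weighted average of the $K_i$, $K_T$ the mean
pairwise distance over all individuals pooled, and the statistic is
$K_{ST} = 1 - K_S/K_T$.  The permutation null re-assigns site labels at
fixed sample sizes; the test is one-sided (large $K_{ST}$ means
differentiation; negative values indicate excess within-site diversity,
not structure).  Weights are $w_i = n_i/\sum n_j$ by default, following
the sample-size-weighted definition; the $(n_i-1)$-proportional variant
found in parts of the subdivision-test literature is available via
`weights = "hbk"`.  When the number of distinct label arrangements
$\binom{n}{n_1}$ is at most 20000 the test enumerates all of them and
reports the exact proportion of arrangements with $K_{ST}$ at least the
observed value (the observed arrangement included, so p is never 0);
otherwise Monte-Carlo sampling applies the $(1+b)/(1+n_{perm})$ rule.
5000 permutations by default.

`panmixia_screen()` runs the test for every usable site pair within one
marker and reports the connected components of the graph whose edges are
non-rejected pairs — the "panmictic groups".  Markers are screened
independently (microsatellites, COI, CR); no combined-marker p is formed.
Pairwise decisions use raw p-values at level &alpha; (reproducing the
decision rule such screens conventionally report); a Bonferroni-adjusted
call is included as an extra column for comparison, not used for the
groupings.

## Telemetry analysis

Distances are great-circle (haversine) on a sphere of radius 6371.0088 km.
The **speed filter** implements the stated rule — remove locations
requiring swimming speeds above 2 m/s — rather than a full
angle-and-distance Argos filter: removal is iterative and greedy (the
point whose removal most reduces the violation count goes first; ties
break toward the larger adjacent implied speed, then the later fix),
recomputing implied speeds after every removal, because a single pass can
strand violations.  The output satisfies the constraint exactly and the
filter is idempotent.

Seasons follow the calendar-month convention for this system: ice-bound
December–May, open-water June–November, in UTC.  The **seasonal test**
compares mean distance from the capture site (the breeding-site anchor)
between seasons; the statistic is the absolute difference of seasonal
means — permutation-equivalent to the t statistic under equal variances,
which avoids committing to a variance-pooling formula — and the null
permutes season labels over the track's fixes at fixed counts
(two-sided, $(1+b)/(1+n_{perm})$).  A season with no data yields NA.

**Haulout summaries** work on hourly dry-time fractions.  Days with fewer
than 20 of 24 hourly values are excluded; remaining gaps are left missing,
not imputed.  Per day the mid-range is (min + max)/2, and the circadian
summary reports, per hour of day, the fraction of days whose dry time
strictly exceeds that day's mid-range, plus the per-hour mean and range,
the longest run of fully wet hours, and the minimum hourly dry minutes.
The strict inequality makes a constant day contribute zero exceedance
everywhere.  The exceedance is invariant under positive rescaling of a
day's values when the daily minimum is zero (the mid-range scales with
the values); it is *not* invariant under adding a constant, since the
mid-range shifts equally.

## The synthetic-data generators

The generators are first-class, tested code: their defaults *are* the
emulated study conditions, fixed once.

**Genotypes** (`simulate_island_genotypes()`): ancestral allele
frequencies per locus are drawn from a flat Dirichlet; each site drifts
around them with site frequencies
$p_{site} \sim \mathrm{Dirichlet}(p\,(1-F)/F)$, which gives
$E[(p_{site}-p)^2] = p(1-p)F$ — the per-site drift level is therefore the
quantity the Weir–Cockerham estimator targets, and recovery is checked
directly (bias below 0.05 at targets 0.01–0.3 with 9 loci and 50 per
site).  Genotypes are drawn in Hardy–Weinberg proportions within sites,
so the HWE test's null calibration can use the generator as its null.  A
scaled migration rate may be given instead and is converted through the
island-model equilibrium $F = 1/(1+4Nm)$.  A coalescent simulation would
add genealogical realism (linkage, allele-frequency spectra shaped by
mutation models) but would control F_ST only indirectly; direct control
was preferred because F_ST recovery is what the downstream stages test.

The emulated design (`study_sites()`) has eleven sites totalling 354
genotyped seals in three groups: nine Arctic sites at F = 0.005
(effectively panmictic), a Baltic-like satellite at Nm = 20
(F = 1/81 &asymp; 0.012, inside the 10–45 migrants-per-generation
equivalence for a connected satellite), and a Saimaa-like isolate at
F = 0.75, chosen so the realized pairwise &theta; against the other sites
falls in the pronounced-differentiation band (roughly 0.26–0.37 across
seeds) that characterises a landlocked, bottlenecked subspecies.  Nine
loci carry 4–15 alleles; 2% of genotypes are missing at random.

**mtDNA** (`simulate_mtdna_haplotypes()`): a random root sequence spawns a
shared haplotype pool plus per-site private haplotypes, each haplotype
placed at its own substitution positions so all are mutually distinct at
`divergence` sites.  Connected sites draw from a frequency profile with
two prevalent shared haplotypes; an isolate site concentrates at least 95%
of its sample on one private haplotype, allocated deterministically
(`ceiling(0.95 n)`, so 21 of 22 samples share one haplotype).  COI uses a
12-haplotype shared pool, the hypervariable control region a 20-haplotype
pool; both are 475 bp, the length of a 1-based inclusive trimming window
[90, 564].  (Published descriptions of such windows sometimes quote a
retained length inconsistent with the coordinates; the package always
takes explicit coordinates literally.)

**Movement** (`simulate_track()`): the seal's distance from its capture
site follows a continuous piecewise-linear excursion path — zero at the
midpoints of near-site months, an AR(1)-correlated draw around
`summer_mean_km` at the midpoints of long-range months — travelled along
one persistent random bearing, with local scatter (`winter_sd_km`) and
Argos-like noise on every fix, and fix times evenly spaced with jitter.
The continuous path keeps implied travel speeds realistic (well under
2 m/s), so the speed filter removes essentially only injected outliers;
an earlier design that drew independent positions per fix produced
spurious regime-boundary "teleports" that the filter would eat.  Null
calibration of the seasonal test uses tracks with the long-range regime
disabled (`summer_months = integer(0)`), under which season labels are
exchangeable by construction — a same-mean two-regime configuration would
not be an exact null because the regimes differ in shape.  Distances are
converted to degrees with a local equirectangular projection at the
capture latitude on the generation side; all analysis-side distances are
great-circle.

**Haulout** (`simulate_haulout()`): hourly dry fractions at a baseline
level, elevated within a daily dry window (default 04:00–19:00, a 15-hour
haulout period), Gaussian noise added wherever the mean level is positive,
clipped to [0, 1].  A zero mean level yields an exact zero — a seal that
never hauls out produces an all-wet sensor record — which makes the
longest-wet-bout statistic exact on that degenerate input.

**What the generators do not emulate:** null alleles, allelic dropout and
genotyping error; linkage between loci; coalescent genealogy and mutation
processes (stepwise microsatellite mutation, mtDNA rate heterogeneity
beyond the gamma correction); ice-field geometry and Argos location
quality classes; tag duty-cycling and transmission gaps beyond simple
missingness.  Passing tests therefore demonstrate correctness of the
statistics and calibration of the permutation machinery under clean
sampling structure, not robustness to those artefacts.

## Numerical and design choices

* All Monte-Carlo permutation p-values use the add-one rule
  $(1+b)/(1+n_{perm})$, so $p \ge 1/(1+n_{perm})$ and p is never 0;
  exhaustive K_ST enumeration reports the exact arrangement proportion.
  Whether legacy subdivision-test software used this rule or $b/n_{perm}$
  is ambiguous; the add-one rule was chosen and is documented here.
* Tie handling in permutation counts uses small tolerances (1e-9 on
  log-probabilities, 1e-12 on distances/statistics) so that exact ties
  count as "as extreme", keeping the tests valid rather than
  anti-conservative.
* Every stochastic stage derives its seed from the master seed and a
  stream label (`sub_seed()`, a polynomial string hash modulo
  $2^{31}-1$), so partial re-runs reproduce exactly and results never
  depend on evaluation order.
* GenePop output always uses 3-digit allele coding with the
  comma-after-id layout; the reader accepts 2- or 3-digit coding and both
  id layouts, decodes all-zero fields as whole-genotype missing, and
  rejects half-called genotypes — downstream pairwise-deletion rules
  assume whole-genotype missingness.
* Mid-scale problem sizes in the test suite (200 null replicates at 99
  permutations for calibrations; 500 subsampling replicates for the
  rarefaction oracle; three seeds for the full-study pattern check) were
  chosen to make the binomial acceptance bands meaningful while keeping
  the suite comfortably fast; the acceptance script runs the full 16000
  AMOVA and 5000 K_ST permutations of the emulated study.

## Known limitations

* The TN93+gamma distance requires all four bases present in the pooled
  pair when the corresponding change class is observed; heavily degenerate
  compositions raise saturation errors rather than guessing.
* The HWE exact test is conservative for very small samples or few
  alleles (discrete support); interpret non-rejections at n &lt; 10 with
  care.
* The one-level AMOVA does not implement the hierarchical (region/site)
  three-level design, and no bootstrap-over-loci confidence intervals are
  provided for &theta;.
* The duplicate screen's one-mismatch rule over-flags in low-diversity
  populations (see above); `remove_duplicate_genotypes()` is a policy
  choice, not an inference.
* The speed filter is the stated 2 m/s rule, not a full Argos
  quality-class filter; tracks dominated by poor-quality fixes need
  upstream quality screening.
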
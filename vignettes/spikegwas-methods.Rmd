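---
title: "Methods: trait dissection, mixed-model mapping and haplotype analysis in spikegwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait dissection, mixed-model mapping and haplotype analysis in spikegwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spikegwas maps the genetic architecture of cereal spike morphology by
dissecting yield-component measurements into assimilate-partitioning
ratios and running a mixed-linear-model association scan over them. This
vignette is the package's account of the statistical machinery: the models,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices that a
reader of the results should know about.

## The trait panel

Twelve traits are measured per spike (lengths, dry weights of grain, awn,
chaff, rachis and whole spike, grain and spikelet counts, and the
per-spikelet analogues). Fifteen further traits are ratios of these —
thousand kernel weight `(grain weight / grain number) x 1000`, spikelet
density `spikelet number / spike length`, fruiting efficiency
`grain number / chaff weight`, and the remaining pairwise partitioning
ratios for the whole spike and the central spikelet
(`trait_definitions()` lists all 27). Ratios are always computed per
accession x year x replicate **before** any averaging
(`derive_traits()`): a mean of ratios is not a ratio of means, and the
package asserts this ordering in its tests. Records whose denominator is
zero or missing are dropped and counted, never imputed.

## Variance components, heritability and BLUEs

For each trait the two-way model

$$Y_{ijk} = \mu + G_i + Y_j + (GY)_{ij} + \varepsilon_{ijk}$$

is summarized by the classical expected-mean-squares method of moments
(`anova_components()`): `var_e = MS_error`,
`var_GxE = (MS_GxY - MS_error) / r`,
`var_G = (MS_G - MS_GxY) / (r y)`, with negative estimates clamped to
zero and flagged. Genotype and year are tested against the interaction
mean square and the interaction against the error, the appropriate
denominators when year and interaction are treated as random. Balanced
designs use a closed-form sums-of-squares path (identical to `aov()`, and
tested to be so) because the moment equations only need cell and marginal
means; unbalanced designs fall back to sequential `aov()` sums of squares.

Broad-sense heritability is computed on the entry-mean basis,

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GY}/y + \sigma^2_e/(ry)},$$

the two-year five-replicate form generalized to $y$ years and $r$
replicates. With components (4, 2, 5) and $y = 2, r = 5$ this gives
0.7273, a value the test suite pins by direct substitution. $H^2$ is
scale-invariant and lies in $[0, 1]$ because of the clamping.

Genotype values entering the scan are BLUEs from
`value ~ genotype (fixed) + year (random) + genotype:year (random)`. A
fully balanced design makes every BLUE the genotype's raw mean, and that
closed form is used exactly; unbalanced designs are fitted by REML via
lme4, and the tests compare those fits to an explicit
generalized-least-squares oracle. A BLUE of genotype is only defined with genotype fixed; users who prefer
the all-random parameterization of the same two-way model can call
`compute_blues(genotype_random = TRUE)`, which returns BLUPs (shrunken
genotype predictions) instead.

Multiple comparisons use Fisher's LSD after a one-way ANOVA
(`lsd_groups()`): two groups differ when their mean difference exceeds
$t_{1-\alpha/2,\,df_e}\sqrt{MSE\,(1/n_i + 1/n_j)}$; compact letters are
assigned by insert-and-absorb, so sharing a letter means "not
significantly different".

## Kinship, PCA, LD

The kinship matrix is the simple-matching similarity: the fraction of loci
at which two accessions carry the identical genotype category (0/1/2),
missing loci excluded pairwise. It is symmetric with unit diagonal but can
be slightly indefinite after pairwise exclusion, so mixed models floor its
eigenvalues at 1e-6 before use.

PCA LD-prunes first (greedy sliding windows, 50 kb span, step 5 kept
SNPs, r² > 0.2 removes the later SNP, swept to a fixed point), then
centers each SNP at twice its allele frequency, standardizes by the
binomial standard deviation, mean-imputes missing calls, and
eigendecomposes the accession covariance. The top three PCs are the
default covariate set.

LD is the squared Pearson correlation of unphased dosages over jointly
non-missing accessions — the genotypic r² of Plink/PopLDdecay on unphased
data, invariant to allele relabelling. `ld_decay()` reports two decay
summaries because two conventions circulate: the half-max distance (first
distance bin whose mean r² falls to half the curve's maximum, no
interpolation) and the interpolated distance at r² = 0.50. On a flat
curve that never reaches half its maximum the half-max distance is `NA`
by construction.

Tajima's D follows the 1989 constants with the allele-count convention of
VCF-based tools: `n = 2 x accessions` chromosomes, a site's pairwise
diversity from its alternate-allele count. Sites with missing calls use
their own called chromosome count in the diversity term while the
constants use the full `n`; this approximation is adequate at the few
percent missingness the pipeline filters to.

## The mixed-model scan and its thresholds

The association model is $y = g\alpha + S\beta + u + e$ with
$\mathrm{cov}(u) \propto K$. The null model is fitted by
single-variance-component REML in the eigenbasis of K, profiling the
variance ratio $\lambda = \sigma^2_g/\sigma^2_e$ by one-dimensional
optimization of the REML log-likelihood over $\log\lambda \in [-10, 10]$.
The default scan mode fixes $\lambda$ at the null estimate (the
P3D/EMMAX approximation) and tests each SNP by generalized least squares
in the rotated, rescaled basis — a Wald t-test on $\alpha$ with
per-SNP mean imputation of missing dosages (inside the test only). The
`exact` mode re-optimizes $\lambda$ per SNP. The two agree closely for
the bulk of SNPs (median |Δlog10 p| well under 0.05 in the tests); the
rare larger deviations occur for SNPs strongly confounded with structure,
the known P3D approximation error, which is why `exact` exists for spot
checks.

Two caveats worth knowing. First, with simple-matching K the eigenvalue
spectrum beyond the leading component (absorbed by the intercept) is
nearly flat, so the REML profile in $\lambda$ is shallow for phenotypes
without polygenic signal; the boundary estimate is reached in only about
half of such datasets even though the fitted polygenic variance share is
essentially zero. Second, the kinship partially absorbs strong causal
SNPs (proximal contamination), a power cost faithful to scans that do not
use leave-one-chromosome-out kinship.

Genome-wide significance is assessed three ways: Bonferroni
$\alpha/n$ with $n$ the LD-pruned marker count (at a pruned
count of 2,756,291 this is 1.81e-08, i.e. $-\log_{10}p = 7.74$; note the
division and the $-\log_{10}$ form are self-consistent); an empirical
threshold from phenotype permutations (each permutation shuffles y across
accessions with S and K fixed, reruns the approximate scan, and records
the genome-wide minimum p; the threshold is the 0.05 type-1 empirical
quantile of those minima over 100 permutations); and a working threshold
of $-\log_{10}p = 5.00$ used for peak calling, the conventional moderate
threshold for this panel size. Permutation procedures for GWAS are
described in several inequivalent ways in the literature (quantiles of
all ranked p-values versus quantiles of per-permutation minima); the
minimum-p empirical-quantile convention implemented here is the one that
controls the family-wise error rate, and phenotype (not genotype)
shuffling is used as is standard for mixed models.

## Peaks, regions and candidate genes

Significant SNPs (working threshold) are delineated into intervals per
chromosome as the connected components of the graph with edges where
pairwise r² > 0.1, computed among the significant SNPs only. Interval
bounds are the min/max member positions (1-based inclusive). Adjacent
intervals whose lead SNPs (most significant member; ties to the smaller
coordinate) lie strictly closer than 5 Mb are merged iteratively, the
lead re-derived after every merge, until stable. An interval is flagged a
peak when it holds strictly more than 10 significant SNPs. Overlapping
peaks from different traits collapse into unified regions
(`cross_trait_summary()`), which records each region's supporting traits
and flags regions exclusive to ratio traits — the package-level
embodiment of the argument that assimilate-partitioning ratios reveal
loci invisible in their component traits. Regions could equally be merged across traits before the 5 Mb rule;
this package delineates per trait and overlaps afterwards, one
consistent convention applied throughout.

Candidate genes are the annotation entries intersecting ±500 kb around a
peak's lead SNP, at distance 0 when the lead lies inside the gene span
and otherwise the gap to the nearest gene edge, ranked by an expression
filter first (FPKM ≥ 1 in any of the six spike-development stages
ZM1–ZM6 — an operational form of "expressed during spikelet and floret
initiation"; the threshold is exposed because high expression is a
qualitative notion) and distance second.

## Haplotypes

Within a gene region, haplotypes are identical unphased dosage strings
over the region's polymorphic SNPs — the natural definition in a selfing
crop where heterozygosity is minimal and phase is uninformative.
Complete accessions define the groups; groups reaching 5% of the panel
(inclusive; the cutoff is exposed rather than fixed because no
single frequency rule defines "major" in common usage) are labelled Hap-1, Hap-2, … by
descending count, ties broken by the dosage string for determinism.
Accessions with missing calls join a major haplotype only when their
non-missing sites match exactly one major string; everything else pools
into "minor". Per-haplotype trait effects report the group mean of the
accession BLUEs, the difference from a reference haplotype as a
percentage and in absolute units side by side, and LSD letters.
Frequencies tabulate by geographic region or by release decade (one bin
to 1970, then ten-year bins to 2020), and percentages sum to 100 within
each group. Coverage (share of accessions in major haplotypes) is always
computed from the counts; with counts 88/59/129/18 over 306 accessions it
is 96.08%.

## The synthetic-data generator

Every stage is testable against ground truth because the generator
produces genotypes, phenotypes, metadata, annotation and expression with
the statistical structure the analysis assumes.

**Genotypes.** Chromosomes are tiled with LD blocks. Each block draws one
founder frequency (uniform on 0.25–0.75) and per-subpopulation
Balding–Nichols frequencies at a configurable F~st~ (default 0.1, 10
subpopulations); each accession draws two founder indicators per block
and every SNP copies its indicator with a per-SNP flip probability
$\varepsilon = (1 - r_2^{1/4})/2$, chosen because at founder frequency
1/2 the dosage correlation between block mates is $(1-2\varepsilon)^2$,
so the mean within-block r² lands at the configured value (0.8 by
default; the tests verify ±0.1) while blocks are mutually independent.
Missing calls are dropped in at the configured rate. This is a
desk-scale, analytically tunable scheme, not a coalescent: it produces
the right second-order structure (block LD, subpopulation divergence,
MAF spectrum after filtering) but no recombination gradients within
blocks, no mutation-age structure, and no realistic polyploid genome
organisation, so passing tests speak to the statistics of the pipeline,
not to wheat demography.

**Phenotypes.** Trait values are generated as
$\mu_t \exp(x/100)$ where $x$ sums the genetic, year, interaction and
residual effects with the configured variances (defaults
$\sigma^2_G = 4, \sigma^2_{GY} = 2, \sigma^2_e = 5$, year variance 1) —
the exponential guarantees strict positivity (ratios need positive
denominators) while a trait with mean 100 carries the configured
variance components on the observed scale to within a fraction of a
percent; a trait with mean $\mu_t$ carries them scaled by
$(\mu_t/100)^2$. The recovery tests therefore read the trait whose mean
is 100 (spike length in mm). Counts are rounded to integers after
simulation. A configurable fraction (`trait_cor`, default 0.5) of every
variance component is shared across the 12 component traits, making
spike components co-vary the way parts of one spike do; the true trait
covariance of real spikes is unknown, so this is a knob, not a
calibration. The polygenic accession term is built from genome-wide SNP
effects (so its covariance tracks the realized kinship) and is
standardized to the configured variance; SNPs in LD blocks holding a
planted QTL are excluded from that basis so a QTL's variance share is
delivered as documented. QTL effects attach to measured component traits
only — never directly to ratios — with `qtl_h2` the fraction of the
trait's total single-observation variance (the effect is inflated by
$1/(1-\sum h^2)$ so the fractions are exact); ratio-trait signals then
emerge mechanistically from the numerator and denominator, which is the
point of the dissection.

**Metadata, annotation, expression.** Each subpopulation has a home
region among seven continental labels, inherited with probability
`region_coupling` (default 0.8); release years are uniform on 1900–2020.
Genes tile each chromosome (one per 200 kb, 3 kb span) and expression is
log-normal with a configurable silent fraction, so the candidate-gene
filter has both positives and negatives.

## Designed experiments behind the headline checks

The acceptance checks run at sizes that keep a full desk-scale replication
under a few minutes of one CPU: null calibration and the permutation
threshold at 300 accessions x 2,000 near-independent SNPs; QTL recovery at
306 accessions x 5,000 SNPs with five planted QTLs at 5% of variance each,
20 replicate datasets; variance-component recovery at 500 genotypes x 2
years x 5 replicates, 100 replicates; ratio-trait power at 306 accessions
x 900 SNPs, 50 replicates. Two design choices deserve a note. A planted
QTL counts as *recovered* when a mapped region lies within one LD block
(500 kb) of it — the generator's mapping resolution — rather than by
strict positional containment, which would score a correctly found locus
as a miss whenever the flanking significant SNPs happen to sit on one side
of the causal variant. The antagonistic-QTL demonstration plants 2% of
variance on each of grain weight and chaff weight with opposite signs:
with half of the background variance shared between the components, the
ratio cancels the shared part and roughly quadruples the QTL's variance
share, which by design puts the component scans well below the working
threshold (power ≈ 0.05) and the ratio scan well above it (power ≈ 1) —
the mechanism by which partitioning ratios expose loci that their
components hide.

## Known limitations

- The generator's LD is blockwise-constant; there is no within-block decay
  and no cross-block admixture LD beyond what subpopulation structure
  induces, so LD-decay summaries on simulated data are stylized.
- Variance components assume a crossed genotype x year layout with
  replicates; multi-location trials and spatial field trends are out of
  scope.
- The scan is single-trait; no multi-trait mixed models, G x E scans or
  rare-variant tests.
- Haplotypes are unphased dosage strings; statistical phasing and
  haplotype networks are out of scope, and Tajima's D is the only
  selection statistic.
- P3D p-values deviate from exact per-SNP REML for SNPs heavily
  confounded with structure; use `mode = "exact"` to spot-check a region
  of interest.
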
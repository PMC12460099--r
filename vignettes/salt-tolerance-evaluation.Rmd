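---
title: "Evaluating seedling-stage salt tolerance in structured crop panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating seedling-stage salt tolerance in structured crop panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

saltpanel implements a complete evaluation-and-mapping chain for seedling
salt tolerance in a diploid (or allotetraploid, dosage-coded) germplasm
panel: from replicated raw measurements under control and salt stress,
through a composite tolerance score, to a mixed-model genome scan and
candidate-interval analysis. This vignette explains the underlying models,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical conventions the
package commits to.

## The phenotype model

Each trait is measured on control plants and on plants grown under
200 mmol/L NaCl, in a trial crossing years and replicates. The
salt-tolerance index of a cell is the ratio

$$\mathrm{STI} = \frac{\text{measurement under salt stress}}
                      {\text{measurement under control conditions}},$$

computed per (accession, year, replicate, trait) cell; when a cell holds
several plants, `compute_sti()` takes the ratio of cell means. STI is
dimensionless and scale-invariant: rescaling all raw measurements of a
trait (changing units, say) leaves it unchanged, which the test suite
asserts as a property.

Year-to-year and replicate effects are removed by a REML mixed model,

$$\mathrm{STI} \sim \text{accession} + (1\,|\,\mathrm{rep}) +
  (1\,|\,\mathrm{year{:}rep}) + (1\,|\,\mathrm{year}),$$

fitted per trait with lme4. Accession is fixed; replicate, year and
replicate-within-year are independent random intercepts. We code the
accession factor without an intercept, so the fixed-effect coefficients
are estimated marginal means on the STI scale; these are the BLUEs that
all downstream stages consume. Variance components are non-negative by
construction (constrained REML). Two numerical caveats are worth knowing:

* In the balanced, zero-variance limit the BLUEs coincide with plain
  accession means (tested to 1e-6).
* With only two year levels, the year and year-within-replicate variances
  are weakly identified and their constrained-REML estimates are
  component-wise biased near the zero boundary: the estimates trade off
  against each other and truncation at zero redistributes their means.
  This is a property of constrained REML at few factor levels, not of the
  implementation -- the same code is unbiased (within Monte-Carlo error)
  on an 8-year x 6-replicate design. Residual variance and the accession
  effects themselves are unaffected.
* A trait observed in a single year degrades, with a warning, to a
  replicate-only random-effects model.

## The membership-function composite score

Four trait STIs are condensed into one panel-level score. The chain is:

1. **PCA** (`run_pca()`): trait columns are standardized and the
   correlation matrix eigendecomposed, so eigenvalues sum to the number
   of traits and the contribution rate of component $i$ is
   $P_i = 100\,\lambda_i/\sum\lambda$. Correlation-matrix PCA (rather
   than covariance) is used because the traits, although all
   dimensionless ratios, differ several-fold in spread; the choice also
   makes eigenvalue totals interpretable. Eigenvectors are unit-norm
   with the sign convention that each vector's largest-magnitude
   coefficient is positive; any consistent rescaling or sign choice
   cancels later (see below).
2. **Component selection** (`select_components()`): the smallest $k$
   whose cumulative contribution reaches a threshold, 85% by default.
3. **Comprehensive scores** $F_{ai} = \sum_j E_{ji}\,x_{aj}$ over the
   standardized traits -- the projection of accession $a$ onto retained
   eigenvector $i$.
4. **Membership values** $\mu(F_i) = (F_i - F_i^{\min}) /
   (F_i^{\max} - F_i^{\min})$, a column-wise min-max rescaling across
   the panel. Because this map is invariant to affine transforms of a
   column, the eigenvector scaling in step 1 is immaterial; a sign flip
   *would* matter, which is why the sign convention is fixed before this
   step (the suite asserts that forced flips are absorbed).
5. **Weights** $W_i = P_i / \sum_{i \le k} P_i$ over the retained
   components only.
6. **D value** $D = \sum_i \mu(F_i)\,W_i$, bounded in $[0,1]$; higher D
   means more salt tolerant.

`classify_tolerance()` then clusters the one-dimensional D values with
Ward's minimum-variance linkage on Euclidean distances (`hclust`,
`ward.D2`) and cuts the tree into five groups, relabelled I-V by
descending class mean so group I is the most tolerant. Clustering
operates on D alone, not on the trait matrix: D is the published basis
for the grouping, and a one-dimensional Ward cut is easy to audit (the
suite checks it against an exhaustive scalar implementation for panels
of up to eight accessions). The whole chain is deterministic; repeated
runs agree to 1e-12.

Degenerate inputs are refused loudly: a constant trait stops the PCA
with the trait named; a constant comprehensive-score column (all
accessions identical on a retained component) stops the membership step
with a remediation hint.

## Genotype-side statistics

`filter_variants()` applies the conventional GWAS filters -- minor allele
frequency above 0.05 and per-site call rate above 0.8, both strict
inequalities, mirroring VCFtools `--maf` / `--max-missing` semantics.

`kinship()` is the VanRaden genomic relationship matrix on mean-imputed,
frequency-standardized dosages; `genotype_pca()` takes its top
eigenvectors scaled by the root eigenvalues. Under the Balding-Nichols
generator the mean self-kinship is approximately $1 + F_{ST}$, which the
suite uses as a theory check.

LD is measured as the squared Pearson correlation of dosages over
pairwise-complete accessions (composite LD, no phasing). `ld_decay()`
bins pairwise r² by physical distance and reports two interpolated decay
distances: where the curve falls to the absolute value 0.5 (the primary
figure, matching the conventional reporting threshold) and where it falls
to half its short-distance maximum, defined as the first bin's mean.
A crossing requires the curve to start above the target; an unlinked,
flat curve therefore reports "beyond the maximum distance" rather than a
spurious noise crossing.

`ld_prune()` follows the PLINK convention (window 50 SNPs, step 50,
r² threshold 0.2): within each window, a violating pair is resolved by
removing the later-positioned SNP, repeatedly, until no pair violates.
The retained count is the effective SNP number, and
`effective_snp_threshold()` sets the genome-wide significance level to
its reciprocal.

F~ST~ uses the Weir-Cockerham (1984) estimator with full heterozygosity
terms; windowed values are ratio-of-sums over the SNPs in a window, the
recommended way to combine the variance components. Nucleotide diversity
per window is the sum of unbiased per-SNP expected heterozygosities
$2p(1-p)\,n/(n-1)$ divided by the window length, i.e. per-site pi over
all sites including invariant ones. Windows are 100 kb advancing by
20 kb by default, 1-based inclusive, anchored at position 1, terminal
partial windows kept; the BED export shifts to half-open coordinates.

## The association scan

`lmm_scan()` fits, per SNP,
$y = W\alpha + x\beta + u + \varepsilon$ with
$u \sim (0, \sigma_g^2 K)$ and $\varepsilon \sim (0, \sigma_e^2 I)$.
The kinship matrix is eigendecomposed once; the variance ratio
$\delta = \sigma_e^2/\sigma_g^2$ is estimated under the covariate-only
null by maximum likelihood on a log10 grid (-5 to 5, 61 points) refined
with Brent optimization, then reused for every SNP -- the
"population parameters previously determined" approximation that mixed
model GWAS tools use at this scale. Each SNP gets a generalized
least-squares Wald test with a t reference distribution on
$n - p - 1$ degrees of freedom. Three principal components are included
as fixed covariates by default. Design properties the suite verifies:
with identity kinship the scan collapses exactly to ordinary least
squares; p-values are invariant to allele-coding flips; the null scan on
a structured panel has genomic inflation within [0.9, 1.1]; and the
type-I error at 5% is binomially consistent over 10,000 unstructured
null SNPs.

One known limitation is proximal contamination: the kinship matrix
includes the tested SNP and its neighbours, so very strong single loci
are partially absorbed into the polygenic term and their association
signal deflates. Leave-one-chromosome-out kinship would avoid this and
is deliberately out of scope here.

Significance follows a dual rule (`call_significant()`): a SNP passes
with $p$ below the strict reciprocal-effective-SNP threshold in any
single environment, or below 1e-5 in at least two environments or
phenotypes. "Environments" are the per-year accession means and the
BLUE, per trait. Significant SNPs are extended by 100-kb flanks on both
sides, clipped to the chromosome, and overlapping-or-touching intervals
are merged into QTLs (`define_qtl()`), each reported with its minimum-p
lead SNP. Within a QTL, `haplotype_contrast()` groups accessions by
their exact dosage string over the region's SNPs (accessions with
missing calls there are dropped; heterozygotes form their own strings)
and contrasts the two largest groups of at least five accessions with a
two-sided Welch t test.

## What the synthetic generator emulates -- and what it does not

`simulate_genotypes()` draws ancestral allele frequencies uniformly on
[0.05, 0.5] and subpopulation frequencies from the Balding-Nichols
distribution $\mathrm{Beta}\!\left(p\frac{1-F}{F},
(1-p)\frac{1-F}{F}\right)$, the standard generative model whose single
parameter is the target F~ST~; dosages are binomial within
subpopulation, and calls are masked missing completely at random.
Defaults emulate the scale of a real evaluation panel: 240 accessions in
4 subpopulations, 4 chromosomes (half labelled A, half D, mimicking an
allotetraploid's subgenomes), genome-wide F~ST~ 0.15, 2% missingness.

`simulate_phenotypes()` generates, per accession/trait/year/replicate, a
latent STI equal to the trait mean plus genetic effect plus year,
replicate, year-within-replicate and residual noise -- exactly the
random-effects structure the BLUE model assumes -- then emits *raw*
paired measurements (control at the trait baseline with 5% noise; salt
as control times latent STI) so the STI stage is genuinely exercised.
Latent STIs are clamped at 0.01 to keep measurements positive, with the
clamp count logged. Genetic effects are the sum of configured causal-SNP
effects on standardized dosages and a correlated polygenic remainder
scaled so each trait's total genetic variance hits its configured value.

The per-trait defaults are choices, not published values: STI means
(0.62, 0.49, 0.58, 0.59) and genetic standard deviations (0.05, 0.09,
0.10, 0.08) for RPH, RSFW, RSDW, RRDW place the simulated panel on the
scale typical of seedling salt-stress trials (trait CVs of roughly
8-18%); design variances (year 6e-4, rep 3e-4, year:rep 3e-4, residual
1.5e-3) keep design noise subordinate to genetic signal, as a
well-conducted trial should; and the genetic correlation matrix couples
shoot fresh and dry weight strongly (0.8) while leaving plant height and
root dry weight nearly independent (0.16), the pattern expected of
biomass-related seedling traits. All are config-exposed.

Features of real data the generator does *not* emulate: linkage
disequilibrium beyond shared subpopulation drift (SNPs are conditionally
independent, so LD-decay curves on simulated panels are flat);
genotyping error correlated with heterozygosity; selection or admixture
gradients; trait distributions with outliers or measurement truncation;
and missingness that is informative. Green tests on simulated panels
therefore validate the estimators and the pipeline contracts, not the
package's behaviour under every pathology of field data.

## Problem sizes and determinism

All randomness flows from a single integer seed per configuration
(genotypes use the seed itself, phenotypes the seed plus one), and
regeneration is byte-identical, including the CSV writer's output. The
test suite exercises the panel at the emulated scale where the check is
about that scale (240 accessions for BLUE recovery, calibration scans of
10,000 SNPs, 20-seed recovery experiments) and at toy scale (3-5
accessions, 3-10 SNPs) where an exhaustive or hand-computed oracle is
the point; these sizes are the package's validation design. The pipeline
demo (`default_config()`) runs end-to-end in well under five minutes on
one CPU.

## Known limitations

* Constrained-REML component bias at few factor levels, described above.
* Proximal contamination in the association scan, described above.
* Haplotype grouping by exact dosage-string identity is conservative in
  regions with many SNPs or residual missingness: string diversity grows
  quickly and the two-largest-group contrast may find no qualifying
  groups. Narrow the region or raise `min_group` awareness accordingly.
* The Ward cut of one-dimensional D values can split visually contiguous
  accessions when the panel's D distribution is nearly uniform; class
  boundaries are then data-driven rather than biologically sharp.
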
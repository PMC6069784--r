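---
title: "Simulating and dissecting an eight-founder MAGIC population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and dissecting an eight-founder MAGIC population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magicpop)
library(dplyr)
```

## The population model

`magicpop` simulates and analyses multi-parent advanced generation
intercross (MAGIC) populations built from eight inbred founders through a
fixed funnel: four two-way crosses (A x B, C x D, E x F, G x H), two
four-way crosses (ABCD and EFGH), reciprocal eight-way intercrosses, and
single-seed descent (SSD) to F4. The default founder layout is the set of
eight European winter-wheat cultivars with Julius at position H as the
reference founder; identity-by-state (IBS) dosages count copies of the
Julius allele (homozygous Julius = 2, heterozygous = 1, homozygous
non-Julius = 0).

Each simulated chromosome is a founder mosaic: an ordered list of segments
in centimorgans, each tagged with the founder it descends from. Meiosis
draws a Poisson number of crossovers with mean L/100 (the Haldane model —
breakpoints uniform, no interference) and alternates parental chromatids
at the breakpoints. The model is deliberately simple: crossover
interference, mutation and cytoplasmic inheritance are not represented,
and reciprocal eight-way crosses are modelled identically (the reciprocals
exist in the crossing scheme only to balance allele frequencies).

Two analytic consequences anchor the test suite:

* after g selfing generations a locus heterozygous in the eight-way F1 is
  still heterozygous with probability 2^-g (1/8 at F4), and
* every line is expected to carry 12.5% of each founder's genome.

The default `sim_config()` fixes a realistic crossing design: 141
eight-way seeds drawn from 18 ABCD x 85 EFGH four-way plants, 15 selfed F2
seeds per eight-way plant (a budget of 2,115 lineages), 910 lines, three
SSD generations. All of these are free parameters of the configuration
rather than hard-coded constants, so any variant of the design (more
families, deeper inbreeding, smaller panels) can be simulated. `four_way_plants = NULL` gives every eight-way seed its
own independently simulated four-way parents, which makes lines mutually
independent — the configuration used for calibration experiments (below).

### Founder allele panels

For every SNP the panel draws the number k of founders that carry the
reference allele (k = 1..7; the reference founder carries its own allele
by construction), with weights defaulting to the relative per-group SNP counts typical of
an elite eight-founder wheat panel (see `wm_afg_weights()`). The expected reference-allele
frequency in the population is k/8 — the allele-frequency-group (AFG) law
that `assign_afg()` exposes and the segregation module tests against.

By default carrier sets are drawn independently per SNP. Real elite
founders share local haplotypes, which is what produces high r-squared
between tightly linked SNPs; with independent carrier sets the r-squared
of even perfectly cosegregating SNPs averages only ~0.12. The optional
`founder_ld_scale` parameter makes each SNP copy its left neighbour's
carrier set with probability exp(-d/scale), creating founder haplotype
blocks; with `founder_ld_scale = 5` a simulated population shows a smooth
LD decay crossing r² = 0.2 at a few cM, qualitatively matching elite
wheat panels. The default remains independent assignment because every
frequency-law calibration is exact there; analyses that need realistic
local LD (the LD-decay example in the tests) opt in.

### The default plant-height architecture

`wm_trait_model()` fixes the study conditions used by the recovery
experiments: intercept 84 cm; the two semi-dwarfing loci at 4B 56.0 cM
(homozygous Julius contrast +12.8 cm; Julius carries the tall allele,
shared by six founders) and 4D 69.2 cM (-14.9 cm; Julius carries the
dwarfing allele, shared by four founders); nine small loci with contrasts
of 2.4-5.3 cm spread over nine chromosomes; and one
additive-by-additive pair on 2B x 7B with aa = +13.7 cm whose member
markers also carry small main effects (+3.0 / -3.6 cm) — in real
panels most epistatic markers coincide with main-effect QTL regions, and
a pure interaction with no marginal effect would be invisible to the 0.15
single-marker pre-screen. The pair's marker loci are pinned to balanced
founder carriage (4 of 8, split across both funnel sides) so the product
term is uncorrelated with either main effect; with unbalanced
frequencies the interaction term (aa/4)·x1·x2 leaks a marginal effect
(aa/2)·E[x_other] into each locus.

Phenotypes follow
`value = mu + sum(a_j x_j) + sum((aa/4) x1 x2) + year + GxY + residual`
with x = dosage - 1. The aa/4 coefficient is chosen so that the class-mean
contrast `(JJ + NN) - (JN + NJ)` equals aa exactly in the noiseless case.
Defaults (year variance 25, genotype-by-year 5, residual 16 cm², two
years, one replicate) give V_G ≈ 110 cm², line-mean SD ≈ 11 cm and
broad-sense heritability ≈ 0.9, realistic values for plant height in
European winter wheat.

## Quality control and dosage coding

`qc_filter()` removes SNPs with more than 10% missing calls, more than
10% heterozygous calls, or minor allele frequency below 1% (strict
inequalities). MAF is allele-based: heterozygotes contribute one allele of
each kind and missing calls are excluded from the denominator — with
mostly inbred lines the allele-based and genotype-based definitions
almost coincide, and the allele-based one matches the allele-frequency
framing used throughout the package. Filters are applied missing → het → MAF so
that each removed SNP has one unambiguous primary reason; the surviving
set does not depend on the order. `impute_mean()` performs mean
imputation and preserves per-SNP means exactly. `assign_unmapped()`
places unmapped SNPs at the position of the mapped SNP with the strongest
2x2 chi-square association over homozygous classes; the significance
floor defaults to a Bonferroni-corrected 0.05 across anchors, and queries
below the floor stay unassigned rather than being forced onto the map.

## Segregation distortion by allele-frequency group

`sd_test()` compares each SNP's observed reference-allele count against
the k/8 expectation of its AFG with a 1-df chi-square, and applies
Bonferroni-Holm genome-wide. Counting two alleles per line overstates the
information in an inbred population: the two alleles of an F4 line are
identical copies with probability F = 1 - 2^-3 = 7/8, so the plain
allele-count chi-square is overdispersed by a factor of about 1 + F =
1.875, and its raw p-values are far from uniform even under neutrality
(around 15% of SNPs fall below p = 0.05). The test therefore divides the
statistic by (1 + F-hat), with F-hat the pooled genome-wide inbreeding
coefficient estimated from the heterozygote deficit — Wright's
correction. With independent lines this restores the nominal type-I
error; `correct_inbreeding = FALSE` recovers the plain textbook
allele-count test. Note that the correction cannot repair
pseudo-replication from shared funnel ancestry: under the default
141-family design lines are positively correlated and the test remains
anticonservative — an unavoidable property of any per-SNP frequency test
applied to a family-structured population. The
calibration experiment in the test suite therefore uses unlinked loci
(one SNP per micro-chromosome) and independent funnels, which is the null
model the per-SNP test actually assumes.

`detect_sdr()` calls a segregation-distortion region when at least three
consecutive mapped SNPs are significant at adjusted p < 0.01; direction is
recorded per member but not required to be uniform. SNPs at identical
positions count as adjacent in input order. `founder_selection_events()`
looks only at unique SNPs (AFG 1 and 7), where the distorted allele can be
traced to one founder; for AFG 7 the unique founder carries the
*alternative* allele, so a reference-allele excess is a deficit of that
founder's allele and the direction is inverted. Groups need strictly more
than 10 SNPs to be reported.

A non-obvious property verified by brute force: removing double dwarfs
(lines homozygous for the dwarfing founder origin at both Rht loci)
depresses the dwarf-allele frequency at *both* loci, and the absolute
deficit 2k(1-p)/(2(n-k)) is larger at the locus where the dwarf allele is
rarer — every removed line contributes the same two dwarf alleles at each
locus, and the same absolute removal moves a rare allele's frequency
further. A much larger distortion at the common-allele locus than at the
rare-allele locus — the pattern reported for Rht-D1 versus Rht-B1 in real
wheat MAGIC panels — therefore cannot arise from double-dwarf removal
alone and indicates additional selection.

## Diversity and linkage disequilibrium

`genetic_similarity()` is the simple-matching proportion over shared
non-missing SNPs, with dosage states compared exactly.
`similarity_pca()` treats the similarity matrix as an observations x
variables table, column-centres it and uses singular value decomposition
without scaling (all columns are on the same similarity scale, so scaling
would only inflate noise). `ld_decay()` computes squared Pearson
correlations of dosages for intra-chromosomal pairs, fits a second-degree
LOESS (span 0.3 by default, configurable), and estimates
population-specific background LD as the 95th percentile of r-squared
among unlinked pairs, with "unlinked" operationalised as
inter-chromosomal. The
decay distance is the first downward crossing of the fitted curve with
the reference level (0.2), located by linear interpolation on a 512-point
grid.

## The cross-validated stepwise scan

`cv_gwas()` reimplements the "Model-A" multiple-regression scan: 20
repeats of five-fold cross-validation (100 model fits), forward/backward
stepwise selection with p ≤ 0.001 to enter and to stay, detection rate =
number of fits whose final model contains the SNP. No kinship or
structure covariate is included: the population is a funnel design whose
principal components carry no dominant axis. Marker-trait associations
need detection ≥ 35 of 100 and Bonferroni-Holm adjusted p < 0.01; the
adjustment family is all tested SNPs (genome-wide). The family matters:
with the family restricted to the handful of SNPs in the final model, the
chance-best SNP of a 1,000-marker null scan (raw p around 1e-3, detected
in well over 35 fits because training sets overlap 80%) passes the 0.01
threshold in a substantial fraction of replicates, while the genome-wide
family keeps the null scan clean in ≥ 95% of replicates — the behaviour
the calibration experiments require.

Reported per-SNP quantities are estimator decisions of this
implementation:

* **effect** — hard-class contrast, mean of lines with dosage ≥ 1.5 minus
  mean of lines with dosage ≤ 0.5 (homozygous reference vs alternative);
* **validation R²** — for each fit that selected the SNP, the reduction
  in held-out error sum of squares when the SNP is added to the rest of
  that fit's model, divided by the held-out total sum of squares, then
  averaged (a semi-partial R², which keeps the sum over QTL ≤ 100% for
  near-orthogonal predictors);
* **final p-values** — from one stepwise refit on all lines.

`call_qtl()` groups same-sign MTAs within 5 cM (single linkage) into QTL
represented by the member with the smallest adjusted p. Stepwise
tie-breaks are deterministic: candidates are ordered by chromosome,
position and SNP id, and the first minimum wins.

## The di-genic epistasis scan

The scan is a staged pipeline: single-marker pre-screen at
p < 0.15; all candidate pairs tested with `trait ~ x1 + x2 + x1:x2` on
centred dosages; Benjamini-Hochberg FDR across pairs at q ≤ 0.01
(Benjamini-Hochberg is the standard step-up FDR procedure); joint
forward/backward selection over the significant product terms with their
main effects always present; single-linkage grouping of pairs whose
orientation-matched endpoints lie within 7 cM.

The interaction *test* uses the product of centred dosages, which keeps
heterozygous and imputed lines in the model, while the *aa effect* uses
hard homozygous classification (J: dosage ≥ 1.5; N: ≤ 0.5; intermediates
excluded) — the test keeps all information while the effect is defined
only over clean homozygous classes. `aa = (JJ + NN) - (JN + NJ)`. When
exactly one mixed class is empty, twice the mean of the surviving mixed
class is substituted for the missing sum term and the record is flagged
(`na_rule_used`) so downstream users can treat such estimates with
caution; an empty homozygous class leaves aa undefined. `epistatic_variance()` is 100 x SS(interaction) /
SS(between the four homozygous classes), with main effects fitted first.

Two properties tie the simulator and estimator together: with phenotypes
built from the (aa/4)·x1·x2 term and no noise, `aa_effect()` returns the
injected aa exactly; and relabelling the reference allele at exactly one
locus flips the sign of aa while swapping the loci leaves it unchanged.

## Phenotype summaries

`line_means()` averages replicates within year and then years — with one
replicate per year and fixed genotype / random year effects this equals
the least-squares mean. `variance_components()` equates observed and
expected mean squares on the line x year layout. With one replicate per
year the genotype-by-year and residual components are statistically
confounded; the implementation estimates a pooled error V_E = V_GY + V_R
and refuses to fabricate the split. Heritability on an entry-mean basis is
`h² = V_G / (V_G + V_GY/y + V_R/(y r))`, reducing to `V_G / (V_G + V_E/y)`
in the pooled case. Negative method-of-moments solutions are truncated to
zero with a warning. `transgressive_count()` declares a line transgressive
when its mean lies beyond the extreme founder mean by more than a
two-sided least-significant difference built from the error variance and
the record counts; the LSD on the entry-mean error is the standard field
criterion for declaring a line significantly taller or shorter than a
founder.

## Problem sizes and calibration experiments

The test suite's heavier experiments use these sizes, chosen to estimate
each quantity with useful precision:

* funnel law checks: 520 lines, 1,600 SNPs (over 200 in AFG 1), with
  chromosome-level means as independent replicates for the Monte-Carlo
  standard error — AFG-1 SNPs all track the Julius origin, so linked SNPs
  are strongly correlated and a per-SNP standard error would be too
  optimistic;
* chi-square calibration: 500 independent-funnel lines at 2,000 unlinked
  loci (one per 0.01 cM micro-chromosome), Kolmogorov-Smirnov uniformity
  of the raw p-values;
* null GWAS: 100 pure-noise phenotypes on one fixed 400-line, 1,000-SNP
  population;
* end-to-end recovery: one 910-line, ~800-SNP population analysed
  through the full GWAS and epistasis pipeline, plus four further
  simulated populations over which the aa estimate is averaged — the
  single-population sampling SD of the raw class-mean aa estimator at
  V_G ≈ 110 cm² is ~1.3 cm, so the mean of five replicates is the
  appropriate parameter-recovery measurement;
* variance-component recovery: 30 replicates of 900 lines x 2 years.

## Known limitations

* The meiosis model has no crossover interference; segment-length
  distributions are exponential rather than gamma-like.
* Genotyping error is a symmetric "spurious heterozygote" model; allele
  dropout and cluster-calling artefacts of array data are not emulated.
* The bulk DNA of several F4:5 seedlings genotyped per line in the real
  protocol is approximated by the F4 parent's genotype with residual
  heterozygous calls allowed.
* Passing the simulation-based tests shows the estimators recover the
  generator's truth under the stated design; field data add
  spatial/temporal structure, genotype-calling artefacts and selection
  histories that the generator does not model.
* The chi-square distortion test treats lines as independent; under the
  realistic shared-funnel design it remains anticonservative even after
  the inbreeding correction, and distortion calls on such data should be
  read as descriptive rather than strictly calibrated.
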
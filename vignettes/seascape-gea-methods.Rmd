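---
title: "Detecting putatively adaptive loci along a seascape: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting putatively adaptive loci along a seascape: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`seagea` implements an individual-based genotype–environment association
(GEA) workflow for marine population genomics: starting from a diploid
biallelic SNP panel, sample coordinates, and a table of environmental
variables, it identifies loci whose allele dosages covary with
environmental gradients after controlling for neutral spatial structure,
and then characterises the population structure of the putatively adaptive
panel. This vignette explains the statistical machinery, the tunable
parameters, the synthetic data generator used for verification, and the
design decisions that were genuinely open.

## The model

Let $Y$ be the $n \times L$ matrix of minor-allele dosages (mean-imputed,
column-centred), $X$ the $n \times q$ matrix of retained environmental
predictors, and $Z$ the $n \times r$ matrix of selected spatial
eigenvectors. The core analysis is a partial redundancy analysis (pRDA):

1. residualize $Y$ and $X$ on $[1, Z]$ by least squares;
2. regress the residual response on the residual predictors and
   eigendecompose the fitted values: the singular value decomposition of
   $Q_X^\top Y_\mathrm{res}$ gives constrained axes with eigenvalues
   $\lambda_a = d_a^2/(n-1)$;
3. partition total genotype variance into conditioned (space), constrained
   (environment net of space), and residual fractions from the projection
   trace identities; the three fractions sum to one by construction.

Locus loadings are reported in a species-score scaling (unit eigenvector
times $\sqrt{\lambda_a}$). Candidate detection standardizes the loadings
per axis, so the scaling choice affects reported magnitudes only, never
which loci are flagged.

Significance uses a permutation ANOVA with pseudo-$F$
statistics: residuals of the reduced model are permuted while the
conditioning variables are held fixed, and
$p = (\#\{F^\ast \ge F\} + 1)/(n_\mathrm{perm} + 1)$. Three scopes are
available: the overall constrained fraction, marginal per-variable tests
(each variable tested conditional on the others plus $Z$), and sequential
per-axis tests (each axis tested with the preceding axes added to the
conditioners, using the leading eigenvalue as the statistic). Loci whose
loading lies at least `sd_mult = 3` standard deviations from the mean
loading on a significant axis are candidates; a locus extreme on several
axes is reported once, on the axis of its largest $|z|$. Each candidate is
then assigned the retained environmental variable with the largest
absolute Spearman rank correlation against its *observed* (non-imputed)
dosages — imputation would bias rank correlations toward the site mean, so
it is used for the ordination only.

## Spatial covariates

Spatial structure is summarised by distance-based Moran's eigenvector maps
(dbMEM) built from least-cost oceanic distances: sampling points are
snapped to a rasterized water mask, and shortest over-water paths are
computed on the 8-connected water-cell graph with great-circle edge
lengths. The classical dbMEM construction truncates the distance matrix at
$t$ (by default the longest minimum-spanning-tree edge, which guarantees
a connected neighbour graph), replaces beyond-threshold entries with $4t$,
double-centres $-\tfrac12 d^2$, and eigendecomposes. Positive-eigenvalue
eigenvectors (positive spatial autocorrelation, broad- to fine-scale in
eigenvalue order) are the candidate spatial covariates.

Distances and MEMs are computed **between individual sampling
coordinates** by default. A site-centroid mode exists, but with few sites
it is degenerate for this analysis: the centroid-level MEM basis spans the
entire between-site space, so once forward selection has retained the
(genuinely significant) spatial patterns, conditioning removes *all*
site-level variation — including every environmental cline — and the GEA
can no longer detect anything. Individual-level MEMs, which mix
between-site and within-site coordinate variation, shrink site-level
patterns rather than annihilating them, preserving the
adaptive-versus-neutral contrast that the method relies on.

## Variable selection

Environmental variables are z-score standardized, then reduced in two
deterministic stages: while any pair correlates beyond `r_max = 0.7`, the
member of the worst pair with the larger mean absolute correlation to the
remaining variables is dropped (ties: the later column); then variables
with variance inflation factor at or above `vif_max = 3` are dropped
largest-first, with the VIF computed from the regression definition
$1/(1-R_j^2)$. The drop rule inside a correlated pair is not dictated by
the problem; retaining the member less redundant with everything else
keeps the most information and is deterministic.

Both MEMs and environmental variables are then forward-selected against
the genotype response with a *double stopping rule*: a global permutation
pre-test of the all-candidate model must pass first; afterwards the best
remaining candidate is added only while its permutation p-value (residuals
of the current reduced model permuted, Freedman–Lane style) is at most
`alpha` and the cumulative adjusted $R^2$ stays below the global model's
adjusted $R^2$. The step-wise null is, by default, the chosen candidate's
own permutation distribution: paired with the global pre-test this holds
the probability of selecting anything under a null response at the nominal
`alpha` (verified by Monte-Carlo calibration in the test suite). An
optional `"max"` null — the distribution of the largest gain over all
remaining candidates — corrects the per-step selection bias exactly but
makes the overall procedure conservative, because it stacks a second
full-level gate on top of the global one.

One design choice departs from running the two selections independently:
in the pipeline, MEM selection is conditioned on the full standardized
candidate environmental table. With a spatially smooth environment, the
environmental clines *are* among the highest-variance spatial patterns in
the genotypes, so unconditioned MEM selection preferentially retains
exactly those patterns and the subsequent pRDA conditions away the signal
it is meant to find. Conditioning the spatial selection on the measured
gradients makes the spatial control represent spatial structure *not*
attributable to the environment — the component that a partial analysis
should remove. On the default synthetic fixture this is the difference
between recovering essentially all planted loci and recovering half or
fewer. Both behaviours are available through the `Z` argument of
`forward_select_mems()`.

## Quality control

Dosages count the globally minor allele (loci are flipped, with their
ref/alt book-keeping, whenever the alternate allele frequency exceeds
0.5). Locus filters keep loci with missingness at most `max_locus_missing`
and minor allele count at least `min_mac = 3`, recomputed after any
individual removal. Relatedness uses the standardized allele-sharing
moment estimator (the genomic-relationship-matrix form): per locus
$w = (x - 2\hat p)/\sqrt{2\hat p(1-\hat p)}$ and the pairwise mean of
$w_i w_j$ over pairwise-complete loci, clipped to $[-1, 1]$, with pairs
below a 50-locus overlap floor reported as missing. Its expectations —
about 1 for duplicates, 0.5 for parent–offspring, 0 for unrelated pairs —
are exactly what a thresholded duplicate/close-kin screen at
$|R| > 0.5$ needs; with small samples the estimator is biased downward by
roughly $1/n$ (frequencies are estimated from the sample itself), which is
immaterial at that threshold. Pruning is greedy: repeatedly remove the
individual involved in the most over-threshold pairs (ties: more missing
data, then the lexicographically smaller id), so exactly one member of an
isolated pair is removed and no over-threshold pair survives.

## Population structure of the candidate panel

Per-site diversity uses the unbiased expected heterozygosity
$2\hat p(1-\hat p)\cdot 2n/(2n-1)$ (the form chosen here; the source of
the convention is a genuinely open question in published tables) and the
observed heterozygote fraction, averaged over loci with at least two
genotyped individuals at the site. Differentiation is the Weir–Cockerham
variance-component estimator $\hat\theta$, combined across loci as a
ratio of summed components (not a mean of ratios); pairwise significance
comes from permuting individuals between the two sites (10,000
permutations by default) with Benjamini–Yekutieli correction across pairs
at FDR 10%. PCA is the eigendecomposition of the centred, imputed dosage
matrix.

Model-based clustering is a maximum-likelihood finite mixture: cluster-
specific allele frequencies, binomial genotype likelihoods under
within-cluster Hardy–Weinberg proportions, EM to a log-likelihood
tolerance of $10^{-6}$ (at most 500 iterations), best of 10 random
restarts. This reproduces the K-selection and soft-assignment surface of
ancestry programs without per-allele ancestry fractions: admixture
proportions arise as posterior memberships, which is a behavioural
difference on genuinely admixed individuals. AIC counts $K \times L$
allele-frequency parameters (membership weights excluded), matching the
convention of snap-assignment clustering; cross-validation masks 10% of
the observed genotype entries per replicate and scores the mean squared
error of predicting the masked dosages from memberships times cluster
frequencies. On clinal data (as the default fixture produces) AIC
legitimately supports large K — a smooth gradient is not a small set of
discrete panmictic clusters; the planted-K recovery checks therefore use
island-model simulations where the truth is discrete.

## Functional context and enrichment

SNP context is classified from GFF3 gene models with precedence exonic >
intronic > promoter > intergenic; the promoter window is 2000 bp upstream
of the transcription start, strand-aware, and configurable (the window
length is not standardized across annotation tools). Enrichment compares
candidate loci against the full filtered panel per GO term with a
two-sided Fisher's exact test and Benjamini–Hochberg correction at FDR 5%
(the harsher B-Y form is reserved for the correlated F_ST tests). The
background is locus-level, not gene-level: the candidate set is drawn from
loci, so the natural exchangeable unit under the null is the locus.

## The synthetic seascape generator

All verification runs on simulated seascapes with a planted truth set.
The generator emulates a ddRAD-style coastal study: 9 sites along a 1-D
coast, about 22 individuals per site (200 total), 2000 neutral and 50
adaptive biallelic SNPs, 1% uniform missingness, and a pair of planted
duplicate individuals for the relatedness screen. Its components:

- **Environment.** Each variable is a deterministic smooth function of
  along-coast position (sigmoid, sine, or localized bump by default —
  a regional temperature transition, alternating embayment salinity, and
  an upwelling-like productivity peak) plus Gaussian site noise
  (sd 0.15 on the standardized scale). A target correlation matrix, when
  given, is imposed exactly on the noise-free values via an orthogonalized
  smooth basis.
- **Neutral loci.** Site allele frequencies follow a 1-D stepping-stone
  diffusion: beta-perturbed along the site chain, with the concentration
  calibrated by root finding so the realized multilocus Weir–Cockerham
  F_ST matches the target (0.02 by default, inside the weak-differentiation
  range reported for wide-ranging marine vertebrates).
- **Adaptive loci.** Site frequency $p_s = \mathrm{logit}^{-1}(a + b z_s)$
  with $z_s$ the standardized driving variable (assigned round-robin) and
  $b = 2$ log-odds per SD by default; genotypes are Binomial(2, $p_s$).
- **Coordinates.** Individuals scatter seaward around their site centroid
  (sd 0.1 degrees, about 10 km, against roughly 40 km site spacing) —
  the at-sea sampling scatter that makes individual-level MEMs
  meaningful.

What the generator does **not** emulate: linkage disequilibrium between
loci (all loci are independent), haplotype structure, genotyping error
beyond missingness, non-equilibrium demography, and environment-dependent
sampling effort. Passing the recovery checks therefore demonstrates that
the statistical machinery detects single-locus logistic clines against
isolation-by-distance noise at the stated effect size — not that it would
detect weak polygenic selection or survive strong LD in real data.

## Numerical choices and degenerate inputs

- Permutation p-values are always $(b+1)/(n_\mathrm{perm}+1)$, so the
  smallest attainable p with 100 permutations is about 0.0099.
- Mean imputation preserves locus means exactly; an all-missing locus is
  an error.
- Predictors absorbed by the conditioners (e.g. $Z = X$) are treated as
  aliased and dropped, leaving a model with zero constrained axes rather
  than an error; genuinely collinear predictor columns are an error naming
  the offending columns.
- A constrained axis with zero loading SD yields no candidates, with a
  warning; a constant candidate dosage vector gets no best predictor.
- Eigenvector signs are fixed (largest-magnitude element positive) so
  outputs are reproducible across BLAS implementations.
- Every stage derives its own RNG stream from the global seed and the
  stage name, so a stage re-run in isolation reproduces its in-pipeline
  behaviour and the full pipeline is byte-identical under a fixed seed.

## Verification problem sizes

The test suite exercises the ordination against brute-force oracles on
dozens of random small instances (up to 20 individuals, 30 loci), checks
permutation calibration over 200 simulated null datasets of 60
individuals by 200 loci, scores candidate recovery over ten seeds of the
default 200 x 2050 fixture, and verifies cluster-number recovery over ten
seeds of three-population island models (150 loci, 20 individuals per
population). These sizes were chosen to make every distributional claim
testable at desk scale while keeping the complete suite fast enough to
run routinely.

## Known limitations

- The EM mixture is not the block-relaxation admixture likelihood; on
  strongly admixed individuals the soft memberships and the per-allele
  ancestry fractions differ.
- The relatedness estimator is a screen, not a pedigree estimator; its
  small-sample bias makes it unsuitable for estimating relatedness
  coefficients close to the threshold in panels of a few dozen
  individuals.
- Least-cost distances use the 8-connected octile approximation; paths at
  unfavourable bearings overshoot great-circle lengths by up to ~8%, and
  refinement reduces snapping error but not the angular overhead.
- The sequential axis test conditions on fitted prior axes, which is one
  of several defensible schemes; published implementations differ in
  detail.
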
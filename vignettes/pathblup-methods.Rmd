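---
title: "Genomic mixed models and LD-preserving pathway association: methods and design"
author: "pathBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic mixed models and LD-preserving pathway association: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathBLUP)
```

# Scope

pathBLUP analyses replicated phenotypes measured on a panel of inbred,
fully genotyped lines. Its five stages are: (1) a genomic mixed model
(GBLUP) fitted by REML for SNP heritability and line-level genomic
values; (2) back-solving of genome-ordered per-marker effects; (3) a
GO SNP-set association test whose null is built by circular shifts of
the effect vector; (4) a cross-trait overlap test on sub-threshold
sets; and (5) partitioning of within-set genetic variance to genes. A
synthetic-data generator supplies ground truth for all of them. This
vignette records the model assumptions, the tunable parameters, the
numerical choices, and the design decisions made where the design was
genuinely open. It states no empirical claim that the package's test
suite and acceptance script do not themselves recompute.

# The genomic mixed model

Observations follow

$$\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{Z}\mathbf{g} +
\boldsymbol\varepsilon, \qquad
\mathbf{g} \sim N(\mathbf{0}, \mathbf{G}\sigma_g^2), \qquad
\boldsymbol\varepsilon \sim N(\mathbf{0}, \mathbf{I}\sigma_\varepsilon^2),$$

with fixed effects (intercept, *Wolbachia* status, five inversion
factors, experimental block — all configurable; binary covariates may
be coded 0/1 or as two-level factors, which is equivalent) and the
genomic relationship matrix $\mathbf{G} = \mathbf{W}\mathbf{W}'/m$.
Each column of $\mathbf{W}$ is the centred, scaled minor-allele count:
$w_i = (a_i - 2p_i)/\sqrt{2p_i(1-p_i)}$, with $p_i$ the *sample* minor
allele frequency. Frequencies are recomputed on the analysed line
subset, so markers monomorphic in the subset must be removed first
(`filterMarkers()`, which also drops MAF $\le$ 0.05 by default). SNP
heritability is $h^2_{SNP} = \sigma_g^2/(\sigma_g^2 +
\sigma_\varepsilon^2)$.

## Scaling on fully inbred genotypes

The $\sqrt{2p(1-p)}$ denominator equals the genotype standard deviation
only under Hardy–Weinberg heterozygosity. On fully inbred lines the
allele counts are essentially {0, 2}, their variance is $4p(1-p)$, and
each column of $\mathbf{W}$ has sample variance near 2 — so
$\mathrm{diag}(\mathbf{G}) \approx 2$ rather than 1. Consequences:

* `scaleGenotypes()` applies the formula above verbatim by default
  (fidelity to the standard GBLUP presentation);
* `scaleGenotypes(..., empirical = TRUE)` divides each centred column
  by its sample standard deviation instead, giving
  $\mathrm{diag}(\mathbf{G}) \approx 1$;
* under the default scaling on inbred data, $\sigma_g^2$ is roughly
  half the per-line genetic variance, so $h^2_{SNP}$ as defined above
  is attenuated relative to the realized variance-ratio heritability.
  The package's heritability-recovery validation therefore runs under
  the empirical scaling, where the estimator tracks the realized value
  closely; the attenuation under the textbook scaling is a property of
  the scaling convention, not of the REML machinery.

## REML

The restricted likelihood is profiled on $\lambda = \sigma_g^2 /
\sigma_\varepsilon^2$ in the eigenbasis of $\mathbf{H} =
\mathbf{Z}\mathbf{G}\mathbf{Z}'$ (one symmetric eigendecomposition per
fit). For fixed $\lambda$, GLS of the rotated response on the rotated
design with weights $1/(\lambda d_i + 1)$ yields the profiled
$\hat\sigma_\varepsilon^2$ in closed form. The profile is scanned on a
121-point grid of $\log\lambda \in [-18, 18]$ and polished with Brent's
method (tolerance 1e-10); $\lambda = 0$ is evaluated explicitly, so
nonnegativity holds by construction and boundary solutions
($\hat\sigma_g^2 = 0$, or $\lambda$ at the upper scan edge) are
reported via the `boundary` slot rather than clipped. Additive
constants in $2\pi$ are dropped from the reported log-likelihood.

Degeneracies are handled explicitly: when $\mathbf{H}$ is numerically
proportional to the identity (for instance $\mathbf{G} = \mathbf{I}$
with one observation per line) only $\sigma_g^2 + \sigma_\varepsilon^2$
is identifiable; the fit warns, sets `identifiable = FALSE`, and
reports the $\sigma_g^2 = 0$ boundary solution. Rank-deficient designs
(confounded inversion levels are common with 20–30 lines) are pruned to
a full-rank column set by pivoted QR, with the dropped columns
recorded. $\mathbf{G}$ is never jittered; downstream back-solving uses
a pseudoinverse, so singular $\mathbf{G}$ is acceptable.

Line BLUPs are $\hat{\mathbf{g}} = \hat\sigma_g^2 \mathbf{G}\mathbf{Z}'
\hat{\mathbf{V}}^{-1}(\mathbf{y} - \mathbf{X}\hat{\mathbf{b}})$. The
optimizer is validated against a brute-force two-stage
$100 \times 100$ grid over $(\sigma_g^2, \sigma_\varepsilon^2)$ (coarse
sweep to $3\,\mathrm{var}(y)$, then an equally sized refinement around
the coarse argmax) computed from the dense REML definition on fixtures
of at most 60 observations.

## Bootstrap CI and genomic correlations

The 95% CI for $h^2_{SNP}$ resamples *observations* with replacement
(10,000 replicates by default; the same number of observations as the
data), refits per replicate — rebuilding $\mathbf{Z}$, dropping lines
absent from a replicate — and takes nearest-rank 2.5%/97.5% quantiles.
A `lineMeans = TRUE` mode resamples line means instead, for comparison.
Replicates whose fit fails are skipped and counted (warning above 10%).
Cross-trait genomic correlations are Spearman rank correlations of the
line BLUPs on shared lines, with the two-sided t-approximation p-value
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df.

# Marker effects and the rotation test

Marker effects are the minimum-norm back-solution
$\hat{\mathbf{s}} = \mathbf{W}'(\mathbf{W}\mathbf{W}')^{-1}
\hat{\mathbf{g}}$, computed via the eigendecomposition of
$\mathbf{W}\mathbf{W}' (= m\mathbf{G})$ with the standard spectral
cutoff (machine epsilon × max dimension × largest eigenvalue). Because
$\hat{\mathbf{g}}$ from a $\mathbf{W}\mathbf{W}'$-based fit lies in the
row space of $\mathbf{W}$, the reconstruction
$\mathbf{W}\hat{\mathbf{s}}$ matches $\hat{\mathbf{g}}$ to numerical
precision; the relative residual is returned so callers can verify.

Markers are kept in genome order with chromosome arms concatenated in
the fixed order 2L, 2R, 3L, 3R, X, 4 (configurable; any fixed order is
valid as long as it is used consistently). SNPs map to a gene when
their position lies within gene start − 5,000 bp and gene end +
5,000 bp, *boundaries inclusive* — the window is a parameter and the
inclusive convention is asserted in tests. BED (0-based half-open) and
GFF3/VCF (1-based) inputs are normalised to 1-based inclusive
coordinates internally. A marker near two genes maps to both; within a
SNP-set the marker union is deduplicated so no marker is double-counted
in the set statistic. Sets are retained when they hold more than 10
member genes and at least 200 distinct markers (both thresholds are
arguments of `buildSnpSets()`).

The set statistic is the signed sum $T_{sum} = \sum_i \hat{s}_i$ over
member markers. The null distribution rotates the entire effect vector:
a random start $j$ is drawn uniformly on $\{1, \dots, m\}$ (with
replacement across rotations; $j = 1$, the identity, is allowed) and
the vector becomes $(\hat{s}_j, \dots, \hat{s}_m, \hat{s}_1, \dots,
\hat{s}_{j-1})$ while all set-to-index mappings stay fixed. Rotation
preserves the multiset of effects and every adjacency except the single
seam, so the local LD-induced correlation of neighbouring effects
survives under the null. All sets are evaluated against the *same*
rotations, which keeps per-rotation statistics jointly comparable — a
requirement for using the per-trait results in the overlap test.

Two p-value modes are provided. `"proportion"` is the plain one-tailed
proportion $\#\{T_{perm} > T_{obs}\}/B$, which can return 0;
the default `"plus_one"` uses $(\#\{T_{perm} \ge T_{obs}\} + 1)/(B +
1)$, a valid p-value under exchangeability that is bounded away from
zero. Sets are called significant at the strict threshold $p < 0.005$
(`significantSets()`), chosen so that with hundreds of sets per class
only a handful of false positives is expected (`expectedCounts()`).

Two caveats are inherent to the signed statistic. Effects of opposite
sign cancel, so a set whose members carry symmetric positive and
negative effects can be powerful biologically yet invisible to
$T_{sum}$; a two-sided $|T|$ option exists (`twoSided = TRUE`) but is
off by default to keep the printed one-tailed behaviour. And because
the test is one-tailed upper, enrichment of strongly *negative* effects
drives p toward 1.

# Overlap across traits

For each GO class, an incidence matrix has one row per SNP-set and one
column per trait, with a 1 where that trait's empirical p is strictly
below 0.05. The observed pairwise overlap (rows flagged in both
columns) is compared with overlaps after independently permuting each
column 10,000 times — margins are preserved by construction, so the
null overlap for a pair with $k_1$, $k_2$ flags among $n$ sets is
exactly Hypergeometric$(n, k_1, k_2)$; the permutation p (fraction of
permutations with overlap $\ge$ observed) is validated against that
closed form. Overlap is reported pairwise; an all-column intersection
is not part of the default output. The analytic expectations are
$n\alpha$ significant sets per trait and $n\alpha^2$ shared sets per
pair, reported unrounded and rounded to the nearest integer (half away
from zero). No multiplicity correction is applied across trait pairs.

# Variance partitioning within a set

For member gene $x$ with $m_x$ set markers, the per-line gene effect is
$\hat{f}_x = \mathbf{W}_x \hat{\mathbf{s}}_x$; when the genes partition
the set's markers these vectors sum exactly to the set-level effect
vector (asserted to 1e-10 in tests). $\mathrm{Var}F_x$ is the sample
variance of $\hat{f}_x$ across lines ($n-1$ denominator — any
consistent choice cancels in the shares) divided by $m_x$, and shares
are $\mathrm{Var}F$ normalised to sum to 1 within the set. The
variance is taken across *lines* of the per-line gene effect, the
literal reading of the defining formula. Genes with share strictly
greater than 20% are flagged. Shares are invariant to rescaling all
marker effects (both numerator and denominator scale by $c^2$).
Markers shared by two member genes contribute to both genes' vectors,
consistent with the multi-assignment mapping; the additivity identity
is only asserted on partitions.

# Phenotype preprocessing

Proportion traits (egg-to-adult viability) use the angular transform
$\arcsin\sqrt{p}$, monotone from [0, 1] to [0, $\pi/2$]. The literal
squared-arcsine $\arcsin(p)^2$ is available behind
`variant = "squared"` for sensitivity analysis, as the two readings of
"arcsine-squared" differ; the angular transform is the default because
it is the standard variance-stabiliser for proportions. Assay-plate
correction (`plateEqualize()`) shifts each plate additively to the
grand mean — means are equalised exactly while within-plate deviations
and the overall mean are preserved; no rescaling is applied.

# The synthetic panel

The generator emulates the structure of a small inbred reference panel:

* **Lines and genotypes.** Default 25 lines (the 20–30 range typical of
  single-trait subsets), fully inbred so counts are {0, 2}; an
  `inbreeding` parameter converts a fraction of calls to heterozygous.
* **LD.** Markers come in blocks (default 10 markers at 100 bp
  spacing). Each block has two ancestral haplotypes; a line copies one
  per block and each call deviates with probability `mutProb` (default
  0.02). Within-block genotype correlation is high, between-block
  correlation is asymptotically zero, which is exactly the structure
  the rotation null is designed to respect. Block allele frequencies
  are drawn so every marker's sample MAF lies inside `mafRange`
  (default (0.05, 0.5]); markers pushed outside by mutation have their
  mutations reverted.
* **Annotation.** Genes are laid round-robin across the arms as
  disjoint intervals; GO sets draw member genes uniformly with sizes
  uniform on `goSizeRange`, in classes BP/MF/CC.
* **Traits.** True effects are iid N(0, 1) on the markers of the
  configured causal sets (or a random 10% of markers when no causal
  set is named), $g = \mathbf{W}\mathbf{s}$ with the same scaling used
  downstream, and the residual SD is set from the *realized* genetic
  variance so that the realized $\mathrm{Var}(Zg)/(\mathrm{Var}(Zg) +
  \mathrm{Var}(\varepsilon))$ matches `h2Target` up to residual
  sampling noise; the realized value is what `GroundTruth` records and
  what validation compares against. Covariates: Wolbachia ~
  Bernoulli(0.5) per line, five two-level inversion factors per line,
  block assigned round-robin over replicates; fixed-effect sizes
  default to 0.5 (Wolbachia) and 0.25 (inversions, block) on the
  phenotype scale — small relative to the genetic SD in the default
  configurations, as inversion and infection effects typically are.
* **Determinism.** Each generator seeds the RNG from `seed` (plus a
  fixed offset per stage), so identical configurations reproduce
  byte-identical outputs.

What the generator does *not* emulate: coalescent-accurate LD decay,
realistic recombination maps, missing or erroneous genotype calls,
overlapping gene models, or the measurement process of the assays.
Passing the validation suites therefore demonstrates correctness of the
statistical machinery under a controlled architecture, not robustness
to every feature of real panel data.

# Validation problem sizes

The acceptance suite (and `scripts/acceptance.R`) uses these sizes,
chosen to make Monte-Carlo error small relative to each check's
tolerance while keeping a full run in minutes on one core:

* REML vs grid: 5 fixtures of 24–60 observations, two-stage
  100×100 grids; agreement asserted on the log-likelihood (optimizer
  never below the grid) and on $h^2$ (within 1e-3 of the grid argmax).
* Heritability recovery: $h^2 \in \{0.2, 0.5, 0.8\}$, 30 lines × 5
  replicates, 3,000 markers, 50 seeds per level; absolute bias of the
  mean below 0.05 (measured ≲ 0.01).
* Back-solve: 100 random full-row-rank systems; worst relative
  reconstruction residual below 1e-8 (measured ~1e-14).
* Rotation calibration: 10,000 null effects, 500 random sets of 50–500
  markers, 1,000 rotations; the fraction of sets with $p < 0.05$ must
  sit inside the binomial 99% interval around 0.05 and the KS distance
  from uniform below 0.05. Sets share rotations, so their p-values are
  dependent; the KS bound is the acknowledged tightest of the checks.
* Power: a set of 100 markers spiked by +2 SD must rank below the 5th
  percentile of 199 null sets in at least 45 of 50 seeds.
* Overlap: 20 margin configurations, 10,000 permutations each,
  compared at an observed overlap whose exact tail probability is
  ~1–10% (where Monte-Carlo error is a few thousandths); worst
  absolute error below 0.01.

# Known limitations

* Single-trait REML only; genomic correlations are computed from
  per-trait BLUPs, not a bivariate model.
* The signed $T_{sum}$ cancels opposing effects (discussed above).
* Observation-level bootstrap treats observations as exchangeable;
  with strong line structure the line-mean mode may be preferable.
* The overlap test assumes the same catalog across traits and
  independence across sets within a trait; correlated sets (shared
  genes) make the hypergeometric null approximate for real catalogs,
  though the permutation preserves exactly the margins it conditions
  on.
* No indel/SV handling, no liftover, no live annotation-database
  queries: gene and GO tables are user-supplied files.
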
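---
title: "Variance decomposition and multiblock kernel OPLS for designed lipidomics experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance decomposition and multiblock kernel OPLS for designed lipidomics experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidAMOPLS)
```

This vignette is the package's account of its statistical machinery: the
model and its assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical and design decisions that were genuinely open.

## The data and its pre-treatment

The starting object is a `LipidFeatureSet`: an intensity matrix over
injections (biological samples, pooled QCs, blanks) and lipid features,
with the two design factors — cell origin (four levels) and treatment
status (naïve / resistant) — attached to the biological injections.
Intensities are arbitrary MS peak areas, non-negative, with `NA` marking
non-detection; MS-DIAL-style exports that write 0 for non-detected peaks
are handled by the `zeroIsMissing` flag (default `TRUE`).

Four quality rules are evaluated on the **raw** table, because the QC
intensity and repeatability thresholds are meaningful only before any
rescaling:

| rule | parameter | default | meaning |
|---|---|---|---|
| missingness vs blank | `missingFrac`, `blankMult` | 0.75, 5 | a biological cell counts as missing when absent or ≤ 5 × the feature's mean blank signal; drop when > 75% missing |
| QC intensity | `qcMinMean` | 1e5 | mean pooled-QC intensity below quantifiable range |
| QC repeatability | `qcMaxCv` | 0.40 | sd/mean over QC injections (n − 1 denominator) |
| zero spread | — | IQR = 0 | interquartile range over biological samples (linear-interpolation quartiles) |

Three choices here were open and are fixed as follows. Missingness is
computed across *biological* samples only: QCs are pooled copies of the
samples and blanks carry no biology, so including them would dilute the
rate with rows that cannot legitimately "miss" a biological feature.
Features with no blank signal fall back to absolute missingness. Removal
is by the union of the four rule sets, but the report also attributes each
removed feature to its *first* failing rule in the order above, which
makes filter reports additive and comparable across runs.

Probabilistic quotient normalization then corrects per-sample dilution:
the reference spectrum is the per-feature median over QC injections, each
row's dilution factor is the median quotient of its present intensities to
the reference (features with missing or non-positive reference excluded;
at least 10 evaluable quotients are required per row), and the row is
divided by its factor. QC and blank rows are corrected the same way for
uniformity — a blank row's factor is meaningless but blanks play no role
downstream of filtering. PQN is idempotent and equivariant under global
rescaling, which the test suite asserts as properties.

Residual missing cells are imputed as half the feature's minimum observed
biological intensity — the conventional stand-in for "below detection".
This estimator is deliberately crude and biased low: an imputed cell sits
several standard deviations below its feature mean, so datasets with
non-trivial missingness will show an inflated residual share in the
variance decomposition (see *Limitations*). Finally each feature is
centred and scaled to unit variance (n − 1 denominator); the scaling
parameters are kept so loadings can be back-transformed.

## Two-way variance decomposition

For the scaled biological matrix $X$ ($n \times p$) with factors A
(origin) and B (status), `decomposeEffects()` forms

$$X = \mathbf{1}m' + X_A + X_B + X_{AB} + E,$$

with level-mean deviations in $X_A$, $X_B$, the cell-mean double-centred
term in $X_{AB}$, and within-cell residuals $E$. Both factors are treated
as fixed; there are no covariates or random effects. In a balanced design
the four matrices are pairwise orthogonal, reconstruction is exact, and
the sum-of-squares shares
$\lVert X_e\rVert_F^2 / \lVert X - \mathbf{1}m'\rVert_F^2$ sum to exactly
1 — this is why the shares are reported against the grand-mean-centred
total. Unbalanced designs error by default; an opt-in `weighted` mode uses
per-cell means with unweighted level averaging (Type-III-like), an
extension for which orthogonality and the unit sum are no longer
guaranteed. The shares are computed on the scaled matrix, consistent with
the model being fitted after unit-variance scaling; the caller can
decompose any matrix it prefers.

## The multiblock kernel-OPLS model

Each block $b \in \{A, B, AB, E\}$ contributes a sample-space Gram kernel
$K_b = X_b X_b'$, normalized to unit Frobenius norm so no block dominates
by scale; the consensus kernel is their unweighted mean. Keeping the
residual as a block of its own lets the orthogonal component be read
against it. An all-zero block (e.g. the residual of a saturated design)
keeps a zero kernel and a warning; its contribution to every component is
then zero.

The response $Y$ codes the design as column-centred indicator blocks
(4 origin + 2 status + 8 cell columns; rank 7). With $P_Y$ the orthogonal
projector onto $\mathrm{col}(Y)$:

* predictive components are the leading eigenpairs of $P_Y K P_Y$
  (default: all 7);
* each orthogonal component is the leading eigenpair of
  $(I - P_Y)\,K\,(I - P_Y)$, and is deflated from the kernel before the
  predictive components are re-estimated;
* block contributions are
  $\lambda_{b,c} = t_c' K_b t_c \,/\, \sum_b t_c' K_b t_c$ (rows sum
  to 1), and each predictive component is attributed to the block with the
  largest $\lambda$;
* per-component explained variance projects the centred data matrix on the
  score ($\lVert t_c p_c'\rVert_F^2 / \lVert X_c\rVert_F^2$ with
  $p_c = X' t_c / t_c' t_c$); because all scores are mutually orthogonal
  these shares are non-negative and sum to at most 1;
* $R^2Y$ is the fraction of response sum of squares explained by the
  predictive scores.

Numerical choices: eigenpairs are extracted by Ritz-accelerated subspace
iteration with a deterministic start (the leading columns of the matrix),
a guard block of 8 extra vectors to resolve eigenvalue clusters, a
relative residual tolerance of 1e-10 and a hard cap of 10^4 iterations
(exceeding it is an error, not a silent fallback); the small Rayleigh
matrices are diagonalised by a self-contained cyclic Jacobi routine, so
the estimator never routes through the LAPACK eigensolver that serves as
its independent oracle in the tests. Component signs follow the
convention that the largest-magnitude loading entry is positive, ties
broken by the lowest feature index. Attribution of components to effects
is by largest $\lambda$ and is *reported*, never forced: on data where an
effect is weak its components may legitimately be claimed by another
block.

The model is descriptive, not predictive: there is no classification of
new samples and only linear kernels are used, because the aim is to
explain the variation attached to each design effect.

## Permutation inference

The significance statistic for an effect is the $\lambda$-weighted
explained variance summed over the predictive components attributed to it
— the two quantities through which the model is interpreted. The null
re-runs the *entire* decomposition + fit with permuted labels: a main
effect permutes its own factor within strata of the other factor
(restricted permutation, preserving the untested structure); the
interaction permutes the joint cell assignment, which preserves the
margins exactly but is only an approximate interaction null — an exact
one does not exist for this design. P-values use the add-one estimator
$(1 + \#\{null \ge obs\})/(1 + n_{perm})$, so the smallest reportable
value is $1/(n_{perm}+1)$ — with 10^3 permutations the floor is ~0.001,
and the package reports that floor rather than any smaller nominal level.
Per-effect random streams are derived deterministically from the
top-level seed and the effect name, so adding one tested effect never
perturbs another's null.

The number of orthogonal components is selected by the same logic:
component $k$ is retained iff its captured data variance exceeds the 95th
percentile of that quantity under full permutation of the sample labels,
stopping at the first failure. The test suite verifies both directions:
a planted design-orthogonal source is found (returns 1) and pure noise is
rejected (returns 0), and the per-effect p-values are uniform under a
zero-effect generator.

## What the generator emulates — and what it does not

`simulateLipidData()` produces the study regime the package targets: a
balanced 4 × 2 design with 6 replicates per cell (48 biological samples),
5 pooled-QC and 3 blank injections, and 750 lipid features drawn from a
class palette spanning the common glycerophospholipid, sphingolipid and
neutral-lipid classes with carbons in [30, 60] and double bonds in
[0, 8]. Replicate count and palette proportions are generator choices —
realistic for cultured-cell lipidomics, not claims about any particular
study. Effects are generated on the log-intensity scale and
exponentiated, matching the multiplicative nature of MS intensities: for
every feature the centred sum of squares is split *exactly* into the
requested origin / resistance / interaction / residual fractions (default
58.4 / 7.8 / 18.1 / 15.7%), with residual noise kept i.i.d. across all
design strata but scaled through its within-cell part, so the requested
fractions are exact on the log scale and recovery through
exponentiation + PQN + unit-variance scaling is well-posed. The
per-feature design-plus-noise log-sd defaults to 0.25 (~25% biological
CV), baselines are log-normal around 1e6, dilution factors log-normal
with sd 0.2, missingness 2% — values a practitioner would call typical
for a cultured-cell lipidomics table that has already passed feature
curation.

Optional knobs plant verifiable structure: a rank-one design-orthogonal
source carrying a chosen variance fraction (for the orthogonal-selection
tests), a subset of effect-free features (for loading-localisation
tests), features whose blank signal defeats the 5× rule, and class-level
log2 fold changes in one origin (for the signature reports).

The generator does **not** emulate chromatographic drift or batch
structure, retention times, isotope or adduct patterns, censored
(intensity-dependent) missingness, or heavy-tailed analytical error.
Passing tests therefore demonstrate correctness of the estimators under
clean multiplicative noise, not robustness to every artefact of a real
acquisition.

Two systematic distortions are worth knowing when reading simulation
results. First, the log-to-linear transform is convex, so on the linear
scale the within-cell noise is heteroscedastic; at the default log-sd the
recovered origin share sits ~1–2 points below the requested 58.4%.
Second, half-minimum imputation places imputed cells far below their
feature means; at a few percent missingness this inflates the recovered
residual share by several points. Both effects are visible in the README
example and are properties of the (faithfully implemented) conventional
methods, not estimator bugs — which is why the decomposition-recovery
checks run on complete data.

## Problem sizes used by the tests

The suite exercises the estimators at 8–48 samples and 10–300 features,
permutation tests at 19–99 permutations, and the calibration experiment
at 50 seeded replicates of a zero-effect generator with 99 permutations
each; the acceptance script runs the full chain at 750 features × 48
samples with 999 permutations. These sizes were chosen so the full suite
completes in a few minutes while every check retains its statistical
meaning (e.g. a 99-permutation floor of 0.01 still discriminates a strong
effect from its null).

## Limitations

* Exact enumeration for degenerate permutation spaces is not implemented;
  the restricted-permutation spaces of any supported balanced design are
  far larger than practical permutation counts, so sampled permutations
  are always used.
* The interaction permutation scheme is approximate (see above).
* The imputation method is the field's conventional half-minimum; more
  principled censored-likelihood imputation is out of scope.
* No drift or batch correction beyond PQN is provided, and no
  classification of new samples.
* `chainLengthShift()` derives acyl carbons by subtracting a fixed
  sphingoid backbone (d18, configurable) from the total composition;
  species with atypical backbones will be mislabelled by ±the carbon
  difference.
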
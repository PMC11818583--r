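# lipidAMOPLS

Statistical analysis of untargeted lipidomics experiments with a crossed
two-factor design, built around ANOVA multiblock orthogonal partial least
squares (AMOPLS). The motivating application is comparing the lipidomes of
four colorectal-cancer cell lines (DLD1, HCT116, LS174T, SW620) before and
after acquiring resistance to the FOLFOXIRI chemotherapy combination: a
balanced 4 (cell origin) × 2 (naïve / resistant) design measured by
LC-HRMS, where ordinary PCA or PLS-DA cannot untangle which lipid shifts
belong to which experimental factor.

The package is aimed at analysts who already have an aligned feature table
(e.g. an MS-DIAL export: injections × lipid features, with pooled-QC and
blank injections) and want a tested, reproducible route from that table to
effect sizes, component models, permutation p-values and lipid-signature
summaries.

## The method

Given the unit-variance-scaled biological-sample matrix **X** (n × p) and
the two fixed factors A (origin, 4 levels) and B (resistance, 2 levels),
the matrix is first decomposed by classical two-way ANOVA into pure effect
matrices,

    X = 1 m' + X_A + X_B + X_AB + E,

where row i of **X**_A holds the A-level mean deviation for sample i, and
so on. In a balanced design the four matrices are mutually orthogonal and
the sum-of-squares shares ‖X_e‖²_F / ‖X − 1m'‖²_F sum to 1 — the "effect
proportions" reported as percentages.

Each block (the three effect matrices plus the residual) then contributes a
sample-space kernel K_b = X_b X_b′, scaled to unit Frobenius norm; their
mean is the consensus kernel **K**. A kernel-OPLS model is estimated on
**K** against the column-centred dummy response **Y** coding the design
(4 + 2 + 8 indicator columns, rank 7): predictive score vectors tp1..tpA
span the Y-correlated part of kernel space, and each orthogonal score tpo
captures the dominant Y-uncorrelated structure, deflated from the kernel
before the predictive components are re-estimated. For every component c
the block contributions

    λ_{b,c} = t_c′ K_b t_c / Σ_b t_c′ K_b t_c

identify which effect the component summarises; per-component explained
data variance and R²Y complete the model summary. Effect significance and
the number of orthogonal components are assessed by random permutations of
the design labels (restricted permutations for the main effects).

Around this core the package implements the standard pre-treatment chain —
missingness-versus-blank, QC-intensity, QC-CV and zero-IQR feature filters;
probabilistic quotient normalization (PQN) against the median pooled-QC
spectrum; half-minimum imputation; unit-variance scaling — plus a lipid
shorthand parser ("SM 36:1;2O", "PC O-34:2", …), class-composition,
log2 fold-change and chain-length-shift reports, and a synthetic-data
generator with exactly controlled ground-truth effect structure.

## Worked example

```r
library(lipidAMOPLS)

sim  <- simulateLipidData(simConfig(nFeatures = 300, replicatesPerCell = 6,
                                    seed = 14))
sim$table
#> LipidFeatureSet: 300 features x 56 injections (48 biological, 5 QC, 3 blank)
#> design: origin {DLD1, HCT116, LS174T, SW620} x resistance {naive, resistant}

fl   <- filterFeatures(sim$table)
fl$report
#> FilterReport: 300 -> 296 features
#>   failing missingness : 0
#>   failing qc_intensity: 4
#>   failing qc_cv       : 0
#>   failing iqr         : 0

norm <- pqnNormalize(fl$table)
imp  <- imputeMissing(norm$table)
bio  <- biologicalSamples(imp)
X    <- uvScale(intensityMatrix(bio))$scaled
dec  <- decomposeEffects(X, designFactors(bio))
dec
#> EffectDecomposition: 48 samples x 296 features
#> sum-of-squares shares (%):
#>      origin  resistance interaction    residual
#>       50.21        6.95       17.16       25.68

model <- fitAmopls(dec, nOrth = 1)
model
#> AmoplsModel: 7 predictive + 1 orthogonal component(s), R2Y = 1.0000
#> component variance (%) and attribution:
#>      variance attribution
#> tp1      6.95  resistance
#> tp2      6.47 interaction
#> tp3     18.12      origin
#> tp4      5.95 interaction
#> tp5     16.88      origin
#> tp6     15.20      origin
#> tp7      4.73 interaction
#> tpo1     1.26  orthogonal

effectSignificance(X, designFactors(bio), "resistance", nPerm = 999, seed = 1)
#> PermutationResult[resistance]: observed = 0.06949, p = 0.001 (999 permutations)
```

Reading the output: just over half of the centred variance here is carried
by the cell origin, ~7% by acquired resistance and ~17% by their
interaction (the generator's default regime; the residual share is
inflated above the configured 15.7% by the half-minimum imputation of the
simulated missing cells). Each predictive component is attributed to the
effect with the largest block contribution λ, and the resistance effect is
significant at the empirical permutation floor 1/(999 + 1).
`runPipeline(pipelineConfig(...))` chains all of these stages and writes
every table (scores, loadings, block contributions, effect proportions,
filter report, permutation p-values, class compositions, fold changes) to
an output directory; `classComposition()`, `log2FoldChange()` and
`chainLengthShift()` produce the descriptive lipid-signature tables.

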
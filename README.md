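# mycflux

Integrative modeling of the transcriptional response to acute MYC
activation, for computational biologists analyzing matched ChIP-seq and
total/nascent RNA-seq time courses (e.g. a MYC-ER fibroblast system sampled
at 0, 10 min, 30 min, 1 h, 2 h and 4 h after 4-OHT, with a 10-min 4sU pulse
before each collection).

The package implements three linked analyses plus a fully specified
synthetic-data generator so that every inference stage can be validated
against known ground truth:

**1. The MYC promoter share.** Each promoter's share of the total genomic
MYC signal is `s_i = b_i / Σ_j b_j`. Because activation increases total MYC
binding, a promoter gains share only if its own log2 binding change `δ_i`
exceeds the *share-neutral threshold*

```
δ* = log2( Σ(b_after + pc) / Σ(b_before + pc) )
```

which exactly partitions share gainers from losers. `δ_i` is used as a
predictor of transcriptional outcome (induced vs repressed), evaluated by
ROC analysis with exact Mann–Whitney tie handling, trimmed loess trends
with Spearman correlations, and cofactor-stratified Youden-optimal
thresholds.

**2. RNA kinetic rates.** Pre-mRNA `P` (intronic signal) and mature mRNA
`M` (exonic − intronic) follow the two-compartment ODE

```
dP/dt = k1(t) − k2(t)·P        (synthesis, processing)
dM/dt = k2(t)·P − k3(t)·M      (processing, degradation)
```

`k1` is measured directly from pooled nascent exonic+intronic signal over
the labeling window; `k2` and `k3` are fitted per gene by weighted least
squares under constant / sigmoid / impulse functional forms, with
AIC + goodness-of-fit model selection and a Benjamini–Hochberg-corrected
likelihood-ratio test for temporal variability of each rate.

**3. RNAPII compartment flux.** RNAPII densities at the promoter (`Pr`),
gene body (`Gb`) and TES (`Te`) follow

```
dPr/dt = p1(t) − p2(t)·Pr
dGb/dt = p2(t)·Pr − p3(t)·Gb      with  k1(t) = p3(t)·Gb(t)
dTe/dt = p3(t)·Gb − p4(t)·Te
```

where `p1` is net promoter flux (may go negative: net loss of RNAPII), `p2`
pause-release, `p3` elongation and `p4` TES release. Rates are inferred per
response cluster by a finite-difference initialization followed by joint
least-squares refinement, with single-parameter explained-variance
attribution and in-silico parameter freezing.

Hierarchical clustering (Ward, k = 14, clusters under 30 genes removed by
default) and PCA summarize response archetypes and feed cluster-mean
profiles to the RNAPII model.

## Worked example

```r
library(mycflux)

## a synthetic cohort with known ground truth
gt <- generateGroundTruth(nGenes = 300, seed = 42)
co <- simulateCohort(gt, NoiseModel(cv = 0.2), replicates = 3)

## MYC share analysis: binding change vs class
b   <- averageReplicates(normalizeSignal(co$tables$MYC))
tab <- shareTable(b[, 1], rowMeans(b[, -1]), pseudocount = 1)
roc <- rocInducedVsRepressed(tab$delta, geneClass(gt),
                             neutralThreshold = attr(tab, "neutral_threshold"))
round(c(auc = roc$auc, delta_star = attr(tab, "neutral_threshold"),
        J_at_neutral = roc$neutral_youden), 3)
#>          auc   delta_star J_at_neutral
#>        1.000        1.954        1.000
```

The cohort total MYC binding rises 4-fold, so the share-neutral threshold
sits near `log2(4) = 2`; promoters must gain roughly 4-fold binding before
they gain share, and at that threshold induced and repressed genes are
separated essentially perfectly (AUC = 1, Youden's J = 1 at δ*).

```r
## RNA kinetic rates on a 40-gene subset
ab <- deriveAbundances(co$tables$total_exon, co$tables$total_intron)
k1 <- estimateSynthesis(co$tables$nascent_exon, co$tables$nascent_intron)
cv <- sqrt((ab$cvP^2 + ab$cvM^2) / 2)
fit <- fitRates(ab$P, ab$M, k1, timeGrid(co$tables$total_exon),
                cv = cv, cvK1 = attr(k1, "cv"), nReps = 3,
                genes = geneIds(gt)[1:40])
fit
#> KineticFits: 40 genes, 6 timepoints
#>   k2 forms: constant=39, sigmoid=1
#>   k3 forms: constant=36, sigmoid=4
colSums(testRateVariability(fit)[, c("variable_k1", "variable_k2",
                                     "variable_k3")])
#> variable_k1 variable_k2 variable_k3
#>          17           0           2
```

Synthesis-rate changes dominate (17/40 genes called variable in k1),
processing and degradation changes are rarer — the expected hierarchy for
a transcription-factor activation, built into the generator's defaults.

```r
## RNAPII compartment model at steady state: flux conservation
r <- PolymeraseRates(c(0, 4), p1 = 60, p2 = 2, p3 = 3, p4 = 6)
simulateCompartments(r, times = c(0, 1, 4))
#>   time Pr Gb Te k1
#> 1    0 30 20 10 60
#> 2    1 30 20 10 60
#> 3    4 30 20 10 60
```

At steady state `k1 = p1 = p2·Pr = p3·Gb = p4·Te` (60 = 2·30 = 3·20 =
6·10).

See `vignettes/mycflux-methods.Rmd` for the full model description,
parameter defaults and numerical choices.

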
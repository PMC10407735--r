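---
title: "Scoring molecular network states and classifying QTL effects"
author: "stateQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring molecular network states and classifying QTL effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stateQTL)
```

## The model

A cell's molecular configuration — which transcripts, proteins and
phosphosites are high or low — is not free to vary independently per
molecule. Central signaling (in yeast, the PKA and TOR pathways) couples
growth-promoting programs (ribosome biogenesis, translation) to
stress/respiratory programs in an antagonistic balance, so a large share of
between-strain molecular variation collapses onto a single axis. `stateQTL`
works with a scalar summary of that axis:

$$\mathrm{score}_i \;=\; \mathrm{median}_{f \in I}\, z_{fi} \;-\;
\mathrm{median}_{f \in R}\, z_{fi},$$

where $I$ and $R$ are disjoint sets of axis-induced and axis-repressed
marker features and $z_{fi}$ is feature $f$'s abundance in strain $i$ after
per-feature standardization across strains. Medians make the score robust to
a few aberrant markers; standardization makes it invariant to per-feature
affine rescaling (asserted by a test). The score is on the z-score scale and
is meaningful only as a *relative* quantity within the scored panel.

Genetic variants are then classified by how their molecular consequences sit
on a physical protein-interaction graph:

* **local** — significant targets confined to one or a few proteins;
* **regional** — many targets, but mutually close in the network (one
  functional module) and no shift of the state score;
* **global** — targets spread at or beyond random expectation, together with
  a significant state-score shift.

## Deriving the signature

`deriveMarkerSets()` thresholds a feature × treatment effect matrix from
chemical inhibition of the two pathways (two pathways × two time points by
default). Effects are z-scored against the cross-feature SD of each
treatment; a feature is a candidate when |z| ≥ `kSD` (default 2) in at least
one treatment, and is discarded when any treatment moves it in the strictly
opposite direction. Two conventions matter here:

* **Orientation.** The input is an *inhibition* experiment, so the
  pathway-induced set is the features that consistently *fall* under
  treatment (`direction = "inhibition"`, the default). With
  `direction = "activity"` the thresholds apply to the matrix as given, for
  inputs already oriented as activity responses.
* **Dead zone.** "Opposite direction" uses |z| < 0.1 as numerically zero, so
  a tiny sign flip does not disqualify an otherwise consistent marker.

The SD used is the cross-feature SD per treatment; if replicate columns are
available, a per-feature replicate SD would be a defensible alternative, but
the cross-feature SD needs no replication and is what the package uses.

## Mapping QTL with permutation FDR

`mapQTLrf()` regresses the trait on all markers at once with a Random Forest
(1,000 trees, `mtry = sqrt(p)`, out-of-bag permutation importance —
permutation importance is more stable than impurity importance when markers
are in LD). Significance is empirical: the trait is permuted `nPerm` times,
the forest refit, and each marker's observed importance is ranked against
the null importances. By default the nulls are **pooled across markers
within permutation rounds**, giving p-value resolution of about
1/(`nPerm` × #markers) instead of 1/`nPerm`; a per-marker null is available
via `pooledNull = FALSE`. Benjamini–Hochberg adjustment runs across markers
and contiguous significant runs collapse to peaks. Null calibration (no
significant marker on permuted traits in ≥ 90% of runs, super-uniform
empirical p-values) is asserted in the test suite.

For per-locus molecular evidence, `analyzeLoci()` deliberately does **not**
test each marker marginally: a marker that is, by finite-sample chance,
correlated with the strong latent axis would inherit hundreds of spurious
targets. Instead `jointAlleleEffects()` fits each feature on all analyzed
loci simultaneously, so each locus' effect is conditional on the others —
the same role the multi-marker forest plays in genome-wide mapping. BH runs
per locus across features (default FDR 0.10).

## Network-spread statistics

`buildGraph()` keeps edges with confidence strictly above 0.400 (the
"medium-confidence" convention for STRING-style scores; inputs on the 0–1000
integer scale are detected and rescaled), drops self-loops and collapses
multi-edges. Distances are unweighted shortest paths; the confidence enters
only through the threshold. Pairs with no connecting path get the maximum
finite distance observed among the *same set's* other pairs — the imputed
value is a property of the dataset, not a constant.

`distanceNullEnvelope()` draws uniform random node sets of each required
size and records the 0.05/0.5/0.95 percentiles of the mean pair distance;
`compareDistancePoisson()` tests two distance distributions by modeling each
set's total path length as Poisson with exposure equal to its pair count and
applying the exact conditional binomial — the construction behind "a
two-sided Poisson test" when only totals and pair counts are available. Both
match brute-force oracles (Floyd–Warshall enumeration; closed-form binomial
tails) exactly in the tests.

`classifySpread()` turns evidence into a label with exposed thresholds:
fewer than 5 significant targets → local; mean target distance below the
envelope median with a non-significant state shift (α = 0.05) → regional;
mean distance at/above the median with a significant shift, or above the
0.95 percentile outright → global; the remaining combination is reported as
regional with a `"mixed"` note. These numeric thresholds are this package's
choices — the local/regional/global concept does not come with a canonical
rule — and all of them are arguments.

`pairStateAssociation()` reproduces the pair-correlation-by-distance
analysis: feature pairs with |r| > 0.5, each member correlated with the
score, one coefficient sign-inverted for anti-correlated pairs, the pair
summarized by the absolute mean of the two (sign-corrected) correlations,
binned by graph distance (> 6 collapsed into bin 6), and a Fisher exact test
contrasting bins 1–3 against bins ≥ 4.

## LD clustering of pQTL

`computeLD()` is the squared Pearson correlation of allele codes — the
standard biallelic r², symmetric under allele relabeling. `clusterPQTL()`
merges genomically *adjacent* clusters agglomeratively (complete linkage on
pairwise LD) for as long as every merged cluster keeps min within-cluster
LD ≥ `ldMin` (default 0.9; 0.8 reproduces the relaxed linkage-grouping
variant), i.e. the smallest cluster count compatible with the criterion.
Lead markers carry the most targets (ties → lower position). Adjacent
clusters whose lead markers exceed `ldMin` are merged afterwards, but only
when the merged cluster still satisfies the floor: the within-cluster LD
floor is an invariant of the output, asserted on every run.

## Growth curves, phospho-residuals, counts

`fitRichards()` uses the generalized-logistic parameterization

$$y(t) = A\,\bigl(1 + \nu e^{1+\nu}
e^{(\mu/A)(1+\nu)^{1+1/\nu}(\lambda - t)}\bigr)^{-1/\nu}$$

with $\lambda$ the intercept of the inflection tangent with the baseline.
The fitting loss is ordinary least squares via Levenberg–Marquardt,
initialized at $A$ = max OD, $\mu$ = max finite-difference slope, $\lambda$
= first time OD exceeds baseline + 5% of range, with multi-start over
$\nu \in \{0.5, 1, 2\}$. Several Richards parameterizations circulate in the
growth-curve literature; this exact form and loss are fixed here as package
decisions, and the tests pin down their behavior (parameters recovered within 1–2% on noiseless curves; lag
unbiased within ±2 min at OD noise SD 0.01). Heat-induced lag is
$\lambda_{heat} - \lambda_{mock}$, negative values allowed. Batch correction
subtracts batch means, then iteratively removes any batch whose variance
exceeds 2.5× the mean batch variance.

`phosphoResiduals()` regresses each phosphopeptide's z-values on its host
protein's z-values (simple OLS with intercept) and keeps the residuals,
isolating phosphorylation-rate change from protein-abundance change.
Best-peptide selection (highest adjusted R² against the score) biases
toward proteins with many peptides, so the selection table always reports
the candidate count, and `consistencyAudit()` quantifies how often a
protein's significant peptides disagree in sign (run at FDR 0.05 and 0.25).

`normalizeCounts()` drops genes detected in under half the samples, then
equalizes per-sample medians of counts between the 20% and 80% quantiles by
multiplying each sample by mean(M)/M_i; replicates are averaged on the
corrected scale. The heritability estimator is the adjusted R² of a
strain-identity regression — the share of variance between strains rather
than between replicates; a deliberately simple choice among the many
variance-component estimators. Likewise, the additive multi-locus model is
fixed-effect OLS reporting adjusted R²; a random-effects variant would
return a variance ratio instead of that quantity.

## The synthetic study

Every statistical claim in the package is tested against data with planted
truth, generated by `simConfig()` + `simulateStudy()`:

* **Cross.** 100 haploid strains, 1,000 biallelic markers on 16
  chromosomes; each chromosome is a two-state Markov chain with switch
  probability 0.02 per interval (~12 kb), which reproduces block LD without
  explicit meiosis. Alleles are coded 0/1; no heterozygotes.
* **Latent state.** Three planted loci act on the axis with direct effects
  +0.21, +1.14, −1.41 and product-term interactions +0.89 and −0.90 with the
  strongest locus — conditional-effect patterns of the kind pleiotropic
  yeast loci show (a weak locus whose effect grows to ~+1.1 on one genetic
  background, a strong one damped to ~+0.2 on the other). Non-genetic state
  noise SD 0.5.
* **Features.** 2,000 proteins (plus 1,000 transcripts, 500
  phosphopeptides): 25% load on the axis at ±1; the first 300 proteins are
  the nodes of a 6-module planted-partition graph (within/between edge
  probabilities 0.2/0.01) and share a per-module activity term (SD 0.7) so
  that modules co-vary independently of the state; a regional locus adds
  +1.0 to one module, a local locus +1.5 to a single non-network protein;
  feature noise SD 0.5; per-feature baselines SD 2 give the abundance
  spread that abundance-matched null sampling presumes.
* **Peripheral placement.** Axis-responsive network proteins are sampled
  with inverse-squared-degree weights. Real PKA/TOR-responsive programs are
  dominated by metabolic enzymes and stress proteins that sit at the
  periphery of physical-interaction networks — far enough apart that their
  mean pair distance exceeds the random-sample median, with some pairs
  unreachable — and this placement is what makes the global-vs-random
  distance contrast realistic rather than exchangeable with uniform draws.
* **Inhibition profiles.** Four treatments (two pathways × 20/150 min) with
  per-treatment scales (1, 0.8, 0.9, 0.7): each treatment's effect on a
  feature is −loading × scale + noise (SD 0.2), and 2% of unloaded features
  are injected as sign-inconsistent decoys that the derivation's
  consistency filter must remove.
* **Growth.** Richards curves (A = 1.2, μ = 0.008 OD/min, ν = 1, mock
  λ = 60 min); the true heat-induced lag is 40 min + 25 min for the local
  locus' allele + 12 min per latent-state unit, with replicate lag noise SD
  6 min and OD noise SD 0.005.

What the generator does **not** emulate: diploid genetics and meiotic
interference, intensity-dependent mass-spec missingness (missingness is
uniform at a configurable rate), heavy-tailed degree distributions beyond
the planted-partition model, and environment × genotype interactions.
Passing recovery tests therefore demonstrates correctness of the
statistical machinery under a faithful-but-idealized data model, not
robustness to every artifact of real proteomics data.

## Problem sizes and numerical choices

The test suite runs module tests on a 60-strain, 160-marker, 120-protein
configuration and the end-to-end acceptance checks at the full default size
(100 × 1,000 × 2,000, 300-node graph), with 20-seed replication for the
classification, Poisson-contrast and Fisher-pattern checks; permutation
counts are 50–100 and envelope samples 500–1,000 in those loops. These
sizes are the package's chosen desk-scale study conditions, and the
acceptance script (`scripts/acceptance.R`) re-runs the full pipeline at the
default size from a single seed.

Other numerical conventions: empirical p-values always carry the +1
pseudo-count, so they are never zero; abundance matching uses 10 quantile
bins of mean abundance, relaxing to adjacent bins (with a warning) when a
bin is exhausted; coordination is reported per allele stratum *and* pooled,
since either convention is defensible; missing values are ignored
inside medians and correlation pairs, and are mean-imputed only for PCA and
forest fits (both documented in the function help); ties in top-N effect
ranking and best-peptide selection break by feature ID for determinism; all
simulation stages draw from one config seed with fixed per-stage offsets,
so any stage can be reproduced in isolation.

## Known limitations

* The classification thresholds (5 targets, envelope median/0.95, α =
  0.05) are reasonable defaults, not estimated quantities; near-threshold
  loci will flip labels between seeds (the `"mixed"` note marks the
  ambiguous combination).
* The conditional target-calling in `analyzeLoci()` assumes the analyzed
  loci are the relevant genetic background; an unmodeled strong locus can
  still leak targets onto correlated markers.
* `mapTraitToFeatures()` inherits the Random Forest's preference for
  correlated predictor groups; its FDR is calibrated marginally, per
  predictor.
* The lead-marker merge in `clusterPQTL()` is constrained to preserve the
  within-cluster LD floor; datasets where the published merge rule would
  violate that floor will end with slightly more clusters here.
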
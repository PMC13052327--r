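---
title: "Methods: identifying biological Aging Proteins from plasma NPX profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying biological Aging Proteins from plasma NPX profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analytical problem

Plasma proteomes change both with chronological age and with accumulating
disease burden, and the two signals are entangled: most proteins that rise
in older patients also rise in healthy older adults. `npxaging` implements a
three-group design that separates them. Given log2-scale NPX (Normalized
Protein Expression) profiles for Young Controls (YC), Older Controls (OC)
and recently hospitalized, age- and sex-matched Older Patients (OP), two
pairwise contrasts are run: OC vs YC (the chronological-age axis, unpaired)
and OP vs OC (the disease-burden axis, paired through the matching). A
protein differentially expressed in **both** contrasts is called a
*biological Aging Protein* (AP); proteins significant in exactly one
contrast are *chronological-age-only* or *disease-only*. Downstream stages
characterize the AP set: overlap with literature-derived age/disease/SASP
protein lists keyed by UniProt accession, co-expression clustering with a
stability assessment, pathway over-representation, a mortality signature by
penalized Cox regression, and correlations with clinical measures.

## Differential expression

Each protein is tested with a normality-gated choice of test:
Shapiro–Wilk at level `alpha_normality` (default 0.05) on each group
(unpaired) or on the within-pair differences (paired) routes the protein to
the t-test or to the Wilcoxon rank-sum / signed-rank test. Two readings of
the gate are supported for unpaired data — require *both* groups to pass
(default) or *any* — because the underlying convention ("the distributions
can be assumed normal") does not pin down the quantifier; the choice is a
flag, and with Gaussian data the default gate takes the parametric route
about \(0.95^2 \approx 90\%\) of the time.

Fold changes are ratios of geometric means on the linear scale, which on
log2 NPX data reduces to \(2^{\bar a - \bar b}\). p-values are
Benjamini–Hochberg corrected across the full panel of each comparison, and
significance means **corrected** p < `alpha_fdr` (default 0.05). The raw-p
reading would be more permissive; we adopt the corrected one throughout
(it is the conservative resolution of the convention that "p < 0.05, raw or
corrected, is significant" in a context where corrections were applied),
and note below what this costs in recovery power.

Degenerate inputs are routed, not repaired: constant vectors (Shapiro–Wilk
undefined) fall back to the rank test with a warning; all-tied paired
samples return p = 1. Wilcoxon tests use the exact distribution for tie-free
samples up to n = 25 and the normal approximation with continuity
correction otherwise.

## Category logic and literature overlap

Classification is pure set logic on the two significance vectors, so the
printed-count identities (the AP count plus each exclusive count equals the
corresponding contrast's total) hold on any input by construction.
Literature overlap is computed on UniProt accessions with isoform suffixes
stripped, restricted to the measured panel; every list, every
within-source-kind union and the grand union are reported with two
denominators (category size and list-on-panel size), since published
overlap tables are ambiguous about which they use. *Novel* candidates are
the APs absent from the grand union — deliberately a plain set difference,
so a protein missing from every supplied list counts as novel even when
those lists come from platforms that could not have measured it.
Percentages are printed to one decimal, half-up.

## Clustering and its stability

Proteins are z-scored individually (sample SD, n−1; the convention only
rescales all distances by a common factor but is stated for
reproducibility) and clustered as objects with complete linkage, Euclidean
distance by default and Manhattan as the sensitivity analysis. Proteins are
sorted lexicographically by accession before clustering, which makes the
agglomeration — including tie-breaks — invariant to input column order.

The number of clusters is chosen from the scree of merge heights: with the
height sequence reversed so position *j* is the height at which *j*
clusters merge into *j − 1*, the selected *k* maximizes the second
difference within k ∈ [2, 20]. This is the algorithmic reading of an
elbow read visually off a scree plot; it is overridable (`k = <int>`)
precisely because a visual cut is not an algorithm. All-equal heights
return k = 2 with a warning.

Stability: for each subsampling proportion ν ∈ {0.85, 0.90, 0.95} (100
repeats by default), ⌊νP⌋ proteins are redrawn without replacement,
reclustered with the same distance, linkage and *k*, and compared with the
full-data labels restricted to the drawn proteins by the Rand index. The
raw Rand index scales trivially with cluster-size profiles, so each repeat
also scores a random-label baseline — the restricted reference labels
randomly permuted, preserving the size profile — and the normalized score
is (mean Rand − baseline)/(1 − baseline): 0 is chance, 1 is perfect
reproducibility. Two open choices resolved here: the subsample is cut at
the *full-data* k (stability of the chosen structure, matching per-k
stability curves), and the baseline is empirical (100 permutation draws)
rather than a closed-form constant, since the normalization is described
in the literature only as "by random labels". Per-cluster category
enrichment is an upper-tail hypergeometric test against the whole panel,
BH-corrected across all cluster × category cells.

## Over-representation analysis

Gene sets from GO/KEGG/Reactome/Hallmark GMT files are stacked into one
collection; the measured panel is the background. Proteins map to gene
symbols through an explicit user-supplied mapping table (no identifier
service is consulted); a protein belongs to a set if any of its symbols
does, and contributes once regardless of mapping multiplicity. Sets are
intersected with the background and kept if their background size lies in
[5, 2000] (both bounds are flags; unfiltered published analyses can set
them wide). The test is the upper-tail hypergeometric; the *rich factor*
k/(K·n/N) is the observed/expected hit ratio; BH correction is applied
once across the stacked collection, not per database, so results are
invariant to stacking order.

## The mortality signature

Young Controls carry no events by design and are excluded. For the older
participants the model is a stratified proportional-hazards model: separate
baseline hazards for OC and OP (hospitalization shifts the baseline risk in
ways no covariate should absorb), an unpenalized male-sex indicator, and an
L1 penalty on the standardized protein coefficients (per-SD log hazard
ratios). The solver maximizes the stratified Breslow partial
log-likelihood on the 1/n scale minus λ‖β_protein‖₁ by outer
reweighting (diagonal-Hessian working response) with inner cyclic
coordinate descent and warm starts along a 100-point log-spaced grid from
λ_max (the score bound at the unpenalized-only fit) down to 0.01·λ_max.
Numerical safeguards: convergence when the largest coefficient change
across an outer iteration falls below 1e-7; linear predictors capped at
±80 before exponentiation; coefficients capped at ±30 (the
monotone-likelihood regime); the path stops early once more than
`dfmax` (default: half the event count — the usual events-per-variable
prudence bound) protein coefficients are active or the relative likelihood
gain per grid point drops below 1e-5, because beyond that the partial
likelihood approaches saturation and "selection" is noise. Every fitted
grid point carries a KKT certificate (`kkt_max_violation()`), which the
test suite holds below 1e-5.

λ is chosen by 10-fold cross-validation of the held-out partial-likelihood
deviance in the Verweij–van Houwelingen form, −2(ℓ_all(β) − ℓ_train(β)),
which avoids forming risk sets inside a small held-out fold. Folds are
stratified jointly by group and event status so each training set keeps
events in both strata. Both the deviance minimizer (`lambda_min`, the
default selection rule) and the 1-SE rule (`lambda_1se`) are reported,
because descriptions of such analyses commonly mix the two; the choice is
surfaced in the result rather than hidden.

Stability selection repeats the whole cross-validated selection on
stratified bootstrap resamples (each stratum redrawn with replacement at
its observed size; 1000 resamples at full scale). A resample is redrawn —
and the redraw counted — if any stratum ends up with fewer than two
events: one event cannot simultaneously appear in a training set and leave
the fold structure intact. Proteins selected in at least 50% of resamples
are "robustly selected"; threshold 1.0 recovers the "consistently selected
in every iteration" reading. Bootstrap refits use convergence tolerance
1e-5 rather than 1e-7: selection is a per-protein zero/nonzero indicator
and is insensitive to coefficient changes below that level, while the
looser tolerance keeps 1000 full CV reruns affordable.

## The synthetic cohort generator

Because the motivating cohort data are access-restricted, the generator is
a first-class module that encodes the study conditions: 20 YC and 52
matched OC–OP pairs; a panel whose proteins split into null / age-only /
disease-only / both classes (default 70/10/10/10%); log2-scale shifts of
1 NPX unit added in OC and OP for age-affected proteins and in OP for
disease-affected ones; mostly-upregulated effects (20% of age shifts and
5% of disease shifts negative, matching the reported direction ratios
qualitatively); residual SD 1 NPX. Half the proteins carry a shared OC–OP
pair random effect (SD 0.5 NPX) so the paired test's power gain and the
unpaired path are both exercised — the within-pair correlation is not
reported anywhere, so this is a deliberately round choice. Twenty percent
of proteins get centred log-normal noise (σ_log = 0.8), enough to route a
nontrivial fraction through the Wilcoxon gate. Survival for older
participants follows group-stratified exponential baselines (OC 0.0115,
OP 0.115 events/year — a tenfold patient excess that reproduces roughly 8%
vs 56% seven-year mortality) scaled by exp(Σβ·z_protein + β_sex·male),
with planted hazard proteins (default two, β = 1 per SD) drawn from the
"both" class; Young Controls are censored administratively. The generator
does *not* model plate or bridging batch effects, limits of detection,
missingness, or longitudinal sampling — so passing recovery tests speak to
the statistical pipeline under clean sampling assumptions, not to
robustness against those artifacts.

The cluster-fixture generator places k cluster centers evenly on a circle
in the plane of group-mean profiles with zero size-weighted mean,
orthonormal under the group-size-weighted inner product. Two properties
follow: per-protein z-scoring preserves the geometry exactly (every
cluster's profile variance is identical), and inter-cluster distances are
comparable, so the scree elbow sits at the planted k. `separation` is a
per-sample effect size in noise-SD units. With random centers instead, a
single distant cluster routinely drags the scree elbow to k = 2 — the
circle layout is what makes "the elbow recovers the planted k" a
well-posed claim.

## Problem sizes used in the checks

The packaged checks run scaled-down but structurally faithful versions of
each recovery experiment: AP recovery on 1000-protein panels at the full
20/52/52 design (20 Monte-Carlo replicates in the acceptance script);
clustering on 150-protein, 4-cluster panels over 5 seeds with 20 stability
repeats per ν; the signature on 150-protein cohorts with the candidate set
restricted to the planted "both" class, 100 bootstrap resamples and 10
seeds (the candidate restriction isolates the survival stage from
classification error, which is scored separately); null false-call rates
on 300–500-protein panels over 20–30 replicates. These sizes are the
package's choices for routine verification; every routine accepts the
full-scale parameters.

## Known limitations

* Attainable AP recovery under the design conditions is bounded by the
  age-contrast power against only 20 Young Controls: with BH-corrected
  significance at FDR 0.05 over a 1000-protein panel the per-test
  threshold lands near 0.01 and per-protein power near 0.86–0.88, so
  planted-AP recovery sits in the mid-80s percent range. Raw-p
  thresholding would push it above 95%, but the package keeps the
  corrected rule.
* The scree elbow is a heuristic; on real proteomes with nested or
  unequal-radius clusters the automatic k should be inspected against the
  emitted merge heights (and overridden where the scree is read
  differently).
* The empirical random-label baseline is one reading of stability
  normalization; a different normalizing constant would shift the score
  scale, though not the ordering across ν or k.
* Cox-LASSO selection frequencies from 100-resample runs are noisier than
  the full 1000-resample protocol; the robust-set threshold semantics are
  unchanged.
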
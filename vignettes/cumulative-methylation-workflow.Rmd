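---
title: "Cumulative-methylation diagnostics: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative-methylation diagnostics: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmdx)
```

## The measurement model

The assay quantifies promoter methylation of ten breast-cancer marker
genes in a lymph-node fine-needle aspirate by methylation-specific qPCR.
Each of two cartridges (marker sets) amplifies five target genes and the
ACTB reference; the quantity carried forward per gene is

$$\Delta Ct_g = Ct_g - Ct_{ACTB}^{(s(g))},$$

where $s(g)$ is the gene's own marker set. Using the reference from the
same reaction set is a deliberate choice: the two cartridges are
independent PCR runs, and normalizing across cartridges would import
between-run variation into every gene of the other set.

Calibration relates $\Delta Ct$ to the methylated-DNA fraction $f$. The
plates follow a two-fold dilution design (100%, 50%, …, 3.12%
methylated), which makes $\log_2 f$ the natural regressor: the curve is
fit by ordinary least squares,

$$\Delta Ct = b + m \log_2 f + \varepsilon,$$

and a perfectly efficient PCR doubles template per cycle, giving
$m = -1$ cycle per two-fold dilution. The functional form is a modeling
choice of this package; linearity on the log scale is the standard
standard-curve assumption in quantitative PCR, and the fitted
`residual_rms` (cycles) makes departures visible. Inversion gives percent
methylation,

$$\%M = 100 \cdot 2^{(\Delta Ct - b)/m}, \quad \text{clamped to } [0, 100],$$

and the classifier score is the cumulative methylation
$CM = \sum_{g=1}^{10} \%M_g$, in "CM units" on $[0, 1000]$.

Three conventions matter at the edges:

* **Undetected target → 0%.** A methylated target that never crosses the
  fluorescence threshold is read as absence of methylated template, not
  as missing data. Treating it as missing would bias CM upward in benign
  samples, where most targets are legitimately silent.
* **Extrapolation below the lowest standard (3.12%)** is permitted down
  to the clamp at 0, and values above 100% clamp to 100. Reported
  percentages therefore span the full $[0,100]$ without flagging values
  outside the calibrated range; at very low fractions the quantitation is
  best regarded as semi-quantitative.
* **Adequacy** requires ACTB detected in *both* marker sets at
  $\le$ `actb_max_ct` cycles (default 40, boundary inclusive — a sample
  exactly at the cutoff is kept). Inadequate samples are excluded before
  any scoring, and the filter ledger reports them so cohort size is
  always conserved.

## Classification and combination

The call rule is strict-greater: malignant iff $CM > \tau$. The default
$\tau = 8.5$ CM units is the laboratory threshold of the assay; reading
it as a "threshold *for benign*" puts a score exactly at 8.5 in the
benign class, and the rule (and boundary) is configurable.

`select_threshold()` re-derives a threshold from labeled scores by
scanning candidate cutpoints — midpoints between adjacent sorted unique
scores, plus $\pm\infty$ sentinels — and maximizing sensitivity subject
to a specificity floor (`min_specificity`, default 0.90), breaking ties
toward higher specificity and then the lower threshold. Midpoint
candidates make the selected operating point invariant to strictly
monotone transformations of the score; the tie-break toward lower
thresholds favors sensitivity in deployment, consistent with the rule's
purpose.

The combined molecular + cytology call is the either-positive (OR) rule,
with indeterminate cytology contributing nothing. OR is the only
combination rule that can only raise sensitivity and only lower
specificity relative to the molecular assay alone, which is the observed
behavior the combination is meant to deliver; the dominance is asserted
as a property test, not assumed.

## Evaluation

* Sensitivity, specificity, PPV and NPV are simple ratios of the
  confusion counts, each with a **Clopper–Pearson exact** binomial
  interval. The exact method is conservative but never degenerate at
  proportions near 1, where these assays operate; it also reproduces the
  kind of interval printed in diagnostic-accuracy reports of this type.
  A metric with an empty denominator is returned as `NA` and flagged,
  without failing the rest.
* The ROC-AUC is the empirical probability that a malignant score
  exceeds a benign one with ties counting one half; its interval is
  **DeLong** by default with a stratified bootstrap behind
  `ci_method = "bootstrap"`. Computation is delegated to pROC; the
  package's tests check the estimate against an independent all-pairs
  enumeration.
* Samples with indeterminate cytology are excluded from any analysis in
  which cytology is a comparator or the truth, and counted in the
  ledger; they still receive molecular calls.
* Cross-platform agreement with an external score (e.g. a reference
  laboratory assay's cumulative index) is a Spearman correlation with
  average ranks for ties; the external index's own formula is out of
  scope and it is treated purely as a score vector.

## Subgroup statistics

Group comparisons of CM use the Mann–Whitney test for two groups and
Kruskal–Wallis for more. The two-group asymptotic p-value is the
tie-corrected normal approximation *without* continuity correction, so
that a two-group Kruskal–Wallis gives the identical p-value — keeping the
two-group and multi-group branches mutually consistent. Exact
enumeration is used when both groups have fewer than 8 members and the
data are tie-free.

Call-rate homogeneity across strata uses Fisher's exact test:
hypergeometric for 2×2, and a seeded Monte-Carlo p-value
($\ge 10^5$ draws) for 2×k, where the network algorithm's runtime is
less predictable and a seeded simulation keeps the analysis exactly
reproducible.

The age analyses are two-fold: an OLS regression of CM on age (slope,
its two-sided p, and the Pearson correlation reported side by side —
they share a t statistic but answer differently-scaled questions), and a
per-threshold logistic scan of misclassification against age.
"Misclassification" is defined per class: among benign samples the event
is a false-positive call at the threshold, among malignant samples a
false negative. Complete separation or non-convergence is flagged
(`converged = FALSE`) rather than reported as a coefficient.

## Study-design computations

Two calculations reproduce the design arithmetic of a two-arm
diagnostic study:

* `ci_halfwidth_simulation()` controls the expected width of a
  proportion's confidence interval: per replicate, $n$ Bernoulli
  outcomes at the assumed rate are drawn and a **percentile bootstrap**
  interval is formed. Resampling $n$ Bernoulli outcomes with replacement
  makes each bootstrap proportion an exact $\mathrm{Bin}(n,\hat p)/n$
  draw, so the implementation samples that distribution directly — an
  identity, not an approximation, and orders of magnitude faster. At the
  design point (rate 0.90, $n = 100$, 90% CI) the mean half-width is
  about 0.048, comfortably under the 0.1 design bound and within 20% of
  the closed-form $1.645\sqrt{p(1-p)/n} = 0.0494$.
* `enrollment_probability()` is the exact binomial sum
  $P(m \le K \le N - m)$ for $K \sim \mathrm{Bin}(N, \pi)$: with
  $N = 230$ at $\pi = 0.5$ prevalence the probability of at least 100
  subjects per arm is 0.959. Monte-Carlo is used only as a test oracle.

## What the synthetic generator emulates — and what it does not

`cohort_config()` defines the study conditions the generator reproduces:

| field | default | rationale |
|---|---|---|
| `n_malignant`, `n_benign` | 110, 120 | pre-exclusion arm sizes of a 230-subject prospective cohort at ~50% prevalence |
| `inadequate_rate` | 12/230 | inadequate-DNA exclusions; the generator masks exactly `round(rate·n)` samples so the exclusion ledger is reproducible |
| `benign_scale` | 0.2% per gene | benign per-gene background is exponential; ten genes give CM ~ Gamma(10, 0.2) with median ≈ 1.9 CM units, inside the 1.4–2.4 range benign nodes show |
| `detectable_frac` | 0.91 | fraction of malignant aspirates carrying enough tumor DNA to rise above background; sets the assay's ceiling sensitivity near 91% |
| `per_gene_positive_prob` | 0.5 each | in a detectable tumor, each marker is methylated in roughly half of cases — marker positivity is heterogeneous across tumors |
| `malignant_shape1/2` | Beta(2, 4) | positive genes take percent levels ~ 100·Beta(2,4) (mean 33%), giving broadly elevated malignant CM |
| `cytology_sensitivity/specificity` | 0.925 / 0.953 | the cytology comparator's operating point |
| `indeterminate_rate` | 6/218 | indeterminates drawn independently of truth — 2 + 4 events in a 218-sample study are too sparse to support a dependence model |
| `age_coef` | 0.008 /yr | modest log-scale upward drift of benign background with age, enough to make the misclassification-vs-age scan directionally meaningful without dominating CM |
| `ct_noise_sd` | 0.2 cycles | well-to-well PCR noise on ΔCt |
| `actb_ct_mean/sd` | 28 / 1 cycles | ACTB reference level for adequate specimens |
| `detection_floor_percent` | 0.01% | percent below which a target fails to amplify and is emitted undetected |

The malignant model is two-part on two levels — a sample-level
detectability spike (aspirates may simply miss the metastasis) and a
gene-level positivity spike (tumors methylate different subsets of the
panel) — because that is the simplest structure matching "some genes
methylated, some not, in any given tumor". The generator's **implied
truth** at a threshold is computed by `operating_characteristics()`
directly from the percent model (a large seeded draw, no Ct round trip),
and the parameter-recovery tests require the full Ct-level pipeline to
land within 5 percentage points of it at 500 samples per arm, with AUC
within 0.03.

Deliberately **not** modeled: inter-cartridge batch effects and plate
drift; subtype-specific per-gene methylation structure (the subtype
labels are independent of CM, so subtype comparisons are null by
construction); dependence of cytology errors or indeterminates on tumor
burden; storage-age effects on archival slides; raw fluorescence traces.
Passing tests therefore demonstrate that the analysis chain is correct
and well-calibrated under the stated data structure — they are not
evidence about how the assay behaves on real aspirates, where those
un-modeled effects exist.

## Numerical conventions and problem sizes

Internal arithmetic is double precision throughout; CM and percent
metrics are rounded to one decimal only at the reporting boundary
(profile/report writers). Candidate-threshold ties, boundary samples and
degenerate inputs (constant ages, single-class cohorts, empty
denominators, two-point regressions) follow the rules above and are
covered by tests. The test-suite problem sizes — 500 samples per arm for
parameter recovery, $10^5$ draws for generator truth, 2000×1000 for the
design simulation, full enumeration only below $\binom{8}{4}$-scale —
were chosen to keep every check sharply discriminating while the whole
suite runs in well under a minute.

## Known limitations

* The calibration model assumes a common PCR efficiency across the
  dilution range; efficiency drift at very low template is absorbed into
  the residual, not corrected.
* Percent methylation below the lowest standard is an extrapolation.
* The ten-gene panel membership is configuration, not code: five genes
  are fixed by the assay (AKR1B1, APC, COL6A2, HOXB4, RASSF1) and the
  default fills the rest with placeholders, so any published panel can
  be supplied.
* The exact-interval choice (Clopper–Pearson, DeLong) is one reasonable
  convention among several; both are stated in every report this package
  writes, and the bootstrap AUC interval is available when the DeLong
  normality approximation is doubtful at extreme AUCs.
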
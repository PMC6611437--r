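---
title: "Weighted Dichotomizing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted Dichotomizing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromaWD)
```

## The problem

After radical prostatectomy, some patients relapse quickly (rising PSA —
biochemical recurrence, BCR — within a few years) while others remain
disease-free for many years. A small panel of immunohistochemistry (IHC)
markers quantified in *tumor-adjacent stroma* on tissue microarrays (TMAs)
can carry prognostic signal, but marker–outcome relationships in this
setting are often threshold-like rather than linear: Pearson correlation
between raw intensity and time to recurrence can be near zero even when a
cutoff on the marker separates outcomes well. stromaWD implements an
analysis pipeline built around that observation:

1. **Within-TMA normalization** of raw average staining intensities.
2. **Censoring-aware case redefinition** into aggressive and indolent
   classes.
3. The **Weighted Dichotomizing (WD) classifier**: per-marker optimal
   cutoffs combined by accuracy-proportional weights.
4. **Stratified 10-fold cross-validation** with accuracy, PPV, NPV and
   ROC/AUC.
5. **Median-split Kaplan–Meier and Cox proportional-hazards** comparisons
   of markers and clinical factors.
6. A **synthetic-cohort generator** that plants known cutoffs, directions,
   batch effects and censored BCR times, so every stage can be validated by
   parameter recovery.

## The model

### Normalization

Each TMA is stained in its own reaction, so intensities are comparable
within a TMA but not across TMAs. For each marker within each TMA the raw
average intensity $I$ is rescaled to

$$I' = \frac{I - M}{R},$$

where $M$ is the median and $R = \max - \min$ the range of that
(marker, TMA) stratum. Every stratum ends with median 0 and range 1, and
the transform is exactly invariant to per-stratum affine distortions
$I \mapsto aI + b$ ($a > 0$) — the transform family a batch effect in scale
and offset induces. Two consequences shape the error handling: a stratum
needs at least two non-missing values, and a stratum whose values are all
equal ($R = 0$) is refused rather than silently zeroed. Missing intensities
are excluded from $M$ and $R$ and propagated as missing; no imputation is
performed. $M$ and $R$ are computed per marker within each TMA (not pooled
across markers), since each TMA reaction uses one antibody and pooling
would mix scales.

### Case redefinition

Dichotomous outcome classes are derived from the censored time to BCR:

* **aggressive** — BCR observed within 36 months of surgery;
* **indolent** — BCR-free with at least 72 months of follow-up;
* **excluded** — everyone else (censored too early to know, or relapsed
  between the windows).

Boundaries are read literally (event at exactly 36 months is aggressive;
censoring at exactly 72 months is indolent). A patient whose BCR event
occurs *at or after* 72 months did relapse, so they are excluded rather
than called indolent: the indolent class is reserved for non-relapse cases
with long follow-up. Both windows are arguments of `assignLabels()` with
the defaults above (months throughout; months avoid fractional years when
mixing 3-year and 6-year rules with clinical follow-up data).

### The WD classifier

For marker $i$ with direction "oncogene" (higher expression in aggressive
disease) a case votes $S_i = 1$ (aggressive) when its normalized expression
is at or above the marker's cutoff; a "suppressor" marker votes aggressive
at or below its cutoff. The cutoff is chosen by sweeping **exactly the
sorted observed training values** as candidates and keeping the one with
the highest training accuracy $\alpha_i$; the composite combines the votes
as

$$S = \sum_{i=1}^{k} S_i w_i, \qquad
  w_i = \frac{\alpha_i}{\sum_{j=1}^{k} \alpha_j},$$

and calls a case aggressive when $S \ge 0.5$.

Numerical conventions, all of which matter for exact reproducibility:

* **Equality at the cutoff** goes to the aggressive side for both
  directions, mirroring the $S \ge 0.5$ tie convention of the composite
  rule.
* **Ties between equally accurate cutoffs** are broken toward the smallest
  candidate value, for determinism.
* **No sentinel candidates** beyond the observed values are added. One
  consequence is that the constant "everyone indolent" prediction is not
  representable (the extreme candidate still votes at least one case
  aggressive), so on single-class training strata the attainable $\alpha$
  can be below 1; `searchOptimalCutoff()` documents and tests this rather
  than papering over it.
* Candidate comparison uses exact double equality (`match`), not printed
  representation.
* A marker whose training values are all identical is a degenerate-marker
  error, not a silent constant vote.
* Marker directions come from prior biological knowledge (for the default
  stromal panel: FGFR1 suppressor-like, MYPT1 and LDHB oncogene-like). A
  data-driven mode (`directions = "auto"`, choosing the orientation with
  the higher training $\alpha$) exists but is off by default, because
  fixed directions are part of the method's specification and the auto
  mode costs an extra degree of freedom per marker.
* At prediction time a case with missing votes yields `NA` unless
  `renormalizeMissing = TRUE`, which renormalizes the weights over the
  observed markers; this is an extension for incomplete panels, not part
  of the original procedure.

### Validation

`stratifiedFolds()` shuffles within class (seeded) and deals round-robin,
so per-fold class counts never deviate from the stratified ideal by more
than one: a 36/69 cohort at $k = 10$ gives 3–4 aggressive and 6–7 indolent
cases per fold. When $k$ equals the number of cases the assignment
degenerates to leave-one-out (one case per fold, deterministically);
otherwise each class must have at least $k$ members or stratification is
refused. CV metrics are **pooled over all out-of-fold predictions**, not
averaged per fold — pooling is well defined with unequal folds and matches
reporting a single overall accuracy. PPV/NPV with an empty denominator are
reported as `NA` with an `"undefined"` flag, never as 0. The ROC sweeps
the composite score (which has at most $k+1$ distinct values for $k$
markers) and the AUC is computed in its rank/Mann–Whitney form with ties
counted one half; the suite checks it against exhaustive pairwise
enumeration and against pROC.

### Survival statistics

Kaplan–Meier curves, Cox models and log-rank tests go through the
`survival` package; Cox ties use the **Efron approximation** (a standard
default with good small-sample behavior). The median-split comparison
places cases strictly above the median in group H and everyone else —
including ties at the median — in group L, and reports the H-vs-L p-value
from a Cox model with the group indicator (the log-rank p-value is a
secondary column). The package also ships `coxPartialLogLik()`, the
explicitly coded Efron partial log-likelihood, so tests can verify that
`coxph`'s coefficient maximizes the same objective by brute-force
univariate optimization to $10^{-4}$. Fits with a monotone likelihood
(perfect separation) or convergence warnings are flagged in the output and
raise a warning — never silently reported. The significance convention in
reported tables is $p \le 0.05$.

## What the synthetic generator emulates — and what it does not

`simulateCohort()` draws, per marker, two equal-variance normal
class-conditional distributions whose means sit symmetrically about the
planted cutoff, `classSeparation` noise-SD units apart; which side is
aggressive depends on the marker's direction. This is the simplest model
with a closed-form best achievable ("Bayes") accuracy, which
`bayesAccuracy()` computes prior-aware (the optimal threshold shifts
toward the minority class when priors are unequal, and the majority rate
is a floor). `separationForAccuracy()` inverts it, so the default panel is
*calibrated*: with 36 aggressive and 69 indolent cases, the three markers'
best achievable accuracies equal 0.724, 0.676 and 0.667 — the training
regime the method was designed around. In the zero-noise limit
(`noiseSd = 0`) the separation is read in absolute intensity units so a
noiseless cohort is strictly separable; this limit exists purely to give
the pipeline an exactly solvable case.

Batch effects multiply each (TMA, marker) stratum by a scale drawn from
`batchScaleRange` and add a shift drawn with SD `batchShiftSd` — exactly
the family the normalization removes, making the normalization-invariance
test sharp. Intensities live on a 0–255 Aperio-like average-intensity
scale (default cutoffs 120–150, noise SD 20, 4 TMAs, shift SD 10, scale
0.8–1.25) and are clipped at zero after the batch transform, since
staining intensities are non-negative. BCR times follow the redefinition
rules by construction: aggressive events uniform on (0, 36] months,
indolent censoring uniform on [72, 120] months, and intermediate cases —
which exercise the exclusion path — get, with equal probability, either an
event strictly between the windows or censoring before 72 months.
Clinical covariates (pre-op PSA, Gleason, margin, stage) are drawn with
class-dependent distributions solely to exercise the Cox/correlation
stage; their codings are declared in the generator, since real-world
covariate codings vary.

What passing tests on this generator do **not** show: real Aperio average
intensities are not normal (the family is a stand-in, not a claim about
the data), real batch effects need not be affine, markers are generated
independently given the class (no inter-marker correlation), and BCR-time
distributions inside the windows are uniform by fiat. Recovery of planted
parameters here validates the *machinery*, not the biology.

## Problem sizes and tolerances used by the test suite

The suite validates the cutoff search against exhaustive enumeration on
1,000 random instances ($n \le 30$), the AUC against exhaustive pairwise
comparison up to $n = 50$, weight/score algebra at tolerance $10^{-12}$,
and normalization laws at $10^{-12}$. Parameter recovery uses 50
replicates of a 1,000-case balanced cohort calibrated to accuracies
(0.72, 0.68, 0.67): the mean fitted $\alpha$ per marker is required within
$\pm 0.04$ of its target. The fitted cutoff itself is a maximum-score
estimator with cube-root asymptotics — its sampling deviation at
$n = 1000$ is on the order of 0.1–0.4 noise-SD units, two orders wider
than the inter-case gap around the true cutoff — so cutoff consistency is
meaningful at that $n^{-1/3}$ scale, not at single-gap resolution. Cox
recovery uses 100 replicates of $n = 500$ exponential survival with true
log-hazard ratio 1 (bias bound 0.1, coverage within three Monte-Carlo SEs
of 95%); the permutation-null uniformity check uses 500 permutations.
These sizes were chosen so each property is tested well inside its
asymptotic regime while the whole suite stays quick to run.

## A worked run

```{r example, eval = FALSE}
se  <- simulateCohort(cohortConfig(seed = 1))   # 36 aggressive, 69 indolent
nse <- normalizeBatch(se)
lab <- assignLabels(se)
clf <- fitWD(nse, lab, directions = c(FGFR1 = "suppressor",
                                      MYPT1 = "oncogene",
                                      LDHB  = "oncogene"))
clf
trainingAccuracy(clf, nse, lab)
cv <- runCV(nse, lab, directions = c(FGFR1 = "suppressor",
                                     MYPT1 = "oncogene",
                                     LDHB  = "oncogene"),
            kFolds = 10, seed = 2)
cv@metrics
markerSurvival(nse)$summary
```

`runPipeline(defaultPipelineConfig(outDir, seed))` chains all stages,
writes every intermediate table as CSV, metrics as JSON and a model file
as structured text, and finishes with a manifest (seed, per-stage derived
seeds, configuration hash excluding the output location, package and R
versions, MD5 checksum per output) so a run can be reproduced and verified
byte for byte. All randomness flows from the single top-level seed: the
simulation uses it directly, the CV fold shuffle uses seed + 1, and
seeded code restores the caller's RNG state afterwards.

## Known limitations

* The classifier is intentionally rigid: dichotomous votes, one cutoff per
  marker, no interactions, no continuous-score alternatives. That is the
  method, not an oversight.
* Optimal-cutoff training accuracies are optimistically biased at small
  $n$; the honest performance figure is the cross-validated one, and the
  suite asserts CV accuracy does not beat training accuracy on average.
* Case redefinition discards between-window patients; with heavy
  censoring the usable cohort can be much smaller than the collected one.
* The normalization assumes at least two distinct values per
  (marker, TMA) stratum and is undefined otherwise by design.
* Batch correction beyond per-TMA affine structure (e.g. quantile or
  reference-protein normalization) is out of scope.
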
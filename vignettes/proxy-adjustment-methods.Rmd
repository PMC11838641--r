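---
title: "Proxy confounding adjustment with NLP-derived note features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proxy confounding adjustment with NLP-derived note features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noteps)
```

## The problem

Non-randomized comparisons of two treatments in claims/EHR databases are
confounded by indication: sicker patients are channelled toward one drug, and
much of what makes them "sicker" is recorded nowhere as a clean researcher
covariate. The high-dimensional proxy-adjustment strategy responds by
generating thousands of candidate features — diagnosis/procedure/drug codes
and, in this package, features distilled from free-text clinical notes — and
letting a penalized propensity model decide which proxies carry confounder
signal. Notes matter because some clinical states (frailty, functional
status, symptom burden) surface in narrative text long before, or instead
of, any billable code.

`noteps` implements the full pipeline: note featurization, feature
screening, cross-fitted LASSO propensity scores over eight nested covariate
sets, three propensity-weighting schemes, weighted Cox effect estimation and
standardized-difference balance diagnostics — plus a synthetic cohort
generator with known ground truth, since the linked claims–EHR databases
such methods are developed on cannot be shared.

## The data-generating model

The generator plants a latent "comorbidity state" $U \in \mathbb{R}^L$ per
patient, $U_\ell \sim N(0,1)$ i.i.d., and builds everything else from it:

* **Treatment**: $\Pr(A=1 \mid U, Z) = \operatorname{expit}(\alpha_0 +
  \alpha^\top U + \alpha_{iv} Z)$, with $Z$ a treatment-only factor feeding
  planted instrumental codes.
* **Outcome**: survival time $T \sim \operatorname{Exp}\{\lambda_0
  \exp(\beta A + \gamma^\top U)\}$, administratively censored at 183 days
  (the 6-month intent-to-treat window). With a constant baseline hazard the
  weighted-Cox estimand equals $\beta$ exactly under correct adjustment,
  which makes parameter recovery a clean test.
* **Codes**: each claims/EHR code $j$ is Bernoulli with
  $\operatorname{logit} = b_j + \lambda_j^\top U$. Codes load on a single
  component each, with loadings drawn from $[0.8, 1.8]$ — strong enough that
  a few dozen codes collectively carry most of a component's signal, the
  rich-proxy regime proxy adjustment presumes. Instrumental codes load only
  on $Z$, which has no outcome effect, so instrument screening can be
  validated against truth.
* **Notes**: each patient emits Poisson-many notes of Poisson-many tokens;
  content tokens follow a per-patient softmax over the vocabulary with
  log-rates shifted by $U$, and a fixed stop-word stratum is emitted
  independently of $U$ (so stop-word removal is testable as pure noise
  reduction). All note offsets are strictly pre-index.
* **Note-only confounders**: a configurable fraction of the components of
  $U$ have their *code* loadings zeroed. Their signal reaches the analysis
  only through note tokens — this is the mechanism that lets simulations
  quantify the added value of NLP features.

Latent confounders are continuous rather than binary comorbidity flags:
binary proxies still arise downstream through the Bernoulli code draws, and
a continuous state yields graded code prevalences and token rates with fewer
knobs. Defaults target a treated fraction near 33% and a 6-month outcome
risk of 2–4%, the scale of claims-based cardiovascular safety cohorts.

What the generator does **not** emulate: real clinical language (tokens are
abstract symbols), code semantics and hierarchies, enrollment/washout
eligibility logic, informative censoring, negation, and EHR-discontinuity.
Passing tests therefore show that the *statistical machinery* behaves as
claimed under a known causal structure — not that any particular real-world
study is unbiased.

## Note featurization

Five schemes turn pre-index notes into binary patient features, mirroring
common practice from bag-of-words to transformer embeddings:

1. **n-grams** — documents are tokenized (lowercase, split on
   non-alphanumerics, digits kept), stop words removed *first*, then
   unigrams and bigrams of the filtered sequence are formed, never spanning
   document boundaries. Filter-then-pair increases proxy density
   ("atrial fibrillation" survives an intervening stop word). Features are
   presence indicators, not counts.
2. **Lexicon concepts** — a generic stand-in for clinical term-extraction
   systems: greedy longest-match left-to-right over each tokenized document;
   a match consumes its span, suppressing nested shorter matches. Concept
   presence, no negation handling.
3. **Word-embedding clusters**, 4. **contextual word-embedding clusters**,
   5. **sentence-embedding clusters** — every unit (token occurrence, token
   in context, or note document) is embedded, all embeddings are pooled and
   clustered with mini-batch k-means, and each patient gets one binary
   feature per cluster (1 iff any of their units lands in it). Pretrained
   models plug in through a provider interface (`dim` + `embed()`); the
   built-in providers are deterministic hash embedders — each token maps to
   a fixed pseudo-random unit vector, the contextual variant perturbing it
   by a hash of the flanking tokens — so the pipeline runs reproducibly with
   no model files. Hash embeddings carry no semantics, only identity and
   co-occurrence structure; with real providers the clusters become
   semantic.

Mini-batch k-means is implemented in the package (k-means++ initialization,
batch size 1,024, 100 iterations, assignment ties to the lowest index,
optional restarts scored by full-data within-cluster sum of squares) because
no installed R package provides the mini-batch variant; `stats::kmeans` and
a brute-force exact 2-means serve as small-instance oracles in the tests.
The cluster count `k` defaults to 500 per scheme and is configuration — the
right value depends on corpus size and is not knowable a priori. Document
embeddings under a non-contextual provider are token-vector means; the
"sentence" unit is the note document, since the synthetic text has no
sentence segmentation.

## Screening

Two screens run before any model fitting. The prevalence screen removes
automatically generated binary features (codes and NLP features) with
prevalence strictly below 0.01; researcher-specified and continuous columns
are exempt. The threshold is read as strict — a feature at exactly 0.01
stays. Prevalence is computed per cohort, not per arm.

The instrument screen ranks features by marginal correlation with treatment
(phi coefficient for binary features, point-biserial for continuous ones;
constants get 0 and a flag) and exposes the top of the list for review.
Since a reproducible pipeline cannot contain a literal expert-review step,
exclusion is a *denylist* interface; in simulations the denylist can be
derived from the generator's planted instrumental codes. Adjusting for
instruments inflates variance without removing bias, which the test suite
demonstrates by comparing effect-estimate dispersion with and without the
denylist.

## Propensity estimation

For each of the eight nested covariate sets (researcher-only up to
researcher + codes + one NLP block), the propensity score is estimated by
10-fold cross-fitting: folds are assigned at random stratified by treatment
(guaranteeing both classes in every training split), a LASSO logistic model
is trained on nine folds with its penalty chosen by inner 5-fold
cross-validation minimizing binomial deviance, and predictions are made on
the held-out fold, so every patient's score comes from a model that never
saw them. Scores are clipped to $[10^{-6}, 1-10^{-6}]$ to keep weights and
log-likelihoods finite.

Two estimation choices deserve explanation:

* **Relaxed prediction (default).** A cross-validated LASSO shrinks
  coefficients toward zero, compressing the propensity distribution toward
  the treated fraction. Weights built from shrunk scores remove only part of
  the measured confounding — in this package's diagnostic simulations,
  weighting on the true score or on an unpenalized fit eliminated the
  planted bias while penalized predictions left a material residual. The
  default therefore uses the LASSO at the CV-chosen penalty for *selection*
  and an unpenalized logistic refit on the selected set for *prediction*
  (the relaxed LASSO), per training fold. `relax = FALSE` restores plain
  penalized predictions.
* **Speed settings.** The penalty path uses 30 values down to
  `lambda.min.ratio = 0.02` with coordinate-descent tolerance $10^{-5}$:
  penalty selection is insensitive to finer paths on sparse binary designs,
  and the relaxed refit makes the prediction accuracy independent of path
  resolution.

Inner CV folds are assigned by a deterministic hash of the patient id where
row names exist, which makes the cross-fitted scores invariant to patient
ordering. Continuous covariates are scaled to unit variance before
penalization; binary indicators enter as 0/1; researcher covariates are
penalized like all others. Reported diagnostics are the C-statistic
(Mann–Whitney form, ties one half) and the mean Bernoulli negative
log-likelihood of the pooled out-of-fold predictions; the "predictors
selected" count comes from a full-data refit at the median per-fold penalty
and is reporting-only.

## Weighting, effects, balance

Three weighting schemes are computed from the cross-fitted score:
inverse-probability $w = A/ps + (1-A)/(1-ps)$, overlap
$w = A(1-ps) + (1-A)\,ps$, and matching
$w = A\,\frac{\min(ps, 1-ps)}{ps} + (1-A)\,\frac{\min(ps, 1-ps)}{1-ps}$.
The treatment effect is a one-covariate weighted Cox model (Breslow ties,
robust sandwich variance treating the weights as fixed, 95% CI via the
1.96 normal quantile) over the 6-month window; the unadjusted estimate runs
through the same code path with unit weights. The window is enforced at
generation/ingest; the Cox routine itself is window-agnostic.

Balance is the absolute standardized difference
$d = |m_1 - m_0| / \sqrt{(v_1 + v_0)/2}$ with weighted arm moments (for a
binary feature, weighted prevalences and $p(1-p)$ variances). Weighting
changes the moments, never the formula. Balance is assessed for *all*
features, candidate or not — imbalance in features the model never saw is
exactly how the added value of note features shows up — and the 0.1
threshold is a reporting flag, never a filter.

## Evaluation scenarios and problem sizes

`scenario_note_confounding()` is the reference confounded scenario: n =
2,000; two latent components with $\alpha = (0.7, 0.7)$ and $\gamma =
(0.4, 0.4)$ (planted upward bias, unadjusted log-HR $\approx$ 0.37); one
component note-only, so claims-only adjustment can remove at most half the
confounding; 100 codes; a 300-token vocabulary with strong token loadings
(1.2–2.8) and 4 notes × 50 tokens per patient, so the note proxies carry
most of the note-only component's signal in tokens informative enough for
the LASSO to select — the operating regime the method presumes, and the
one in which its added value over claims-only adjustment is measurable.
These sizes keep a 100-replicate Monte-Carlo run
on one core inside a coffee break while leaving the statistical story
intact: matching-weighted adjustment with claims + n-gram features
(covariate set 4) removes roughly three quarters of the planted bias,
claims-only adjustment (set 2) leaves at least twice the residual,
mirroring at desk scale the qualitative finding that adding NLP features
improves confounding control. `scenario_null()` (randomized, unconfounded, no notes) underpins
coverage and calibration checks.

## Numerical choices and degenerate inputs

* Propensity clipping at $10^{-6}$; weights error on scores at exactly 0
  or 1.
* Cox fitting uses Newton iterations to a $10^{-10}$ log-likelihood
  tolerance; no events in an arm is reported as non-identifiability rather
  than returning a diverging estimate.
* Standardized differences with zero pooled variance: 0 when the arm means
  agree, `Inf` with a warning otherwise.
* Fold assignment guarantees sizes differ by at most one; a training split
  with a single treatment class errors with advice.
* k-means assignment ties break to the lowest cluster index; `k` larger
  than the number of distinct units errors.
* The master seed fans out to per-stage seeds through a Park–Miller
  recurrence, so any stage can be re-run in isolation and all child seeds
  stay inside 32-bit integer range.

## Known limitations

* **Balance at small n.** A standardized difference estimated at n = 2,000
  with a 33% treated fraction has sampling error around 0.047 even for a
  perfectly balanced feature, so with hundreds of features some will exceed
  0.1 by noise alone in nearly every replicate — roughly 3% of pure-noise
  features per replicate in the reference scenario. The "every feature
  below 0.1" pattern reported from cohorts an order of magnitude larger is
  a large-sample statement; at desk scale the meaningful quantities are the
  *fraction* of imbalanced features and its comparison across covariate
  sets, which the replicate summaries report.
* **A residual-bias floor for presence features.** Binary presence
  indicators saturate: a patient far out in the latent severity
  distribution has the same feature vector as one moderately out, so the
  tails of the confounder — which drive a disproportionate share of the
  hazard bias — are only partially recoverable. In the reference scenario
  this caps matching-weighted set-4 adjustment at removing roughly 75–80%
  of the planted bias, and making individual tokens more informative does
  not move it. Count or tf-idf features would raise the ceiling but are
  deliberately out of scope.
* The built-in embedders are semantic-free stand-ins; conclusions about
  embedding-cluster schemes transfer to real pretrained providers only in
  structure, not in performance ranking.
* No negation or uncertainty handling in lexicon matching; no PS trimming;
  no doubly robust or bootstrap inference.

## A worked example

```{r example, eval = FALSE}
library(noteps)

cfg <- run_config(
  sim = scenario_note_confounding(),
  model_ids = c(1, 2, 4), schemes = "matching",
  seed = 42
)
report <- run_experiment(cfg)
report$effects
report$ps_diagnostics
autoplot(report$balance_tables$model4_matching)
```
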
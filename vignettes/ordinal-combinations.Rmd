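---
title: "Constructing and selecting biomarker combinations for single-level prediction of an ordinal outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and selecting biomarker combinations for single-level prediction of an ordinal outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many biomarker studies record an outcome with a small number of ordered
levels — no, mild or severe disease; tumor grade; stages of kidney injury
after surgery — while the clinical question concerns one particular level,
usually the most severe. With an outcome $D \in \{1, \dots, K\}$ and a
marker vector $\mathbf{x}$, "single-level prediction" means building a
scalar risk score that discriminates $D = K$ from $D < K$, measured by the
AUC for that contrast. The ordinal structure raises two distinct questions
that this package addresses:

1. **Construction.** Given a fixed marker panel, does a model that uses all
   $K$ levels produce a better combination than simply dichotomizing the
   outcome at $K - 1$ and fitting a binary logistic model?
2. **Selection.** Given many candidate combinations (for instance, all
   $\binom{p}{2}$ marker pairs), can the information in the lower outcome
   levels make the *choice* among candidates more reliable, and less
   distorted by model selection bias?

## Construction strategies

`fit_combination()` fits seven strategies under one scoring contract:
`predict_risk()` always returns $\hat P(D = K \mid \mathbf{x})$.

* **simple** — binary logistic regression for the dichotomized outcome,
  $\operatorname{logit} P(D \le K-1 \mid \mathbf{x}) = \alpha +
  \boldsymbol{\beta}^\top \mathbf{x}$.
* **sequential** — $K - 1$ binary logistic models, model $k$ fit on the
  subset $D \ge k$ with outcome indicator $D = k$, each with its own slope
  vector; the risk score telescopes,
  $\hat P(D = K) = \prod_{k<K} \{1 - \operatorname{expit}(\hat\alpha_k +
  \hat{\boldsymbol\beta}_k^\top \mathbf{x})\}$.
* **cum_logit** — the proportional-odds (cumulative logit) model
  $\operatorname{logit} P(D \le k \mid \mathbf{x}) = \alpha_k +
  \boldsymbol{\beta}^\top \mathbf{x}$ with a common slope and intercepts
  ordered in $k$.
* **adjcat_logit** — the adjacent-category logit model
  $\log\{P(D = k)/P(D = k+1)\} = \alpha_k + \boldsymbol{\beta}^\top
  \mathbf{x}$, again with a common slope.
* **contratio_logit** — the continuation-ratio logit model
  $\operatorname{logit} P(D = k \mid D \ge k, \mathbf{x}) = \alpha_k +
  \boldsymbol{\beta}^\top \mathbf{x}$; releasing the common-slope
  restriction recovers the sequential strategy exactly.
* **stereotype** — the one-dimensional stereotype model, a compromise
  between the ordinal models and the fully flexible multinomial model:
  level-specific slopes are restricted to $\boldsymbol{\beta}_k = \phi_k
  \boldsymbol{\beta}$ with $\phi_1 = 0$ and $\phi_K = 1$ fixed for
  identifiability. No a-priori ordering is imposed on the remaining
  $\phi_k$: whether the estimates come out ordered is itself informative
  about the outcome's ordinality.
* **baseline_cat** — the baseline-category (multinomial) logit model with
  reference level $K$ and a free slope vector per level.

The likelihoods nest: the adjacent-category model is the stereotype model
with $\phi_k$ linear in $k$, and the stereotype model is the
baseline-category model with rank-one slopes, so
$\ell(\text{adjcat}) \le \ell(\text{stereotype}) \le
\ell(\text{baseline})$ at the respective maxima. The test suite asserts
this sandwich on randomly generated datasets, and for $K = 2$ all seven
strategies collapse to the same binary logistic fit.

### Fitting and numerics

Cumulative-logit fits delegate to `MASS::polr` and baseline-category fits
to `nnet::multinom` (run to a tight `reltol` so the nesting inequality
holds at numerical precision). The adjacent-category and stereotype models
have no suitable implementation among the package's dependencies, so both
are fit by direct maximization of the multinomial likelihood: BFGS with
analytic gradients, followed by Newton polishing with a numerically
differenced Hessian until the gradient sup-norm falls below $10^{-6}$.
The stereotype likelihood is not concave in its joint parameterization,
so the optimizer starts both from a frequency/binary-logistic
initialization and from the fitted adjacent-category solution mapped into
stereotype coordinates ($\phi_k = (k-1)/(K-1)$ after rescaling
$\boldsymbol\beta$); starting from that mapped solution also guarantees the
fitted stereotype likelihood can only improve on the adjacent-category
one. Failures trigger up to five deterministically jittered restarts (no
RNG is consumed, so fitting never perturbs a simulation's seed stream).

Orientation is never patched after the fact: each model is fit in the
parameterization above and `predict_risk()` derives
$\hat P(D = K \mid \mathbf{x})$ from it. A strategy whose assumed ordering
contradicts the data can therefore produce a test AUC far below 0.5 —
that is a finding about the strategy, not an artifact, and the simulation
drivers preserve it.

Separation and other degeneracies are flagged, not silently accepted: a
fit whose coefficient norm diverges (sup-norm above $10^4$) or whose
optimizer fails is marked `converged = FALSE`, excluded from Monte Carlo
summaries, and counted in the reported failure rates.

## The AUC

`auc()` implements the Mann-Whitney estimator with midrank tie handling:
$\widehat{\text{AUC}} = \{\#(\text{case} > \text{control}) + \tfrac12
\#(\text{case} = \text{control})\}/(n_1 n_0)$. Ties receive half credit —
the convention that makes the estimator exactly the normalized Mann-Whitney
U statistic. `conditional_auc()` restricts to the observations in a level
contrast, e.g. $\{3\}$ vs $\{1, 2\}$ or $\{2\}$ vs $\{1\}$. The
implementation sorts cases and controls separately and merge-counts
exceedances; the suite verifies exact agreement (to $10^{-12}$) with an
$O(n^2)$ pair-counting oracle, invariance under strictly monotone score
transformations, and the complement identity under score negation. No
per-fit confidence intervals are computed: the Monte Carlo drivers report
medians and interquartile ranges across replicates instead.

## The selection algorithm

For $K = 3$ and a candidate set of marker tuples (all pairs by default),
`select_combination()` runs:

1. Dichotomize at $D = 3$ vs $D < 3$ and fit every candidate by binary
   logistic regression, $\operatorname{logit} P(D = 3 \mid \mathbf{x}) =
   \theta_0 + \boldsymbol{\theta}^\top \mathbf{x}$.
2. From each fitted score, estimate the apparent AUC for $D = 3$ vs
   $D < 3$ *and* for $D = 2$ vs $D = 1$ in the training data. The lower
   contrast reuses the same fitted score; nothing is refit.
3. Draw $B$ bootstrap resamples of the training rows (default $B = 50$),
   refit every candidate in each resample, and estimate each AUC's
   resubstitution bias as the average of (AUC in the resample) minus
   (AUC of the resample-fit applied to the original training data).
4. Subtract: corrected = apparent − bias.
5. Rank candidates within each contrast (largest corrected AUC = largest
   rank, midranks on ties). The **standard** approach picks the candidate
   maximizing the corrected top-level AUC; the **new** approach picks the
   candidate maximizing the rank sum across contrasts.
6. `evaluate_on_test()` applies both chosen fits to independent test data;
   the estimated model selection bias is (corrected training AUC) −
   (test AUC), so optimism is positive.

For $K > 3$ the contrasts extend downwards: $\{K\}$ vs $\{<K\}$,
$\{K-1\}$ vs $\{<K-1\}$, …, $\{2\}$ vs $\{1\}$, and all ranks are summed.

Design choices where the procedure itself leaves room:

* The bootstrap is unstratified — the plain nonparametric reading of
  "resample the training data". A resample missing a level required by any
  contrast is redrawn (and the redraw count logged) rather than dropped,
  keeping the $B$ used resamples i.i.d. conditional on validity; the same
  $B$ resamples are shared by all candidates so their bias estimates are
  comparable.
* Ranks use the "larger is better" convention with midranks; ties in the
  selection itself are broken by the larger corrected top-level AUC, then
  by lexicographic candidate order.
* Candidates whose original fit did not converge get rank 0 in every
  contrast, are never selected, and are counted in the report.
* The inner loop (hundreds of logistic refits per bootstrap resample) runs
  in compiled code: batched IRLS with warm starts from the training-data
  fit, and the merge-count AUC above.

Because the selection report is produced from a single seeded RNG stream,
an identical seed reproduces the report bit for bit.

## Synthetic data

Two generator families cover the simulation designs the package ships:

* **Conditional Gaussian** (`gen_conditional_gaussian()`): $D$ drawn from
  fixed prevalences, then $\mathbf{X} \mid D = k \sim
  N(\boldsymbol{\mu}_k, \Sigma)$. The shipped construction grid uses two
  markers, $\Sigma = 2 I_2$, level means $(0, \mu, 2)$ for $K = 3$ and
  $(0, 0.5, 1, \mu, 2)$ for $K = 5$ with $\mu \in \{-1, 0, 1, 2, 3\}$, so
  $\mu$ sweeps from well-ordered to order-violating level means. The
  proportional-odds assumption does not hold in this family.
* **Cumulative logit** (`gen_cumulative_logit()`): Gaussian markers and
  $\operatorname{logit} P(D \le k \mid \mathbf{x}) = \alpha_k -
  \boldsymbol{\beta}^\top \mathbf{x}$, so proportional odds holds by
  construction. The intercepts $\alpha_k$ are calibrated to target
  prevalences by monotone bisection on a $10^6$-point sample of the linear
  predictor $\eta = \boldsymbol{\beta}^\top \mathbf{X}$; with Gaussian
  markers $\eta$'s law is known exactly
  ($N(\boldsymbol{\mu}^\top \boldsymbol{\beta},
  \boldsymbol{\beta}^\top \Sigma \boldsymbol{\beta})$), so the calibration
  sample is drawn from it directly instead of materialising a large marker
  matrix. Achieved prevalences are within 0.005 of their targets.

The five shipped selection examples use thirty markers with
compound-symmetric correlation 0.3 and variance 2; Examples 1–2 are
proportional-odds with slopes $(1, 2, 0.5 \times 14, 0.1 \times 14)$ and
Examples 3–5 are conditional-Gaussian with level-mean vectors that make
markers 1–2 the strongest pair and the rest moderately or weakly
informative. Example intercept calibration runs once per session under a
fixed internal seed, so generated datasets depend only on the caller's
seed. For the proportional-odds generator two printed slope conventions
circulate (a sign flip of $\boldsymbol\beta$ combined with reflecting the
Gaussian markers about their mean leaves every distribution of scores and
AUCs unchanged); the generator exposes $\boldsymbol\beta$ directly and the
shipped presets use $(1,2)$, $(1,1.5)$, $(-1,1)$.

Every generator refuses to emit a training set missing an outcome level:
the whole dataset is redrawn (redraws are counted in an attribute), which
keeps draws i.i.d. conditional on validity. Test sets are exempt.

What the generators deliberately do *not* emulate: real biomarker panels
have skewed, heteroskedastic, occasionally missing measurements and
covariance structure far from compound symmetry. Passing the shipped
simulations therefore demonstrates correctness of the algorithms under
their stated models, not robustness to real assay data; the CSV interface
(`read_ordinal_csv()`, with optional log transformation) is the intended
route for the latter.

## Monte Carlo drivers and problem sizes

`run_construction_cell()` and `run_selection_example()` reproduce the two
study designs: training sets of 400 (configurable to 200–1600), test sets
of $10^4$, 1000 construction replicates and 500 selection replicates at
full scale. Per-replicate seeds are derived from the root seed by one
up-front draw, so any replicate can be reproduced in isolation and
summaries are bit-identical across reruns. Non-converged fits are dropped
from medians and reported as failure rates; the exclusion rule is the
package's own choice, made explicit in the summaries.

The package's own automated checks run the drivers at reduced scale —
hundreds rather than thousands of replicates, chosen so the Monte Carlo
standard error of a median is well below the differences of interest
(about 0.002–0.005 in AUC at 300–500 replicates; selection frequencies
carry a standard error of roughly 4–5 percentage points at 100
replicates). The acceptance script (`scripts/acceptance.R`) states the
replicate counts it uses next to each quantity it recomputes.

## Known limitations

* The stereotype fit reports a local maximum in pathological cases; the
  multi-start strategy above makes this rare, and the nesting sandwich is
  still guaranteed against the adjacent-category fit, but not against the
  global optimum.
* Case-control sampling corrections are out of scope; the cumulative and
  continuation-ratio models in particular are known to be biased under
  outcome-dependent sampling.
* Candidate sets are enumerated exhaustively; marker pre-selection by
  univariate association is deliberately not offered (it can discard
  markers whose value only appears in combination), so very large panels
  imply large candidate sets.
* Only the sum of ranks is implemented for the new selection approach;
  weighted rank or weighted AUC averages are not.
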
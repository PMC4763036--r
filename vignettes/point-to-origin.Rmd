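---
title: "Methods: analysing virtual point-to-origin experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing virtual point-to-origin experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pointorigin)
```

## The task and its geometry

In a point-to-origin task the observer passively views a visually
simulated excursion — a straight segment, a turn of signed angle
$\theta$, and a second straight segment — and afterwards indicates the
egocentric quadrant containing the origin of locomotion. The stimulus
kinematics are modelled as five phases: a linear acceleration of
duration $t_{a}$ at $a$ m/s² reaching cruise speed $v = a\,t_a$, a
cruise segment, the turn, a second cruise segment, and a linear
deceleration to rest. The turn has a symmetric triangular
angular-velocity profile: an accelerating half and a decelerating half
at constant angular acceleration $\alpha$ (deg/s²), so covering
$|\theta|$ degrees takes $T = 2\sqrt{|\theta|/\alpha}$ seconds.

Defaults follow the classroom stimulus the package emulates: $a = 10$
m/s², $v = 10$ m/s, $t_a = 1$ s, cruises of 2 s and 3 s, 1 s
deceleration, $\alpha = 15$ deg/s², and the four-trial plan L60°, R90°,
R90°, L60°. With these values a 60° turn takes exactly 4 s and a 90°
turn $2\sqrt{6} \approx 4.899$ s. Descriptions of such stimuli sometimes
round the latter to 5 s; the package always uses the closed form, and
treats the rounded value as prose rounding — whether the original
apparatus clipped the angular acceleration or the duration cannot be
recovered from a rounded description, so we do not guess.

Two modelling choices are not fixed by a phase-wise description:

* **Translation during the turn.** We keep the translational speed
  constant at $v$ along the instantaneous heading, which is continuous
  with both straight phases and produces smooth curved paths. The
  strategy-to-quadrant map below is insensitive to this choice for
  $|\theta| < 135°$.
* **Frame convention.** Bird's-eye right-handed frame: the observer
  starts at the origin facing $+z$, $+x$ is rightward, headings are in
  degrees clockwise from $+z$, so left turns are negative angles.

### Strategies as reference frames

Each hypothesised response strategy corresponds to a reference frame in
which the homing bearing (the direction from the endpoint back to the
origin) is expressed:

* **turner** — frame of the final heading (heading change updated);
* **non-turner** — frame of the initial heading (heading not updated);
* **non-mover** — the *outbound* bearing (origin to endpoint) in the
  initial frame, as if reporting where one went;
* **spinner** — frame of the final heading rotated 180°, as if turning
  to face the path before pointing.

The quadrant (front/back × left/right) of the resulting bearing is the
strategy's predicted answer. For any $|\theta| \in (0°, 135°)$ under the
default path the four predictions are four *distinct* quadrants, so the
map is invertible: every answer determines exactly one per-trial
strategy label (`label_answer()`). Negating $\theta$ mirrors the map
left-right. Bearings that fall exactly on a quadrant boundary (multiples
of 90°) raise a degenerate-geometry error rather than being tie-broken;
the experimental angles never produce them, and silent tie-breaking
would hide a configuration error.

Numerics: trajectories are integrated trapezoidally on a 1 ms grid
(path length agrees with the analytic phase distances to well within
0.1%); the endpoint is also available in closed form, with the curve
displacement evaluated by adaptive quadrature at `rel.tol = 1e-12`.

## Classification

A participant is classified as a user of a strategy when that label
appears in at least 75% of trials — with four trials, at least
`ceiling(0.75 * 4) = 3`; all others are *no-preference*. We read "75% of
trials" as a ceiling because 3/4 is exactly 75%. With four trials and
threshold 3 no tie is possible; for other configurations two labels
could reach the criterion simultaneously, which we classify as
no-preference (conservative).

Preprocessing applies, in order: (1) removal of participants with
missing gender, ethnicity or any trial answer; (2) classification;
(3) removal of spinner-classified participants, whose counts are too
sparse to model — individual spinner *answers* given by other
participants are retained. The exclusion log records counts at each
step, surviving rows keep their order, and the operation is idempotent.

## The synthetic-cohort generator

The generator exists so that every downstream stage has a testable
input with known truth. It emulates a classroom cohort of 501
participants with the subgroup sizes of `reference_cell_sizes()`
(ethnicity × response mode × gender; cells from 17 to 62 participants),
drawing each participant's latent classification from the softmax model
at the cell's covariates, by default using `reference_coefficients()`
capped at magnitude 5. Capping matters: the raw table contains a
non-mover estimate near −12 and a three-way near +10.4 — classic
quasi-separation artifacts — which as *generating* values would make a
class essentially impossible in one cell at any realistic sample size.

Emission: latent-strategy participants answer their strategy's
predicted quadrant on every trial; with per-trial lapse probability
$\varepsilon$ (default 0.05) an answer is replaced by one of the three
other quadrants uniformly. The lapse model is the simplest exchangeable
noise process; nothing in the task description constrains it further.
Latent no-preference participants emit a 2-2 split over two distinct
randomly chosen strategies in random trial order, which *guarantees*
the consistency criterion fails — no-preference is defined only
negatively, so the generator realises it by construction. Gender (and
every other covariate) is fixed per cell rather than redrawn, keeping
fixtures exactly sized. Generation is fully reproducible from the seed.

At $\varepsilon = 0$ classification recovers every latent class exactly
(a tested round-trip identity). At $\varepsilon = 0.05$ a latent
strategy user is misclassified only if at least two of four answers
lapse coherently; the exact probability is obtained in the tests by
enumerating all $4^4$ label patterns and is about 1.4%.

What the generator does *not* emulate: trial-order learning effects
(drifts toward turner answers across trials are tabulated downstream,
not generated), within-participant answer correlation beyond the latent
class, and free-text ethnicity noise (pooling beyond
{Caucasian, Chinese} → Other is the only harmonisation). Passing tests
therefore validate the pipeline's statistical machinery, not these
features of real data.

## The classification model

`fit_strategy_model()` fits the baseline-category multinomial logit
(baseline *no-preference*; reference levels Caucasian, pictorial,
female; all interactions — 12 terms × 3 outcome contrasts = 36
parameters) by maximum likelihood via `nnet::multinom`, with a
deterministic zero start, `reltol = 1e-10` and up to 200 iterations.
Non-convergence is flagged on the fit object rather than raised.
Standard errors above 10 trigger a quasi-separation warning; we report
them rather than switching to penalised fitting, since the saturated
12-cell design with a rare class *will* separate occasionally at
classroom sample sizes and the user should see that.

Likelihood-ratio term tests come in two deletion schemes. The default
(`type = "III"` in the car naming convention) drops exactly the tested
term from the otherwise complete model — one row per term, each
compared against the full fit, which reproduces the familiar
main-effects/2-way/3-way test-table layout. `type = "II"` is the
classical hierarchical scheme (terms containing the tested one removed
from both models). Which scheme an "ANOVA" on a multinomial fit means
is genuinely ambiguous in common usage, so both are provided; the
type II path is cross-checked against `car::Anova` in the tests.
Degrees of freedom are (deleted columns) × (outcome contrasts), e.g. 6
for an ethnicity main effect and 6 for the three-way interaction.

The binary variant (`fit_binary_logistic()`) restricts to the two
dominant classes and fits the same design as a binomial logit.

Training accuracy is the fraction of participants whose
highest-probability class matches their observed classification; for an
intercept-only coefficient vector this equals the modal-class share,
and four balanced classes give the 25% chance level used as the
bootstrap benchmark.

## Odds ratios under baseline rotation

For outcomes $t, b$ and a factor contrast $a$ vs $b^*$ at profile
$x_0$, the odds ratio is
$\exp[(\eta_t(a)-\eta_t(b^*)) - (\eta_b(a)-\eta_b(b^*))]$ with
$\eta_{\text{no-preference}} \equiv 0$. This is computed directly as a
linear combination of coefficients, so it equals the softmax
probability-odds ratio to machine precision (a tested invariant) and is
invariant to which of the 12 baseline rotations
(`enumerate_rotations()`) parametrises the model — rotation changes the
phrasing, not the model.

Wald intervals use the delta method over the full coefficient
covariance when the model was fitted here. When only a *printed*
coefficient table with per-coefficient standard errors is available
(`printed_fit()`), the package falls back to the independent-SE
approximation $\sqrt{\sum c_i^2 \mathrm{SE}_i^2}$, labelled approximate:
it ignores coefficient covariances, so its significance flags are
weaker than refitted ones — point estimates are unaffected. Recomputing
odds ratios from a rounded printed table reproduces published values to
their printed precision in most cases and within about 1% otherwise
(e.g. 9.56 recomputed where 9.58 was printed).

Reporting filters follow the source analysis: keep intervals excluding
1, drop odds ratios outside [0.001, 100] (artifacts of sparse cells
with enormous intervals), and present only the greater-than-one
orientation of each reciprocal pair. A reported contrast and its
double-swap rephrasing (swap both the outcome pair and the levels) have
the same value and are both kept, mirroring how such effects are
conventionally reported in both directions.

## Bootstrap nulls

`null_accuracy()` holds the observed classifications fixed and scores
`B = 10,000` random classifiers: uniform over the four analysis classes
(naive) or drawn from the observed frequencies (weighted). The class
set excludes spinners because they are excluded before modelling, which
is also what makes 25% the right chance level. Intervals are plain
percentile (2.5th–97.5th) — not BCa — matching the construction's
simplicity; comparison with a model accuracy uses strict inequalities,
and falling below the lower bound is flagged separately from exceeding
the upper one. Mean naive accuracy converges to $1/4$ and mean weighted
accuracy to $\sum_k p_k^2$; with marginal shares
$(0.4478, 0.253, 0.1104, 0.1888)$ at $n = 498$ the weighted mean is
about 0.313.

## Validation design and problem sizes

The simulation checks in the test suite use the following sizes, chosen
to make the statistical assertions sharp while keeping the suite quick
to run:

* **Coefficient recovery** — 100 cohorts at 50× the reference cell
  sizes ($n = 25{,}050$), generated from the capped coefficients with
  `lapse_rate = 0`, refit, and the generating vector checked against
  the joint 95% Wald region. Two deliberate choices here: the lapse is
  switched off because with $\varepsilon > 0$ the classification
  distribution is no longer the softmax of the generating coefficients,
  so exact recovery is only defined for the noiseless channel; and the
  Wald quadratic form is evaluated through the observed information,
  $d'Hd$, rather than by inverting the covariance matrix — the two are
  algebraically identical, but near-separated directions (the capped
  ±5 entries put one small cell close to that regime) make the
  covariance numerically singular while leaving $d'Hd$ stable.
* **Type-I calibration** — 1,000 cohorts with every gender coefficient
  zeroed, testing the gender main effect (df = 3) at $\alpha = 0.05$.
  These cohorts use coefficients capped at magnitude 1 and 4× cell
  sizes so that every class stays populated in every covariate cell:
  asymptotic LR calibration is only meaningful away from the separation
  regime.
* **Bootstrap** — $B = 10{,}000$ at $n = 498$; convergence of the
  means is asserted within three Monte-Carlo standard errors.
* **Lapse model** — Monte-Carlo misclassification over 20,000
  single-cell participants against the exact $4^4$-pattern enumeration.

## Interfaces

Everything is driven from R: `run_analysis(run_config(...))` executes
the full pipeline (generate-or-load → preprocess → tabulate → fit →
LR tests → odds ratios → bootstrap) and writes a report bundle with a
JSON manifest sufficient to replay the run; `read_run_config()` accepts
YAML/JSON configurations, and path specifications, cohorts and results
round-trip through JSON/YAML/CSV. A shell-level subcommand interface
was considered and deliberately omitted: the package's users work in R,
and a thin script over `run_analysis()` (of which
`scripts/acceptance.R` is an example) covers batch use.

## Known limitations

* Refitting the model on *real* data requires the raw cohort; printed
  coefficient tables only support the odds-ratio and prediction paths,
  with approximate intervals.
* The saturated three-factor design separates easily at classroom
  sample sizes; the package reports rather than penalises, so users
  with sparse cells should expect flagged standard errors and filtered
  extreme odds ratios.
* The naive bootstrap interval depends on details (class count, n)
  that published analyses do not always state; the package pins them
  (four classes, analysed n) and documents the choice rather than
  matching any particular printed interval exactly.
* Strategy labels are behavioural shorthand; the package deliberately
  makes no claim about underlying reference-frame use by individuals.
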
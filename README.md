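# pointorigin

Analysis toolkit for **virtual point-to-origin experiments**: homing tasks
in which an observer passively views a simulated two-segment excursion — a
straight path, a turn, a second straight path — through a landmark-free
star field, and then indicates the egocentric quadrant (front-left,
front-right, back-left, back-right) that contains the origin of
locomotion. Observers split sharply into answer patterns conventionally
attributed to four strategies:

| strategy    | behaviour                                                        |
|-------------|------------------------------------------------------------------|
| turner      | updated the simulated heading; points back-contralateral to the turn |
| non-turner  | did not update heading; left-right mirrored answer                |
| non-mover   | anterior pointing in the correct hemisphere (origin→endpoint direction) |
| spinner     | anterior pointing in the mirrored hemisphere (as if turned 180° before pointing) |

The package is aimed at spatial-cognition researchers who want a tested,
reproducible pipeline for this class of experiment: it simulates the
stimulus kinematics and derives each strategy's predicted quadrant, labels
answers and classifies participants by a consistency criterion, models
classification on demographic factors, extracts odds ratios under every
baseline rotation, and benchmarks model accuracy against bootstrap nulls.
A synthetic-cohort generator with the same statistical structure makes
every downstream stage testable without raw questionnaire data.

## The model

Participant classification `Y ∈ {no-preference, non-turner, turner,
non-mover}` (spinners are excluded before modelling due to sparseness) is
regressed on ethnicity (Caucasian / Chinese / Other), response mode
(pictorial / text) and gender (female / male) with all interactions, via a
baseline-category multinomial logit:

    P(Y = k | x) = exp(x'β_k) / Σ_j exp(x'β_j),   β_no-preference ≡ 0

with dummy coding against the reference levels Caucasian, pictorial,
female (12 design terms per outcome). Terms are screened with
likelihood-ratio chi-square tests. Pairwise odds ratios between outcomes
`t, b` for a factor contrast `a` vs `b*` at covariate profile `x0` are

    OR = exp[(η_t(a) − η_t(b*)) − (η_b(a) − η_b(b*))]

with Wald intervals on the log scale; enumerating every choice of
reference levels ("baseline rotation") surfaces all pairwise contrasts.
Classifier accuracy is benchmarked against percentile intervals of two
bootstrap nulls: uniform random classification (naive; chance = 25% for
four classes) and classification drawn from the observed class
frequencies (weighted; mean → Σ p²).

Trial geometry is a five-phase trajectory (linear acceleration, cruise,
turn with a symmetric triangular angular-velocity profile — duration
`2·sqrt(|θ|/α)` — cruise, deceleration). Each strategy corresponds to a
reference frame in which the homing bearing is expressed, which fixes its
predicted quadrant; for turn magnitudes below 135° the strategy→quadrant
map is a bijection.

## Worked example

```r
library(pointorigin)

spec <- path_spec(-60)          # 60° left turn, default kinematics
end_pose(spec)
#> <pose> x = -48.874 m, z = 74.652 m, heading = -60.000 deg
strategy_quadrant_map(-60)
#>     turner non-turner  non-mover    spinner
#>       "BL"       "BR"       "FL"       "FR"

# odds ratio from a reported coefficient table, no refitting needed:
odds_ratio(reference_coefficients(), "turner", "non-turner",
           "gender", "male", "female",
           profile = list(ethnicity = "Caucasian", response_mode = "pictorial"))
#> <or_record> turner vs non-turner | gender: male vs female | ethnicity=Caucasian, response_mode=pictorial
#>   OR = 3.604

# full pipeline on a synthetic 501-participant cohort:
res <- run_analysis(run_config(seed = 1))
res
#> <po_run> synthetic cohort: 501 -> 501 analysed (0 incomplete, 0 spinner)
#>   training accuracy 0.509 | 58 significant ORs
#>   null accuracy: naive [0.212, 0.287] outside-high | weighted [0.265, 0.341] outside-high
```

The end pose says the left-60° excursion terminates 48.9 m left and
74.7 m ahead of the origin facing −60°; the homing direction is back-left
for a turner and back-right for a non-turner, matching the map. The OR of
3.60 says that, among Caucasian participants answering pictorially, the
odds of a turner (rather than non-turner) classification are 3.6 times
higher for males. In the pipeline run, the fitted model's 50.9% training
accuracy lies above both bootstrap null intervals — better than chance
under either null.

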
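---
title: "Simulating standardized test-set construction for diabetic retinopathy grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating standardized test-set construction for diabetic retinopathy grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drtestset)
```

## The problem

Regulatory evaluation of AI medical devices for diabetic retinopathy (DR)
screening needs test sets that are independent of the developers, annotated
to a defensible reference standard, and reported in a way that lets
algorithms be compared. `drtestset` models that whole workflow at the label
level: a seven-class cohort (no apparent DR, mild / moderate / severe NPDR,
PDR, other fundus diseases, ungradable), a panel of confusion-matrix
annotators recruited through a qualification exam, a two-round adjudication
process that produces the reference standard with provenance accounting,
rater-agreement statistics, and per-class diagnostic evaluation of
algorithms under test (AUTs) that emit binary referral decisions
(classes 2–4 are referrable, classes 0, 1, 5, 6 are not).

No pixels are simulated anywhere: once annotation starts, the entire
analysis operates on class labels, so an image is a record
`(image_id, true_class, raw_label, site_id, camera_id, excluded)`.

## The reader model

Every labelling source — junior annotator, senior arbitrator, raw hospital
label — is a 7×7 row-stochastic confusion matrix `P(assigned = j | truth = i)`.
`adjacent_confusion(accuracy, adjacency_weight)` builds these: the diagonal
is `accuracy` on every row, and for the ordinal severity classes 0–4 a
fraction `adjacency_weight` (default 0.7) of the error mass falls evenly on
the severity-adjacent classes within 0–4, the remainder spreading uniformly
over the other classes. Classes 5 and 6 are treated as non-ordinal, so
their errors are uniform. The adjacency structure is this package's own
modelling assumption — graders confuse neighbouring severities (the
microaneurysms of mild NPDR against the blot hemorrhages of moderate NPDR)
far more often than distant ones — and `adjacency_weight` is exposed
precisely because no empirical error structure is available to fit.

Raw hospital labels default to a diagonal of 0.6164, the accuracy level
observed for uncurated labels; junior annotators are simulated in the
0.75–0.90 accuracy band with exam-admitted panels landing near 0.83.

Randomness is organised as one root seed with named substreams
(`substream_seed(root, actor_id)`): every reader, sampler and AUT draws
from its own stream, so adding or removing one actor never perturbs
another's reads. This is what makes the blinding property testable — the
round-1 tests assert that deleting a reader leaves the other reads
byte-identical.

## Qualification

Candidates sit an exam of 100 photographs composed of 18% nonreferrable DR,
45% referrable DR, 32% other ocular diseases and 6% ungradable images.
Those percentages sum to 101; they are renormalized proportionally, since
nothing privileges one category, and apportioned by largest remainder (the
renormalized quotas 17.82 / 44.55 / 31.68 / 5.94 yield counts
18 / 44 / 32 / 6). Scoring is exact 7-class matching; a referral-level
option exists because the original scoring granularity is not documented.
Admission is inclusive at the threshold (accuracy ≥ 0.80): a reported
passing candidate sat at exactly 80%, so the strict reading ("greater
than 80%") would contradict the observed outcome; both threshold and
strictness are configurable. A 120-item exam preset is available
(`exam_spec(n_items = 120)`) because the exam size is reported
inconsistently (100 in the protocol, 120 in the results); the 100-item
protocol value is the default.

For a candidate whose confusion diagonal is `a`, the class-level exam score
is Binomial(`n_items`, `a`)/`n_items` regardless of item composition, so the
admission probability is the binomial tail `P(X ≥ 80)` — a property the
test suite checks by simulation.

## Two-round adjudication

Round 1: each image is read blind by one group of 3 juniors. Unanimous
images form the *prequalified pool*; discordant ones the *arbitration
pool*. `floor(0.10 × pool)` prequalified images are sampled for inspection
(3694 concordant images yield exactly 369 samples). Round 2: a senior panel
of three (one leader) reads all arbitration and sampled images
independently; the consensus is the modal label, and when all three
disagree the leader's label stands. That tie rule is a deterministic
surrogate for the panel's discussion, which has no documented model; the
consensus rule is a plug-in (`round_two(..., consensus = )`) so alternatives
can be substituted.

Final labels: unsampled prequalified images keep their unanimous round-1
label; sampled and arbitration images take the round-2 label. Provenance is
classified from the round-1 votes against the final label — `unanimous`,
`majority` (2 of 3), `minority` (1 of 3), or `arbitration_only` (no vote
matches). A sampled image whose unanimous label is overturned in round 2 is
deliberately reclassified by the same rule (it can become
`arbitration_only`): in the real workflow the directly-accepted consensus
share sits *below* the unanimous-pool share, which implies overturned
unanimous labels were re-attributed. Whether fully split 1-1-1 votes should
be reported separately from true minorities is ambiguous in the field's
accounting, so `provenance_summary(distinguish_split = TRUE)` exposes both
readings.

If the sampled disagreement rate exceeds 0.05, inspection escalates:
another sample of the same rate is drawn (`double_sample`), at most twice,
after which the whole remaining prequalified pool goes to round 2
(`full_review`). The threshold, action and cycle cap are this package's
quantification of a qualitatively described policy.

## Agreement statistics

`fleiss_kappa()` implements the standard multi-rater chance-corrected
agreement on an items × categories count table; `cohen_kappa()` the
two-source unweighted version. Both are unweighted by default because no
weighting scheme is documented for the reference workflow; a linear-weight
variant for the ordinal classes was considered and rejected as
surface-without-evidence. When expected agreement is 1 (all ratings in one
category) the conventional value 1 is returned for perfect observed
agreement and 0 otherwise, with a warning — a continuity convention the
tests exercise explicitly. Both implementations are cross-checked against
independently coded direct-formula oracles on exhaustively enumerated small
tables, to 1e-12.

Intra-rater repeatability defaults to exact percent agreement — the honest
statistic for nominal labels — with ICC(2,1) on integer-coded labels
available (`intra_rater(method = "icc")`, verified against an `aov()`
variance-components oracle) for comparability with reports that quote an
intraclass correlation for categorical grades.

Because the Fleiss kappa of the reference study is not clearly attributed
to exam data or production round-1 data, the pipeline computes both
(`agreement$fleiss_kappa` and `qualification$exam_fleiss`).

## Evaluation and the reconstruction identity

AUT outputs are modelled as binary referral calls: the published overall
and per-class tables are fully explained by binary decisions, making this
the minimal consistent model; a 7-class output adapter
(`read_aut_calls()`) maps class outputs through `to_referrable()` before
scoring. Per-class decision capability is the fraction of a class's images
given the correct referral decision — a per-class sensitivity for classes
2–4 and specificity for the rest. A class absent from the reference is
reported `NA`, never 0 or 1.

The exact identity the package exhibits on every run:

```
sensitivity = Σ_{c∈{2,3,4}} n_c · cap_c / Σ_{c∈{2,3,4}} n_c
specificity = Σ_{c∈{0,1,5,6}} n_c · cap_c / Σ_{c∈{0,1,5,6}} n_c
accuracy    = Σ_c n_c · cap_c / N
```

`reconstruct_overall()` evaluates it with one numerical refinement: each
numerator `cap_c · n_c` is snapped to the nearest integer, because a
capability is a correct-decision count over an integer denominator. For
capabilities measured on the same cohort the snap is a no-op (the identity
holds to 1e-12 on every stochastic run, seeds 1–20 at the full 6327-image
size), while for capabilities quoted at 6 decimals it repairs the rounding
and reproduces the published overall table *exactly* at 6 decimals for all
five benchmark AUTs — without snapping, several cells are off by one unit
in the sixth decimal. Report rounding is 6 decimals; all internal
computation is unrounded.

## What the simulation does and does not show

The generator reproduces the *statistical structure* the analysis assumes:
class-conditional reader errors, independent blinded reads, the published
cohort composition (`testset_composition()`: 873 / 262 / 1118 / 579 / 540 /
2600 / 355, total 6327), raw labels at 61.64% accuracy, and the five
benchmark AUT capability vectors. Passing tests therefore demonstrate the
correctness of the workflow arithmetic, the agreement statistics and the
evaluation identities — not that real annotators behave like homogeneous
confusion matrices. Real reading panels have image-difficulty effects,
correlated errors within hard images, fatigue and drift; none of these are
modelled (reads are conditionally independent given the true class), which
is why emergent quantities like the unanimity share or Fleiss kappa land
*near* but not *on* the published panel outcomes, and why those panel
outcomes are checked as properties (parameter recovery within three
binomial standard errors) rather than as point targets. Site and camera
strata are label-neutral by default for the same reason: no site effect is
documented, and an invented one would only blur the workflow properties
under test.

## Defaults and problem sizes

| Parameter | Default | Why |
|---|---|---|
| cohort composition | 6327 images as above | the reference test set |
| adjacency_weight | 0.7 | most errors on neighbouring severities |
| raw-label diagonal | 0.6164 | observed raw-label accuracy |
| candidates | 47, accuracy U(0.75, 0.90) | recruitment pool and reported accuracy band |
| juniors | 15 admitted, 5 groups of 3 | workloads land in 1000–1500 images |
| senior accuracies | 0.92, 0.92, 0.95 (leader) | seniors outperform the junior band; leader best |
| sample_rate | 0.10, floor | published sampling rule |
| escalation | threshold 0.05, double_sample, ≤2 cycles | quantified from a qualitative policy |
| exam pool | 150 images/class | comfortably covers category demand |
| repeat readings | 200 images/annotator | stable intra-rater estimate at panel scale |

The test suite runs the full 6327-image pipeline twice (determinism check)
plus one full-scale smoke run and twenty 6327-image identity runs; the
whole suite completes in well under a minute on one CPU. Monte-Carlo
recovery tests use 10^4–10^5 draws, sized so that three-standard-error
bands are decisive.

## Degenerate inputs and numerical choices

Empty prequalified pools sample zero images without error; an empty
inspection sample warns and does not escalate. Excluded records are refused
by every reader and never enter adjudication or evaluation. Confusion rows
must sum to 1 within 1e-9. Kappa degeneracies return the conventional
values described above. Largest-remainder ties break by category order.
`senior_consensus` breaks a (theoretically possible with larger panels)
two-mode tie in favour of the leader's label, else the lower severity code.
Workload bounds are checked only when supplied, so toy configurations
(one group, ten images) remain expressible.
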
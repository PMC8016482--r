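---
title: "Modeling generalization via latent task states: task, models, and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling generalization via latent task states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskstates)
```

## The scientific problem

Many tasks that differ in their surface features share an abstract structure.
An agent that represents that structure can transfer what it learns in one
setting to another without any direct experience or feedback — the hallmark of
an abstract, generative task representation. `taskstates` implements a
complete desk-scale pipeline for studying this ability with an acquired
equivalence design: a three-phase "category betting" task in which nine scene
contexts cluster into three *latent states* (LSs) because contexts in a
cluster share the same category-value associations.

* **Initial training.** Three old item categories (hands, foods, leaves) are
  trained in all nine contexts. Within each latent state exactly one category
  has a high (0.9) reward probability and the others a low (0.1) one; selling
  gains +50 or loses −25 gold. Contexts are introduced in three groups of
  three ("roadwork" events), two 54-trial blocks per group (nine conditions ×
  6-trial mini-blocks, nested by context), followed by a 216-trial reminder
  block over all nine contexts (8-trial mini-blocks).
* **New-category training.** Three new categories (faces, animals, objects)
  are trained in one context per latent state (90 trials, 10-trial
  mini-blocks); two of the three new categories are high-valued per state and
  the payoffs become +50/−100.
* **Generalization.** The six held-out contexts are probed with the new
  categories, without feedback, first in a 180-trial mini-blocked phase
  (18 conditions × 10) and then in six pseudo-randomized 180-trial runs
  (1080 trials over two sessions; payoffs doubled to +100/−200). Correct
  responding is only possible by transferring new-category values through the
  latent state linking each held-out context to its trained partner.

The generator reproduces this layout exactly, including the sequence
statistics: randomized runs are rejection-sampled so that consecutive trials
share a latent state at the chance rate 6/18 (33%) and a context at 3/18
(16.7%), within a ±5 percentage-point tolerance. Training inter-trial
intervals are lognormal with a post-clipping mean of 1 s on [0.5, 4] s
(log-scale SD 0.5, a shape choice; the distribution is stated only by its
mean and range); scanner-run ITIs are uniform on [1, 9] s, the stated range.

A note on payoffs: with the stated probabilities and payoffs the marginal
expected value of selling blindly is +2.5 gold in initial training and −5
gold afterwards, not exactly zero; the probabilities and payoffs are
implemented exactly as specified and no adjustment is made.

## Spreading-activation models of generalization RTs

Four memory-network models map a generalization trial sequence to predicted
reaction times. All share the same dynamics. Each node $i$ carries an
activation $a_i \in [0, 1]$, initialized at 0, updated after every trial by a
Rescorla–Wagner step toward the asymptote 1:

$$a_i \leftarrow a_i + r_i\,(1 - a_i),$$

where the rate $r_i$ depends on the node's relation to the probed condition.
Direct retrieval runs at rate $\alpha_1$, mediated retrieval contributes a
factor $\alpha_2$ per intervening associative step, and incidental retrieval
of task-related but currently irrelevant nodes runs at $\alpha_3$; multi-step
paths multiply their rates, giving a power-law fall-off with path length. The
predicted raw RT of a trial is the joint asymptotic activation of the probed
read-out nodes minus their current, *pre-update* activation — retrieval is
slow exactly when the probed representation is weakly activated. Using the
pre-update state makes the very first generalization trial maximally slow
(raw RT at its ceiling), matching the deliberative first inference.

The models differ only in their architecture:

* **CAR** (conjunctive associative retrieval): one node per context–category
  conjunction (27 initial-training, 9 new-training, 18 generalization
  conjunctions). Generalization is carried by chains of mediated retrieval
  through conjunctions that share values. Read-out: the current trial's
  conjunction ($\mathrm{RT} = 1 - a$).
* **IAR** (independent associative retrieval): 9 context nodes plus
  category-value nodes instantiated as experienced, linked by shared
  associations. Read-out: current context + current category-value node.
* **LS**: 3 latent-state nodes plus state-by-category nodes, no context
  representation at all — activation transfers fully between contexts of a
  state. Read-out: current state + state-category node.
* **HLS** (hierarchical latent state): latent-state, context, and
  context-by-category nodes with contexts nested under their states, so
  context and category activation is inherited from the state
  ($\alpha_1^2$, $\alpha_1^3$ for the current context and context-category).
  Read-out: current context + context-category node.

Every node receives exactly one rate per trial from an enumerated relation
class; where two textual retrieval pathways would reach the same node, the
more direct (higher-priority) class wins. Two such choices deserve note.
First, in HLS the non-probed categories of the *current* context update at
$\alpha_1 \alpha_2^2$, the same rate as categories nested in the other
contexts of the active state (the alternative reading $\alpha_1^2 \alpha_2$
differs only in a mediated-path ordering; at fitted parameters the two are
close and the choice does not alter the model ranking). Second, in CAR the
new-training conjunction matching the probed category takes the direct rate
$\alpha_1$ rather than the mediated $\alpha_2^2$ it would also qualify for.
All node updates within a trial are computed simultaneously from the
pre-trial state.

Predicted raw RTs are z-scored across the included trials before comparison
with (z-scored) observed RTs, so any affine choice of read-out is
inconsequential — which also resolves the ambiguity of a "context + category"
read-out for CAR, where no separate context node exists. If the raw
predictions are constant (e.g. all rates zero) the z-score is degenerate; the
prediction is returned as a flagged zero vector and treated as maximally
penalized during fitting.

### Implementation note: a closed-form prediction engine

Because the update multiplies complements, $1 - a_i$ after $T$ trials equals
$\prod_{t \le T} (1 - r_{i,t})$, and $r_{i,t}$ only depends on the trial's
relation class. `predict_sequence()` therefore precomputes, for each trial's
read-out nodes, the count of earlier trials in each relation class; a
prediction at new parameter values then costs two small matrix–vector
products. The explicit trial-stepping engine (`step_trial()`) is retained and
the two are verified to agree to machine precision, alongside hand-derived
RT series for all four models.

## Maximum-likelihood fitting and recovery

The likelihood is a Gaussian linear regression of observed on predicted
z-scored RTs: slope, intercept, and residual variance are profiled at their
least-squares/ML values (the variance floored at $10^{-6}$ to keep perfect
fits bounded), leaving $(\alpha_1, \alpha_2, \alpha_3) \in [0,1]^3$ as the
only searched parameters. `fit_model()` minimizes the negative log-likelihood
with bounded L-BFGS-B from 30 uniform random starting points by default
(`cross_model_recovery()` uses 10 per fit — ample for a smooth
three-parameter objective — to keep its 320 fits fast). Only correct
generalization trials enter a fit; fits with fewer than 10 usable trials are
refused.

Two recovery utilities validate the machinery on synthetic data, standing in
for analyses that would otherwise require participant data:

* `cross_model_recovery()` simulates RTs from each model (default: 540-trial
  randomized sequences, noise SD 0.5 z-units, 20 replicates, shared
  generating parameters $(0.9, 0.5, 0.1)$) and fits all four models to every
  dataset. Distinguishable models show diagonal dominance — each generator is
  best fit by itself.
* `parameter_recovery()` refits the generating model to its own simulations
  (noise SD 0.3) and reports per-parameter recovery error and how often the
  generated ordering $\alpha_1 > \alpha_2 > \alpha_3$ survives.

`rmsd_by_trial_type()` compares models where they differ most: trials are
labeled as the first trial of the $n$-th context of the $m$-th latent state
in presentation order, as category mini-block switches, or as within-mini-block
trials. Associative models without a latent-state representation systematically
overestimate RTs on category-switch trials, because newly trained
category-values reach them only through mediated retrieval.

## Behavioral analyses

* `fit_power_curve()` fits $y = a\,t^{x}$ to a within-mini-block curve by
  least squares, best of 10 unconstrained BFGS runs started from standard
  normal draws. On noiseless in-class data the exact parameters are
  recovered.
* `learning_curve_rates()` builds the position-wise mean accuracy (or RT)
  curve across mini-blocks and returns the fitted rate exponent. Options
  restrict the curve to the first $k$ mini-blocks or to the first mini-block
  of each of the first three contexts, matching how training and
  generalization speeding curves are summarized.
* `switch_cost_analysis()` log-transforms correct-trial RTs, z-scores them
  within session per subject, drops run-initial trials (no previous trial),
  and contrasts latent-state switch versus stay *among context-switch trials
  only*, so a state switch is never confounded with a mere context change.
  A context-and-state stay cell quantifies the additional repetition benefit.
* `ls_repetition_curves()` organizes the mini-blocked generalization phase by
  latent-state (1–3) and context (first/second) presentation order: the
  second context of an already-activated state should start faster and speed
  up less than the first.

Group-level inference uses paired/one-sample t-tests (and sign-flip
permutations in the RSA module); mini-block curves are averaged within
subject at each position before fitting, a choice the analyses leave open.

## Representational similarity analysis

Hypothesis RDMs over the 18 generalization conditions use ordinal distances:
1/2 for same/different latent state, context, and value (any affine choice is
equivalent after predictor z-scoring); the category RDM encodes the animacy
gradient 1 (within), 2 (faces–animals), 3 (animals–objects), 4
(faces–objects), the animals–objects cell being fixed by the ordering
constraint rather than a stated value; the visual RDM takes Euclidean
distances between 2-D context coordinates from the similarity judgment task.
Interactions are elementwise products of z-scored lower-triangle vectors.

`crossnobis_rdm()` estimates the empirical RDM by cross-validated Mahalanobis
distances: for conditions $i, j$ and runs $A \ne B$,
$d_{ij} = \mathrm{mean}_{A \ne B}\,
(b_{iA} - b_{jA})^\top \Sigma^{-1} (b_{iB} - b_{jB}) / V$.
Cross-validation across independent runs removes the noise bias, so null
distances average zero and can be negative. The noise covariance $\Sigma$ is
estimated from run-centered residuals with Ledoit–Wolf-style shrinkage of the
off-diagonal toward zero, the intensity chosen analytically from the data;
the fold scheme and regularization are estimator choices made here, at the
dataset/ROI level (no searchlight traversal or cluster inference).

`rdm_regression()` regresses the (unstandardized) empirical lower triangle on
the z-scored hypothesis vectors plus an intercept, all predictors competing
simultaneously; rank deficiency is flagged and resolved by pseudo-inverse.
`group_test()` applies one-sample t-tests (optionally sign-flip permutations)
to per-subject coefficients.

## The synthetic-data generator

`simulate_subject_behavior()` produces a full experiment per subject.
Training accuracy follows a saturating within-mini-block curve from chance
(0.5) toward $1 - \text{lapse}$ at rate `training_learning_rate`;
generalization choices are correct with probability $1 - \text{lapse}$
(default lapse 0.02, near the observed 96% accuracy regime). Generalization
RTs come from the agent's generative activation model: the z-scored
prediction is mapped to seconds by $s \cdot z + o$ plus Gaussian noise of SD
$s \cdot \sigma_z$ (defaults $s = 0.5$ s, $o = 1.2$ s, $\sigma_z = 0.3$),
floored at 0.2 s. This calibration puts post-first-trial RTs near 1.1–1.2 s
with a several-second first inference, the qualitative regime of the observed
data, without asserting any printed means.

One dynamical choice matters: activation is monotone and saturating, so a
single network carried across all 1260 generalization trials would make
late-run predictions constant and wash out switch costs. The simulator
therefore re-initializes the network at generalization onset *and at each
scanner run* — re-engagement of retrieval dynamics after a break — which
preserves latent-state sensitivity in every run. Model fitting itself is
unaffected (fits target the mini-blocked phase, one fresh network).

`generate_pattern_dataset()` plants factor codes (latent state, context,
category, value) as orthonormal channel patterns scaled by per-factor
amplitudes, adds compound-symmetric correlated Gaussian noise per run, and
provides matched residuals for covariance estimation. Orthonormal codes make
planted-effect recovery interpretable — real patterns offer no such
orthogonality, so passing tests demonstrate estimator correctness, not
real-data performance. Note that crossnobis distances are quadratic in
pattern amplitude, so planted regression betas scale with amplitude squared.
`generate_visual_similarity_coords()` draws context coordinates uniformly on
the unit square, independent of the latent-state assignment; independence
from the LS structure holds among distinct-context pairs (same-context pairs
have visual distance 0 and are within-state by construction).

## Problem sizes and numerical choices

Recovery analyses use 540-trial sequences, 20 replicates, and 10 restarts
per fit; the RMSD comparison uses 12 simulated subjects on the 180-trial
blocked phase; behavioral pipelines use 16-subject cohorts; RSA calibration
uses 200 null datasets and 2000 null cohorts. These sizes give stable
statistics on a single CPU in minutes. Other numerics: the z-score
degeneracy tolerance is an SD below $10^{-10}$; optimizer bound overshoot
from finite-difference gradients is clamped; rejection sampling of run
orders errs after 1000 attempts rather than looping.

## What the synthetic tests do and do not show

Passing recovery and pipeline tests establishes that the implementation is
internally correct and that the analyses detect the structures they target at
realistic noise levels. They do not certify the models against human data:
real RT distributions are heavy-tailed, real learning is not a fixed lapse
curve, real voxel patterns are not factor-orthogonal, and per-participant
best-fit parameters vary. Quantities that depend on the deposited participant
data (NLL sums, best-model counts, printed test statistics) are outside what
synthetic cohorts can reproduce and are deliberately not asserted anywhere.
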
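---
title: "Methods: division of labour and performance in tandem-running ants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: division of labour and performance in tandem-running ants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemdol)
```

## The system and the questions

*Temnothorax* ants recruit nestmates to candidate nest sites by tandem
running: a knowledgeable leader physically guides a single follower from the
old nest to the new one.  During a colony emigration dozens of tandem runs
occur, each either *successful* (the pair reaches a new nest together) or
*failed* (the pair loses contact en route).  `tandemdol` implements a
complete analysis chain for asking how the division of labour between
leading and following relates to the performance of tandem teams:

1. How specialised are individuals, and how repeatable are their roles
   across emigrations?
2. How often do individuals switch between leading and following within an
   emigration, and does switching depend on their role consistency?
3. Does removing the most prominent leaders and/or followers before a test
   emigration degrade tandem performance?
4. Which components of a pair's experience predict tandem success,
   straight-line progress of failed runs, and duration of successful runs?

The experimental design mirrored throughout the package is: several
colonies perform four *baseline* emigrations that establish per-ant task
profiles, then a targeted removal is applied, and a fifth *test* emigration
measures performance.

## Experience metrics

For each ant and each role the package computes two complementary
quantities over the baseline emigrations:

* **Consistency** `C_L` (`C_F`): the number of baseline emigrations in
  which the ant led (followed) at least once — an integer from 0 to 4 under
  the default design.
* **Activity** `A_L` (`A_F`): the total number of tandem runs the ant led
  (followed) across all baselines.

Consistency captures *reliability across contexts*, activity captures
*volume*; both are needed because tandem running is unevenly distributed
across emigrations.

Per-tandem task switching is scored from each ant's acts ordered by tandem
rank within each emigration.  `P(F->L)` is the fraction of an ant's
follower acts that have a same-emigration successor act and whose successor
is a leader act; `P(L->F)` analogously.  Transitions never cross emigration
boundaries: an emigration's last act has no successor.  For the textbook
sequence — following once then leading three times in one emigration
(F,L,L,L), then following twice and leading once in the next (F,F,L) — two
of the three follower acts with successors are followed by leading, so
`P(F->L) = 2/3`, and no leader act is followed by following, so
`P(L->F) = 0`:

```{r}
compute_switch_probabilities(worked_example_events())[1, ]
```

Population-level switching is reported as the pooled ratio (total switches
over total scorable source acts), not the mean of per-ant ratios, so ants
contribute in proportion to their data; the per-ant mean is also returned
because figures of per-ant points use it.  Cross-emigration repeatability
uses Spearman rank correlations of per-ant counts — the counts are heavily
skewed, so a rank-based estimator is the defensible default — excluding
ants with zero counts in both emigrations of a pair.

## Permutation and resampling nulls

Two associations are tested against explicit nulls.

**Within-pair asymmetry.**  The statistic is the mean over colonies of the
colony-mean per-tandem difference `C_L(leader) − C_L(follower)`.  The
default null permutes the baseline profiles among each colony's tandem
runners while keeping every tandem's leader/follower assignment.  When
baseline experience is unrelated to test-emigration roles, the profile
labels are exchangeable, so this null is calibrated by construction; it
also preserves the fact that the same ant may appear on both sides of
different tandems, which an independent re-draw of leaders and followers
destroys (we ship that re-draw scheme too, as `scheme = "redraw_pools"`,
and measured it to be conservative for exactly this reason).

**Switching vs consistency.**  Naively shuffling consistency values among
ants is *not* a valid null here: switching into leading is what creates
leading consistency, so `P(F->L)` and `C_L` are mechanically coupled even
when every ant shares identical switching probabilities.  In calibration
runs on a specialisation-free generator the shuffle null rejected over 90%
of the time.  The default scheme is therefore a *sequence bootstrap*:
every ant's within-emigration role sequences are regenerated from the
pooled switching process — each ant's first acts keep their observed roles
(they reflect recruitment into the emigration, not switching), transitions
are resampled with pooled probabilities estimated leave-one-ant-out — and
both the switching probabilities and the consistencies are recomputed from
the resampled sequences.  The test then asks whether the observed slope of
`P(F->L)` on `C_L` exceeds what the shared process alone produces.  The
shuffle scheme remains available (`scheme = "shuffle_consistency"`) for
sensitivity analysis.

Empirical p-values always use the finite-sample `+1` correction,
`(1 + #extreme) / (1 + n)`, so p is never zero; two-sided p-values are
`2 × min(one-sided)` capped at 1, which is robust to asymmetric nulls.

## Targeted removal design

Tandem runners (ants with at least one baseline tandem) are ranked
hierarchically for each role: by consistency, ties broken by activity,
residual ties by ant id so the ordering is total and reproducible.  Each
treatment removes half of the runner pool, assembled from role quartiles
of size `round(0.25 × n)`:

| treatment          | removed                                        |
|--------------------|------------------------------------------------|
| `leader_removal`   | top leaders + bottom followers                 |
| `follower_removal` | top followers + bottom leaders                 |
| `both_removal`     | top leaders + top followers                    |
| `control`          | bottom leaders + bottom followers              |

The control removes the same *number* of ants while leaving prominent
leaders and followers in place, separating the disturbance of removal from
the loss of expertise.  Because an ant can sit in both selected quartiles,
and because `2 × round(0.25 n)` need not equal `round(0.5 n)`, the second
role's ranking is walked in its quartile direction, skipping ants already
removed, until exactly `round(0.5 × n)` ants (rounding half away from
zero) are removed.  This back-fill preserves the stated 50% removal
invariant for every pool size.

## Performance metrics

Performance analyses use only forward tandem runs without follower
switches; reverse runs are behaviourally distinct and a switched follower
has ambiguous experience.  Three metrics are computed on the test
emigration:

* **success rate** — the fraction of runs reaching a new nest;
* **straight-line distance** (failures only) — `D − l`, with `l` the
  beeline distance from the break-up point to the nearest new-nest
  entrance and `D = 35` cm the common initial-to-new distance.  A break-up
  at a new-nest entrance scores 35 cm, one at the initial nest scores 0.
  Pairs that wander beyond `D` from both nests receive negative values;
  these are reported as-is (the formula is applied unconditionally) and are
  identifiable by sign, rather than silently clipped;
* **time taken** (successes only) — `t_end − t_start`, i.e. the interval
  from leaving the initial nest to arriving at the new nest.

Colony summaries average within colony; grand means are means of colony
means so that colonies, not tandem counts, are the unit of replication.

## Colony-level treatment models and multimodel inference

Treatment effects on colony-level responses are tested with mixed models
(binomial GLMM on success/failure counts with a logit link; Gaussian LMMs
for the other two metrics) with a random intercept for replicate, a
likelihood-ratio chi-square for the treatment term, and all six pairwise
contrasts on the estimated marginal means with Benjamini–Hochberg
correction.

Individual-level models relate per-tandem performance to the global fixed
structure `C_L + A_L + C_F + A_F + rank + C_L:C_F + A_L:A_F`, with nested
random intercepts for replicate, colony within replicate, leader identity
and follower identity (the same ant may lead or follow repeatedly).  The
binary success response uses a binomial GLMM (Laplace approximation;
`nAGQ = 0` is available and used for large replicated model-set runs, where
it changes individual estimates marginally but leaves rankings and
importances essentially untouched); Gaussian responses are fitted by
maximum likelihood rather than REML so that models differing in fixed
effects are comparable by information criteria.

Rather than stepwise selection, the package fits **all 50
marginality-respecting subsets** of the global model (interactions only
alongside both main effects), ranks them by AICc — the small-sample
correction is the default because test-emigration datasets have a few
hundred tandems at most; plain AIC is a switch — and computes Akaike
weights `w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2)`.  The **95% confidence set** is
the smallest top-ranked prefix with cumulative weight ≥ 0.95.  Within it
(weights renormalised):

* **relative importance** of a term is the summed weight of member models
  containing it;
* **model-averaged coefficients** use full (zero-substitution) averaging by
  default — a term absent from a model contributes 0 — with conditional
  averaging as an option, and unconditional standard errors
  `SE = Σ w_i sqrt(se_i² + (β_i − β̄)²)` combining within-model sampling
  variance and between-model spread.  A coefficient is called significant
  when `|β̄| > 1.96 SE`.

Predictors are standardised (zero mean, unit SD) on the analysed rows
before fitting so averaged coefficients are comparable across terms.
Collinearity is summarised per confidence-set model by the mean absolute
pairwise predictor correlation and variance inflation factors
`VIF_j = 1/(1 − R²_j)`; a *filtered* confidence set drops member models
containing any predictor pair with `|r|` above a threshold (default 0.7),
as a guard against importance leaking between near-redundant terms.
Models that fail to fit are excluded with a logged reason and the weights
renormalised.

## The synthetic emigration generator

The generator exists for two purposes: calibration studies (type-I error
of the permutation tests, parameter recovery of the model-averaging chain)
and worked examples at realistic scale.  It is act-sequence based:

1. Each worker carries latent logit-scale propensities for participation,
   leading and following; leading and following propensities are
   negatively correlated by default (`role_cor = −0.3`), creating
   lead/follow specialists.
2. Each emigration, a set of core participants is drawn by participation
   propensity.  Each core ant receives a chain of tandem acts whose roles
   follow a per-ant Markov switching process: chains mostly *start as
   follower acts* (`lead_state_p = 0.08` plus the leading propensity) and
   switch into leading with per-act probability
   `plogis(qlogis(pi_FL) + fl_mod (C_L-to-date − switch_center))`, so
   established leaders re-enter leading readily — the structure implied by
   a high observed P(F->L) and the observation that almost all leaders
   also follow within an emigration.
3. Tandem runs are assembled by consuming chain acts in order and pairing
   the next leading act with the next following act; when one role is
   under-supplied a previously uninvolved nestmate is recruited for a
   single act, reproducing the large pool of one-time followers.  Because
   every chain act is realised in order, observed transition statistics
   match the generating Markov parameters without selection bias (an
   earlier pool-based design failed exactly this check: pooled P(F->L) was
   0.63 when the generating value was 0.5, because switching correlated
   with being drawn again).
4. Success is Bernoulli with
   `logit(p) = alpha + beta_CL · C_L-to-date(leader) + gamma_rank · rank`;
   failures break up along the corridor to a new nest with Gaussian lateral
   scatter (`breakup_sd = 3` cm) clipped to the 46 × 78 cm arena;
   successes draw log-normal durations (median 600 s).
5. All randomness flows from one root seed through per-colony substreams,
   so colonies are independent and identical configurations reproduce
   byte-identical event files.

Defaults were calibrated once, by simulation, to the summary statistics
the analyses assume: ~32–35% of a 90-worker colony participates in at
least one tandem per emigration, ~19% lead at least once versus ~28%
following at least once, pooled switching near P(F->L) = 0.57 and
P(L->F) = 0.16, and a median of ~35 tandem runs per emigration (clipped to
13–66).  `pi_FL`/`pi_LF` are per-act chain parameters; their defaults
(0.53/0.13) sit slightly below the pooled targets because the positive
consistency modulation lifts the pooled values.

What the generator does *not* emulate: spatially explicit movement and
pheromone trails, nest-choice dynamics between the two new nests, temporal
clustering of tandems within an emigration, and any dependence of
performance on arena geometry beyond the break-up scatter.  Passing tests
therefore demonstrate that the *analysis chain* behaves correctly on data
with the assumed statistical structure, not that real colonies satisfy
that structure.

## Numerical choices and degenerate inputs

* Events arriving without ranks are ranked by start time, ties broken by
  file order.  Ranks must be gapless within (colony, emigration).
* Event files are CSV, UTF-8, booleans as `true`/`false`, missing break-up
  coordinates as empty fields, numerics at 6 significant digits —
  re-writing a read file is byte-identical.
* Undefined switching probabilities (no scorable source act) propagate as
  `NA` and are excluded from group summaries with counts reported.
* Quartile and half-pool sizes round half away from zero; removal requires
  at least 4 runners.
* Mixed-model convergence failures are flagged and the affected subset
  model is dropped from the set; singular fits (zero variance components)
  are retained, as usual in this tier of analysis.
* Random terms whose grouping factor has one level in the analysed rows
  are dropped automatically; colony-level treatment models fall back to
  fixed-effects fits on degenerate inputs (constant responses), and
  pairwise contrasts fall back to direct Wald contrasts on the
  fixed-effect covariance when the marginal-means machinery cannot handle
  an exactly singular fit.
* Permutation p-values are never zero by construction; all resampling
  functions take an explicit seed and restore the caller's RNG state.

## Problem sizes used in the shipped checks

The packaged tests run the calibration studies at reduced but still
informative sizes chosen to keep the default suite comfortably
interactive: type-I calibration uses 200 specialisation-free datasets of 3
colonies × 70 workers with 500 resamples each; parameter recovery uses 20
replicates of the full 12-colony design with `nAGQ = 0`; the
removal-effect study uses 20 replicates of 12 colonies split 3/3/3/3
across treatments.  These sizes were fixed when the studies were designed.

## Known limitations

* The sequence bootstrap is mildly conservative (measured type-I around
  3–5% at nominal 5%) because pooled transition parameters are estimated
  from the same data; leave-one-ant-out estimation removes most but not
  all of the shrinkage.
* The pair-asymmetry re-draw scheme (`redraw_pools`) is retained for
  comparability but known conservative; the profile-shuffle default is the
  calibrated one.
* Model-set fitting refits every subset independently; with the default
  random-effect structure this is ~50 mixed models per response.
* The generator's fillers make following less repeatable than leading, but
  it does not model follower-specific learning across emigrations.
* Because multi-act core ants accumulate experience in both roles, removing
  the top-ranked followers also removes some capable leaders; targeted
  follower removal therefore produces a small success deficit (about a
  third of the leader-removal effect under defaults) rather than none.
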
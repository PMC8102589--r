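# tandemdol

Division of labour and performance in ant tandem-running teams.

`Temnothorax` ants emigrating to a new nest recruit nestmates by **tandem
running**: an experienced leader physically guides one follower along the
route.  A tandem run either succeeds (the pair reaches the new nest) or
fails (the pair loses contact en route).  `tandemdol` is an R package for
analysing how the division of labour between leading and following relates
to the performance of these two-ant teams.  It is aimed at behavioural
ecologists working with per-tandem emigration records (colony, emigration,
rank, leader, follower, direction, outcome, break-up location, timing).

## What it computes

* **Experience profiles** per ant over the baseline emigrations: leading /
  following *consistency* (number of emigrations with at least one act in
  the role, `C_L`, `C_F`) and *activity* (total tandem runs in the role,
  `A_L`, `A_F`).
* **Task switching**: per-tandem switching probabilities `P(F→L)` and
  `P(L→F)` from each ant's rank-ordered acts (transitions never cross
  emigration boundaries), pooled population values, cross-emigration
  Spearman repeatability, within-pair consistency differences, and the
  directed leader→follower recruitment network.
* **Resampling nulls** for (a) leader-vs-follower consistency asymmetry
  (profile permutation within colony) and (b) the association between
  switching probability and consistency (a sequence bootstrap that
  preserves the mechanical coupling between switching and consistency).
* **Targeted removal designs**: hierarchical ranking of tandem runners
  (consistency, then activity, then id) and the four removal treatments
  (prominent leaders, prominent followers, both, control), each removing
  `round(0.5 × n_runners)` ants built from `round(0.25 × n)` quartiles.
* **Performance metrics** on forward, switch-free runs: success rate,
  straight-line distance of failed runs (`35 cm − l`, with `l` the beeline
  distance from the break-up point to the nearest new-nest entrance), and
  duration of successful runs; colony summaries and means of colony means.
* **Mixed-effects inference**: colony-level treatment comparisons
  (binomial GLMM / Gaussian LMM, likelihood-ratio χ², BH-corrected
  pairwise contrasts) and individual-level all-subsets multimodel
  inference over `C_L + A_L + C_F + A_F + rank + C_L:C_F + A_L:A_F` with
  AICc ranking, Akaike weights `w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2)`, 95%
  confidence sets, relative predictor importance, full model-averaged
  coefficients with unconditional SEs, and collinearity diagnostics
  (mean |r|, VIF).
* **A synthetic emigration generator** with known ground truth (latent
  role propensities, Markov task switching, logistic success model
  `logit(p) = α + β_CL·C_L + γ_rank·rank`) for calibration and
  parameter-recovery studies.

## Worked example

```r
library(tandemdol)

# simulate a 12-colony experiment: 4 baseline emigrations + 1 test emigration
sim  <- simulate_experiment(sim_config(n_colonies = 12, seed = 11))
prof <- experience_profiles(sim$events, baseline_emigrations = 1:4)

# task switching: the textbook two-emigration sequence (F,L,L,L) + (F,F,L)
compute_switch_probabilities(worked_example_events())[1, ]
#>   colony_id ant_id n_F_succ n_FL n_L_succ n_LF      P_FL P_LF
#> 1        C1      a        3    2        2    0 0.6666667    0

# multimodel inference on test-emigration success
ev5 <- filter_performance_events(sim$events[sim$events$emigration == 5, ])
ms  <- enumerate_and_rank_subsets(model_table(ev5, prof), "success")
round(relative_importance(ms), 3)
#>     C_L     A_L     C_F     A_F    rank C_L:C_F A_L:A_F
#>   1.000   0.354   0.339   0.288   0.244   0.078   0.039
subset(model_average(ms), term == "C_L")
#>   term estimate        se        z significant
#> 2  C_L 1.231436 0.2461955 5.001860        TRUE
```

The generator's default success model has `β_CL = 0.8` (log-odds of
success per emigration of leader consistency); the analysis chain ranks
`C_L` as the most important predictor (importance 1.000) and recovers a
significantly positive model-averaged coefficient — leader consistency is
the signal, the other six terms are noise, and the averaged coefficients
of those terms sit near zero.

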
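test_that("empirical p-values use the +1 correction and the requested tail", {
  null99 <- seq(-1, 1, length.out = 99)
  expect_equal(empirical_p(2, null99, "greater"), 1 / 100)
  expect_equal(empirical_p(-2, null99, "less"), 1 / 100)
  expect_equal(empirical_p(0, rep(0, 50), "greater"), 1)
  # two-sided equals twice the smaller one-sided tail, capped at 1
  expect_equal(empirical_p(2, null99, "two_sided"),
               2 * empirical_p(2, null99, "greater"))
  expect_equal(empirical_p(0, null99, "two_sided"), 1)
  # monotone in the observed statistic for a fixed null
  ps <- sapply(c(-0.5, 0, 0.5, 1.5), empirical_p, null = null99,
               tail = "greater")
  expect_true(all(diff(ps) < 0))
  # p is never zero
  expect_gt(empirical_p(10, null99, "greater"), 0)
})

make_asym_data <- function(seed = 1, specialised = TRUE) {
  cfg <- if (specialised) sim_config(n_colonies = 3, seed = seed)
  else sim_config(n_colonies = 3, lead_sd = 0, follow_sd = 0, role_cor = 0,
                  participate_sd = 0, fl_mod = 0, lf_mod = 0, beta_CL = 0,
                  seed = seed)
  sim <- simulate_experiment(cfg)
  list(base = sim$events[sim$events$emigration <= 4, ],
       test = sim$events[sim$events$emigration == 5, ],
       roster = sim$roster)
}

test_that("pair-asymmetry null is reproducible and detects real asymmetry", {
  d <- make_asym_data(21, specialised = TRUE)
  prof <- experience_profiles(d$base)
  r1 <- null_pair_asymmetry(d$test, prof, n_permutations = 200, seed = 4)
  r2 <- null_pair_asymmetry(d$test, prof, n_permutations = 200, seed = 4)
  expect_identical(r1$null_distribution, r2$null_distribution)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$n_permutations, 200L)
  # in the specialised simulator leaders are the experienced ants, so the
  # observed asymmetry should sit far in the upper tail of the null
  expect_gt(r1$observed, 0)
  expect_lt(r1$p_value, 0.05)
  # both schemes agree on the observed statistic
  r3 <- null_pair_asymmetry(d$test, prof, n_permutations = 200, seed = 4,
                            scheme = "redraw_pools")
  expect_identical(r3$observed, r1$observed)
})

test_that("identical profiles give a null-centred pair statistic", {
  d <- make_asym_data(22, specialised = FALSE)
  prof <- experience_profiles(d$base, roster = d$roster)
  prof$C_L <- 2L; prof$C_F <- 2L   # every ant in the colony identical
  r <- null_pair_asymmetry(d$test, prof, n_permutations = 200, seed = 1)
  expect_equal(r$observed, 0)
  expect_equal(r$p_value, 1)
})

test_that("few permutations trigger a warning", {
  d <- make_asym_data(23, specialised = FALSE)
  prof <- experience_profiles(d$base)
  expect_warning(null_pair_asymmetry(d$test, prof, n_permutations = 50,
                                     seed = 1), "fewer than 100")
})

test_that("switch-consistency test is reproducible and flags degenerate input", {
  d <- make_asym_data(24, specialised = TRUE)
  prof <- experience_profiles(d$base)
  st <- compute_switch_probabilities(d$base)
  r1 <- null_switch_consistency(st, prof, n_permutations = 200, seed = 9,
                                events = d$base)
  r2 <- null_switch_consistency(st, prof, n_permutations = 200, seed = 9,
                                events = d$base)
  expect_identical(r1$null_distribution, r2$null_distribution)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
  # constant consistency values make the slope undefined
  prof0 <- prof; prof0$C_L <- 1L
  expect_error(null_switch_consistency(st, prof0, n_permutations = 200,
                                       seed = 9, events = d$base),
               "constant")
  # fewer than 5 scored ants is refused
  expect_error(null_switch_consistency(st[1:3, ], prof, n_permutations = 200,
                                       seed = 9, events = d$base),
               "fewer than 5")
})

test_that("the consistency-shuffle scheme preserves the value multiset", {
  d <- make_asym_data(25, specialised = TRUE)
  prof <- experience_profiles(d$base)
  st <- compute_switch_probabilities(d$base)
  r <- null_switch_consistency(st, prof, n_permutations = 150, seed = 2,
                               scheme = "shuffle_consistency")
  expect_identical(r$n_permutations, 150L)
  # a strongly monotone toy table: the observed slope must sit at the
  # extreme of its exhaustive shuffle distribution
  toy_st <- data.frame(colony_id = "C1", ant_id = letters[1:5],
                       n_F_succ = rep(10L, 5), n_FL = c(1L, 2L, 3L, 4L, 5L),
                       n_L_succ = rep(0L, 5), n_LF = rep(0L, 5),
                       P_FL = c(0.1, 0.2, 0.3, 0.4, 0.5), P_LF = NA_real_,
                       stringsAsFactors = FALSE)
  toy_prof <- data.frame(colony_id = "C1", ant_id = letters[1:5],
                         C_L = 0:4, C_F = 0L, A_L = 1:5, A_F = 1L,
                         stringsAsFactors = FALSE)
  r_toy <- null_switch_consistency(toy_st, toy_prof, n_permutations = 400,
                                   seed = 3, scheme = "shuffle_consistency")
  expect_equal(r_toy$observed, 0.1)
  expect_lt(r_toy$p_value, 0.05)
})

test_that("switch-consistency covers all four probability-consistency panels", {
  d <- make_asym_data(26, specialised = TRUE)
  prof <- experience_profiles(d$base)
  st <- compute_switch_probabilities(d$base)
  for (pr in c("P_FL", "P_LF")) for (cs in c("C_L", "C_F")) {
    r <- null_switch_consistency(st, prof, n_permutations = 120, seed = 5,
                                 probability = pr, consistency = cs,
                                 events = d$base)
    expect_s3_class(r, "perm_test")
    expect_true(is.finite(r$observed))
  }
})
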
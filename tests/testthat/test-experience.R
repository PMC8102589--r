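test_that("consistency counts emigrations and activity counts tandem runs", {
  # led 3x in emigration 1, led 1x + followed 2x in emigration 2, absent after
  ev <- events_from_roles(list(c("F", "L", "L", "L"), c("F", "F", "L")))
  prof <- experience_profiles(ev, baseline_emigrations = 1:4)
  a <- prof[prof$ant_id == "a", ]
  expect_identical(a$C_L, 2L)
  expect_identical(a$A_L, 4L)
  expect_identical(a$C_F, 2L)
  expect_identical(a$A_F, 3L)
  # each partner acted exactly once
  partners <- prof[prof$ant_id != "a", ]
  expect_true(all(partners$A_L + partners$A_F == 1))

  # an ant leading in all four baselines
  ev4 <- events_from_roles(list(c("L", "L", "L"), c("L", "L", "L"),
                                c("L", "L", "L"), c("L", "L", "L")))
  a4 <- experience_profiles(ev4)[1, ]
  expect_identical(a4$C_L, 4L)
  expect_identical(a4$A_L, 12L)
})

test_that("roster ants without baseline tandems get all-zero profiles", {
  ev <- events_from_roles(list(c("L", "F")))
  roster <- data.frame(colony_id = "C1",
                       worker_id = c("a", "p01", "p02", "idle"),
                       stringsAsFactors = FALSE)
  prof <- experience_profiles(ev, roster = roster)
  idle <- prof[prof$ant_id == "idle", ]
  expect_identical(unname(unlist(idle[, c("C_L", "C_F", "A_L", "A_F")])),
                   rep(0L, 4))
})

test_that("activity totals balance the number of baseline events", {
  sim <- simulate_experiment(sim_config(n_colonies = 2, seed = 3))
  base <- sim$events[sim$events$emigration <= 4, ]
  prof <- experience_profiles(base)
  expect_identical(sum(prof$A_L), nrow(base))
  expect_identical(sum(prof$A_F), nrow(base))
  expect_true(all(prof$C_L <= 4 & prof$C_F <= 4))
  expect_true(all(prof$A_L >= prof$C_L & prof$A_F >= prof$C_F))
  expect_true(all((prof$A_L == 0) == (prof$C_L == 0)))
})

test_that("switching probabilities reproduce the two-emigration worked example", {
  ev <- worked_example_events()
  st <- compute_switch_probabilities(ev)
  a <- st[st$ant_id == "a", ]
  expect_equal(a$P_FL, 2 / 3)
  expect_equal(a$P_LF, 0)
  expect_identical(a$n_F_succ, 3L)
  expect_identical(a$n_L_succ, 2L)
})

test_that("transitions never cross emigration boundaries and single acts are undefined", {
  # (L,F) then (L,F): both L acts have successors (P_LF = 1), the F acts
  # end their emigrations so P_FL is undefined
  ev <- events_from_roles(list(c("L", "F"), c("L", "F")))
  a <- compute_switch_probabilities(ev)
  a <- a[a$ant_id == "a", ]
  expect_equal(a$P_LF, 1)
  expect_identical(a$n_L_succ, 2L)
  expect_true(is.na(a$P_FL))

  single <- compute_switch_probabilities(events_from_roles(list("L")))
  s <- single[single$ant_id == "a", ]
  expect_true(is.na(s$P_FL) && is.na(s$P_LF))
})

test_that("switch counting matches a brute-force enumerator on all length-8 role strings", {
  for (code in 0:255) {
    roles <- ifelse(bitwAnd(code, 2^(0:7)) > 0, "L", "F")
    ev <- events_from_roles(list(roles[1:5], roles[6:8]))
    st <- compute_switch_probabilities(ev)
    a <- st[st$ant_id == "a", ]
    bf <- brute_force_switch(ev, "a")
    expect_identical(a$n_F_succ, as.integer(bf$n_F_succ))
    expect_identical(a$n_FL, as.integer(bf$n_FL))
    expect_identical(a$n_L_succ, as.integer(bf$n_L_succ))
    expect_identical(a$n_LF, as.integer(bf$n_LF))
    # denominators sum to acts-1 per emigration
    expect_identical(a$n_F_succ + a$n_L_succ, 4L + 2L)
  }
})

test_that("overall switching probabilities pool transition counts", {
  st <- data.frame(colony_id = "C1", ant_id = c("a", "b"),
                   n_F_succ = c(2L, 2L), n_FL = c(1L, 2L),
                   n_L_succ = c(0L, 0L), n_LF = c(0L, 0L),
                   P_FL = c(0.5, 1), P_LF = c(NA, NA),
                   stringsAsFactors = FALSE)
  ov <- overall_switch_probabilities(st)
  expect_equal(ov$P_FL, 3 / 4)          # pooled, not mean of ratios
  expect_equal(ov$P_FL_mean, 0.75)
  expect_true(is.na(ov$P_LF))
  one <- overall_switch_probabilities(st[2, ])
  expect_equal(one$P_FL, 1)
})

test_that("pooled switching recovers the generating parameter without modulation", {
  ps <- sapply(1:4, function(s) {
    cfg <- sim_config(n_colonies = 4, pi_FL = 0.5, pi_LF = 0.5,
                      fl_mod = 0, lf_mod = 0, lead_sd = 0, follow_sd = 0,
                      role_cor = 0, beta_CL = 0, seed = s)
    sim <- simulate_experiment(cfg)
    ov <- overall_switch_probabilities(
      compute_switch_probabilities(sim$events[sim$events$emigration <= 4, ]))
    c(ov$P_FL, ov$P_LF)
  })
  expect_equal(mean(ps[1, ]), 0.5, tolerance = 0.05)
  expect_equal(mean(ps[2, ]), 0.5, tolerance = 0.05)
})

test_that("cross-emigration correlations recover hand-ranked Spearman values", {
  mk <- function(counts_by_em) {
    rows <- list(); k <- 0
    for (em in seq_along(counts_by_em)) {
      counts <- counts_by_em[[em]]
      r <- 0
      for (ant in names(counts)) for (j in seq_len(counts[[ant]])) {
        k <- k + 1; r <- r + 1
        rows[[k]] <- event_row(emigration = em, rank = r, leader = ant,
                               follower = sprintf("q%03d", k),
                               t_start = r * 10, t_end = r * 10 + 5)
      }
    }
    tandem_events(do.call(rbind, rows))
  }
  # identical counts -> rho = 1; reversed ranking -> rho = -1
  ev <- mk(list(c(a = 3, b = 2, c = 1), c(a = 3, b = 2, c = 1)))
  expect_equal(cross_emigration_correlations(ev, "lead", 1:2)$r[1, 2], 1)
  ev2 <- mk(list(c(a = 3, b = 2, c = 1), c(a = 1, b = 2, c = 3)))
  expect_equal(cross_emigration_correlations(ev2, "lead", 1:2)$r[1, 2], -1)
  # 4-ant toy table against the rank-formula oracle
  ev3 <- mk(list(c(a = 3, b = 2, c = 1, d = 0),
                 c(a = 2, b = 3, c = 0, d = 1)))
  x <- c(3, 2, 1, 0); y <- c(2, 3, 0, 1)
  rho_hand <- 1 - 6 * sum((rank(x) - rank(y))^2) / (4 * (16 - 1))
  expect_equal(cross_emigration_correlations(ev3, "lead", 1:2)$r[1, 2],
               rho_hand)
})

test_that("pair consistency differences are signed per role and averaged by colony", {
  prof <- data.frame(colony_id = "C1", ant_id = c("x", "y", "z"),
                     C_L = c(4L, 1L, 2L), C_F = c(0L, 3L, 2L),
                     A_L = c(8L, 1L, 2L), A_F = c(0L, 5L, 2L),
                     stringsAsFactors = FALSE)
  class(prof) <- c("experience_profiles", "data.frame")
  ev <- tandem_events(rbind(
    event_row(emigration = 5, rank = 1, leader = "x", follower = "y"),
    event_row(emigration = 5, rank = 2, leader = "z", follower = "z2",
              t_start = 10, t_end = 70),
    event_row(emigration = 5, rank = 3, leader = "y", follower = "x",
              t_start = 20, t_end = 80)))
  pd <- pair_consistency_differences(ev, prof)
  expect_equal(pd$per_tandem$d_lead, c(4 - 1, 2 - 0, 1 - 4))
  expect_equal(pd$per_tandem$d_follow, c(3 - 0, 0 - 2, 0 - 3))
  expect_equal(pd$colony_means$d_lead, mean(c(3, 2, -3)))
  expect_identical(pd$n_unprofiled, 1L)   # z2 has no profile
  # identical profiles give zero differences
  ev0 <- tandem_events(event_row(leader = "x", follower = "x2"))
  prof0 <- prof; prof0$ant_id <- c("x", "x2", "z")
  prof0[1:2, c("C_L", "C_F", "A_L", "A_F")] <- 1L
  pd0 <- pair_consistency_differences(ev0, prof0)
  expect_equal(pd0$per_tandem$d_lead, 0)
  expect_equal(pd0$per_tandem$d_follow, 0)
})

test_that("the recruitment network keeps one directed edge per tandem", {
  ev <- tandem_events(rbind(
    event_row(rank = 1, leader = "a", follower = "b"),
    event_row(rank = 2, leader = "a", follower = "b", t_start = 10, t_end = 70),
    event_row(rank = 3, leader = "a", follower = "c", t_start = 20, t_end = 80)))
  g <- build_recruitment_network(ev)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)   # parallel edges kept
  n_led <- igraph::vertex_attr(g, "n_led")
  expect_equal(sort(n_led, decreasing = TRUE), c(3, 0, 0))
  empty <- build_recruitment_network(ev[0, ])
  expect_equal(igraph::vcount(empty), 0)
  # edge count always equals event count on simulated data
  sim <- simulate_experiment(sim_config(n_colonies = 1, seed = 2))
  expect_equal(igraph::ecount(build_recruitment_network(sim$events)),
               nrow(sim$events))
})
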
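# helper: minimal model-set skeleton for closed-form checks
mk_modelset <- function(weights, term_sets, coefs = NULL, level = 0.95) {
  o <- order(-weights)
  weights <- weights[o]; term_sets <- term_sets[o]
  if (!is.null(coefs)) coefs <- coefs[o]
  ms <- structure(list(
    models = data.frame(model = seq_along(weights),
                        terms = vapply(term_sets, paste, "", collapse = "+"),
                        k = 1, logLik = 0, IC = 0, delta = 0,
                        weight = weights, cum_weight = cumsum(weights),
                        converged = TRUE, stringsAsFactors = FALSE),
    coefs = coefs, term_sets = term_sets, response = "success",
    ic = "AICc", level = level, n = 100, dropped = list(), data = NULL,
    fits = NULL), class = "tandem_modelset")
  confidence_set_95(ms, level)
}

test_that("AICc and Akaike weights match their closed forms", {
  expect_equal(aicc(-100, 3, 50), 200 + 6 + 2 * 3 * 4 / 46)
  expect_identical(aicc(-10, 5, 6), Inf)
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(10, 12))
  expect_equal(w[2] / w[1], exp(-1))
  expect_equal(sum(akaike_weights(runif(7, 100, 120))), 1)
})

test_that("subset enumeration respects marginality and matches brute force", {
  subsets <- enumerate_term_subsets()
  mains <- c("C_L", "A_L", "C_F", "A_F", "rank")
  ints <- c("C_L:C_F", "A_L:A_F")
  # independent brute-force enumeration over all 2^7 term combinations
  count <- 0
  for (code in 0:(2^7 - 1)) {
    sel <- c(mains, ints)[bitwAnd(code, 2^(0:6)) > 0]
    ok <- TRUE
    for (it in intersect(ints, sel))
      if (!all(strsplit(it, ":")[[1]] %in% sel)) ok <- FALSE
    if (ok) count <- count + 1
  }
  expect_equal(length(subsets), count)   # 50 marginality-respecting subsets
  keys <- sapply(subsets, function(s) paste(sort(s), collapse = "|"))
  expect_identical(anyDuplicated(keys), 0L)
  for (s in subsets)
    for (it in intersect(ints, s))
      expect_true(all(strsplit(it, ":")[[1]] %in% s))
})

test_that("the 95% confidence set is the smallest prefix reaching 0.95", {
  ts <- replicate(4, character(), simplify = FALSE)
  ms <- mk_modelset(c(0.6, 0.3, 0.08, 0.02), ts)
  expect_identical(ms$models$in_set, c(TRUE, TRUE, TRUE, FALSE))
  one <- mk_modelset(1, list(character()))
  expect_identical(one$models$in_set, TRUE)
  unif <- mk_modelset(rep(1 / 100, 100),
                      replicate(100, character(), simplify = FALSE))
  expect_identical(sum(unif$models$in_set), 95L)
})

test_that("relative importance sums renormalised weights over member models", {
  ts <- list(c("C_L"), c("A_L"), c("C_L", "A_L"))
  ms <- mk_modelset(c(0.5, 0.3, 0.2), ts)
  imp <- relative_importance(ms)
  expect_equal(unname(imp["C_L"]), 0.7)
  expect_equal(unname(imp["A_L"]), 0.5)
  expect_equal(unname(imp["rank"]), 0)
  # a term in every member model has importance 1
  ms2 <- mk_modelset(c(0.7, 0.3), list(c("C_L"), c("C_L", "rank")))
  expect_equal(unname(relative_importance(ms2)["C_L"]), 1)
})

test_that("model averaging follows the zero-substitution rule and B-A errors", {
  cf <- function(terms, est, se)
    data.frame(term = c("(Intercept)", terms),
               estimate = c(0, est), se = c(0, se),
               stringsAsFactors = FALSE)
  # identical coefficient everywhere: average is that value, spread is 0
  ms <- mk_modelset(c(0.6, 0.4), list("C_L", c("C_L", "rank")),
                    list(cf("C_L", 2, 0.5), cf(c("C_L", "rank"), c(2, 1),
                                               c(0.5, 0.2))))
  avg <- model_average(ms)
  cl <- avg[avg$term == "C_L", ]
  expect_equal(cl$estimate, 2)
  expect_equal(cl$se, 0.5)
  # a term absent from half the weight averages to half its value
  rk <- avg[avg$term == "rank", ]
  expect_equal(rk$estimate, 0.4 * 1)
  # hand-computed unconditional SE: sum_i w_i sqrt(se_i^2 + (b_i - bbar)^2)
  se_hand <- 0.6 * sqrt(0 + (0 - 0.4)^2) + 0.4 * sqrt(0.2^2 + (1 - 0.4)^2)
  expect_equal(rk$se, se_hand)
  # conditional averaging ignores models lacking the term
  avg_c <- model_average(ms, method = "conditional")
  expect_equal(avg_c[avg_c$term == "rank", "estimate"], 1)
  # a single-model confidence set reproduces that model's coefficients
  ms1 <- mk_modelset(1, list("C_L"), list(cf("C_L", 1.5, 0.3)))
  a1 <- model_average(ms1)
  expect_equal(a1[a1$term == "C_L", "estimate"], 1.5)
  expect_equal(a1[a1$term == "C_L", "se"], 0.3)
})

test_that("random-intercept fits degrade gracefully to ordinary regression", {
  set.seed(1)
  n <- 120
  d <- data.frame(replicate = rep(c("A", "B"), each = n / 2),
                  colony = rep(c("A:C1", "A:C2", "B:C3", "B:C4"), each = n / 4),
                  leader = sample(paste0("L", 1:8), n, TRUE),
                  follower = sample(paste0("F", 1:30), n, TRUE),
                  C_L = rnorm(n), A_L = rnorm(n), C_F = rnorm(n),
                  A_F = rnorm(n), rank = rnorm(n))
  d$sld <- 10 + 3 * d$C_L + rnorm(n)
  d$success <- NA; d$time <- NA
  f <- fit_random_intercept_model(d, "C_L", "sld")
  expect_true(is.finite(f$AICc))
  # no real grouping structure: estimates match plain least squares
  ls <- coef(lm(sld ~ C_L, data = d))
  expect_equal(f$coefs$estimate[f$coefs$term == "C_L"],
               unname(ls["C_L"]), tolerance = 0.05)
  # zero between-group variance: intercept-only model returns the grand mean
  d0 <- d; d0$sld <- 5 + rnorm(n, sd = 0.1)
  f0 <- fit_random_intercept_model(d0, character(), "sld")
  expect_equal(f0$coefs$estimate[1], mean(d0$sld), tolerance = 0.01)
  vc <- as.data.frame(lme4::VarCorr(f0$fit))
  expect_lt(max(vc$vcov[vc$grp != "Residual"]), 0.01)
})

test_that("full model-set pipeline ranks, weights and averages coherently", {
  sim <- simulate_experiment(sim_config(n_colonies = 4, seed = 61))
  prof <- experience_profiles(sim$events)
  ev5 <- filter_performance_events(sim$events[sim$events$emigration == 5, ])
  tab <- model_table(ev5, prof)
  ms <- enumerate_and_rank_subsets(tab, "success", nAGQ = 0)
  expect_identical(nrow(ms$models), 50L)
  expect_equal(sum(ms$models$weight), 1)
  expect_true(!is.unsorted(ms$models$IC))
  expect_gte(ms$models$cum_weight[max(which(ms$models$in_set))], 0.95)
  imp <- relative_importance(ms)
  expect_true(all(imp >= 0 & imp <= 1))
  avg <- model_average(ms)
  expect_true(all(is.finite(avg$estimate)))
  expect_identical(coef(ms), setNames(avg$estimate, avg$term))
  s <- summary(ms)
  expect_s3_class(s, "summary.tandem_modelset")
})

test_that("collinearity report matches closed forms and the regression oracle", {
  set.seed(3)
  n <- 200
  z <- matrix(rnorm(3 * n), ncol = 3)
  d <- data.frame(replicate = "A", colony = "A:C1",
                  leader = paste0("L", 1:n), follower = paste0("F", 1:n),
                  C_L = z[, 1], A_L = z[, 2],
                  C_F = 0.8 * scale(z[, 1])[, 1] +
                    sqrt(1 - 0.64) * scale(z[, 3])[, 1],
                  A_F = rnorm(n), rank = rnorm(n))
  d$sld <- 1 + d$C_L + rnorm(n); d$success <- NA; d$time <- NA
  ms <- structure(list(
    models = data.frame(model = 1:2, terms = c("C_L+A_L", "C_L+C_F"),
                        k = 1, logLik = 0, IC = 0, delta = 0,
                        weight = c(0.5, 0.5), cum_weight = c(0.5, 1),
                        converged = TRUE, in_set = TRUE,
                        stringsAsFactors = FALSE),
    term_sets = list(c("C_L", "A_L"), c("C_L", "C_F")),
    response = "sld", ic = "AICc", level = 0.95, n = n,
    dropped = list(), data = tandemdol:::.standardise(d), fits = NULL),
    class = "tandem_modelset")
  rep_ <- collinearity_report(ms, threshold = 0.7)
  pm <- rep_$per_model
  # near-orthogonal pair: VIF close to 1; r = 0.8 pair: VIF = 1/(1-r^2)
  r12 <- abs(cor(d$C_L, d$A_L)); r13 <- abs(cor(d$C_L, d$C_F))
  expect_equal(pm$mean_abs_r, c(r12, r13), tolerance = 1e-8)
  expect_equal(pm$max_vif, 1 / (1 - c(r12, r13)^2), tolerance = 1e-6)
  expect_false(pm$filtered_out[1])
  expect_true(pm$filtered_out[2])   # |r| = 0.8 exceeds the 0.7 threshold
  expect_identical(rep_$filtered_models, 1L)
})
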
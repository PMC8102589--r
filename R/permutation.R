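#' Empirical permutation p-value
#'
#' Finite-sample-corrected empirical p-value
#' `(1 + #\{null at least as extreme\}) / (1 + n)`, so p is never zero.  The
#' two-sided value is `min(1, 2 * min(p_greater, p_less))`, robust to
#' asymmetric nulls.
#'
#' @param observed observed statistic.
#' @param null vector of null-distribution draws.
#' @param tail `"greater"`, `"less"` or `"two_sided"`.
#' @return p-value in (0, 1].
#' @export
empirical_p <- function(observed, null, tail = c("greater", "less", "two_sided")) {
  tail <- match.arg(tail)
  stopifnot(length(null) > 0, is.finite(observed))
  pg <- (1 + sum(null >= observed)) / (1 + length(null))
  pl <- (1 + sum(null <= observed)) / (1 + length(null))
  switch(tail,
         greater = pg,
         less = pl,
         two_sided = min(1, 2 * min(pg, pl)))
}

.new_perm_result <- function(test, statistic, observed, null, seed, tail, extra = list()) {
  structure(c(list(test = test, statistic = statistic,
                   observed = observed, null_distribution = null,
                   n_permutations = length(null),
                   p_value = empirical_p(observed, null, tail),
                   tail = tail, seed = seed), extra),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test:", x$test, "\n")
  cat("  statistic:", x$statistic, "\n")
  cat("  observed =", signif(x$observed, 4),
      " (null mean ", signif(mean(x$null_distribution), 4), ")\n", sep = "")
  cat("  p =", signif(x$p_value, 4), " (", x$tail, ", ",
      x$n_permutations, " permutations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Permutation null for within-pair consistency asymmetry
#'
#' Tests whether leaders are more consistent in the leading role than the
#' followers they lead.  The observed statistic is the mean over colonies of
#' the colony-mean per-tandem difference `C_L(leader) - C_L(follower)`.  The
#' null is built within colony, holding the tandem count and the observed
#' role pools fixed:
#'
#' * `"shuffle_profiles"` (default): permute the baseline profiles among the
#'   colony's tandem runners, keeping the observed leader/follower assignment
#'   of every tandem — exactly exchangeable when baseline experience is
#'   unrelated to test-emigration roles, and calibrated in simulation;
#' * `"redraw_pools"`: for each tandem, independently re-draw the leader
#'   uniformly from the colony's set of observed leaders and the follower
#'   from the set of observed followers.  Because the independent re-draw
#'   destroys the correlation induced by ants appearing in both pools, this
#'   scheme is conservative; it is retained for sensitivity analysis.
#'
#' @param events tandem events to score (typically the test emigration).
#' @param profiles baseline [experience_profiles()].
#' @param n_permutations number of null draws (warning below 100).
#' @param seed integer seed for the permutation stream.
#' @param scheme permutation scheme, see above.
#' @return A `perm_test` object (one-tailed, greater).
#' @export
null_pair_asymmetry <- function(events, profiles, n_permutations = 1000,
                                seed = 1L, scheme = c("shuffle_profiles",
                                                      "redraw_pools")) {
  scheme <- match.arg(scheme)
  if (n_permutations < 100)
    warning("fewer than 100 permutations: p-value resolution is poor")
  key <- paste(profiles$colony_id, profiles$ant_id, sep = "\r")
  CL <- setNames(as.numeric(profiles$C_L), key)
  get0 <- function(k) { v <- CL[k]; v[is.na(v)] <- 0; unname(v) }
  colonies <- unique(events$colony_id)
  per_colony <- list()
  for (cid in colonies) {
    ev <- events[events$colony_id == cid, , drop = FALSE]
    if (nrow(ev) < 2) next   # too few tandems to be informative
    per_colony[[cid]] <- ev
  }
  if (!length(per_colony)) stop("no colony with at least 2 tandems")
  obs <- mean(vapply(per_colony, function(ev)
    mean(get0(paste(ev$colony_id, ev$leader_id, sep = "\r")) -
           get0(paste(ev$colony_id, ev$follower_id, sep = "\r"))), 0))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  nulls <- matrix(0, n_permutations, length(per_colony))
  for (j in seq_along(per_colony)) {
    ev <- per_colony[[j]]
    cid <- ev$colony_id[1]
    n_t <- nrow(ev)
    if (scheme == "redraw_pools") {
      lead_pool <- get0(paste(cid, unique(ev$leader_id), sep = "\r"))
      fol_pool <- get0(paste(cid, unique(ev$follower_id), sep = "\r"))
      L <- matrix(lead_pool[sample.int(length(lead_pool), n_t * n_permutations,
                                       replace = TRUE)],
                  n_t, n_permutations)
      F_ <- matrix(fol_pool[sample.int(length(fol_pool), n_t * n_permutations,
                                       replace = TRUE)],
                   n_t, n_permutations)
      nulls[, j] <- colMeans(L - F_)
    } else {
      runners <- unique(c(ev$leader_id, ev$follower_id))
      vals <- get0(paste(cid, runners, sep = "\r"))
      li <- match(ev$leader_id, runners)
      fi <- match(ev$follower_id, runners)
      for (b in seq_len(n_permutations)) {
        perm <- vals[sample.int(length(vals))]
        nulls[b, j] <- mean(perm[li] - perm[fi])
      }
    }
  }
  .new_perm_result("pair-asymmetry", "mean over colonies of colony-mean C_L(leader) - C_L(follower)",
                   obs, rowMeans(nulls), seed, "greater",
                   list(scheme = scheme, n_colonies = length(per_colony)))
}

#' Resampling null for switching-consistency association
#'
#' Tests the association between a per-ant switching probability and a
#' consistency score (the four combinations of P(F->L), P(L->F) with C_L,
#' C_F).  The observed statistic is the least-squares slope of the per-ant
#' switching probability on the ant's consistency, across ants with a
#' defined probability.  Two null schemes are available:
#'
#' * `"sequence_bootstrap"` (default): regenerates every ant's within-
#'   emigration role sequences from the pooled switching process,
#'   conditioning on each ant's observed number of acts per emigration and
#'   on its observed first-act roles (first acts reflect recruitment, not
#'   switching); transition probabilities are pooled leave-one-ant-out, and
#'   *both* the switching probabilities and the consistencies are
#'   recomputed from the resampled sequences.  This preserves the
#'   mechanical coupling between switching and consistency — an ant that
#'   happens to switch into leading thereby acquires leading consistency
#'   even when all ants share identical switching probabilities — so the
#'   test asks whether the observed association exceeds what that shared
#'   process alone produces.
#' * `"shuffle_consistency"`: shuffles the consistency values among the
#'   scored ants within each colony, keeping the per-ant probabilities.
#'   This breaks the mechanical coupling as well and therefore rejects
#'   generously whenever consistency and switching are computed from the
#'   same act records; it is retained for sensitivity analysis.
#'
#' Two-tailed p with the +1 correction.
#'
#' @param stats a `switch_stats` data frame (see
#'   [compute_switch_probabilities()]).
#' @param profiles baseline [experience_profiles()].
#' @param n_permutations number of null draws.
#' @param seed integer seed.
#' @param probability `"P_FL"` or `"P_LF"`.
#' @param consistency `"C_L"` or `"C_F"`.
#' @param events the baseline `tandem_events` the statistics were computed
#'   from; required for the `"sequence_bootstrap"` scheme.
#' @param scheme null-construction scheme, see above.
#' @return A `perm_test` object (two-tailed).
#' @export
null_switch_consistency <- function(stats, profiles, n_permutations = 1000,
                                    seed = 1L,
                                    probability = c("P_FL", "P_LF"),
                                    consistency = c("C_L", "C_F"),
                                    events = NULL,
                                    scheme = c("sequence_bootstrap",
                                               "shuffle_consistency")) {
  probability <- match.arg(probability)
  consistency <- match.arg(consistency)
  scheme <- match.arg(scheme)
  if (n_permutations < 100)
    warning("fewer than 100 permutations: p-value resolution is poor")
  key <- paste(profiles$colony_id, profiles$ant_id, sep = "\r")
  cons <- setNames(as.numeric(profiles[[consistency]]), key)
  p <- stats[[probability]]
  ok <- !is.na(p)
  if (sum(ok) < 5)
    stop("fewer than 5 ants with a defined ", probability)
  d <- data.frame(colony = stats$colony_id[ok],
                  y = p[ok],
                  x = unname(cons[paste(stats$colony_id[ok], stats$ant_id[ok],
                                        sep = "\r")]))
  d$x[is.na(d$x)] <- 0
  if (stats::sd(d$x) == 0)
    stop("consistency values are constant: slope undefined")
  slope <- function(x, y) stats::cov(x, y) / stats::var(x)
  obs <- slope(d$x, d$y)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  null <- numeric(n_permutations)
  if (scheme == "shuffle_consistency") {
    groups <- split(seq_len(nrow(d)), d$colony)
    xs <- d$x
    for (b in seq_len(n_permutations)) {
      xp <- xs
      for (g in groups) xp[g] <- xs[g[sample.int(length(g))]]
      null[b] <- slope(xp, d$y)
    }
  } else {
    if (is.null(events))
      stop("scheme 'sequence_bootstrap' needs the baseline events")
    null <- .switch_bootstrap_null(events, n_permutations, probability,
                                   consistency)
    null <- null[!is.na(null)]
    if (!length(null)) stop("all bootstrap draws degenerate")
  }
  .new_perm_result("switch-consistency",
                   paste0("slope of ", probability, " on ", consistency),
                   obs, null, seed, "two_sided",
                   list(probability = probability, consistency = consistency,
                        scheme = scheme, n_ants = nrow(d)))
}

# null slopes from resampled role sequences under the pooled switching
# process, conditioning on each ant's act counts per emigration
.switch_bootstrap_null <- function(events, n_draws, probability, consistency,
                                   stat = NULL) {
  acts <- rbind(
    data.frame(colony_id = events$colony_id, ant_id = events$leader_id,
               emigration = events$emigration, rank = events$rank,
               role = "L", stringsAsFactors = FALSE),
    data.frame(colony_id = events$colony_id, ant_id = events$follower_id,
               emigration = events$emigration, rank = events$rank,
               role = "F", stringsAsFactors = FALSE))
  acts <- acts[order(acts$colony_id, acts$ant_id, acts$emigration, acts$rank), ]
  n <- nrow(acts)
  same <- c(acts$colony_id[-1] == acts$colony_id[-n] &
              acts$ant_id[-1] == acts$ant_id[-n] &
              acts$emigration[-1] == acts$emigration[-n], FALSE)
  first <- c(TRUE, !same[-n])
  next_role <- c(acts$role[-1], NA)
  ant <- paste(acts$colony_id, acts$ant_id, sep = "\r")
  # pooled parameters of the shared switching process, leave-one-ant-out so
  # each ant's resampled chains do not reuse its own transitions
  fl_d <- (same & acts$role == "F") + 0
  fl_n <- (same & acts$role == "F" & next_role == "L") + 0
  lf_d <- (same & acts$role == "L") + 0
  lf_n <- (same & acts$role == "L" & next_role == "F") + 0
  tot <- c(sum(fl_d), sum(fl_n), sum(lf_d), sum(lf_n))
  by_ant <- rowsum(cbind(fl_d, fl_n, lf_d, lf_n), ant)
  loo <- sweep(-by_ant, 2, tot, "+")    # totals minus each ant's counts
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  p_fl_ant <- setNames(safe_div(loo[, 2], loo[, 1]), rownames(loo))
  p_lf_ant <- setNames(safe_div(loo[, 4], loo[, 3]), rownames(loo))
  p_fl_row <- unname(p_fl_ant[ant])
  p_lf_row <- unname(p_lf_ant[ant])

  em_key <- paste(ant, acts$emigration, sep = "\r")
  fant <- factor(ant)
  fem <- factor(em_key, levels = unique(em_key))
  em_ant <- factor(ant[!duplicated(em_key)])   # ant of each emigration block
  pos <- stats::ave(seq_len(n), em_key, FUN = seq_along)
  src <- if (probability == "P_FL") "F" else "L"
  dst <- if (probability == "P_FL") "L" else "F"
  crole <- if (consistency == "C_L") "L" else "F"
  # simulate all draws at once: `roleL` is an n x n_draws logical matrix
  # (TRUE = leading act), filled chain position by chain position
  u <- matrix(stats::runif(n * n_draws), n, n_draws)
  roleL <- matrix(FALSE, n, n_draws)
  # first acts keep their observed roles (they reflect recruitment into
  # the emigration, not switching); only the transitions are resampled
  roleL[first, ] <- acts$role[first] == "L"
  if (max(pos) > 1) for (j in 2:max(pos)) {
    i <- which(pos == j)
    prev <- roleL[i - 1, , drop = FALSE]
    roleL[i, ] <- ifelse(prev, u[i, , drop = FALSE] >= p_lf_row[i],
                         u[i, , drop = FALSE] < p_fl_row[i])
  }
  is_src <- if (src == "L") roleL else !roleL
  is_dst_next <- rbind((if (dst == "L") roleL else !roleL)[-1, , drop = FALSE],
                       matrix(FALSE, 1, n_draws))
  den <- rowsum((is_src & same) + 0, fant)
  num <- rowsum((is_src & same & is_dst_next) + 0, fant)
  em_has <- rowsum((if (crole == "L") roleL else !roleL) + 0, fem) > 0
  cvals <- rowsum(em_has + 0, em_ant)
  cvals <- cvals[rownames(den), , drop = FALSE]
  if (is.null(stat)) {
    # default slope, vectorised over draws with per-draw missingness masks
    ok <- den > 0
    m <- colSums(ok)
    y <- ifelse(ok, num / pmax(den, 1), 0)
    x <- ifelse(ok, cvals, 0)
    xbar <- colSums(x) / m
    ybar <- colSums(y) / m
    sxy <- colSums(x * y) - m * xbar * ybar
    sxx <- colSums(x * x) - m * xbar^2
    out <- ifelse(m >= 3 & sxx > 0, sxy / sxx, NA_real_)
    return(out)
  }
  vapply(seq_len(n_draws), function(b) {
    keep <- den[, b] > 0
    y <- num[keep, b] / den[keep, b]
    x <- cvals[keep, b]
    if (length(y) < 3 || stats::sd(x) == 0) return(NA_real_)
    stat(x, y, den[keep, b])
  }, 0)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
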
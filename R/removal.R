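#' Hierarchical ranking of tandem runners for one role
#'
#' Ranks a colony's tandem runners for the leading or following task: ants
#' are ordered by role consistency (descending); ties are broken by role
#' activity (descending); residual ties by ant id (lexicographic), which
#' makes the ordering total and deterministic.
#'
#' @param profiles an [experience_profiles()] data frame for one colony.
#' @param role `"lead"` or `"follow"`.
#' @param runners_only keep only ants with at least one baseline tandem in
#'   either role (the "tandem runner" pool; default `TRUE`).
#' @return A data frame of class `role_ranking` ordered best-ranked first,
#'   with columns `ant_id`, `consistency`, `activity`.
#' @export
hierarchical_rank <- function(profiles, role = c("lead", "follow"),
                              runners_only = TRUE) {
  role <- match.arg(role)
  if (length(unique(profiles$colony_id)) > 1)
    stop("profiles must come from a single colony")
  p <- profiles
  if (runners_only)
    p <- p[p$A_L + p$A_F > 0, , drop = FALSE]
  cons <- if (role == "lead") p$C_L else p$C_F
  act <- if (role == "lead") p$A_L else p$A_F
  o <- order(-cons, -act, p$ant_id, method = "radix")
  out <- data.frame(ant_id = p$ant_id[o], consistency = cons[o],
                    activity = act[o], stringsAsFactors = FALSE)
  attr(out, "role") <- role
  attr(out, "colony_id") <- if (nrow(p)) p$colony_id[1] else NA_character_
  class(out) <- c("role_ranking", "data.frame")
  out
}

# round half away from zero (for non-negative x)
.round_half_up <- function(x) floor(x + 0.5)

#' Build a targeted-removal plan
#'
#' Constructs the set of ants to remove before the test emigration.  Every
#' treatment removes `round(0.5 * n_runners)` ants, assembled from the top
#' or bottom quartiles (`round(0.25 * n_runners)` ants) of the two
#' hierarchical rankings:
#'
#' * `leader_removal`: top-ranked leaders + bottom-ranked followers;
#' * `follower_removal`: top-ranked followers + bottom-ranked leaders;
#' * `both_removal`: top-ranked leaders + top-ranked followers;
#' * `control`: bottom-ranked leaders + bottom-ranked followers.
#'
#' The first-listed role's quartile is taken in full; the second role's
#' ranking is then walked in its quartile direction, skipping ants already
#' removed, until the 50% total is reached.  This absorbs overlaps between
#' the two quartiles (an ant prominent in both) and any rounding mismatch
#' between twice the quartile size and the 50% target.
#'
#' @param lead_rank,follow_rank [hierarchical_rank()] outputs over the same
#'   runner pool.
#' @param treatment one of `"leader_removal"`, `"follower_removal"`,
#'   `"both_removal"`, `"control"`.
#' @param colony_id colony identifier recorded in the plan.
#' @return An object of class `removal_plan` with `removed_ids`,
#'   `retained_ids`, `treatment`, `colony_id`, `n_runners`.
#' @export
build_removal_plan <- function(lead_rank, follow_rank,
                               treatment = c("leader_removal",
                                             "follower_removal",
                                             "both_removal", "control"),
                               colony_id = attr(lead_rank, "colony_id")) {
  treatment <- match.arg(treatment)
  runners <- sort(lead_rank$ant_id)
  if (!identical(runners, sort(follow_rank$ant_id)))
    stop("lead and follow rankings must cover the same runner pool")
  n <- length(runners)
  if (n < 4) stop("fewer than 4 tandem runners: quartiles undefined")
  q <- .round_half_up(0.25 * n)
  target <- .round_half_up(0.5 * n)
  top <- function(r) r$ant_id
  bottom <- function(r) rev(r$ant_id)
  pick <- switch(treatment,
    leader_removal = list(first = top(lead_rank), second = bottom(follow_rank)),
    follower_removal = list(first = top(follow_rank), second = bottom(lead_rank)),
    both_removal = list(first = top(lead_rank), second = top(follow_rank)),
    control = list(first = bottom(lead_rank), second = bottom(follow_rank)))
  removed <- pick$first[seq_len(min(q, target))]
  for (id in pick$second) {
    if (length(removed) >= target) break
    if (!(id %in% removed)) removed <- c(removed, id)
  }
  structure(list(colony_id = colony_id, treatment = treatment,
                 removed_ids = sort(removed),
                 retained_ids = sort(setdiff(runners, removed)),
                 n_runners = n, quartile_size = q,
                 target_fraction = 0.5),
            class = "removal_plan")
}

#' @export
print.removal_plan <- function(x, ...) {
  cat("Removal plan (", x$treatment, "), colony ", x$colony_id, "\n", sep = "")
  cat("  runners:", x$n_runners, "| quartile:", x$quartile_size,
      "| removed:", length(x$removed_ids), "\n")
  cat("  removed ids:", paste(x$removed_ids, collapse = " "), "\n")
  invisible(x)
}

#' Removal function for the simulator
#'
#' Returns a `function(baseline_events, roster)` suitable for
#' [simulate_experiment()]'s `removal_fn` argument: it computes baseline
#' experience profiles, ranks the colony's tandem runners hierarchically for
#' both roles, and returns the removal set of the requested treatment.
#'
#' @param treatment treatment label, see [build_removal_plan()].
#' @param baseline_emigrations baseline emigration numbers (default 1:4).
#' @return A function returning the removed ant ids for one colony.
#' @export
treatment_removal_fn <- function(treatment, baseline_emigrations = 1:4) {
  force(treatment)
  function(baseline_events, roster) {
    prof <- experience_profiles(baseline_events,
                                baseline_emigrations = baseline_emigrations)
    plan <- build_removal_plan(hierarchical_rank(prof, "lead"),
                               hierarchical_rank(prof, "follow"),
                               treatment = treatment,
                               colony_id = prof$colony_id[1])
    plan$removed_ids
  }
}
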
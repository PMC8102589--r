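#' Per-ant role consistency and activity profiles
#'
#' Two complementary experience measures are computed from the baseline
#' emigrations for each ant and each role.  *Consistency* is the number of
#' baseline emigrations in which the ant performed the role in at least one
#' tandem run: leading consistency `C_L` and following consistency `C_F`,
#' each ranging from 0 to the number of baselines.  *Activity* is the total
#' number of tandem runs in which the ant performed the role across all
#' baselines: leading activity `A_L` and following activity `A_F`.
#'
#' @param events a `tandem_events` table (all directions; experience counts
#'   every tandem act, including reverse runs and follower switches).
#' @param baseline_emigrations integer vector of emigration numbers that
#'   constitute the baseline (default `1:4`).
#' @param roster optional roster; if given, workers with no baseline tandems
#'   receive all-zero profiles instead of being absent.
#' @return A data frame of class `experience_profiles` with columns
#'   `colony_id`, `ant_id`, `C_L`, `C_F`, `A_L`, `A_F` and attribute
#'   `n_baseline`.
#' @examples
#' ev <- simulate_experiment(sim_config(n_colonies = 1, seed = 1))$events
#' head(experience_profiles(ev))
#' @export
experience_profiles <- function(events, baseline_emigrations = 1:4,
                                roster = NULL) {
  stopifnot(length(baseline_emigrations) >= 1)
  ev <- events[events$emigration %in% baseline_emigrations, , drop = FALSE]
  acts <- rbind(
    data.frame(colony_id = ev$colony_id, ant_id = ev$leader_id,
               emigration = ev$emigration, role = "L",
               stringsAsFactors = FALSE),
    data.frame(colony_id = ev$colony_id, ant_id = ev$follower_id,
               emigration = ev$emigration, role = "F",
               stringsAsFactors = FALSE))
  if (nrow(acts)) {
    key <- factor(paste(acts$colony_id, acts$ant_id, sep = "\r"))
    agg <- function(sel, f) {
      v <- tapply(seq_len(nrow(acts))[sel], droplevels(key[sel]), f)
      out <- setNames(rep(0L, nlevels(key)), levels(key))
      out[names(v)] <- as.integer(v)
      out
    }
    isL <- acts$role == "L"
    A_L <- agg(isL, length)
    A_F <- agg(!isL, length)
    C_L <- agg(isL, function(i) length(unique(acts$emigration[i])))
    C_F <- agg(!isL, function(i) length(unique(acts$emigration[i])))
    first <- !duplicated(key)
    prof <- data.frame(colony_id = acts$colony_id[first],
                       ant_id = acts$ant_id[first],
                       stringsAsFactors = FALSE)
    k <- as.character(key[first])
    prof$C_L <- unname(C_L[k]); prof$C_F <- unname(C_F[k])
    prof$A_L <- unname(A_L[k]); prof$A_F <- unname(A_F[k])
  } else {
    prof <- data.frame(colony_id = character(), ant_id = character(),
                       C_L = integer(), C_F = integer(),
                       A_L = integer(), A_F = integer(),
                       stringsAsFactors = FALSE)
  }
  if (!is.null(roster)) {
    have <- paste(prof$colony_id, prof$ant_id)
    add <- roster[!(paste(roster$colony_id, roster$worker_id) %in% have), ,
                  drop = FALSE]
    if (nrow(add))
      prof <- rbind(prof, data.frame(colony_id = add$colony_id,
                                     ant_id = add$worker_id,
                                     C_L = 0L, C_F = 0L, A_L = 0L, A_F = 0L,
                                     stringsAsFactors = FALSE))
  }
  prof <- prof[order(prof$colony_id, prof$ant_id), ]
  rownames(prof) <- NULL
  attr(prof, "n_baseline") <- length(baseline_emigrations)
  class(prof) <- c("experience_profiles", "data.frame")
  prof
}

#' Per-ant task-switching probabilities
#'
#' Orders each ant's tandem acts within each emigration by rank and counts
#' transitions between consecutive acts of that ant.  Transitions are never
#' counted across emigration boundaries.  The switching probability
#' `P(F->L)` is the number of follower acts whose next same-emigration act
#' was a leader act, divided by the number of follower acts that have a
#' same-emigration successor act (and analogously for `P(L->F)`).  An ant
#' whose acts in a role all lack successors has an undefined (`NA`)
#' probability for that role.
#'
#' @param events a `tandem_events` table, typically restricted to the
#'   baseline emigrations before calling.
#' @return A data frame of class `switch_stats` with columns `colony_id`,
#'   `ant_id`, `n_F_succ`, `n_FL`, `n_L_succ`, `n_LF`, `P_FL`, `P_LF`.
#' @examples
#' # an ant that followed once then led three times (one emigration),
#' # then followed twice and led once (next emigration)
#' ev <- worked_example_events()
#' compute_switch_probabilities(ev)
#' @export
compute_switch_probabilities <- function(events) {
  acts <- rbind(
    data.frame(colony_id = events$colony_id, ant_id = events$leader_id,
               emigration = events$emigration, rank = events$rank,
               role = "L", stringsAsFactors = FALSE),
    data.frame(colony_id = events$colony_id, ant_id = events$follower_id,
               emigration = events$emigration, rank = events$rank,
               role = "F", stringsAsFactors = FALSE))
  acts <- acts[order(acts$colony_id, acts$ant_id, acts$emigration, acts$rank), ]
  n <- nrow(acts)
  res <- list()
  if (n) {
    same_ant <- c(acts$colony_id[-1] == acts$colony_id[-n] &
                    acts$ant_id[-1] == acts$ant_id[-n], FALSE)
    same_em <- c(acts$emigration[-1] == acts$emigration[-n], FALSE)
    has_succ <- same_ant & same_em
    next_role <- c(acts$role[-1], NA)
    key <- paste(acts$colony_id, acts$ant_id, sep = "\r")
    f_succ <- has_succ & acts$role == "F"
    l_succ <- has_succ & acts$role == "L"
    tab <- function(sel) {
      v <- tapply(sel, key, sum)
      v[is.na(v)] <- 0
      v
    }
    n_F_succ <- tab(f_succ)
    n_FL <- tab(f_succ & next_role == "L")
    n_L_succ <- tab(l_succ)
    n_LF <- tab(l_succ & next_role == "F")
    uk <- names(n_F_succ)
    parts <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
    res <- data.frame(colony_id = parts[, 1], ant_id = parts[, 2],
                      n_F_succ = as.integer(n_F_succ),
                      n_FL = as.integer(n_FL),
                      n_L_succ = as.integer(n_L_succ),
                      n_LF = as.integer(n_LF),
                      stringsAsFactors = FALSE)
    res$P_FL <- ifelse(res$n_F_succ > 0, res$n_FL / res$n_F_succ, NA_real_)
    res$P_LF <- ifelse(res$n_L_succ > 0, res$n_LF / res$n_L_succ, NA_real_)
  } else {
    res <- data.frame(colony_id = character(), ant_id = character(),
                      n_F_succ = integer(), n_FL = integer(),
                      n_L_succ = integer(), n_LF = integer(),
                      P_FL = numeric(), P_LF = numeric(),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(res$colony_id, res$ant_id), ]
  rownames(res) <- NULL
  class(res) <- c("switch_stats", "data.frame")
  res
}

#' Population-level pooled switching probabilities
#'
#' Pools transition counts over ants: `sum(n_FL) / sum(n_F_succ)` (and the
#' analogue for L->F).  This is a pooled ratio, not a mean of per-ant
#' ratios, so ants contribute in proportion to their number of scorable
#' transitions.  Per-ant means are also returned for comparison.
#'
#' @param stats a `switch_stats` data frame.
#' @return A list with `P_FL`, `P_LF` (pooled), `P_FL_mean`, `P_LF_mean`
#'   (means of defined per-ant ratios) and the pooled transition counts.
#' @export
overall_switch_probabilities <- function(stats) {
  stopifnot(nrow(stats) > 0)
  nF <- sum(stats$n_F_succ); nL <- sum(stats$n_L_succ)
  if (nF == 0 && nL == 0)
    warning("no scorable transitions: both probabilities undefined")
  list(P_FL = if (nF > 0) sum(stats$n_FL) / nF else NA_real_,
       P_LF = if (nL > 0) sum(stats$n_LF) / nL else NA_real_,
       P_FL_mean = mean(stats$P_FL, na.rm = TRUE),
       P_LF_mean = mean(stats$P_LF, na.rm = TRUE),
       n_F_succ = nF, n_L_succ = nL)
}

#' Cross-emigration repeatability of role counts
#'
#' For each ordered pair of baseline emigrations (i, j), computes the
#' Spearman rank correlation across ants of per-ant tandem counts in a role:
#' leads in i vs leads in j (`role = "lead"`), follows vs follows
#' (`"follow"`), or leads in i vs follows in j for j > i
#' (`"lead_vs_follow"`).  Ants with zero counts in both emigrations of a
#' pair are excluded from that pair; pairs with fewer than 3 contributing
#' ants are left `NA`.
#'
#' @param events a `tandem_events` table.
#' @param role one of `"lead"`, `"follow"`, `"lead_vs_follow"`.
#' @param baseline_emigrations emigration numbers to correlate (default 1:4).
#' @return A list of matrices `r`, `p`, `n` indexed by emigration pair.
#' @export
cross_emigration_correlations <- function(events,
                                          role = c("lead", "follow",
                                                   "lead_vs_follow"),
                                          baseline_emigrations = 1:4) {
  role <- match.arg(role)
  ems <- sort(baseline_emigrations)
  stopifnot(length(ems) >= 2)
  ev <- events[events$emigration %in% ems, , drop = FALSE]
  uid <- function(col, ant) paste(col, ant, sep = "\r")
  ants <- unique(c(uid(ev$colony_id, ev$leader_id),
                   uid(ev$colony_id, ev$follower_id)))
  count_role <- function(em, which_role) {
    id <- if (which_role == "L") uid(ev$colony_id, ev$leader_id) else
      uid(ev$colony_id, ev$follower_id)
    tab <- table(factor(id[ev$emigration == em], levels = ants))
    as.numeric(tab)
  }
  k <- length(ems)
  r <- p <- nn <- matrix(NA_real_, k, k, dimnames = list(ems, ems))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (b <= a) next
    x <- switch(role,
                lead = count_role(ems[a], "L"),
                follow = count_role(ems[a], "F"),
                lead_vs_follow = count_role(ems[a], "L"))
    y <- switch(role,
                lead = count_role(ems[b], "L"),
                follow = count_role(ems[b], "F"),
                lead_vs_follow = count_role(ems[b], "F"))
    keep <- x > 0 | y > 0
    x <- x[keep]; y <- y[keep]
    nn[a, b] <- length(x)
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) next
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    r[a, b] <- unname(ct$estimate)
    p[a, b] <- ct$p.value
  }
  structure(list(role = role, r = r, p = p, n = nn),
            class = "emigration_correlations")
}

#' @export
print.emigration_correlations <- function(x, ...) {
  cat("Cross-emigration Spearman correlations (", x$role, ")\n", sep = "")
  cat("rho:\n"); print(round(x$r, 3))
  cat("p:\n"); print(signif(x$p, 3))
  invisible(x)
}

#' Within-pair consistency differences
#'
#' For each tandem run, the signed difference in leading consistency between
#' its leader and its follower (`d_lead = C_L(leader) - C_L(follower)`), and
#' the difference in following consistency between its follower and its
#' leader (`d_follow = C_F(follower) - C_F(leader)`), using profiles computed
#' on the baseline emigrations.  Positive values mean the ant performing a
#' role was the more consistent of the pair in that role.  Participants
#' without a profile are treated as all-zero (never seen in a baseline
#' tandem) and counted.
#'
#' @param events tandem events to score (typically the test emigration).
#' @param profiles an `experience_profiles` data frame from the baselines.
#' @return A list with the per-tandem data frame `per_tandem`, the per-colony
#'   mean differences `colony_means`, and `n_unprofiled` participants that
#'   defaulted to zero.
#' @export
pair_consistency_differences <- function(events, profiles) {
  key <- paste(profiles$colony_id, profiles$ant_id, sep = "\r")
  CL <- setNames(profiles$C_L, key)
  CF <- setNames(profiles$C_F, key)
  lk <- paste(events$colony_id, events$leader_id, sep = "\r")
  fk <- paste(events$colony_id, events$follower_id, sep = "\r")
  n_unprofiled <- sum(!(unique(c(lk, fk)) %in% key))
  get0 <- function(map, k) ifelse(is.na(map[k]), 0, map[k])
  per <- data.frame(colony_id = events$colony_id,
                    emigration = events$emigration, rank = events$rank,
                    d_lead = unname(get0(CL, lk) - get0(CL, fk)),
                    d_follow = unname(get0(CF, fk) - get0(CF, lk)),
                    stringsAsFactors = FALSE)
  cm <- aggregate(cbind(d_lead, d_follow) ~ colony_id, data = per, FUN = mean)
  list(per_tandem = per, colony_means = cm, n_unprofiled = n_unprofiled)
}

#' Directed tandem recruitment network
#'
#' Builds the colony's recruitment network: one node per participating ant
#' and one directed edge per tandem run, pointing from leader to follower.
#' Parallel edges are kept (repeated leader-follower pairs).  Each node
#' carries `n_led`, the number of tandem runs it led in the supplied events.
#'
#' @param events a `tandem_events` table (typically one colony's baselines).
#' @return An `igraph` directed multigraph with edge attributes `emigration`
#'   and `rank`.
#' @export
build_recruitment_network <- function(events) {
  if (nrow(events) == 0)
    return(igraph::make_empty_graph(n = 0, directed = TRUE))
  edges <- data.frame(from = paste(events$colony_id, events$leader_id),
                      to = paste(events$colony_id, events$follower_id),
                      emigration = events$emigration, rank = events$rank,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  led <- table(edges$from)
  n_led <- rep(0, igraph::vcount(g))
  names(n_led) <- igraph::V(g)$name
  n_led[names(led)] <- as.numeric(led)
  igraph::set_vertex_attr(g, "n_led", value = unname(n_led))
}

#' Participation summary across emigrations
#'
#' For each (colony, emigration), the fraction of the colony's workforce
#' that engaged in at least one tandem run, and the fractions acting as a
#' leader or as a follower at least once.  The roster supplies the workforce
#' size.
#'
#' @param events a `tandem_events` table.
#' @param roster roster data frame (`colony_id`, `worker_id`).
#' @return A data frame with one row per (colony, emigration) and the
#'   attribute `means` holding the grand means of the three fractions.
#' @export
participation_summary <- function(events, roster) {
  n_workers <- table(roster$colony_id)
  keys <- unique(events[, c("colony_id", "emigration")])
  keys <- keys[order(keys$colony_id, keys$emigration), ]
  res <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- events$colony_id == keys$colony_id[i] &
      events$emigration == keys$emigration[i]
    nl <- unique(events$leader_id[sel])
    nf <- unique(events$follower_id[sel])
    N <- as.numeric(n_workers[keys$colony_id[i]])
    data.frame(colony_id = keys$colony_id[i], emigration = keys$emigration[i],
               frac_participating = length(union(nl, nf)) / N,
               frac_leading = length(nl) / N,
               frac_following = length(nf) / N,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "means") <- colMeans(res[, 3:5])
  res
}

#' Worked-example act sequences as an event table
#'
#' A minimal one-colony event table in which the focal ant `a` followed once
#' and then led three times in emigration 1 (sequence F,L,L,L) and followed
#' twice then led once in emigration 2 (F,F,L).  Partner ants are distinct
#' bystanders, so only `a`'s transitions are of interest.  Useful as a
#' self-check for [compute_switch_probabilities()]: `a` has
#' `P(F->L) = 2/3` and `P(L->F) = 0`.
#'
#' @param ant id of the focal ant (default `"a"`).
#' @return A validated `tandem_events` table of 7 runs.
#' @export
worked_example_events <- function(ant = "a") {
  roles <- list(`1` = c("F", "L", "L", "L"), `2` = c("F", "F", "L"))
  rows <- list()
  k <- 0
  for (em in names(roles)) for (i in seq_along(roles[[em]])) {
    k <- k + 1
    partner <- sprintf("p%02d", k)
    lead <- roles[[em]][i] == "L"
    rows[[k]] <- data.frame(
      colony_id = "C1", replicate_id = "A", emigration = as.integer(em),
      rank = i,
      leader_id = if (lead) ant else partner,
      follower_id = if (lead) partner else ant,
      direction = "forward", follower_switch = FALSE, outcome = "success",
      break_x = NA_real_, break_y = NA_real_,
      t_start = (i - 1) * 100, t_end = (i - 1) * 100 + 60,
      destination_nest = "new1", stringsAsFactors = FALSE)
  }
  tandem_events(do.call(rbind, rows))
}
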
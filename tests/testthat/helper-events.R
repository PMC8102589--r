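# builders for small hand-written event tables

event_row <- function(colony = "C1", replicate = "A", emigration = 1L,
                      rank = 1L, leader = "L1", follower = "F1",
                      direction = "forward", follower_switch = FALSE,
                      outcome = "success", break_x = NA_real_,
                      break_y = NA_real_, t_start = 0, t_end = 60,
                      destination = "new1") {
  if (outcome == "fail" && destination == "new1") destination <- "none"
  data.frame(colony_id = colony, replicate_id = replicate,
             emigration = as.integer(emigration), rank = as.integer(rank),
             leader_id = leader, follower_id = follower,
             direction = direction, follower_switch = follower_switch,
             outcome = outcome, break_x = break_x, break_y = break_y,
             t_start = t_start, t_end = t_end,
             destination_nest = destination, stringsAsFactors = FALSE)
}

# events realising given per-emigration role sequences for a focal ant,
# with distinct single-use partners
events_from_roles <- function(roles_by_emigration, ant = "a",
                              colony = "C1") {
  rows <- list(); k <- 0
  for (em in seq_along(roles_by_emigration)) {
    roles <- roles_by_emigration[[em]]
    for (i in seq_along(roles)) {
      k <- k + 1
      partner <- sprintf("p%02d", k)
      lead <- roles[i] == "L"
      rows[[k]] <- event_row(colony = colony, emigration = em, rank = i,
                             leader = if (lead) ant else partner,
                             follower = if (lead) partner else ant,
                             t_start = (i - 1) * 100,
                             t_end = (i - 1) * 100 + 60)
    }
  }
  tandem_events(do.call(rbind, rows))
}

# independent brute-force transition counter used as an oracle: walks each
# ant's (emigration, rank)-ordered acts and tallies consecutive same-
# emigration pairs
brute_force_switch <- function(events, ant, colony = "C1") {
  acts <- list()
  for (i in seq_len(nrow(events))) {
    if (events$colony_id[i] != colony) next
    if (events$leader_id[i] == ant)
      acts[[length(acts) + 1]] <- c(events$emigration[i], events$rank[i], 1)
    if (events$follower_id[i] == ant)
      acts[[length(acts) + 1]] <- c(events$emigration[i], events$rank[i], 0)
  }
  if (!length(acts))
    return(list(n_F_succ = 0, n_FL = 0, n_L_succ = 0, n_LF = 0))
  m <- do.call(rbind, acts)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  n_F_succ <- n_FL <- n_L_succ <- n_LF <- 0
  if (nrow(m) > 1) for (i in 1:(nrow(m) - 1)) {
    if (m[i, 1] != m[i + 1, 1]) next
    if (m[i, 3] == 0) {
      n_F_succ <- n_F_succ + 1
      if (m[i + 1, 3] == 1) n_FL <- n_FL + 1
    } else {
      n_L_succ <- n_L_succ + 1
      if (m[i + 1, 3] == 0) n_LF <- n_LF + 1
    }
  }
  list(n_F_succ = n_F_succ, n_FL = n_FL, n_L_succ = n_L_succ, n_LF = n_LF)
}
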
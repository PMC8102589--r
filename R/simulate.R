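#' Configuration for the synthetic emigration generator
#'
#' Defines the study conditions emulated by [simulate_experiment()]: colonies
#' of paint-marked workers perform `n_baseline` baseline emigrations plus an
#' optional test emigration; each emigration produces a ranked sequence of
#' tandem runs between a leader and a follower.
#'
#' The generator is act-sequence based.  Each emigration, a set of *core*
#' participants is drawn (weighted by a latent participation propensity);
#' each core ant receives a chain of tandem acts whose roles follow a
#' per-ant Markov switching process: the first act is a leading act with a
#' probability shaped by the ant's latent leading propensity, and after a
#' following act the next act is a leading act with probability
#' `plogis(qlogis(pi_FL) + fl_mod * (C_L_to_date - switch_center))`
#' (analogously `pi_LF`, `lf_mod` and `C_F` to date for leading acts), so
#' consistent leaders switch back into leading more readily.  Tandem runs
#' are then assembled by pairing the next unconsumed leading act with the
#' next unconsumed following act; when one role is under-supplied, a
#' previously uninvolved nestmate is recruited for a single act (weighted by
#' its propensity for that role), which reproduces the large pool of
#' one-time followers seen in real emigrations.  Because every chain act is
#' realised in order, the per-tandem switching probabilities of the
#' generated records match the generating Markov parameters without
#' selection bias.
#'
#' Tandem success is Bernoulli with
#' `logit(p) = alpha + beta_CL * C_L_to_date(leader) + gamma_rank * rank`;
#' failures break up on the corridor towards a new nest with Gaussian
#' lateral scatter, successes draw a log-normal duration.
#'
#' Defaults emulate the field conditions the analyses assume: 12 colonies of
#' ~90 workers, 4 baselines + 1 test emigration, a median of 35 tandem runs
#' per emigration (clipped to 13--66), ~32% of the workforce in at least one
#' tandem per emigration with leading (~19%) more exclusive than following
#' (~28%), pooled switching probabilities near P(F->L) = 0.57 and
#' P(L->F) = 0.16, and success increasing with leader consistency.  Note
#' that `pi_FL`/`pi_LF` are per-act chain parameters; the default values
#' (0.53/0.13) together with the positive consistency modulation place the
#' pooled observed probabilities at the 0.57/0.16 level.
#'
#' @param n_colonies number of colonies.
#' @param workers_per_colony workers per colony (field colonies held 71-116).
#' @param n_baseline number of baseline emigrations.
#' @param include_test_emigration generate the (n_baseline+1)-th emigration?
#' @param p_participate target mean per-emigration participation fraction.
#' @param participate_sd SD of the latent participation propensity.
#' @param lead_sd,follow_sd SDs of the latent leading/following propensities.
#' @param role_cor correlation between leading and following propensities.
#' @param core_share fraction of the participation target recruited as core
#'   (multi-act) participants; the rest join as single-act fillers.
#' @param act_coupling coupling of chain length to the leading propensity
#'   (leaders perform more acts, making leading the more repeatable role).
#' @param core_act_frac fraction of the act budget `2 * n_tandems` assigned
#'   to core chains.
#' @param lead_state_p baseline probability that a chain starts with a
#'   leading act (before the leading propensity is added).
#' @param pi_FL,pi_LF baseline per-act switching probabilities F->L, L->F.
#' @param fl_mod,lf_mod logit-scale modulation of switching by the ant's
#'   consistency to date (per emigration unit).
#' @param switch_center consistency value at which modulation is zero.
#' @param alpha success-model intercept (logit scale).
#' @param beta_CL success-model effect of leader consistency to date
#'   (log-odds per emigration).
#' @param gamma_rank success-model effect of within-emigration rank.
#' @param duration_meanlog,duration_sdlog log-normal parameters of the
#'   duration (s) of successful runs.
#' @param breakup_sd lateral SD (cm) of break-up locations about the route.
#' @param p_reverse probability a run is a reverse tandem.
#' @param p_follower_switch probability of a mid-run follower replacement.
#' @param tandems_meanlog,tandems_sdlog,tandems_min,tandems_max log-normal
#'   parameters and clipping range of the per-emigration tandem-count draw
#'   that sets the act budget.
#' @param seed root random seed; all colony substreams derive from it.
#' @return A `sim_config` list.
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(n_colonies = 12,
                       workers_per_colony = 90,
                       n_baseline = 4,
                       include_test_emigration = TRUE,
                       p_participate = 0.32,
                       participate_sd = 1.0,
                       lead_sd = 1.6,
                       follow_sd = 0.8,
                       role_cor = -0.3,
                       core_share = 0.64,
                       act_coupling = 0.25,
                       core_act_frac = 0.80,
                       lead_state_p = 0.08,
                       pi_FL = 0.53,
                       pi_LF = 0.13,
                       fl_mod = 0.4,
                       lf_mod = 0.4,
                       switch_center = 0,
                       alpha = -0.5,
                       beta_CL = 0.8,
                       gamma_rank = 0,
                       duration_meanlog = log(600),
                       duration_sdlog = 0.4,
                       breakup_sd = 3,
                       p_reverse = 0.10,
                       p_follower_switch = 0.08,
                       tandems_meanlog = log(35),
                       tandems_sdlog = 0.32,
                       tandems_min = 13,
                       tandems_max = 66,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_colonies >= 1, cfg$workers_per_colony >= 2,
            cfg$n_baseline >= 1,
            cfg$p_participate >= 0, cfg$p_participate <= 1,
            cfg$pi_FL >= 0, cfg$pi_FL <= 1, cfg$pi_LF >= 0, cfg$pi_LF <= 1,
            cfg$p_reverse >= 0, cfg$p_reverse <= 1,
            cfg$p_follower_switch >= 0, cfg$p_follower_switch <= 1,
            cfg$tandems_min >= 1, cfg$tandems_max >= cfg$tandems_min,
            abs(cfg$role_cor) <= 1, cfg$core_share > 0, cfg$core_share <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic substream seed for a colony, kept inside 32-bit range
.colony_seed <- function(seed, colony_index) {
  as.integer((as.double(seed) * 48271 + colony_index * 1013904223) %% 2147483647)
}

#' Generate one colony's roster and latent propensities
#'
#' Deterministic given `(config$seed, colony_index)`.  Each worker carries
#' three latent propensities on the logit scale: participation (`z_p`),
#' leading (`z_l`) and following (`z_f`); the last two are drawn from a
#' bivariate normal with correlation `config$role_cor`.  With
#' `p_participate = 0`, `z_p` is `-Inf` for every worker and no ant can be
#' recruited into any tandem downstream.
#'
#' @param config a [sim_config()].
#' @param colony_index colony number (1-based).
#' @return A list with `roster` (colony_id, worker_id), `workers` (latent
#'   propensities per worker) and `colony_id`.
#' @export
generate_colony_roster <- function(config, colony_index) {
  set.seed(.colony_seed(config$seed, colony_index))
  n <- config$workers_per_colony
  colony_id <- sprintf("C%02d", colony_index)
  ids <- sprintf("w%03d", seq_len(n))
  z_p <- stats::rnorm(n, 0, config$participate_sd)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  z_l <- config$lead_sd * z1
  z_f <- config$follow_sd * (config$role_cor * z1 +
                               sqrt(1 - config$role_cor^2) * z2)
  if (config$p_participate == 0) z_p <- rep(-Inf, n)
  workers <- data.frame(colony_id = colony_id, ant_id = ids,
                        z_p = z_p, z_l = z_l, z_f = z_f,
                        stringsAsFactors = FALSE)
  list(colony_id = colony_id,
       roster = data.frame(colony_id = colony_id, worker_id = ids,
                           stringsAsFactors = FALSE),
       workers = workers)
}

# clamp a probability parameter, honouring exact 0 and 1
.clamp_p <- function(base, shift) {
  if (base <= 0) return(0)
  if (base >= 1) return(1)
  stats::plogis(stats::qlogis(base) + shift)
}

.empty_emigration <- function(st) {
  empty <- data.frame(
    colony_id = character(), replicate_id = character(),
    emigration = integer(), rank = integer(),
    leader_id = character(), follower_id = character(),
    direction = character(), follower_switch = logical(),
    outcome = character(), break_x = numeric(), break_y = numeric(),
    t_start = numeric(), t_end = numeric(),
    destination_nest = character(), stringsAsFactors = FALSE)
  list(events = empty, psucc = numeric(0), st = st)
}

# one emigration for one colony; st carries per-ant running consistency
.sim_emigration <- function(cfg, workers, emigration, replicate_id, geom, st) {
  n_w <- nrow(workers)
  n_t_budget <- round(stats::rlnorm(1, cfg$tandems_meanlog, cfg$tandems_sdlog))
  n_t_budget <- max(cfg$tandems_min, min(cfg$tandems_max, n_t_budget))
  if (all(!is.finite(workers$z_p)) || n_w < 2) return(.empty_emigration(st))

  # core participants: multi-act ants drawn by participation propensity
  n_core <- round(cfg$p_participate * n_w * cfg$core_share)
  n_core <- max(2, min(n_core, n_w, 2 * n_t_budget - 2))
  w_part <- exp(workers$z_p - max(workers$z_p))
  cores <- sample.int(n_w, n_core, prob = w_part)
  # chain lengths: 1 + Poisson extras, longer for strong leaders
  extra_target <- max(0, 2 * n_t_budget * cfg$core_act_frac - n_core)
  lam_raw <- exp(cfg$act_coupling * workers$z_l[cores])
  lam <- extra_target * lam_raw / sum(lam_raw)
  k <- 1L + stats::rpois(n_core, lam)

  # per-ant role chains from the Markov switching process
  chains <- vector("list", n_core)
  for (j in seq_len(n_core)) {
    i <- cores[j]
    p0 <- .clamp_p(cfg$lead_state_p, workers$z_l[i])
    p_fl <- .clamp_p(cfg$pi_FL, cfg$fl_mod * (st$C_L[i] - cfg$switch_center))
    p_lf <- .clamp_p(cfg$pi_LF, cfg$lf_mod * (st$C_F[i] - cfg$switch_center))
    roles <- character(k[j])
    roles[1] <- if (stats::runif(1) < p0) "L" else "F"
    if (k[j] > 1) for (a in 2:k[j]) {
      roles[a] <- if (roles[a - 1] == "F") {
        if (stats::runif(1) < p_fl) "L" else "F"
      } else {
        if (stats::runif(1) < p_lf) "F" else "L"
      }
    }
    chains[[j]] <- roles
  }

  # assemble tandems: consume chain acts in order, pair L with F acts,
  # recruit single-act fillers when a role is under-supplied
  ptr <- rep(1L, n_core)
  left <- k
  unused <- setdiff(seq_len(n_w), cores)
  pop_filler <- function(role_w) {
    if (!length(unused)) return(NA_integer_)
    w <- exp(role_w[unused] - max(role_w[unused]))
    pick <- if (length(unused) == 1L) unused else
      unused[sample.int(length(unused), 1L, prob = w)]
    unused <<- setdiff(unused, pick)
    pick
  }
  lead_i <- integer(0); foll_i <- integer(0)
  repeat {
    if (!any(left > 0)) break
    readyL <- cores[left > 0 & vapply(seq_len(n_core), function(j)
      left[j] > 0 && chains[[j]][ptr[j]] == "L", TRUE)]
    readyF <- cores[left > 0 & vapply(seq_len(n_core), function(j)
      left[j] > 0 && chains[[j]][ptr[j]] == "F", TRUE)]
    if (length(readyL)) {
      li <- if (length(readyL) == 1L) readyL else sample(readyL, 1L)
    } else {
      li <- pop_filler(workers$z_l)
      if (is.na(li)) break
    }
    fcand <- setdiff(readyF, li)
    if (length(fcand)) {
      fi <- if (length(fcand) == 1L) fcand else sample(fcand, 1L)
    } else {
      fi <- pop_filler(workers$z_f)
      if (is.na(fi)) break
    }
    lead_i <- c(lead_i, li); foll_i <- c(foll_i, fi)
    for (x in c(li, fi)) {
      j <- match(x, cores)
      if (!is.na(j)) { ptr[j] <- ptr[j] + 1L; left[j] <- left[j] - 1L }
    }
  }
  n_t <- length(lead_i)
  if (n_t == 0) return(.empty_emigration(st))

  # success depends on the leader's consistency to date and rank
  cl <- st$C_L[lead_i]
  psucc <- stats::plogis(cfg$alpha + cfg$beta_CL * cl +
                           cfg$gamma_rank * seq_len(n_t))
  succ <- stats::runif(n_t) < psucc
  direction <- ifelse(stats::runif(n_t) < cfg$p_reverse, "reverse", "forward")
  fswitch <- stats::runif(n_t) < cfg$p_follower_switch
  nest <- sample(c("new1", "new2"), n_t, replace = TRUE)
  dur <- stats::rlnorm(n_t, cfg$duration_meanlog, cfg$duration_sdlog)
  t_start <- sort(round(stats::runif(n_t, 0, 12000), 1))
  break_x <- rep(NA_real_, n_t); break_y <- rep(NA_real_, n_t)
  dest <- rep("none", n_t)
  for (t in seq_len(n_t)) {
    from <- if (direction[t] == "forward") geom$initial_entrance else
      if (nest[t] == "new1") geom$new1_entrance else geom$new2_entrance
    to <- if (direction[t] == "forward")
      (if (nest[t] == "new1") geom$new1_entrance else geom$new2_entrance) else
        geom$initial_entrance
    if (succ[t]) {
      dest[t] <- if (direction[t] == "forward") nest[t] else "initial"
    } else {
      frac <- stats::runif(1, 0.02, 0.98)
      axis <- (to - from) / sqrt(sum((to - from)^2))
      perp <- c(-axis[2], axis[1])
      pt <- from + frac * (to - from) + stats::rnorm(1, 0, cfg$breakup_sd) * perp
      break_x[t] <- min(max(round(pt[1], 2), 0), geom$arena_x)
      break_y[t] <- min(max(round(pt[2], 2), 0), geom$arena_y)
      dur[t] <- dur[t] * frac
    }
  }
  t_end <- round(t_start + dur, 1)

  # update running consistency with this emigration's realised acts
  led <- unique(lead_i); fol <- unique(foll_i)
  st$C_L[led] <- st$C_L[led] + 1L
  st$C_F[fol] <- st$C_F[fol] + 1L

  events <- data.frame(
    colony_id = workers$colony_id[1], replicate_id = replicate_id,
    emigration = emigration, rank = seq_len(n_t),
    leader_id = workers$ant_id[lead_i], follower_id = workers$ant_id[foll_i],
    direction = direction, follower_switch = fswitch,
    outcome = ifelse(succ, "success", "fail"),
    break_x = break_x, break_y = break_y,
    t_start = t_start, t_end = t_end,
    destination_nest = dest, stringsAsFactors = FALSE)
  list(events = events, psucc = psucc, st = st)
}

#' Simulate a multi-colony emigration experiment
#'
#' Generates tandem-run events for `n_baseline` baseline emigrations per
#' colony, plus (optionally) a test emigration, with known ground truth.
#' All randomness flows from `config$seed` through per-colony substreams,
#' so the output is reproducible and colonies are independent.
#'
#' If `removal_fn` is supplied, it is called per colony after the baselines
#' with that colony's baseline events and roster and must return a character
#' vector of worker ids to exclude from the test emigration (the targeted
#' removal); see [treatment_removal_fn()].
#'
#' @param config a [sim_config()].
#' @param removal_fn optional `function(baseline_events, roster) -> ids`.
#' @param geometry an [arena_geometry()].
#' @return A list with `events` (validated [tandem_events()] table),
#'   `roster`, and `truth` (per-worker latent propensities, per-event
#'   success probabilities aligned with `events`, generating parameters,
#'   removed ids per colony).
#' @examples
#' sim <- simulate_experiment(sim_config(n_colonies = 2, seed = 42))
#' table(sim$events$emigration)
#' @export
simulate_experiment <- function(config, removal_fn = NULL,
                                geometry = arena_geometry()) {
  stopifnot(inherits(config, "sim_config"))
  reps <- rep(c("A", "B", "C"), each = ceiling(config$n_colonies / 3),
              length.out = config$n_colonies)
  all_events <- list(); all_roster <- list(); all_workers <- list()
  all_psucc <- list(); removed <- list()
  old <- .save_seed(); on.exit(.restore_seed(old))
  for (ci in seq_len(config$n_colonies)) {
    col <- generate_colony_roster(config, ci)
    st <- list(C_L = integer(config$workers_per_colony),
               C_F = integer(config$workers_per_colony))
    col_events <- list(); col_psucc <- list()
    for (em in seq_len(config$n_baseline)) {
      out <- .sim_emigration(config, col$workers, em, reps[ci], geometry, st)
      col_events[[em]] <- out$events
      col_psucc[[em]] <- out$psucc
      st <- out$st
    }
    if (config$include_test_emigration) {
      workers_test <- col$workers
      st_test <- st
      if (!is.null(removal_fn)) {
        base_ev <- tandem_events(do.call(rbind, col_events))
        rm_ids <- removal_fn(base_ev, col$roster)
        removed[[col$colony_id]] <- rm_ids
        keep <- !(col$workers$ant_id %in% rm_ids)
        workers_test <- col$workers[keep, , drop = FALSE]
        st_test <- list(C_L = st$C_L[keep], C_F = st$C_F[keep])
      }
      out <- .sim_emigration(config, workers_test, config$n_baseline + 1L,
                             reps[ci], geometry, st_test)
      col_events[[config$n_baseline + 1L]] <- out$events
      col_psucc[[config$n_baseline + 1L]] <- out$psucc
    }
    all_events[[ci]] <- do.call(rbind, col_events)
    all_psucc[[ci]] <- unlist(col_psucc)
    all_roster[[ci]] <- col$roster
    all_workers[[ci]] <- col$workers
  }
  events <- tandem_events(do.call(rbind, all_events))
  roster <- do.call(rbind, all_roster)
  truth <- list(workers = do.call(rbind, all_workers),
                p_success = unlist(all_psucc),
                params = config,
                removed = removed)
  validate_events(events, roster)
  list(events = events, roster = roster, truth = truth)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic emigration configuration\n")
  cat("  colonies:", x$n_colonies, "x", x$workers_per_colony, "workers;",
      x$n_baseline, "baseline emigrations",
      if (x$include_test_emigration) "+ test emigration" else "", "\n")
  cat("  participation target:", x$p_participate,
      "| switching pi_FL/pi_LF:", x$pi_FL, "/", x$pi_LF, "\n")
  cat("  success model: logit(p) =", x$alpha, "+", x$beta_CL, "* C_L +",
      x$gamma_rank, "* rank\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
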
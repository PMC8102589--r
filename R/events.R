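#' Construct a table of tandem-run events
#'
#' A tandem-run event table holds one row per observed tandem run: the colony
#' and replicate it belongs to, the emigration number (1--5), the rank of the
#' run within its emigration, the leader and follower identities, the run
#' direction (`forward` from the initial nest towards a new nest, `reverse`
#' from a new nest back), whether the follower was replaced mid-run
#' (`follower_switch`), the outcome (`success` if the pair reached a new nest,
#' `fail` if they broke apart en route), break-up coordinates in cm (failures
#' only), start/end times in seconds, and the destination nest.
#'
#' Ranks must form a gapless sequence 1..n within each (colony, emigration).
#' If `rank` is missing it is assigned from `t_start`, ties broken by row
#' order.
#'
#' @param df data frame with columns `colony_id`, `replicate_id`,
#'   `emigration`, `rank`, `leader_id`, `follower_id`, `direction`,
#'   `follower_switch`, `outcome`, `break_x`, `break_y`, `t_start`, `t_end`,
#'   `destination_nest`.
#' @param roster optional worker roster (see [read_roster()]); if supplied,
#'   every leader and follower must appear on their colony's roster.
#' @param validate validate invariants (default `TRUE`).
#' @return A `tandem_events` data frame.
#' @seealso [read_events()], [write_events()], [validate_events()]
#' @export
tandem_events <- function(df, roster = NULL, validate = TRUE) {
  missing_cols <- setdiff(.event_cols, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[, .event_cols]
  df$colony_id <- as.character(df$colony_id)
  df$replicate_id <- as.character(df$replicate_id)
  df$emigration <- as.integer(df$emigration)
  df$leader_id <- as.character(df$leader_id)
  df$follower_id <- as.character(df$follower_id)
  df$direction <- as.character(df$direction)
  df$follower_switch <- as.logical(df$follower_switch)
  df$outcome <- as.character(df$outcome)
  df$break_x <- as.numeric(df$break_x)
  df$break_y <- as.numeric(df$break_y)
  df$t_start <- as.numeric(df$t_start)
  df$t_end <- as.numeric(df$t_end)
  df$destination_nest <- as.character(df$destination_nest)
  if (nrow(df) > 0 && all(is.na(df$rank))) {
    df$rank <- NA_integer_
    for (key in unique(paste(df$colony_id, df$emigration))) {
      i <- which(paste(df$colony_id, df$emigration) == key)
      df$rank[i] <- rank(df$t_start[i], ties.method = "first")
    }
  }
  df$rank <- as.integer(df$rank)
  rownames(df) <- NULL
  class(df) <- c("tandem_events", "data.frame")
  if (validate) validate_events(df, roster)
  df
}

.event_cols <- c("colony_id", "replicate_id", "emigration", "rank",
                 "leader_id", "follower_id", "direction", "follower_switch",
                 "outcome", "break_x", "break_y", "t_start", "t_end",
                 "destination_nest")

#' Validate a tandem-event table
#'
#' Checks every event invariant and fails with a row-addressable message on
#' the first violation found:
#' * leader and follower differ;
#' * `direction` in \{forward, reverse\}, `outcome` in \{success, fail\};
#' * failures (and only failures) carry break-up coordinates, inside the
#'   arena bounds (0 <= x <= 46, 0 <= y <= 78);
#' * `t_end >= t_start`;
#' * ranks within each (colony, emigration) are 1..n with no gaps or
#'   duplicates;
#' * with a roster, all participants belong to their colony's roster.
#'
#' @param events a `tandem_events` table.
#' @param roster optional roster data frame (`colony_id`, `worker_id`).
#' @param arena_x,arena_y arena bounds in cm.
#' @return `events`, invisibly, if valid; otherwise an error.
#' @export
validate_events <- function(events, roster = NULL, arena_x = 46, arena_y = 78) {
  df <- events
  bad <- function(i, msg) stop("validation error: row ", i, ": ", msg, call. = FALSE)
  n <- nrow(df)
  if (n == 0) return(invisible(df))
  if (anyNA(df$colony_id) || anyNA(df$emigration))
    bad(which(is.na(df$colony_id) | is.na(df$emigration))[1],
        "missing colony_id or emigration")
  i <- which(df$leader_id == df$follower_id)
  if (length(i)) bad(i[1], "leader_id equals follower_id")
  i <- which(!df$direction %in% c("forward", "reverse"))
  if (length(i)) bad(i[1], paste0("invalid direction '", df$direction[i[1]], "'"))
  i <- which(!df$outcome %in% c("success", "fail"))
  if (length(i)) bad(i[1], paste0("invalid outcome '", df$outcome[i[1]], "'"))
  i <- which(df$outcome == "fail" & (is.na(df$break_x) | is.na(df$break_y)))
  if (length(i)) bad(i[1], "failed run lacks break-up coordinates")
  i <- which(df$outcome == "success" & (!is.na(df$break_x) | !is.na(df$break_y)))
  if (length(i)) bad(i[1], "successful run must not carry break-up coordinates")
  i <- which(df$outcome == "fail" &
               (df$break_x < 0 | df$break_x > arena_x |
                  df$break_y < 0 | df$break_y > arena_y))
  if (length(i)) bad(i[1], "break-up coordinates outside arena bounds")
  i <- which(!is.na(df$t_start) & !is.na(df$t_end) & df$t_end < df$t_start)
  if (length(i)) bad(i[1], "t_end earlier than t_start")
  key <- paste(df$colony_id, df$emigration, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    r <- sort(df$rank[idx])
    if (anyNA(r)) bad(idx[which(is.na(df$rank[idx]))[1]], "missing rank")
    expect <- seq_along(r)
    if (!identical(as.integer(r), as.integer(expect))) {
      gap <- setdiff(expect, r)
      what <- if (length(gap)) paste0("gap at rank ", gap[1]) else
        paste0("duplicate rank ", r[which(duplicated(r))[1]])
      bad(idx[1], paste0("ranks for colony ", df$colony_id[idx[1]],
                         " emigration ", df$emigration[idx[1]],
                         " are not 1..n (", what, ")"))
    }
  }
  if (!is.null(roster)) {
    for (cid in unique(df$colony_id)) {
      ids <- roster$worker_id[roster$colony_id == cid]
      idx <- which(df$colony_id == cid)
      i <- idx[!(df$leader_id[idx] %in% ids & df$follower_id[idx] %in% ids)]
      if (length(i)) bad(i[1], paste0("participant not on roster of colony ", cid))
    }
  }
  invisible(df)
}

#' Read tandem-run events from a CSV file
#'
#' Expects the comma-separated, UTF-8 schema written by [write_events()]:
#' one header row, booleans as `true`/`false`, missing break-up coordinates
#' as empty fields.
#'
#' @param path path to an events CSV file.
#' @param roster optional roster to validate participants against.
#' @return A validated `tandem_events` table, row order preserved.
#' @export
read_events <- function(path, roster = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(colony_id = "character",
                                       replicate_id = "character",
                                       leader_id = "character",
                                       follower_id = "character"))
  missing_cols <- setdiff(.event_cols, names(df))
  if (length(missing_cols))
    stop("schema error in ", path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df$follower_switch <- df$follower_switch %in% c("true", "TRUE", TRUE)
  tandem_events(df, roster = roster)
}

#' Write tandem-run events to a CSV file
#'
#' Deterministic column order and stable decimal formatting (6 significant
#' digits for coordinates and times), so that writing the same event list
#' twice produces byte-identical files and `read_events()` round-trips.
#'
#' @param events a `tandem_events` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)[, .event_cols]
  fmt_num <- function(x) ifelse(is.na(x), "", as.character(signif(x, 6)))
  out <- data.frame(
    colony_id = df$colony_id, replicate_id = df$replicate_id,
    emigration = df$emigration, rank = df$rank,
    leader_id = df$leader_id, follower_id = df$follower_id,
    direction = df$direction,
    follower_switch = ifelse(df$follower_switch, "true", "false"),
    outcome = df$outcome,
    break_x = fmt_num(df$break_x), break_y = fmt_num(df$break_y),
    t_start = fmt_num(df$t_start), t_end = fmt_num(df$t_end),
    destination_nest = df$destination_nest,
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(out), sep = ",")), con)
  invisible(path)
}

#' Read / write a worker roster
#'
#' A roster lists every paint-marked worker of each colony, one row per
#' worker (`colony_id`, `worker_id`).
#'
#' @param path CSV path.
#' @return Data frame with columns `colony_id`, `worker_id`.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(colony_id = "character",
                                       worker_id = "character"))
  if (!all(c("colony_id", "worker_id") %in% names(df)))
    stop("schema error: roster needs columns colony_id, worker_id")
  if (any(duplicated(df))) stop("duplicate roster rows")
  df
}

#' @param roster roster data frame.
#' @rdname read_roster
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(roster[, c("colony_id", "worker_id")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter events for performance analysis
#'
#' Performance analyses use only forward tandem runs without follower
#' switches: reverse runs are behaviourally distinct and follower switches
#' make the follower's experience ambiguous, so both are excluded.
#'
#' @param events a `tandem_events` table.
#' @return The retained events, original order preserved.  Idempotent.
#' @export
filter_performance_events <- function(events) {
  keep <- events$direction == "forward" & !events$follower_switch
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tandem_events", "data.frame")
  out
}

#' @export
print.tandem_events <- function(x, ...) {
  cat("Tandem-run events: ", nrow(x), " runs, ",
      length(unique(x$colony_id)), " colonies, emigrations ",
      if (nrow(x)) paste(range(x$emigration), collapse = "-") else "-", "\n",
      sep = "")
  if (nrow(x)) {
    tab <- table(x$outcome)
    cat("  outcomes: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "; reverse runs: ", sum(x$direction == "reverse"),
        "; follower switches: ", sum(x$follower_switch), "\n", sep = "")
  }
  NextMethod()
}
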
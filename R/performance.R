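#' Straight-line distance covered by a failed tandem run
#'
#' The distance credited to an unsuccessful tandem run is `D - l`, where `l`
#' is the beeline distance from the break-up location to the entrance of the
#' nearest new nest and `D` is the (common) distance from the initial nest
#' to either new nest.  A break-up at a new-nest entrance scores `D` (35 cm
#' by default); a break-up at the initial-nest entrance scores 0.  The value
#' can be negative if the pair broke up farther than `D` from both nests;
#' such values are returned as-is (the formula is applied unconditionally)
#' and can be identified by sign.
#'
#' @param break_xy numeric length-2 (x, y) in cm, or a 2-column matrix of
#'   break-up points.
#' @param geometry an [arena_geometry()].
#' @return Straight-line distance(s) in cm.
#' @examples
#' geom <- arena_geometry()
#' straight_line_distance(geom$new1_entrance, geom)     # 35
#' straight_line_distance(geom$initial_entrance, geom)  # 0
#' @export
straight_line_distance <- function(break_xy, geometry = arena_geometry()) {
  m <- if (is.matrix(break_xy)) break_xy else matrix(break_xy, ncol = 2)
  if (anyNA(m)) stop("straight_line_distance is defined only for failed runs",
                     " with break-up coordinates")
  d1 <- sqrt((m[, 1] - geometry$new1_entrance[1])^2 +
               (m[, 2] - geometry$new1_entrance[2])^2)
  d2 <- sqrt((m[, 1] - geometry$new2_entrance[1])^2 +
               (m[, 2] - geometry$new2_entrance[2])^2)
  geometry$D - pmin(d1, d2)
}

#' Per-colony tandem performance summaries
#'
#' Computes the three tandem performance metrics per colony on events that
#' have already passed [filter_performance_events()]:
#' * `success_rate`: fraction of runs reaching a new nest;
#' * `mean_sld`: mean straight-line distance (cm) over failed runs;
#' * `mean_time`: mean duration `t_end - t_start` (s) over successful runs.
#'
#' Metrics whose subset is empty are `NA`.  Grand means across colonies are
#' means of colony means (each colony weighs equally, regardless of its
#' tandem count) and are stored in the `grand_means` attribute.
#'
#' @param events filtered `tandem_events` (forward, no follower switch),
#'   typically the test emigration.
#' @param plans optional list of [build_removal_plan()] objects (or a data
#'   frame with `colony_id`, `treatment`) used to label colonies.
#' @param geometry an [arena_geometry()].
#' @return A data frame of class `performance_summary`, one row per colony,
#'   with attribute `grand_means`.
#' @export
summarize_performance <- function(events, plans = NULL,
                                  geometry = arena_geometry()) {
  if (any(events$direction != "forward") || any(events$follower_switch))
    stop("events must be filtered with filter_performance_events() first")
  treatments <- NULL
  if (!is.null(plans)) {
    if (is.data.frame(plans)) {
      treatments <- setNames(plans$treatment, plans$colony_id)
    } else {
      treatments <- setNames(vapply(plans, `[[`, "", "treatment"),
                             vapply(plans, `[[`, "", "colony_id"))
    }
  }
  colonies <- sort(unique(events$colony_id))
  rows <- lapply(colonies, function(cid) {
    ev <- events[events$colony_id == cid, , drop = FALSE]
    succ <- ev$outcome == "success"
    sld <- if (any(!succ))
      mean(straight_line_distance(cbind(ev$break_x[!succ], ev$break_y[!succ]),
                                  geometry)) else NA_real_
    tt <- if (any(succ)) mean(ev$t_end[succ] - ev$t_start[succ]) else NA_real_
    data.frame(colony_id = cid,
               replicate_id = ev$replicate_id[1],
               treatment = if (is.null(treatments)) NA_character_ else
                 unname(treatments[cid]),
               n_tandems = nrow(ev),
               n_success = sum(succ),
               success_rate = if (nrow(ev)) mean(succ) else NA_real_,
               mean_sld = sld, mean_time = tt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "grand_means") <- c(
    success_rate = mean(out$success_rate, na.rm = TRUE),
    mean_sld = mean(out$mean_sld, na.rm = TRUE),
    mean_time = mean(out$mean_time, na.rm = TRUE))
  class(out) <- c("performance_summary", "data.frame")
  out
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("Tandem performance by colony\n")
  NextMethod()
  gm <- attr(x, "grand_means")
  cat("\nGrand means (of colony means): success_rate = ",
      signif(gm["success_rate"], 3), ", mean_sld = ",
      signif(gm["mean_sld"], 4), " cm, mean_time = ",
      signif(gm["mean_time"], 4), " s\n", sep = "")
  invisible(x)
}
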
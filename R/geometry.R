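#' Arena geometry for a binary-choice emigration
#'
#' Describes the rectangular emigration arena (46 x 78 cm) containing the
#' initial nest and two identical new nests whose entrances are equidistant
#' from the initial-nest entrance.  The separation `D` between the initial
#' nest and either new nest is the full length of a tandem route and is the
#' reference distance for the straight-line-distance performance metric.
#'
#' The default layout places the initial nest near the top of the arena and
#' the two new nests symmetrically below it, each exactly `D` cm away.
#'
#' @param initial_entrance numeric length-2, (x, y) of the initial-nest
#'   entrance in cm.
#' @param new1_entrance,new2_entrance numeric length-2, (x, y) of the two
#'   new-nest entrances in cm.  Both must be `D` cm from `initial_entrance`.
#' @param D distance in cm from the initial-nest entrance to either new-nest
#'   entrance (default 35).
#' @param arena_x,arena_y arena dimensions in cm (default 46 x 78).
#'
#' @return An object of class `arena_geometry`.
#' @examples
#' geom <- arena_geometry()
#' geom$D
#' @export
arena_geometry <- function(initial_entrance = c(23, 70),
                           new1_entrance = NULL,
                           new2_entrance = NULL,
                           D = 35,
                           arena_x = 46, arena_y = 78) {
  if (is.null(new1_entrance) || is.null(new2_entrance)) {
    # symmetric default: nests offset +-14 cm laterally, D cm from initial
    dx <- 14
    dy <- sqrt(D^2 - dx^2)
    new1_entrance <- c(initial_entrance[1] - dx, initial_entrance[2] - dy)
    new2_entrance <- c(initial_entrance[1] + dx, initial_entrance[2] - dy)
  }
  geom <- structure(
    list(initial_entrance = as.numeric(initial_entrance),
         new1_entrance = as.numeric(new1_entrance),
         new2_entrance = as.numeric(new2_entrance),
         D = D, arena_x = arena_x, arena_y = arena_y),
    class = "arena_geometry")
  d1 <- .dist2(geom$initial_entrance, geom$new1_entrance)
  d2 <- .dist2(geom$initial_entrance, geom$new2_entrance)
  if (abs(d1 - D) > 1e-6 || abs(d2 - D) > 1e-6)
    stop("both new-nest entrances must be exactly D = ", D,
         " cm from the initial-nest entrance (got ",
         signif(d1, 6), ", ", signif(d2, 6), ")")
  for (p in list(geom$initial_entrance, geom$new1_entrance, geom$new2_entrance))
    if (p[1] < 0 || p[1] > arena_x || p[2] < 0 || p[2] > arena_y)
      stop("nest entrance outside the arena")
  geom
}

.dist2 <- function(a, b) sqrt(sum((a - b)^2))

#' @export
print.arena_geometry <- function(x, ...) {
  cat("Emigration arena ", x$arena_x, " x ", x$arena_y, " cm\n", sep = "")
  cat("  initial nest entrance: (", x$initial_entrance[1], ", ",
      x$initial_entrance[2], ")\n", sep = "")
  cat("  new nest entrances:    (", x$new1_entrance[1], ", ",
      x$new1_entrance[2], "), (", x$new2_entrance[1], ", ",
      x$new2_entrance[2], ")\n", sep = "")
  cat("  initial-to-new distance D = ", x$D, " cm\n", sep = "")
  invisible(x)
}
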
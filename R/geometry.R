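#' Parametric Y-maze geometry
#'
#' Describes a symmetric three-arm maze: arms of equal length and width
#' separated by 120 degrees, meeting in a central intersection, each closed
#' by a rounded (semicircular) cul-de-sac. The bottom arm points along the
#' negative y axis; the other two arms point up-left and up-right. A sample
#' belongs to an arm when it lies in that arm's rectangle (or end cap)
#' deeper than `arm_width / sqrt(3)`, the depth at which neighbouring arm
#' rectangles stop overlapping; in-maze samples nearer the centre belong to
#' the intersection.
#'
#' @param arm `"short"` or `"long"`, preset geometries. The long maze has
#'   arms twice as long as the short one.
#' @param arm_length Centre-to-cap-start arm length in arena units
#'   (overrides the preset when given). Must be positive.
#' @param arm_width Arm width in arena units.
#' @return An object of class `maze_geometry`.
#' @examples
#' g <- maze_geometry("short")
#' maze_contains(g, 0, -1.5)
#' maze_arm(g, c(0, 0), c(-1.5, 0))
#' @export
maze_geometry <- function(arm = c("short", "long"), arm_length = NULL,
                          arm_width = 1) {
  arm <- match.arg(arm)
  if (is.null(arm_length)) {
    arm_length <- if (arm == "short") 2 else 4
  }
  if (!is.numeric(arm_length) || length(arm_length) != 1 || arm_length <= 0) {
    stop("`arm_length` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(arm_width) || length(arm_width) != 1 || arm_width <= 0) {
    stop("`arm_width` must be a single positive number", call. = FALSE)
  }
  if (arm_length <= arm_width / sqrt(3)) {
    stop("`arm_length` must exceed the intersection depth arm_width/sqrt(3)",
         call. = FALSE)
  }
  structure(
    list(arm = arm, arm_length = arm_length, arm_width = arm_width,
         y_intersect = arm_width / sqrt(3), cap_radius = arm_width / 2),
    class = "maze_geometry"
  )
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat(sprintf(
    "Y-maze geometry (%s): arm length %.3g, width %.3g, 3 arms at 120 deg\n",
    x$arm, x$arm_length, x$arm_width))
  invisible(x)
}

#' Maze containment query
#'
#' @param geom A [maze_geometry()].
#' @param x,y Numeric coordinate vectors (arena units).
#' @return Logical vector, `TRUE` for points inside the maze.
#' @export
maze_contains <- function(geom, x, y) {
  stopifnot(inherits(geom, "maze_geometry"), length(x) == length(y))
  maze_contains_cpp(as.numeric(x), as.numeric(y),
                    geom$arm_length, geom$arm_width)
}

#' Arm membership of maze points
#'
#' @inheritParams maze_contains
#' @return Character vector with values `"bottom"`, `"left"`, `"right"`,
#'   `"intersection"`, or `NA` for points outside the maze.
#' @export
maze_arm <- function(geom, x, y) {
  stopifnot(inherits(geom, "maze_geometry"), length(x) == length(y))
  code <- maze_arm_cpp(as.numeric(x), as.numeric(y),
                       geom$arm_length, geom$arm_width)
  c("bottom", "left", "right", "intersection")[code + 1L]
}

#' Distance to the nearest wall and inward normal
#'
#' Intersection points, which have no unambiguous nearest wall segment in
#' this parametric geometry, get a very large distance and a zero normal.
#'
#' @inheritParams maze_contains
#' @return A tibble with columns `dist`, `nx`, `ny`.
#' @export
maze_wall <- function(geom, x, y) {
  stopifnot(inherits(geom, "maze_geometry"), length(x) == length(y))
  m <- maze_wall_cpp(as.numeric(x), as.numeric(y),
                     geom$arm_length, geom$arm_width)
  tibble::tibble(dist = m[, 1], nx = m[, 2], ny = m[, 3])
}

#' Normalization span of the bottom arm
#'
#' The trajectory normalization maps raw y from the deepest reachable point
#' of the bottom arm (cap end) to the upper edge of the arm (just below the
#' intersection) onto \[0, 1\]. This helper returns the raw y of the arm's
#' upper edge and the physical span used by that map when the full arm is
#' explored.
#'
#' @param geom A [maze_geometry()].
#' @return A list with `y_top` (raw y of the arm's upper edge, negative),
#'   `y_floor` (raw y of the cap end) and `span`.
#' @export
maze_norm_span <- function(geom) {
  y_top <- -geom$y_intersect
  y_floor <- -(geom$arm_length + geom$cap_radius)
  list(y_top = y_top, y_floor = y_floor, span = y_top - y_floor)
}

#' Cul-de-sac threshold in another maze's normalized coordinates
#'
#' The cul-de-sac boundary used by the crossing analyses defaults to
#' `y = 0.34` in short-maze normalized units. Because normalization maps
#' each maze's own arm onto \[0, 1\], the physically matched threshold in a
#' different geometry (e.g. the long maze) sits at a smaller normalized y.
#'
#' @param geom Target [maze_geometry()].
#' @param yc_short Threshold in short-maze normalized units.
#' @param short_geom The reference short geometry.
#' @return Normalized threshold for `geom` at the same physical height
#'   above the cap end.
#' @export
yc_for_geometry <- function(geom, yc_short = 0.34,
                            short_geom = maze_geometry("short")) {
  yc_short * maze_norm_span(short_geom)$span / maze_norm_span(geom)$span
}
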
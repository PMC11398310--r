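#' Regular 2D grid over the maze plane
#'
#' @param xlim,ylim Ranges in normalized units.
#' @param bin Square bin side length.
#' @return A `field_grid` list with bin edges.
#' @export
field_grid <- function(xlim = c(-0.6, 0.6), ylim = c(-0.5, 0.5), bin = 0.05) {
  structure(list(xb = seq(xlim[1], xlim[2], by = bin),
                 yb = seq(ylim[1], ylim[2], by = bin)),
            class = "field_grid")
}

select_condition <- function(trials, phase, turn) {
  pts <- trials$points
  tt <- trials$trials
  if (turn != "all") {
    keep <- paste(tt$id[tt$turn == turn], tt$trial[tt$turn == turn])
    pts <- pts[paste(pts$id, pts$trial) %in% keep, , drop = FALSE]
  }
  if (phase == "inward") pts <- pts[pts$y < 0, , drop = FALSE]
  if (phase == "outward") pts <- pts[pts$y > 0, , drop = FALSE]
  pts
}

bin_index <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE)
  i[i < 1 | i >= length(edges)] <- NA_integer_
  i
}

#' Occupancy histogram over 2D maze bins
#'
#' Per-individual 2D sample histograms are normalized to unit mass and
#' then averaged over individuals, so every individual contributes
#' equally regardless of trial count. Conditions select the movement
#' phase (inward y < 0, outward y > 0) and the eventual turn.
#'
#' @param trials A normalized `ymaze_trials`.
#' @param grid A [field_grid()].
#' @param phase `"inward"`, `"outward"`, or `"all"`.
#' @param turn `"left"`, `"right"`, or `"all"`.
#' @return A tibble `xmid`, `ymid`, `w` (mass, sums to 1 over the grid).
#' @export
occupancy_hist2d <- function(trials, grid = field_grid(),
                             phase = c("all", "inward", "outward"),
                             turn = c("all", "left", "right")) {
  phase <- match.arg(phase)
  turn <- match.arg(turn)
  pts <- select_condition(trials, phase, turn)
  if (!nrow(pts)) stop("no samples match the requested condition", call. = FALSE)
  ix <- bin_index(pts$x, grid$xb)
  iy <- bin_index(pts$y, grid$yb)
  ok <- !is.na(ix) & !is.na(iy)
  nx <- length(grid$xb) - 1L
  ny <- length(grid$yb) - 1L
  ids <- unique(pts$id[ok])
  acc <- matrix(0, nx, ny)
  for (ind in ids) {
    s <- ok & pts$id == ind
    m <- matrix(0, nx, ny)
    tab <- table(factor(ix[s], levels = seq_len(nx)),
                 factor(iy[s], levels = seq_len(ny)))
    m[] <- as.numeric(tab)
    tot <- sum(m)
    if (tot > 0) acc <- acc + m / tot
  }
  acc <- acc / length(ids)
  xm <- (grid$xb[-1] + grid$xb[-length(grid$xb)]) / 2
  ym <- (grid$yb[-1] + grid$yb[-length(grid$yb)]) / 2
  tibble::tibble(
    xmid = rep(xm, times = ny),
    ymid = rep(ym, each = nx),
    w = as.numeric(acc)
  )
}

#' Mean-velocity vector field over 2D maze bins
#'
#' Velocities are forward differences of consecutive samples within a
#' trial (no smoothing), binned by the position of the first sample of
#' each pair. Each occupied bin reports the direction of the mean
#' displacement vector (unit norm) and its relative visit frequency;
#' bins without samples have undefined direction and zero weight.
#'
#' @inheritParams occupancy_hist2d
#' @return A tibble `xmid`, `ymid`, `ux`, `uy`, `weight`, `n`.
#' @export
velocity_field <- function(trials, grid = field_grid(),
                           phase = c("all", "inward", "outward"),
                           turn = c("all", "left", "right")) {
  phase <- match.arg(phase)
  turn <- match.arg(turn)
  pts <- select_condition(trials, phase, turn)
  if (nrow(pts) < 2) stop("no samples match the requested condition", call. = FALSE)
  pts <- pts[order(pts$id, pts$trial, pts$k), , drop = FALSE]
  same <- pts$id[-nrow(pts)] == pts$id[-1] &
    pts$trial[-nrow(pts)] == pts$trial[-1] &
    pts$k[-1] == pts$k[-nrow(pts)] + 1L
  i0 <- which(same)
  dx <- pts$x[i0 + 1L] - pts$x[i0]
  dy <- pts$y[i0 + 1L] - pts$y[i0]
  ix <- bin_index(pts$x[i0], grid$xb)
  iy <- bin_index(pts$y[i0], grid$yb)
  ok <- !is.na(ix) & !is.na(iy)
  nx <- length(grid$xb) - 1L
  cell <- (iy[ok] - 1L) * nx + ix[ok]
  sum_dx <- tapply(dx[ok], cell, sum)
  sum_dy <- tapply(dy[ok], cell, sum)
  cnt <- tapply(dx[ok], cell, length)
  ny <- length(grid$yb) - 1L
  xm <- (grid$xb[-1] + grid$xb[-length(grid$xb)]) / 2
  ym <- (grid$yb[-1] + grid$yb[-length(grid$yb)]) / 2
  out <- tibble::tibble(
    xmid = rep(xm, times = ny),
    ymid = rep(ym, each = nx),
    ux = NA_real_, uy = NA_real_, weight = 0, n = 0L
  )
  cells <- as.integer(names(cnt))
  vx <- as.numeric(sum_dx)
  vy <- as.numeric(sum_dy)
  nrm <- sqrt(vx^2 + vy^2)
  out$ux[cells] <- ifelse(nrm > 0, vx / nrm, NA_real_)
  out$uy[cells] <- ifelse(nrm > 0, vy / nrm, NA_real_)
  out$n[cells] <- as.integer(cnt)
  out$weight[cells] <- as.numeric(cnt) / sum(cnt)
  out
}
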
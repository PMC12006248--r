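## Polygon helpers shared by the IHC and lymph-node pipelines.
## Convention: 0-based pixel coordinates, x to the right, y down; polygon
## area by the shoelace formula; membership by even-odd crossing with points
## on the boundary counted inside.

#' Signed polygon area (shoelace formula)
#'
#' @param x,y numeric vertex coordinates of a simple polygon (open ring;
#'   the closing edge is implied).
#' @return Unsigned area in squared input units.
#' @export
polygon_area <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  xs <- c(x, x[1]); ys <- c(y, y[1])
  abs(sum(xs[-length(xs)] * ys[-1] - xs[-1] * ys[-length(ys)])) / 2
}

#' Polygon perimeter
#'
#' @inheritParams polygon_area
#' @return Total edge length including the closing edge.
#' @export
polygon_perimeter <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
  sum(sqrt(dx^2 + dy^2))
}

#' Point-in-polygon test
#'
#' Even-odd crossing-number test, vectorized over query points. Points lying
#' exactly on a polygon edge or vertex count as inside.
#'
#' @param px,py query point coordinates.
#' @param vx,vy polygon vertices.
#' @param eps tolerance for the on-boundary check.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  stopifnot(n >= 3, length(vy) == n, length(px) == length(py))
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary: distance from point to segment below eps
    ddx <- x2 - x1; ddy <- y2 - y1
    len2 <- ddx^2 + ddy^2
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - x1) * ddx + (py - y1) * ddy) / len2)) else 0
    d2 <- (px - (x1 + t * ddx))^2 + (py - (y1 + t * ddy))^2
    on_edge <- on_edge | d2 <= eps^2
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | on_edge
}

## Rasterize a polygon ROI into a logical mask of the given image dimensions
## (rows = y, cols = x, 0-based pixel centres at integer coordinates).
rasterize_polygon <- function(vx, vy, dim_yx) {
  ny <- dim_yx[1]; nx <- dim_yx[2]
  xr <- range(vx); yr <- range(vy)
  x0 <- max(0, floor(xr[1])); x1 <- min(nx - 1, ceiling(xr[2]))
  y0 <- max(0, floor(yr[1])); y1 <- min(ny - 1, ceiling(yr[2]))
  m <- matrix(FALSE, ny, nx)
  if (x0 > x1 || y0 > y1) return(m)
  xs <- x0:x1; ys <- y0:y1
  g <- expand.grid(x = xs, y = ys)
  hit <- point_in_polygon(g$x, g$y, vx, vy)
  m[cbind(g$y + 1L, g$x + 1L)] <- hit
  m
}

## Seed-scoped RNG: run `expr` under `seed` and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
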
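#' @name paleorange-geometry
#' @title Equal-area projection, grid and extent-of-occurrence geometry
#'
#' @description
#' Range sizes by extent of occurrence (EOO) are measured as the summed area
#' of equal-area grid cells whose (closed) squares overlap the convex hull of
#' the occupied lakes. All geometry happens in a Lambert azimuthal equal-area
#' (LAEA) frame centred on the mean lake position, on an authalic sphere, so
#' planar cell areas equal true areas. "Overlap" is closed-set intersection:
#' a boundary touch counts.
NULL

# Authalic Earth radius, metres: sphere with the WGS84 ellipsoid's area.
EARTH_RADIUS_M <- 6371007.181

#' Project lakes into a Lambert azimuthal equal-area frame
#'
#' The projection is centred on the mean longitude/latitude of the registry
#' (order-invariant), with planar coordinates in metres.
#'
#' @param registry Lake registry data frame (`lake_id`, `lon`, `lat`).
#' @return A data frame (`lake_id`, `x`, `y`) of class `projected_lakes`,
#'   with the centre stored in attribute `"center"`.
#' @export
project_lakes <- function(registry) {
  registry <- validate_lake_registry(registry)
  if (nrow(registry) < 1) stop("project_lakes: empty registry", call. = FALSE)
  center <- c(lon = mean(registry$lon), lat = mean(registry$lat))
  xy <- laea_forward(registry$lon, registry$lat, center)
  out <- data.frame(lake_id = registry$lake_id, x = xy$x, y = xy$y,
                    stringsAsFactors = FALSE)
  attr(out, "center") <- center
  class(out) <- c("projected_lakes", "data.frame")
  out
}

# Spherical LAEA forward equations.
laea_forward <- function(lon, lat, center) {
  lam <- lon * pi / 180; phi <- lat * pi / 180
  lam0 <- center[["lon"]] * pi / 180; phi0 <- center[["lat"]] * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  if (any(denom < 1e-10)) {
    stop("project_lakes: point antipodal to projection centre", call. = FALSE)
  }
  kp <- sqrt(2 / denom)
  list(x = EARTH_RADIUS_M * kp * cos(phi) * sin(lam - lam0),
       y = EARTH_RADIUS_M * kp * (cos(phi0) * sin(phi) -
                                    sin(phi0) * cos(phi) * cos(lam - lam0)))
}

#' Build an equal-area analysis grid over projected lakes
#'
#' Cells are axis-aligned squares of side `cell_km` kilometres. The origin is
#' anchored at the lower-left corner of the projected bounding box minus half
#' a cell, so no input lake sits exactly on a grid line at default precision.
#' A point exactly on a cell boundary is assigned to the cell with the
#' smaller index.
#'
#' @param projected A [project_lakes()] result (or any data frame with
#'   numeric `x`, `y` in metres).
#' @param cell_km Cell side, kilometres (default 200).
#' @return An object of class `range_grid`: list with `origin` (metres),
#'   `side` (metres), `nx`, `ny`, and `cell_area_km2`.
#' @export
make_grid <- function(projected, cell_km = 200) {
  side <- cell_km * 1000
  x0 <- min(projected$x) - side / 2
  y0 <- min(projected$y) - side / 2
  nx <- max(1L, as.integer(ceiling((max(projected$x) - x0) / side)))
  ny <- max(1L, as.integer(ceiling((max(projected$y) - y0) / side)))
  structure(list(origin = c(x = x0, y = y0), side = side,
                 nx = nx, ny = ny, cell_area_km2 = cell_km^2),
            class = "range_grid")
}

# Cell column/row of points; ceiling convention so an exact boundary falls in
# the smaller-index cell.
cell_of <- function(grid, x, y) {
  ix <- pmax(1L, as.integer(ceiling((x - grid$origin[["x"]]) / grid$side)))
  iy <- pmax(1L, as.integer(ceiling((y - grid$origin[["y"]]) / grid$side)))
  cbind(ix = ix, iy = iy)
}

cell_key <- function(cells) paste(cells[, 1], cells[, 2], sep = ":")

# --- planar predicates (closed sets, absolute tolerance in metres) ---------

GEOM_TOL <- 1e-3  # one millimetre at metre scale

# Is point (px, py) inside or on the closed polygon (vx, vy)? Ray casting
# plus an explicit on-boundary test.
point_in_polygon <- function(px, py, vx, vy, tol = GEOM_TOL) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    # boundary test: distance from point to edge (j, i)
    if (point_on_segment(px, py, vx[j], vy[j], vx[i], vy[i], tol)) return(TRUE)
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

point_on_segment <- function(px, py, ax, ay, bx, by, tol = GEOM_TOL) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) 0 else ((px - ax) * dx + (py - ay) * dy) / len2
  t <- min(1, max(0, t))
  qx <- ax + t * dx; qy <- ay + t * dy
  (px - qx)^2 + (py - qy)^2 <= tol^2
}

# Closed segment-segment intersection (touching counts), via orientations
# with a tolerance, handling collinear overlap.
segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy, tol = GEOM_TOL) {
  orient <- function(ox, oy, px, py, qx, qy) {
    v <- (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
    scale <- max(abs(px - ox), abs(py - oy), abs(qx - ox), abs(qy - oy), 1)
    if (abs(v) <= tol * scale) 0 else sign(v)
  }
  o1 <- orient(ax, ay, bx, by, cx, cy)
  o2 <- orient(ax, ay, bx, by, dx, dy)
  o3 <- orient(cx, cy, dx, dy, ax, ay)
  o4 <- orient(cx, cy, dx, dy, bx, by)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && point_on_segment(cx, cy, ax, ay, bx, by, tol)) ||
  (o2 == 0 && point_on_segment(dx, dy, ax, ay, bx, by, tol)) ||
  (o3 == 0 && point_on_segment(ax, ay, cx, cy, dx, dy, tol)) ||
  (o4 == 0 && point_on_segment(bx, by, cx, cy, dx, dy, tol))
}

# Does the closed segment (a, b) intersect the closed axis-aligned rectangle?
segment_intersects_rect <- function(ax, ay, bx, by, xlo, ylo, xhi, yhi,
                                    tol = GEOM_TOL) {
  # quick reject on bounding boxes
  if (max(ax, bx) < xlo - tol || min(ax, bx) > xhi + tol ||
      max(ay, by) < ylo - tol || min(ay, by) > yhi + tol) return(FALSE)
  inside <- function(px, py) {
    px >= xlo - tol && px <= xhi + tol && py >= ylo - tol && py <= yhi + tol
  }
  if (inside(ax, ay) || inside(bx, by)) return(TRUE)
  corners <- matrix(c(xlo, ylo, xhi, ylo, xhi, yhi, xlo, yhi), ncol = 2,
                    byrow = TRUE)
  for (i in 1:4) {
    j <- if (i == 4) 1 else i + 1
    if (segments_intersect(ax, ay, bx, by, corners[i, 1], corners[i, 2],
                           corners[j, 1], corners[j, 2], tol)) return(TRUE)
  }
  FALSE
}

# Does the closed convex polygon intersect the closed rectangle?
polygon_intersects_rect <- function(vx, vy, xlo, ylo, xhi, yhi,
                                    tol = GEOM_TOL) {
  # any polygon vertex in rectangle
  if (any(vx >= xlo - tol & vx <= xhi + tol &
          vy >= ylo - tol & vy <= yhi + tol)) return(TRUE)
  # any rectangle corner in polygon
  cx <- c(xlo, xhi, xhi, xlo); cy <- c(ylo, ylo, yhi, yhi)
  for (i in 1:4) {
    if (point_in_polygon(cx[i], cy[i], vx, vy, tol)) return(TRUE)
  }
  # any edge pair crossing
  n <- length(vx)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if (segment_intersects_rect(vx[i], vy[i], vx[j], vy[j],
                                xlo, ylo, xhi, yhi, tol)) return(TRUE)
  }
  FALSE
}

# Collinearity of a projected point set, tolerance relative to extent.
points_collinear <- function(x, y) {
  n <- length(x)
  if (n <= 2) return(TRUE)
  ext <- max(max(x) - min(x), max(y) - min(y))
  if (ext == 0) return(TRUE)
  i0 <- which.min(x + y * 1e-9); i1 <- which.max(x + y * 1e-9)
  # fall back to extremes along y when x-range is degenerate
  if (abs(x[i1] - x[i0]) + abs(y[i1] - y[i0]) == 0) {
    i0 <- which.min(y); i1 <- which.max(y)
  }
  dx <- x[i1] - x[i0]; dy <- y[i1] - y[i0]
  len <- sqrt(dx^2 + dy^2)
  d <- abs(dx * (y - y[i0]) - dy * (x - x[i0])) / len
  all(d <= 1e-9 * ext + GEOM_TOL)
}

#' Grid cells forming the extent of occurrence of an occupied-lake set
#'
#' Returns the set of grid cells whose closed squares overlap the convex hull
#' of the occupied lakes. Degenerate hulls follow the point/segment rules:
#' one lake gives its containing cell; two lakes (or any collinear set) give
#' the cells crossed by the segment between the two extreme points.
#'
#' @param occupied Character vector of occupied lake ids (non-empty).
#' @param grid A [make_grid()] object.
#' @param projected A [project_lakes()] result containing the occupied lakes.
#' @return Integer matrix with columns `ix`, `iy`, one row per cell.
#' @export
eoo_cells <- function(occupied, grid, projected) {
  if (length(occupied) < 1) stop("eoo_cells: empty occupied set", call. = FALSE)
  idx <- match(occupied, projected$lake_id)
  if (anyNA(idx)) {
    stop("eoo_cells: unknown lake(s): ",
         paste(occupied[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  x <- projected$x[idx]; y <- projected$y[idx]
  if (length(x) == 1) return(cell_of(grid, x, y))

  if (points_collinear(x, y)) {
    # extreme points of the collinear set
    t <- (x - x[1]) * (x[which.max(abs(x - x[1]) + abs(y - y[1]))] - x[1]) +
         (y - y[1]) * (y[which.max(abs(x - x[1]) + abs(y - y[1]))] - y[1])
    a <- which.min(t); b <- which.max(t)
    return(cells_hit_by(grid, function(xlo, ylo, xhi, yhi) {
      segment_intersects_rect(x[a], y[a], x[b], y[b], xlo, ylo, xhi, yhi)
    }, range(x), range(y)))
  }
  h <- grDevices::chull(x, y)
  vx <- x[h]; vy <- y[h]
  cells_hit_by(grid, function(xlo, ylo, xhi, yhi) {
    polygon_intersects_rect(vx, vy, xlo, ylo, xhi, yhi)
  }, range(vx), range(vy))
}

# Scan candidate cells in the (padded) bounding box of the feature and keep
# those the predicate accepts.
cells_hit_by <- function(grid, hit, xr, yr) {
  ix_lo <- max(1L, cell_of(grid, xr[1] - GEOM_TOL, yr[1] - GEOM_TOL)[1, 1])
  iy_lo <- max(1L, cell_of(grid, xr[1] - GEOM_TOL, yr[1] - GEOM_TOL)[1, 2])
  ix_hi <- cell_of(grid, xr[2] + GEOM_TOL, yr[2] + GEOM_TOL)[1, 1]
  iy_hi <- cell_of(grid, xr[2] + GEOM_TOL, yr[2] + GEOM_TOL)[1, 2]
  hits <- list(); k <- 0L
  for (ix in ix_lo:ix_hi) {
    xlo <- grid$origin[["x"]] + (ix - 1) * grid$side
    for (iy in iy_lo:iy_hi) {
      ylo <- grid$origin[["y"]] + (iy - 1) * grid$side
      if (hit(xlo, ylo, xlo + grid$side, ylo + grid$side)) {
        k <- k + 1L
        hits[[k]] <- c(ix, iy)
      }
    }
  }
  m <- do.call(rbind, hits)
  colnames(m) <- c("ix", "iy")
  m
}

#' Extent-of-occurrence range size of an occupied-lake set
#'
#' The summed area (km^2) of the grid cells returned by [eoo_cells()]. A
#' single occupied lake yields the area of its containing cell.
#'
#' @inheritParams eoo_cells
#' @return Area in square kilometres.
#' @export
#' @examples
#' reg <- generate_lakes(5, seed = 3)
#' pr <- project_lakes(reg)
#' g <- make_grid(pr)
#' eoo_range(reg$lake_id[1], g, pr)  # one lake: one 200 x 200 km cell
eoo_range <- function(occupied, grid, projected) {
  nrow(eoo_cells(occupied, grid, projected)) * grid$cell_area_km2
}
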
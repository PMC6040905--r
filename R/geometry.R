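#' @useDynLib emsclust, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile rnorm runif rbinom rmultinom setNames
#' @importFrom utils read.csv write.csv head
#' @importFrom grDevices chull
NULL

EARTH_RADIUS_M <- 6371000
# points within a micron of an edge count as on-boundary (absorbs projection
# round-trip float error while staying far below any physical distinction)
BOUNDARY_TOL_M <- 1e-6

as_xy <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 2)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2) stop("expected two-column coordinates")
  colnames(p) <- c("x", "y")
  p
}

as_lonlat <- function(p) {
  if (is.data.frame(p)) {
    if (all(c("lon", "lat") %in% names(p))) p <- cbind(p$lon, p$lat)
    else p <- as.matrix(p)
  }
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 2)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2) stop("expected lon/lat coordinates")
  colnames(p) <- c("lon", "lat")
  p
}

#' Project geographic coordinates onto a local planar system
#'
#' Local equirectangular projection about a reference point: east/north
#' offsets in metres on a sphere of radius \code{R}. At city scale (extents of
#' a few kilometres) planar distances agree with great-circle distances to
#' within about two metres, which is the same tolerance under which NAD83 and
#' WGS84 coordinates are treated as interchangeable here; a full geodesy stack
#' is deliberately out of scope.
#'
#' @param points matrix or data frame of lon/lat in decimal degrees (WGS84
#'   axis order: longitude first).
#' @param reference length-2 lon/lat used as the projection origin.
#' @param R sphere radius in metres.
#' @return matrix with columns \code{x}, \code{y} in metres.
#' @seealso [plane_to_geo()] for the inverse.
#' @export
#' @examples
#' geo_to_plane(c(-71.10, 42.38), reference = c(-71.11, 42.37))
geo_to_plane <- function(points, reference, R = EARTH_RADIUS_M) {
  p <- as_lonlat(points)
  ref <- as.numeric(reference)
  if (length(ref) != 2) stop("reference must be a single lon/lat pair")
  bad <- abs(p[, 1] - ref[1]) > 0.5 | abs(p[, 2] - ref[2]) > 0.5
  if (any(bad, na.rm = TRUE)) {
    stop(sprintf(
      "%d point(s) farther than 0.5 degrees from the projection reference; %s",
      sum(bad, na.rm = TRUE),
      "the local planar projection is only valid at city scale"))
  }
  rad <- pi / 180
  cbind(
    x = R * (p[, 1] - ref[1]) * rad * cos(ref[2] * rad),
    y = R * (p[, 2] - ref[2]) * rad)
}

#' Inverse of the local planar projection
#'
#' @param xy matrix of planar x/y metres.
#' @inheritParams geo_to_plane
#' @return matrix with columns \code{lon}, \code{lat} in decimal degrees.
#' @export
plane_to_geo <- function(xy, reference, R = EARTH_RADIUS_M) {
  xy <- as_xy(xy)
  ref <- as.numeric(reference)
  rad <- pi / 180
  cbind(
    lon = ref[1] + xy[, 1] / (R * rad * cos(ref[2] * rad)),
    lat = ref[2] + xy[, 2] / (R * rad))
}

shoelace_area <- function(ring) {
  ring <- as_xy(ring)
  n <- nrow(ring)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(ring[, 1] * ring[j, 2] - ring[j, 1] * ring[, 2])) / 2
}

#' Planar polygon analysis window
#'
#' Container for the study window: an outer ring (and optional holes) of
#' planar coordinates in metres, its area, and the lon/lat reference used to
#' project it. Areas come from the shoelace formula (holes subtracted).
#'
#' @param outer n x 2 matrix of ring vertices in metres (not closed: the last
#'   vertex differs from the first).
#' @param holes optional list of hole rings.
#' @param reference lon/lat projection origin associated with the window
#'   (may be NULL for purely synthetic planar work).
#' @param validate check ring size and positive area.
#' @return object of class \code{poly_window} with elements \code{rings}
#'   (list of matrices, first = outer), \code{area} (m^2), \code{reference},
#'   \code{degenerate}.
#' @export
#' @examples
#' w <- poly_window(rbind(c(0, 0), c(100, 0), c(100, 50), c(0, 50)))
#' w$area
poly_window <- function(outer, holes = list(), reference = NULL,
                        validate = TRUE) {
  outer <- as_xy(outer)
  # drop an explicitly closed ring's repeated vertex
  n <- nrow(outer)
  if (n >= 2 && all(outer[1, ] == outer[n, ])) outer <- outer[-n, , drop = FALSE]
  holes <- lapply(holes, as_xy)
  area <- shoelace_area(outer) - sum(vapply(holes, shoelace_area, 0))
  degenerate <- nrow(outer) < 3 || area <= 0
  if (validate && degenerate) {
    stop("window outer ring must have >= 3 vertices and positive area")
  }
  structure(
    list(rings = c(list(outer), holes), area = area,
         reference = reference, degenerate = degenerate),
    class = "poly_window")
}

#' @export
print.poly_window <- function(x, ...) {
  cat(sprintf("<poly_window> %d ring(s), area %.1f m^2%s\n",
              length(x$rings), x$area,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

window_flat <- function(w) {
  lens <- vapply(w$rings, nrow, 0L)
  list(
    vx = unlist(lapply(w$rings, function(r) r[, 1]), use.names = FALSE),
    vy = unlist(lapply(w$rings, function(r) r[, 2]), use.names = FALSE),
    start = as.integer(cumsum(c(0L, lens[-length(lens)]))),
    len = as.integer(lens))
}

#' Test planar points for window membership
#'
#' Even-odd (ray crossing) membership; points on the boundary count as
#' inside — the package's clipping convention.
#'
#' @param xy matrix of planar points (metres).
#' @param window a [poly_window()].
#' @return logical vector.
#' @export
points_in_window <- function(xy, window) {
  xy <- as_xy(xy)
  f <- window_flat(window)
  points_in_polygon_cpp(xy[, 1], xy[, 2], f$vx, f$vy, f$start, f$len,
                        BOUNDARY_TOL_M)
}

#' Distance from points to the window boundary
#'
#' @inheritParams points_in_window
#' @return numeric vector of metres (0 on the boundary).
#' @export
dist_to_boundary <- function(xy, window) {
  xy <- as_xy(xy)
  f <- window_flat(window)
  dist_to_boundary_cpp(xy[, 1], xy[, 2], f$vx, f$vy, f$start, f$len)
}

#' Fraction of a circle's circumference inside the window
#'
#' The denominator of Ripley's isotropic edge correction: for a circle centred
#' at an interior point, the fraction of its circumference lying inside the
#' window. Computed numerically by testing \code{resolution} equally spaced
#' angles for membership (error at most ~1/resolution for windows whose edges
#' are long relative to the arc step); circles entirely in the interior
#' short-circuit to 1.
#'
#' @param center planar point (length-2 or 1 x 2 matrix), must be inside the
#'   window.
#' @param radius circle radius in metres, > 0 (vectorised with center rows).
#' @param window a [poly_window()].
#' @param resolution number of angular samples, >= 64.
#' @return numeric fraction(s) in \[0, 1\].
#' @export
#' @examples
#' w <- poly_window(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)))
#' circle_inside_fraction(c(500, 5), 10, w)  # ~ 2/3: half-plane cut at 5 m
circle_inside_fraction <- function(center, radius, window, resolution = 720) {
  xy <- as_xy(center)
  if (resolution < 64) stop("resolution must be at least 64")
  if (any(radius <= 0)) stop("radius must be positive")
  if (!all(points_in_window(xy, window))) {
    stop("circle center lies outside the window")
  }
  radius <- rep_len(as.numeric(radius), nrow(xy))
  f <- window_flat(window)
  circle_fraction_cpp(xy[, 1], xy[, 2], radius, f$vx, f$vy, f$start, f$len,
                      as.integer(resolution), BOUNDARY_TOL_M)
}

#' Convex hull of planar points
#'
#' Minimal convex polygon containing the points, as a [poly_window()].
#' Collinear or single-point inputs yield a degenerate hull with area 0 and
#' \code{degenerate = TRUE} rather than an error, so single-location clusters
#' summarise cleanly.
#'
#' @param xy matrix of planar points (>= 1 row).
#' @return a \code{poly_window}; vertices in counter-clockwise order.
#' @export
convex_hull <- function(xy) {
  xy <- as_xy(xy)
  if (nrow(xy) == 0) stop("convex hull of an empty point set is undefined")
  idx <- unique(chull(xy[, 1], xy[, 2]))  # chull returns clockwise order
  verts <- xy[rev(idx), , drop = FALSE]
  verts <- unique(verts)
  poly_window(verts, validate = FALSE)
}

#' Run-weighted centroid of planar points
#'
#' Arithmetic mean of coordinates; coincident points count with multiplicity,
#' so a 76-run location pulls the centroid 76 times harder than a 1-run one.
#'
#' @param xy matrix of planar points (>= 1 row).
#' @return length-2 named numeric (x, y).
#' @export
centroid_points <- function(xy) {
  xy <- as_xy(xy)
  if (nrow(xy) == 0) stop("centroid of an empty point set is undefined")
  c(x = mean(xy[, 1]), y = mean(xy[, 2]))
}
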
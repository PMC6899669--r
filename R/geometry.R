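#' Volume geometry
#'
#' Describes a regular 2D or 3D attenuation grid in world coordinates.
#' Voxel `i` (0-based along each axis) has its center at
#' `origin + i * spacing` (mm).  By default the grid is centered on the
#' isocenter (world origin): `origin = -(shape - 1) / 2 * spacing`.
#'
#' @param shape integer grid dimensions, length 2 (`nx, ny`) or 3
#'   (`nx, ny, nz`); the third axis is the rotation axis `z`.
#' @param spacing mm per voxel along each axis (recycled if scalar).
#' @param origin world-mm coordinate of the center of the first voxel, or
#'   `NULL` for the centered default.
#' @return an object of class `volume_geometry` with fields `shape`,
#'   `spacing`, `origin`.
#' @examples
#' volume_geometry(c(64, 64), spacing = 2)
#' @export
volume_geometry <- function(shape, spacing = 1, origin = NULL) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (!nd %in% c(2L, 3L)) stop("shape must have length 2 or 3")
  if (any(shape < 1L)) stop("all shape entries must be >= 1")
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(spacing <= 0)) stop("all spacings must be > 0")
  if (is.null(origin)) origin <- -(shape - 1) / 2 * spacing
  origin <- rep_len(as.numeric(origin), nd)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "volume_geometry")
}

#' Detector geometry
#'
#' A flat detector: 1D (a pixel row) for 2D beams, 2D (`u` columns by `v`
#' rows, `v` along the rotation axis) for the cone beam.  The physical
#' coordinate of pixel `i` (0-based) is `s = (i - (n-1)/2) * spacing +
#' offset`, i.e. pixel centers with the detector center on the principal
#' ray when `offset = 0`.
#'
#' @param shape integer pixel counts (length 1 or 2).
#' @param spacing mm per pixel (recycled).
#' @param offset mm displacement of the detector center from the principal
#'   ray (recycled; default 0).
#' @return an object of class `detector_geometry`.
#' @export
detector_geometry <- function(shape, spacing = 1, offset = 0) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (!nd %in% c(1L, 2L)) stop("detector shape must have length 1 or 2")
  if (any(shape < 1L)) stop("pixel counts must be >= 1")
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(spacing <= 0)) stop("detector spacings must be > 0")
  offset <- rep_len(as.numeric(offset), nd)
  structure(list(shape = shape, spacing = spacing, offset = offset),
            class = "detector_geometry")
}

#' Detector pixel coordinates
#'
#' Physical (mm) coordinates of the pixel centers along one detector axis.
#'
#' @param det a [detector_geometry()].
#' @param axis which detector axis (1 = `u`, 2 = `v`).
#' @return numeric vector of mm coordinates.
#' @export
detector_coords <- function(det, axis = 1) {
  n <- det$shape[axis]
  (seq_len(n) - 1 - (n - 1) / 2) * det$spacing[axis] + det$offset[axis]
}

#' Scan geometry
#'
#' Everything that defines the implicit system matrix `A`: beam type,
#' volume and detector layout, and the circular trajectory.  View angles
#' are uniform on the half-open interval
#' `[start_angle, start_angle + angular_range)`:
#' `beta_i = start_angle + i * angular_range / n_views`.  At `beta = 0`
#' rays travel along `+y` (central ray direction `(-sin b, cos b)`) with
#' the detector axis along `+x`; the fan/cone source sits at
#' `-SID * (-sin b, cos b)`.  The cone-beam orbit lies in the `z = 0`
#' plane and each view carries a 3x4 projection matrix.
#'
#' @param beam `"parallel2d"`, `"fan2d"` or `"cone3d"`.
#' @param volume a [volume_geometry()] (2D for 2D beams, 3D for cone).
#' @param detector a [detector_geometry()] (1D for 2D beams, 2D for cone).
#' @param n_views number of projections.
#' @param angular_range covered angle in radians (default `pi` for
#'   parallel, `2*pi` otherwise).
#' @param start_angle first view angle in radians.
#' @param sid source-to-isocenter distance in mm (fan/cone).
#' @param sdd source-to-detector distance in mm (fan/cone).
#' @param matrices list of 3x4 projection matrices (cone only); computed
#'   from the circular orbit via [cone_projection_matrices()] when `NULL`.
#' @return an object of class `scan_geometry` with fields `beam`, `volume`,
#'   `detector`, `n_views`, `angles`, `angular_range`, `start_angle`,
#'   `sid`, `sdd`, `matrices`.
#' @examples
#' g <- scan_geometry("parallel2d", volume_geometry(c(64, 64)),
#'                    detector_geometry(95), n_views = 90)
#' @export
scan_geometry <- function(beam = c("parallel2d", "fan2d", "cone3d"),
                          volume, detector, n_views,
                          angular_range = NULL, start_angle = 0,
                          sid = NULL, sdd = NULL, matrices = NULL) {
  beam <- match.arg(beam)
  stopifnot(inherits(volume, "volume_geometry"),
            inherits(detector, "detector_geometry"))
  n_views <- as.integer(n_views)
  if (n_views < 1L) stop("n_views must be >= 1")
  if (is.null(angular_range))
    angular_range <- if (beam == "parallel2d") pi else 2 * pi
  if (angular_range <= 0) stop("angular_range must be > 0")
  nd_vol <- if (beam == "cone3d") 3L else 2L
  nd_det <- if (beam == "cone3d") 2L else 1L
  if (length(volume$shape) != nd_vol)
    stop(sprintf("%s requires a %dD volume", beam, nd_vol))
  if (length(detector$shape) != nd_det)
    stop(sprintf("%s requires a %dD detector", beam, nd_det))
  if (beam != "parallel2d") {
    if (is.null(sid) || is.null(sdd))
      stop("fan/cone geometries require sid and sdd")
    if (!(sid > 0 && sid < sdd))
      stop("need 0 < sid < sdd")
  }
  geom <- structure(
    list(beam = beam, volume = volume, detector = detector,
         n_views = n_views,
         angles = start_angle + (seq_len(n_views) - 1) * angular_range / n_views,
         angular_range = angular_range, start_angle = start_angle,
         sid = sid, sdd = sdd, matrices = matrices),
    class = "scan_geometry")
  if (beam == "cone3d") {
    if (is.null(matrices)) geom$matrices <- cone_projection_matrices(geom)
    if (length(geom$matrices) != n_views)
      stop("need one projection matrix per view")
  }
  geom
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %s: %d views over %.4f rad from %.4f\n",
              x$beam, x$n_views, x$angular_range, x$start_angle))
  cat("  volume:  ", paste(x$volume$shape, collapse = " x "),
      " @ ", paste(signif(x$volume$spacing, 4), collapse = " x "), " mm\n",
      sep = "")
  cat("  detector:", paste(x$detector$shape, collapse = " x "),
      "@", paste(signif(x$detector$spacing, 4), collapse = " x "), "mm\n")
  if (!is.null(x$sid))
    cat(sprintf("  SID %.1f mm, SDD %.1f mm\n", x$sid, x$sdd))
  invisible(x)
}

#' Angular increment of a scan
#' @param geom a [scan_geometry()].
#' @return `angular_range / n_views` in radians.
#' @export
delta_beta <- function(geom) geom$angular_range / geom$n_views

#' Circular 2D trajectory
#'
#' Uniformly spaced view angles and unit central-ray direction vectors for
#' a circular 2D trajectory.  View `i` (0-based) has angle
#' `beta_i = start_angle + i * angular_range / n_views` and central ray
#' direction `(-sin beta_i, cos beta_i)`; the interval is half-open (the
#' view at `start_angle + angular_range` is excluded).
#'
#' @param n_views number of views (>= 1).
#' @param start_angle first angle, radians.
#' @param angular_range covered range, radians (> 0).
#' @return list with `angles` (length `n_views`) and `rays`
#'   (`n_views` x 2 matrix of unit vectors).
#' @examples
#' circular_trajectory_2d(4, 0, pi)$angles  # 0, pi/4, pi/2, 3pi/4
#' @export
circular_trajectory_2d <- function(n_views, start_angle = 0, angular_range = pi) {
  n_views <- as.integer(n_views)
  if (n_views < 1L) stop("n_views must be >= 1")
  if (angular_range <= 0) stop("angular_range must be > 0")
  angles <- start_angle + (seq_len(n_views) - 1) * angular_range / n_views
  list(angles = angles, rays = cbind(-sin(angles), cos(angles)))
}

#' Cone-beam projection matrices for a circular orbit
#'
#' Builds one 3x4 projection matrix per view for a circular source orbit of
#' radius SID in the `z = 0` plane: `P = K [R | t]` with camera axes
#' (detector `u`, detector `v` = `+z`, principal ray), `t = -R * source`,
#' and intrinsics mapping mm to 0-based detector pixel units with the
#' principal point at the pixel where the detector coordinate is zero.
#' Projecting the isocenter `(0, 0, 0, 1)` yields exactly that principal
#' point, and the homogeneous depth `w` equals the distance (mm) of the
#' point from the source along the principal ray, so `w > 0` in front of
#' the source.
#'
#' @param geom a cone-beam [scan_geometry()] with `sid`/`sdd` set.
#' @return list of `n_views` numeric 3x4 matrices.
#' @export
cone_projection_matrices <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (geom$beam != "cone3d") stop("projection matrices require a cone3d geometry")
  if (is.null(geom$sid) || is.null(geom$sdd)) stop("sid and sdd must be set")
  det <- geom$detector
  cu <- (det$shape[1] - 1) / 2 - det$offset[1] / det$spacing[1]
  cv <- (det$shape[2] - 1) / 2 - det$offset[2] / det$spacing[2]
  K <- rbind(c(geom$sdd / det$spacing[1], 0, cu),
             c(0, geom$sdd / det$spacing[2], cv),
             c(0, 0, 1))
  lapply(geom$angles, function(b) {
    d <- c(-sin(b), cos(b), 0)          # principal ray
    u <- c(cos(b), sin(b), 0)           # detector u axis
    v <- c(0, 0, 1)                     # detector v axis
    R <- rbind(u, v, d)
    src <- -geom$sid * d
    unname(K %*% cbind(R, -R %*% src))
  })
}

#' Project a world point through a projection matrix
#'
#' Applies the homogeneous map and divides by depth.
#'
#' @param P a 3x4 projection matrix.
#' @param point world mm 3-vector.
#' @return `c(u, v)` continuous 0-based detector pixel coordinates.
#' @export
project_world_point <- function(P, point) {
  stopifnot(is.matrix(P), all(dim(P) == c(3, 4)), length(point) == 3)
  h <- as.numeric(P %*% c(point, 1))
  if (h[3] <= 0)
    stop("degenerate projection: point at or behind the source plane (w <= 0)")
  c(u = h[1] / h[3], v = h[2] / h[3])
}

#' Half fan angle of a divergent-beam geometry
#'
#' `gamma_max = atan(half detector width / SDD)` in radians, measured at
#' the source over the physical detector extent (`u` axis for cone).
#'
#' @param geom a fan/cone [scan_geometry()].
#' @return radians.
#' @export
half_fan_angle <- function(geom) {
  if (geom$beam == "parallel2d") stop("fan angle undefined for parallel beam")
  atan(geom$detector$shape[1] * geom$detector$spacing[1] / 2 / geom$sdd)
}

#' Short-scan angular range
#'
#' The minimal complete fan/cone-beam range `pi + 2 * gamma_max`, where
#' `gamma_max` is the half fan angle.  A parallel scan needs only `pi`
#' and has no short-scan notion, so parallel geometries are rejected.
#'
#' @param geom a fan/cone [scan_geometry()].
#' @return radians.
#' @examples
#' g <- scan_geometry("fan2d", volume_geometry(c(32, 32)),
#'                    detector_geometry(64, 4), n_views = 10,
#'                    sid = 500, sdd = 1000)
#' short_scan_range(g)  # pi + 2 * atan(128 / 1000)
#' @export
short_scan_range <- function(geom) {
  if (geom$beam == "parallel2d")
    stop("short scan undefined for parallel beam (pi suffices)")
  pi + 2 * half_fan_angle(geom)
}

# camera center and inverted 3x3 block of a projection matrix (internal)
decompose_projection_matrix <- function(P) {
  M <- P[, 1:3, drop = FALSE]
  if (abs(det(M)) < 1e-12) stop("projection matrix 3x3 block is singular")
  Minv <- solve(M)
  list(source = as.numeric(-Minv %*% P[, 4]), minv = Minv)
}
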
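#' Ellipse / ellipsoid primitive
#'
#' An additive attenuation primitive: a rotated ellipse (2D) or an
#' ellipsoid rotated about the z axis (3D).
#'
#' @param center world mm center (length 2 or 3).
#' @param semi_axes mm semi-axes (same length as `center`).
#' @param rotation radians, counterclockwise about z.
#' @param value additive attenuation contributed inside the primitive.
#' @return object of class `ellipse_primitive`.
#' @export
ellipse_primitive <- function(center, semi_axes, rotation = 0, value = 1) {
  stopifnot(length(center) %in% c(2, 3), length(semi_axes) == length(center))
  if (any(semi_axes <= 0)) stop("semi_axes must be > 0")
  structure(list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
                 rotation = as.numeric(rotation), value = as.numeric(value)),
            class = c("ellipse_primitive", "ct_primitive"))
}

#' Axis-aligned box primitive
#'
#' @param center world mm center (length 2 or 3).
#' @param half_widths mm half-widths per axis.
#' @param value additive attenuation.
#' @return object of class `box_primitive`.
#' @export
box_primitive <- function(center, half_widths, value = 1) {
  stopifnot(length(center) %in% c(2, 3), length(half_widths) == length(center))
  if (any(half_widths <= 0)) stop("half_widths must be > 0")
  structure(list(center = as.numeric(center), half_widths = as.numeric(half_widths),
                 value = as.numeric(value)),
            class = c("box_primitive", "ct_primitive"))
}

# primitives -> parameter matrix consumed by the C++ rasterizer
primitive_matrix <- function(primitives, ndim) {
  if (length(primitives) == 0)
    return(matrix(numeric(0), ncol = 9))
  rows <- lapply(primitives, function(p) {
    c3 <- function(v) c(v, rep(0, 3 - length(v)))
    if (inherits(p, "ellipse_primitive")) {
      c(0, c3(p$center), c(p$semi_axes, rep(1, 3 - length(p$semi_axes))),
        p$rotation, p$value)
    } else if (inherits(p, "box_primitive")) {
      c(1, c3(p$center), c3(p$half_widths), 0, p$value)
    } else stop("unknown primitive type")
  })
  do.call(rbind, rows)
}

#' Rasterize primitives onto a grid
#'
#' Each voxel receives, summed over all primitives, the primitive value
#' times the fraction of `supersampling^d` sub-voxel sample points that
#' fall inside the primitive.  Primitives are additive: overlaps sum,
#' which is how nested-contrast phantoms such as Shepp-Logan are encoded.
#'
#' @param primitives list of [ellipse_primitive()] / [box_primitive()].
#' @param geom a [volume_geometry()].
#' @param supersampling sub-samples per axis per voxel (>= 1).
#' @return a [volume_grid()].
#' @examples
#' g <- volume_geometry(c(32, 32))
#' disk <- ellipse_primitive(c(0, 0), c(10, 10))
#' v <- rasterize(list(disk), g, supersampling = 4)
#' @export
rasterize <- function(primitives, geom, supersampling = 2) {
  stopifnot(inherits(geom, "volume_geometry"))
  supersampling <- as.integer(supersampling)
  if (supersampling < 1L) stop("supersampling must be >= 1")
  nd <- length(geom$shape)
  vals <- if (length(primitives) == 0) {
    numeric(prod(geom$shape))
  } else {
    cpp_rasterize(primitive_matrix(primitives, nd), geom$shape, geom$spacing,
                  geom$origin, supersampling, nd)
  }
  volume_grid(vals, geom)
}

# Shepp-Logan head phantom parameter table on the canonical [-1, 1]^2
# field of view (Shepp & Logan 1974, as reproduced by Kak & Slaney).
# Columns: x0, y0, a, b, phi_deg.  The 3D z-parameters (z0, c) follow the
# CONRAD-style ellipsoid extension popularized by the phantom3d
# implementation; they are a documented convention, not part of the
# original 2D table.
shepp_logan_table <- function() {
  m <- rbind(
    c( 0.00,  0.0000, 0.6900, 0.9200,   0,  0.00, 0.810),
    c( 0.00, -0.0184, 0.6624, 0.8740,   0,  0.00, 0.780),
    c( 0.22,  0.0000, 0.1100, 0.3100, -18,  0.00, 0.220),
    c(-0.22,  0.0000, 0.1600, 0.4100,  18,  0.00, 0.280),
    c( 0.00,  0.3500, 0.2100, 0.2500,   0, -0.15, 0.410),
    c( 0.00,  0.1000, 0.0460, 0.0460,   0,  0.25, 0.050),
    c( 0.00, -0.1000, 0.0460, 0.0460,   0,  0.25, 0.050),
    c(-0.08, -0.6050, 0.0460, 0.0230,   0,  0.00, 0.050),
    c( 0.00, -0.6050, 0.0230, 0.0230,   0,  0.00, 0.020),
    c( 0.06, -0.6050, 0.0230, 0.0460,   0,  0.00, 0.020))
  colnames(m) <- c("x0", "y0", "a", "b", "phi_deg", "z0", "c")
  m
}

# additive intensities: "standard" = original grey levels,
# "modified" = high-contrast variant common in visualization
shepp_logan_values <- function(variant) {
  switch(variant,
         standard = c(2, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
         modified = c(1, -0.80, -0.20, -0.20, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10),
         stop("variant must be 'standard' or 'modified'"))
}

#' Shepp-Logan ellipse set
#'
#' The ten ellipses (or ellipsoids) of the Shepp-Logan head phantom as
#' primitives, scaled from the canonical `[-1, 1]` field of view to a
#' physical half-extent per axis.
#'
#' @param half_extent mm half-extent per axis (length 2 or 3; recycled).
#' @param dims 2 or 3.
#' @param variant `"modified"` (high contrast, default) or `"standard"`
#'   (the original grey levels).
#' @return list of [ellipse_primitive()].
#' @export
shepp_logan_primitives <- function(half_extent, dims = 2,
                                   variant = c("modified", "standard")) {
  variant <- match.arg(variant)
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  he <- rep_len(as.numeric(half_extent), dims)
  tab <- shepp_logan_table()
  vals <- shepp_logan_values(variant)
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    if (dims == 2) {
      ellipse_primitive(center = c(r["x0"], r["y0"]) * he,
                        semi_axes = c(r["a"], r["b"]) * he,
                        rotation = r["phi_deg"] * pi / 180, value = vals[i])
    } else {
      ellipse_primitive(center = c(r["x0"], r["y0"], r["z0"]) * he,
                        semi_axes = c(r["a"], r["b"], r["c"]) * he,
                        rotation = r["phi_deg"] * pi / 180, value = vals[i])
    }
  })
}

#' Shepp-Logan phantom
#'
#' Rasterizes the published 10-ellipse Shepp-Logan head phantom (or its
#' ellipsoid extension) scaled to the physical extent of the volume.
#'
#' @param geom a [volume_geometry()] (2D or 3D to match `dims`).
#' @param dims 2 or 3; defaults to the dimensionality of `geom`.
#' @param variant `"modified"` (default) or `"standard"`.
#' @param supersampling rasterization sub-samples per axis.
#' @return a [volume_grid()].
#' @examples
#' ph <- shepp_logan(volume_geometry(c(64, 64), spacing = 2))
#' @export
shepp_logan <- function(geom, dims = length(geom$shape),
                        variant = c("modified", "standard"),
                        supersampling = 2) {
  variant <- match.arg(variant)
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  if (length(geom$shape) != dims)
    stop("geometry dimensionality must match dims")
  he <- geom$shape * geom$spacing / 2
  rasterize(shepp_logan_primitives(he, dims, variant), geom, supersampling)
}

#' Analytic parallel-beam sinogram of an ellipse set
#'
#' Closed-form Radon transform: the line integral of a constant-value
#' ellipse along the ray at angle `theta` and (signed, mm) detector
#' coordinate `s` is the chord length `2ab / W^2 * sqrt(W^2 - t^2)` scaled
#' by the value, where `W^2 = a^2 cos^2(theta - phi) + b^2 sin^2(theta -
#' phi)` is the squared half-width of the ellipse shadow and `t` the ray
#' offset from the ellipse center.  Used as the exact oracle against which
#' the ray-marched projector is validated.
#'
#' @param ellipses list of 2D [ellipse_primitive()].
#' @param geom a parallel-beam [scan_geometry()].
#' @return a [projection_stack()] of exact line integrals (value*mm).
#' @export
analytic_sinogram <- function(ellipses, geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (geom$beam != "parallel2d")
    stop("the analytic sinogram oracle supports only the parallel beam")
  s <- detector_coords(geom$detector)
  out <- matrix(0, geom$n_views, geom$detector$shape[1])
  for (e in ellipses) {
    if (length(e$center) != 2 || !inherits(e, "ellipse_primitive"))
      stop("analytic_sinogram expects 2D ellipse primitives")
    a <- e$semi_axes[1]; b <- e$semi_axes[2]
    for (vi in seq_len(geom$n_views)) {
      th <- geom$angles[vi]
      u <- c(cos(th), sin(th))                    # detector axis
      t <- s - sum(e$center * u)                  # ray offset from center
      W2 <- (a * cos(th - e$rotation))^2 + (b * sin(th - e$rotation))^2
      inside <- t^2 < W2
      chord <- numeric(length(s))
      chord[inside] <- 2 * a * b / W2 * sqrt(W2 - t[inside]^2)
      out[vi, ] <- out[vi, ] + e$value * chord
    }
  }
  projection_stack(out, geom)
}
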
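#' Volume grid
#'
#' Attenuation values on a regular grid together with its world-coordinate
#' metadata.  Values are stored as a base-R array whose `dim` equals the
#' geometry's `shape` (axis order x, y[, z]).
#'
#' @param values numeric array (or vector, reshaped) of attenuation values.
#' @param geometry a [volume_geometry()].
#' @return an object of class `volume_grid` with fields `values`, `geometry`.
#' @export
volume_grid <- function(values, geometry) {
  stopifnot(inherits(geometry, "volume_geometry"))
  values <- as.numeric(values)
  if (length(values) != prod(geometry$shape))
    stop("value count does not match geometry shape")
  structure(list(values = array(values, dim = geometry$shape),
                 geometry = geometry),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels @ %s mm, range [%.4g, %.4g]\n",
              paste(x$geometry$shape, collapse = " x "),
              paste(signif(x$geometry$spacing, 4), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Projection stack (sinogram)
#'
#' Per-view detector samples (line integrals in value*mm) plus the scan
#' geometry that produced them.  For 2D beams `values` is an
#' `n_views x n_pixels` matrix; for the cone beam an
#' `n_views x n_u x n_v` array.
#'
#' @param values numeric array of measurements (first dimension = views).
#' @param geometry a [scan_geometry()].
#' @return an object of class `projection_stack`.
#' @export
projection_stack <- function(values, geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  dims <- c(geometry$n_views, geometry$detector$shape)
  values <- array(as.numeric(values), dim = dims)
  structure(list(values = values, geometry = geometry),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  cat(sprintf("<projection_stack> %s (%s beam), range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = " x "),
              x$geometry$beam, min(x$values), max(x$values)))
  invisible(x)
}

# shared validation helper
check_same_geometry <- function(a, b, what) {
  if (!isTRUE(all.equal(a, b, tolerance = 1e-12)))
    stop(sprintf("geometry mismatch: %s", what))
  invisible(TRUE)
}
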
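#' Projector configuration
#'
#' @param step_fraction ray-march step as a fraction of the smallest voxel
#'   spacing, in (0, 1]; default 0.5.
#' @param fbp_weighting logical: apply the FDK distance weight
#'   `U^-2`, `U = (SID + depth along the principal ray) / SID`, inside the
#'   fan/cone back projection (for FBP/FDK use).  Leave `FALSE` for the
#'   plain operator used as a gradient.
#' @return object of class `projector_config`.
#' @export
projector_config <- function(step_fraction = 0.5, fbp_weighting = FALSE) {
  step_fraction <- as.numeric(step_fraction)
  if (!(step_fraction > 0 && step_fraction <= 1))
    stop("step_fraction must be in (0, 1]")
  structure(list(step_fraction = step_fraction,
                 fbp_weighting = isTRUE(fbp_weighting)),
            class = "projector_config")
}

# per-view source positions and inverted 3x3 blocks for the cone kernels
cone_ray_tables <- function(geom) {
  dec <- lapply(geom$matrices, decompose_projection_matrix)
  list(srcs = do.call(rbind, lapply(dec, `[[`, "source")),
       minvs = do.call(rbind, lapply(dec, function(d) as.numeric(t(d$minv)))))
}

cone_pmat_table <- function(geom)
  do.call(rbind, lapply(geom$matrices, function(P) as.numeric(t(P))))

beam_code <- function(geom) switch(geom$beam, parallel2d = 0L, fan2d = 1L, cone3d = 2L)

#' Ray-driven forward projection
#'
#' Casts one ray per (view, detector pixel) through the volume, marching
#' from volume entry to exit in steps of `step_fraction * min(spacing)`
#' and accumulating bi/trilinearly interpolated samples times the step
#' length (mm), i.e. a true sampled line integral.  Samples outside the
#' grid contribute zero.  Parallel and fan rays are built from the view
#' angle and detector coordinate; cone rays are derived from each view's
#' projection matrix (source = camera center, direction through the pixel),
#' so calibrated matrices are supported.
#'
#' @param vol a [volume_grid()] whose geometry equals `geom$volume`.
#' @param geom a [scan_geometry()].
#' @param cfg a [projector_config()].
#' @return a [projection_stack()] of line integrals (value*mm).
#' @examples
#' g <- scan_geometry("parallel2d", volume_geometry(c(32, 32)),
#'                    detector_geometry(47), n_views = 24)
#' sino <- forward_project(shepp_logan(g$volume), g)
#' @export
forward_project <- function(vol, geom, cfg = projector_config()) {
  stopifnot(inherits(vol, "volume_grid"), inherits(geom, "scan_geometry"))
  check_same_geometry(vol$geometry, geom$volume,
                      "volume grid does not match scan geometry")
  step <- cfg$step_fraction * min(geom$volume$spacing)
  vg <- geom$volume
  if (geom$beam == "cone3d") {
    if (is.null(geom$matrices)) stop("cone3d requires projection matrices")
    rt <- cone_ray_tables(geom)
    out <- numeric(geom$n_views * prod(geom$detector$shape))
    cpp_raycone(as.numeric(vol$values), vg$shape, vg$spacing, vg$origin,
                rt$srcs, rt$minvs, geom$detector$shape[1],
                geom$detector$shape[2], out, step, FALSE)
  } else {
    out <- matrix(0, geom$n_views, geom$detector$shape[1])
    cpp_ray2d(as.numeric(vol$values), vg$shape, vg$spacing, vg$origin,
              geom$angles, geom$detector$shape[1], geom$detector$spacing[1],
              geom$detector$offset[1], beam_code(geom),
              if (is.null(geom$sid)) 0 else geom$sid,
              if (is.null(geom$sdd)) 0 else geom$sdd, step, out, FALSE)
  }
  projection_stack(out, geom)
}

#' Exact transpose of the ray-driven forward projector
#'
#' Applies `A^T` for the same discretized `A` as [forward_project()]:
#' every ray revisits exactly the sample positions of the forward march
#' and scatters its sinogram value times step length back through the
#' interpolation weights.  This is the registered gradient of the
#' projector layer; it is *not* the voxel-driven [back_project()].
#'
#' @inheritParams back_project
#' @return a [volume_grid()] holding `A^T p`.
#' @export
forward_project_transpose <- function(stack, geom = stack$geometry,
                                      cfg = projector_config()) {
  stopifnot(inherits(stack, "projection_stack"))
  check_same_geometry(stack$geometry, geom, "stack does not match geometry")
  step <- cfg$step_fraction * min(geom$volume$spacing)
  vg <- geom$volume
  vol <- numeric(prod(vg$shape))
  if (geom$beam == "cone3d") {
    rt <- cone_ray_tables(geom)
    cpp_raycone(vol, vg$shape, vg$spacing, vg$origin, rt$srcs, rt$minvs,
                geom$detector$shape[1], geom$detector$shape[2],
                as.numeric(stack$values), step, TRUE)
  } else {
    cpp_ray2d(vol, vg$shape, vg$spacing, vg$origin, geom$angles,
              geom$detector$shape[1], geom$detector$spacing[1],
              geom$detector$offset[1], beam_code(geom),
              if (is.null(geom$sid)) 0 else geom$sid,
              if (is.null(geom$sdd)) 0 else geom$sdd, step,
              matrix(stack$values, geom$n_views), TRUE)
  }
  volume_grid(vol, vg)
}

#' Voxel-driven back projection
#'
#' For every voxel and every view, computes the voxel's continuous
#' detector coordinate (orthogonal projection for the parallel beam,
#' source-voxel ray/detector intersection for the fan beam, perspective
#' division through the projection matrix for the cone beam), linearly
#' interpolates the measured row/image, and accumulates.  The result is
#' scaled by the angular increment `delta_beta`, so FBP-style sums need no
#' further view normalization.  With `cfg$fbp_weighting`, fan/cone
#' contributions are additionally multiplied by the FDK distance weight
#' `U^-2` with `U = (SID + voxel depth along the principal ray) / SID`.
#' Detector coordinates outside the detector contribute zero.
#'
#' Note this voxel-driven operator and the ray-driven forward projector
#' form an *unmatched* pair: it is not the exact transpose of
#' [forward_project()] (that is [forward_project_transpose()]); the
#' residual discrepancy is quantified in the package tests.
#'
#' @param stack a [projection_stack()].
#' @param geom a [scan_geometry()] equal to the stack's.
#' @param cfg a [projector_config()].
#' @return a [volume_grid()].
#' @export
back_project <- function(stack, geom = stack$geometry,
                         cfg = projector_config()) {
  stopifnot(inherits(stack, "projection_stack"))
  check_same_geometry(stack$geometry, geom, "stack does not match geometry")
  vg <- geom$volume
  vol <- numeric(prod(vg$shape))
  if (geom$beam == "cone3d") {
    cpp_backcone(as.numeric(stack$values), cone_pmat_table(geom),
                 geom$detector$shape[1], geom$detector$shape[2],
                 vol, vg$shape, vg$spacing, vg$origin,
                 cfg$fbp_weighting, if (is.null(geom$sid)) 1 else geom$sid,
                 delta_beta(geom), FALSE)
  } else {
    cpp_backproject2d(matrix(stack$values, geom$n_views), geom$angles,
                      geom$detector$shape[1], geom$detector$spacing[1],
                      geom$detector$offset[1], beam_code(geom),
                      if (is.null(geom$sid)) 0 else geom$sid,
                      if (is.null(geom$sdd)) 0 else geom$sdd,
                      vol, vg$shape, vg$spacing, vg$origin,
                      cfg$fbp_weighting, delta_beta(geom), FALSE)
  }
  volume_grid(vol, vg)
}

#' Exact transpose of the voxel-driven back projector
#'
#' Applies `B^T` for the same discretized `B` as [back_project()]
#' (including the `delta_beta` scale and, if configured, the FDK distance
#' weight): each voxel's value is splatted onto its detector footprint.
#' This is the registered gradient of the back-projector layer.
#'
#' @param vol a [volume_grid()].
#' @inheritParams back_project
#' @return a [projection_stack()] holding `B^T x`.
#' @export
back_project_transpose <- function(vol, geom, cfg = projector_config()) {
  stopifnot(inherits(vol, "volume_grid"), inherits(geom, "scan_geometry"))
  check_same_geometry(vol$geometry, geom$volume,
                      "volume grid does not match scan geometry")
  vg <- geom$volume
  if (geom$beam == "cone3d") {
    out <- numeric(geom$n_views * prod(geom$detector$shape))
    cpp_backcone(out, cone_pmat_table(geom),
                 geom$detector$shape[1], geom$detector$shape[2],
                 as.numeric(vol$values), vg$shape, vg$spacing, vg$origin,
                 cfg$fbp_weighting, if (is.null(geom$sid)) 1 else geom$sid,
                 delta_beta(geom), TRUE)
  } else {
    out <- matrix(0, geom$n_views, geom$detector$shape[1])
    cpp_backproject2d(out, geom$angles, geom$detector$shape[1],
                      geom$detector$spacing[1], geom$detector$offset[1],
                      beam_code(geom),
                      if (is.null(geom$sid)) 0 else geom$sid,
                      if (is.null(geom$sdd)) 0 else geom$sdd,
                      as.numeric(vol$values), vg$shape, vg$spacing, vg$origin,
                      cfg$fbp_weighting, delta_beta(geom), TRUE)
  }
  projection_stack(out, geom)
}

#' Materialize the system matrix for a small problem
#'
#' The operator is normally applied on the fly because the system matrix
#' is far too large to store; for tiny problems it can be materialized
#' exactly, as the definition-level oracle for adjointness and linearity
#' tests.  Column `j` is [forward_project()] applied to the `j`-th unit
#' basis volume, flattened in column-major (array) order; rows are
#' flattened projection stacks.
#'
#' @param geom a [scan_geometry()].
#' @param cfg a [projector_config()].
#' @param max_elements refuse to build more than this many entries
#'   (default `2^22`).
#' @return dense numeric matrix (`n_rays` x `n_voxels`).
#' @export
explicit_system_matrix <- function(geom, cfg = projector_config(),
                                   max_elements = 2^22) {
  n_vox <- prod(geom$volume$shape)
  n_rays <- geom$n_views * prod(geom$detector$shape)
  if (as.double(n_vox) * n_rays > max_elements)
    stop(sprintf("refusing to materialize %g matrix elements (cap %g)",
                 as.double(n_vox) * n_rays, max_elements))
  A <- matrix(0, n_rays, n_vox)
  basis <- numeric(n_vox)
  for (j in seq_len(n_vox)) {
    basis[j] <- 1
    A[, j] <- as.numeric(
      forward_project(volume_grid(basis, geom$volume), geom, cfg)$values)
    basis[j] <- 0
  }
  A
}
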
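#' Filtered backprojection / FDK reconstruction
#'
#' Analytic reconstruction for all three beam types:
#'
#' * **parallel2d** — ramp-filter every row ([ramp_frequency_filter()] in
#'   cycles/mm) and back-project; with the angular increment applied in
#'   [back_project()], a scan covering `[0, pi)` reconstructs absolute
#'   attenuation values with no further normalization.
#' * **fan2d** (short scan) — pre-weight rows by cosine and Parker
#'   redundancy weights, ramp-filter at the detector spacing rescaled to
#'   the isocenter plane (`tau * SID/SDD`), then distance-weighted
#'   (`U^-2`) back projection.
#' * **cone3d** (FDK, short scan or full scan) — cosine pre-weight per
#'   detector image (Parker weights added for a short scan), row-wise ramp
#'   filtering along `u` at the rescaled spacing, then distance-weighted
#'   matrix-based back projection.
#'
#' Fan reconstructions require the short-scan range
#' `pi + 2*gamma_max`; cone reconstructions accept either the short scan
#' or a full `2*pi` orbit (where redundancy is uniform and the sum is
#' halved instead of Parker-weighted).
#'
#' @param stack a [projection_stack()].
#' @param geom the matching [scan_geometry()] (defaults to the stack's).
#' @param cfg a [projector_config()]; `fbp_weighting` is forced on for
#'   fan/cone.
#' @return a [volume_grid()].
#' @examples
#' g <- scan_geometry("parallel2d", volume_geometry(c(64, 64)),
#'                    detector_geometry(95), n_views = 90)
#' rec <- fbp(forward_project(shepp_logan(g$volume), g))
#' @export
fbp <- function(stack, geom = stack$geometry, cfg = projector_config()) {
  stopifnot(inherits(stack, "projection_stack"))
  check_same_geometry(stack$geometry, geom, "stack does not match geometry")
  nd <- geom$detector$shape[1]
  if (geom$beam == "parallel2d") {
    filt <- ramp_frequency_filter(default_pad_length(nd),
                                  geom$detector$spacing[1])
    return(back_project(filter_projections(stack, filt), geom, cfg))
  }
  # divergent beams: pre-weight, filter on the virtual isocenter detector,
  # distance-weighted back projection
  full_scan <- abs(geom$angular_range - 2 * pi) < 1e-6
  short_scan <- abs(geom$angular_range - short_scan_range(geom)) < 1e-6
  if (!full_scan && !short_scan)
    stop("fan/cone FBP requires a short scan (pi + 2*gamma_max) or, for cone, a full 2*pi scan")
  if (geom$beam == "fan2d" && !short_scan)
    stop("fan FBP requires the short-scan range pi + 2*gamma_max")
  w <- cosine_weights(geom)
  w <- if (short_scan) w * parker_weights(geom) else w / 2
  tau_iso <- geom$detector$spacing[1] * geom$sid / geom$sdd
  filt <- ramp_frequency_filter(default_pad_length(nd), tau_iso)
  pre <- projection_stack(stack$values * w, geom)
  cfg$fbp_weighting <- TRUE
  back_project(filter_projections(pre, filt), geom, cfg)
}

#' Smoothed total variation and its gradient
#'
#' Isotropic total variation with an `epsilon`-smoothed magnitude:
#' \deqn{TV_\epsilon(x) = \sum_j \left(\sqrt{\sum_d (D_d x)_j^2 +
#'   \epsilon^2} - \epsilon\right)}
#' with forward differences `D_d` along every axis and a zero (replicated)
#' difference at the far boundary, so constants have exactly zero value
#' and gradient.  The gradient is the exact analytic gradient of this
#' functional: the negative divergence of the normalized differences.
#'
#' @param vol a [volume_grid()] or numeric array.
#' @param epsilon smoothing constant (> 0); in the units of the voxel
#'   values.
#' @return list with `value` (scalar) and `gradient` (array shaped like
#'   the input).
#' @export
tv_value_and_gradient <- function(vol, epsilon = 1e-6) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  x <- if (inherits(vol, "volume_grid")) vol$values else vol
  nd <- length(dim(x))
  if (is.null(dim(x))) { x <- array(x, length(x)); nd <- 1 }
  shift_fwd <- function(a, d) {        # a[i+1] along axis d, replicated end
    idx <- lapply(dim(a), seq_len)
    idx[[d]] <- pmin(idx[[d]] + 1L, dim(a)[d])
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  diffs <- lapply(seq_len(nd), function(d) shift_fwd(x, d) - x)
  mag <- sqrt(Reduce(`+`, lapply(diffs, function(g) g^2)) + epsilon^2)
  value <- sum(mag) - epsilon * length(x)
  grad <- array(0, dim(x))
  for (d in seq_len(nd)) {
    nd_field <- diffs[[d]] / mag       # normalized forward difference
    # d/dx_j of sum(mag): -nd_field at j, +nd_field at the site whose
    # forward neighbor is j (negative divergence)
    grad <- grad - nd_field
    back <- array(0, dim(x))
    src <- lapply(dim(x), seq_len); src[[d]] <- seq_len(dim(x)[d] - 1L)
    dst <- lapply(dim(x), seq_len); dst[[d]] <- seq_len(dim(x)[d] - 1L) + 1L
    back <- do.call(`[<-`, c(list(back), dst,
                             list(do.call(`[`, c(list(nd_field), src,
                                                 list(drop = FALSE))))))
    grad <- grad + back
  }
  list(value = value, gradient = grad)
}

#' Iterative reconstruction configuration
#'
#' @param lambda_tv total-variation weight (>= 0).
#' @param step_size initial gradient step (> 0); halved by backtracking
#'   whenever a step would increase the objective.
#' @param iterations gradient-descent iterations.
#' @param tv_epsilon TV smoothing constant (> 0, default `1e-6`; in the
#'   units of the voxel values).
#' @param init `"zeros"` or `"fbp"` (warm start from [fbp()]).
#' @param seed integer seed (the default pipeline is deterministic).
#' @return object of class `iterative_config`.
#' @export
iterative_config <- function(lambda_tv = 0, step_size = 1e-3, iterations = 50,
                             tv_epsilon = 1e-6, init = c("zeros", "fbp"),
                             seed = 0) {
  if (lambda_tv < 0) stop("lambda_tv must be >= 0")
  if (step_size <= 0) stop("step_size must be > 0")
  if (tv_epsilon <= 0) stop("tv_epsilon must be > 0")
  structure(list(lambda_tv = lambda_tv, step_size = step_size,
                 iterations = as.integer(iterations),
                 tv_epsilon = tv_epsilon, init = match.arg(init),
                 seed = as.integer(seed)),
            class = "iterative_config")
}

#' TV-regularized iterative reconstruction
#'
#' Minimizes \deqn{f(x) = \|Ax - p\|_2^2 + \lambda\, TV_\epsilon(x)} by
#' gradient descent, exactly the objective of the known-operator
#' "training" formulation of iterative reconstruction: the volume is the
#' only trainable quantity and the projector is a fixed differentiable
#' layer.  The data-term gradient is `2 A^T (Ax - p)` with `A^T` the
#' projector layer's registered gradient (the exact transpose of the
#' ray-driven forward projector).  Steps use backtracking: whenever a step
#' would increase `f`, the step is halved (up to 40 times); the returned
#' objective trace is therefore non-increasing.  After an accepted step
#' the step size is doubled again up to the configured `step_size`.
#'
#' @param stack a [projection_stack()] of measurements `p`.
#' @param geom the matching [scan_geometry()].
#' @param cfg an [iterative_config()].
#' @param proj_cfg a [projector_config()] for the operator
#'   discretization.
#' @return list with `volume` (a [volume_grid()]) and `trace` (data frame
#'   with columns `iteration`, `data_term`, `tv_term`, `objective`,
#'   `step`).
#' @export
iterative_tv <- function(stack, geom = stack$geometry,
                         cfg = iterative_config(),
                         proj_cfg = projector_config()) {
  stopifnot(inherits(stack, "projection_stack"),
            inherits(cfg, "iterative_config"))
  check_same_geometry(stack$geometry, geom, "stack does not match geometry")
  p <- stack$values
  op <- projector_layer(geom, proj_cfg)
  x <- if (cfg$init == "fbp") fbp(stack, geom, proj_cfg)$values
       else array(0, geom$volume$shape)

  objective <- function(x) {
    r <- op$forward(x) - p
    dt <- sum(r^2)
    tv <- if (cfg$lambda_tv > 0)
      tv_value_and_gradient(x, cfg$tv_epsilon)$value else 0
    list(data_term = dt, tv_term = tv,
         total = dt + cfg$lambda_tv * tv, resid = r)
  }
  ob <- objective(x)
  if (!is.finite(ob$total)) stop("non-finite objective at initialization")
  trace <- data.frame(iteration = 0, data_term = ob$data_term,
                      tv_term = ob$tv_term, objective = ob$total, step = NA)
  alpha <- cfg$step_size
  for (it in seq_len(cfg$iterations)) {
    g <- 2 * op$gradient(ob$resid)
    if (cfg$lambda_tv > 0)
      g <- g + cfg$lambda_tv * tv_value_and_gradient(x, cfg$tv_epsilon)$gradient
    accepted <- FALSE
    for (bt in 0:40) {
      xn <- x - alpha * g
      obn <- objective(xn)
      if (!is.finite(obn$total)) stop("non-finite objective during descent")
      if (obn$total <= ob$total) { accepted <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!accepted) break                    # step underflow: converged
    x <- xn; ob <- obn
    trace <- rbind(trace,
                   data.frame(iteration = it, data_term = ob$data_term,
                              tv_term = ob$tv_term, objective = ob$total,
                              step = alpha))
    alpha <- min(2 * alpha, cfg$step_size)
  }
  list(volume = volume_grid(x, geom$volume), trace = trace)
}
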
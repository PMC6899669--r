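#' Differentiable operator
#'
#' A forward map bundled with its registered gradient operator, the
#' known-operator building block: chains of such operators are end-to-end
#' differentiable because each layer knows how to map an upstream gradient
#' back to its input space.
#'
#' @param forward function: input array -> output array.
#' @param gradient function: upstream gradient array -> input-space
#'   gradient array (same shape as the forward input).
#' @param name label used in messages.
#' @return object of class `differentiable_op`.
#' @export
differentiable_op <- function(forward, gradient, name = "op") {
  stopifnot(is.function(forward), is.function(gradient))
  structure(list(forward = forward, gradient = gradient, name = name),
            class = "differentiable_op")
}

#' @export
print.differentiable_op <- function(x, ...) {
  cat(sprintf("<differentiable_op> %s\n", x$name)); invisible(x)
}

#' Forward-projection layer
#'
#' The system matrix `A` as a differentiable operator: forward is the
#' ray-driven [forward_project()], and the registered gradient is the
#' exact transpose [forward_project_transpose()] of the same
#' discretization, so finite-difference gradient checks hold to numerical
#' precision.  (The voxel-driven [back_project()] is a different, unmatched
#' operator; use [backprojector_layer()] for it.)
#'
#' Inputs and outputs are plain arrays (volume-shaped in, stack-shaped
#' out) so layers can be composed freely.
#'
#' @param geom a [scan_geometry()].
#' @param cfg a [projector_config()].
#' @return a [differentiable_op()].
#' @export
projector_layer <- function(geom, cfg = projector_config()) {
  differentiable_op(
    forward = function(x)
      forward_project(volume_grid(x, geom$volume), geom, cfg)$values,
    gradient = function(g)
      forward_project_transpose(projection_stack(g, geom), geom, cfg)$values,
    name = sprintf("forward_projector[%s]", geom$beam))
}

#' Back-projection layer
#'
#' The voxel-driven back projection as a differentiable operator: forward
#' is [back_project()] (stack-shaped in, volume-shaped out, including the
#' `delta_beta` scale and any configured FDK weighting) and the registered
#' gradient is its exact transpose [back_project_transpose()], a
#' forward-projection-like detector splat.
#'
#' @inheritParams projector_layer
#' @return a [differentiable_op()].
#' @export
backprojector_layer <- function(geom, cfg = projector_config()) {
  differentiable_op(
    forward = function(p)
      back_project(projection_stack(p, geom), geom, cfg)$values,
    gradient = function(g)
      back_project_transpose(volume_grid(g, geom$volume), geom, cfg)$values,
    name = sprintf("back_projector[%s]", geom$beam))
}

#' Finite-difference gradient check
#'
#' Verifies a layer's registered gradient against central finite
#' differences of the scalar loss `L(x) = <w, forward(x)>` with a seeded
#' random weight array `w`.  The analytic gradient is `gradient(w)`;
#' the numeric derivative of coordinate `i` is
#' `(L(x + h e_i) - L(x - h e_i)) / (2h)` with
#' `h = 1e-4 * max(1, max|x|)`, evaluated on a seeded random subset of at
#' least `n_coords` coordinates.
#'
#' @param op a [differentiable_op()].
#' @param x input array at which to check.
#' @param seed integer seed for `w` and the coordinate subset.
#' @param n_coords number of coordinates to probe (default 32).
#' @return the maximum relative deviation
#'   `max |analytic - numeric| / max(|numeric|, eps)` over the probed
#'   coordinates, with attributes `analytic` and `numeric`.
#' @examples
#' g <- scan_geometry("parallel2d", volume_geometry(c(8, 8)),
#'                    detector_geometry(11), n_views = 6)
#' finite_difference_gradcheck(projector_layer(g),
#'                             array(0, c(8, 8)), seed = 0)
#' @export
finite_difference_gradcheck <- function(op, x, seed = 0, n_coords = 32) {
  stopifnot(inherits(op, "differentiable_op"))
  y <- op$forward(x)
  if (!all(is.finite(y))) stop("forward produced non-finite values")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  w <- array(stats::rnorm(length(y)), dim = dim(y) %||% length(y))
  idx <- sample(length(x), min(max(32, n_coords), length(x)))
  if (!is.null(old)) on.exit(assign(".Random.seed", old, globalenv()))
  g_an <- op$gradient(w)
  if (!all(is.finite(g_an))) stop("gradient produced non-finite values")
  h <- 1e-4 * max(1, max(abs(x)))
  loss <- function(z) sum(w * op$forward(z))
  num <- vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (loss(xp) - loss(xm)) / (2 * h)
  }, numeric(1))
  an <- as.numeric(g_an)[idx]
  if (!all(is.finite(num))) stop("finite differences produced non-finite values")
  eps <- 1e-8 * max(1, max(abs(num)))
  dev <- max(abs(an - num) / pmax(abs(num), eps))
  structure(dev, analytic = an, numeric = num)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pipeline xhat(K) = B F^-1 diag(K) F p for a list of padded row-spectra;
# returns list of reconstructed value arrays (linear in K)
filter_pipeline_apply <- function(K, spectra, geoms, cfg) {
  lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]            # pad x n_views complex
    n <- nrow(sp)
    w <- full_spectrum(frequency_filter(K, n))
    q <- Re(stats::mvfft(sp * w, inverse = TRUE)) / n
    nd <- geoms[[i]]$detector$shape[1]
    back_project(projection_stack(t(q[seq_len(nd), , drop = FALSE]),
                                  geoms[[i]]), geoms[[i]], cfg)$values
  })
}

#' Learn the FBP reconstruction filter by gradient descent
#'
#' Treats the per-frequency diagonal weights `K` of the FBP pipeline
#' `xhat = B F^-1 K F p` as free parameters and minimizes
#' `1/2 sum_i || xhat_i - target_i ||^2` over one or more
#' (sinogram, reference volume) training pairs by gradient descent, with
#' the gradient obtained through the differentiable chain (the
#' back-projection layer's registered gradient, then the inverse/forward
#' Fourier factors).  Because the reconstruction is linear in `K` the
#' problem is a convex quadratic; with `step_size = NULL` an exact line
#' search is used (one extra linear-pipeline application per iteration)
#' and the loss is non-increasing by construction.
#'
#' The quadratic is badly conditioned in the frequency index (the descent
#' rate of weight `k` scales with the sinogram's spectral energy at `k`,
#' which decays steeply), so by default the descent direction is scaled by
#' a per-frequency Jacobi preconditioner `d_k = ||column_k||^2` computed
#' once at start-up; this is still first-order descent on the same
#' objective, converges orders of magnitude faster, and remains monotone
#' under the exact line search.  Set `precondition = FALSE` for plain
#' steepest descent.
#'
#' `K` is a half spectrum over the non-negative frequencies of the padded
#' row length (symmetric extension implied), exactly as in
#' [frequency_filter()].
#'
#' @param stacks a [projection_stack()] or list of them (parallel beam).
#' @param targets a [volume_grid()] or list matching `stacks`.
#' @param init initial filter: a [frequency_filter()], a numeric half
#'   spectrum, or `NULL` for zeros.
#' @param step_size fixed gradient step, or `NULL` (default) for an exact
#'   line search.
#' @param iterations gradient-descent iterations.
#' @param seed integer seed (reserved; the procedure is deterministic).
#' @param pad_length padded row length; default [default_pad_length()] of
#'   the detector row.
#' @param precondition scale descent directions by the per-frequency
#'   Jacobi preconditioner (default `TRUE`).
#' @return list with `filter` (a [frequency_filter()]), `losses`
#'   (per-iteration objective, length `iterations + 1` including the
#'   initial loss), and `steps` (accepted step sizes).
#' @export
learn_fbp_filter <- function(stacks, targets, init = NULL, step_size = NULL,
                             iterations = 100, seed = 0, pad_length = NULL,
                             precondition = TRUE) {
  if (inherits(stacks, "projection_stack")) stacks <- list(stacks)
  if (inherits(targets, "volume_grid")) targets <- list(targets)
  if (length(stacks) < 1 || length(stacks) != length(targets))
    stop("need matching, non-empty lists of sinograms and targets")
  geoms <- lapply(stacks, `[[`, "geometry")
  for (i in seq_along(stacks)) {
    if (geoms[[i]]$beam != "parallel2d")
      stop("filter learning supports the parallel beam")
    check_same_geometry(targets[[i]]$geometry, geoms[[i]]$volume,
                        "target does not match sinogram geometry")
  }
  nd <- geoms[[1]]$detector$shape[1]
  if (is.null(pad_length)) pad_length <- default_pad_length(nd)
  nk <- pad_length %/% 2 + 1
  K <- if (is.null(init)) numeric(nk)
       else if (inherits(init, "frequency_filter")) init$weights
       else as.numeric(init)
  if (length(K) != nk) stop("init filter length does not match pad_length")
  cfg <- projector_config()

  # precompute row spectra F p (pad x n_views) per training pair
  spectra <- lapply(stacks, function(st) {
    padded <- matrix(0, pad_length, st$geometry$n_views)
    padded[seq_len(nd), ] <- t(st$values)
    stats::mvfft(padded)
  })
  tvals <- lapply(targets, `[[`, "values")
  blayers <- lapply(geoms, function(g) backprojector_layer(g, cfg))

  grad_K <- function(resids) {
    g <- numeric(nk)
    for (i in seq_along(resids)) {
      gs <- blayers[[i]]$gradient(resids[[i]])      # d loss / d filtered rows
      gpad <- matrix(0, pad_length, geoms[[i]]$n_views)
      gpad[seq_len(nd), ] <- t(gs)
      G <- stats::mvfft(gpad)
      full <- rowSums(Re(spectra[[i]] * Conj(G))) / pad_length
      half <- full[seq_len(nk)]
      if (pad_length > 2) {
        mid <- 2:(ceiling(pad_length / 2))          # paired +/- frequencies
        half[mid] <- 2 * half[mid]
      }
      g <- g + half
    }
    g
  }
  loss_of <- function(recons)
    0.5 * sum(vapply(seq_along(recons),
                     function(i) sum((recons[[i]] - tvals[[i]])^2), numeric(1)))

  diag_pre <- if (precondition && iterations > 0) {
    d <- vapply(seq_len(nk), function(i) {
      e <- numeric(nk); e[i] <- 1
      sum(vapply(filter_pipeline_apply(e, spectra, geoms, cfg),
                 function(m) sum(m^2), numeric(1)))
    }, numeric(1))
    pmax(d, 1e-12 * max(d, 0) + 1e-300)
  } else rep(1, nk)

  recon <- filter_pipeline_apply(K, spectra, geoms, cfg)
  losses <- loss_of(recon)
  steps <- numeric(0)
  for (it in seq_len(iterations)) {
    resid <- lapply(seq_along(recon), function(i) recon[[i]] - tvals[[i]])
    g <- grad_K(resid)
    dir <- g / diag_pre
    gd <- sum(g * dir)
    if (gd == 0) { losses <- c(losses, losses[length(losses)]); next }
    if (is.null(step_size)) {
      Md <- filter_pipeline_apply(dir, spectra, geoms, cfg)
      denom <- sum(vapply(Md, function(m) sum(m^2), numeric(1)))
      alpha <- if (denom > 0) gd / denom else 0
    } else alpha <- step_size
    K <- K - alpha * dir
    recon <- filter_pipeline_apply(K, spectra, geoms, cfg)
    losses <- c(losses, loss_of(recon))
    steps <- c(steps, alpha)
  }
  list(filter = frequency_filter(K, pad_length,
                                 geoms[[1]]$detector$spacing[1]),
       losses = losses, steps = steps)
}
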
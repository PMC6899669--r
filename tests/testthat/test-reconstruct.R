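test_that("parallel FBP reconstructs absolute attenuation values", {
  vg <- volume_geometry(c(128, 128))
  g <- scan_geometry("parallel2d", vg, detector_geometry(183), n_views = 180)
  ph <- shepp_logan(vg)
  sino <- forward_project(ph, g)
  rec <- fbp(sino)
  expect_lt(rel_rmse(rec$values, ph$values), 0.05)
  # linearity of the whole pipeline
  rec3 <- fbp(projection_stack(3 * sino$values, g))
  expect_equal(rec3$values, 3 * rec$values, tolerance = 1e-12)
  # zero sinogram reconstructs a zero volume
  expect_equal(fbp(projection_stack(numeric(180 * 183), g))$values,
               array(0, c(128, 128)))
})

test_that("more views never hurt the parallel reconstruction", {
  vg <- volume_geometry(c(128, 128))
  ph <- shepp_logan(vg)
  rmse <- vapply(c(90, 180), function(nv) {
    g <- scan_geometry("parallel2d", vg, detector_geometry(183), n_views = nv)
    rel_rmse(fbp(forward_project(ph, g))$values, ph$values)
  }, numeric(1))
  expect_lte(rmse[2], rmse[1])
})

test_that("fan short-scan FBP with Parker weighting reconstructs the slice", {
  g <- short_scan_fan(n = 128, nd = 383, n_views = 180)
  ph <- shepp_logan(g$volume)
  rec <- fbp(forward_project(ph, g))
  expect_lt(rel_rmse(rec$values, ph$values), 0.07)
  # a plain full-range fan scan (neither short nor 2*pi) is rejected
  expect_error(fbp(forward_project(ph, tiny_fan(128, 383, 32, 250, 500))),
               "short")
})

test_that("FDK central slice agrees with the 2D fan reconstruction", {
  vg3 <- volume_geometry(c(33, 33, 33), 3)
  sid <- 400; sdd <- 800
  det3 <- detector_geometry(c(81, 81), 3)
  probe <- scan_geometry("cone3d", vg3, det3, 2, sid = sid, sdd = sdd)
  g3 <- scan_geometry("cone3d", vg3, det3, 96,
                      angular_range = short_scan_range(probe),
                      sid = sid, sdd = sdd)
  ph3 <- rasterize(zsym_primitives_3d(), vg3, 2)
  rec3 <- fbp(forward_project(ph3, g3))
  vg2 <- volume_geometry(c(33, 33), 3)
  g2 <- scan_geometry("fan2d", vg2, detector_geometry(81, 3), 96,
                      angular_range = short_scan_range(probe),
                      sid = sid, sdd = sdd)
  slice <- volume_grid(ph3$values[, , 17], vg2)
  rec2 <- fbp(forward_project(slice, g2))
  disc <- sqrt(mean((rec3$values[, , 17] - rec2$values)^2)) /
    sqrt(mean(rec2$values^2))
  expect_lt(disc, 0.02)
})

test_that("smoothed TV vanishes on constants and measures step perimeters", {
  cv <- tv_value_and_gradient(array(3.3, c(6, 7)), 1e-6)
  expect_equal(cv$value, 0)
  expect_equal(cv$gradient, array(0, c(6, 7)))
  # an indicator step of height 1: TV tends to the edge length
  st <- array(0, c(32, 32)); st[1:16, ] <- 1
  expect_equal(tv_value_and_gradient(st, 1e-8)$value, 32, tolerance = 1e-6)
  expect_error(tv_value_and_gradient(st, 0), "epsilon")
})

test_that("the TV gradient matches finite differences", {
  set.seed(7)
  x <- array(stats::rnorm(8 * 9), c(8, 9))
  eps <- 1e-2
  an <- tv_value_and_gradient(x, eps)$gradient
  h <- 1e-6
  idx <- sample(length(x), 24)
  num <- vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (tv_value_and_gradient(xp, eps)$value -
       tv_value_and_gradient(xm, eps)$value) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num - as.numeric(an)[idx]) / pmax(abs(num), 1e-8)), 1e-5)
})

test_that("unregularized descent solves the scalar problem exactly", {
  vg1 <- volume_geometry(c(1, 1))
  g1 <- scan_geometry("parallel2d", vg1, detector_geometry(1), n_views = 1)
  a <- explicit_system_matrix(g1)[1, 1]
  p_star <- 2.5
  res <- iterative_tv(projection_stack(p_star, g1), g1,
                      iterative_config(0, step_size = 0.4, iterations = 80))
  expect_equal(as.numeric(res$volume$values), p_star / a, tolerance = 1e-6)
})

test_that("the objective trace is non-increasing under backtracking", {
  g <- tiny_parallel(16, 23, 12)
  ph <- shepp_logan(g$volume)
  sino <- forward_project(ph, g)
  # deliberately too-large step: backtracking must still give descent
  res <- iterative_tv(sino, g,
                      iterative_config(0.5, step_size = 1, iterations = 25,
                                       tv_epsilon = 1e-3))
  expect_true(all(diff(res$trace$objective) <= 1e-9))
  expect_true(all(c("data_term", "tv_term", "step") %in% names(res$trace)))
})

test_that("descent shrinks the residual by an order of magnitude", {
  g <- tiny_parallel(16, 23, 12)
  ph <- shepp_logan(g$volume)
  sino <- forward_project(ph, g)
  res <- iterative_tv(sino, g,
                      iterative_config(0, step_size = 5e-3, iterations = 60))
  ratio <- sqrt(res$trace$data_term[1] /
                  utils::tail(res$trace$data_term, 1))
  expect_gt(ratio, 10)
})

test_that("TV regularization beats FBP under sparse sampling", {
  vg <- volume_geometry(c(64, 64))
  g <- scan_geometry("parallel2d", vg, detector_geometry(95), n_views = 24)
  ph <- shepp_logan(vg)
  sino <- forward_project(ph, g)
  rmse_fbp <- rel_rmse(fbp(sino)$values, ph$values)
  res <- iterative_tv(sino, g,
                      iterative_config(lambda_tv = 2, step_size = 5e-4,
                                       iterations = 60, tv_epsilon = 1e-3,
                                       init = "fbp"))
  expect_lt(rel_rmse(res$volume$values, ph$values), rmse_fbp)
})
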
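test_that("rasterization is additive and area-accurate", {
  vg <- volume_geometry(c(64, 64))
  expect_equal(rasterize(list(), vg)$values, array(0, c(64, 64)))
  # a disk covering the whole grid fills every voxel
  big <- ellipse_primitive(c(0, 0), c(200, 200))
  expect_equal(rasterize(list(big), vg, 2)$values, array(1, c(64, 64)))
  # disk radius 10 mm on 1 mm voxels: total mass within 1% of pi * 100
  disk <- ellipse_primitive(c(0, 0), c(10, 10))
  v4 <- rasterize(list(disk), vg, 4)
  expect_lt(abs(sum(v4$values) * prod(vg$spacing) - pi * 100) / (pi * 100),
            0.01)
  # doubling supersampling reduces the area error
  err <- vapply(c(2, 4, 8), function(ss)
    abs(sum(rasterize(list(disk), vg, ss)$values) - pi * 100), numeric(1))
  expect_true(all(diff(err) < 0))
  # overlapping primitives sum
  two <- rasterize(list(disk, disk), vg, 2)
  expect_equal(two$values, 2 * rasterize(list(disk), vg, 2)$values)
  # boxes are axis-aligned half-width sets
  bx <- rasterize(list(box_primitive(c(0, 0), c(5, 3), 2)), vg, 1)
  expect_equal(sum(bx$values), 2 * 10 * 6)
})

test_that("Shepp-Logan matches the published parameter table pointwise", {
  vg <- volume_geometry(c(129, 129), spacing = 2 / 129)  # [-1,1] FOV, odd: center voxel at 0
  for (variant in c("modified", "standard")) {
    ph <- shepp_logan(vg, variant = variant, supersampling = 1)
    # membership oracle: value at a probe point is the sum of the values of
    # the ellipses containing it
    prims <- shepp_logan_primitives(1, 2, variant)
    probe_value <- function(p) {
      sum(vapply(prims, function(e) {
        q <- p - e$center
        r <- c(cos(e$rotation) * q[1] + sin(e$rotation) * q[2],
               -sin(e$rotation) * q[1] + cos(e$rotation) * q[2])
        if (sum((r / e$semi_axes)^2) <= 1) e$value else 0
      }, numeric(1)))
    }
    center <- (129 + 1) / 2
    expect_equal(ph$values[center, center], probe_value(c(0, 0)))
    # a few off-center voxel centers
    for (idx in list(c(65, 90), c(80, 65), c(65, 30), c(40, 60))) {
      p <- vg$origin + (idx - 1) * vg$spacing
      expect_equal(ph$values[idx[1], idx[2]], probe_value(p),
                   info = paste(variant, paste(idx, collapse = ",")))
    }
  }
})

test_that("Shepp-Logan is zero outside the skull and within the value range", {
  vg <- volume_geometry(c(96, 96), spacing = 2.2 / 96)
  ph <- shepp_logan(vg, supersampling = 2)
  # voxels whose center is clearly outside the outer ellipse are exactly 0
  he <- vg$shape * vg$spacing / 2
  xs <- vg$origin[1] + (seq_len(96) - 1) * vg$spacing[1]
  out <- outer(xs, xs, function(x, y)
    (x / (0.69 * he[1]))^2 + (y / (0.92 * he[2]))^2 > 1.1)
  expect_true(all(ph$values[out] == 0))
  expect_gte(min(ph$values), -1e-12)     # additive rounding only
  expect_lte(max(ph$values), 1)
  ph_std <- shepp_logan(vg, variant = "standard", supersampling = 2)
  expect_gte(min(ph_std$values), -1e-12)
  expect_lte(max(ph_std$values), 2)
})

test_that("the x-symmetric ellipse subset rasterizes mirror-symmetrically", {
  vg <- volume_geometry(c(64, 64), spacing = 2 / 64)
  prims <- shepp_logan_primitives(1, 2, "modified")
  sym <- prims[c(1, 2, 5, 6, 7, 9)]      # ellipses centered on the y axis
  v <- rasterize(sym, vg, 4)$values
  mirrored <- v[64:1, ]
  expect_lt(max(abs(v - mirrored)), 1e-12)
})

test_that("3D Shepp-Logan extends the 2D table with ellipsoids", {
  vg3 <- volume_geometry(c(32, 32, 32), spacing = 2 / 32)
  ph3 <- shepp_logan(vg3, supersampling = 1)
  expect_equal(dim(ph3$values), c(32, 32, 32))
  expect_gte(min(ph3$values), -1e-12)
  # far z slices lie outside the outer ellipsoid (c = 0.81)
  expect_equal(max(abs(ph3$values[, , 1])), 0)
  # the central z slice carries the familiar 2D structure: nonzero interior
  expect_gt(max(ph3$values[, , 16]), 0.9)
})

test_that("analytic sinogram equals the chord length of a disk", {
  g <- scan_geometry("parallel2d", volume_geometry(c(32, 32)),
                     detector_geometry(41), n_views = 12)
  r <- 13.5
  sino <- analytic_sinogram(list(ellipse_primitive(c(0, 0), c(r, r))), g)
  s <- detector_coords(g$detector)
  chord <- ifelse(abs(s) < r, 2 * sqrt(pmax(r^2 - s^2, 0)), 0)
  for (v in seq_len(g$n_views))
    expect_equal(sino$values[v, ], chord, tolerance = 1e-14)
  # rotational symmetry: all rows identical
  expect_equal(max(apply(sino$values, 2, function(cc) diff(range(cc)))), 0)
})

test_that("analytic sinogram conserves mass per view", {
  g <- scan_geometry("parallel2d", volume_geometry(c(32, 32)),
                     detector_geometry(1), n_views = 7)
  e <- ellipse_primitive(c(4, -7), c(11, 6), rotation = 0.7, value = 1.3)
  # Gauss-Legendre in the substituted variable s = c_u + W sin(phi), where
  # the integrand becomes smooth; evaluate the oracle at the nodes
  gl_nodes <- function(n) {             # Golub-Welsch
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    ev <- eigen(diag(0, n) + rbind(cbind(0, diag(b)), 0) +
                cbind(rbind(0, diag(b)), 0), symmetric = TRUE)
    list(x = rev(ev$values), w = rev(2 * ev$vectors[1, ]^2))
  }
  gl <- gl_nodes(24)
  for (v in seq_len(g$n_views)) {
    th <- g$angles[v]
    u <- c(cos(th), sin(th))
    W <- sqrt((e$semi_axes[1] * cos(th - e$rotation))^2 +
              (e$semi_axes[2] * sin(th - e$rotation))^2)
    cu <- sum(e$center * u)
    phi <- pi / 2 * gl$x                 # in [-pi/2, pi/2]
    svals <- cu + W * sin(phi)
    pvals <- vapply(svals, function(sv) {
      gs <- scan_geometry("parallel2d", g$volume,
                          detector_geometry(1, 1, offset = sv),
                          n_views = g$n_views, angular_range = g$angular_range)
      analytic_sinogram(list(e), gs)$values[v, 1]
    }, numeric(1))
    # ds = W cos(phi) dphi with dphi = (pi/2) dx: the integrand is smooth
    mass <- (pi / 2) * W * sum(gl$w * pvals * cos(phi))
    area <- pi * prod(e$semi_axes) * e$value
    expect_lt(abs(mass - area) / area, 1e-10)
  }
  expect_error(analytic_sinogram(list(e), tiny_fan()), "parallel")
})
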
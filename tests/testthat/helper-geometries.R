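# small geometries and fixtures shared across tests; everything is built
# in code so the suite needs no data files

tiny_parallel <- function(n = 16, nd = 23, n_views = 24) {
  scan_geometry("parallel2d", volume_geometry(c(n, n)),
                detector_geometry(nd), n_views = n_views)
}

tiny_fan <- function(n = 16, nd = 31, n_views = 24, sid = 50, sdd = 100) {
  scan_geometry("fan2d", volume_geometry(c(n, n)), detector_geometry(nd),
                n_views = n_views, sid = sid, sdd = sdd)
}

tiny_cone <- function(n = 8, nd = 12, n_views = 10, sid = 30, sdd = 60) {
  scan_geometry("cone3d", volume_geometry(c(n, n, n)),
                detector_geometry(c(nd, nd)), n_views = n_views,
                sid = sid, sdd = sdd)
}

short_scan_fan <- function(n = 64, nd = 191, n_views = 90,
                           sid = 250, sdd = 500) {
  vol <- volume_geometry(c(n, n))
  det <- detector_geometry(nd)
  probe <- scan_geometry("fan2d", vol, det, n_views = 2, sid = sid, sdd = sdd)
  scan_geometry("fan2d", vol, det, n_views = n_views,
                angular_range = short_scan_range(probe), sid = sid, sdd = sdd)
}

rel_rmse <- function(a, b) sqrt(mean((a - b)^2)) / diff(range(b))

# z-symmetric three-ellipsoid phantom used for cone/fan consistency checks
zsym_primitives_3d <- function() {
  list(ellipse_primitive(c(0, 0, 0), c(50, 40, 45), 0, 1),
       ellipse_primitive(c(15, 5, 0), c(15, 10, 20), 0.3, 0.5),
       ellipse_primitive(c(-20, -10, 0), c(10, 18, 25), -0.5, -0.4))
}

zsym_primitives_2d <- function() {
  lapply(zsym_primitives_3d(), function(p)
    ellipse_primitive(p$center[1:2], p$semi_axes[1:2], p$rotation, p$value))
}
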
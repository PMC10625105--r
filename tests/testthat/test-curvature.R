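test_that("circumradius curvature is exact on hand geometries", {
  expect_equal(circumradius_curvature(c(0, 0), c(1, 0), c(2, 0)), 0)
  # circumcentre (1, 0), radius 1, bulging up
  expect_equal(circumradius_curvature(c(0, 0), c(1, 1), c(2, 0)), 1)
  expect_equal(circumradius_curvature(c(0, 0), c(1, -1), c(2, 0)), -1)
  set.seed(7)
  for (i in 1:50) {
    R <- runif(1, 0.5, 100)
    th <- sort(runif(3, -1.2, 1.2))
    p <- cbind(R * sin(th), R * cos(th) - R)  # bulge up, x-ordered
    expect_equal(circumradius_curvature(p[1, ], p[2, ], p[3, ]), 1 / R,
                 tolerance = 1e-9)
  }
  expect_error(circumradius_curvature(c(0, 0), c(0, 0), c(1, 1)),
               "coincident")
})

test_that("z-profile traces the midsurface and interpolates sparse bins", {
  gf <- generate_membrane_trajectory(flat_config(n_lipids = 100))
  pf <- z_profile(gf$trajectory, 1, 20)
  expect_true(all(abs(pf$z) < 1e-9))
  g <- generate_membrane_trajectory(sinusoid_config(A = 2, n_lipids = 2000))
  p <- z_profile(g$trajectory, 1, 120)
  expect_lt(max(abs(p$z - 2 * sin(2 * pi * p$x / 52))), 0.05)
  # more bins than beads: interpolation flags, no error
  gs <- generate_membrane_trajectory(flat_config(n_lipids = 10))
  ps <- z_profile(gs$trajectory, 1, 200)
  expect_true(any(ps$interpolated))
  expect_false(anyNA(ps$z))
})

test_that("slice curvatures match the analytic sinusoid and circle", {
  an <- (2 * pi / 52)^2  # A = 1
  prof <- analytic_profile(function(x) sin(2 * pi * x / 52))
  for (spec in list(c(30, 0.15), c(300, 0.01))) {
    cs <- slice_curvatures(prof, spec[1])
    crest <- which.min(abs(cs$x - 13))
    trough <- which.min(abs(cs$x - 39))
    expect_within(cs$curvature[crest], an, spec[2])
    expect_gt(cs$curvature[crest], 0)
    expect_lt(cs$curvature[trough], 0)
  }
  # constant profile: all zero
  expect_true(all(slice_curvatures(analytic_profile(function(x) 0 * x),
                                   30)$curvature == 0))
  # circle-arc profile: 1/R on interior slices
  th <- seq(0.25, 2.89, length.out = 500); R <- 30
  pr <- data.frame(x = R * cos(th) + 30, z = R * sin(th) - 20,
                   n = 1L, interpolated = FALSE)
  pr <- pr[order(pr$x), ]
  attr(pr, "Lx") <- 60
  class(pr) <- c("membrane_profile", "data.frame")
  cs <- slice_curvatures(pr, 30)
  expect_lt(max(abs(cs$curvature[5:26] - 1 / R)), 0.02 / R)
  # flipping the membrane flips every curvature sign
  profm <- analytic_profile(function(x) -sin(2 * pi * x / 52))
  expect_equal(slice_curvatures(profm, 30)$curvature,
               -slice_curvatures(prof, 30)$curvature, tolerance = 1e-12)
})

test_that("peak-to-peak spread is max minus min, rigid-shift invariant", {
  co <- array(0, c(3, 3, 1))
  co[, 3, 1] <- c(-3.1, 0, 4.0)
  tr <- manual_traj(co, c(5, 5, 20),
                    list(bead_group("p", 1:3, "phosphate")))
  expect_equal(peak_to_peak(tr)$h, 7.1)
  gf <- generate_membrane_trajectory(flat_config())
  expect_equal(peak_to_peak(gf$trajectory)$mean, 3.9)
  shifted <- gf$trajectory
  shifted$coords[, 3, ] <- shifted$coords[, 3, ] + 5
  expect_equal(peak_to_peak(shifted)$h, peak_to_peak(gf$trajectory)$h)
})

test_that("proteins pinned on a persistent buckle prefer positive curvature", {
  cfg <- generator_config(
    box = c(52, 13), n_lipids_per_leaflet = 600, n_proteins = 2,
    undulation_modes = data.frame(m = 1, amplitude = 3, amplitude_sd = 0,
                                  phase = 0, phase_drift = 0),
    diffusion_coefficient = 0, protein_init = cbind(c(12, 14.5), 6.5),
    thinning = list(depth = 0.7, sigma = 2.5), n_frames = 40, seed = 5)
  g <- generate_membrane_trajectory(cfg)
  cp <- curvature_preference(g$trajectory, seed = 3)
  expect_gt(cp$near$estimate, 0)
  expect_lt(cp$away$estimate, 0)
  expect_gt(cp$mean_radius_near, 0)
})

test_that("near/away labels partition the slices and flat membranes are neutral", {
  g <- generate_membrane_trajectory(flat_config(n_lipids = 400,
                                                n_proteins = 2,
                                                box = c(52, 13),
                                                n_frames = 12,
                                                lateral_jitter = 0.1))
  tr <- g$trajectory
  cs <- slice_curvatures(z_profile(tr, 1, 120), 30)
  coms <- protein_coms(tr)
  near <- vapply(cs$x, function(xj)
    any(abs((coms[, 1, 1] - xj + 26) %% 52 - 26) <= 3), logical(1))
  expect_equal(sum(near) + sum(!near), 30)
  cp <- suppressWarnings(curvature_preference(tr, seed = 2))
  expect_lt(abs(cp$near$estimate), 0.01)
  expect_lt(abs(cp$away$estimate), 0.01)
})
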
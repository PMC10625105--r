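test_that("flat membrane places leaflets at +/- d0/2", {
  g <- generate_membrane_trajectory(flat_config())
  tr <- g$trajectory
  up <- tr$groups[["phosphate_upper"]]$indices
  lo <- tr$groups[["phosphate_lower"]]$indices
  expect_true(all(abs(tr$coords[up, 3, ] - 3.9 / 2) < 1e-12))
  expect_true(all(abs(tr$coords[lo, 3, ] + 3.9 / 2) < 1e-12))
})

test_that("single-mode undulation gives the closed-form peak-to-peak spread", {
  g <- generate_membrane_trajectory(sinusoid_config(A = 2, n_lipids = 800,
                                                    jitter = 0))
  pp <- peak_to_peak(g$trajectory)
  # 2A + d0 = 7.9 nm, minus a sliver of lattice discretization at the crest
  expect_within(pp$mean, 2 * 2 + 3.9, 0.005)
})

test_that("generation is deterministic given (config, seed)", {
  cfg <- generator_preset("active", n_frames = 10, n_lipids_per_leaflet = 80)
  g1 <- generate_membrane_trajectory(cfg)
  g2 <- generate_membrane_trajectory(cfg)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  expect_identical(g1$truth$protein_xy, g2$truth$protein_xy)
  g3 <- generate_membrane_trajectory(generator_preset(
    "active", n_frames = 10, n_lipids_per_leaflet = 80, seed = 2))
  expect_false(identical(g1$trajectory$coords, g3$trajectory$coords))
})

test_that("protein shell and rotor rings stay rigid while the rotor turns", {
  cfg <- generator_preset("active", n_frames = 60, n_lipids_per_leaflet = 40,
                          rotation = list(rate = 0.47, model = "smooth",
                                          substeps = 10))
  tr <- generate_membrane_trajectory(cfg)$trajectory
  for (gname in c("protein_1", "rotor_bottom_2", "rotor_top_1")) {
    idx <- tr$groups[[gname]]$indices
    d1 <- dist(tr$coords[idx, , 1])
    for (f in c(30, 60))
      expect_lt(max(abs(dist(tr$coords[idx, , f]) - d1)), 1e-6)
  }
  # the rotor really rotates relative to the shell
  ang <- rotor_angle_series(tr, 1L)
  expect_gt(abs(ang[60] - ang[1]), 0.5)
})

test_that("bead count and group structure are stable across frames", {
  g <- generate_membrane_trajectory(flat_config(n_proteins = 2,
                                                box = c(30, 10)))
  tr <- g$trajectory
  expect_false(anyNA(tr$coords))
  roles <- vapply(tr$groups, `[[`, "", "role")
  expect_setequal(unique(roles),
                  c("phosphate", "chain-anchor", "protein",
                    "rotor-bottom-anchor", "rotor-top-anchor"))
  expect_equal(sum(lengths(lapply(tr$groups, `[[`, "indices"))),
               n_beads(tr))
})

test_that("pair-distance sampler reproduces the ideal gas and a harmonic well", {
  # flat potential: l^2 uniform on [0, L^2]
  d <- sample_pair_distances(NULL, 1e5, seed = 3, support = c(0, 10))
  ks <- suppressWarnings(ks.test(d^2, "punif", 0, 100))
  expect_gt(ks$p.value, 0.01)
  # structured potential: histogram against quadrature of the analytic density
  spec <- potential_spec(depth = 1.5, location = 6, width = 1)
  s <- sample_pair_distances(spec, 2e5, seed = 8, support = c(0, 12))
  h <- hist(s, breaks = seq(0, 12, 0.25), plot = FALSE)
  V <- pair_potential_value(spec, h$mids)
  expected <- 2 * pi * h$mids * exp(-V)
  expected <- expected / sum(expected * 0.25)
  sel <- expected * 0.25 * 2e5 > 50
  chi2 <- sum((h$counts[sel] - 2e5 * 0.25 * expected[sel])^2 /
                (2e5 * 0.25 * expected[sel]))
  expect_lt(chi2, qchisq(0.999, sum(sel) - 1))
  expect_error(sample_pair_distances(spec, 0), "n must be")
})

test_that("free diffusion keeps the pair-distance distribution at the 2*pi*l ideal gas", {
  # uniform initial placement is stationary under free diffusion, so early
  # frames of independent runs are equilibrium draws
  box <- c(26, 13)
  d <- unlist(lapply(1:120, function(s) {
    cfg <- flat_config(n_lipids = 8, n_proteins = 2, n_frames = 2,
                       box = box, seed = 1000 + s,
                       protein_init = "random", protein_radius = 0.4,
                       diffusion_coefficient = 5)
    g <- generate_membrane_trajectory(cfg)
    lateral_distance(g$truth$protein_xy[1, , 1], g$truth$protein_xy[2, , 1],
                     box)
  }))
  d <- d[d < box[2] / 2]  # restrict to the planar (non-toroidal) regime
  ks <- suppressWarnings(ks.test(d^2, "punif", 0, (box[2] / 2)^2))
  expect_gt(ks$p.value, 0.01)
})

test_that("contact series construction matches requested gaps and lengths", {
  ct <- generate_contact_series(list(c(2, 3), c(1, 1)))
  expect_identical(ct$series, c(F, F, T, T, T, F, T))
  expect_equal(ct$events$duration_frames, c(3, 1))
  expect_identical(generate_contact_series(list())$series, logical(0))
  expect_error(generate_contact_series(list(c(-1, 2))), "negative")
})

test_that("rotation series has the right trend in both step models", {
  expect_equal(generate_rotation_series(0, 0.01, 50), rep(0, 50))
  sm <- generate_rotation_series(1, 0.001, 1000, "smooth")
  expect_equal(diff(sm), rep(2 * pi / 1000, 999))
  st <- generate_rotation_series(0.47, 0.01, 1e5, "stepwise",
                                 substeps = 10, seed = 42)
  expect_within(rotation_rate(st, 0.01), 0.47, 0.02)
})
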
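test_that("leaflet assignment matches the generator ground truth", {
  gf <- generate_membrane_trajectory(flat_config(n_lipids = 80))
  lab <- assign_leaflets(gf$trajectory, 1)
  expect_equal(unname(lab[seq_len(80)]), rep("upper", 80))
  expect_equal(unname(lab[80 + seq_len(80)]), rep("lower", 80))
  # strongly buckled: labels still perfect at A = 3
  g <- generate_membrane_trajectory(sinusoid_config(A = 3, n_lipids = 600,
                                                    box = c(52, 13)))
  lab2 <- assign_leaflets(g$trajectory, 1)
  expect_equal(unname(lab2[g$truth$leaflet_upper]), rep("upper", 600))
  expect_equal(unname(lab2[g$truth$leaflet_lower]), rep("lower", 600))
})

test_that("thickness profile is flat at d0 without thinning", {
  cfg <- flat_config(n_lipids = 300, n_proteins = 1, box = c(40, 10),
                     thinning = NULL, lateral_jitter = 0.05, n_frames = 3)
  tp <- thickness_profile(generate_membrane_trajectory(cfg)$trajectory)
  expect_true(all(abs(tp$value - 3.9) < 0.02))
  # no proteins: directed to the protein-free summary
  g0 <- generate_membrane_trajectory(flat_config(n_lipids = 60))
  expect_error(thickness_profile(g0$trajectory), "mean_thickness")
  expect_equal(mean_thickness(g0$trajectory), 3.9, tolerance = 1e-9)
})

test_that("tilt correction converts the vertical cut to normal thickness", {
  # triangle-wave midsurface with |slope| = 1 (45 degrees) built by hand:
  # leaflets offset vertically by (d0/2) * sqrt(2), so the vertical P-P
  # distance is d0 * sqrt(2) and the corrected thickness is d0
  Lx <- 40; d0 <- 3.9
  x <- seq(0.05, Lx - 0.05, by = 0.1)
  tri <- ifelse(x < Lx / 2, x, Lx - x) - Lx / 4
  nb <- length(x)
  co <- array(0, c(2 * nb + 1, 3, 1))
  off <- d0 * sqrt(2) / 2
  co[seq_len(nb), , 1] <- cbind(x, 2.5, tri + off)
  co[nb + seq_len(nb), , 1] <- cbind(x, 2.5, tri - off)
  co[2 * nb + 1, , 1] <- c(10, 2.5, 0)  # token protein bead
  tr <- manual_traj(co, c(Lx, 5, 30),
                    list(bead_group("ph_u", seq_len(nb), "phosphate"),
                         bead_group("ph_l", nb + seq_len(nb), "phosphate"),
                         bead_group("prot", 2L * nb + 1L, "protein", 1L)))
  raw <- thickness_profile(tr, bin_width = 2, correction = FALSE)
  cor <- thickness_profile(tr, bin_width = 2, correction = TRUE)
  # interior bins (folds of the triangle wave excluded)
  sel <- raw$r > 3 & raw$r < 8
  expect_equal(mean(raw$value[sel]), d0 * sqrt(2), tolerance = 0.02)
  expect_equal(mean(cor$value[sel]), d0, tolerance = 0.02)
  expect_true(all(cor$value <= raw$value + 1e-9))
})

test_that("planted thinning is recovered near the protein and at far field", {
  cfg <- generator_config(box = c(52, 13), n_lipids_per_leaflet = 400,
                          n_proteins = 1, protein_init = cbind(26, 6.5),
                          diffusion_coefficient = 0,
                          thinning = list(depth = 0.7, sigma = 2.5),
                          undulation_modes = NULL, n_frames = 5, seed = 3)
  tp <- thickness_profile(generate_membrane_trajectory(cfg)$trajectory)
  expect_within(min(tp$value), 3.2, 0.05)
  expect_within(mean(tp$value[tp$r > 10]), 3.9, 0.02)
})

test_that("periodic Voronoi areas are exact on a lattice and conserve the box", {
  pts <- as.matrix(expand.grid(x = (0:9 + 0.5) * 2, y = (0:7 + 0.5) * 2.5))
  a <- voronoi_cell_areas(pts, c(20, 20))
  expect_true(all(abs(a - 5) < 1e-9))
  expect_lt(abs(sum(a) - 400) / 400, 1e-6)
  set.seed(8)
  rnd <- cbind(runif(200, 0, 20), runif(200, 0, 20))
  ar <- voronoi_cell_areas(rnd, c(20, 20))
  expect_lt(abs(sum(ar) - 400) / 400, 1e-6)
  expect_true(all(ar > 0))
  expect_error(voronoi_cell_areas(rnd[1:3, ], c(20, 20)), "at least 4")
})

test_that("area-per-chain profile sees the planted near-protein dilation", {
  mkcfg <- function(dil) generator_config(
    box = c(32, 32), n_lipids_per_leaflet = 512, n_proteins = 1,
    protein_init = cbind(16, 16), diffusion_coefficient = 0,
    lateral_jitter = 0.02, area_dilation = dil, thinning = NULL,
    n_frames = 2, seed = 9)
  prof <- function(dil) {
    ap <- area_per_chain_profile(
      generate_membrane_trajectory(mkcfg(dil))$trajectory, "upper",
      bin_width = 1)
    near <- ap$r >= 3.5 & ap$r <= 5.5
    far <- ap$r >= 10 & ap$r <= 14
    weighted.mean(ap$value[near], ap$n[near]) /
      weighted.mean(ap$value[far], ap$n[far])
  }
  contrast <- prof(list(delta = 0.01, range = 6)) - prof(NULL)
  expect_within(contrast, 0.01, 0.5)
})
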
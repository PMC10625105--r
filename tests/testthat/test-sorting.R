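test_that("sorting ratio composes intensity ratios and is scale invariant", {
  rec <- sorting_record(10, 10, 10, 10)
  expect_equal(sorting_ratio(rec), 1)
  rec2 <- sorting_record(2.2, 1, 1, 1)
  expect_equal(sorting_ratio(rec2), 2.2)
  rec3 <- sorting_record(22, 10, 10, 10)
  expect_equal(sorting_ratio(rec3), sorting_ratio(rec2))
  # swapping protein/lipid channels together with the PCFs inverts S
  recA <- sorting_record(3, 2, 5, 4, PCF1 = 1.1, PCF2 = 0.9)
  recB <- sorting_record(5, 4, 3, 2, PCF1 = 0.9, PCF2 = 1.1)
  expect_equal(sorting_ratio(recA), 1 / sorting_ratio(recB))
  expect_error(sorting_record(-1, 1, 1, 1), "positive")
})

test_that("tube radius follows the aspiration slope relation", {
  # slope -0.01, R_p = 5 um, R_V = 10 um -> 100 nm
  L_t <- seq(0, 10, 1)
  L_p <- 5 - 0.01 * L_t
  expect_equal(tube_radius_from_aspiration(L_t, L_p, 5, 10), 100)
  # R_V -> infinity limit: r_t = -slope * R_p
  expect_equal(tube_radius_from_aspiration(L_t, L_p, 5, 1e9),
               0.01 * 5 * 1000, tolerance = 1e-6)
  expect_error(tube_radius_from_aspiration(L_t, rep(5, 11), 5, 10),
               "non-negative slope")
  expect_error(tube_radius_from_aspiration(L_t, L_p, 10, 5), "R_p must be")
})

test_that("fluorescence-radius calibration recovers the factor from noisy pairs", {
  ratio <- seq(0.2, 2, length.out = 20)
  expect_equal(calibrate_radius_factor(100 * ratio, ratio), 100)
  set.seed(10)
  noisy <- 100 * ratio * exp(rnorm(20, 0, 0.05))
  expect_within(calibrate_radius_factor(noisy, ratio), 100, 0.02)
  expect_equal(radius_from_fluorescence(0.5, 100), 50)
  expect_error(calibrate_radius_factor(100, 1), ">= 2")
})

test_that("binned sorting curve recovers the e-fold curvature of the model", {
  set.seed(11)
  cshape <- 0.03
  cc <- runif(300, 0.005, 0.075)
  recs <- lapply(cc, function(ci)
    sorting_record(exp(ci / cshape) * exp(rnorm(1, 0, 0.03)), 1, 1, 1,
                   r_t = 1 / ci))
  bs <- bin_sorting_vs_curvature(recs)
  expect_true(all(diff(bs$curve$S) > 0))
  expect_within(estimate_cshape(bs$curve), cshape, 0.1)
  expect_false(is.na(bs$window_50pm20))
  # identical records: flat curve at that S
  flat <- lapply(c(40, 60), function(r)
    sorting_record(2, 1, 1, 1, r_t = r))
  bf <- bin_sorting_vs_curvature(flat)
  expect_true(all(bf$curve$S == 2))
  # records outside all bins: masked output
  far <- list(sorting_record(2, 1, 1, 1, r_t = 5))  # c = 0.2 > max edge
  expect_null(bin_sorting_vs_curvature(far)$curve)
})

test_that("wedge-angle and e-fold relations are exact inverses", {
  expect_equal(spontaneous_curvature_from_wedge(0, 3), 0)
  expect_equal(wedge_from_curvature(0, 3), 0)
  phis <- seq(1, 179, 7)
  back <- wedge_from_curvature(spontaneous_curvature_from_wedge(phis, 4), 4)
  expect_equal(back, phis, tolerance = 1e-9)
  # monotone increasing in phi at fixed R
  cps <- spontaneous_curvature_from_wedge(phis, 4)
  expect_true(all(diff(cps) > 0))
  expect_error(wedge_from_curvature(0.5, 3), "unphysical")
  # e-fold relation: c_shape * (A kappa c_P) = 1 identically, halving under
  # doubled area
  expect_equal(efold_sorting_curvature(25.6, 10, 0.03) * 25.6 * 10 * 0.03, 1)
  expect_equal(efold_sorting_curvature(50, 10, 0.03),
               efold_sorting_curvature(25, 10, 0.03) / 2)
  expect_equal(curvature_from_efold(50, 10, efold_sorting_curvature(50, 10, 0.07)),
               0.07)
  expect_error(efold_sorting_curvature(0, 10, 0.03), "positive")
})

test_that("sorting and tube-pull CSV readers validate their schemas", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(I_tube_prot = c(2, 3), I_GUV_prot = 1,
                       I_tube_lip = 1, I_GUV_lip = 1, r_t = c(50, 40)),
            f, row.names = FALSE)
  recs <- read_sorting_records(f)
  expect_length(recs, 2)
  expect_equal(sorting_ratio(recs[[1]]), 2)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_sorting_records(bad), "missing columns")
  tp <- tempfile(fileext = ".csv")
  write.csv(data.frame(L_t = 0:5, L_p = 5 - 0.02 * (0:5), R_p = 4, R_V = 12),
            tp, row.names = FALSE)
  rec <- read_tubepull_record(tp)
  expect_equal(tube_radius_from_aspiration(rec$L_t, rec$L_p, rec$R_p,
                                           rec$R_V),
               0.02 * 4 / (1 - 4 / 12) * 1000)
})
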
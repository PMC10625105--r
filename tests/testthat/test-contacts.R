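test_that("distance series metrics behave geometrically", {
  cfg <- flat_config(n_lipids = 30, n_proteins = 2, box = c(30, 13),
                     protein_init = cbind(c(10, 16), 6.5),
                     diffusion_coefficient = 0, n_frames = 2)
  tr <- generate_membrane_trajectory(cfg)$trajectory
  ds <- distance_series(tr)
  expect_equal(unique(round(ds$com, 6)), 6)
  # shells of radius 3 facing each other: minimum bead separation well below
  # the centre distance (ring discretisation keeps it slightly above 0)
  expect_lt(max(ds$min_bead), 1)
  expect_true(all(ds$min_bead <= ds$com + 1e-9))
  # single protein: empty series
  tr1 <- generate_membrane_trajectory(flat_config(n_lipids = 20,
                                                  n_proteins = 1,
                                                  box = c(20, 10)))$trajectory
  expect_equal(nrow(distance_series(tr1)), 0L)
})

test_that("minimum-bead distance equals an explicit brute-force scan", {
  cfg <- flat_config(n_lipids = 20, n_proteins = 3, box = c(30, 12),
                     protein_init = "random", diffusion_coefficient = 3,
                     n_frames = 4, seed = 9)
  tr <- generate_membrane_trajectory(cfg)$trajectory
  ds <- distance_series(tr)
  prot <- groups_by_role(tr, "protein")
  for (row in sample(nrow(ds), 10)) {
    r <- ds[row, ]
    ai <- prot[[r$pair_i]]$indices; aj <- prot[[r$pair_j]]$indices
    best <- Inf
    for (i in ai) for (j in aj)
      best <- min(best, lateral_distance(tr$coords[i, , r$frame],
                                         tr$coords[j, , r$frame], tr$box))
    expect_equal(r$min_bead, best, tolerance = 1e-12)
  }
})

test_that("cluster fraction counts below-threshold observations", {
  mk <- function(d) {
    out <- data.frame(frame = seq_along(d), pair_i = 1L, pair_j = 2L,
                      min_bead = d, com = d)
    attr(out, "dt") <- 1
    class(out) <- c("distance_series", "data.frame")
    out
  }
  expect_equal(cluster_fraction(mk(rep(10, 20)))$fraction, 0)
  expect_equal(cluster_fraction(mk(rep(1, 20)))$fraction, 1)
  expect_equal(cluster_fraction(mk(rep(c(1, 10), 10)))$fraction, 0.5)
  # non-decreasing in threshold
  set.seed(3)
  d <- mk(runif(200, 0, 5))
  fr <- vapply(c(0.5, 1, 2, 4),
               function(th) cluster_fraction(d, th)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("contact events recover planted runs exactly and tile the series", {
  ct <- generate_contact_series(list(c(2, 3), c(1, 1)))
  ev <- contact_events(series_to_distances(ct$series))
  expect_equal(ev$duration_frames, c(3, 1))
  expect_equal(ev$start, ct$events$start)
  expect_true(ev$truncated[2])  # run ends at the trajectory edge
  # nothing below threshold
  expect_equal(nrow(contact_events(series_to_distances(rep(FALSE, 10)))), 0L)
  # randomized plants: exact recovery at debounce 0
  set.seed(14)
  for (i in 1:60) {
    n <- sample(1:6, 1)
    plants <- lapply(seq_len(n), function(k) c(sample(1:5, 1), sample(1:7, 1)))
    ct <- generate_contact_series(plants)
    ser <- c(ct$series, FALSE)  # guard frame: no truncation at the end
    ev <- contact_events(series_to_distances(ser))
    expect_equal(ev$duration_frames, ct$events$duration_frames)
    expect_equal(sum(ev$duration_frames), sum(ser))
  }
  # debounce merges runs across short gaps
  ser <- c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  ev0 <- contact_events(series_to_distances(ser), debounce = 0)
  ev1 <- contact_events(series_to_distances(ser), debounce = 1)
  expect_equal(nrow(ev0), 3L)
  expect_equal(nrow(ev1), 2L)
  expect_equal(ev1$duration_frames[1], 4L)
})

test_that("self-weighted lifetime is sum tau^2 over sum tau", {
  expect_equal(weighted_lifetime(5), 5)
  expect_equal(weighted_lifetime(c(1, 3)), 2.5)
  expect_equal(weighted_lifetime(rep(4, 7)), 4)
  set.seed(2)
  tau <- rexp(50)
  expect_gte(weighted_lifetime(tau), mean(tau))
  expect_error(weighted_lifetime(numeric(0)), "no events")
})

test_that("attractive rotating proteins cluster more than passive ones", {
  run <- function(pot, seed) {
    cfg <- generator_config(box = c(26, 13), n_lipids_per_leaflet = 12,
                            n_proteins = 2, pair_potential = pot,
                            protein_init = "spread",
                            diffusion_coefficient = 5, thinning = NULL,
                            n_frames = 1500, dt = 0.01, seed = seed)
    distance_series(generate_membrane_trajectory(cfg)$trajectory)
  }
  active <- cluster_fraction(run(potential_spec(depth = 1.5), 31))
  passive <- cluster_fraction(run(NULL, 32))
  expect_gt(active$fraction, passive$fraction)
  expect_gt(active$ci[1], passive$ci[2])  # non-overlapping bootstrap CIs
})
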
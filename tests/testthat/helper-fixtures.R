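# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the default run stays fast.

# minimal flat bilayer with optional proteins
flat_config <- function(n_lipids = 60, n_proteins = 0, n_frames = 2,
                        box = c(20, 8), seed = 1, lateral_jitter = 0, ...) {
  generator_config(box = box, n_lipids_per_leaflet = n_lipids,
                   n_proteins = n_proteins, lateral_jitter = lateral_jitter,
                   n_frames = n_frames, seed = seed, ...)
}

# single persistent undulation mode, no proteins
sinusoid_config <- function(A = 2, m = 1, n_lipids = 800, n_frames = 1,
                            box = c(52, 8), jitter = 0.05, seed = 1, ...) {
  generator_config(box = box, n_lipids_per_leaflet = n_lipids,
                   n_proteins = 0,
                   undulation_modes = data.frame(m = m, amplitude = A,
                                                 amplitude_sd = 0, phase = 0,
                                                 phase_drift = 0),
                   lateral_jitter = jitter, n_frames = n_frames,
                   seed = seed, ...)
}

# analytic membrane profile object (bypasses bead binning)
analytic_profile <- function(fz, Lx = 52, n_bins = 3000) {
  x <- (seq_len(n_bins) - 0.5) * Lx / n_bins
  out <- data.frame(x = x, z = fz(x), n = 10L, interpolated = FALSE)
  attr(out, "Lx") <- Lx
  class(out) <- c("membrane_profile", "data.frame")
  out
}

# hand-built trajectory from an n_beads x 3 x n_frames array
manual_traj <- function(coords, box, groups = list(), dt = 1) {
  trajectory(coords, box, (seq_len(dim(coords)[3]) - 1) * dt, groups)
}

expect_within <- function(value, target, tol_rel) {
  expect_lt(abs(value - target), tol_rel * abs(target))
}
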
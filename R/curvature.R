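# Membrane profile extraction and circumradius curvature along the long box
# axis. The bilayer is quasi-planar with a large aspect ratio, so its shape
# is summarised by the mean phosphate z-profile along x; local curvature is
# the reciprocal circumradius of triangles formed by consecutive profile
# points, signed so that bulging toward +z is positive.

phosphate_indices <- function(traj) {
  ph <- groups_by_role(traj, "phosphate")
  if (length(ph) == 0L) stop("trajectory has no phosphate groups")
  sort(unique(unlist(lapply(ph, `[[`, "indices"))))
}

# Coarse pooled midplane reference: wide bins guarantee both leaflets are
# represented, so the pooled mean tracks the midsurface well enough to
# split beads into leaflets even on a strongly buckled membrane.
midplane_reference <- function(x, z, Lx, target_width = 3.5) {
  nb <- max(3L, floor(Lx / target_width))
  bin <- pmin(nb, floor((x %% Lx) / Lx * nb) + 1L)
  zm <- rep(NA_real_, nb)
  agg <- tapply(z, bin, mean)
  zm[as.integer(names(agg))] <- agg
  occ <- which(!is.na(zm))
  centers <- (seq_len(nb) - 0.5) * Lx / nb
  xo <- c(centers[occ] - Lx, centers[occ], centers[occ] + Lx)
  stats::approx(xo, rep(zm[occ], 3), xout = x %% Lx, ties = "ordered")$y
}

binned_leaflet_means <- function(x, z, upper, Lx, n_bins) {
  bin <- pmin(n_bins, floor((x %% Lx) / Lx * n_bins) + 1L)
  one <- function(sel) {
    n <- tabulate(bin[sel], n_bins)
    s <- rep(NA_real_, n_bins)
    agg <- tapply(z[sel], bin[sel], mean)
    s[as.integer(names(agg))] <- agg
    list(z = s, n = n)
  }
  list(up = one(upper), lo = one(!upper), bin = bin)
}

#' Phosphate z-profile along x for one frame
#'
#' Bins the (wrapped) x-coordinates of all phosphate beads into `n_bins`
#' bins partitioning `[0, Lx)`. Both leaflets enter the profile: the bin
#' value is the balanced mean of the per-leaflet mean z values, which
#' coincides with the pooled phosphate mean when leaflet counts are equal
#' and is robust to count imbalance when they are not (for a flat bilayer
#' the profile is 0; for a buckled one it traces the midsurface). Bins
#' missing one or both leaflets are filled by periodic linear
#' interpolation and flagged.
#'
#' @param traj A [trajectory()].
#' @param frame Frame index.
#' @param n_bins Number of x-bins (>= 3).
#' @return A `membrane_profile`: data frame with columns `x` (bin centres),
#'   `z` (profile height, nm), `n` (bead count), `interpolated`; the box
#'   length is attached as attribute `Lx`.
#' @export
z_profile <- function(traj, frame = 1L, n_bins = 120L) {
  if (n_bins < 3L) stop("z_profile: n_bins must be >= 3")
  idx <- phosphate_indices(traj)
  co <- frame_coords(traj, frame)
  Lx <- traj$box[1]
  x <- co[idx, 1] %% Lx
  z <- co[idx, 3]
  mid <- midplane_reference(x, z, Lx)
  upper <- z - mid >= 0
  bm <- binned_leaflet_means(x, z, upper, Lx, n_bins)
  n <- bm$up$n + bm$lo$n
  if (all(n == 0L)) stop("z_profile: all bins empty")
  both <- bm$up$n > 0 & bm$lo$n > 0
  zm <- rep(NA_real_, n_bins)
  zm[both] <- (bm$up$z[both] + bm$lo$z[both]) / 2
  if (!any(both)) {
    # single-leaflet system: fall back to the pooled mean
    pooled <- bm$up$n > 0 | bm$lo$n > 0
    zm[pooled] <- ifelse(bm$up$n[pooled] > 0, bm$up$z[pooled],
                         bm$lo$z[pooled])
    both <- pooled
  }
  interp <- !both
  if (any(interp)) {
    occ <- which(!interp)
    centers <- (seq_len(n_bins) - 0.5) * Lx / n_bins
    xo3 <- c(centers[occ] - Lx, centers[occ], centers[occ] + Lx)
    zm[interp] <- stats::approx(xo3, rep(zm[occ], 3),
                                xout = centers[interp], ties = "ordered")$y
  }
  out <- data.frame(x = (seq_len(n_bins) - 0.5) * Lx / n_bins,
                    z = zm, n = n, interpolated = interp)
  attr(out, "Lx") <- Lx
  class(out) <- c("membrane_profile", "data.frame")
  out
}

#' Signed circumradius curvature of three profile points
#'
#' The curvature magnitude is the reciprocal of the circumradius of the
#' circle through three (x, z) points; the sign is positive when the
#' membrane bulges toward +z (the circumcentre lies below the arc).
#' Collinear points give curvature 0.
#'
#' @param p1,p2,p3 Numeric length-2 vectors `(x, z)`; must be distinct.
#' @return Signed curvature in 1/nm.
#' @export
circumradius_curvature <- function(p1, p2, p3) {
  pts <- rbind(p1, p2, p3)
  if (any(duplicated(round(pts, 12))))
    stop("circumradius_curvature: coincident points")
  a <- sqrt(sum((p2 - p1)^2)); b <- sqrt(sum((p3 - p2)^2))
  cc <- sqrt(sum((p3 - p1)^2))
  cross <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
    (p2[2] - p1[2]) * (p3[1] - p1[1])
  if (abs(cross) < 1e-14 * a * b) return(0)
  # |curvature| = 2|cross| / (a b c); bulge toward +z when the middle point
  # lies above the p1-p3 chord, i.e. cross < 0 for x-ordered points
  -sign(cross) * 2 * abs(cross) / (a * b * cc)
}

profile_interp <- function(profile, xout) {
  Lx <- attr(profile, "Lx")
  xo <- c(profile$x - Lx, profile$x, profile$x + Lx)
  zo <- rep(profile$z, 3)
  stats::approx(xo, zo, xout = xout %% Lx, ties = "ordered")$y
}

#' Slice a membrane profile and compute per-slice curvatures
#'
#' Cuts the box into `n_slices` fragments of equal width; the intersection
#' points of the slice boundaries with the (interpolated) profile are the
#' vertices of triangles from which one signed circumradius curvature per
#' boundary is computed, with periodic wrapping supplying the end triplets.
#'
#' @param profile A [z_profile()] result.
#' @param n_slices Number of slices (default 30).
#' @return A `curvature_slices` data frame with columns `x` (boundary
#'   positions) and `curvature` (1/nm).
#' @export
slice_curvatures <- function(profile, n_slices = 30L) {
  Lx <- attr(profile, "Lx")
  if (length(unique(profile$x)) < 3L)
    stop("slice_curvatures: degenerate profile")
  xb <- (seq_len(n_slices) - 1L) * Lx / n_slices
  zb <- profile_interp(profile, xb)
  dx <- Lx / n_slices
  curv <- vapply(seq_len(n_slices), function(j) {
    jm <- if (j == 1L) n_slices else j - 1L
    jp <- if (j == n_slices) 1L else j + 1L
    circumradius_curvature(c(xb[j] - dx, zb[jm]), c(xb[j], zb[j]),
                           c(xb[j] + dx, zb[jp]))
  }, numeric(1))
  out <- data.frame(x = xb, curvature = curv)
  attr(out, "Lx") <- Lx
  class(out) <- c("curvature_slices", "data.frame")
  out
}

#' Curvature preference of membrane regions near versus away from proteins
#'
#' Per frame, each slice is labelled *near* if any protein centre of mass
#' lies within `vicinity_cutoff` (lateral x-distance, periodic) of the
#' slice position, else *away*. The per-frame mean slice curvatures of the
#' two label classes form time series whose means and 95% confidence
#' intervals are estimated with the autocorrelation-aware
#' [subsampled_bootstrap()].
#'
#' @param traj A [trajectory()] with protein groups.
#' @param vicinity_cutoff Lateral cutoff (nm); default 3, the protein
#'   radius.
#' @param n_slices Number of curvature slices (default 30).
#' @param n_bins Profile bins per frame.
#' @param seed Seed passed to the bootstrap.
#' @return List with `near` and `away` ([subsampled_bootstrap()] results
#'   for the mean curvature), the corresponding mean radii
#'   (`1/mean curvature`, nm), and the per-frame series.
#' @export
curvature_preference <- function(traj, vicinity_cutoff = 3, n_slices = 30L,
                                 n_bins = 120L, seed = 1L) {
  coms <- protein_coms(traj)
  nf <- n_frames(traj)
  Lx <- traj$box[1]
  near_series <- away_series <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    cs <- slice_curvatures(z_profile(traj, f, n_bins), n_slices)
    px <- coms[, 1, f]
    near <- vapply(cs$x, function(xj)
      any(abs(min_image_dx(px - xj, Lx)) <= vicinity_cutoff), logical(1))
    if (any(near)) near_series[f] <- mean(cs$curvature[near])
    if (any(!near)) away_series[f] <- mean(cs$curvature[!near])
  }
  ns <- near_series[!is.na(near_series)]
  as <- away_series[!is.na(away_series)]
  if (length(ns) == 0L) stop("curvature_preference: no near slices in any frame")
  if (length(as) == 0L) stop("curvature_preference: no away slices in any frame")
  bs_or_na <- function(series, sd) {
    tryCatch(subsampled_bootstrap(series, seed = sd),
             error = function(e) {
               warning("curvature_preference: ", conditionMessage(e),
                       "; CI unavailable", call. = FALSE)
               structure(list(estimate = mean(series), ci = c(NA_real_, NA_real_),
                              n_eff = NA_integer_, I = NA_real_,
                              n_boot = 0L, seed = sd, replicates = numeric(0)),
                         class = "resample_result")
             })
  }
  near_bs <- bs_or_na(ns, seed)
  away_bs <- bs_or_na(as, seed + 1L)
  list(near = near_bs, away = away_bs,
       mean_radius_near = 1 / near_bs$estimate,
       mean_radius_away = 1 / away_bs$estimate,
       near_series = near_series, away_series = away_series)
}

#' Peak-to-peak undulation statistics
#'
#' Per frame, the spread `h = max(z) - min(z)` over all phosphate beads
#' (both leaflets pooled); the distribution of `h` summarises the
#' undulation magnitude. For a flat bilayer `h` equals the leaflet
#' separation.
#'
#' @param traj A [trajectory()] with phosphate groups.
#' @return An `undulation_stats` list with `h` (per-frame spread, nm),
#'   `mean`, and `sd`.
#' @export
peak_to_peak <- function(traj) {
  idx <- phosphate_indices(traj)
  nf <- n_frames(traj)
  h <- vapply(seq_len(nf), function(f) {
    z <- traj$coords[idx, 3, f]
    max(z) - min(z)
  }, numeric(1))
  structure(list(h = h, mean = mean(h), sd = stats::sd(h)),
            class = "undulation_stats")
}

#' @export
print.undulation_stats <- function(x, ...) {
  cat(sprintf("peak-to-peak spread: <h> = %.3f nm, SD = %.3f nm (%d frames)\n",
              x$mean, x$sd, length(x$h)))
  invisible(x)
}
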
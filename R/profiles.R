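# Bilayer thickness and area-per-acyl-chain as functions of the distance to
# the nearest protein: the observables of hydrophobic mismatch. Thickness is
# the inter-leaflet phosphate (P-P) z-distance with a cosine correction for
# the local surface tilt; chain areas come from a periodic Voronoi
# tessellation over chain-anchor beads with protein beads as extra seeds.

#' Assign phosphate beads to leaflets
#'
#' Buckling breaks any global z-rule, so each phosphate is labelled upper
#' or lower by the sign of `z - local midplane`, where the local midplane
#' is the x-binned mean z of all phosphates.
#'
#' @param traj A [trajectory()].
#' @param frame Frame index.
#' @return Character vector (`"upper"`/`"lower"`) per phosphate bead, with
#'   the phosphate bead indices as names and an `ambiguous` attribute
#'   flagging beads within 0.2 nm of the midplane.
#' @export
assign_leaflets <- function(traj, frame = 1L) {
  idx <- phosphate_indices(traj)
  co <- frame_coords(traj, frame)
  Lx <- traj$box[1]
  zmid <- midplane_reference(co[idx, 1] %% Lx, co[idx, 3], Lx)
  dz <- co[idx, 3] - zmid
  lab <- ifelse(dz >= 0, "upper", "lower")
  names(lab) <- idx
  attr(lab, "ambiguous") <- abs(dz) < 0.2
  if (length(unique(lab)) == 1L)
    warning("assign_leaflets: only one leaflet present")
  lab
}

#' Mean bilayer thickness, protein-free summary
#'
#' Mean inter-leaflet P-P distance over frames, without any reference to
#' proteins.
#'
#' @param traj A [trajectory()].
#' @param frames Frame indices (default all).
#' @return Mean thickness (nm).
#' @export
mean_thickness <- function(traj, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  idx <- phosphate_indices(traj)
  mean(vapply(frames, function(f) {
    lab <- assign_leaflets(traj, f)
    z <- frame_coords(traj, f)[idx, 3]
    mean(z[lab == "upper"]) - mean(z[lab == "lower"])
  }, numeric(1)))
}

# per-frame leaflet z means on an x-grid plus local slope of the midplane;
# bins missing a leaflet are filled by periodic linear interpolation of that
# leaflet's profile, so the grid is fully defined even when the two
# leaflets' beads interleave along x
leaflet_grid <- function(traj, f, wx) {
  Lx <- traj$box[1]
  nbx <- max(8L, round(Lx / wx))
  idx <- phosphate_indices(traj)
  lab <- assign_leaflets(traj, f)
  co <- frame_coords(traj, f)
  x <- co[idx, 1] %% Lx; z <- co[idx, 3]
  bin <- pmin(nbx, floor(x / Lx * nbx) + 1L)
  centers <- (seq_len(nbx) - 0.5) * Lx / nbx
  mz <- function(sel) {
    n <- tabulate(bin[sel], nbx)
    s <- rep(NA_real_, nbx)
    agg <- tapply(z[sel], bin[sel], mean)
    s[as.integer(names(agg))] <- agg
    miss <- is.na(s)
    if (any(miss) && any(!miss)) {
      occ <- which(!miss)
      xo <- c(centers[occ] - Lx, centers[occ], centers[occ] + Lx)
      s[miss] <- stats::approx(xo, rep(s[occ], 3), xout = centers[miss],
                               ties = "ordered")$y
    }
    if (all(is.na(s))) stop("leaflet_grid: one leaflet has no beads")
    list(z = s, n = n)
  }
  up <- mz(lab == "upper"); lo <- mz(lab == "lower")
  zm <- (up$z + lo$z) / 2
  # periodic central-difference slope of the midplane
  zl <- c(zm[nbx], zm[-nbx]); zr <- c(zm[-1], zm[1])
  slope <- (zr - zl) / (2 * Lx / nbx)
  list(x = (seq_len(nbx) - 0.5) * Lx / nbx, zu = up$z, zl = lo$z,
       nu = up$n, nl = lo$n, slope = slope, nbx = nbx)
}

#' Bilayer thickness versus distance to the nearest protein
#'
#' Per frame and x-position, the thickness is the z-difference between the
#' upper and lower leaflet mean phosphate levels; with `correction = TRUE`
#' (default) it is multiplied by `cos(theta_loc)`, where `theta_loc =
#' atan(local midplane slope)`, to convert the vertical cut into the true
#' normal thickness. Each measurement is binned by the lateral
#' minimum-image x-distance from the nearest protein centre of mass and
#' averaged over frames.
#'
#' @param traj A [trajectory()] with phosphate and protein groups.
#' @param bin_width Radial bin width (nm), default 0.5.
#' @param correction Apply the curvature (tilt-cosine) correction.
#' @param x_bin_width Width of the x-grid on which leaflet levels are
#'   measured (nm).
#' @param frames Frame indices (default all).
#' @return A `radial_profile` data frame with `r` (bin centres, nm),
#'   `value` (thickness, nm), `n` (measurement count); zero-count bins are
#'   dropped.
#' @export
thickness_profile <- function(traj, bin_width = 0.5, correction = TRUE,
                              x_bin_width = 0.5, frames = NULL) {
  prot <- groups_by_role(traj, "protein")
  if (length(prot) == 0L)
    stop("thickness_profile: no protein groups; use mean_thickness() for ",
         "the protein-free summary")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  coms <- protein_coms(traj)
  Lx <- traj$box[1]
  rmax <- Lx / 2
  nbr <- ceiling(rmax / bin_width)
  acc_v <- acc_n <- numeric(nbr)
  for (f in frames) {
    g <- leaflet_grid(traj, f, x_bin_width)
    ok <- (g$nu + g$nl) > 0 & is.finite(g$slope) &
      is.finite(g$zu) & is.finite(g$zl)
    if (!any(ok)) next
    d <- g$zu[ok] - g$zl[ok]
    if (correction) d <- d * cos(atan(g$slope[ok]))
    px <- coms[, 1, f]
    r <- vapply(g$x[ok], function(xj)
      min(abs(min_image_dx(px - xj, Lx))), numeric(1))
    rb <- pmin(nbr, floor(r / bin_width) + 1L)
    for (k in seq_along(rb)) {
      acc_v[rb[k]] <- acc_v[rb[k]] + d[k]
      acc_n[rb[k]] <- acc_n[rb[k]] + 1
    }
  }
  keep <- acc_n > 0
  out <- data.frame(r = (which(keep) - 0.5) * bin_width,
                    value = acc_v[keep] / acc_n[keep], n = acc_n[keep])
  class(out) <- c("radial_profile", "data.frame")
  out
}

chain_indices <- function(traj) {
  ch <- groups_by_role(traj, "chain-anchor")
  if (length(ch) == 0L) stop("trajectory has no chain-anchor groups")
  sort(unique(unlist(lapply(ch, `[[`, "indices"))))
}

#' Area per acyl chain versus distance to the nearest protein
#'
#' Per frame and leaflet, a periodic 2D Voronoi tessellation is built over
#' the lateral positions of that leaflet's chain-anchor beads, with the
#' protein beads spanning the leaflet included as seeds; each chain's area
#' is its cell area, scaled by `1 / cos(theta_loc)` to undo the lateral
#' projection. Protein-seed cells are excluded, and chain areas are binned
#' by lateral distance to the nearest protein centre of mass.
#'
#' @param traj A [trajectory()] with chain-anchor and protein groups.
#' @param leaflet `"upper"` or `"lower"`.
#' @param bin_width Radial bin width (nm), default 0.5.
#' @param frames Frame indices; defaults to all (the tessellation is the
#'   expensive step, so subsampling frames is common).
#' @param correction Apply the projection correction.
#' @return A `radial_profile` data frame (`r`, `value` = area in nm^2,
#'   `n`).
#' @export
area_per_chain_profile <- function(traj, leaflet = c("upper", "lower"),
                                   bin_width = 0.5, frames = NULL,
                                   correction = TRUE) {
  leaflet <- match.arg(leaflet)
  prot <- groups_by_role(traj, "protein")
  if (length(prot) == 0L)
    stop("area_per_chain_profile: no protein groups")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  coms <- protein_coms(traj)
  box <- traj$box
  ch_idx <- chain_indices(traj)
  prot_idx <- sort(unlist(lapply(prot, `[[`, "indices")))
  nbr <- ceiling(box[1] / 2 / bin_width)
  acc_v <- acc_n <- numeric(nbr)
  for (f in frames) {
    g <- leaflet_grid(traj, f, 0.5)
    co <- frame_coords(traj, f)
    # assign chains and protein beads to leaflets by the midplane
    prof_mid <- function(xx) {
      xs <- c(g$x - box[1], g$x, g$x + box[1])
      zm <- rep((g$zu + g$zl) / 2, 3)
      okk <- is.finite(zm)
      stats::approx(xs[okk], zm[okk], xout = xx %% box[1], ties = "ordered")$y
    }
    side <- function(idx) {
      dz <- co[idx, 3] - prof_mid(co[idx, 1])
      if (leaflet == "upper") idx[dz >= 0] else idx[dz < 0]
    }
    ci <- side(ch_idx); pi_ <- side(prot_idx)
    seeds <- rbind(co[ci, 1:2, drop = FALSE], co[pi_, 1:2, drop = FALSE])
    if (nrow(seeds) < 4L) stop("area_per_chain_profile: fewer than 4 seeds")
    areas <- voronoi_cell_areas(seeds, box[1:2])
    nchain <- length(ci)
    a <- areas[seq_len(nchain)]
    if (correction) {
      sl <- g$slope[pmin(g$nbx, floor((co[ci, 1] %% box[1]) /
                                        box[1] * g$nbx) + 1L)]
      sl[!is.finite(sl)] <- 0
      a <- a / cos(atan(sl))
    }
    px <- matrix(coms[, 1:2, f], ncol = 2)
    r <- vapply(seq_len(nchain), function(k)
      min(lateral_distance(px, matrix(co[ci[k], 1:2], nrow(px), 2,
                                      byrow = TRUE), box)),
      numeric(1))
    rb <- pmin(nbr, floor(r / bin_width) + 1L)
    for (k in seq_along(rb)) {
      acc_v[rb[k]] <- acc_v[rb[k]] + a[k]
      acc_n[rb[k]] <- acc_n[rb[k]] + 1
    }
  }
  keep <- acc_n > 0
  out <- data.frame(r = (which(keep) - 0.5) * bin_width,
                    value = acc_v[keep] / acc_n[keep], n = acc_n[keep])
  class(out) <- c("radial_profile", "data.frame")
  out
}
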
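# Protein orientation kinematics: tilt of the protein axis with respect to
# the box normal, and the rotor rotation rate extracted from the unwrapped
# azimuth of the rotor anchor ring.

#' Tilt angle of a protein axis in one frame
#'
#' The angle between the +z axis of the box and the vector pointing from
#' the centre of mass of the bottom anchor ring to that of the top anchor
#' ring.
#'
#' @param frame_xyz `n_beads x 3` coordinate matrix of one frame.
#' @param bottom,top [bead_group()]s of the bottom and top anchor rings
#'   (must share a `protein_id`).
#' @return Tilt angle in degrees, in `[0, 180]`.
#' @export
tilt_angle <- function(frame_xyz, bottom, top) {
  if (length(bottom$indices) == 0L || length(top$indices) == 0L)
    stop("tilt_angle: empty anchor group")
  if (!is.na(bottom$protein_id) && !is.na(top$protein_id) &&
      bottom$protein_id != top$protein_id)
    stop("tilt_angle: anchor groups belong to different proteins")
  B <- colMeans(frame_xyz[bottom$indices, , drop = FALSE])
  T_ <- colMeans(frame_xyz[top$indices, , drop = FALSE])
  v <- T_ - B
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("tilt_angle: zero-length axis vector")
  acos(pmin(1, pmax(-1, v[3] / nv))) * 180 / pi
}

#' Per-frame tilt angles for all proteins
#'
#' @param traj A [trajectory()] with rotor anchor groups.
#' @return Matrix `n_frames x n_proteins` of tilt angles (degrees);
#'   columns named by protein id.
#' @export
tilt_series <- function(traj) {
  bots <- groups_by_role(traj, "rotor-bottom-anchor")
  tops <- groups_by_role(traj, "rotor-top-anchor")
  if (length(bots) == 0L) stop("tilt_series: no rotor anchor groups")
  ids <- sort(vapply(bots, `[[`, integer(1), "protein_id"))
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nf, length(ids),
                dimnames = list(NULL, ids))
  for (p in seq_along(ids)) {
    b <- Filter(function(g) g$protein_id == ids[p], bots)[[1]]
    t_ <- Filter(function(g) g$protein_id == ids[p], tops)[[1]]
    for (f in seq_len(nf))
      out[f, p] <- tilt_angle(frame_coords(traj, f), b, t_)
  }
  out
}

#' Unwrap a wrapped angle series
#'
#' Accumulates minimal angular differences so the result is continuous;
#' valid only when per-frame steps stay below pi.
#'
#' @param theta Angles in radians (any branch).
#' @return Unwrapped angle series.
#' @export
unwrap_angles <- function(theta) {
  d <- diff(theta)
  d <- (d + pi) %% (2 * pi) - pi
  cumsum(c(theta[1], d))
}

#' Rotor angle series of one protein
#'
#' The azimuth of the first bottom-rotor anchor bead around the ring
#' centroid, measured in the plane perpendicular to the protein axis
#' (bottom-to-top anchor COM vector), unwrapped over frames.
#'
#' @param traj A [trajectory()].
#' @param protein_id Protein identifier.
#' @return Numeric vector of unwrapped angles (radians).
#' @export
rotor_angle_series <- function(traj, protein_id) {
  bots <- Filter(function(g) g$protein_id == protein_id,
                 groups_by_role(traj, "rotor-bottom-anchor"))
  tops <- Filter(function(g) g$protein_id == protein_id,
                 groups_by_role(traj, "rotor-top-anchor"))
  if (length(bots) == 0L || length(tops) == 0L)
    stop("rotor_angle_series: missing rotor anchors for protein ", protein_id)
  b <- bots[[1]]; t_ <- tops[[1]]
  nf <- n_frames(traj)
  raw <- numeric(nf)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    Bc <- colMeans(co[b$indices, , drop = FALSE])
    Tc <- colMeans(co[t_$indices, , drop = FALSE])
    u <- Tc - Bc; u <- u / sqrt(sum(u^2))
    # orthonormal in-plane basis
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    v <- co[b$indices[1], ] - Bc
    raw[f] <- atan2(sum(v * e2), sum(v * e1))
  }
  unwrap_angles(raw)
}

#' Rotation rate from an unwrapped angle series
#'
#' Least-squares slope of the unwrapped angle versus time, divided by
#' `2 pi` (turns per microsecond). Regression, rather than the endpoint
#' difference, keeps the estimate robust to thermal wiggle around the
#' stepping trend.
#'
#' @param angles Unwrapped angle series (radians), or a matrix with one
#'   column per protein (rates averaged over proteins).
#' @param dt Frame spacing (us).
#' @return Rotation rate in turns/us (signed).
#' @export
rotation_rate <- function(angles, dt) {
  if (is.matrix(angles))
    return(mean(apply(angles, 2, rotation_rate, dt = dt)))
  n <- length(angles)
  if (n < 2L) stop("rotation_rate: need at least 2 frames")
  if (any(abs(diff(angles)) >= pi))
    stop("rotation_rate: angular step >= pi between frames (aliasing)")
  tt <- (seq_len(n) - 1) * dt
  slope <- stats::cov(tt, angles) / stats::var(tt)
  slope / (2 * pi)
}
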
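# Synthetic bilayer+protein trajectory generator with known ground truth.
# The generator emulates the statistical structure the trajectory analyses
# assume -- sinusoidal undulation modes of a quasi-1D buckled bilayer, local
# thinning around proteins, lateral protein diffusion in a short-range
# attractive pair potential, slope-coupled protein tilt and stepwise rotor
# rotation -- so that every analysis stage can be validated by parameter
# recovery without running molecular dynamics.

#' Specify a protein-protein pair potential
#'
#' A Gaussian attractive well plus a harmonic soft-core repulsion:
#' `V(l) = -depth * exp(-(l - location)^2 / (2 width^2))`
#' ` + k_core * (core_radius - l)^2  for l < core_radius`.
#'
#' @param depth Well depth in kBT (>= 0).
#' @param location Centre-to-centre distance of the minimum (nm); must
#'   exceed `core_radius`.
#' @param width Gaussian width of the well (nm).
#' @param core_radius Onset of the soft-core repulsion (nm).
#' @param k_core Harmonic constant of the repulsion (kBT/nm^2).
#' @return Object of class `potential_spec`.
#' @export
potential_spec <- function(depth = 1.5, location = 6, width = 1,
                           core_radius = 4.5, k_core = 5) {
  if (depth < 0) stop("potential_spec: depth must be >= 0")
  if (location <= core_radius)
    stop("potential_spec: location must exceed core_radius")
  if (width <= 0 || core_radius < 0 || k_core < 0)
    stop("potential_spec: width must be positive, core terms non-negative")
  structure(list(depth = depth, location = location, width = width,
                 core_radius = core_radius, k_core = k_core),
            class = "potential_spec")
}

#' Evaluate a pair potential
#' @param spec A [potential_spec()].
#' @param l Centre-to-centre distances (nm).
#' @return `V(l)` in kBT.
#' @export
pair_potential_value <- function(spec, l) {
  v <- -spec$depth * exp(-(l - spec$location)^2 / (2 * spec$width^2))
  core <- l < spec$core_radius
  v[core] <- v[core] + spec$k_core * (spec$core_radius - l[core])^2
  v
}

#' Radial force of a pair potential, `-dV/dl`
#' @inheritParams pair_potential_value
#' @export
pair_potential_force <- function(spec, l) {
  f <- -spec$depth * exp(-(l - spec$location)^2 / (2 * spec$width^2)) *
    (l - spec$location) / spec$width^2
  core <- l < spec$core_radius
  f[core] <- f[core] + 2 * spec$k_core * (spec$core_radius - l[core])
  f
}

#' Generator configuration
#'
#' Defaults reproduce the study conditions of the simulated system: a
#' 52 x 13 nm bilayer of 2 x 856 POPC lipids hosting 4 rotary proteins of
#' radius 3 nm, baseline P-P thickness 3.9 nm, frame spacing 0.01 us.
#'
#' @param box Lateral box `c(Lx, Ly)` in nm.
#' @param Lz Vertical box extent (nm), only used for file output.
#' @param n_lipids_per_leaflet Lipid count per leaflet.
#' @param undulation_modes Data frame with columns `m` (mode index),
#'   `amplitude` (nm), `amplitude_sd` (nm; > 0 draws a fresh amplitude each
#'   frame), `phase` (radians; `NA` draws a fresh uniform phase each
#'   frame), `phase_drift` (radians/frame). `NULL` for a flat membrane.
#' @param d0 Baseline bilayer (P-P) thickness (nm).
#' @param thinning `list(depth =, sigma =)`: Gaussian thinning of depth nm
#'   (saturating when wells of several proteins overlap) with lateral decay
#'   sigma nm around each protein; `NULL` for none.
#' @param n_proteins Number of proteins.
#' @param protein_radius Protein shell radius (nm).
#' @param pair_potential A [potential_spec()] or `NULL` (free diffusion).
#' @param diffusion_coefficient Lateral protein diffusion constant
#'   (nm^2/us).
#' @param tilt_coupling Scale linking protein tilt to the local membrane
#'   slope angle (1 = tilt follows the slope exactly).
#' @param rotation `list(rate =, model =, substeps =)`: rotor turns/us,
#'   `"smooth"` or `"stepwise"` stepping, steps per turn.
#' @param area_dilation `list(delta =, range =)`: fractional lateral
#'   dilation of lipid positions within `range` nm of a protein; `NULL`
#'   for none.
#' @param protein_init `"spread"`, `"clustered"`, `"random"`, or an
#'   `n_proteins x 2` matrix of initial xy positions.
#' @param lateral_jitter Per-frame lateral jitter SD of lipid positions
#'   (nm).
#' @param n_frames,dt Number of frames and frame spacing (us).
#' @param dynamics_substeps Euler-Maruyama substeps per frame.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(box = c(52, 13), Lz = 20,
                             n_lipids_per_leaflet = 856,
                             undulation_modes = NULL,
                             d0 = 3.9, thinning = NULL,
                             n_proteins = 4, protein_radius = 3,
                             pair_potential = NULL,
                             diffusion_coefficient = 5,
                             tilt_coupling = 1,
                             rotation = list(rate = 0, model = "smooth",
                                             substeps = 10),
                             area_dilation = NULL,
                             protein_init = "spread",
                             lateral_jitter = 0.1,
                             n_frames = 500, dt = 0.01,
                             dynamics_substeps = 5, seed = 1) {
  if (any(box <= 0) || Lz <= 0) stop("generator_config: box extents must be positive")
  if (d0 <= 0) stop("generator_config: d0 must be positive")
  if (!is.null(thinning)) {
    if (thinning$depth >= d0)
      stop("generator_config: thinning depth must be smaller than d0")
    if (thinning$sigma <= 0) stop("generator_config: thinning sigma must be positive")
  }
  if (!is.null(undulation_modes)) {
    um <- as.data.frame(undulation_modes)
    needed <- c("m", "amplitude")
    if (!all(needed %in% names(um)))
      stop("generator_config: undulation_modes needs columns m, amplitude")
    if (is.null(um$amplitude_sd)) um$amplitude_sd <- 0
    if (is.null(um$phase)) um$phase <- NA_real_
    if (is.null(um$phase_drift)) um$phase_drift <- 0
    if (any(um$amplitude < 0)) stop("generator_config: amplitudes must be >= 0")
    if (any(um$amplitude + 3 * um$amplitude_sd > Lz / 2))
      stop("generator_config: amplitudes must stay below Lz/2")
    undulation_modes <- um
  }
  if (n_frames < 1 || dt <= 0) stop("generator_config: need n_frames >= 1, dt > 0")
  if (n_proteins > 0 &&
      n_proteins * pi * protein_radius^2 > 0.9 * box[1] * box[2])
    stop("generator_config: protein footprints exceed the box area")
  structure(list(box = box, Lz = Lz,
                 n_lipids_per_leaflet = n_lipids_per_leaflet,
                 undulation_modes = undulation_modes, d0 = d0,
                 thinning = thinning, n_proteins = n_proteins,
                 protein_radius = protein_radius,
                 pair_potential = pair_potential,
                 diffusion_coefficient = diffusion_coefficient,
                 tilt_coupling = tilt_coupling, rotation = rotation,
                 area_dilation = area_dilation, protein_init = protein_init,
                 lateral_jitter = lateral_jitter, n_frames = n_frames,
                 dt = dt, dynamics_substeps = dynamics_substeps,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Preset generator configurations
#'
#' `"control"` emulates the passive (non-rotating) condition: thermal
#' undulations with per-frame random single-mode amplitudes calibrated so
#' the peak-to-peak spread distribution has mean 6.9 nm and SD 0.65 nm
#' over the 3.9 nm baseline thickness, a slight (0.2 nm) first-shell
#' thinning, and no protein-protein attraction. `"active"` emulates the
#' rotating (hydrolysis-mode) condition: a persistent single-mode buckle
#' (peak-to-peak ~ 11 nm), strong thinning to 3.2 nm, a 1.5 kBT attractive
#' well at 6 nm, ~1% lipid area dilation within 6 nm, and stepwise rotor
#' rotation at 0.47 turns/us. `"active_twomode"` uses two persistent lower
#' modes instead of one (the alternative buckled state).
#'
#' @param name One of `"control"`, `"active"`, `"active_twomode"`.
#' @param ... Overrides passed on to [generator_config()].
#' @return A `generator_config`.
#' @export
generator_preset <- function(name = c("control", "active", "active_twomode"),
                             ...) {
  name <- match.arg(name)
  base <- switch(
    name,
    control = list(
      undulation_modes = data.frame(m = 1, amplitude = 1.5,
                                    amplitude_sd = 0.325, phase = NA_real_,
                                    phase_drift = 0),
      thinning = list(depth = 0.2, sigma = 0.6),
      pair_potential = NULL,
      rotation = list(rate = 0, model = "smooth", substeps = 10),
      area_dilation = NULL,
      protein_init = "spread",
      n_frames = 1000),
    active = list(
      undulation_modes = data.frame(m = 1, amplitude = 3.55,
                                    amplitude_sd = 0, phase = 0.7,
                                    phase_drift = 0.003),
      thinning = list(depth = 0.7, sigma = 2.5),
      pair_potential = potential_spec(depth = 1.5, location = 6, width = 1,
                                      core_radius = 4.5),
      rotation = list(rate = 0.47, model = "stepwise", substeps = 10),
      area_dilation = list(delta = 0.01, range = 6),
      protein_init = "clustered",
      n_frames = 500),
    active_twomode = list(
      undulation_modes = data.frame(m = c(1, 2), amplitude = c(1.4, 1.0),
                                    amplitude_sd = 0, phase = c(0.7, 2.1),
                                    phase_drift = c(0.003, -0.005)),
      thinning = list(depth = 0.7, sigma = 2.5),
      pair_potential = potential_spec(depth = 1.5, location = 6, width = 1,
                                      core_radius = 4.5),
      rotation = list(rate = 0.47, model = "stepwise", substeps = 10),
      area_dilation = list(delta = 0.01, range = 6),
      protein_init = "clustered",
      n_frames = 500))
  do.call(generator_config, utils::modifyList(base, list(...)))
}

# rectangular lattice of n points filling the box
lipid_lattice <- function(n, box, offset = 0) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  nx <- max(1L, round(sqrt(n * box[1] / box[2])))
  ny <- ceiling(n / nx)
  sx <- box[1] / nx; sy <- box[2] / ny
  g <- expand.grid(x = (seq_len(nx) - 0.5) * sx, y = (seq_len(ny) - 0.5) * sy)
  pts <- as.matrix(g[seq_len(n), , drop = FALSE])
  pts[, 1] <- (pts[, 1] + offset * sx) %% box[1]
  pts
}

# protein bead template in the body frame; rows: 16 shell, 8 bottom rotor,
# 8 top rotor anchors
protein_template <- function(R) {
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  shell <- rbind(cbind(R * cos(ang), R * sin(ang), -1.2),
                 cbind(R * cos(ang), R * sin(ang), 1.2))
  rotor_b <- cbind(0.5 * R * cos(ang), 0.5 * R * sin(ang), -1.5)
  rotor_t <- cbind(0.5 * R * cos(ang), 0.5 * R * sin(ang), 1.5)
  list(shell = shell, rotor_b = rotor_b, rotor_t = rotor_t)
}

rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)

min_image_dx <- function(dx, L) dx - L * round(dx / L)

# thinning factor in [0, 1]: saturating combination of per-protein Gaussian
# wells (x-distances only: the bilayer is quasi-1D)
thinning_fraction <- function(x, prot_x, sigma, Lx) {
  if (length(prot_x) == 0L) return(rep(0, length(x)))
  keep <- rep(1, length(x))
  for (xp in prot_x) {
    dxp <- min_image_dx(x - xp, Lx)
    keep <- keep * (1 - exp(-dxp^2 / (2 * sigma^2)))
  }
  1 - keep
}

#' Generate a synthetic bilayer+protein trajectory with ground truth
#'
#' Builds frames in which the two phosphate leaflets are offset by half the
#' local thickness along the local normal of the midsurface
#' `z(x) = sum_m A_m sin(2 pi m x / Lx + phi_m)`, acyl-chain anchor beads
#' sit below the phosphates, and proteins are rigid bead cylinders whose
#' centres follow overdamped Langevin dynamics in the configured pair
#' potential (laterally periodic). Thickness is locally reduced near
#' protein centres, protein axes tilt with the local slope, and rotor
#' anchor rings advance according to the configured rotation model.
#'
#' @param cfg A [generator_config()].
#' @return List with `trajectory` (a [trajectory()]) and `truth`, a ground
#'   truth record holding the per-frame mode realizations, true protein
#'   centre paths, tilt and rotor-angle series, thickness parameters,
#'   leaflet identities and true close-contact events.
#' @export
generate_membrane_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 5L)
  box <- cfg$box; Lx <- box[1]; nf <- cfg$n_frames
  nl <- cfg$n_lipids_per_leaflet
  np <- cfg$n_proteins

  # --- undulation realizations ------------------------------------------
  set.seed(sub_seeds[1])
  modes <- cfg$undulation_modes
  n_modes <- if (is.null(modes)) 0L else nrow(modes)
  amp <- matrix(0, nf, max(1L, n_modes))
  pha <- matrix(0, nf, max(1L, n_modes))
  if (n_modes > 0L) {
    for (k in seq_len(n_modes)) {
      amp[, k] <- if (modes$amplitude_sd[k] > 0)
        pmax(0, stats::rnorm(nf, modes$amplitude[k], modes$amplitude_sd[k]))
      else rep(modes$amplitude[k], nf)
      pha[, k] <- if (is.na(modes$phase[k])) stats::runif(nf, 0, 2 * pi)
      else modes$phase[k] + modes$phase_drift[k] * (seq_len(nf) - 1)
    }
  }
  zbar_f <- function(f, x) {
    z <- rep(0, length(x))
    if (n_modes > 0L) for (k in seq_len(n_modes))
      z <- z + amp[f, k] * sin(2 * pi * modes$m[k] * x / Lx + pha[f, k])
    z
  }
  slope_f <- function(f, x) {
    s <- rep(0, length(x))
    if (n_modes > 0L) for (k in seq_len(n_modes))
      s <- s + amp[f, k] * (2 * pi * modes$m[k] / Lx) *
        cos(2 * pi * modes$m[k] * x / Lx + pha[f, k])
    s
  }

  # --- protein centre dynamics ------------------------------------------
  set.seed(sub_seeds[2])
  prot_xy <- array(NA_real_, c(max(1L, np), 2L, nf))
  if (np > 0L) {
    init <- cfg$protein_init
    pos <- if (is.matrix(init)) {
      if (nrow(init) != np) stop("protein_init matrix must have n_proteins rows")
      init
    } else if (identical(init, "spread")) {
      cbind((seq_len(np) - 0.5) * Lx / np, box[2] / 2)
    } else if (identical(init, "clustered")) {
      spacing <- if (!is.null(cfg$pair_potential))
        cfg$pair_potential$location + 1 else 2 * cfg$protein_radius + 1
      cbind((seq_len(np) - 1) * spacing + 2, box[2] / 2)
    } else if (identical(init, "random")) {
      ok <- FALSE
      for (attempt in seq_len(1000L)) {
        cand <- cbind(stats::runif(np, 0, Lx), stats::runif(np, 0, box[2]))
        dmin <- Inf
        if (np > 1L) for (i in seq_len(np - 1)) for (j in (i + 1):np)
          dmin <- min(dmin, lateral_distance(cand[i, ], cand[j, ], box))
        if (np == 1L || dmin >= 2 * cfg$protein_radius) { pos <- cand; ok <- TRUE; break }
      }
      if (!ok) stop("could not place proteins without overlap in 1000 attempts")
      pos
    } else stop("unknown protein_init")
    pos <- wrap_lateral(pos, box)

    D <- cfg$diffusion_coefficient
    h <- cfg$dt / cfg$dynamics_substeps
    sdstep <- sqrt(2 * D * h)
    for (f in seq_len(nf)) {
      prot_xy[, , f] <- pos
      if (f == nf) break
      for (s in seq_len(cfg$dynamics_substeps)) {
        force <- matrix(0, np, 2)
        if (!is.null(cfg$pair_potential) && np > 1L) {
          for (i in seq_len(np - 1)) for (j in (i + 1):np) {
            dx <- min_image_dx(pos[j, 1] - pos[i, 1], Lx)
            dy <- min_image_dx(pos[j, 2] - pos[i, 2], box[2])
            l <- sqrt(dx^2 + dy^2)
            if (l < 1e-9) next
            fr <- pair_potential_force(cfg$pair_potential, l)
            # fr > 0 pushes j away from i
            force[j, ] <- force[j, ] + fr * c(dx, dy) / l
            force[i, ] <- force[i, ] - fr * c(dx, dy) / l
          }
        }
        pos <- pos + D * force * h +
          matrix(stats::rnorm(2 * np, 0, sdstep), np, 2)
        pos <- wrap_lateral(pos, box)
      }
    }
  }

  # --- rotor rotation ----------------------------------------------------
  rotor_angles <- matrix(0, nf, max(1L, np))
  if (np > 0L && cfg$rotation$rate >= 0) {
    for (p in seq_len(np)) {
      rotor_angles[, p] <- generate_rotation_series(
        cfg$rotation$rate, cfg$dt, nf,
        step_model = cfg$rotation$model,
        substeps = cfg$rotation$substeps,
        seed = sub_seeds[3] + p)
    }
  }

  # --- bead assembly -----------------------------------------------------
  set.seed(sub_seeds[4])
  lat_u <- lipid_lattice(nl, box, offset = 0)
  lat_l <- lipid_lattice(nl, box, offset = 0.5)
  tmpl <- protein_template(cfg$protein_radius)
  n_prot_beads <- if (np > 0L) np * (16L + 8L + 8L) else 0L
  nb <- 2L * nl + 4L * nl + n_prot_beads
  coords <- array(NA_real_, c(nb, 3L, nf))
  tilt_true <- matrix(0, nf, max(1L, np))

  thick_at <- function(x, px) {
    d <- rep(cfg$d0, length(x))
    if (!is.null(cfg$thinning) && np > 0L)
      d <- d - cfg$thinning$depth *
        thinning_fraction(x, px, cfg$thinning$sigma, Lx)
    d
  }

  # push lipids out of each protein footprint with the area-preserving map
  # r' = sqrt(r^2 + R^2): lipid areal density (and hence Voronoi areas) away
  # from the footprint is unchanged, and no lipid sits under a protein
  exclude_footprints <- function(xy, px_xy) {
    if (np == 0L) return(xy)
    Rx <- cfg$protein_radius + 0.3
    for (p in seq_len(nrow(px_xy))) {
      dx <- min_image_dx(xy[, 1] - px_xy[p, 1], Lx)
      dy <- min_image_dx(xy[, 2] - px_xy[p, 2], box[2])
      r <- sqrt(dx^2 + dy^2)
      aff <- r > 1e-9
      fac <- sqrt(r[aff]^2 + Rx^2) / r[aff]
      xy[aff, 1] <- xy[aff, 1] + dx[aff] * (fac - 1)
      xy[aff, 2] <- xy[aff, 2] + dy[aff] * (fac - 1)
    }
    xy
  }

  dilate <- function(xy, px_xy) {
    if (is.null(cfg$area_dilation) || np == 0L) return(xy)
    delta <- cfg$area_dilation$delta; r0 <- cfg$area_dilation$range
    # radial displacement about the nearest protein centre
    dbest <- rep(Inf, nrow(xy)); ux <- uy <- rep(0, nrow(xy))
    for (p in seq_len(np)) {
      dx <- min_image_dx(xy[, 1] - px_xy[p, 1], Lx)
      dy <- min_image_dx(xy[, 2] - px_xy[p, 2], box[2])
      r <- sqrt(dx^2 + dy^2)
      better <- r < dbest
      dbest[better] <- r[better]
      ux[better] <- dx[better]; uy[better] <- dy[better]
    }
    r <- dbest
    u <- ifelse(r < r0, (delta / 2) * r,
                ifelse(r < 3 * r0, (delta / 2) * r0^2 / r, 0))
    scale <- ifelse(r > 1e-9, u / r, 0)
    xy + cbind(ux, uy) * scale
  }

  place_leaflet <- function(f, lat, side, px) {
    jit <- matrix(stats::rnorm(2 * nrow(lat), 0, cfg$lateral_jitter),
                  nrow(lat), 2)
    xy <- wrap_lateral(dilate(exclude_footprints(lat + jit, px), px), box)
    x <- xy[, 1]
    z0 <- zbar_f(f, x); s <- slope_f(f, x)
    invn <- 1 / sqrt(1 + s^2)
    t <- thick_at(x, px[, 1]) / 2
    phos <- cbind(x - side * t * s * invn, xy[, 2], z0 + side * t * invn)
    tc <- pmax(0.2, t - 0.8)
    ca1 <- cbind(x - side * tc * s * invn, (xy[, 2] - 0.22) %% box[2],
                 z0 + side * tc * invn)
    ca2 <- cbind(x - side * tc * s * invn, (xy[, 2] + 0.22) %% box[2],
                 z0 + side * tc * invn)
    list(phos = phos, chains = rbind(ca1, ca2))
  }

  for (f in seq_len(nf)) {
    px <- if (np > 0L) matrix(prot_xy[, , f], np, 2) else matrix(0, 0, 2)
    up <- place_leaflet(f, lat_u, +1, px)
    lo <- place_leaflet(f, lat_l, -1, px)
    fr <- rbind(up$phos, lo$phos, up$chains, lo$chains)
    if (np > 0L) {
      for (p in seq_len(np)) {
        xp <- px[p, 1]
        s <- slope_f(f, xp)
        alpha <- cfg$tilt_coupling * atan(s)
        tilt_true[f, p] <- abs(alpha) * 180 / pi
        Rb <- rot_y(alpha)
        body <- rbind(tmpl$shell,
                      tmpl$rotor_b %*% t(rot_z(rotor_angles[f, p])),
                      tmpl$rotor_t %*% t(rot_z(rotor_angles[f, p])))
        world <- body %*% t(Rb)
        world[, 1] <- world[, 1] + xp
        world[, 2] <- world[, 2] + px[p, 2]
        world[, 3] <- world[, 3] + zbar_f(f, xp)
        fr <- rbind(fr, world)
      }
    }
    coords[, , f] <- fr
  }

  # --- groups ------------------------------------------------------------
  idx <- 0L
  g <- list()
  add <- function(name, n, role, pid = NA_integer_) {
    gr <- bead_group(name, idx + seq_len(n), role, pid)
    idx <<- idx + n
    g[[length(g) + 1L]] <<- gr
  }
  add("phosphate_upper", nl, "phosphate")
  add("phosphate_lower", nl, "phosphate")
  add("chains_upper", 2L * nl, "chain-anchor")
  add("chains_lower", 2L * nl, "chain-anchor")
  if (np > 0L) for (p in seq_len(np)) {
    add(sprintf("protein_%d", p), 16L, "protein", p)
    add(sprintf("rotor_bottom_%d", p), 8L, "rotor-bottom-anchor", p)
    add(sprintf("rotor_top_%d", p), 8L, "rotor-top-anchor", p)
  }

  traj <- trajectory(coords, c(box, cfg$Lz), (seq_len(nf) - 1) * cfg$dt, g)

  # --- ground truth ------------------------------------------------------
  true_contacts <- NULL
  if (np > 1L) {
    pairs <- utils::combn(np, 2)
    recs <- list()
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      dcc <- lateral_distance(t(prot_xy[i, , ]), t(prot_xy[j, , ]), box)
      dmin <- pmax(0, dcc - 2 * cfg$protein_radius)
      r <- rle(dmin < 0.7)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      sel <- which(r$values)
      if (length(sel))
        recs[[length(recs) + 1L]] <- data.frame(
          pair_i = i, pair_j = j, start = starts[sel], end = ends[sel] + 1L,
          duration_frames = r$lengths[sel])
    }
    true_contacts <- if (length(recs)) do.call(rbind, recs) else
      data.frame(pair_i = integer(0), pair_j = integer(0),
                 start = integer(0), end = integer(0),
                 duration_frames = integer(0))
  }

  truth <- list(config = cfg,
                mode_m = if (n_modes > 0L) modes$m else integer(0),
                amplitudes = amp, phases = pha,
                protein_xy = prot_xy, tilt_deg = tilt_true,
                rotor_angles = rotor_angles,
                thickness = list(d0 = cfg$d0, thinning = cfg$thinning),
                leaflet_upper = seq_len(nl),
                leaflet_lower = nl + seq_len(nl),
                contacts = true_contacts,
                pair_potential = cfg$pair_potential)
  list(trajectory = traj, truth = truth)
}

#' Sample protein pair distances from a pair potential
#'
#' Draws i.i.d. centre-to-centre distances from the two-dimensional
#' Boltzmann density `p(l) proportional to 2 pi l exp(-V(l))` on a finite
#' support, by inverse-CDF sampling on a fine quadrature grid. This is the
#' exact inverse of the Boltzmann inversion performed by
#' [boltzmann_invert()], so recovered potentials can be checked against the
#' specification that generated the sample.
#'
#' @param spec A [potential_spec()], or `NULL` for a flat (ideal-gas)
#'   potential.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @param support `c(lmin, lmax)` sampling support in nm.
#' @return Numeric vector of `n` distances (nm).
#' @export
sample_pair_distances <- function(spec, n, seed = 1L, support = c(0, 12)) {
  if (n < 1) stop("sample_pair_distances: n must be >= 1")
  grid <- seq(max(support[1], 1e-6), support[2], length.out = 4001L)
  V <- if (is.null(spec)) rep(0, length(grid)) else pair_potential_value(spec, grid)
  w <- 2 * pi * grid * exp(-V)
  if (!all(is.finite(w)) || sum(w) <= 0)
    stop("sample_pair_distances: density not integrable on the support")
  dg <- diff(grid)
  cdf <- c(0, cumsum((w[-1] + w[-length(w)]) / 2 * dg))
  cdf <- cdf / cdf[length(cdf)]
  set.seed(as.integer(seed))
  u <- stats::runif(n)
  # invert the piecewise-linear CDF
  stats::approx(cdf, grid, xout = u, ties = "ordered")$y
}

#' Generate a boolean contact series with known event durations
#'
#' Builds an in-contact indicator series from a list of (gap, contact
#' length) pairs, so that the maximal runs of `TRUE` equal the requested
#' contact durations exactly. Serves as the round-trip oracle for
#' [contact_events()].
#'
#' @param durations List of length-2 integer vectors `c(gap, length)`
#'   (frames, non-negative).
#' @return List with `series` (logical vector) and `events` (data frame of
#'   start, end (half-open), duration_frames).
#' @export
generate_contact_series <- function(durations) {
  series <- logical(0)
  starts <- integer(0); lens <- integer(0)
  for (d in durations) {
    gap <- as.integer(d[1]); len <- as.integer(d[2])
    if (gap < 0 || len < 0) stop("generate_contact_series: negative durations")
    series <- c(series, rep(FALSE, gap))
    if (len > 0L) {
      starts <- c(starts, length(series) + 1L)
      lens <- c(lens, len)
      series <- c(series, rep(TRUE, len))
    }
  }
  list(series = series,
       events = data.frame(start = starts, end = starts + lens,
                           duration_frames = lens))
}

#' Generate a rotor angle series
#'
#' Smooth rotation advances linearly at `2 pi rate`; stepwise rotation
#' advances by `2 pi / substeps` at exponentially distributed waiting
#' times, so the mean slope is still `2 pi rate` (the rotor steps between
#' discrete positions, as a c-ring does between proton-transfer events).
#'
#' @param rate Rotation rate in turns/us (>= 0).
#' @param dt Frame spacing (us).
#' @param n_frames Number of frames.
#' @param step_model `"smooth"` or `"stepwise"`.
#' @param substeps Steps per full turn for the stepwise model.
#' @param seed Integer seed (stepwise model only).
#' @return Numeric vector of unwrapped angles (radians) at frame times.
#' @export
generate_rotation_series <- function(rate, dt, n_frames,
                                     step_model = c("smooth", "stepwise"),
                                     substeps = 10L, seed = 1L) {
  if (rate < 0) stop("generate_rotation_series: rate must be >= 0")
  step_model <- match.arg(step_model)
  tt <- (seq_len(n_frames) - 1) * dt
  if (step_model == "smooth" || rate == 0) return(2 * pi * rate * tt)
  set.seed(as.integer(seed))
  lambda <- rate * substeps  # step events per us
  Ttot <- tt[n_frames]
  n_exp <- max(10L, ceiling(lambda * Ttot + 6 * sqrt(lambda * Ttot + 1)))
  ev <- cumsum(stats::rexp(n_exp, lambda))
  while (ev[length(ev)] < Ttot) ev <- c(ev, ev[length(ev)] +
                                          cumsum(stats::rexp(n_exp, lambda)))
  counts <- findInterval(tt, ev)
  (2 * pi / substeps) * counts
}
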
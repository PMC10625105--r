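# Units used package-wide: lengths in nm, times in microseconds, angles in
# degrees at user-facing boundaries, energies in units of kBT.

#' Construct a bead group
#'
#' A bead group names a set of bead indices and assigns them a role within
#' the bilayer/protein system (lipid phosphates by leaflet, acyl-chain
#' anchors, the protein shell, or the rotor anchor rings used for tilt and
#' rotation readouts).
#'
#' @param name Group label.
#' @param indices Integer vector of bead indices (1-based, as in GRO/PDB
#'   serial numbering).
#' @param role One of `"phosphate"`, `"chain-anchor"`, `"protein"`,
#'   `"rotor-bottom-anchor"`, `"rotor-top-anchor"`.
#' @param protein_id Integer protein identifier, or `NA` for lipid groups.
#'   Required for protein and rotor-anchor roles.
#' @return An object of class `bead_group`.
#' @export
bead_group <- function(name, indices, role, protein_id = NA_integer_) {
  roles <- c("phosphate", "chain-anchor", "protein",
             "rotor-bottom-anchor", "rotor-top-anchor")
  if (!is.character(name) || length(name) != 1L)
    stop("bead_group: 'name' must be a single string")
  if (!role %in% roles)
    stop("bead_group: unknown role '", role, "'")
  indices <- as.integer(indices)
  if (length(indices) < 1L || anyNA(indices) || any(indices < 1L))
    stop("bead_group: indices must be positive integers")
  if (anyDuplicated(indices))
    stop("bead_group: duplicated indices in group '", name, "'")
  if (role %in% c("rotor-bottom-anchor", "rotor-top-anchor") && is.na(protein_id))
    stop("bead_group: rotor anchor group '", name, "' must reference a protein_id")
  structure(list(name = name, indices = indices, role = role,
                 protein_id = as.integer(protein_id)),
            class = "bead_group")
}

#' Construct a trajectory
#'
#' The central container consumed by every analysis: an ordered stack of
#' frames of bead coordinates in a laterally periodic box, plus named bead
#' groups. Coordinates are stored as an `n_beads x 3 x n_frames` array in nm;
#' the box is periodic in x and y only (z is the membrane normal and free).
#'
#' @param coords Numeric array `n_beads x 3 x n_frames` (nm).
#' @param box Numeric length-3 vector `c(Lx, Ly, Lz)` in nm.
#' @param times Frame timestamps in microseconds (strictly increasing,
#'   uniformly spaced).
#' @param groups List of [bead_group()] objects.
#' @return An object of class `trajectory` with accessors `n_frames()`,
#'   `n_beads()`.
#' @export
trajectory <- function(coords, box, times, groups = list()) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  box <- as.numeric(box)
  if (length(box) == 2L) box <- c(box, 4 * max(box))
  if (length(box) != 3L || any(box[1:2] <= 0))
    stop("trajectory: box must give positive lateral extents Lx, Ly")
  times <- as.numeric(times)
  if (length(times) != dim(coords)[3])
    stop("trajectory: one timestamp per frame required")
  if (length(times) > 1L) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("trajectory: timestamps must be strictly increasing")
    if (max(dts) - min(dts) > 1e-6 * max(dts))
      stop("trajectory: frame spacing must be uniform")
  }
  nb <- dim(coords)[1]
  for (g in groups) {
    if (!inherits(g, "bead_group")) stop("trajectory: groups must be bead_group objects")
    if (any(g$indices > nb))
      stop("trajectory: group '", g$name, "' references bead index ",
           max(g$indices), " but trajectory has ", nb, " beads")
  }
  prot <- Filter(function(g) g$role == "protein", groups)
  if (length(prot) > 1L) {
    idx <- unlist(lapply(prot, `[[`, "indices"))
    if (anyDuplicated(idx))
      stop("trajectory: protein groups have overlapping bead indices")
  }
  names(groups) <- vapply(groups, `[[`, "", "name")
  structure(list(coords = coords, box = box, times = times, groups = groups),
            class = "trajectory")
}

#' @rdname trajectory
#' @param traj A `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname trajectory
#' @export
n_beads <- function(traj) dim(traj$coords)[1]

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d beads, box %.2f x %.2f x %.2f nm\n",
              n_frames(x), n_beads(x), x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  dt = %g us, groups: %s\n", traj_dt(x),
              paste(names(x$groups), collapse = ", ")))
  invisible(x)
}

#' Frame spacing of a trajectory in microseconds
#' @param traj A `trajectory`.
#' @export
traj_dt <- function(traj) {
  if (n_frames(traj) < 2L) return(NA_real_)
  mean(diff(traj$times))
}

#' Extract one frame's coordinates
#' @param traj A `trajectory`.
#' @param i Frame index.
#' @return `n_beads x 3` numeric matrix (nm).
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Groups of a given role
#' @param traj A `trajectory`.
#' @param role Role string to filter on.
#' @export
groups_by_role <- function(traj, role) {
  Filter(function(g) g$role == role, traj$groups)
}

#' Protein identifiers present in a trajectory
#' @param traj A `trajectory`.
#' @export
protein_ids <- function(traj) {
  ids <- vapply(groups_by_role(traj, "protein"), `[[`, integer(1), "protein_id")
  sort(unname(ids))
}

#' Per-frame protein centre-of-mass positions
#' @param traj A `trajectory`.
#' @return Array `n_proteins x 3 x n_frames`; rownames are protein ids.
#' @export
protein_coms <- function(traj) {
  prot <- groups_by_role(traj, "protein")
  if (length(prot) == 0L) stop("trajectory has no protein groups")
  ids <- order(vapply(prot, `[[`, integer(1), "protein_id"))
  prot <- prot[ids]
  nf <- n_frames(traj)
  out <- array(NA_real_, c(length(prot), 3L, nf))
  for (p in seq_along(prot)) {
    idx <- prot[[p]]$indices
    out[p, , ] <- apply(traj$coords[idx, , , drop = FALSE], c(2, 3), mean)
  }
  dimnames(out) <- list(vapply(prot, `[[`, integer(1), "protein_id"), NULL, NULL)
  out
}

#' Minimum-image lateral (xy) distance under periodic boundaries
#'
#' Distances are computed in the xy plane only; z is the free membrane
#' normal. Supports vectorised input: `a` and `b` may be matrices with
#' points in rows.
#'
#' @param a,b Numeric vectors of length >= 2, or matrices with x,y in the
#'   first two columns.
#' @param box Lateral box extents `c(Lx, Ly)` (nm), both positive.
#' @return Minimum-image xy distance(s) in nm.
#' @export
lateral_distance <- function(a, b, box) {
  if (any(box[1:2] <= 0)) stop("lateral_distance: box extents must be positive")
  a <- rbind(a); b <- rbind(b)
  dx <- a[, 1] - b[, 1]; dy <- a[, 2] - b[, 2]
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  unname(sqrt(dx * dx + dy * dy))
}

#' Wrap lateral coordinates into the primary box image
#' @param xy Matrix with x,y columns.
#' @param box `c(Lx, Ly)`.
#' @export
wrap_lateral <- function(xy, box) {
  xy <- rbind(xy)
  xy[, 1] <- xy[, 1] %% box[1]
  xy[, 2] <- xy[, 2] %% box[2]
  xy
}

# ---------------------------------------------------------------------------
# I/O: GRO (fixed-column, nm), multi-frame PDB (Angstrom), JSON group sidecar

read_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); times <- numeric(0)
  i <- 1L
  while (i <= length(lines)) {
    title <- lines[i]
    if (i + 1L > length(lines)) break
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) stop("GRO format error: bad atom count at line ", i + 1L)
    if (i + 1L + natoms + 1L > length(lines))
      stop("GRO format error: truncated frame starting at line ", i)
    at <- lines[(i + 2L):(i + 1L + natoms)]
    x <- as.numeric(substr(at, 21, 28))
    y <- as.numeric(substr(at, 29, 36))
    z <- as.numeric(substr(at, 37, 44))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop("GRO format error: unparsable coordinates in frame at line ", i)
    boxline <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]])
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_)
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    boxes[[length(boxes) + 1L]] <- boxline[1:3]
    i <- i + natoms + 3L
  }
  if (length(frames) == 0L) stop("GRO format error: no frames found in ", path)
  nb <- vapply(frames, nrow, integer(1))
  if (length(unique(nb)) != 1L)
    stop("GRO format error: bead count differs across frames")
  if (anyNA(times)) times <- seq_along(frames) - 1
  list(coords = array(unlist(frames), c(nb[1], 3L, length(frames))),
       box = boxes[[1L]], times = times)
}

write_gro_frames <- function(coords, box, times, path) {
  nb <- dim(coords)[1]; nf <- dim(coords)[3]
  con <- file(path, "w")
  on.exit(close(con))
  resid <- sprintf("%5d%-5s%5s%5d", (seq_len(nb) - 1L) %% 99999L + 1L,
                   "BEAD", "BD", (seq_len(nb) - 1L) %% 99999L + 1L)
  for (f in seq_len(nf)) {
    writeLines(sprintf("curvsort frame t= %.6f", times[f]), con)
    writeLines(sprintf("%d", nb), con)
    writeLines(paste0(resid, sprintf("%8.3f%8.3f%8.3f",
                                     coords[, 1, f], coords[, 2, f], coords[, 3, f])),
               con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
  invisible(path)
}

read_pdb_frames <- function(path) {
  lines <- readLines(path)
  atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0L) {
    frames <- list(which(atom))
  } else {
    ends <- c(model_starts[-1] - 1L, length(lines))
    frames <- lapply(seq_along(model_starts), function(k) {
      rng <- model_starts[k]:ends[k]
      rng[atom[rng]]
    })
  }
  parse <- function(idx) {
    at <- lines[idx]
    cbind(as.numeric(substr(at, 31, 38)),
          as.numeric(substr(at, 39, 46)),
          as.numeric(substr(at, 47, 54))) / 10  # Angstrom -> nm
  }
  coords <- lapply(frames, parse)
  nb <- vapply(coords, nrow, integer(1))
  if (any(nb == 0L)) stop("PDB format error: empty MODEL in ", path)
  if (length(unique(nb)) != 1L)
    stop("PDB format error: bead count differs across MODELs")
  cry <- lines[startsWith(lines, "CRYST1")]
  box <- if (length(cry)) {
    c(as.numeric(substr(cry[1], 7, 15)), as.numeric(substr(cry[1], 16, 24)),
      as.numeric(substr(cry[1], 25, 33))) / 10
  } else {
    apply(coords[[1]], 2, function(v) diff(range(v))) + 1
  }
  list(coords = array(unlist(coords), c(nb[1], 3L, length(coords))),
       box = box, times = seq_along(coords) - 1)
}

write_pdb_frames <- function(coords, box, times, path) {
  nb <- dim(coords)[1]; nf <- dim(coords)[3]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1] * 10, box[2] * 10, box[3] * 10, 90, 90, 90), con)
  serial <- (seq_len(nb) - 1L) %% 99999L + 1L
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf("ATOM  %5d  BD  BEA A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       serial, serial %% 9999L,
                       coords[, 1, f] * 10, coords[, 2, f] * 10, coords[, 3, f] * 10),
               con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a bead-group metadata sidecar
#'
#' The sidecar is JSON with schema
#' `{"groups": [{"name", "role", "indices", "protein_id"}]}`; indices are
#' 1-based, matching GRO/PDB serial numbering.
#'
#' @param path Path to the JSON sidecar.
#' @param n_beads Optional bead count for bounds validation.
#' @return List of [bead_group()] objects.
#' @export
read_group_metadata <- function(path, n_beads = NULL) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(meta$groups)) stop("metadata error: no 'groups' entry in ", path)
  gs <- meta$groups
  if (is.data.frame(gs)) gs <- split(gs, seq_len(nrow(gs)))
  groups <- lapply(gs, function(g) {
    pid <- if (is.null(g$protein_id) || length(g$protein_id) == 0 ||
               is.na(g$protein_id[[1]])) NA_integer_ else as.integer(g$protein_id[[1]])
    bead_group(as.character(g$name[[1]]), unlist(g$indices),
               as.character(g$role[[1]]), pid)
  })
  if (!is.null(n_beads)) {
    for (g in groups)
      if (any(g$indices > n_beads))
        stop("metadata error: group '", g$name, "' references bead index ",
             max(g$indices), " outside 1..", n_beads)
  }
  unname(groups)
}

#' Write a bead-group metadata sidecar
#' @param groups List of [bead_group()] objects.
#' @param path Output JSON path.
#' @export
write_group_metadata <- function(groups, path) {
  jsonlite::write_json(
    list(groups = lapply(groups, function(g)
      list(name = g$name, role = g$role, indices = g$indices,
           protein_id = if (is.na(g$protein_id)) NULL else g$protein_id))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gro")) return("gro")
  if (ext %in% c("pdb")) return("pdb")
  stop("unsupported trajectory format: '.", ext, "' (supported: gro, pdb)")
}

#' Load a trajectory from disk
#'
#' Reads coordinates from a GRO (single- or multi-frame, nm) or multi-frame
#' PDB file (Angstrom, converted to nm) together with a JSON group-metadata
#' sidecar naming bead roles.
#'
#' @param coord_path Coordinate file path (`.gro` or `.pdb`).
#' @param metadata_path Optional JSON sidecar path; `NULL` for no groups.
#' @param dt Frame spacing override in microseconds; if `NULL`, timestamps
#'   embedded in the file (GRO `t=` titles) or unit spacing are used.
#' @return A [trajectory()].
#' @export
load_trajectory <- function(coord_path, metadata_path = NULL, dt = NULL) {
  fmt <- format_from_path(coord_path)
  raw <- switch(fmt, gro = read_gro_frames(coord_path),
                pdb = read_pdb_frames(coord_path))
  times <- raw$times
  if (!is.null(dt)) times <- (seq_len(dim(raw$coords)[3]) - 1) * dt
  groups <- if (!is.null(metadata_path))
    read_group_metadata(metadata_path, n_beads = dim(raw$coords)[1]) else list()
  trajectory(raw$coords, raw$box, times, groups)
}

#' Write a trajectory to disk
#'
#' @param traj A [trajectory()].
#' @param coord_path Output coordinate path.
#' @param format `"gro"` or `"pdb"`; inferred from the extension if `NULL`.
#' @param metadata_path Optional path for the JSON group sidecar.
#' @return `coord_path`, invisibly.
#' @export
write_trajectory <- function(traj, coord_path, format = NULL,
                             metadata_path = NULL) {
  if (n_frames(traj) == 0L) stop("write_trajectory: trajectory has no frames")
  fmt <- if (is.null(format)) format_from_path(coord_path) else match.arg(format, c("gro", "pdb"))
  switch(fmt,
         gro = write_gro_frames(traj$coords, traj$box, traj$times, coord_path),
         pdb = write_pdb_frames(traj$coords, traj$box, traj$times, coord_path))
  if (!is.null(metadata_path)) write_group_metadata(traj$groups, metadata_path)
  invisible(coord_path)
}
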
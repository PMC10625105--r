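# Periodic 2D Voronoi cell areas by half-plane clipping. Each seed's cell
# starts as a generous bounding square and is cut by the perpendicular
# bisector of every sufficiently close seed (periodic ghost images
# included); the result is the exact Voronoi cell, so cell areas tile the
# box to floating-point accuracy.

clip_halfplane <- function(poly, m, d) {
  # keep the side (x - m) . d <= 0
  s <- (poly[, 1] - m[1]) * d[1] + (poly[, 2] - m[2]) * d[2]
  n <- nrow(poly)
  if (n == 0L) return(poly)
  keep <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (s[i] <= 0) { k <- k + 1L; keep[[k]] <- poly[i, ] }
    if ((s[i] < 0) != (s[j] < 0)) {
      t <- s[i] / (s[i] - s[j])
      k <- k + 1L; keep[[k]] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (k == 0L) return(matrix(numeric(0), 0, 2))
  do.call(rbind, keep[seq_len(k)])
}

shoelace_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

#' Periodic Voronoi cell areas in 2D
#'
#' Computes the area of every seed's Voronoi cell under periodic boundary
#' conditions in both lateral directions. Cell areas tile the box exactly:
#' their sum equals `Lx * Ly` to floating-point accuracy.
#'
#' @param points `n x 2` matrix of seed positions (nm); wrapped into the
#'   box internally. Needs `n >= 4`.
#' @param box `c(Lx, Ly)`.
#' @return Numeric vector of `n` cell areas (nm^2).
#' @export
voronoi_cell_areas <- function(points, box) {
  points <- wrap_lateral(points, box)
  n <- nrow(points)
  if (n < 4L) stop("voronoi_cell_areas: need at least 4 seeds")
  shifts <- as.matrix(expand.grid(sx = c(-1, 0, 1), sy = c(-1, 0, 1)))
  ghosts <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k)
    cbind(points[, 1] + shifts[k, 1] * box[1],
          points[, 2] + shifts[k, 2] * box[2])))
  rc0 <- 3 * sqrt(box[1] * box[2] / n)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    s <- points[i, ]
    rc <- rc0
    repeat {
      if (2 * sqrt(2) * rc > min(box) * 1.5 && rc > max(box))
        stop("voronoi_cell_areas: cell exceeds the periodic image margin")
      dx <- ghosts[, 1] - s[1]; dy <- ghosts[, 2] - s[2]
      d2 <- dx * dx + dy * dy
      nb <- which(d2 > 1e-18 & d2 <= (2 * sqrt(2) * rc)^2)
      nb <- nb[order(d2[nb])]
      poly <- rbind(s + c(-rc, -rc), s + c(rc, -rc),
                    s + c(rc, rc), s + c(-rc, rc))
      for (q in nb) {
        qp <- ghosts[q, ]
        poly <- clip_halfplane(poly, (s + qp) / 2, qp - s)
        if (nrow(poly) == 0L) break
      }
      if (nrow(poly) == 0L) { areas[i] <- 0; break }
      sup <- max(abs(poly[, 1] - s[1]), abs(poly[, 2] - s[2]))
      if (sup < rc - 1e-9) { areas[i] <- shoelace_area(poly); break }
      rc <- 2 * rc  # cell touched the bounding square: enlarge and redo
    }
  }
  areas
}
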
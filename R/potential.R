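# Boltzmann inversion of pair-distance distributions into an effective
# interaction potential (potential of mean force). In two dimensions the
# distance histogram carries a 2*pi*l Jacobian: an ideal (non-interacting)
# gas of proteins has p(l) proportional to l, not flat. The default
# convention therefore divides p(l) by 2*pi*l before taking the log, which
# makes the ideal-gas potential flat; the literal no-Jacobian form is
# available behind a flag.

#' Normalized histogram density of pair distances
#'
#' @param distances Numeric sample of centre-to-centre distances (nm),
#'   at least 100 values.
#' @param bin_width Histogram bin width (nm), default 0.25.
#' @param range Support `c(min, max)`; defaults to `c(0, max(distances))`.
#' @return A data frame with `l` (bin centres), `p` (density, integrates
#'   to 1 over the support), `count`.
#' @export
distance_histogram <- function(distances, bin_width = 0.25, range = NULL) {
  distances <- distances[is.finite(distances)]
  if (length(distances) < 100L)
    stop("distance_histogram: need at least 100 samples")
  if (bin_width <= 0) stop("distance_histogram: bin width must be positive")
  if (is.null(range)) range <- c(0, max(distances))
  inside <- distances >= range[1] & distances <= range[2]
  if (!any(inside)) stop("distance_histogram: all samples outside range")
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  h <- graphics::hist(distances[inside], breaks = breaks, plot = FALSE)
  data.frame(l = h$mids, p = h$density, count = h$counts)
}

#' Boltzmann-invert a distance density into an effective potential
#'
#' With the Jacobian convention (default), `V(l) = -kBT log(p(l) / (2 pi
#' l)) + const`; without it, `V(l) = -kBT (log p(l) - log Z)` literally.
#' The normalization `Z` is evaluated by trapezoid quadrature of
#' `exp(-V/kBT) 2 pi l` over the support, and the additive gauge constant
#' is fixed so that the mean of `V` over the outer 20% of the support is
#' zero. Bins with `p = 0` have undefined (masked) potential.
#'
#' @param hist A [distance_histogram()] data frame (or any data frame with
#'   columns `l`, `p`).
#' @param jacobian Divide by the `2 pi l` measure before the log (default
#'   TRUE).
#' @param temperature Temperature in kBT units (default 1).
#' @return A `potential_curve` data frame with columns `l`, `p`, `V`
#'   (kBT; `NA` where masked), and attributes `Z`, `jacobian`,
#'   `offset` (the additive constant that was subtracted).
#' @export
boltzmann_invert <- function(hist, jacobian = TRUE, temperature = 1) {
  l <- hist$l; p <- hist$p
  occupied <- p > 0
  if (sum(occupied) < 3L)
    stop("boltzmann_invert: fewer than 3 occupied bins")
  V <- rep(NA_real_, length(l))
  V[occupied] <- if (jacobian)
    -temperature * log(p[occupied] / (2 * pi * l[occupied]))
  else
    -temperature * log(p[occupied])
  # gauge: zero the outer 20% of the support
  lmax <- max(l); lmin <- min(l)
  tail_sel <- occupied & l >= lmax - 0.2 * (lmax - lmin)
  offset <- if (any(tail_sel)) mean(V[tail_sel]) else
    mean(V[occupied][which.max(l[occupied])])
  V <- V - offset
  ok <- is.finite(V)
  Z <- if (sum(ok) >= 2L) {
    lv <- l[ok]; iv <- exp(-V[ok] / temperature) * 2 * pi * lv
    sum(diff(lv) * (iv[-1] + iv[-length(iv)]) / 2)
  } else NA_real_
  out <- data.frame(l = l, p = p, V = V)
  attr(out, "Z") <- Z
  attr(out, "jacobian") <- jacobian
  attr(out, "offset") <- offset
  class(out) <- c("potential_curve", "data.frame")
  out
}

#' Depth and location of the interaction well
#'
#' The well location is the argmin of `V`, refined parabolically over the
#' minimum bin and its neighbours; the depth is measured from the zeroed
#' tail (`0 - V_min`). A flat curve reports depth 0 with an undefined
#' location.
#'
#' @param curve A [boltzmann_invert()] result (>= 5 defined bins).
#' @param flat_tol Curves whose total variation is below this (kBT) are
#'   reported as flat (default 0.05).
#' @return List with `depth` (kBT), `location` (nm, `NA` if flat), and
#'   `flat`.
#' @export
well_parameters <- function(curve, flat_tol = 0.05) {
  ok <- is.finite(curve$V)
  if (sum(ok) < 5L) stop("well_parameters: fewer than 5 defined bins")
  l <- curve$l[ok]; V <- curve$V[ok]
  if (max(V) - min(V) < flat_tol)
    return(list(depth = 0, location = NA_real_, flat = TRUE))
  i <- which.min(V)
  loc <- l[i]
  if (i > 1L && i < length(V)) {
    # parabolic refinement through the minimum and its neighbours
    y1 <- V[i - 1]; y2 <- V[i]; y3 <- V[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom > 0) {
      delta <- 0.5 * (y1 - y3) / denom
      h <- (l[i + 1] - l[i - 1]) / 2
      loc <- l[i] + delta * h
      Vmin <- y2 - 0.25 * (y1 - y3) * delta
      return(list(depth = -Vmin, location = loc, flat = FALSE))
    }
  }
  list(depth = -V[i], location = loc, flat = FALSE)
}
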
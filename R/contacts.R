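# Inter-protein distance series, clustering frequency and close-contact
# lifetimes. Two thresholds from the study design: 2 nm (loose clustering,
# lipid-mediated) and 0.7 nm (close contact, no intervening lipids), both on
# the minimum inter-bead distance; the Boltzmann inversion uses the
# centre-to-centre metric.

#' Per-frame inter-protein distances under two metrics
#'
#' For every unordered protein pair and frame, the minimum-image lateral
#' distances (a) minimised over all inter-protein bead pairs (`min_bead`)
#' and (b) between centres of mass (`com`).
#'
#' @param traj A [trajectory()] with >= 2 protein groups.
#' @return A `distance_series` data frame with columns `frame`, `pair_i`,
#'   `pair_j`, `min_bead`, `com`; frame spacing attached as attribute `dt`.
#' @export
distance_series <- function(traj) {
  prot <- groups_by_role(traj, "protein")
  prot <- prot[order(vapply(prot, `[[`, integer(1), "protein_id"))]
  np <- length(prot)
  nf <- n_frames(traj)
  box <- traj$box
  if (np < 2L) {
    out <- data.frame(frame = integer(0), pair_i = integer(0),
                      pair_j = integer(0), min_bead = numeric(0),
                      com = numeric(0))
    attr(out, "dt") <- traj_dt(traj)
    class(out) <- c("distance_series", "data.frame")
    return(out)
  }
  pairs <- utils::combn(np, 2)
  recs <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ai <- prot[[i]]$indices; aj <- prot[[j]]$indices
    minb <- comd <- numeric(nf)
    for (f in seq_len(nf)) {
      ci <- matrix(traj$coords[ai, 1:2, f], ncol = 2)
      cj <- matrix(traj$coords[aj, 1:2, f], ncol = 2)
      dx <- min_image_dx(outer(ci[, 1], cj[, 1], `-`), box[1])
      dy <- min_image_dx(outer(ci[, 2], cj[, 2], `-`), box[2])
      minb[f] <- sqrt(min(dx * dx + dy * dy))
      comd[f] <- lateral_distance(colMeans(ci), colMeans(cj), box)
    }
    recs[[k]] <- data.frame(frame = seq_len(nf),
                            pair_i = prot[[i]]$protein_id,
                            pair_j = prot[[j]]$protein_id,
                            min_bead = minb, com = comd)
  }
  out <- do.call(rbind, recs)
  attr(out, "dt") <- traj_dt(traj)
  class(out) <- c("distance_series", "data.frame")
  out
}

#' Fraction of observations below a clustering threshold
#'
#' The frequency of spatial clustering: the fraction of (frame, pair)
#' observations with distance below `threshold`. The confidence interval
#' is computed with the autocorrelation-aware [subsampled_bootstrap()] on
#' the per-frame any-pair-clustered indicator.
#'
#' @param ds A [distance_series()].
#' @param threshold Distance threshold in nm (default 2, the loose
#'   clustering criterion).
#' @param metric `"min_bead"` (default) or `"com"`.
#' @param seed Bootstrap seed.
#' @return List with `fraction`, `ci` (95%, from the per-frame
#'   clustered-pair fraction series, whose time mean equals `fraction`),
#'   the per-frame fraction series, and the per-frame any-pair indicator.
#' @export
cluster_fraction <- function(ds, threshold = 2.0, metric = "min_bead",
                             seed = 1L) {
  if (nrow(ds) == 0L) stop("cluster_fraction: empty distance series")
  d <- ds[[match.arg(metric, c("min_bead", "com"))]]
  frac <- mean(d < threshold)
  series <- as.numeric(tapply(d < threshold, ds$frame, mean))
  any_series <- as.numeric(tapply(d < threshold, ds$frame, any))
  ci <- if (stats::var(series) == 0) c(frac, frac) else
    tryCatch(subsampled_bootstrap(series, seed = seed)$ci,
             error = function(e) {
               warning("cluster_fraction: ", conditionMessage(e),
                       "; CI unavailable", call. = FALSE)
               c(NA_real_, NA_real_)
             })
  list(fraction = frac, ci = ci, per_frame_fraction = series,
       per_frame_any = any_series)
}

#' Close-contact events from a distance series
#'
#' Maximal runs of below-threshold frames per protein pair; runs separated
#' by gaps of at most `debounce` frames are merged. Events truncated by
#' the trajectory boundary are flagged.
#'
#' @param ds A [distance_series()].
#' @param threshold Contact threshold in nm (default 0.7, the
#'   close-contact criterion).
#' @param metric `"min_bead"` (default) or `"com"`.
#' @param debounce Maximum gap (frames) across which runs are merged.
#' @return A `contact_events` data frame with columns `pair_i`, `pair_j`,
#'   `start`, `end` (half-open frame interval), `duration_frames`,
#'   `duration` (us, `NA` if the trajectory has no dt), `truncated`.
#' @export
contact_events <- function(ds, threshold = 0.7, metric = "min_bead",
                           debounce = 0L) {
  if (threshold <= 0) stop("contact_events: threshold must be positive")
  metric <- match.arg(metric, c("min_bead", "com"))
  dt <- attr(ds, "dt")
  out <- list()
  for (key in split(seq_len(nrow(ds)),
                    interaction(ds$pair_i, ds$pair_j, drop = TRUE))) {
    sub <- ds[key, ]
    sub <- sub[order(sub$frame), ]
    below <- sub[[metric]] < threshold
    if (debounce > 0L) {
      r <- rle(below)
      gap <- !r$values & r$lengths <= debounce
      # gaps at the ends are not merged
      gap[c(1L, length(gap))] <- FALSE
      r$values[gap] <- TRUE
      below <- inverse.rle(r)
    }
    r <- rle(below)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    if (length(sel) == 0L) next
    nfr <- length(below)
    out[[length(out) + 1L]] <- data.frame(
      pair_i = sub$pair_i[1], pair_j = sub$pair_j[1],
      start = starts[sel], end = ends[sel] + 1L,
      duration_frames = r$lengths[sel],
      duration = if (is.na(dt)) NA_real_ else r$lengths[sel] * dt,
      truncated = starts[sel] == 1L | ends[sel] == nfr)
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(pair_i = integer(0), pair_j = integer(0), start = integer(0),
               end = integer(0), duration_frames = integer(0),
               duration = numeric(0), truncated = logical(0))
  rownames(ev) <- NULL
  class(ev) <- c("contact_events", "data.frame")
  ev
}

#' Build a distance series from a boolean contact indicator
#'
#' Convenience for testing: converts an in-contact indicator (as produced
#' by [generate_contact_series()]) into a one-pair [distance_series()]
#' with distance 0 when in contact and 10 nm otherwise.
#'
#' @param series Logical vector.
#' @param dt Frame spacing (us).
#' @return A `distance_series`.
#' @export
series_to_distances <- function(series, dt = 1) {
  out <- data.frame(frame = seq_along(series), pair_i = 1L, pair_j = 2L,
                    min_bead = ifelse(series, 0, 10),
                    com = ifelse(series, 0, 10))
  attr(out, "dt") <- dt
  class(out) <- c("distance_series", "data.frame")
  out
}

#' Self-weighted mean contact lifetime
#'
#' The average of event lifetimes weighted by the lifetimes themselves,
#' `sum(tau^2) / sum(tau)`. Always at least the arithmetic mean lifetime,
#' with equality iff all durations are equal.
#'
#' @param events A [contact_events()] data frame (>= 1 event), or a
#'   numeric vector of durations.
#' @param include_truncated Include boundary-truncated events (default
#'   TRUE).
#' @return Self-weighted lifetime in the units of `duration` (us for
#'   trajectory-derived events).
#' @export
weighted_lifetime <- function(events, include_truncated = TRUE) {
  tau <- if (is.numeric(events)) events else {
    ev <- events
    if (!include_truncated) ev <- ev[!ev$truncated, ]
    if (all(is.na(ev$duration))) ev$duration_frames else ev$duration
  }
  tau <- tau[!is.na(tau)]
  if (length(tau) == 0L)
    stop("weighted_lifetime: no events; lifetime undefined")
  sum(tau^2) / sum(tau)
}
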
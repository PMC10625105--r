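# Tether-pulling (experimental-side) computations: the sorting ratio from
# two-channel fluorescence of tube versus vesicle, the tube radius from the
# aspiration-length trade-off, the fluorescence-radius calibration, binned
# sorting-versus-curvature curves, and the spontaneous-curvature/wedge-angle
# arithmetic that links protein shape to curvature sorting.

#' Construct a sorting record
#'
#' Background-subtracted fluorescence intensities of the protein and lipid
#' channels in the tube and on the vesicle (GUV), with optional
#' polarization correction factors and tube radius.
#'
#' @param I_tube_prot,I_GUV_prot,I_tube_lip,I_GUV_lip Positive intensities
#'   (arbitrary units).
#' @param PCF1,PCF2 Polarization correction factors (> 0, default 1).
#' @param r_t Tube radius (nm), optional.
#' @param condition Condition label.
#' @return A `sorting_record` list.
#' @export
sorting_record <- function(I_tube_prot, I_GUV_prot, I_tube_lip, I_GUV_lip,
                           PCF1 = 1, PCF2 = 1, r_t = NA_real_,
                           condition = "") {
  vals <- c(I_tube_prot, I_GUV_prot, I_tube_lip, I_GUV_lip)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("sorting_record: intensities must be positive")
  if (PCF1 <= 0 || PCF2 <= 0) stop("sorting_record: PCFs must be positive")
  structure(list(I_tube_prot = I_tube_prot, I_GUV_prot = I_GUV_prot,
                 I_tube_lip = I_tube_lip, I_GUV_lip = I_GUV_lip,
                 PCF1 = PCF1, PCF2 = PCF2, r_t = r_t,
                 condition = condition),
            class = "sorting_record")
}

#' Sorting ratio of a tube-pulling record
#'
#' `S = [PCF1 (I_tube_prot / I_GUV_prot)] / [PCF2 (I_tube_lip /
#' I_GUV_lip)]`: the protein-to-lipid composition of the tube normalized
#' to the vesicle. `S = 1` means no curvature preference; `S > 1` means
#' enrichment of the protein in the highly curved tube.
#'
#' @param rec A [sorting_record()].
#' @return Sorting ratio (dimensionless).
#' @export
sorting_ratio <- function(rec) {
  (rec$PCF1 * rec$I_tube_prot / rec$I_GUV_prot) /
    (rec$PCF2 * rec$I_tube_lip / rec$I_GUV_lip)
}

#' Tube radius from the aspiration-length trade-off
#'
#' When the tube lengthens by `dL_t`, membrane is drawn out of the
#' aspirated protrusion, which shortens by `dL_p`; the slope gives the
#' tube radius as `r_t = -(dL_p/dL_t) R_p / (1 - R_p/R_V)`, with pipette
#' radius `R_p` and vesicle radius `R_V`.
#'
#' @param L_t,L_p Paired tube-length / protrusion-length series (um),
#'   length >= 2.
#' @param R_p,R_V Pipette and vesicle radii (um), `R_p < R_V`.
#' @return Tube radius in nm.
#' @export
tube_radius_from_aspiration <- function(L_t, L_p, R_p, R_V) {
  if (length(L_t) != length(L_p) || length(L_t) < 2L)
    stop("tube_radius_from_aspiration: need paired series of length >= 2")
  if (R_p >= R_V) stop("tube_radius_from_aspiration: R_p must be < R_V")
  slope <- stats::cov(L_t, L_p) / stats::var(L_t)
  if (slope >= 0)
    stop("tube_radius_from_aspiration: non-negative slope dL_p/dL_t ",
         "(no tube material drawn)")
  r_um <- -slope * R_p / (1 - R_p / R_V)
  r_um * 1000
}

#' Calibration factor linking tube radius to lipid fluorescence
#'
#' Least-squares fit through the origin of `r_t = F * (I_tube_lip /
#' I_GUV_lip)`; thereafter the tube radius can be read directly off the
#' lipid channel.
#'
#' @param r_t Tube radii (nm), length >= 2.
#' @param ratio Lipid intensity ratios `I_tube_lip / I_GUV_lip`.
#' @return Calibration factor `F` (nm).
#' @export
calibrate_radius_factor <- function(r_t, ratio) {
  if (length(r_t) != length(ratio) || length(r_t) < 2L)
    stop("calibrate_radius_factor: need >= 2 (radius, ratio) pairs")
  if (all(ratio == 0)) stop("calibrate_radius_factor: degenerate ratios")
  sum(ratio * r_t) / sum(ratio^2)
}

#' Radius from lipid fluorescence via a calibration factor
#' @param ratio Lipid intensity ratio(s).
#' @param F Calibration factor from [calibrate_radius_factor()].
#' @return Radius in nm.
#' @export
radius_from_fluorescence <- function(ratio, F) F * ratio

#' Bin sorting ratios by tube curvature
#'
#' Groups records by the curvature `c = 1/r_t` into the given bins and
#' reports mean sorting with a bootstrap CI per bin, plus the headline
#' window average over tubes with `r_t = 50 +/- 20 nm`.
#'
#' @param records List of [sorting_record()]s, each with a finite `r_t`.
#' @param bin_edges Curvature bin edges (1/nm).
#' @param seed Bootstrap seed.
#' @return List with `curve` (data frame: `c_mid`, `S`, `ci_lo`, `ci_hi`,
#'   `n`; empty bins are masked out) and `window_50pm20` (mean sorting for
#'   records with radii in [30, 70] nm, `NA` if none).
#' @export
bin_sorting_vs_curvature <- function(records,
                                     bin_edges = seq(0, 0.08, by = 0.01),
                                     seed = 1L) {
  r_t <- vapply(records, `[[`, numeric(1), "r_t")
  if (any(!is.finite(r_t) | r_t <= 0))
    stop("bin_sorting_vs_curvature: every record needs a positive r_t")
  S <- vapply(records, sorting_ratio, numeric(1))
  cc <- 1 / r_t
  bin <- cut(cc, bin_edges, include.lowest = TRUE)
  rows <- lapply(levels(bin), function(lv) {
    sel <- which(bin == lv)
    if (length(sel) == 0L) return(NULL)
    i <- match(lv, levels(bin))
    s <- S[sel]
    ci <- if (length(s) >= 5L && stats::var(s) > 0)
      subsampled_bootstrap(s, seed = seed, I = 1)$ci else c(NA_real_, NA_real_)
    data.frame(c_mid = (bin_edges[i] + bin_edges[i + 1]) / 2,
               S = mean(s), ci_lo = ci[1], ci_hi = ci[2], n = length(s))
  })
  curve <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  win <- which(r_t >= 30 & r_t <= 70)
  list(curve = curve,
       window_50pm20 = if (length(win)) mean(S[win]) else NA_real_)
}

#' E-fold sorting curvature from a binned sorting curve
#'
#' Under the exponential sorting model `S(c) = exp(c / c_shape)`, the
#' e-fold curvature is the reciprocal slope of `log S` versus `c`,
#' estimated by least squares over the binned curve.
#'
#' @param curve The `curve` data frame from [bin_sorting_vs_curvature()].
#' @return Estimated `c_shape` (1/nm).
#' @export
estimate_cshape <- function(curve) {
  ok <- is.finite(curve$S) & curve$S > 0
  if (sum(ok) < 2L) stop("estimate_cshape: need >= 2 bins")
  fit <- stats::lm(log(S) ~ c_mid, data = curve[ok, ],
                   weights = curve$n[ok])
  1 / unname(stats::coef(fit)[2])
}

#' Spontaneous curvature of a conical membrane inclusion
#'
#' A wedge-shaped (conical) inclusion of radius `R_P` and wedge angle
#' `phi_P` imposes a preferred membrane curvature
#' `c_P = sin(phi_P / 2) / R_P`.
#'
#' @param phi_P Wedge angle in degrees, in `[0, 180]`.
#' @param R_P Inclusion radius (nm), > 0.
#' @return Spontaneous curvature in 1/nm.
#' @export
spontaneous_curvature_from_wedge <- function(phi_P, R_P) {
  if (any(phi_P < 0 | phi_P > 180))
    stop("spontaneous_curvature_from_wedge: phi_P must be in [0, 180]")
  if (any(R_P <= 0)) stop("spontaneous_curvature_from_wedge: R_P must be > 0")
  sin(phi_P / 2 * pi / 180) / R_P
}

#' Wedge angle from a spontaneous curvature
#'
#' Exact inverse of [spontaneous_curvature_from_wedge()]:
#' `phi_P = 2 asin(c_P R_P)`.
#'
#' @param c_P Spontaneous curvature (1/nm).
#' @param R_P Inclusion radius (nm).
#' @return Wedge angle in degrees.
#' @export
wedge_from_curvature <- function(c_P, R_P) {
  x <- c_P * R_P
  if (any(abs(x) > 1))
    stop("wedge_from_curvature: |c_P * R_P| > 1 is unphysical")
  2 * asin(x) * 180 / pi
}

#' E-fold sorting curvature of an inclusion
#'
#' The curvature at which the sorting ratio of an inclusion of in-plane
#' area `A_p`, in a membrane of bending modulus `kappa`, with spontaneous
#' curvature `c_P`, changes by a factor of e:
#' `c_shape = kBT / (A_p kappa c_P)` with `kappa` in kBT units.
#'
#' @param A_p Inclusion area (nm^2), > 0.
#' @param kappa Membrane bending modulus (kBT), > 0.
#' @param c_P Spontaneous curvature (1/nm), > 0.
#' @return `c_shape` in 1/nm.
#' @export
efold_sorting_curvature <- function(A_p, kappa, c_P) {
  if (any(c(A_p, kappa, c_P) <= 0))
    stop("efold_sorting_curvature: all inputs must be positive")
  1 / (A_p * kappa * c_P)
}

#' Spontaneous curvature from an observed e-fold sorting curvature
#'
#' Inverts the e-fold relation: `c_P = kBT / (A_p kappa c_shape)`.
#'
#' @param A_p Inclusion area (nm^2).
#' @param kappa Bending modulus (kBT).
#' @param c_shape Observed e-fold sorting curvature (1/nm).
#' @return `c_P` in 1/nm.
#' @export
curvature_from_efold <- function(A_p, kappa, c_shape) {
  if (any(c(A_p, kappa, c_shape) <= 0))
    stop("curvature_from_efold: all inputs must be positive")
  1 / (A_p * kappa * c_shape)
}

#' Read sorting records from a CSV table
#'
#' Expected columns: `I_tube_prot`, `I_GUV_prot`, `I_tube_lip`,
#' `I_GUV_lip`; optional `PCF1`, `PCF2`, `r_t`, `condition`.
#'
#' @param path CSV path.
#' @return List of [sorting_record()]s.
#' @export
read_sorting_records <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("I_tube_prot", "I_GUV_prot", "I_tube_lip", "I_GUV_lip")
  if (!all(needed %in% names(df)))
    stop("read_sorting_records: missing columns ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    sorting_record(df$I_tube_prot[i], df$I_GUV_prot[i], df$I_tube_lip[i],
                   df$I_GUV_lip[i],
                   PCF1 = if ("PCF1" %in% names(df)) df$PCF1[i] else 1,
                   PCF2 = if ("PCF2" %in% names(df)) df$PCF2[i] else 1,
                   r_t = if ("r_t" %in% names(df)) df$r_t[i] else NA_real_,
                   condition = if ("condition" %in% names(df))
                     as.character(df$condition[i]) else ""))
}

#' Read a tube-pull record from a CSV table
#'
#' Expected columns: `L_t`, `L_p` (um); radii are passed separately or as
#' columns `R_p`, `R_V` (constant within the file).
#'
#' @param path CSV path.
#' @param R_p,R_V Pipette and vesicle radii (um); defaults taken from the
#'   file columns if present.
#' @return List with `L_t`, `L_p`, `R_p`, `R_V`.
#' @export
read_tubepull_record <- function(path, R_p = NULL, R_V = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("L_t", "L_p") %in% names(df)))
    stop("read_tubepull_record: missing columns L_t, L_p")
  if (is.null(R_p)) R_p <- df$R_p[1]
  if (is.null(R_V)) R_V <- df$R_V[1]
  list(L_t = df$L_t, L_p = df$L_p, R_p = R_p, R_V = R_V)
}
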
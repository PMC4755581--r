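# Geometric parameter extraction: length, width, thickness, slenderness,
# in-plane angle beta (circumferential Y = 0, range [-90, 90)) and
# out-of-plane tilt angle alpha (range [0, 90]).

#' Project a volume on the XY plane and fit an equivalent ellipse
#'
#' The binary projection of a reconstructed cell approximates an ellipse;
#' its axes and orientation come from second-order image moments.
#'
#' @param volume a \linkS4class{BinaryVolume}.
#' @return A list: \code{mask} (2D logical projection), \code{centroid}
#'   (px), \code{majorAxis}/\code{minorAxis} (unit 2D vectors),
#'   \code{axisRatio}, \code{indeterminate} (TRUE for near-isotropic
#'   projections, axis ratio < 1.05).
#' @export
projectAndFit <- function(volume) {
  stopifnot(is(volume, "BinaryVolume"))
  proj <- apply(volume@voxels, c(1, 2), any)
  if (!any(proj)) stop("empty projection")
  idx <- which(proj, arr.ind = TRUE)
  ctr <- colMeans(idx)
  cc <- sweep(idx, 2, ctr)
  # add the 1/12 px variance of a unit pixel so single-row masks stay valid
  C <- crossprod(cc) / nrow(cc) + diag(2) / 12
  ev <- eigen(C, symmetric = TRUE)
  ratio <- sqrt(ev$values[1] / max(ev$values[2], 1e-12))
  list(mask = proj, centroid = ctr,
       majorAxis = ev$vectors[, 1], minorAxis = ev$vectors[, 2],
       axisRatio = ratio, indeterminate = ratio < 1.05)
}

#' In-plane orientation angle of a fitted region
#'
#' Signed angle between the projected long axis and the circumferential (Y)
#' direction, folded into [-90, 90); exactly +/-90 maps to -90.
#'
#' @param region result of \code{\link{projectAndFit}}.
#' @return beta in degrees, or NA (with a warning) when the projection is
#'   near-isotropic.
#' @export
inPlaneAngle <- function(region) {
  if (isTRUE(region$indeterminate)) {
    warning("orientation indeterminate: projection axis ratio < 1.05")
    return(NA_real_)
  }
  u <- region$majorAxis
  fold90(rad2deg(atan2(u[1], u[2])))
}

#' Length, width and thickness of a binary volume
#'
#' Length is the extent of the XY projection along the fitted long axis and
#' width the mean perpendicular chord over the central 50\% of the length
#' (averaging several positions suppresses pixelation noise at the tapered
#' ends). Thickness is the maximal per-(x,y)-column z extent. All values are
#' in micrometres via the volume's spacing.
#'
#' @param volume a \linkS4class{BinaryVolume}.
#' @param region optional precomputed \code{\link{projectAndFit}} result.
#' @return Named numeric vector \code{c(L, W, T)} in micrometres.
#' @export
lengthWidthThickness <- function(volume, region = NULL) {
  stopifnot(is(volume, "BinaryVolume"))
  sp <- volume@spacing
  if (abs(sp[1] - sp[2]) > 1e-9)
    stop("anisotropic in-plane spacing is not supported")
  if (is.null(region)) region <- projectAndFit(volume)
  idx <- which(region$mask, arr.ind = TRUE)
  u <- region$majorAxis
  w <- region$minorAxis
  s <- (idx[, 1] - region$centroid[1]) * u[1] +
    (idx[, 2] - region$centroid[2]) * u[2]
  t <- (idx[, 1] - region$centroid[1]) * w[1] +
    (idx[, 2] - region$centroid[2]) * w[2]
  L <- (max(s) - min(s) + 1) * sp[1]
  # average perpendicular chord over the central 50% of the long axis; the
  # chord is the pixel count per unit-length axial bin (area-based, robust
  # to single-pixel boundary jitter) and the average is the median across
  # bins, insensitive to a localized bulge where a neighboring cell crossed
  mid <- s >= stats::quantile(s, 0.25) & s <= stats::quantile(s, 0.75)
  bins <- floor(s[mid])                  # uniform 1-px bins
  chord <- tapply(t[mid], bins, length)
  W <- stats::median(chord) * sp[1]
  # thickness: z extent of occupied (x, y) voxel columns, taken as the 98th
  # percentile (type-1 quantile, exact on uniform slabs) so one or two
  # scatter-stretched columns cannot set it
  zext <- apply(volume@voxels, c(1, 2), function(col) {
    wz <- which(col)
    if (!length(wz)) 0L else max(wz) - min(wz) + 1L
  })
  Tz <- stats::quantile(zext[zext > 0], 0.98, names = FALSE, type = 1) * sp[3]
  c(L = L, W = W, T = Tz)
}

#' Out-of-plane tilt angle from 3D surface coordinates
#'
#' Forms the 3-by-3 covariance matrix of the surface point coordinates and
#' takes the first principal eigenvector as the tilt direction; alpha is the
#' arcsine of its |z| component, in [0, 90] degrees. The
#' \code{normalized} variant rescales each coordinate axis to unit variance
#' before the decomposition (size normalization).
#'
#' @param coords n-by-3 matrix of surface coordinates (physical units).
#' @param normalized use size-normalized coordinates (default FALSE).
#' @return alpha in degrees, with the unit principal vector attached as
#'   attribute \code{"axis"}; NA (with a warning) for degenerate isotropic
#'   point sets.
#' @export
tiltAngle <- function(coords, normalized = FALSE) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4) stop("need at least 4 points")
  C <- stats::cov(coords)
  if (normalized) {
    s <- sqrt(diag(C))
    s[s < 1e-12] <- 1
    C <- C / tcrossprod(s)
  }
  ev <- eigen(C, symmetric = TRUE)
  if (ev$values[1] < 1e-12 || ev$values[1] / max(ev$values[2], 1e-12) < 1.05) {
    warning("tilt angle indeterminate: near-isotropic covariance")
    return(NA_real_)
  }
  v1 <- ev$vectors[, 1]
  v1 <- v1 / sqrt(sum(v1^2))
  alpha <- rad2deg(asin(min(1, abs(v1[3]))))
  attr(alpha, "axis") <- v1
  alpha
}

#' Tilt angle of a binary volume
#'
#' Extracts the surface voxel coordinates (scaled by spacing) and applies
#' \code{\link{tiltAngle}}.
#'
#' @param volume a \linkS4class{BinaryVolume}.
#' @param normalized size-normalized variant flag.
#' @return alpha in degrees.
#' @export
tiltAngleOfVolume <- function(volume, normalized = FALSE) {
  stopifnot(is(volume, "BinaryVolume"))
  xyz <- surfaceVoxelCoords(volume@voxels)
  if (nrow(xyz) < 4) stop("volume too small for tilt estimation")
  tiltAngle(sweep(xyz, 2, volume@spacing, "*"), normalized = normalized)
}

#' Full morphometry of one reconstructed cell volume
#'
#' @param volume the cell's \linkS4class{BinaryVolume}.
#' @param nucleusVolume optional nucleus \linkS4class{BinaryVolume}; when
#'   given, the tilt angle is measured on the nucleus (the default choice
#'   for population summaries), otherwise on the cell volume.
#' @return One-row data.frame: L, W, T (um), slenderness, beta, alpha
#'   (degrees).
#' @export
measureCell <- function(volume, nucleusVolume = NULL) {
  region <- projectAndFit(volume)
  lwt <- lengthWidthThickness(volume, region)
  beta <- inPlaneAngle(region)
  alphaSrc <- if (is.null(nucleusVolume)) volume else nucleusVolume
  alpha <- tryCatch(as.numeric(tiltAngleOfVolume(alphaSrc)),
                    warning = function(w) NA_real_,
                    error = function(e) NA_real_)
  data.frame(L = lwt[["L"]], W = lwt[["W"]], T = lwt[["T"]],
             slenderness = lwt[["L"]] / lwt[["W"]],
             beta = beta, alpha = alpha)
}

#' Fit a two-component Gaussian mixture to in-plane angles
#'
#' VSMC in-plane orientations are bimodal (two oblique families roughly
#' symmetric about the circumferential direction); the mixture is fitted by
#' expectation-maximization with unequal variances.
#'
#' @param betas numeric vector of angles in degrees (>= 20 values).
#' @param seed integer seed (the EM initialization is deterministic, the
#'   seed only guards optional randomized restarts).
#' @return A list: \code{means}, \code{sds}, \code{weights} (sorted by
#'   mean), \code{converged}, \code{degenerate} (TRUE when the fit collapsed
#'   to one effective component).
#' @export
fitOrientationMixture <- function(betas, seed = 1L) {
  betas <- as.numeric(betas)
  if (length(betas) < 20) stop("need at least 20 angles")
  if (stats::sd(betas) < 1e-9) {
    return(list(means = c(betas[1], betas[1]), sds = c(0, 0),
                weights = c(1, 0), converged = TRUE, degenerate = TRUE))
  }
  set.seed(seed)
  fit <- mclust::Mclust(betas, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) {
    return(list(means = rep(mean(betas), 2), sds = rep(stats::sd(betas), 2),
                weights = c(1, 0), converged = FALSE, degenerate = TRUE))
  }
  ord <- order(fit$parameters$mean)
  list(means = unname(fit$parameters$mean[ord]),
       sds = unname(sqrt(fit$parameters$variance$sigmasq))[ord],
       weights = unname(fit$parameters$pro[ord]),
       converged = TRUE,
       degenerate = min(fit$parameters$pro) < 0.02)
}

#' Summarize a population of cell morphometries
#'
#' @param records list of \linkS4class{CellRecord} objects or a data.frame
#'   of morphometry rows.
#' @param group optional grouping vector (e.g. heart index).
#' @return data.frame with mean, SD and median per parameter (per group
#'   when \code{group} is given).
#' @export
summarizePopulation <- function(records, group = NULL) {
  df <- if (is.data.frame(records)) records
        else do.call(rbind, lapply(records, morphometry))
  params <- intersect(c("L", "W", "T", "slenderness", "beta", "alpha"),
                      colnames(df))
  one <- function(d, tag) {
    do.call(rbind, lapply(params, function(p) {
      v <- d[[p]][is.finite(d[[p]])]
      data.frame(group = tag, parameter = p, n = length(v),
                 mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
                 median = stats::median(v))
    }))
  }
  if (is.null(group)) return(one(df, "all"))
  do.call(rbind, lapply(split(seq_len(nrow(df)), group), function(i)
    one(df[i, , drop = FALSE], as.character(group[i[1]]))))
}

#' Relative difference between algorithmic and manual values
#'
#' Defined as (algorithm - manual) / manual, reported in percent.
#'
#' @param algorithm,manual numeric values or vectors.
#' @return Percent difference(s).
#' @examples
#' relativeDifference(75.3, 63.1)  # 19.3 (%)
#' @export
relativeDifference <- function(algorithm, manual) {
  100 * (algorithm - manual) / manual
}
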
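# Coil-sensitivity detrending: a full trivariate cubic polynomial (20
# monomials x^i y^j z^k, i+j+k <= 3) is fitted by ordinary least squares to
# the intensities of a non-contiguous blood-pool VOI, extrapolated over the
# heart, and divided out of the volume. Coordinates are normalized to
# [-1, 1] per axis over the volume bounding box before fitting, for the
# conditioning of the 20-term design.

cubic_terms <- function() {
  ex <- expand.grid(i = 0:3, j = 0:3, k = 0:3)
  ex[ex$i + ex$j + ex$k <= 3, , drop = FALSE]
}

cubic_design <- function(coords, center, scale, terms = cubic_terms()) {
  x <- (coords[, 1] - center[1]) / scale[1]
  y <- (coords[, 2] - center[2]) / scale[2]
  z <- (coords[, 3] - center[3]) / scale[3]
  m <- matrix(1, nrow(coords), nrow(terms))
  for (t in seq_len(nrow(terms)))
    m[, t] <- x^terms$i[t] * y^terms$j[t] * z^terms$k[t]
  m
}

vol_coords <- function(dm, which = NULL) {
  if (is.null(which)) {
    as.matrix(expand.grid(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])))
  } else {
    which(which, arr.ind = TRUE)
  }
}

#' Fit the coil-sensitivity trend over a blood-pool VOI
#'
#' Least-squares fit of the 20-term trivariate cubic polynomial to the
#' volume intensities inside a (typically non-contiguous) VOI placed in the
#' blood pool, which is assumed homogeneous except for coil shading. The
#' fitted smooth trend is the coil-sensitivity estimate; dividing it out
#' of the volume removes the shading.
#'
#' @param volume 3D numeric array.
#' @param voi_mask Logical/0-1 3D array marking the VOI. At least 100
#'   voxels (5x the 20 coefficients) with positive signal are required,
#'   and the VOI geometry must not be degenerate (e.g. coplanar voxels).
#' @return An object of class `coil_trend`: coefficients, coordinate
#'   normalization, fit residual summary (`rms`, relative `rms_rel`), and
#'   the volume dimensions. Evaluate with `predict()`.
#' @export
fit_trend <- function(volume, voi_mask) {
  dm <- dim(volume)
  if (length(dm) != 3L) stop("'volume' must be a 3D array", call. = FALSE)
  if (!identical(dim(voi_mask), dm))
    stop("'voi_mask' dimensions must match 'volume'", call. = FALSE)
  sel <- voi_mask != 0
  n <- sum(sel)
  if (n < 100)
    stop("VOI too small: need >= 100 voxels (5 per coefficient), got ", n,
         call. = FALSE)
  y <- volume[sel]
  if (any(!is.finite(y)) || any(y <= 0))
    stop("VOI signal must be finite and positive", call. = FALSE)

  center <- (dm + 1) / 2
  scale <- pmax((dm - 1) / 2, 1)
  coords <- vol_coords(dm, sel)
  X <- cubic_design(coords, center, scale)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("degenerate VOI geometry: the cubic design is rank-deficient ",
         "(rank ", qrX$rank, " of ", ncol(X), "). Spread the VOI over ",
         "more slices/positions.", call. = FALSE)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  rms <- sqrt(mean(res^2))

  structure(
    list(coefficients = as.numeric(beta), center = center, scale = scale,
         dim = dm, n_voi = n, rms = rms, rms_rel = rms / mean(y)),
    class = "coil_trend")
}

#' @export
print.coil_trend <- function(x, ...) {
  cat(sprintf(
    "Cubic coil-sensitivity trend: %d coefficients fit to %d VOI voxels\n",
    length(x$coefficients), x$n_voi))
  cat(sprintf("  residual RMS %.4g (%.2f%% of VOI mean)\n",
              x$rms, 100 * x$rms_rel))
  invisible(x)
}

#' Evaluate a fitted coil trend
#'
#' @param object A [fit_trend()] result.
#' @param newdata Optional n x 3 matrix of voxel coordinates; defaults to
#'   every voxel of the fitted volume, returned as a 3D array.
#' @param ... Unused.
#' @return Trend values: a 3D array if `newdata` is `NULL`, else a vector.
#' @export
predict.coil_trend <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    coords <- vol_coords(object$dim)
    v <- cubic_design(coords, object$center, object$scale) %*%
      object$coefficients
    return(array(v, object$dim))
  }
  as.numeric(cubic_design(as.matrix(newdata), object$center, object$scale) %*%
               object$coefficients)
}

#' Divide a fitted coil trend out of a volume
#'
#' The cubic trend is extrapolated over `region` (default: the whole
#' volume) and divided out. The trend must be strictly positive over the
#' region — a cubic can change sign when extrapolated far from the VOI, and
#' silent sign flips are refused.
#'
#' @param volume 3D numeric array.
#' @param trend A `coil_trend` from [fit_trend()].
#' @param region Optional logical/0-1 3D mask over which to detrend;
#'   voxels outside pass through unchanged and are flagged in the
#'   `"outside_region"` attribute.
#' @return The detrended volume (same dimensions).
#' @export
apply_detrend <- function(volume, trend, region = NULL) {
  stopifnot(inherits(trend, "coil_trend"))
  dm <- dim(volume)
  if (!identical(dm, trend$dim))
    stop("'volume' dimensions differ from those the trend was fit on",
         call. = FALSE)
  tv <- predict(trend)
  sel <- if (is.null(region)) array(TRUE, dm) else region != 0
  if (any(tv[sel] <= 0))
    stop("extrapolated trend is non-positive inside the region; ",
         "restrict 'region' or enlarge the VOI", call. = FALSE)
  out <- volume
  out[sel] <- volume[sel] / tv[sel]
  if (!all(sel)) attr(out, "outside_region") <- !sel
  out
}

#' Fit and apply coil detrending in one step
#'
#' @inheritParams fit_trend
#' @inheritParams apply_detrend
#' @return List with `volume` (detrended), `trend` (the model) and
#'   `trend_volume` (the evaluated trend).
#' @export
detrend <- function(volume, voi_mask, region = NULL) {
  tr <- fit_trend(volume, voi_mask)
  list(volume = apply_detrend(volume, tr, region), trend = tr,
       trend_volume = predict(tr))
}
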
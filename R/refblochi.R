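# Single-TI T1 mapping engine: one-point M0 calibration against a reference
# T1, grid-search inversion of the monotone signal-to-T1 curve, and the
# refblochi() model-fitting front end.

#' T1 search grid
#'
#' The practical post-contrast T1 range over which the signal model is
#' inverted; defaults to 100-800 ms with a 2.5 ms grid density.
#'
#' @param t1_min_ms,t1_max_ms Grid range (ms).
#' @param step_ms Grid step (ms, > 0).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(t1_min_ms = 100, t1_max_ms = 800, step_ms = 2.5) {
  if (!(t1_min_ms > 0 && t1_max_ms > t1_min_ms && step_ms > 0))
    stop("need 0 < t1_min_ms < t1_max_ms and step_ms > 0", call. = FALSE)
  structure(list(t1_min_ms = t1_min_ms, t1_max_ms = t1_max_ms,
                 step_ms = step_ms),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid A `grid_spec` object.
#' @return `t1_grid()`: the numeric vector of grid T1 values (ms).
#' @export
t1_grid <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  seq(grid$t1_min_ms, grid$t1_max_ms, by = grid$step_ms)
}

#' Single-point M0 calibration
#'
#' Estimates the scalar signal scaling M0 (the combined proton density,
#' T2*-weighting and global gain left after coil detrending) by dividing
#' the measured signal of a reference tissue of known T1 — typically the
#' blood pool — by the model T1-weighting at that T1.
#'
#' @param ref_signal Mean (detrended) signal of the reference tissue
#'   (a.u., > 0).
#' @param ref_t1_ms Reference T1 (ms, > 0).
#' @param params The [seq_params()] protocol.
#' @return The scalar M0 estimate.
#' @export
estimate_m0 <- function(ref_signal, ref_t1_ms, params) {
  if (!is.finite(ref_signal) || ref_signal <= 0)
    stop("'ref_signal' must be finite and > 0", call. = FALSE)
  fr <- f_weight(params, ref_t1_ms)
  if (!is.finite(fr) || fr < 1e-6)
    stop("calibration is degenerate: the model weighting at the reference ",
         "T1 is at or below the null point (f(ref_t1) < 1e-6)",
         call. = FALSE)
  ref_signal / fr
}

# Precompute the model signal over the grid once per protocol; reused for
# every voxel (identical to per-voxel evaluation by construction).
signal_lut <- function(params, grid) {
  t1 <- t1_grid(grid)
  list(t1 = t1, f = f_weight(params, t1))
}

#' Grid-search inversion of the signal model
#'
#' Maps signal values to T1 by minimizing `|signal - m0 * f(T1)|` over the
#' search grid. Ties are broken toward the smaller T1. Signals outside the
#' model range clamp to a grid endpoint and are flagged; non-finite signals
#' yield `NA` and are flagged invalid.
#'
#' @param signal Numeric vector of (detrended) signal values.
#' @param m0 Scalar M0 estimate from [estimate_m0()] (> 0).
#' @param params The [seq_params()] protocol.
#' @param grid A [grid_spec()].
#' @return Numeric vector of T1 estimates (ms) with logical attributes
#'   `"boundary"` (estimate hit a grid endpoint) and `"invalid"`
#'   (non-finite input).
#' @export
invert_signal <- function(signal, m0, params, grid = grid_spec()) {
  if (!is.finite(m0) || m0 <= 0) stop("'m0' must be > 0", call. = FALSE)
  lut <- signal_lut(params, grid)
  invert_signal_lut(signal, m0, lut)
}

invert_signal_lut <- function(signal, m0, lut, chunk = 20000L) {
  fg <- m0 * lut$f
  ng <- length(fg)
  out <- rep(NA_real_, length(signal))
  idx_all <- rep(NA_integer_, length(signal))
  ok <- which(is.finite(signal))
  for (start in seq(1L, length(ok), by = chunk)) {
    sel <- ok[start:min(start + chunk - 1L, length(ok))]
    d <- abs(outer(signal[sel], fg, "-"))
    # max.col on the negated distances with ties = "first" picks the
    # smallest T1 among equally good grid points (grid is ascending)
    idx <- max.col(-d, ties.method = "first")
    idx_all[sel] <- idx
    out[sel] <- lut$t1[idx]
  }
  attr(out, "boundary") <- !is.na(idx_all) & (idx_all == 1L | idx_all == ng)
  attr(out, "invalid") <- !is.finite(signal)
  out
}

#' Single-TI T1 mapping from one LGE volume (T1-refBlochi)
#'
#' Fits a voxel-wise post-contrast T1 map to a single 3D inversion-recovery
#' FLASH magnitude volume. The signal model is the Bloch steady-state
#' T1-weighting of the protocol ([f_weight()]); the unknown scalar M0 is
#' calibrated from a single reference tissue (usually the blood pool, whose
#' T1 is supplied from a separate measurement), and each voxel's signal is
#' inverted through the monotone signal-T1 curve by grid search.
#'
#' If a blood-pool VOI mask is supplied via `voi`, the volume is first
#' detrended for coil sensitivity ([fit_trend()] / [apply_detrend()]) and
#' the calibration signal is taken from the detrended volume.
#'
#' @param image 3D numeric array: the LGE magnitude volume.
#' @param params The [seq_params()] protocol.
#' @param ref_t1_ms Reference-tissue T1 (ms).
#' @param ref_signal Scalar reference signal (a.u.). Either this or
#'   `ref_roi` must be given.
#' @param ref_roi Logical/0-1 3D array marking the reference ROI; the
#'   reference signal is its mean over the (detrended) volume.
#' @param mask Optional logical/0-1 3D array of voxels to map; defaults to
#'   all voxels.
#' @param grid A [grid_spec()].
#' @param voi Optional blood-pool VOI mask used to fit and divide out the
#'   coil-sensitivity trend before mapping.
#' @return An object of class `refblochi` with components `t1` (T1 map,
#'   ms; `NA` outside the mask), `boundary` (grid-endpoint flags),
#'   `invalid` (non-finite input flags), `m0` (scalar calibration),
#'   `image` (the volume actually inverted, after any detrending),
#'   `trend` (the fitted [coil_trend] model or `NULL`), `mask`, `params`,
#'   `grid` and `call`. Methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `plot`.
#' @examples
#' prm <- seq_params(5, 15, 300, 900, 33)
#' spec <- phantom_spec(geometry = "tubes", noise = "none", protocol = prm)
#' ph <- generate_phantom(spec)
#' fit <- refblochi(ph$image, prm, ref_t1_ms = 200,
#'                  ref_roi = ph$truth$labels == 1)
#' summary(fit)
#' @export
refblochi <- function(image, params, ref_t1_ms, ref_signal = NULL,
                      ref_roi = NULL, mask = NULL, grid = grid_spec(),
                      voi = NULL) {
  stopifnot(inherits(params, "seq_params"))
  if (length(dim(image)) != 3L)
    stop("'image' must be a 3D array", call. = FALSE)
  if (!is.null(mask) && !identical(dim(mask), dim(image)))
    stop("'mask' dimensions must match 'image'", call. = FALSE)

  trend <- NULL
  if (!is.null(voi)) {
    trend <- fit_trend(image, voi)
    image <- apply_detrend(image, trend)
  }
  if (is.null(ref_signal)) {
    if (is.null(ref_roi))
      stop("supply either 'ref_signal' or 'ref_roi'", call. = FALSE)
    if (!identical(dim(ref_roi), dim(image)))
      stop("'ref_roi' dimensions must match 'image'", call. = FALSE)
    ref_signal <- mean(image[ref_roi != 0])
  }
  m0 <- estimate_m0(ref_signal, ref_t1_ms, params)

  msk <- if (is.null(mask)) array(TRUE, dim(image)) else mask != 0
  lut <- signal_lut(params, grid)
  est <- invert_signal_lut(image[msk], m0, lut)

  t1 <- array(NA_real_, dim(image))
  boundary <- array(FALSE, dim(image))
  invalid <- array(FALSE, dim(image))
  t1[msk] <- est
  boundary[msk] <- attr(est, "boundary")
  invalid[msk] <- attr(est, "invalid")

  structure(
    list(t1 = t1, boundary = boundary, invalid = invalid, m0 = m0,
         ref_t1_ms = ref_t1_ms, ref_signal = ref_signal, image = image,
         trend = trend, mask = msk, params = params, grid = grid,
         call = match.call()),
    class = "refblochi")
}

#' @export
print.refblochi <- function(x, ...) {
  cat("Single-TI Bloch-model T1 map (refblochi)\n")
  print(x$params)
  cat(sprintf("  grid: %g-%g ms, step %g ms\n",
              x$grid$t1_min_ms, x$grid$t1_max_ms, x$grid$step_ms))
  cat(sprintf("  calibration: ref T1 %g ms, M0 = %.6g\n",
              x$ref_t1_ms, x$m0))
  cat(sprintf("  %d voxels mapped, %d at grid boundary, %d invalid\n",
              sum(x$mask), sum(x$boundary), sum(x$invalid)))
  invisible(x)
}

#' @export
summary.refblochi <- function(object, ...) {
  v <- object$t1[object$mask & !object$invalid]
  out <- list(
    n_mapped = sum(object$mask),
    n_boundary = sum(object$boundary),
    n_invalid = sum(object$invalid),
    m0 = object$m0,
    ref_t1_ms = object$ref_t1_ms,
    t1_quantiles = stats::quantile(v, c(0, .25, .5, .75, 1), names = TRUE),
    params = object$params, grid = object$grid)
  class(out) <- "summary.refblochi"
  out
}

#' @export
print.summary.refblochi <- function(x, ...) {
  cat("Single-TI Bloch-model T1 map (refblochi)\n")
  print(x$params)
  cat(sprintf("  M0 = %.6g (ref T1 %g ms)\n", x$m0, x$ref_t1_ms))
  cat(sprintf("  voxels: %d mapped / %d boundary / %d invalid\n",
              x$n_mapped, x$n_boundary, x$n_invalid))
  cat("  T1 (ms) quantiles:\n")
  print(round(x$t1_quantiles, 1))
  invisible(x)
}

#' @export
coef.refblochi <- function(object, ...) c(m0 = object$m0)

#' @export
#' @rdname refblochi
#' @param object,x A fitted `refblochi` object.
#' @param t1_ms For `predict`: T1 values at which to evaluate the
#'   calibrated signal model; defaults to the fitted T1 map.
#' @param ... Unused.
predict.refblochi <- function(object, t1_ms = NULL, ...) {
  if (is.null(t1_ms)) {
    out <- array(NA_real_, dim(object$t1))
    sel <- object$mask & !object$invalid
    out[sel] <- object$m0 * f_weight(object$params, object$t1[sel])
    return(out)
  }
  object$m0 * f_weight(object$params, t1_ms)
}

#' @export
residuals.refblochi <- function(object, ...) {
  object$image - predict(object)
}

#' @export
plot.refblochi <- function(x, slice = ceiling(dim(x$t1)[3] / 2), ...) {
  sl <- x$t1[, , slice]
  graphics::image(sl, col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, asp = dim(sl)[2] / dim(sl)[1],
                  main = sprintf("T1 map (ms), slice %d", slice), ...)
  invisible(x)
}

#' Extracellular volume fraction approximation (ECVa)
#'
#' Approximates ECV from post-contrast T1 of myocardium and blood using
#' assumed (population) native T1 values, avoiding a pre-contrast scan:
#'
#' \deqn{ECVa = \left(\frac{1}{T1_m} - \frac{1}{T1_{m0}}\right)
#'   \frac{1 - HCT}{\frac{1}{T1_b} - \frac{1}{T1_{b0}}}}
#'
#' The result is not clamped: values above `1 - hct` can occur in
#' pathology and are reported as computed.
#'
#' @param t1_m_ms Post-contrast myocardial T1 (ms). Vectorized.
#' @param t1_b_ms Post-contrast blood T1 (ms).
#' @param t1_m0_ms Assumed native myocardial T1 (ms), default 1150.
#' @param t1_b0_ms Assumed native blood T1 (ms), default 1500.
#' @param hct Hematocrit fraction in (0, 1), default 0.45.
#' @return ECVa fraction(s).
#' @examples
#' ecva(300, 350)              # a typical post-contrast voxel
#' ecva(350, 350)              # blood-equivalent voxel -> 1 - hct
#' @export
ecva <- function(t1_m_ms, t1_b_ms, t1_m0_ms = 1150, t1_b0_ms = 1500,
                 hct = 0.45) {
  if (any(c(t1_m_ms, t1_b_ms, t1_m0_ms, t1_b0_ms) <= 0, na.rm = TRUE))
    stop("all T1 values must be > 0", call. = FALSE)
  if (hct <= 0 || hct >= 1) stop("'hct' must be in (0, 1)", call. = FALSE)
  den <- 1 / t1_b_ms - 1 / t1_b0_ms
  if (any(abs(den) < 1e-12))
    stop("degenerate input: blood R1 change is zero", call. = FALSE)
  (1 / t1_m_ms - 1 / t1_m0_ms) * (1 - hct) / den
}

#' Water content of whole blood
#'
#' The hematocrit-weighted water fraction of blood,
#' `(1 - hct) * plasma + hct * erythrocyte`, used to argue that proton
#' density is nearly matched between blood and myocardium (both about 80%
#' water), so that M0 heterogeneity is a small error source for the
#' single-point calibration.
#'
#' @param hct Hematocrit fraction, default 0.45.
#' @param water_plasma Water fraction of plasma, default 0.93.
#' @param water_rbc Water fraction of erythrocytes, default 0.64.
#' @return Water fraction of whole blood.
#' @export
water_content_blood <- function(hct = 0.45, water_plasma = 0.93,
                                water_rbc = 0.64) {
  (1 - hct) * water_plasma + hct * water_rbc
}
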
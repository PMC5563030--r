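# Synthetic digital phantoms with known ground truth: a schematic
# cardiac-like geometry (blood pool, myocardial shell, scar sector,
# background) and a Gd-doped-water-style tube array. Each voxel's signal is
# C * A * PD * exp(-TE/T2*) * f(T1) plus optional noise, and every factor
# is returned as a truth volume. The geometry is deliberately schematic:
# the mapping method is voxel-wise, so geometry only exercises detrending
# and masking.

#' Compartment M0 composition
#'
#' The non-T1 weighting of each compartment: a global scale times proton
#' density times the T2* weighting `exp(-TE/T2*)`. Defaults give
#' near-unity heterogeneity across cardiac compartments
#' (myocardium/blood about 1.03, scar/blood about 0.94 — the in vivo
#' scale of proton-density and T2* variation).
#'
#' @param a_const Global scale A.
#' @param pd Named proton-density factors per compartment.
#' @param t2star_ms Named T2* (ms) per compartment.
#' @param te_ms Echo time (ms).
#' @return An object of class `m0_composition`.
#' @export
m0_composition <- function(
    a_const = 1,
    pd = c(background = 0.30, blood = 0.80, myocardium = 0.84,
           scar = 0.76),
    t2star_ms = c(background = 30, blood = 100, myocardium = 48,
                  scar = 60),
    te_ms = 1.9) {
  if (a_const <= 0 || te_ms < 0 || any(pd <= 0) || any(t2star_ms <= 0))
    stop("all composition factors must be positive", call. = FALSE)
  structure(list(a_const = a_const, pd = pd, t2star_ms = t2star_ms,
                 te_ms = te_ms),
            class = "m0_composition")
}

m0_factors <- function(comp, compartments) {
  vapply(compartments, function(nm) {
    if (!nm %in% names(comp$pd))
      stop("no composition entry for compartment '", nm, "'", call. = FALSE)
    comp$a_const * comp$pd[[nm]] *
      exp(-comp$te_ms / comp$t2star_ms[[nm]])
  }, numeric(1))
}

#' Phantom specification
#'
#' Declares the geometry, per-compartment T1s, M0 composition, coil field,
#' noise model and protocol of a synthetic phantom.
#'
#' Noise is Gaussian on the signed model signal by default, matching the
#' way precision is usually simulated for these sequences; a Rician mode
#' (the magnitude of complex Gaussian noise) is available for realism
#' studies of magnitude images. The SNR is defined as the mean noiseless
#' signal of the reference compartment (blood, or the first tube) divided
#' by the noise standard deviation.
#'
#' @param geometry `"cardiac"` (nested blood pool / myocardial shell /
#'   scar sector / background) or `"tubes"` (array of tubes spanning the
#'   post-contrast T1 range).
#' @param dim Volume dimensions (voxels).
#' @param spacing Voxel spacing (mm).
#' @param t1_ms Named per-compartment T1s (cardiac) or per-tube T1 vector
#'   (tubes; default 6 tubes evenly spanning 200-560 ms).
#' @param composition An [m0_composition()]; for `"tubes"` a single
#'   blood-like composition is used for all tubes.
#' @param coil `"none"` or `"polynomial"`: a smooth strictly-positive
#'   multiplicative field, the exponential of a seeded random low-order
#'   polynomial.
#' @param coil_amplitude Approximate log-range of the coil field.
#' @param noise `"none"`, `"gaussian"` or `"rician"`.
#' @param snr Blood SNR used when `noise != "none"`.
#' @param protocol A [seq_params()]; default is the base tube-phantom
#'   protocol TR/alpha/N/RR/TI = 3.8 ms/15 deg/37/800 ms/300 ms.
#' @param seed Integer seed making the phantom reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(
    geometry = c("cardiac", "tubes"),
    dim = c(32, 32, 10),
    spacing = c(1.2, 1.2, 3),
    t1_ms = NULL,
    composition = m0_composition(),
    coil = c("none", "polynomial"),
    coil_amplitude = 0.4,
    noise = c("gaussian", "none", "rician"),
    snr = 20,
    protocol = seq_params(tr_ms = 3.8, flip_deg = 15, ti_ms = 300,
                          rr_ms = 800, n_views = 37),
    seed = 1L) {
  geometry <- match.arg(geometry)
  coil <- match.arg(coil)
  noise <- match.arg(noise)
  stopifnot(inherits(protocol, "seq_params"),
            inherits(composition, "m0_composition"))
  if (is.null(t1_ms)) {
    t1_ms <- if (geometry == "cardiac") {
      c(background = 700, blood = 280, myocardium = 450, scar = 220)
    } else {
      seq(200, 560, length.out = 6)
    }
  }
  if (any(t1_ms <= 0)) stop("T1s must be > 0", call. = FALSE)
  if (noise != "none" && snr <= 0) stop("'snr' must be > 0", call. = FALSE)
  structure(list(geometry = geometry, dim = as.integer(dim),
                 spacing = spacing, t1_ms = t1_ms,
                 composition = composition, coil = coil,
                 coil_amplitude = coil_amplitude, noise = noise, snr = snr,
                 protocol = protocol, seed = as.integer(seed)),
            class = "phantom_spec")
}

# labels: cardiac 0 background / 1 blood / 2 myocardium / 3 scar;
# tubes 0 background / tube index.
phantom_labels <- function(spec) {
  dm <- spec$dim
  lab <- array(0L, dm)
  cx <- (dm[1] + 1) / 2; cy <- (dm[2] + 1) / 2
  if (spec$geometry == "cardiac") {
    r_blood <- 0.28 * min(dm[1:2])
    r_myo <- 0.42 * min(dm[1:2])
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
      r <- sqrt((i - cx)^2 + (j - cy)^2)
      if (r <= r_blood) lab[i, j, ] <- 1L
      else if (r <= r_myo) {
        ang <- atan2(j - cy, i - cx)
        lab[i, j, ] <- if (ang > 0 & ang < pi / 2) 3L else 2L
      }
    }
  } else {
    k <- length(spec$t1_ms)
    ncol_t <- ceiling(sqrt(k))
    nrow_t <- ceiling(k / ncol_t)
    rad <- 0.38 * min(dm[1] / ncol_t, dm[2] / nrow_t)
    t <- 0L
    for (r0 in seq_len(nrow_t)) for (c0 in seq_len(ncol_t)) {
      t <- t + 1L
      if (t > k) break
      tx <- (c0 - 0.5) * dm[1] / ncol_t
      ty <- (r0 - 0.5) * dm[2] / nrow_t
      for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
        if ((i - tx)^2 + (j - ty)^2 <= rad^2) lab[i, j, ] <- t
    }
  }
  lab
}

coil_field <- function(spec) {
  dm <- spec$dim
  if (spec$coil == "none") return(array(1, dm))
  # exponential of a seeded random low-order polynomial: smooth, positive
  cf <- stats::runif(9, -1, 1)
  g <- vol_coords(dm)
  x <- (g[, 1] - (dm[1] + 1) / 2) / (dm[1] / 2)
  y <- (g[, 2] - (dm[2] + 1) / 2) / (dm[2] / 2)
  z <- (g[, 3] - (dm[3] + 1) / 2) / (max(dm[3] - 1, 1) / 2)
  pol <- cf[1] * x + cf[2] * y + cf[3] * z + cf[4] * x * y +
    cf[5] * x * z + cf[6] * y * z + cf[7] * x^2 + cf[8] * y^2 + cf[9] * z^2
  pol <- pol / max(abs(pol)) * spec$coil_amplitude / 2
  array(exp(pol), dm)
}

phantom_truth <- function(spec) {
  lab <- phantom_labels(spec)
  dm <- spec$dim
  t1 <- array(NA_real_, dm)
  m0 <- array(0, dm)
  if (spec$geometry == "cardiac") {
    comp_names <- c("background", "blood", "myocardium", "scar")
    fac <- m0_factors(spec$composition, comp_names)
    for (c0 in 0:3) {
      sel <- lab == c0
      t1[sel] <- spec$t1_ms[[comp_names[c0 + 1]]]
      m0[sel] <- fac[[c0 + 1]]
    }
  } else {
    fac_tube <- m0_factors(spec$composition, "blood")
    t1[lab == 0L] <- 1000   # water background, outside the mapped range
    m0[lab == 0L] <- 0.15 * fac_tube
    for (t in seq_along(spec$t1_ms)) {
      sel <- lab == t
      t1[sel] <- spec$t1_ms[t]
      m0[sel] <- fac_tube
    }
  }
  list(t1 = t1, m0 = m0, labels = lab)
}

reference_mask <- function(spec, labels) {
  if (spec$geometry == "cardiac") labels == 1L else labels == 1L
}

#' Generate a synthetic LGE phantom volume
#'
#' Emits a simulated magnitude LGE volume plus the full ground truth
#' (T1, M0, coil field, compartment labels). The noiseless voxel signal is
#' `coil * m0 * f(T1)` with `f` the protocol's T1-weighting.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (3D array, `"spacing"` attribute), `truth`
#'   (list of `t1`, `m0`, `coil`, `labels` arrays), `ref_mask` (the
#'   reference/blood compartment), `sigma` (the noise SD used, 0 if none)
#'   and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  truth <- phantom_truth(spec)
  coil <- coil_field(spec)
  f <- array(0, spec$dim)
  ok <- !is.na(truth$t1)
  f[ok] <- f_weight(spec$protocol, truth$t1[ok])
  clean <- coil * truth$m0 * f
  ref <- reference_mask(spec, truth$labels)
  sigma <- 0
  img <- clean
  if (spec$noise != "none") {
    sigma <- mean(clean[ref]) / spec$snr
    if (spec$noise == "gaussian") {
      img <- clean + array(stats::rnorm(length(clean), 0, sigma), spec$dim)
    } else {
      img <- sqrt((clean + stats::rnorm(length(clean), 0, sigma))^2 +
                    stats::rnorm(length(clean), 0, sigma)^2)
      img <- array(img, spec$dim)
    }
  }
  attr(img, "spacing") <- spec$spacing
  list(image = img,
       truth = list(t1 = truth$t1, m0 = truth$m0, coil = coil,
                    labels = truth$labels),
       ref_mask = ref, sigma = sigma, spec = spec)
}

#' Generate a synthetic multi-TI LGE series
#'
#' Emits one inversion-prepared volume per TI and one no-inversion volume
#' from the same phantom truth, bundled as an [mti_series()].
#'
#' @param spec A [phantom_spec()].
#' @param tis_ms Inversion times (ms), default `c(100, 200, 300)`.
#' @return List with `series` (an `mti_series`), `truth`, `ref_mask` and
#'   `spec`.
#' @export
generate_multi_ti <- function(spec, tis_ms = c(100, 200, 300)) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  truth <- phantom_truth(spec)
  coil <- coil_field(spec)
  ok <- !is.na(truth$t1)
  ref <- reference_mask(spec, truth$labels)

  make_vol <- function(fvals, sigma) {
    clean <- array(0, spec$dim)
    clean[ok] <- fvals
    clean <- coil * truth$m0 * clean
    if (spec$noise == "none") return(clean)
    if (spec$noise == "gaussian")
      return(clean +
               array(stats::rnorm(length(clean), 0, sigma), spec$dim))
    array(sqrt((clean + stats::rnorm(length(clean), 0, sigma))^2 +
                 stats::rnorm(length(clean), 0, sigma)^2), spec$dim)
  }
  # noise SD referenced to the TI volume closest to the protocol's TI
  sigma <- 0
  if (spec$noise != "none") {
    ti_ref <- tis_ms[which.min(abs(tis_ms - spec$protocol$ti_ms))]
    pr <- update_params(spec$protocol, ti_ms = ti_ref)
    clean_ref <- array(0, spec$dim)
    clean_ref[ok] <- f_weight(pr, truth$t1[ok])
    sigma <- mean((coil * truth$m0 * clean_ref)[ref]) / spec$snr
  }
  imgs <- lapply(tis_ms, function(ti) {
    pr <- update_params(spec$protocol, ti_ms = ti)
    make_vol(f_weight(pr, truth$t1[ok]), sigma)
  })
  noinv <- make_vol(mzss_noinv(spec$protocol, truth$t1[ok]), sigma)
  list(series = mti_series(imgs, tis_ms, noinv, spec$protocol),
       truth = list(t1 = truth$t1, m0 = truth$m0, coil = coil,
                    labels = truth$labels),
       ref_mask = ref, spec = spec)
}

#' The tube-phantom protocol family
#'
#' The seven-protocol family used to probe sensitivity of the mapper to
#' acquisition settings, around the base tube-phantom protocol
#' TR/alpha/N/RR/TI = 3.8 ms/15 deg/37/800 ms/300 ms: flip angle lowered
#' to 10 degrees, RR changed to 700 and to 900 ms, N raised to 51, TR
#' raised to 5.4 ms, and an SNR/4 variant of the base protocol (same
#' timing, noise level tag `snr_factor = 0.25`).
#'
#' @return Named list; each element has `label`, `params` (a
#'   [seq_params()]) and `snr_factor` (multiplies the phantom SNR).
#' @export
protocol_suite <- function() {
  base <- seq_params(tr_ms = 3.8, flip_deg = 15, ti_ms = 300,
                     rr_ms = 800, n_views = 37)
  entry <- function(label, params, snr_factor = 1)
    list(label = label, params = params, snr_factor = snr_factor)
  list(
    base = entry("base", base),
    alpha10 = entry("flip 10 deg", update_params(base, flip_deg = 10)),
    rr700 = entry("RR 700 ms", update_params(base, rr_ms = 700)),
    rr900 = entry("RR 900 ms", update_params(base, rr_ms = 900)),
    n51 = entry("N = 51", update_params(base, n_views = 51)),
    tr54 = entry("TR 5.4 ms", update_params(base, tr_ms = 5.4)),
    snr4 = entry("SNR / 4", base, snr_factor = 0.25))
}
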
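# Accuracy and precision machinery for the single-TI mapper: analytic
# first-order bias propagation, direct noiseless bias simulation for the
# four major error sources, and Monte-Carlo precision curves.

default_accuracy_protocol <- function()
  seq_params(tr_ms = 5, flip_deg = 15, ti_ms = 300, rr_ms = 900,
             n_views = 33)

#' First-order T1 bias from a biased M0 calibration (Category 1)
#'
#' When the single-point calibration over- or under-estimates M0 by a
#' factor `delta` (estimated M0 = delta * true M0) while the signal model
#' itself is correct, the resulting T1 bias is approximately
#' `(1 - delta) f(T1) / (delta f'(T1))`. Because `|f'|` decreases with T1
#' while `f` also decreases, this bias shrinks as T1 grows — which is why a
#' short reference T1 (blood) keeps the bias of longer-T1 tissues below
#' the calibration error itself.
#'
#' @param delta M0 bias factor (> 0).
#' @param t1_ms True T1 (ms). Vectorized.
#' @param params The [seq_params()] protocol.
#' @return Approximate T1 bias (ms).
#' @export
bias_category1 <- function(delta, t1_ms, params) {
  if (delta <= 0) stop("'delta' must be > 0", call. = FALSE)
  fp <- f_prime(params, t1_ms)
  if (any(abs(fp) < 1e-10))
    stop("ill-conditioned: |f'| vanishes at some requested T1",
         call. = FALSE)
  (1 - delta) * f_weight(params, t1_ms) / (delta * as.numeric(fp))
}

#' First-order T1 bias from a biased signal model (Category 2)
#'
#' When the true signal follows `f_true` while calibration and inversion
#' use the protocol model `f` (with an M0 bias factor `delta` as in
#' Category 1), the T1 bias is approximately
#' `(f_true(T1) - delta f(T1)) / (delta f'(T1))`. Model errors of this
#' kind (wrong effective RR, imperfect inversion) grow with T1.
#'
#' @param f_true Function of T1 (ms) returning the true T1-weighting.
#' @inheritParams bias_category1
#' @return Approximate T1 bias (ms).
#' @export
bias_category2 <- function(f_true, delta, t1_ms, params) {
  if (delta <= 0) stop("'delta' must be > 0", call. = FALSE)
  fp <- f_prime(params, t1_ms)
  if (any(abs(fp) < 1e-10))
    stop("ill-conditioned: |f'| vanishes at some requested T1",
         call. = FALSE)
  (f_true(t1_ms) - delta * f_weight(params, t1_ms)) /
    (delta * as.numeric(fp))
}

#' Describe one accuracy-error scenario
#'
#' The four major error sources of the single-TI method:
#' `"ref_t1_bias"` (the reference T1 is off by `magnitude` ms),
#' `"m0_heterogeneity"` (non-reference tissue has M0 scaled by factor
#' `magnitude` relative to the calibrated reference),
#' `"rr_error"` (the nominal RR used for modeling is `magnitude` ms while
#' the true RR generates the signal), and
#' `"imperfect_inversion"` (the true signal has inversion factor
#' `magnitude` while the model assumes a perfect inversion).
#'
#' @param kind Scenario kind (see above).
#' @param magnitude Scenario magnitude: delta-T1 in ms, an M0 factor, a
#'   nominal RR in ms, or an inversion factor, respectively.
#' @param params True acquisition protocol; defaults to the accuracy
#'   protocol TR/alpha/TI/RR/N = 5 ms/15 deg/300 ms/900 ms/33.
#' @param ref_t1_ms Reference (blood) T1, default 280 ms.
#' @param t1_range True-T1 evaluation range (ms), default `c(200, 600)`.
#' @return An object of class `bias_scenario`.
#' @export
bias_scenario <- function(kind = c("ref_t1_bias", "m0_heterogeneity",
                                   "rr_error", "imperfect_inversion"),
                          magnitude,
                          params = default_accuracy_protocol(),
                          ref_t1_ms = 280, t1_range = c(200, 600)) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "seq_params"))
  if (kind == "imperfect_inversion" &&
      (magnitude <= 0 || magnitude > 1))
    stop("inversion factor must be in (0, 1]", call. = FALSE)
  if (kind == "m0_heterogeneity" && magnitude <= 0)
    stop("M0 factor must be > 0", call. = FALSE)
  if (kind == "rr_error" && magnitude <= 0)
    stop("nominal RR must be > 0", call. = FALSE)
  structure(list(kind = kind, magnitude = magnitude, params = params,
                 ref_t1_ms = ref_t1_ms, t1_range = t1_range),
            class = "bias_scenario")
}

# True signal model, nominal (mapping) model and calibration bias factor
# delta implied by a scenario. Calibration always divides the reference
# tissue's *true* signal by the nominal model at the assumed reference T1.
scenario_models <- function(scenario) {
  prm <- scenario$params
  ref <- scenario$ref_t1_ms
  switch(scenario$kind,
    ref_t1_bias = {
      nominal <- prm
      list(f_true = function(t1) f_weight(prm, t1), nominal = nominal,
           m0_true = 1,
           delta = f_weight(prm, ref) /
             f_weight(prm, ref + scenario$magnitude))
    },
    m0_heterogeneity = {
      list(f_true = function(t1) f_weight(prm, t1), nominal = prm,
           m0_true = scenario$magnitude, delta = 1 / scenario$magnitude)
    },
    rr_error = {
      nominal <- update_params(prm, rr_ms = scenario$magnitude)
      list(f_true = function(t1) f_weight(prm, t1), nominal = nominal,
           m0_true = 1,
           delta = f_weight(prm, ref) / f_weight(nominal, ref))
    },
    imperfect_inversion = {
      list(f_true = function(t1)
             f_imperfect(prm, t1, beta = scenario$magnitude),
           nominal = prm, m0_true = 1,
           delta = f_imperfect(prm, ref, beta = scenario$magnitude) /
             f_weight(prm, ref))
    })
}

#' Simulate the T1 bias of the single-TI mapper under an error scenario
#'
#' Generates noiseless true signals over the scenario's T1 range, performs
#' the single-point calibration with the scenario's (possibly wrong)
#' reference or model, inverts by grid search, and returns the bias curve.
#' True T1s are evaluated on the mapping grid resolution so the curve
#' measures model bias rather than grid quantization. Deterministic.
#'
#' @param scenario A [bias_scenario()].
#' @param grid A [grid_spec()].
#' @return Data frame with columns `t1_true`, `t1_est`, `bias_ms`.
#' @export
simulate_bias <- function(scenario, grid = grid_spec()) {
  stopifnot(inherits(scenario, "bias_scenario"))
  mdl <- scenario_models(scenario)
  t1_true <- seq(scenario$t1_range[1], scenario$t1_range[2],
                 by = grid$step_ms)
  s <- mdl$m0_true * mdl$f_true(t1_true)
  # single-point calibration: the reference tissue's true signal divided by
  # the nominal model at the assumed reference T1; this equals
  # delta * m0_true by construction of the scenario's delta
  m0_hat <- mdl$delta * mdl$m0_true
  est <- invert_signal(s, m0_hat, mdl$nominal, grid)
  data.frame(t1_true = t1_true, t1_est = as.numeric(est),
             bias_ms = as.numeric(est) - t1_true)
}

#' Analytic first-order bias curve for an error scenario
#'
#' Evaluates the Category-1 or Category-2 bias formula
#' ([bias_category1()], [bias_category2()]) with the `delta` and model
#' pair implied by the scenario, for direct comparison with
#' [simulate_bias()].
#'
#' @inheritParams simulate_bias
#' @param t1_ms True T1s at which to evaluate; defaults to the scenario
#'   range at the default grid step.
#' @return Data frame with columns `t1_true`, `bias_ms`.
#' @export
analytic_bias <- function(scenario, t1_ms = NULL) {
  stopifnot(inherits(scenario, "bias_scenario"))
  mdl <- scenario_models(scenario)
  if (is.null(t1_ms))
    t1_ms <- seq(scenario$t1_range[1], scenario$t1_range[2], by = 2.5)
  b <- if (scenario$kind %in% c("ref_t1_bias", "m0_heterogeneity")) {
    bias_category1(mdl$delta, t1_ms, mdl$nominal)
  } else {
    bias_category2(mdl$f_true, mdl$delta, t1_ms, mdl$nominal)
  }
  data.frame(t1_true = t1_ms, bias_ms = as.numeric(b))
}

#' Monte-Carlo precision specification
#'
#' @param params Protocol without its RR fixed (the RR options are swept);
#'   default TR/alpha/TI/N = 5 ms/15 deg/300 ms/33.
#' @param rr_ms RR options (ms), default `c(750, 950)`.
#' @param snr Blood-SNR options, default `c(10, 15)`: the noiseless blood
#'   signal (at the reference T1) over the Gaussian noise SD.
#' @param ref_t1_ms Reference (blood) T1, default 280 ms.
#' @param t1_ms True T1s to evaluate, default 200-500 ms in 50 ms steps.
#' @param n_reps Replicates per condition, default 10000.
#' @param seed Seed for the noise draws.
#' @return An object of class `precision_spec`.
#' @export
precision_spec <- function(
    params = seq_params(tr_ms = 5, flip_deg = 15, ti_ms = 300,
                        rr_ms = 950, n_views = 33),
    rr_ms = c(750, 950), snr = c(10, 15), ref_t1_ms = 280,
    t1_ms = seq(200, 500, by = 50), n_reps = 10000L, seed = 1L) {
  stopifnot(inherits(params, "seq_params"))
  if (any(snr <= 0) || n_reps < 1)
    stop("need snr > 0 and n_reps >= 1", call. = FALSE)
  structure(list(params = params, rr_ms = rr_ms, snr = snr,
                 ref_t1_ms = ref_t1_ms, t1_ms = t1_ms,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "precision_spec")
}

#' Monte-Carlo precision of the single-TI T1 estimate
#'
#' For every (RR, SNR, true T1) condition: generate `n_reps` signals
#' `f(T1) + N(0, sigma)` with `sigma = f(ref_t1)/SNR`, calibrate M0 from
#' the noiseless reference signal (a noisy reference would conflate
#' calibration error with voxel noise), invert each replicate by grid
#' search, and report the SD of the estimates. Estimates clipped at the
#' grid bounds are included in the SD.
#'
#' @param spec A [precision_spec()].
#' @param grid A [grid_spec()].
#' @return Data frame with columns `t1_true`, `rr_ms`, `snr`, `sd_ms`
#'   (and `mean_ms` of the estimates).
#' @export
monte_carlo_precision <- function(spec, grid = grid_spec()) {
  stopifnot(inherits(spec, "precision_spec"))
  set.seed(spec$seed)
  out <- list()
  for (rr in spec$rr_ms) {
    prm <- update_params(spec$params, rr_ms = rr)
    lut <- signal_lut(prm, grid)
    ref_sig <- f_weight(prm, spec$ref_t1_ms)   # noiseless, M0 = 1
    m0_hat <- estimate_m0(ref_sig, spec$ref_t1_ms, prm)
    for (sn in spec$snr) {
      sigma <- ref_sig / sn
      for (t1 in spec$t1_ms) {
        s <- f_weight(prm, t1) + stats::rnorm(spec$n_reps, 0, sigma)
        est <- invert_signal_lut(s, m0_hat, lut)
        out[[length(out) + 1L]] <- data.frame(
          t1_true = t1, rr_ms = rr, snr = sn,
          sd_ms = stats::sd(est), mean_ms = mean(est))
      }
    }
  }
  do.call(rbind, out)
}
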
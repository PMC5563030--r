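# Steady-state signal models for the inversion-recovery FLASH (3D LGE)
# sequence. All closed forms are validated in the test suite against
# bloch_steady_state(), a discrete Bloch recursion run to its periodic
# steady state. Signals are taken just prior to the first readout pulse
# (centric phase-encode ordering); the sin(alpha) receive factor is part of
# the global scaling absorbed into M0.

check_t1 <- function(t1_ms) {
  if (!is.numeric(t1_ms) || length(t1_ms) == 0L)
    stop("'t1_ms' must be numeric", call. = FALSE)
  if (any(!is.finite(t1_ms)) || any(t1_ms <= 0))
    stop("'t1_ms' must be finite and > 0", call. = FALSE)
  as.numeric(t1_ms)
}

#' Perturbation coefficient of the readout pulse train
#'
#' The factor `p >= 1` by which the train of small-flip-angle readout pulses
#' raises the recovered longitudinal magnetization at the end of each
#' inversion period, relative to the simple two-exponential
#' inversion-recovery model. With `E = exp(-TR/T1)`, `Q = cos(alpha) * E`:
#'
#' \deqn{p = \frac{1 - (1 - E)\,(1 - Q^N)/(1 - Q)}{E^N}}
#'
#' with the limit `(1 - Q^N)/(1 - Q) -> N` as `Q -> 1`. `p = 1` exactly when
#' `alpha = 90` degrees with `N = 1`, and in the `alpha -> 0` limit.
#'
#' @param params A [seq_params()] protocol.
#' @param t1_ms Longitudinal relaxation time(s), ms (> 0). Vectorized.
#' @return Dimensionless `p`, same length as `t1_ms`.
#' @export
perturbation_coefficient <- function(params, t1_ms) {
  stopifnot(inherits(params, "seq_params"))
  t1_ms <- check_t1(t1_ms)
  e_tr <- exp(-params$tr_ms / t1_ms)
  q <- cos(params$flip_rad) * e_tr
  n <- params$n_views
  geo <- ifelse(abs(1 - q) < 1e-12, n, (1 - q^n) / (1 - q))
  (1 - (1 - e_tr) * geo) / e_tr^n
}

# p * exp(-RR/T1) computed without forming p (whose E^-N factor overflows
# for T1 << TR): p * e^{-RR/T1} = (1 - (1-E) geo) * e^{-(RR - N TR)/T1}.
p_times_err <- function(params, t1_ms) {
  e_tr <- exp(-params$tr_ms / t1_ms)
  q <- cos(params$flip_rad) * e_tr
  n <- params$n_views
  geo <- ifelse(abs(1 - q) < 1e-12, n, (1 - q^n) / (1 - q))
  (1 - (1 - e_tr) * geo) *
    exp(-(params$rr_ms - n * params$tr_ms) / t1_ms)
}

#' Simple inversion-recovery steady-state signal
#'
#' The classical two-exponential steady-state longitudinal magnetization of
#' a repeated (inversion, TI, 90 degree excitation, recovery) block, which
#' ignores the perturbation by the readout pulse train:
#' `M0 * (1 - 2 exp(-TI/T1) + exp(-RR/T1))`.
#'
#' @param t1_ms T1 (ms, > 0). Vectorized.
#' @param m0 Scaling factor (arbitrary units).
#' @param ti_ms Inversion time (ms, > 0).
#' @param rr_ms Inversion-to-inversion interval (ms, > 0).
#' @return Signal in the units of `m0`.
#' @export
mzss_simple <- function(t1_ms, m0, ti_ms, rr_ms) {
  t1_ms <- check_t1(t1_ms)
  if (!all(is.finite(m0))) stop("'m0' must be finite", call. = FALSE)
  if (ti_ms <= 0 || rr_ms <= 0)
    stop("'ti_ms' and 'rr_ms' must be > 0", call. = FALSE)
  m0 * (1 - 2 * exp(-ti_ms / t1_ms) + exp(-rr_ms / t1_ms))
}

#' T1-weighting of the inversion-recovery FLASH signal
#'
#' The steady-state LGE signal for unit M0, including the perturbation from
#' the readout pulse train and, through `params$inversion_factor`, an
#' imperfect inversion (see [f_imperfect()]). For a perfect inversion:
#'
#' \deqn{f(T_1) = \frac{1 - 2 e^{-TI/T_1} + p\, e^{-RR/T_1}}
#'                    {1 + \cos^N(\alpha)\, e^{-RR/T_1}}}
#'
#' For the TI ~ 300 ms protocols used for post-contrast mapping, `f` is
#' strictly decreasing and positive over the 100-800 ms T1 range, which is
#' what gives the one-to-one signal-to-T1 relationship the mapper relies on.
#'
#' @inheritParams perturbation_coefficient
#' @return Dimensionless weighting, same length as `t1_ms`.
#' @export
f_weight <- function(params, t1_ms) {
  stopifnot(inherits(params, "seq_params"))
  t1_ms <- check_t1(t1_ms)
  e_ti <- exp(-params$ti_ms / t1_ms)
  e_rr <- exp(-params$rr_ms / t1_ms)
  cn <- cos(params$flip_rad)^params$n_views
  (1 - 2 * e_ti + p_times_err(params, t1_ms)) / (1 + cn * e_rr)
}

#' T1-weighting with an imperfect inversion
#'
#' Generalizes [f_weight()] to an inversion pulse of efficiency
#' `beta` in (0, 1] (the inversion multiplies Mz by `-beta`):
#'
#' \deqn{f_\beta(T_1) = \frac{1 - (1+\beta) e^{-TI/T_1}
#'                            + p\,\beta\, e^{-RR/T_1}}
#'                           {1 + \beta \cos^N(\alpha)\, e^{-RR/T_1}}}
#'
#' Equals [f_weight()] with a perfect inversion when `beta = 1`.
#'
#' @inheritParams perturbation_coefficient
#' @param beta Inversion factor in (0, 1]; defaults to
#'   `params$inversion_factor`.
#' @return Dimensionless weighting, same length as `t1_ms`.
#' @export
f_imperfect <- function(params, t1_ms, beta = params$inversion_factor) {
  stopifnot(inherits(params, "seq_params"))
  if (beta <= 0 || beta > 1) stop("'beta' must be in (0, 1]", call. = FALSE)
  t1_ms <- check_t1(t1_ms)
  e_ti <- exp(-params$ti_ms / t1_ms)
  e_rr <- exp(-params$rr_ms / t1_ms)
  cn <- cos(params$flip_rad)^params$n_views
  (1 - (1 + beta) * e_ti + beta * p_times_err(params, t1_ms)) /
    (1 + beta * cn * e_rr)
}

#' Inversion-recovery FLASH steady-state signal
#'
#' `m0` times the T1-weighting of the protocol (see [f_weight()] and
#' [f_imperfect()]); uses the protocol's `inversion_factor` (1 by default,
#' in which case this is the perfect-inversion model and reduces exactly to
#' [mzss_simple()] when `alpha = 90` degrees and `N = 1`).
#'
#' @inheritParams perturbation_coefficient
#' @param m0 Scaling factor (arbitrary units).
#' @return Signal in the units of `m0`.
#' @export
mzss_ir <- function(params, t1_ms, m0 = 1) {
  if (!all(is.finite(m0))) stop("'m0' must be finite", call. = FALSE)
  m0 * f_imperfect(params, t1_ms)
}

#' Steady-state signal with the inversion pulse disabled
#'
#' The model for the no-inversion LGE measurement used by the multi-TI fit
#' (the inversion time plays no role):
#'
#' \deqn{M_{zss} = M_0 \frac{1 - p\, e^{-RR/T_1}}
#'                          {1 - \cos^N(\alpha)\, e^{-RR/T_1}}}
#'
#' The `alpha -> 0` limit (`p -> 1`, `cos^N -> 1`) is the undisturbed
#' equilibrium `M0`; the removable 0/0 is guarded numerically.
#'
#' @inheritParams mzss_ir
#' @return Signal in the units of `m0`.
#' @export
mzss_noinv <- function(params, t1_ms, m0 = 1) {
  stopifnot(inherits(params, "seq_params"))
  if (!all(is.finite(m0))) stop("'m0' must be finite", call. = FALSE)
  t1_ms <- check_t1(t1_ms)
  e_rr <- exp(-params$rr_ms / t1_ms)
  cn <- cos(params$flip_rad)^params$n_views
  den <- 1 - cn * e_rr
  out <- ifelse(abs(den) < 1e-14, 1,
                (1 - p_times_err(params, t1_ms)) / den)
  m0 * out
}

#' Numerical derivative of the T1-weighting
#'
#' Central finite difference of [f_weight()] with step `h_ms` (default 1 ms,
#' well below the 2.5 ms mapping grid). The perturbation coefficient depends
#' on T1, so a numerical derivative is preferred over the error-prone
#' symbolic one. Within the post-contrast range of the TI ~ 300 ms
#' protocols, `f'` is negative and its magnitude decreases with T1 (long T1
#' species are estimated with poorer precision).
#'
#' Evaluation points within `h_ms` of `bounds` fall back to a one-sided
#' difference; those entries are flagged in the `"one_sided"` attribute of
#' the result.
#'
#' @inheritParams perturbation_coefficient
#' @param h_ms Finite-difference step (ms).
#' @param bounds Domain limits (ms) inside which `f` can be evaluated;
#'   defaults to the mapping grid range `c(100, 800)`.
#' @return `df/dT1` in 1/ms, with a logical `"one_sided"` attribute.
#' @export
f_prime <- function(params, t1_ms, h_ms = 1, bounds = c(100, 800)) {
  t1_ms <- check_t1(t1_ms)
  lo <- pmax(t1_ms - h_ms, bounds[1])
  hi <- pmin(t1_ms + h_ms, bounds[2])
  one_sided <- (lo != t1_ms - h_ms) | (hi != t1_ms + h_ms)
  out <- (f_weight(params, hi) - f_weight(params, lo)) / (hi - lo)
  attr(out, "one_sided") <- one_sided
  out
}

#' Discrete Bloch recursion oracle
#'
#' Simulates the sequence period by period until the longitudinal
#' magnetization just prior to the first readout pulse converges: optional
#' inversion (`Mz -> -beta * Mz`), free recovery over TI, `N` cycles of
#' (readout pulse `Mz -> Mz cos(alpha)`, recovery over TR), then free
#' recovery over `RR - TI - N*TR`. This is the independent validation
#' reference for every closed-form model in the package; it makes no use of
#' the perturbation-coefficient algebra.
#'
#' @inheritParams mzss_ir
#' @param invert If `FALSE`, the inversion pulse is disabled (the no
#'   inversion model).
#' @param tol Convergence tolerance on the period-to-period change of the
#'   pre-readout magnetization.
#' @param max_periods Maximum number of simulated periods before a
#'   non-convergence error.
#' @return Converged signal just prior to the first readout pulse, scaled
#'   by `m0`.
#' @export
bloch_steady_state <- function(params, t1_ms, m0 = 1, invert = TRUE,
                               tol = 1e-13, max_periods = 10000L) {
  stopifnot(inherits(params, "seq_params"))
  t1_ms <- check_t1(t1_ms)
  beta <- params$inversion_factor
  ca <- cos(params$flip_rad)
  t_free <- params$rr_ms - params$ti_ms - params$n_views * params$tr_ms
  one <- function(t1) {
    relax <- function(mz, t) 1 - (1 - mz) * exp(-t / t1)
    mz <- 0
    prev <- Inf
    for (k in seq_len(max_periods)) {
      if (invert) mz <- -beta * mz
      mz <- relax(mz, params$ti_ms)
      pre <- mz
      for (i in seq_len(params$n_views)) {
        mz <- relax(ca * mz, params$tr_ms)
      }
      mz <- relax(mz, t_free)
      if (abs(pre - prev) < tol) return(pre)
      prev <- pre
    }
    stop("Bloch recursion did not converge within 'max_periods'",
         call. = FALSE)
  }
  m0 * vapply(t1_ms, one, numeric(1))
}
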
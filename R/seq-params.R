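#' Inversion-recovery FLASH sequence parameters
#'
#' Bundles the timing and pulse parameters of the 3D LGE (inversion-recovery
#' spoiled gradient echo) sequence shared by every signal formula in the
#' package: the repetition time of the readout pulse train, the excitation
#' flip angle, the inversion time, the inversion-to-inversion interval
#' (one or more cardiac R-R intervals), the number of readout pulses per
#' segment (views per segment), and the inversion efficiency.
#'
#' Angles are given in degrees at every user interface and converted to
#' radians once, internally.
#'
#' @param tr_ms Repetition time between two readout pulses (ms, > 0).
#' @param flip_deg Excitation flip angle of the readout pulses
#'   (degrees, in (0, 90]; 90 degrees with `n_views = 1` is the classical
#'   simple IR-GRE limit).
#' @param ti_ms Inversion time: inversion pulse to first readout pulse
#'   (ms, > 0).
#' @param rr_ms Inversion-to-inversion interval (ms, > 0). Must leave a
#'   non-negative free-recovery interval: `ti_ms + n_views * tr_ms <= rr_ms`.
#' @param n_views Number of readout pulses per segment (integer >= 1).
#' @param inversion_factor Inversion efficiency beta in (0, 1];
#'   1 is a perfect 180 degree inversion.
#'
#' @return An object of class `seq_params`.
#' @examples
#' seq_params(tr_ms = 5, flip_deg = 15, ti_ms = 300, rr_ms = 900, n_views = 33)
#' @export
seq_params <- function(tr_ms, flip_deg, ti_ms, rr_ms, n_views,
                       inversion_factor = 1) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    as.numeric(x)
  }
  tr_ms <- num1(tr_ms, "tr_ms")
  flip_deg <- num1(flip_deg, "flip_deg")
  ti_ms <- num1(ti_ms, "ti_ms")
  rr_ms <- num1(rr_ms, "rr_ms")
  n_views <- num1(n_views, "n_views")
  inversion_factor <- num1(inversion_factor, "inversion_factor")

  if (tr_ms <= 0) stop("'tr_ms' must be > 0", call. = FALSE)
  if (ti_ms <= 0) stop("'ti_ms' must be > 0", call. = FALSE)
  if (rr_ms <= 0) stop("'rr_ms' must be > 0", call. = FALSE)
  if (flip_deg <= 0 || flip_deg > 90)
    stop("'flip_deg' must be in (0, 90]", call. = FALSE)
  if (n_views < 1 || n_views != round(n_views))
    stop("'n_views' must be an integer >= 1", call. = FALSE)
  if (inversion_factor <= 0 || inversion_factor > 1)
    stop("'inversion_factor' must be in (0, 1]", call. = FALSE)
  if (ti_ms + n_views * tr_ms > rr_ms + 1e-9)
    stop("invalid timing: ti_ms + n_views * tr_ms exceeds rr_ms ",
         "(negative free-recovery interval)", call. = FALSE)

  structure(
    list(tr_ms = tr_ms, flip_deg = flip_deg, flip_rad = flip_deg * pi / 180,
         ti_ms = ti_ms, rr_ms = rr_ms, n_views = as.integer(n_views),
         inversion_factor = inversion_factor),
    class = "seq_params")
}

#' @export
print.seq_params <- function(x, ...) {
  cat(sprintf(
    "IR-FLASH protocol: TR/alpha/TI/RR/N = %g ms/%g deg/%g ms/%g ms/%d",
    x$tr_ms, x$flip_deg, x$ti_ms, x$rr_ms, x$n_views))
  if (x$inversion_factor < 1)
    cat(sprintf(", inversion factor %g", x$inversion_factor))
  cat("\n")
  invisible(x)
}

#' Modify a protocol
#'
#' Returns a copy of a `seq_params` object with the named fields replaced,
#' re-validating the invariants.
#'
#' @param params A [seq_params()] object.
#' @param ... Named fields to replace (`tr_ms`, `flip_deg`, `ti_ms`,
#'   `rr_ms`, `n_views`, `inversion_factor`).
#' @return A new `seq_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "seq_params"))
  new <- utils::modifyList(
    params[c("tr_ms", "flip_deg", "ti_ms", "rr_ms", "n_views",
             "inversion_factor")],
    list(...))
  do.call(seq_params, new)
}
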
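# Volume and sidecar I/O. Volumes are NIfTI-1 only (DICOM conversion is
# upstream of this tool); masks are NIfTI volumes with nonzero = included.
# Sequence-parameter sidecars are JSON or YAML with times in ms and the
# flip angle in degrees.

#' Read a 3D NIfTI volume
#'
#' @param path Path to a NIfTI-1 file.
#' @return A 3D array (an `RNifti` image carrying spacing and orientation
#'   metadata); a `"spacing"` attribute (mm per axis) is attached.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L)
    stop("expected a 3D volume, got ", length(dm), "D: ", path,
         call. = FALSE)
  attr(img, "spacing") <- RNifti::pixdim(img)[seq_len(3)]
  img
}

#' Write a 3D volume as NIfTI
#'
#' @param volume 3D numeric array; a `"spacing"` attribute (mm) is
#'   honored, as is `RNifti` metadata if present.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Optional spacing override (mm per axis).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing = NULL) {
  if (length(dim(volume)) != 3L)
    stop("'volume' must be a 3D array", call. = FALSE)
  spacing <- spacing %||% attr(volume, "spacing") %||% c(1, 1, 1)
  img <- RNifti::asNifti(unclass(as.array(volume)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a sequence-parameter sidecar
#'
#' JSON or YAML (by file extension) with keys `tr_ms`, `flip_deg`,
#' `ti_ms`, `rr_ms`, `n_views` and optional `inversion_factor`
#' (default 1).
#'
#' @param path Path to the sidecar.
#' @return A validated [seq_params()] object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  need <- c("tr_ms", "flip_deg", "ti_ms", "rr_ms", "n_views")
  miss <- setdiff(need, names(lst))
  if (length(miss))
    stop("sidecar ", path, " is missing key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  seq_params(tr_ms = lst$tr_ms, flip_deg = lst$flip_deg,
             ti_ms = lst$ti_ms, rr_ms = lst$rr_ms, n_views = lst$n_views,
             inversion_factor = lst$inversion_factor %||% 1)
}

#' Write a JSON run report
#'
#' Serializes a named list (tool version, protocol echo, seeds, M0, grid,
#' warnings, timings) as pretty-printed JSON.
#'
#' @param report Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  report$tool <- report$tool %||%
    paste0("refblochi ", as.character(utils::packageVersion("refblochi")))
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

params_as_list <- function(p)
  p[c("tr_ms", "flip_deg", "ti_ms", "rr_ms", "n_views",
      "inversion_factor")]
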
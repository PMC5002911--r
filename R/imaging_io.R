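#' Calf muscles analysed by the oximetry pipeline
#'
#' The four calf muscles segmented for volume-of-interest (VOI) analysis:
#' gastrocnemius, soleus, anterior tibialis, and peroneus longus.
#'
#' @return Character vector of muscle names.
#' @export
calf_muscles <- function() {
  c("gastrocnemius", "soleus", "anterior_tibialis", "peroneus_longus")
}

stop_with <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "muscleBOLD_error")))
}

#' Construct a 4D BOLD series
#'
#' Container for a dynamic BOLD acquisition: a 4-dimensional array of signal
#' intensities (x, y, z, time; arbitrary scanner units), the voxel size in mm,
#' and the repetition time TR in seconds. Frame `i` covers the interval
#' `[(i-1)*tr, i*tr)` and is timestamped at its window centre `(i-0.5)*tr`,
#' so that event timings (time to peak, time to recovery) are unbiased.
#'
#' @param voxels 4D numeric array of signal intensities, time as 4th axis.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#' @param tr Repetition time in seconds (> 0).
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(voxels, voxel_size, tr) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L)
    stop_with("muscleBOLD_not_4d", "'voxels' must be a 4-D array (x, y, z, time)")
  if (any(dim(voxels) < 1L))
    stop_with("muscleBOLD_bad_dims", "all array dimensions must be positive")
  if (dim(voxels)[4L] < 2L)
    stop_with("muscleBOLD_not_timeseries",
              "a BOLD series needs at least 2 time frames, got %d", dim(voxels)[4L])
  if (!all(is.finite(voxels)))
    stop_with("muscleBOLD_nonfinite", "signal intensities must all be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop_with("muscleBOLD_bad_voxel_size", "'voxel_size' must be 3 positive mm values")
  tr <- as.numeric(tr)
  if (length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop_with("muscleBOLD_bad_tr", "'tr' must be a single positive number of seconds")
  structure(list(voxels = voxels, voxel_size = voxel_size, tr = tr),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<bold_series> %d x %d x %d voxels, %d frames, TR = %g s (%.1f min)\n",
              d[1], d[2], d[3], d[4], x$tr, d[4] * x$tr / 60))
  cat(sprintf("  voxel size: %g x %g x %g mm\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Read a 4D BOLD series from a NIfTI file
#'
#' The repetition time is taken from the header time step (4th pixdim) unless
#' overridden; intensities are returned as stored, with only the header
#' scale factors applied by the NIfTI reader.
#'
#' @param path Path to a `.nii` / `.nii.gz` file containing a 4D image.
#' @param tr Optional TR in seconds, overriding the header value.
#' @return A [bold_series()].
#' @export
read_bold_series <- function(path, tr = NULL) {
  if (!file.exists(path))
    stop_with("muscleBOLD_missing_file", "file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop_with("muscleBOLD_not_timeseries",
              "%s is a %d-D image, not a time series (need 4-D)", path, length(d))
  pd <- RNifti::pixdim(img)
  if (is.null(tr)) tr <- pd[4L]
  if (!is.finite(tr) || tr <= 0)
    stop_with("muscleBOLD_bad_tr",
              "nonpositive TR (%s) in header of %s; pass 'tr' explicitly", tr, path)
  bold_series(array(as.numeric(img), dim = d), voxel_size = pd[1:3], tr = tr)
}

#' Write a BOLD series to a NIfTI file
#'
#' @param series A [bold_series()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_bold_series <- function(series, path) {
  stopifnot(inherits(series, "bold_series"))
  img <- RNifti::asNifti(series$voxels)
  RNifti::pixdim(img) <- c(series$voxel_size, series$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a muscle VOI label map
#'
#' A 3D integer volume in which 0 marks background and each positive label is
#' mapped to a muscle name by `legend`. The map must share spatial dimensions
#' with the BOLD series it annotates; coregistration itself is an upstream
#' responsibility and is only shape-checked here (see [validate_alignment()]).
#'
#' @param labels 3D integer array; 0 = background.
#' @param legend Named character vector mapping label integers (names) to
#'   muscle names, e.g. `c("1" = "gastrocnemius", "2" = "soleus")`.
#' @param voxel_size Numeric length-3 voxel size in mm.
#' @return An object of class `voi_label_map`.
#' @export
voi_label_map <- function(labels, legend, voxel_size) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop_with("muscleBOLD_not_3d", "'labels' must be a 3-D array")
  if (any(labels != round(labels)))
    stop_with("muscleBOLD_float_mask",
              "label volume contains non-integer values; masks are not rounded")
  labels <- array(as.integer(round(labels)), dim = dim(labels))
  legend <- check_legend(legend)
  present <- unique(as.vector(labels))
  missing <- setdiff(as.integer(names(legend)), present)
  if (length(missing))
    stop_with("muscleBOLD_legend_mismatch",
              "legend references label(s) absent from the mask: %s",
              paste(missing, collapse = ", "))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_with("muscleBOLD_bad_voxel_size", "'voxel_size' must be 3 positive mm values")
  structure(list(labels = labels, legend = legend, voxel_size = voxel_size),
            class = "voi_label_map")
}

check_legend <- function(legend) {
  legend <- unlist(legend)
  if (is.null(names(legend)) || any(names(legend) == ""))
    stop_with("muscleBOLD_bad_legend",
              "legend must map label integers (names) to muscle names")
  ints <- suppressWarnings(as.integer(names(legend)))
  if (any(is.na(ints)) || any(ints <= 0L))
    stop_with("muscleBOLD_bad_legend", "legend labels must be positive integers")
  if (anyDuplicated(ints) || anyDuplicated(legend))
    stop_with("muscleBOLD_bad_legend", "legend labels and muscle names must be unique")
  stats::setNames(as.character(legend), as.character(ints))
}

#' @export
print.voi_label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<voi_label_map> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  for (lab in names(x$legend)) {
    cat(sprintf("  %s -> %s (%d voxels)\n", lab, x$legend[[lab]],
                sum(x$labels == as.integer(lab))))
  }
  invisible(x)
}

#' Read a VOI label map from a NIfTI file
#'
#' The on-disk volume must be integer-typed; float-valued masks are rejected
#' rather than rounded, so that accidental interpolation (e.g. from a
#' resampling step) cannot silently corrupt VOI membership.
#'
#' @param path Path to a 3D integer NIfTI file.
#' @param legend Named character vector or path to a JSON/YAML file mapping
#'   label integers to muscle names.
#' @inherit voi_label_map return
#' @export
read_voi_labels <- function(path, legend) {
  if (!file.exists(path))
    stop_with("muscleBOLD_missing_file", "file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop_with("muscleBOLD_not_3d", "%s is %d-D; a label map must be 3-D", path, length(d))
  hdr <- RNifti::niftiHeader(img)
  int_codes <- c(2L, 4L, 8L, 256L, 512L, 768L, 1024L, 1280L)  # NIfTI integer dtypes
  if (!(hdr$datatype %in% int_codes))
    stop_with("muscleBOLD_float_mask",
              "%s is stored with float datatype %d; masks must be integer-typed",
              path, hdr$datatype)
  if (is.character(legend) && length(legend) == 1L && file.exists(legend))
    legend <- read_voi_legend(legend)
  voi_label_map(array(as.integer(img), dim = d), legend,
                voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write a VOI label map to a NIfTI file
#'
#' @param mask A [voi_label_map()].
#' @param path Output NIfTI path; the volume is written with int32 datatype.
#' @param legend_path Optional path to also write the legend as JSON.
#' @return `path`, invisibly.
#' @export
write_voi_labels <- function(mask, path, legend_path = NULL) {
  stopifnot(inherits(mask, "voi_label_map"))
  img <- RNifti::asNifti(array(as.integer(mask$labels), dim = dim(mask$labels)))
  RNifti::pixdim(img) <- mask$voxel_size
  RNifti::writeNifti(img, path, datatype = "int32")
  if (!is.null(legend_path))
    jsonlite::write_json(as.list(mask$legend), legend_path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a VOI legend from JSON or YAML
#'
#' @param path File with a `{label_int: muscle_name}` mapping.
#' @return Named character vector suitable for [voi_label_map()].
#' @export
read_voi_legend <- function(path) {
  if (!file.exists(path))
    stop_with("muscleBOLD_missing_file", "file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  check_legend(raw)
}

#' Check that a BOLD series and a label map are geometrically aligned
#'
#' Coregistration of the functional series with the anatomy-derived mask is
#' assumed to have happened upstream; this check only enforces matching
#' spatial dimensions and voxel sizes (within 1e-6 mm) before any VOI
#' statistic is computed.
#'
#' @param series A [bold_series()].
#' @param mask A [voi_label_map()].
#' @return Invisibly, `list(series = series, mask = mask)` on success.
#' @export
validate_alignment <- function(series, mask) {
  if (inherits(series, "voi_label_map") && inherits(mask, "bold_series")) {
    tmp <- series; series <- mask; mask <- tmp  # argument order is immaterial
  }
  stopifnot(inherits(series, "bold_series"), inherits(mask, "voi_label_map"))
  ds <- dim(series$voxels)[1:3]
  dm <- dim(mask$labels)
  if (!all(ds == dm))
    stop_with("muscleBOLD_dim_mismatch",
              "spatial dimensions differ: series %s vs mask %s",
              paste(ds, collapse = "x"), paste(dm, collapse = "x"))
  if (any(abs(series$voxel_size - mask$voxel_size) > 1e-6))
    stop_with("muscleBOLD_voxel_size_mismatch",
              "voxel sizes differ: series (%s) mm vs mask (%s) mm",
              paste(series$voxel_size, collapse = ", "),
              paste(mask$voxel_size, collapse = ", "))
  invisible(list(series = series, mask = mask))
}
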
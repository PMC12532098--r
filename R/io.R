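#' Extract normalized 2-D slices from a NIfTI volume
#'
#' Loads a 3-D volume, min-max normalizes intensities per volume to \[0, 1\],
#' extracts 2-D slices along the chosen axis and drops slices whose
#' foreground fraction (pixels above 0.05 after normalization) falls below a
#' threshold. In-plane pixel spacing is taken from the header.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param axis slicing axis, 1-3 (default 3, axial for RAS-ish volumes).
#' @param foreground_min_fraction minimum fraction of foreground pixels for a
#'   slice to be kept (default 0, keep all).
#' @return list of slice records: `list(volume_id, slice_index, spacing,
#'   data)` with 0-based `slice_index` and `data` a matrix in \[0, 1\].
#' @export
load_slices <- function(path, axis = 3L, foreground_min_fraction = 0) {
  if (!axis %in% 1:3) stop_config("axis must be 1, 2 or 3")
  vol <- read_nifti(path)
  v <- vol$data
  rng <- range(v)
  if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1]) else v <- v * 0
  n_slices <- dim(v)[axis]
  spacing <- vol$pixdim[setdiff(1:3, axis)]
  spacing[!is.finite(spacing) | spacing <= 0] <- 1
  vid <- sub("\\.nii(\\.gz)?$", "", basename(path))
  out <- list()
  for (i in seq_len(n_slices)) {
    sl <- switch(axis, v[i, , ], v[, i, ], v[, , i])
    if (mean(sl > 0.05) < foreground_min_fraction) next
    out[[length(out) + 1L]] <- list(volume_id = vid, slice_index = i - 1L,
                                    spacing = spacing, data = sl)
  }
  out
}

#' Write slice records back to a NIfTI volume
#'
#' Slices are stacked along the third axis; spacing is preserved exactly.
#' A load -> save -> load round trip preserves data to float32 precision.
#'
#' @param records list of slice records (as from [load_slices()], or any
#'   list of `list(spacing, data)` with equal-shape matrices).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_slices <- function(records, path) {
  if (length(records) == 0) stop_config("no slices to save")
  d <- dim(records[[1]]$data)
  vol <- array(0, dim = c(d, length(records)))
  for (i in seq_along(records)) {
    check_same_shape(records[[i]]$data, records[[1]]$data, "slices")
    vol[, , i] <- records[[i]]$data
  }
  sp <- records[[1]]$spacing
  write_nifti(vol, path, pixdim = c(rep_len(sp, 2), 1))
  invisible(path)
}
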
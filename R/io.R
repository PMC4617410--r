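# Readers and writers for the supported formats: tab-delimited time x voxel
# matrices, BIDS-style events TSV, and NIfTI (4-D data + 3-D ROI mask).

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path)

#' Read an ROI time series
#'
#' Reads either a tab-delimited matrix (rows = volumes, columns = voxels,
#' header = voxel ids) or a 4-D NIfTI volume together with a binary 3-D ROI
#' mask on the same grid. For NIfTI input the voxels are the nonzero mask
#' positions taken in column-major order over (x, y, z), which fixes a
#' deterministic voxel ordering across reads.
#'
#' @param path path to a `.tsv`/text matrix or a `.nii`/`.nii.gz` 4-D image.
#' @param mask_path path to a 3-D binary mask NIfTI; required for NIfTI
#'   input.
#' @return a tibble, one row per volume, one column per voxel.
#' @export
read_roi_timeseries <- function(path, mask_path = NULL) {
  if (is_nifti_path(path)) {
    if (is.null(mask_path)) abort("NIfTI input requires `mask_path`.")
    rlang::check_installed("RNifti")
    img <- RNifti::readNifti(path)
    msk <- RNifti::readNifti(mask_path)
    if (length(dim(img)) != 4) abort("Expected a 4-D NIfTI image.")
    if (!identical(dim(img)[1:3], dim(msk)[1:3])) {
      abort("Image and mask grids do not match.")
    }
    idx <- which(msk != 0)
    if (length(idx) == 0) abort("Empty mask: no nonzero voxels.")
    flat <- matrix(img, nrow = prod(dim(img)[1:3]), ncol = dim(img)[4])
    mat <- t(flat[idx, , drop = FALSE])
    colnames(mat) <- sprintf("vox%06d", idx)
    return(as_bold_tibble(mat))
  }
  dat <- utils::read.delim(path, check.names = FALSE)
  if (!all(vapply(dat, is.numeric, logical(1)))) {
    abort("Non-numeric cells in time-series matrix.")
  }
  as_bold_tibble(as.matrix(dat))
}

#' Write an ROI time series as a tab-delimited matrix
#'
#' Mirrors [read_roi_timeseries()] bit-exactly for round trips.
#'
#' @param x time series (matrix or tibble).
#' @param path output path.
#' @export
write_roi_timeseries <- function(x, path) {
  x <- as_bold_matrix(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a BIDS-style events table to per-volume labels
#'
#' Volume `t` (0-based) is labeled by the event whose half-open interval
#' `[onset, onset + duration)` covers time `t * tr`. Uncovered volumes are
#' labeled `"unlabeled"`. Overlapping events are an error.
#'
#' @param path events TSV with columns `onset`, `duration` (seconds) and
#'   optionally `trial`, `phase`, `label`, `choice_block`, `landmark`,
#'   `error`.
#' @param tr sampling interval in seconds.
#' @param n_volumes number of volumes in the paired run.
#' @return a label-sequence tibble, one row per volume.
#' @export
read_events <- function(path, tr, n_volumes) {
  stopifnot(tr > 0, n_volumes >= 1)
  ev <- utils::read.delim(path, check.names = FALSE)
  if (nrow(ev) == 0 || !all(c("onset", "duration") %in% names(ev))) {
    ev <- tibble::tibble(onset = numeric(), duration = numeric())
  }
  events_to_labels(ev, tr, n_volumes)
}

events_to_labels <- function(ev, tr, n_volumes) {
  run_end <- n_volumes * tr
  if (nrow(ev) > 0) {
    ev <- ev[order(ev$onset), , drop = FALSE]
    if (any(ev$onset >= run_end)) abort("Event onset beyond the end of the run.")
    ends <- ev$onset + ev$duration
    if (nrow(ev) > 1 && any(ev$onset[-1] < ends[-nrow(ev)] - 1e-9)) {
      abort("Overlapping events in the events table.")
    }
  }
  t_sec <- (seq_len(n_volumes) - 1) * tr
  out <- tibble::tibble(
    volume = seq_len(n_volumes), onset = t_sec,
    trial = 1L, phase = NA_character_, label = "unlabeled",
    choice_block = 0L, landmark = NA_character_, error = FALSE
  )
  if (nrow(ev) == 0) return(out)
  hit <- findInterval(t_sec + 1e-9, ev$onset)
  covered <- hit >= 1 & t_sec < (ev$onset + ev$duration)[pmax(hit, 1)] - 1e-9
  fill <- function(col, default) {
    if (col %in% names(ev)) ifelse(covered, ev[[col]][hit], default) else NULL
  }
  out$label[covered] <- as.character(ev$label[hit[covered]] %||% "event")
  for (col in c("trial", "choice_block")) {
    v <- fill(col, NA_integer_)
    if (!is.null(v)) out[[col]] <- dplyr::coalesce(as.integer(v), out[[col]])
  }
  for (col in c("phase", "landmark")) {
    v <- fill(col, NA_character_)
    if (!is.null(v)) out[[col]] <- dplyr::coalesce(as.character(v), out[[col]])
  }
  if ("error" %in% names(ev)) {
    v <- fill("error", 0)
    out$error <- !is.na(v) & as.numeric(v) != 0
  }
  out
}

#' Write a label sequence as a BIDS-style events TSV
#'
#' Consecutive volumes sharing the same (trial, label, choice block) collapse
#' into one event row with `onset` and `duration` in seconds. Reading the
#' file back with [read_events()] at the same `tr` reproduces the per-volume
#' labels.
#'
#' @param labels a label-sequence tibble.
#' @param path output path.
#' @param tr sampling interval in seconds.
#' @export
write_events <- function(labels, path, tr) {
  stopifnot(is.data.frame(labels), tr > 0)
  key <- paste(labels$trial, labels$label, labels$choice_block,
               cumsum(c(1, diff(labels$volume)) != 1))
  r <- rle(key)
  idx <- cumsum(c(1, head(r$lengths, -1)))
  ev <- tibble::tibble(
    onset = (labels$volume[idx] - 1) * tr,
    duration = r$lengths * tr,
    trial = labels$trial[idx],
    phase = labels$phase[idx],
    label = labels$label[idx],
    choice_block = labels$choice_block[idx],
    landmark = labels$landmark[idx],
    error = as.integer(labels$error[idx])
  )
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
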
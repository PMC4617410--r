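# Internal helpers shared across modules.

#' Coerce a BOLD time series to a numeric matrix
#'
#' Accepts a numeric matrix (time x voxels) or a data frame with one column
#' per voxel, and returns a numeric matrix. Column names are kept as voxel
#' identifiers (generated as `v001`, `v002`, ... when absent).
#'
#' @param x matrix or data frame, rows = volumes, columns = voxels.
#' @return numeric matrix with voxel column names.
#' @keywords internal
as_bold_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("BOLD time series must be a numeric matrix or data frame (time x voxels).")
  }
  if (anyNA(x)) abort("BOLD time series contains missing values.")
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("v%03d", seq_len(ncol(x)))
  }
  x
}

# Return the series in tibble form (the package's user-facing convention).
as_bold_tibble <- function(x) {
  tibble::as_tibble(as.data.frame(x))
}

#' Extract the per-volume label vector from a label sequence
#'
#' @param labels a label-sequence tibble (with a `label` column) or a plain
#'   character/factor vector.
#' @keywords internal
label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    if (!"label" %in% names(labels)) abort("Label sequence tibble needs a `label` column.")
    as.character(labels$label)
  } else {
    as.character(labels)
  }
}

# Per-volume trial ids; defaults to a single trial when absent.
trial_vector <- function(labels, n) {
  if (is.data.frame(labels) && "trial" %in% names(labels)) {
    as.integer(labels$trial)
  } else {
    rep(1L, n)
  }
}

check_paired <- function(x, labels) {
  n <- if (is.data.frame(labels) || is.matrix(labels)) nrow(labels) else length(labels)
  if (nrow(x) != n) {
    abort(sprintf(
      "Time series (%d volumes) and label sequence (%d volumes) are not paired.",
      nrow(x), n
    ))
  }
  invisible(TRUE)
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing so every randomized step of a pipeline
#' consumes its own reproducible stream. Stays below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... further integers or strings identifying the consumer.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  parts <- list(...)
  h <- as.double(master) %% 2147483647
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.double(p)
    h <- (h * 69069 + v * 12345 + 1) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
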
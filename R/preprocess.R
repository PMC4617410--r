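# The preprocessing chain applied before multivariate analysis:
# standardization + detrending + discrete-cosine high-pass, nuisance
# regression, Wiener deconvolution of the hemodynamic response, per-trial
# control-phase subtraction, and behavioral-error exclusion.

# SPM-style DCT-II high-pass basis: components with period >= cutoff.
dct_highpass_basis <- function(Tn, tr, cutoff_s) {
  K <- floor(2 * Tn * tr / cutoff_s)
  if (K < 1) return(NULL)
  t <- seq_len(Tn)
  sapply(seq_len(K), function(k) cos(pi * k * (2 * t - 1) / (2 * Tn)))
}

#' Standardize, detrend and high-pass filter a time series
#'
#' Per voxel: removes a linear trend, projects out a discrete-cosine basis of
#' all components with period at least `highpass_cutoff_s` (an exact,
#' phase-free high-pass in the 256 s cutoff convention), then scales to zero
#' mean and unit variance. Voxels left with (numerically) zero variance are
#' dropped with a warning, never imputed.
#'
#' @param x time series (matrix or tibble, time x voxels).
#' @param tr sampling interval in seconds.
#' @param highpass_cutoff_s high-pass cutoff period in seconds (default 256);
#'   must exceed `2 * tr`.
#' @return a tibble of filtered, standardized values.
#' @export
standardize_detrend_filter <- function(x, tr, highpass_cutoff_s = 256) {
  x <- as_bold_matrix(x)
  if (nrow(x) < 2) abort("Need at least 2 volumes.")
  if (highpass_cutoff_s <= 2 * tr) abort("`highpass_cutoff_s` must exceed 2 * tr.")
  Tn <- nrow(x)
  t <- seq_len(Tn)
  X <- cbind(1, t - mean(t))
  B <- dct_highpass_basis(Tn, tr, highpass_cutoff_s)
  if (!is.null(B)) X <- cbind(X, B)
  res <- x - X %*% qr.coef(qr(X), x)
  s <- apply(res, 2, stats::sd)
  keep <- s > 1e-12
  if (!all(keep)) {
    warn(paste0(
      "Dropping ", sum(!keep), " zero-variance voxel(s) after filtering: ",
      paste(colnames(x)[!keep], collapse = ", ")
    ))
    res <- res[, keep, drop = FALSE]
    s <- s[keep]
  }
  if (ncol(res) == 0) abort("All voxels had zero variance after filtering.")
  as_bold_tibble(sweep(res, 2, s, `/`))
}

#' Regress nuisance covariates out of a time series
#'
#' Returns the least-squares residuals of every voxel on an intercept plus
#' the given regressors (e.g. six head-motion parameters). Collinear
#' regressor columns are dropped with a warning.
#'
#' @param x time series (matrix or tibble).
#' @param regressors numeric matrix (time x k) of nuisance covariates.
#' @return a tibble of residuals.
#' @export
regress_nuisance <- function(x, regressors) {
  x <- as_bold_matrix(x)
  R <- as.matrix(regressors)
  if (nrow(R) != nrow(x)) abort("Regressor rows must match the time dimension.")
  X <- cbind(intercept = 1, R)
  fit <- stats::lm.fit(X, x)
  coefs <- if (is.matrix(fit$coefficients)) fit$coefficients else as.matrix(fit$coefficients)
  aliased <- apply(coefs, 1, function(r) all(is.na(r)))
  if (any(aliased)) {
    warn(paste0("Dropping ", sum(aliased), " collinear regressor column(s)."))
  }
  res <- fit$residuals
  colnames(res) <- colnames(x)
  as_bold_tibble(res)
}

#' Wiener deconvolution of the hemodynamic response
#'
#' Frequency-domain Wiener filter against an HRF kernel:
#' `X(f) = Y(f) H*(f) / (|H(f)|^2 + noise_level)`, applied per voxel with
#' zero padding (no circular wrap-around). `noise_level` is the assumed
#' noise-to-signal power ratio, i.e. the reciprocal of the assumed SNR; it
#' trades restoration sharpness against noise amplification. Output length
#' equals input length. Note that the final `length(h)` volumes of a
#' truncated acquisition are only weakly constrained by the data and are
#' recovered less accurately.
#'
#' @param x time series (matrix, vector, or tibble).
#' @param tr sampling interval in seconds (used for the default kernel).
#' @param noise_level scalar Wiener regularization (default 0.02).
#' @param hrf kernel to deconvolve; default [canonical_hrf()] at `tr`.
#' @return deconvolved series, tibble (or vector for vector input).
#' @export
deconvolve_hrf <- function(x, tr, noise_level = 0.02, hrf = NULL) {
  if (noise_level < 0) abort("`noise_level` must be non-negative.")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as_bold_matrix(x)
  h <- hrf %||% canonical_hrf(tr)
  Tn <- nrow(xm)
  L <- length(h)
  np <- Tn + 2L * L
  H <- fft(c(h, rep(0, np - L)))
  G <- Conj(H) / (Mod(H)^2 + noise_level)
  out <- apply(xm, 2, function(col) {
    Y <- fft(c(col, rep(0, np - Tn)))
    Re(fft(Y * G, inverse = TRUE))[seq_len(Tn)] / np
  })
  out <- matrix(out, nrow = Tn, dimnames = list(NULL, colnames(xm)))
  if (vec) drop(out) else as_bold_tibble(out)
}

#' Subtract per-trial control-phase means
#'
#' For every trial and every mapped task class, subtracts (voxel-wise) the
#' mean over that trial's corresponding control-class volumes from every
#' volume of the task class. Compensates sensory-motor demands so that
#' higher cognitive components dominate the class contrasts. Unmapped labels
#' pass through unchanged.
#'
#' @param x time series (matrix or tibble).
#' @param labels paired label-sequence tibble (needs `label` and `trial`).
#' @param map named character vector, task label -> control label; default
#'   [default_control_map()].
#' @return a tibble of control-subtracted values.
#' @export
subtract_control_means <- function(x, labels, map = default_control_map()) {
  x <- as_bold_matrix(x)
  check_paired(x, labels)
  lab <- label_vector(labels)
  trial <- trial_vector(labels, nrow(x))
  out <- x
  for (tr_id in unique(trial)) {
    in_trial <- trial == tr_id
    for (task_class in intersect(names(map), unique(lab[in_trial]))) {
      rows <- in_trial & lab == task_class
      ctrl <- in_trial & lab == map[[task_class]]
      if (!any(ctrl)) {
        abort(sprintf(
          "Trial %s has no control volumes of class '%s' (needed for task class '%s').",
          tr_id, map[[task_class]], task_class
        ))
      }
      out[rows, ] <- sweep(out[rows, , drop = FALSE], 2,
                           colMeans(x[ctrl, , drop = FALSE]), `-`)
    }
  }
  as_bold_tibble(out)
}

#' Exclude behavioral-error volumes
#'
#' Removes volumes whose error flag is set, preserving order and trial
#' structure, and returns the consistent (time series, labels) pair.
#'
#' @param x time series (matrix or tibble).
#' @param labels paired label-sequence tibble with an `error` column.
#' @return a list with elements `bold` (tibble) and `labels` (tibble).
#' @export
exclude_error_timepoints <- function(x, labels) {
  x <- as_bold_matrix(x)
  check_paired(x, labels)
  keep <- !(labels$error %||% rep(FALSE, nrow(x)))
  list(
    bold = as_bold_tibble(x[keep, , drop = FALSE]),
    labels = labels[keep, , drop = FALSE]
  )
}
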
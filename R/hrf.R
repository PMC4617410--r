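#' Canonical double-gamma hemodynamic response function
#'
#' The standard double-gamma HRF (response peak near 6 s, undershoot near
#' 16 s, peak-to-undershoot ratio 6) sampled at the acquisition interval and
#' normalized to unit peak.
#'
#' @param tr sampling interval in seconds.
#' @param duration_s kernel length in seconds (default 32).
#' @param peak_delay,undershoot_delay gamma shape parameters (seconds).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return numeric vector, the sampled kernel.
#' @export
#' @examples
#' h <- canonical_hrf(1.8)
#' plot(seq_along(h) - 1, h, type = "b")
canonical_hrf <- function(tr, duration_s = 32, peak_delay = 6,
                          undershoot_delay = 16, ratio = 6) {
  stopifnot(tr > 0, duration_s > tr)
  t <- seq(0, duration_s, by = tr)
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    stats::dgamma(t, shape = undershoot_delay, rate = 1) / ratio
  h / max(h)
}

#' Convolve a signal matrix with an HRF kernel
#'
#' Causal linear convolution, column by column. With `keep_tail = FALSE`
#' (default) the output is truncated to the input length, emulating an
#' acquisition that stops with the task; with `keep_tail = TRUE` the full
#' convolution (length T + length(h) - 1) is returned.
#'
#' @param x numeric matrix or vector (time x voxels).
#' @param h HRF kernel, e.g. [canonical_hrf()].
#' @param keep_tail keep the convolution tail beyond the input length?
#' @return matrix (or vector) of the convolved signal.
#' @export
convolve_hrf <- function(x, h, keep_tail = FALSE) {
  vec <- is.null(dim(x))
  x <- if (vec) matrix(x, ncol = 1) else as_bold_matrix(x)
  Tn <- nrow(x)
  L <- length(h)
  out_len <- if (keep_tail) Tn + L - 1L else Tn
  np <- Tn + L
  H <- fft(c(h, rep(0, np - L)))
  y <- apply(x, 2, function(col) {
    Y <- fft(c(col, rep(0, np - Tn)))
    Re(fft(Y * H, inverse = TRUE))[seq_len(out_len)] / np
  })
  y <- matrix(y, nrow = out_len, dimnames = list(NULL, colnames(x)))
  if (vec) drop(y) else y
}
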
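# Bootstrap distributions, bootstrap-normalized statistics, non-parametric
# p-values, and the voxel-subsampling protocol for comparing ROIs of
# different sizes.

new_stat_result <- function(statistic, observed, boot, scheme, B, seed,
                            normalization = "mean", extra = list()) {
  smaller_is_stronger <- statistic == "wilks"
  exceed <- if (smaller_is_stronger) sum(boot <= observed) else sum(boot >= observed)
  p <- (1 + exceed) / (1 + length(boot))
  normalized <- switch(normalization,
    mean = observed / mean(boot),
    z = (observed - mean(boot)) / stats::sd(boot),
    abort("`normalization` must be 'mean' or 'z'.")
  )
  structure(
    c(list(
      statistic = statistic, observed = observed, bootstrap_values = boot,
      normalized = normalized, p_value = p, scheme = scheme,
      B = as.integer(B), rng_seed = seed, normalization = normalization
    ), extra),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf(
    "<stat_result> %s (%s bootstrap, B = %d): observed = %.4g, normalized = %.4g, p = %.4g\n",
    x$statistic, x$scheme, x$B, x$observed, x$normalized, x$p_value
  ))
  invisible(x)
}

#' @export
tidy.stat_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, scheme = x$scheme, B = x$B,
    observed = x$observed, bootstrap_mean = mean(x$bootstrap_values),
    normalized = x$normalized, p_value = x$p_value
  )
}

#' @export
glance.stat_result <- function(x, ...) tidy(x, ...)

#' @export
autoplot.stat_result <- function(object, ...) {
  df <- tibble::tibble(value = object$bootstrap_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, color = "red") +
    ggplot2::labs(
      x = object$statistic,
      y = "bootstrap count",
      title = sprintf("%s vs %s-bootstrap null (p = %.3g)",
                      object$statistic, object$scheme, object$p_value)
    )
}

# Shared inner loop: observed + B resampled statistic values.
boot_statistic_values <- function(x, labels, statistic, B, scheme, ridge,
                                  min_shift) {
  xtx <- if (statistic %in% c("t2", "wilks")) crossprod(x) else NULL
  observed <- compute_statistic(x, factor(label_vector(labels)), statistic,
                                ridge, xtx = xtx)
  boot <- vapply(seq_len(B), function(b) {
    lb <- resample_labels(labels, scheme, min_shift = min_shift)
    compute_statistic(x, factor(label_vector(lb)), statistic, ridge, xtx = xtx)
  }, numeric(1))
  list(observed = observed, boot = boot)
}

#' Bootstrap distribution and normalized statistic
#'
#' Computes the observed statistic on the true labels, re-computes it on `B`
#' label resamplings of the chosen scheme, and returns the bootstrap-
#' normalized value `observed / mean(bootstrap)` (about 1 under the null)
#' together with the add-one non-parametric p-value
#' `(1 + #\{bootstrap >= observed\}) / (1 + B)`. For Wilks' lambda, where
#' smaller values mean stronger separation, the exceedance direction is
#' reversed.
#'
#' @param x time series (matrix or tibble).
#' @param labels paired label-sequence tibble.
#' @param statistic one of `"t2"`, `"wilks"`, `"gcr"`, `"md"`.
#' @param B number of bootstrap resamples (default 1000).
#' @param scheme resampling scheme: `"block"` (default), `"cycle"`,
#'   `"random"`.
#' @param seed integer seed.
#' @param ridge ridge fraction passed to the statistic.
#' @param min_shift minimum cycle shift (volumes).
#' @param normalization `"mean"` (default, observed / bootstrap mean) or
#'   `"z"` (bootstrap z-score).
#' @return an object of class `stat_result`.
#' @export
bootstrap_distribution <- function(x, labels, statistic = c("t2", "wilks", "gcr", "md"),
                                   B = 1000, scheme = c("block", "cycle", "random"),
                                   seed = 1, ridge = 1e-6, min_shift = 3,
                                   normalization = "mean") {
  statistic <- match.arg(statistic)
  scheme <- match.arg(scheme)
  if (B < 1) abort("`B` must be at least 1.")
  x <- as_bold_matrix(x)
  check_paired(x, labels)
  res <- with_seed(seed, {
    boot_statistic_values(x, labels, statistic, B, scheme, ridge, min_shift)
  })
  new_stat_result(statistic, res$observed, res$boot, scheme, B, seed,
                  normalization)
}

#' Voxel-subsampled statistic with pooled bootstrap
#'
#' To compare ROIs with different voxel counts on an equal footing, the
#' statistic is computed `repeats` times on `n_voxels` voxels drawn at
#' random without replacement (conventionally the size of the smallest ROI
#' under study); the observed value is the mean over subsets and
#' significance is assessed against the pooled bootstrap distribution of all
#' `repeats * B` resampled values.
#'
#' @inheritParams bootstrap_distribution
#' @param n_voxels subset size (must not exceed the voxel count).
#' @param repeats number of voxel subsets (default 50).
#' @return a `stat_result` whose `bootstrap_values` has length
#'   `repeats * B`, with extra fields `repeats`, `n_voxels` and
#'   `subset_observed`.
#' @export
subsampled_statistic <- function(x, labels, statistic = c("t2", "wilks", "gcr", "md"),
                                 n_voxels, repeats = 50, B = 1000,
                                 scheme = c("block", "cycle", "random"),
                                 seed = 1, ridge = 1e-6, min_shift = 3,
                                 normalization = "mean") {
  statistic <- match.arg(statistic)
  scheme <- match.arg(scheme)
  x <- as_bold_matrix(x)
  check_paired(x, labels)
  V <- ncol(x)
  if (n_voxels > V) abort("`n_voxels` exceeds the number of voxels.")
  res <- with_seed(seed, {
    per <- lapply(seq_len(repeats), function(r) {
      vox <- sample.int(V, n_voxels)
      boot_statistic_values(x[, vox, drop = FALSE], labels, statistic, B,
                            scheme, ridge, min_shift)
    })
    list(
      observed = vapply(per, `[[`, numeric(1), "observed"),
      boot = unlist(lapply(per, `[[`, "boot"))
    )
  })
  new_stat_result(
    statistic, mean(res$observed), res$boot, scheme, B, seed, normalization,
    extra = list(repeats = as.integer(repeats), n_voxels = as.integer(n_voxels),
                 subset_observed = res$observed)
  )
}
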
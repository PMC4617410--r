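# Multivariate test statistics quantifying the discriminability of labeled
# task stages in voxel space: Hotelling-Lawley trace (generalized T2),
# Wilks' lambda, Roy's greatest characteristic root, and the two-class
# Mahalanobis distance.

#' Within- and between-class scatter matrices
#'
#' Classical MANOVA scatter convention:
#' `within = sum_c sum_{t in c} (y_t - mu_c)(y_t - mu_c)'` and
#' `between = sum_c n_c (mu_c - mu)(mu_c - mu)'`.
#'
#' @param x time series (matrix or tibble, time x voxels).
#' @param labels class labels: a label-sequence tibble or a vector, one label
#'   per volume. At least two classes, each with at least two volumes.
#' @return an object of class `scatter_pair`: list with `within`, `between`,
#'   `n_total`, `n_classes`, `class_sizes`.
#' @export
#' @examples
#' sp <- class_scatter(matrix(c(0, 2, 4, 6)), c("A", "A", "B", "B"))
#' sp$within   # 4
#' sp$between  # 16
class_scatter <- function(x, labels) {
  x <- as_bold_matrix(x)
  lab <- label_vector(labels)
  check_paired(x, labels)
  f <- factor(lab)
  sizes <- table(f)
  if (length(sizes) < 2) abort("Need at least 2 classes.")
  if (any(sizes < 2)) {
    abort(paste0(
      "Every class needs at least 2 volumes; too small: ",
      paste(names(sizes)[sizes < 2], collapse = ", ")
    ))
  }
  sp <- scatter_pair_fast(x, f)
  structure(
    c(sp, list(
      n_total = nrow(x), n_classes = length(sizes),
      class_sizes = stats::setNames(as.integer(sizes), names(sizes))
    )),
    class = "scatter_pair"
  )
}

# Core scatter computation on a matrix + factor (no validation); used in the
# bootstrap inner loop. W = Y'Y - sum_c n_c mu_c mu_c'; B from centered
# class means. Symmetrized against round-off.
scatter_pair_fast <- function(x, f, xtx = NULL) {
  n_c <- tabulate(f)
  M <- rowsum(x, f, reorder = TRUE) / n_c
  mu <- colSums(M * n_c) / sum(n_c)
  Ms <- sqrt(n_c) * M
  if (is.null(xtx)) xtx <- crossprod(x)
  W <- xtx - crossprod(Ms)
  Mc <- sqrt(n_c) * sweep(M, 2, mu, `-`)
  B <- crossprod(Mc)
  list(within = (W + t(W)) / 2, between = (B + t(B)) / 2)
}

#' @export
print.scatter_pair <- function(x, ...) {
  cat("<scatter_pair> ", ncol(x$within), " voxels, ", x$n_classes,
      " classes, n = ", x$n_total, "\n", sep = "")
  invisible(x)
}

regularize_within <- function(W, ridge) {
  if (ridge > 0) W + diag(ridge * mean(diag(W)), ncol(W)) else W
}

# Eigenvalues of within^{-1} between via the symmetric generalized problem
# (Cholesky whitening); clips round-off negatives to zero.
wb_eigenvalues <- function(W, B, ridge = 1e-6) {
  Wr <- regularize_within(W, ridge)
  R <- tryCatch(chol(Wr), error = function(e) NULL)
  if (is.null(R)) {
    abort("Within-class scatter is singular even after ridge regularization; use more volumes or fewer voxels.")
  }
  Li <- backsolve(R, diag(ncol(W)), transpose = TRUE) # L^{-1}, W = L L'
  M <- Li %*% B %*% t(Li)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  pmax(ev, 0)
}

#' MANOVA test statistics from a scatter pair
#'
#' Computes the eigenvalues `lambda_i` of the (ridge-regularized)
#' `within^{-1} between` matrix and the three classical statistics:
#' Hotelling's generalized T2 (Hotelling-Lawley trace) `sum lambda_i`,
#' Wilks' lambda `prod 1 / (1 + lambda_i)`, and Roy's greatest
#' characteristic root `max lambda_i`. Larger T2/GCR and smaller Wilks'
#' lambda mean stronger separation of the classes.
#'
#' @param sp a [class_scatter()] result (or a list with `within` and
#'   `between`).
#' @param ridge diagonal ridge, as a fraction of the mean within-scatter
#'   diagonal (default 1e-6).
#' @return an object of class `manova_stats` with fields `t2`, `wilks`,
#'   `gcr`, `eigenvalues`.
#' @export
#' @examples
#' sp <- class_scatter(matrix(c(0, 2, 4, 6)), c("A", "A", "B", "B"))
#' manova_statistics(sp, ridge = 0) # t2 = 4, wilks = 0.2, gcr = 4
manova_statistics <- function(sp, ridge = 1e-6) {
  ev <- wb_eigenvalues(sp$within, sp$between, ridge)
  structure(
    list(
      t2 = sum(ev), wilks = prod(1 / (1 + ev)), gcr = max(ev),
      eigenvalues = sort(ev, decreasing = TRUE),
      n_classes = sp$n_classes %||% NA_integer_,
      n_total = sp$n_total %||% NA_integer_
    ),
    class = "manova_stats"
  )
}

#' @export
print.manova_stats <- function(x, ...) {
  cat(sprintf(
    "<manova_stats> T2 = %.4g, Wilks = %.4g, GCR = %.4g (%s classes, n = %s)\n",
    x$t2, x$wilks, x$gcr, x$n_classes, x$n_total
  ))
  invisible(x)
}

#' @export
tidy.manova_stats <- function(x, ...) {
  tibble::tibble(
    statistic = c("t2", "wilks", "gcr"),
    value = c(x$t2, x$wilks, x$gcr)
  )
}

#' @export
glance.manova_stats <- function(x, ...) {
  tibble::tibble(
    t2 = x$t2, wilks = x$wilks, gcr = x$gcr,
    n_classes = x$n_classes, n_total = x$n_total
  )
}

# One named statistic from data + class factor; the bootstrap inner kernel.
# `md` is the two-class Mahalanobis distance.
compute_statistic <- function(x, f, statistic, ridge = 1e-6, xtx = NULL) {
  f <- droplevels(f)
  sp <- scatter_pair_fast(x, f, xtx = xtx)
  if (statistic == "md") {
    n_c <- tabulate(f)
    if (length(n_c) != 2) abort("Mahalanobis distance needs exactly two classes.")
    M <- rowsum(x, f, reorder = TRUE) / n_c
    d <- M[2, ] - M[1, ]
    S <- regularize_within(sp$within / (nrow(x) - 2), ridge)
    R <- tryCatch(chol(S), error = function(e) {
      abort("Pooled covariance is singular even after ridge regularization.")
    })
    z <- backsolve(R, d, transpose = TRUE)
    return(sqrt(sum(z^2)))
  }
  Wr <- regularize_within(sp$within, ridge)
  R <- tryCatch(chol(Wr), error = function(e) {
    abort("Within-class scatter is singular even after ridge regularization; use more volumes or fewer voxels.")
  })
  if (statistic == "t2") {
    Winv <- chol2inv(R)
    return(sum(Winv * sp$between))
  }
  if (statistic == "wilks") {
    ldW <- 2 * sum(log(diag(R)))
    ldWB <- 2 * sum(log(diag(chol(Wr + sp$between))))
    return(exp(ldW - ldWB))
  }
  if (statistic == "gcr") {
    return(max(wb_eigenvalues(sp$within, sp$between, ridge)))
  }
  abort(sprintf("Unknown statistic '%s'.", statistic))
}

#' Mahalanobis distance between two classes
#'
#' `MD = sqrt((mu_1 - mu_2)' S^{-1} (mu_1 - mu_2))` with `S` the pooled
#' within-class covariance `within / (N - 2)`, ridge-regularized like
#' [manova_statistics()]. Affine-invariant two-class separation.
#'
#' @param x time series (matrix or tibble).
#' @param labels two-class labels (tibble or vector), each class with at
#'   least two volumes.
#' @param ridge diagonal ridge fraction (default 1e-6).
#' @return the Mahalanobis distance (scalar).
#' @export
#' @examples
#' mahalanobis_distance(matrix(c(0, 2, 4, 6)), c("A", "A", "B", "B")) # 2.8284
mahalanobis_distance <- function(x, labels, ridge = 1e-6) {
  x <- as_bold_matrix(x)
  lab <- label_vector(labels)
  check_paired(x, labels)
  f <- factor(lab)
  if (nlevels(f) != 2) abort("Mahalanobis distance needs exactly two classes.")
  if (any(table(f) < 2)) abort("Each class needs at least two volumes.")
  compute_statistic(x, f, "md", ridge)
}
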
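# Dimension reduction and discriminant projection: PAM k-medoids voxel
# selection on correlation distance, shrinkage-regularized Fisher LDA, and
# pooled z-scored projections across participants.

#' Select representative voxels by k-medoids
#'
#' PAM (build + swap) k-medoids over voxel time courses with distance
#' `d(i, j) = 1 - cor(y_i, y_j)` (scale-free, standard for time-course
#' prototyping; `"euclidean"` is available as an option). The returned
#' medoid voxels optimally represent the ROI in a prototypical sense and are
#' reported in increasing voxel-index order.
#'
#' @param x time series (matrix or tibble).
#' @param k number of medoid voxels to select.
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @return integer vector of k voxel indices (sorted increasing).
#' @export
kmedoids_select <- function(x, k, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  x <- as_bold_matrix(x)
  V <- ncol(x)
  if (k < 1 || k > V) abort("`k` must be between 1 and the number of voxels.")
  if (k == V) return(seq_len(V))
  d <- if (metric == "correlation") {
    stats::as.dist(1 - stats::cor(x))
  } else {
    stats::dist(t(x))
  }
  fit <- cluster::pam(d, k = k, diss = TRUE, keep.diss = FALSE,
                      cluster.only = FALSE, variant = "original")
  sort(as.integer(fit$id.med))
}

# Total cost (summed distance of every voxel to its nearest medoid) of a
# medoid set; used by tests as the PAM objective.
kmedoids_cost <- function(x, medoids, metric = "correlation") {
  x <- as_bold_matrix(x)
  D <- if (metric == "correlation") 1 - stats::cor(x) else as.matrix(stats::dist(t(x)))
  sum(apply(D[, medoids, drop = FALSE], 1, min))
}

#' Fit a regularized Fisher linear discriminant
#'
#' Finds the direction in voxel space maximizing between-class mean
#' separation relative to within-class scatter, with the shrinkage estimate
#' `Sw <- (1 - xi) * Sw + xi * diag(Sw)` guarding against high-dimensional,
#' sparse sampling (regularization parameter `xi`, default 0.2). The
#' direction is unit-norm and oriented so the second class projects higher
#' than the first.
#'
#' @param x time series (matrix or tibble), typically restricted to
#'   [kmedoids_select()] voxels.
#' @param labels two-class labels (tibble or vector).
#' @param xi shrinkage weight in \[0, 1\].
#' @param voxels optional voxel indices to restrict to.
#' @return an object of class `fisher_lda` with fields `direction`
#'   (unit vector), `xi`, `class_order`, `selected_voxels`, `means`.
#' @export
fit_fisher_lda <- function(x, labels, xi = 0.2, voxels = NULL) {
  if (xi < 0 || xi > 1) abort("`xi` must be in [0, 1].")
  x <- as_bold_matrix(x)
  lab <- label_vector(labels)
  check_paired(x, labels)
  if (!is.null(voxels)) {
    x <- x[, voxels, drop = FALSE]
  } else {
    voxels <- seq_len(ncol(x))
  }
  f <- factor(lab)
  if (nlevels(f) != 2) abort("Fisher LDA here is two-class.")
  if (any(table(f) < 2)) abort("Each class needs at least two volumes.")
  sp <- scatter_pair_fast(x, f)
  Sw <- sp$within / (nrow(x) - 2)
  Sreg <- (1 - xi) * Sw + xi * diag(diag(Sw), ncol(Sw))
  n_c <- tabulate(f)
  M <- rowsum(x, f, reorder = TRUE) / n_c
  delta <- M[2, ] - M[1, ]
  w <- tryCatch(solve(Sreg, delta), error = function(e) {
    abort("Regularized within-class covariance is singular; increase `xi` above 0.")
  })
  w <- w / sqrt(sum(w^2))
  if (sum(w * delta) < 0) w <- -w # class_2 mean projects higher
  structure(
    list(
      direction = w, xi = xi, class_order = levels(f),
      selected_voxels = as.integer(voxels),
      means = M, voxel_names = colnames(x)
    ),
    class = "fisher_lda"
  )
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat(sprintf(
    "<fisher_lda> %d voxels, xi = %.2f, classes %s < %s\n",
    length(x$direction), x$xi, x$class_order[1], x$class_order[2]
  ))
  invisible(x)
}

#' @export
tidy.fisher_lda <- function(x, ...) {
  tibble::tibble(
    voxel = x$selected_voxels,
    voxel_name = x$voxel_names %||% as.character(x$selected_voxels),
    weight = as.numeric(x$direction)
  )
}

#' Project data onto the discriminant direction
#'
#' @param object a [fit_fisher_lda()] model.
#' @param newdata time series (matrix or tibble) over the model's voxel
#'   space (full space; the model's `selected_voxels` are used).
#' @param ... unused.
#' @return numeric vector of LDA1 projections.
#' @export
predict.fisher_lda <- function(object, newdata, ...) {
  nd <- as_bold_matrix(newdata)
  if (ncol(nd) != length(object$direction)) {
    if (max(object$selected_voxels) <= ncol(nd)) {
      nd <- nd[, object$selected_voxels, drop = FALSE]
    } else {
      abort("`newdata` does not match the model's voxel space.")
    }
  }
  drop(nd %*% object$direction)
}

#' Pool z-scored discriminant projections across participants
#'
#' Projects each participant's class-labeled volumes onto their own LDA1,
#' z-transforms the projections within participant (bringing all
#' participants onto a common scale), and concatenates them with class
#' labels retained — the input for the class-histogram visualization of a
#' contrast. Participants whose labels contain only one class are excluded
#' with a warning.
#'
#' @param models list of [fit_fisher_lda()] models, one per participant.
#' @param data list (same length) of lists with elements `bold` and `label`
#'   (a class vector or label tibble), the volumes to project.
#' @return a tibble with columns `participant`, `class`, `projection_z`.
#' @export
project_and_pool <- function(models, data) {
  stopifnot(length(models) == length(data))
  out <- lapply(seq_along(models), function(p) {
    lab <- label_vector(data[[p]]$label)
    if (length(unique(lab)) < 2) {
      warn(sprintf("Participant %d excluded: only one class present.", p))
      return(NULL)
    }
    proj <- predict(models[[p]], data[[p]]$bold)
    tibble::tibble(
      participant = p, class = lab,
      projection_z = as.numeric(scale(proj))
    )
  })
  dplyr::bind_rows(out)
}

#' Histogram of pooled discriminant projections
#'
#' @param projections a [project_and_pool()] tibble.
#' @return a ggplot object.
#' @export
plot_projection_histogram <- function(projections) {
  ggplot2::ggplot(projections,
                  ggplot2::aes(x = .data$projection_z, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.6, position = "identity") +
    ggplot2::labs(x = "LDA1 projection (z)", y = "choice volumes")
}
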
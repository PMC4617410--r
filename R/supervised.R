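# Supervised analyses: lag/lead alignment profiles, per-trial statistics for
# error processing, and hypothesis-driven choice groupings contrasted by
# Mahalanobis distance.

#' Lag/lead profile of a multivariate statistic
#'
#' Shifts the behavioral labels by each lag (positive lag = labels applied
#' later relative to the data, i.e. the data is assumed to trail the
#' behavior; negative = leads), truncating the non-overlapping ends within
#' each trial, and recomputes the statistic. After hemodynamic deconvolution
#' the profile of a label-locked signal peaks at lag zero.
#'
#' @param x time series (matrix or tibble).
#' @param labels paired label-sequence tibble.
#' @param lags integer vector of shifts in volumes (default -5:5).
#' @param statistic one of `"t2"`, `"wilks"`, `"gcr"` (default `"t2"`).
#' @param ridge ridge fraction.
#' @return a tibble of class `lag_profile` with columns `lag`, `value`, and
#'   attribute `peak_lag` (for Wilks the peak is the minimum).
#' @export
lag_profile <- function(x, labels, lags = -5:5, statistic = "t2", ridge = 1e-6) {
  x <- as_bold_matrix(x)
  check_paired(x, labels)
  trial <- trial_vector(labels, nrow(x))
  lab <- label_vector(labels)
  shortest <- min(table(trial))
  if (max(abs(lags)) >= shortest) {
    abort(sprintf("Largest |lag| (%d) must be below the shortest trial length (%d).",
                  max(abs(lags)), shortest))
  }
  vals <- vapply(lags, function(L) {
    rows <- integer(0)
    shifted <- character(0)
    for (tr_id in unique(trial)) {
      i <- which(trial == tr_id)
      n <- length(i)
      if (L >= 0) {
        rows <- c(rows, i[(L + 1):n])
        shifted <- c(shifted, lab[i[1:(n - L)]])
      } else {
        rows <- c(rows, i[1:(n + L)])
        shifted <- c(shifted, lab[i[(-L + 1):n]])
      }
    }
    compute_statistic(x[rows, , drop = FALSE], factor(shifted), statistic, ridge)
  }, numeric(1))
  peak <- if (statistic == "wilks") lags[which.min(vals)] else lags[which.max(vals)]
  out <- tibble::tibble(lag = as.integer(lags), statistic = statistic, value = vals)
  class(out) <- c("lag_profile", class(out))
  attr(out, "peak_lag") <- peak
  out
}

#' Peak lag of a lag profile
#' @param profile a [lag_profile()] result.
#' @return the lag (volumes) at which the statistic peaks.
#' @export
peak_lag <- function(profile) attr(profile, "peak_lag")

#' @export
autoplot.lag_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "peak_lag"), linetype = 2) +
    ggplot2::labs(x = "label shift (volumes; + = lag, - = lead)",
                  y = object$statistic[1],
                  title = sprintf("Peak at lag %d", attr(object, "peak_lag")))
}

#' Per-trial multivariate statistics
#'
#' Computes Hotelling's generalized T2 within each trial independently (over
#' the task-stage classes present in that trial) and flags a trial as an
#' error trial iff any of its choice blocks carries an error flag. Error
#' volumes are retained here — the per-trial contrast between error and
#' non-error trials is the analysis of interest. Trials with fewer than two
#' usable classes are skipped with a warning.
#'
#' @param x time series (matrix or tibble).
#' @param labels paired label-sequence tibble.
#' @param ridge ridge fraction.
#' @return a tibble with one row per trial: `trial`, `n_volumes`, `t2`,
#'   `error_trial`.
#' @export
per_trial_statistics <- function(x, labels, ridge = 1e-6) {
  x <- as_bold_matrix(x)
  check_paired(x, labels)
  trial <- trial_vector(labels, nrow(x))
  lab <- label_vector(labels)
  err <- labels$error %||% rep(FALSE, nrow(x))
  rows <- lapply(unique(trial), function(tr_id) {
    i <- which(trial == tr_id)
    f <- factor(lab[i])
    keep_classes <- names(which(table(f) >= 2))
    use <- i[lab[i] %in% keep_classes]
    f <- factor(lab[use])
    if (nlevels(f) < 2) {
      warn(sprintf("Trial %s skipped: fewer than two usable classes.", tr_id))
      return(NULL)
    }
    tibble::tibble(
      trial = tr_id, n_volumes = length(i),
      t2 = compute_statistic(x[use, , drop = FALSE], f, "t2", ridge),
      error_trial = any(err[i])
    )
  })
  dplyr::bind_rows(rows)
}

#' Build a choice-grouping scheme
#'
#' Groups the twelve choice blocks per trial into two contrast classes:
#' * `memory_load`: blocks 1, 2, 11, 12 are *low* load (two items held),
#'   blocks 5, 6, 7, 8 *high* load (at least four items); 3, 4, 9, 10
#'   excluded.
#' * `visual_saliency`: blocks with houses/church landmarks are *high*,
#'   tree/telephone-booth *low*; neutral (tractor) blocks excluded.
#' * `random`: `n_random` independent draws of two disjoint groups of four
#'   blocks.
#'
#' @param labels label-sequence tibble (needs `choice_block`; `landmark` for
#'   the saliency scheme).
#' @param scheme `"memory_load"`, `"visual_saliency"`, or `"random"`.
#' @param n_random number of random-scheme draws (default 10).
#' @param seed integer seed (random scheme).
#' @return a tibble of class `choice_grouping` with columns `scheme`,
#'   `instance`, `choice_block`, `class` (`class_1`, `class_2`, `excluded`).
#' @export
choice_grouping <- function(labels, scheme = c("memory_load", "visual_saliency", "random"),
                            n_random = 10, seed = 1) {
  scheme <- match.arg(scheme)
  blocks <- 1:12
  assign_one <- function(instance, class1, class2) {
    cls <- rep("excluded", 12)
    cls[class1] <- "class_1"
    cls[class2] <- "class_2"
    tibble::tibble(scheme = scheme, instance = instance,
                   choice_block = blocks, class = cls)
  }
  out <- switch(scheme,
    memory_load = assign_one(1L, c(1, 2, 11, 12), c(5, 6, 7, 8)),
    visual_saliency = {
      lm_map <- labels |>
        dplyr::filter(.data$choice_block > 0) |>
        dplyr::distinct(.data$choice_block, .data$landmark)
      if (nrow(lm_map) == 0 || all(is.na(lm_map$landmark))) {
        abort("Saliency grouping needs landmark annotations on choice blocks.")
      }
      sal <- landmark_saliency(lm_map$landmark)
      assign_one(1L,
                 lm_map$choice_block[!is.na(sal) & sal == "low"],
                 lm_map$choice_block[!is.na(sal) & sal == "high"])
    },
    random = with_seed(seed, {
      dplyr::bind_rows(lapply(seq_len(n_random), function(r) {
        pick <- sample(blocks, 8)
        assign_one(as.integer(r), pick[1:4], pick[5:8])
      }))
    })
  )
  class(out) <- c("choice_grouping", class(out))
  out
}

#' Choice volumes entering a grouping contrast
#'
#' Selects the correct (non-error) choice volumes of the blocks included in
#' one grouping instance, with their contrast class — the rows on which
#' [grouping_contrast()] and the discriminant analyses operate.
#'
#' @param labels label-sequence tibble.
#' @param grouping_instance one instance of a [choice_grouping()] (rows with
#'   a single `instance` value).
#' @return a tibble with columns `row` (volume index), `trial`, `block`,
#'   `class`.
#' @export
grouping_rows <- function(labels, grouping_instance) {
  cls_map <- stats::setNames(grouping_instance$class, grouping_instance$choice_block)
  is_choice <- label_vector(labels) %in% c("choice_train", "choice_test")
  err <- labels$error %||% rep(FALSE, nrow(labels))
  blk <- labels$choice_block %||% rep(0L, nrow(labels))
  use <- is_choice & !err & blk > 0 & cls_map[as.character(blk)] != "excluded"
  use[is.na(use)] <- FALSE
  tibble::tibble(
    row = which(use),
    trial = trial_vector(labels, nrow(labels))[use],
    block = blk[use],
    class = unname(cls_map[as.character(blk[use])])
  )
}

# Permute contrast-class assignments across the included choice blocks
# within each trial (blocks move as units, preserving within-block
# autocorrelation).
permute_block_classes <- function(gr) {
  for (tr_id in unique(gr$trial)) {
    i <- which(gr$trial == tr_id)
    blocks <- unique(gr$block[i])
    cls_of <- vapply(blocks, function(b) gr$class[i][match(b, gr$block[i])], character(1))
    new_cls <- stats::setNames(sample(cls_of), blocks)
    gr$class[i] <- new_cls[as.character(gr$block[i])]
  }
  gr
}

#' Mahalanobis contrast of a choice grouping
#'
#' Computes the Mahalanobis distance between the two contrast classes over
#' the correct choice volumes of the included blocks, and normalizes it by
#' block-permutation bootstraps in which the class-to-block assignment is
#' shuffled within each trial (blocks as units). For the random scheme the
#' observed distances and each bootstrap replicate are averaged across the
#' scheme instances before normalization.
#'
#' @param x time series (matrix or tibble).
#' @param labels paired label-sequence tibble.
#' @param grouping a [choice_grouping()] result.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param ridge ridge fraction.
#' @return a `stat_result` (statistic `"md"`, scheme `"block"`) with extra
#'   field `grouping`.
#' @export
grouping_contrast <- function(x, labels, grouping, B = 1000, seed = 1, ridge = 1e-6) {
  x <- as_bold_matrix(x)
  check_paired(x, labels)
  instances <- split(grouping, grouping$instance)
  rows_list <- lapply(instances, function(gi) {
    gr <- grouping_rows(labels, gi)
    if (length(unique(gr$class)) != 2 || any(table(gr$class) < 2)) {
      abort("A contrast class is empty (or nearly so) after error exclusion.")
    }
    gr
  })
  md_of <- function(gr) {
    compute_statistic(x[gr$row, , drop = FALSE], factor(gr$class), "md", ridge)
  }
  res <- with_seed(seed, {
    observed <- mean(vapply(rows_list, md_of, numeric(1)))
    boot <- vapply(seq_len(B), function(b) {
      mean(vapply(rows_list, function(gr) md_of(permute_block_classes(gr)), numeric(1)))
    }, numeric(1))
    list(observed = observed, boot = boot)
  })
  new_stat_result("md", res$observed, res$boot, "block", B, seed, "mean",
                  extra = list(grouping = grouping$scheme[1],
                               n_instances = length(instances)))
}
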
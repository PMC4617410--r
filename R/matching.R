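# Scoring an unsupervised state sequence against behavioral labels: each
# Viterbi state is assigned to the behavioral class whose binary indicator
# it correlates with best, the mapped sequence is compared volume by volume,
# and the resulting Matching Index is tested against time-series bootstraps.

# Indicator matrix (T x levels) for a discrete sequence.
indicator_matrix <- function(v, levels) {
  out <- matrix(0L, length(v), length(levels),
                dimnames = list(NULL, as.character(levels)))
  out[cbind(seq_along(v), match(v, levels))] <- 1L
  out
}

matching_index_core <- function(state_ind, state_levels, lab) {
  classes <- sort(unique(lab))
  class_ind <- indicator_matrix(lab, classes)
  r <- suppressWarnings(stats::cor(state_ind, class_ind))
  r[!is.finite(r)] <- 0 # zero-variance indicators carry no information
  assign_idx <- apply(r, 1, which.max) # ties -> lowest class index
  state_to_class <- stats::setNames(classes[assign_idx], as.character(state_levels))
  mapped <- state_to_class[match(colnames(state_ind)[max.col(state_ind, "first")],
                                 names(state_to_class))]
  list(
    state_to_class = state_to_class,
    matching_index = 100 * mean(mapped == lab)
  )
}

#' Matching Index between a state sequence and behavioral labels
#'
#' Converts both sequences to binary design vectors (one per state /
#' behavioral class), computes Pearson correlations between every
#' state-class indicator pair, assigns each state to its best-correlated
#' class (ties and zero-variance indicators fall to the first class in
#' sorted order), rebuilds the behavioral sequence from the assigned states
#' and reports `Matching Index = 100 * hits / sequence length`. The index is
#' invariant to any relabeling of the state ids, and equals 100 exactly when
#' the mapped state sequence reproduces the labels.
#'
#' @param states integer (or factor) state sequence, e.g. from
#'   [viterbi_decode()].
#' @param labels behavioral labels: a label-sequence tibble or vector of the
#'   same length.
#' @return an object of class `matching_result` with `state_to_class`,
#'   `matching_index` (percent), `n`.
#' @export
#' @examples
#' matching_index(c(1, 1, 2, 2), c("A", "A", "B", "B"))$matching_index # 100
#' matching_index(c(1, 2, 2, 2), c("A", "A", "B", "B"))$matching_index # 75
matching_index <- function(states, labels) {
  lab <- label_vector(labels)
  if (length(states) != length(lab)) {
    abort("State and label sequences must have equal length.")
  }
  state_levels <- sort(unique(states))
  core <- matching_index_core(indicator_matrix(states, state_levels),
                              state_levels, lab)
  structure(
    c(core, list(n = length(lab))),
    class = "matching_result"
  )
}

#' @export
print.matching_result <- function(x, ...) {
  cat(sprintf("<matching_result> Matching Index = %.1f%% over %d volumes\n",
              x$matching_index, x$n))
  if (!is.null(x$p_values)) {
    print(x$p_values)
  }
  invisible(x)
}

#' @export
tidy.matching_result <- function(x, ...) {
  tibble::tibble(
    state = names(x$state_to_class),
    class = unname(x$state_to_class)
  )
}

#' @export
glance.matching_result <- function(x, ...) {
  out <- tibble::tibble(matching_index = x$matching_index, n = x$n)
  if (!is.null(x$p_values)) {
    wide <- stats::setNames(x$p_values$p_value, paste0("p_", x$p_values$scheme))
    out <- dplyr::bind_cols(out, tibble::as_tibble(as.list(wide)))
  }
  out
}

#' Significance of the Matching Index
#'
#' Tests the observed Matching Index non-parametrically against label
#' resamplings under the cycle-shifting, block-permutation and
#' random-permutation schemes. Every resample re-runs the full state-to-
#' class assignment, so the null accounts for the freedom of the mapping
#' step. p-values use the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + B)`.
#'
#' @param states state sequence (e.g. Viterbi path).
#' @param labels label-sequence tibble (with `trial` for within-trial
#'   resampling).
#' @param B resamples per scheme (default 1000).
#' @param schemes subset of `c("cycle", "block", "random")`.
#' @param min_shift minimum cycle shift (volumes).
#' @param seed integer seed.
#' @return a `matching_result` with added `null_distributions` (named list)
#'   and `p_values` (tibble `scheme`, `p_value`).
#' @export
matching_significance <- function(states, labels, B = 1000,
                                  schemes = c("cycle", "block", "random"),
                                  min_shift = 3, seed = 1) {
  if (B < 1) abort("`B` must be at least 1.")
  if (!is.data.frame(labels)) {
    labels <- tibble::tibble(label = as.character(labels), trial = 1L)
  }
  obs <- matching_index(states, labels)
  state_levels <- sort(unique(states))
  state_ind <- indicator_matrix(states, state_levels)
  nulls <- with_seed(seed, {
    lapply(stats::setNames(schemes, schemes), function(sch) {
      vapply(seq_len(B), function(b) {
        lb <- resample_labels(labels, sch, min_shift = min_shift)
        matching_index_core(state_ind, state_levels, label_vector(lb))$matching_index
      }, numeric(1))
    })
  })
  obs$null_distributions <- nulls
  obs$p_values <- dplyr::bind_rows(lapply(names(nulls), function(sch) {
    tibble::tibble(
      scheme = sch,
      p_value = (1 + sum(nulls[[sch]] >= obs$matching_index)) / (1 + B)
    )
  }))
  obs$B <- as.integer(B)
  obs$rng_seed <- seed
  obs
}
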
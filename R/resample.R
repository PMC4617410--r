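# Label-resampling null schemes. All three operate strictly within trial and
# preserve the per-trial label multiset; they differ in how much of the
# temporal run structure (hence autocorrelation) they keep.

resample_check <- function(labels) {
  if (!is.data.frame(labels) || !"label" %in% names(labels)) {
    abort("Resampling needs a label-sequence tibble with a `label` column.")
  }
}

#' Block-permute labels within trials
#'
#' Identifies the maximal runs of identical consecutive labels within each
#' trial and uniformly permutes the order of those runs, leaving run contents
#' and lengths intact. This preserves the autocorrelation structure of the
#' labeling while destroying its alignment with the data, giving a null that
#' is honest for autocorrelated time series.
#'
#' @param labels label-sequence tibble (uses `label`, `trial`).
#' @return the tibble with the `label` column permuted.
#' @export
block_permute_labels <- function(labels) {
  resample_check(labels)
  trial <- trial_vector(labels, nrow(labels))
  lab <- label_vector(labels)
  for (tr_id in unique(trial)) {
    i <- which(trial == tr_id)
    r <- rle(lab[i])
    ord <- sample.int(length(r$lengths))
    lab[i] <- rep(r$values[ord], r$lengths[ord])
  }
  labels$label <- lab
  labels
}

#' Cycle-shift labels within trials
#'
#' Circularly rotates each trial's label sequence by an offset drawn
#' uniformly from `[min_shift, trial_length - min_shift]`, keeping the
#' complete temporal structure but breaking the phase alignment with the
#' data.
#'
#' @param labels label-sequence tibble.
#' @param min_shift minimum rotation in volumes (default 3), excluding
#'   near-identity shifts.
#' @return the tibble with the `label` column rotated per trial.
#' @export
cycle_shift_labels <- function(labels, min_shift = 3) {
  resample_check(labels)
  trial <- trial_vector(labels, nrow(labels))
  lab <- label_vector(labels)
  for (tr_id in unique(trial)) {
    i <- which(trial == tr_id)
    n <- length(i)
    if (n <= 2 * min_shift) {
      abort(sprintf("Trial %s too short (%d volumes) for min_shift = %d.", tr_id, n, min_shift))
    }
    k <- sample(seq.int(min_shift, n - min_shift), 1)
    lab[i] <- lab[i][c((k + 1):n, 1:k)]
  }
  labels$label <- lab
  labels
}

#' Randomly permute labels within trials
#'
#' The naive exchangeable null: a uniform permutation of labels within each
#' trial. Destroys run structure (so it ignores autocorrelation) while
#' preserving label counts; kept as a reference against which the
#' block-permutation null can be compared.
#'
#' @param labels label-sequence tibble.
#' @return the tibble with the `label` column permuted.
#' @export
random_permute_labels <- function(labels) {
  resample_check(labels)
  trial <- trial_vector(labels, nrow(labels))
  lab <- label_vector(labels)
  for (tr_id in unique(trial)) {
    i <- which(trial == tr_id)
    lab[i] <- lab[i][sample.int(length(i))]
  }
  labels$label <- lab
  labels
}

resample_labels <- function(labels, scheme, min_shift = 3) {
  switch(scheme,
    block = block_permute_labels(labels),
    cycle = cycle_shift_labels(labels, min_shift = min_shift),
    random = random_permute_labels(labels),
    abort(sprintf("Unknown resampling scheme '%s'.", scheme))
  )
}
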
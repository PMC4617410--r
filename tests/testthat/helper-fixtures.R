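# Fixtures built in code: small designs, toy label tibbles, and planted-state
# generators shared across the test files.

small_design <- function(n_trials = 2, ...) {
  task_design(n_trials = n_trials, with_control = FALSE, error_rate = 0, ...)
}

# Minimal per-volume label tibble from a label vector.
toy_labels <- function(labels, trial = 1L, error = FALSE, choice_block = 0L,
                       landmark = NA_character_, tr = 1.8) {
  n <- length(labels)
  tibble::tibble(
    volume = seq_len(n), onset = (seq_len(n) - 1) * tr,
    trial = rep_len(as.integer(trial), n), phase = NA_character_,
    label = as.character(labels),
    choice_block = rep_len(as.integer(choice_block), n),
    landmark = rep_len(landmark, n), error = rep_len(error, n)
  )
}

# Labeled Gaussian data with the given per-class means (rows named by class).
labeled_gaussian <- function(labels, means, sd = 1, seed = 1) {
  set.seed(seed)
  lab <- as.character(labels)
  means[lab, , drop = FALSE] +
    matrix(rnorm(length(lab) * ncol(means), sd = sd), length(lab), ncol(means))
}

# Sticky-chain sample from a diagonal-Gaussian HMM; returns obs + true states.
planted_hmm_data <- function(m, d, Tn, mean_sd = 2, dwell = 8, seed = 1) {
  set.seed(seed)
  mu <- matrix(rnorm(m * d, sd = mean_sd), m, d)
  p_stay <- 1 - 1 / dwell
  A <- matrix((1 - p_stay) / max(m - 1, 1), m, m)
  diag(A) <- p_stay
  z <- integer(Tn)
  z[1] <- sample(m, 1)
  for (t in 2:Tn) z[t] <- sample(m, 1, prob = A[z[t - 1], ])
  list(obs = mu[z, ] + matrix(rnorm(Tn * d), Tn, d), states = z, means = mu)
}
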
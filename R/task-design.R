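#' The nine task-stage labels
#'
#' One trial of the self-paced radial-arm-maze-style task is split into nine
#' cognitively defined stages: navigation at the maze center is *encoding*
#' (training phase) or *retrieval* (test phase); each of six choice blocks per
#' phase contributes *choice* (two volumes before arm entrance), *reward
#' expectation* (traversal to the reward) and *reward consumption* (two
#' volumes from reward acquisition); the inter-phase pause is *delay*.
#'
#' @return character vector of the nine stage labels.
#' @export
task_stage_labels <- function() {
  c(
    "encoding", "choice_train", "rewexp_train", "rewcon_train",
    "delay",
    "retrieval", "choice_test", "rewexp_test", "rewcon_test"
  )
}

#' Control-phase labels
#'
#' The visuomotor control phase mirrors the task-stage structure with its own
#' label alphabet, so per-trial control means can be subtracted class by
#' class.
#'
#' @return character vector of the five control labels.
#' @export
control_labels <- function() {
  c("ctrl_nav", "ctrl_choice", "ctrl_rewexp", "ctrl_rewcon", "ctrl_delay")
}

#' Default mapping from task stages to control classes
#'
#' Used by [subtract_control_means()]: every task stage is paired with the
#' control-phase class matching its sensory-motor demands.
#'
#' @return named character vector (task stage -> control label).
#' @export
default_control_map <- function() {
  c(
    encoding = "ctrl_nav", retrieval = "ctrl_nav",
    choice_train = "ctrl_choice", choice_test = "ctrl_choice",
    rewexp_train = "ctrl_rewexp", rewexp_test = "ctrl_rewexp",
    rewcon_train = "ctrl_rewcon", rewcon_test = "ctrl_rewcon",
    delay = "ctrl_delay"
  )
}

#' Default landmark category per choice block
#'
#' Twelve choice blocks per trial (1-6 training, 7-12 test), each associated
#' with one of five maze landmarks. Houses and church are the high-saliency
#' landmarks, tree and telephone booth the low-saliency ones, and the tractor
#' is neutral (excluded from saliency contrasts). The default assignment
#' balances saliency against the memory-load grouping: each load class
#' contains two high-saliency and two neutral arms, and each saliency class
#' mixes low- and high-load choices.
#'
#' @return named character vector, `landmark[block]` for blocks 1-12.
#' @export
default_landmark_map <- function() {
  stats::setNames(
    c(
      "houses", "church", "tree", "telephone_booth", "tractor", "tractor",
      "houses", "church", "tree", "telephone_booth", "tractor", "tractor"
    ),
    as.character(1:12)
  )
}

landmark_saliency <- function(landmark) {
  dplyr::case_when(
    landmark %in% c("houses", "church") ~ "high",
    landmark %in% c("tree", "telephone_booth") ~ "low",
    landmark == "tractor" ~ "neutral",
    TRUE ~ NA_character_
  )
}

#' Describe a self-paced task design
#'
#' Collects the structural parameters of one scanning run: number of trials,
#' sampling interval, per-segment duration model and behavioral error rate.
#' Self-paced segment durations follow a shifted geometric distribution
#' (minimum one volume) with the given means; `choice` and `reward
#' consumption` segments are fixed at two volumes each by definition of the
#' stage labels.
#'
#' @param n_trials number of task trials (the study cohort completed 5).
#' @param tr sampling interval in seconds (acquisition default 1.8).
#' @param mean_nav_volumes mean duration (volumes) of encoding / retrieval /
#'   control navigation segments preceding each choice block.
#' @param mean_rewexp_volumes mean duration (volumes) of reward-expectation
#'   segments.
#' @param choice_volumes fixed choice-segment length (volumes).
#' @param rewcon_volumes fixed reward-consumption length (volumes).
#' @param delay_s delay and control-delay duration in seconds (default 30 s).
#' @param error_rate probability that a task choice block is a behavioral
#'   error.
#' @param with_control generate the visuomotor control phase and control
#'   delay?
#' @param landmark_map named character vector mapping blocks "1".."12" to
#'   landmarks, see [default_landmark_map()].
#' @return an object of class `task_design`.
#' @export
task_design <- function(n_trials = 5, tr = 1.8,
                        mean_nav_volumes = 3, mean_rewexp_volumes = 2,
                        choice_volumes = 2, rewcon_volumes = 2,
                        delay_s = 30, error_rate = 0.01,
                        with_control = TRUE,
                        landmark_map = default_landmark_map()) {
  if (n_trials < 1) abort("`n_trials` must be at least 1.")
  if (tr <= 0) abort("`tr` must be positive.")
  if (mean_nav_volumes < 1 || mean_rewexp_volumes < 1) {
    abort("Mean segment durations must be at least one volume (invalid duration model).")
  }
  if (choice_volumes < 1 || rewcon_volumes < 1) {
    abort("Fixed segment lengths must be at least one volume (invalid duration model).")
  }
  if (error_rate < 0 || error_rate > 1) abort("`error_rate` must be in [0, 1].")
  if (!all(as.character(1:12) %in% names(landmark_map))) {
    abort("`landmark_map` must name all choice blocks 1..12.")
  }
  structure(
    list(
      n_trials = as.integer(n_trials), tr = tr,
      mean_nav_volumes = mean_nav_volumes,
      mean_rewexp_volumes = mean_rewexp_volumes,
      choice_volumes = as.integer(choice_volumes),
      rewcon_volumes = as.integer(rewcon_volumes),
      delay_s = delay_s, error_rate = error_rate,
      with_control = isTRUE(with_control),
      landmark_map = landmark_map
    ),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  cat(
    "<task_design> ", x$n_trials, " trial(s), TR = ", x$tr, " s, ",
    "delay = ", x$delay_s, " s, error rate = ", x$error_rate,
    if (x$with_control) ", with control phase" else "", "\n",
    sep = ""
  )
  invisible(x)
}
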
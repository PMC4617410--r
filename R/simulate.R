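# Synthetic-data generator: label sequences and multivariate BOLD with
# planted state structure, so every downstream analysis is testable without
# any acquisition.

# Shifted geometric duration: minimum 1 volume, given mean (memoryless
# analog of self-pacing).
rdur <- function(n, mean_volumes) {
  if (mean_volumes <= 1) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 / mean_volumes)
}

#' Generate a per-volume task label sequence
#'
#' Emits one label per volume for `design$n_trials` trials of the self-paced
#' task. Each trial is: optional visuomotor control phase (six control choice
#' blocks) and 30 s control delay, training phase (choice blocks 1-6 with
#' encoding navigation between blocks), delay, test phase (choice blocks 7-12
#' with retrieval navigation). Choice and reward-consumption segments are two
#' volumes each by default; navigation and reward-expectation durations are
#' self-paced (shifted-geometric). Choice blocks are flagged as behavioral
#' errors independently with probability `design$error_rate`; the flag covers
#' the block's choice, reward-expectation and reward-consumption volumes.
#'
#' @param design a [task_design()].
#' @param seed integer seed; identical seeds give identical sequences.
#' @return a tibble with one row per volume: `volume`, `onset` (s), `trial`,
#'   `phase` (`control`/`training`/`delay`/`test`), `label`, `choice_block`
#'   (1-12, 0 outside task choice blocks), `landmark`, `error`.
#' @export
#' @examples
#' labs <- simulate_task_labels(task_design(n_trials = 1), seed = 1)
#' table(labs$label)
simulate_task_labels <- function(design, seed) {
  stopifnot(inherits(design, "task_design"))
  with_seed(seed, {
    delay_vols <- max(1L, as.integer(round(design$delay_s / design$tr)))
    trials <- lapply(seq_len(design$n_trials), function(tr_id) {
      seg <- function(label, len, phase, block = 0L, landmark = NA_character_,
                      error = FALSE) {
        tibble::tibble(
          trial = tr_id, phase = phase, label = label,
          choice_block = as.integer(block), landmark = landmark, error = error,
          .rows = len
        )
      }
      block_segs <- function(block_ids, nav_label, stage_suffix, phase,
                             control = FALSE) {
        err_block <- if (control) {
          rep(FALSE, length(block_ids))
        } else {
          stats::rbinom(length(block_ids), 1, design$error_rate) == 1
        }
        out <- vector("list", length(block_ids))
        for (i in seq_along(block_ids)) {
          b <- block_ids[i]
          lm <- if (control) NA_character_ else design$landmark_map[[as.character(b)]]
          blk <- if (control) 0L else b
          lab <- function(stage) {
            if (control) paste0("ctrl_", stage) else paste0(stage, "_", stage_suffix)
          }
          out[[i]] <- dplyr::bind_rows(
            seg(nav_label, rdur(1, design$mean_nav_volumes), phase),
            seg(lab("choice"), design$choice_volumes, phase, blk, lm, err_block[i]),
            seg(lab("rewexp"), rdur(1, design$mean_rewexp_volumes), phase, blk, lm, err_block[i]),
            seg(lab("rewcon"), design$rewcon_volumes, phase, blk, lm, err_block[i])
          )
        }
        dplyr::bind_rows(out)
      }
      parts <- list()
      if (design$with_control) {
        parts <- c(parts, list(
          block_segs(1:6, "ctrl_nav", NULL, "control", control = TRUE),
          seg("ctrl_delay", delay_vols, "control")
        ))
      }
      parts <- c(parts, list(
        block_segs(1:6, "encoding", "train", "training"),
        seg("delay", delay_vols, "delay"),
        block_segs(7:12, "retrieval", "test", "test")
      ))
      dplyr::bind_rows(parts)
    })
    out <- dplyr::bind_rows(trials)
    out$volume <- seq_len(nrow(out))
    out$onset <- (out$volume - 1) * design$tr
    dplyr::select(
      out, "volume", "onset", "trial", "phase", "label",
      "choice_block", "landmark", "error"
    )
  })
}

#' Configure the BOLD emission model
#'
#' Observations follow `y_t = mu(label_t) + block effects + participant
#' offset + AR(1) noise`, optionally convolved with the canonical HRF before
#' noise addition. State means are either supplied as a matrix (rows named by
#' label) or drawn i.i.d. Gaussian with standard deviation `effect_size` when
#' the generator is materialized. Optional choice-block effects plant a
#' memory-load modulation (low-load blocks 1, 2, 11, 12 vs high-load blocks
#' 5, 6, 7, 8) on one voxel subset and a visual-saliency modulation (high- vs
#' low-saliency landmark) on another, active during choice volumes; these let
#' the grouping contrasts exercise a double dissociation.
#'
#' @param n_voxels number of voxels.
#' @param effect_size standard deviation of drawn state means, in units of
#'   the noise standard deviation (between-stage separation).
#' @param state_means optional matrix (labels x voxels) of planted means,
#'   with rownames covering every label the paired sequence emits.
#' @param noise_sd AR(1) innovation standard deviation.
#' @param ar AR(1) coefficient in \[0, 1).
#' @param hrf `NULL` for label-locked signal, or an HRF kernel (e.g.
#'   [canonical_hrf()]) to convolve the mean signal with.
#' @param participant_shift_sd standard deviation of per-participant,
#'   per-voxel mean offsets.
#' @param load_voxels,load_delta voxel indices and effect size of the
#'   memory-load choice modulation (+/- `load_delta`/2 by load class).
#' @param saliency_voxels,saliency_delta voxel indices and effect size of the
#'   visual-saliency choice modulation.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_voxels = 50, effect_size = 1, state_means = NULL,
                             noise_sd = 1, ar = 0.4, hrf = NULL,
                             participant_shift_sd = 0.5,
                             load_voxels = integer(), load_delta = 0,
                             saliency_voxels = integer(), saliency_delta = 0) {
  if (abs(ar) >= 1) abort("AR(1) coefficient must satisfy |ar| < 1.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (!is.null(state_means)) {
    state_means <- as.matrix(state_means)
    if (is.null(rownames(state_means))) {
      abort("`state_means` must have row names identifying the labels.")
    }
    n_voxels <- ncol(state_means)
  }
  structure(
    list(
      n_voxels = as.integer(n_voxels), effect_size = effect_size,
      state_means = state_means, noise_sd = noise_sd, ar = ar, hrf = hrf,
      participant_shift_sd = participant_shift_sd,
      load_voxels = as.integer(load_voxels), load_delta = load_delta,
      saliency_voxels = as.integer(saliency_voxels),
      saliency_delta = saliency_delta
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(
    "<generator_config> ", x$n_voxels, " voxels, effect size ", x$effect_size,
    ", noise sd ", x$noise_sd, ", AR(1) ", x$ar,
    if (!is.null(x$hrf)) ", HRF convolution" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Draw (or validate) the planted state means of a generator
#'
#' Fixes the state-mean matrix of `config` for the label alphabet of
#' `labels`, so that several participants can share one set of planted
#' patterns. A no-op when means were supplied explicitly.
#'
#' @param config a [generator_config()].
#' @param labels a label sequence (tibble or vector) defining the alphabet.
#' @param seed integer seed for the mean draw.
#' @return the config with `state_means` materialized.
#' @export
materialize_state_means <- function(config, labels, seed) {
  alphabet <- sort(unique(label_vector(labels)))
  if (is.null(config$state_means)) {
    config$state_means <- with_seed(seed, {
      m <- matrix(
        rnorm(length(alphabet) * config$n_voxels, sd = config$effect_size),
        nrow = length(alphabet),
        dimnames = list(alphabet, sprintf("v%03d", seq_len(config$n_voxels)))
      )
      m
    })
  } else if (!all(alphabet %in% rownames(config$state_means))) {
    missing <- setdiff(alphabet, rownames(config$state_means))
    abort(paste0(
      "`state_means` rows do not cover the label alphabet; missing: ",
      paste(missing, collapse = ", ")
    ))
  }
  config
}

# AR(1) noise matrix with stationary start (burn-in discarded).
ar1_noise <- function(Tn, V, ar, sd) {
  if (sd == 0) return(matrix(0, Tn, V))
  burn <- 50L
  eps <- matrix(rnorm((Tn + burn) * V, sd = sd), Tn + burn, V)
  if (ar != 0) {
    eps <- apply(eps, 2, function(e) as.numeric(stats::filter(e, ar, method = "recursive")))
  }
  eps[(burn + 1):(burn + Tn), , drop = FALSE]
}

# Choice-block effect component of the mean signal (memory load / saliency
# modulations during choice volumes).
block_effect_signal <- function(labels, config) {
  Tn <- nrow(labels)
  eff <- matrix(0, Tn, config$n_voxels)
  is_choice <- labels$label %in% c("choice_train", "choice_test")
  if (length(config$load_voxels) && config$load_delta != 0) {
    low <- is_choice & labels$choice_block %in% c(1, 2, 11, 12)
    high <- is_choice & labels$choice_block %in% c(5, 6, 7, 8)
    eff[low, config$load_voxels] <- eff[low, config$load_voxels] - config$load_delta / 2
    eff[high, config$load_voxels] <- eff[high, config$load_voxels] + config$load_delta / 2
  }
  if (length(config$saliency_voxels) && config$saliency_delta != 0) {
    sal <- landmark_saliency(labels$landmark)
    lo <- is_choice & !is.na(sal) & sal == "low"
    hi <- is_choice & !is.na(sal) & sal == "high"
    eff[lo, config$saliency_voxels] <- eff[lo, config$saliency_voxels] - config$saliency_delta / 2
    eff[hi, config$saliency_voxels] <- eff[hi, config$saliency_voxels] + config$saliency_delta / 2
  }
  eff
}

#' Generate a multivariate BOLD time series for a label sequence
#'
#' @param labels a label-sequence tibble from [simulate_task_labels()] (or
#'   any tibble with `label` and, for block effects, `choice_block` /
#'   `landmark` columns).
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param participant_shift optional pre-drawn per-voxel offset vector (used
#'   by [simulate_cohort()]); default none.
#' @return a tibble (time x voxels) of BOLD values, one column per voxel.
#' @export
simulate_bold <- function(labels, config, seed, participant_shift = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.data.frame(labels) || nrow(labels) == 0) {
    abort("`labels` must be a non-empty label-sequence tibble.")
  }
  config <- materialize_state_means(config, labels, derive_seed(seed, "state-means"))
  mu <- config$state_means
  lab <- label_vector(labels)
  Tn <- length(lab)
  signal <- mu[lab, , drop = FALSE] + block_effect_signal(labels, config)
  if (!is.null(config$hrf)) {
    signal <- convolve_hrf(signal, config$hrf, keep_tail = FALSE)
  }
  shift <- participant_shift %||% rep(0, config$n_voxels)
  out <- with_seed(derive_seed(seed, "noise"), {
    signal + ar1_noise(Tn, config$n_voxels, config$ar, config$noise_sd)
  })
  out <- sweep(out, 2, shift, `+`)
  colnames(out) <- colnames(mu)
  rownames(out) <- NULL
  as_bold_tibble(out)
}

#' Simulate a cohort of participants
#'
#' Every participant receives an independently drawn label sequence
#' (self-paced durations and errors differ) and BOLD data sharing one set of
#' planted state means, plus a participant-specific per-voxel mean offset.
#' All per-participant seeds derive deterministically from `seed`.
#'
#' @param n_participants number of participants (the study cohort had 19).
#' @param design a [task_design()].
#' @param config a [generator_config()].
#' @param seed master integer seed.
#' @return a tibble with one row per participant and list-columns `labels`
#'   and `bold`.
#' @export
simulate_cohort <- function(n_participants, design, config, seed) {
  if (n_participants < 1) abort("`n_participants` must be at least 1.")
  # Fix the planted patterns once, over the full design alphabet.
  template <- simulate_task_labels(design, seed = derive_seed(seed, "alphabet"))
  config <- materialize_state_means(config, template, derive_seed(seed, "state-means"))
  out <- lapply(seq_len(n_participants), function(p) {
    labs <- simulate_task_labels(design, seed = derive_seed(seed, "labels", p))
    shift <- with_seed(derive_seed(seed, "shift", p), {
      rnorm(config$n_voxels, sd = config$participant_shift_sd)
    })
    bold <- simulate_bold(labs, config, seed = derive_seed(seed, "bold", p),
                          participant_shift = shift)
    tibble::tibble(participant = p, labels = list(labs), bold = list(bold))
  })
  dplyr::bind_rows(out)
}
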
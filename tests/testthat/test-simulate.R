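test_that("one trial emits exactly the nine task-stage labels", {
  labs <- simulate_task_labels(task_design(n_trials = 1, with_control = FALSE,
                                           mean_nav_volumes = 1,
                                           mean_rewexp_volumes = 1),
                               seed = 1)
  expect_setequal(unique(labs$label), task_stage_labels())
  expect_length(task_stage_labels(), 9)
})

test_that("control phase adds its own mirrored label alphabet", {
  labs <- simulate_task_labels(task_design(n_trials = 1), seed = 1)
  expect_setequal(unique(labs$label), c(task_stage_labels(), control_labels()))
})

test_that("trial structure follows the stage template", {
  labs <- simulate_task_labels(task_design(n_trials = 3), seed = 7)
  # choice blocks numbered 1-6 in training, 7-12 in test, per trial
  for (tr in 1:3) {
    tl <- labs[labs$trial == tr, ]
    expect_setequal(tl$choice_block[tl$phase == "training" & tl$choice_block > 0], 1:6)
    expect_setequal(tl$choice_block[tl$phase == "test" & tl$choice_block > 0], 7:12)
    expect_equal(tl$choice_block[tl$phase == "control"], rep(0L, sum(tl$phase == "control")))
  }
  # choice and reward-consumption segments are exactly 2 volumes
  r <- rle(paste(labs$trial, labs$label, labs$choice_block))
  lab_of_run <- sub("^\\S+ (\\S+) \\S+$", "\\1", r$values)
  expect_true(all(r$lengths[lab_of_run %in% c("choice_train", "choice_test")] == 2))
  expect_true(all(r$lengths[lab_of_run %in% c("rewcon_train", "rewcon_test")] == 2))
  # stage segments are contiguous within trial, durations >= 1
  expect_true(all(r$lengths >= 1))
  # landmark annotations only on task choice blocks, per the default map
  lm <- labs[labs$choice_block > 0, ]
  expect_equal(unname(default_landmark_map()[as.character(lm$choice_block)]),
               lm$landmark)
})

test_that("error flags follow the error rate", {
  labs0 <- simulate_task_labels(task_design(n_trials = 3, error_rate = 0), seed = 2)
  expect_false(any(labs0$error))
  labs1 <- simulate_task_labels(task_design(n_trials = 3, error_rate = 1), seed = 2)
  blk <- labs1[labs1$choice_block > 0, ]
  expect_true(all(blk$error))
  expect_false(any(labs1$error[labs1$label %in% c("encoding", "retrieval", "delay")]))
})

test_that("label generation is deterministic in the seed", {
  d <- task_design(n_trials = 2)
  expect_identical(simulate_task_labels(d, seed = 5), simulate_task_labels(d, seed = 5))
  expect_false(identical(simulate_task_labels(d, seed = 5),
                         simulate_task_labels(d, seed = 6)))
})

test_that("invalid design parameters are configuration errors", {
  expect_error(task_design(mean_nav_volumes = 0.5), "duration")
  expect_error(task_design(n_trials = 0), "n_trials")
  expect_error(generator_config(ar = 1), "AR")
})

test_that("zero-noise output equals the state means exactly", {
  labs <- simulate_task_labels(small_design(1), seed = 3)
  cfg <- generator_config(n_voxels = 4, effect_size = 1, noise_sd = 0, ar = 0)
  bold <- as.matrix(simulate_bold(labs, cfg, seed = 4))
  cfg2 <- materialize_state_means(cfg, labs, seed = derive_seed(4, "state-means"))
  expect_equal(bold, unname(cfg2$state_means[labs$label, ]),
               ignore_attr = TRUE, tolerance = 1e-12)
  # nearest-state-mean decoding recovers the label sequence
  dists <- as.matrix(dist(rbind(bold, cfg2$state_means)))
  dists <- dists[seq_len(nrow(bold)), nrow(bold) + seq_len(nrow(cfg2$state_means))]
  decoded <- rownames(cfg2$state_means)[apply(dists, 1, which.min)]
  expect_equal(decoded, labs$label)
})

test_that("AR(1) noise has the requested lag-1 autocorrelation", {
  labs <- toy_labels(rep("a", 10000))
  cfg <- generator_config(n_voxels = 1, effect_size = 0, noise_sd = 1, ar = 0.6)
  bold <- as.matrix(simulate_bold(labs, cfg, seed = 11))
  resid <- bold[, 1] - mean(bold[, 1])
  ac1 <- cor(resid[-1], resid[-length(resid)]) # sample autocorrelation oracle
  expect_lt(abs(ac1 - 0.6), 0.05)
})

test_that("per-state sample means converge to the planted means", {
  labs <- toy_labels(rep(c("a", "b", "c"), each = 400))
  cfg <- generator_config(n_voxels = 3, effect_size = 1, noise_sd = 1, ar = 0)
  bold <- as.matrix(simulate_bold(labs, cfg, seed = 12))
  cfg <- materialize_state_means(cfg, labs, seed = derive_seed(12, "state-means"))
  for (s in c("a", "b", "c")) {
    dev <- colMeans(bold[labs$label == s, ]) - cfg$state_means[s, ]
    expect_lt(max(abs(dev)), 3 / sqrt(400))
  }
})

test_that("output shape matches the label sequence and config is validated", {
  labs <- toy_labels(rep(c("a", "b"), 25))
  cfg <- generator_config(n_voxels = 6)
  expect_equal(nrow(simulate_bold(labs, cfg, seed = 1)), 50)
  bad <- generator_config(state_means = matrix(0, 1, 3, dimnames = list("a", NULL)))
  expect_error(simulate_bold(labs, bad, seed = 1), "alphabet")
})

test_that("HRF convolution delays the mean signal", {
  labs <- toy_labels(rep(c("a", "b"), each = 30))
  mu <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "v1"))
  cfg <- generator_config(state_means = mu, noise_sd = 0, ar = 0,
                          hrf = canonical_hrf(1.8))
  bold <- as.matrix(simulate_bold(labs, cfg, seed = 1))
  # at the a->b transition the convolved signal has not yet risen
  expect_lt(bold[31, 1], 1)
  expect_gt(bold[45, 1], 1.5)
})

test_that("cohorts share planted means but differ per participant", {
  d <- small_design(1)
  cfg <- generator_config(n_voxels = 3, participant_shift_sd = 0.5)
  co <- simulate_cohort(3, d, cfg, seed = 21)
  expect_equal(nrow(co), 3)
  expect_false(identical(co$labels[[1]], co$labels[[2]]))
  expect_false(identical(co$bold[[1]], co$bold[[2]]))
  co2 <- simulate_cohort(3, d, cfg, seed = 21)
  expect_identical(co, co2) # determinism in the master seed
})

test_that("a 19-participant cohort of 5-trial runs has the cohort shape", {
  co <- simulate_cohort(19, task_design(n_trials = 5, with_control = FALSE),
                        generator_config(n_voxels = 2), seed = 3)
  expect_equal(nrow(co), 19)
  expect_true(all(vapply(co$labels, function(l) length(unique(l$trial)), numeric(1)) == 5))
})
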
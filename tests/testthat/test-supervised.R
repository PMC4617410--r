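test_that("lag zero reproduces the direct statistic", {
  labs <- simulate_task_labels(small_design(1), seed = 1)
  bold <- simulate_bold(labs, generator_config(n_voxels = 5, effect_size = 1), seed = 2)
  lp <- lag_profile(bold, labs, lags = 0)
  direct <- manova_statistics(class_scatter(bold, labs))$t2
  expect_equal(lp$value, direct, tolerance = 1e-10)
})

test_that("label-locked data peaks at lag zero; HRF shifts and deconvolution restores it", {
  labs <- simulate_task_labels(small_design(2), seed = 3)
  cfg0 <- generator_config(n_voxels = 15, effect_size = 1, ar = 0.3)
  b0 <- simulate_bold(labs, cfg0, seed = 4)
  expect_equal(peak_lag(lag_profile(b0, labs, -5:5)), 0L)
  cfgH <- generator_config(n_voxels = 15, effect_size = 1, ar = 0.3,
                           hrf = canonical_hrf(1.8))
  bH <- simulate_bold(labs, cfgH, seed = 4)
  expect_gt(peak_lag(lag_profile(bH, labs, -5:5)), 0L)
  bD <- deconvolve_hrf(bH, tr = 1.8, noise_level = 0.02)
  expect_equal(peak_lag(lag_profile(bD, labs, -5:5)), 0L)
})

test_that("lag profiles are consistent under a common shift of data and labels", {
  labs <- simulate_task_labels(small_design(1), seed = 5)
  bold <- as.matrix(simulate_bold(labs, generator_config(n_voxels = 8, effect_size = 1.5),
                                  seed = 6))
  lp1 <- lag_profile(bold, labs, -3:3)
  k <- 4
  lp2 <- lag_profile(bold[-(1:k), , drop = FALSE], labs[-(1:k), ], -3:3)
  expect_equal(peak_lag(lp2), peak_lag(lp1))
  expect_equal(lp2$value, lp1$value, tolerance = 0.1)
})

test_that("excessive lags are rejected", {
  labs <- simulate_task_labels(small_design(1), seed = 7)
  bold <- simulate_bold(labs, generator_config(n_voxels = 3), seed = 8)
  expect_error(lag_profile(bold, labs, lags = -nrow(labs):nrow(labs)), "shortest")
})

test_that("per-trial statistics give one row per usable trial", {
  labs <- simulate_task_labels(small_design(5), seed = 9)
  bold <- simulate_bold(labs, generator_config(n_voxels = 6, effect_size = 1), seed = 10)
  pt <- per_trial_statistics(bold, labs)
  expect_equal(nrow(pt), 5)
  expect_equal(pt$trial, 1:5)
  expect_false(any(pt$error_trial))
})

test_that("error trials are flagged at trial granularity", {
  labs <- simulate_task_labels(task_design(n_trials = 4, error_rate = 0.4,
                                           with_control = FALSE), seed = 23)
  bold <- simulate_bold(labs, generator_config(n_voxels = 5, effect_size = 1), seed = 11)
  pt <- per_trial_statistics(bold, labs)
  err_by_trial <- tapply(labs$error, labs$trial, any)
  expect_equal(pt$error_trial, as.logical(err_by_trial[as.character(pt$trial)]))
})

test_that("halved class separation lowers the per-trial T2", {
  d <- small_design(4)
  diffs <- sapply(1:10, function(s) {
    labs <- simulate_task_labels(d, seed = 100 + s)
    cfg <- generator_config(n_voxels = 10, effect_size = 1, ar = 0.3)
    cfg <- materialize_state_means(cfg, labs, seed = 7)
    cfg_half <- cfg
    cfg_half$state_means <- cfg$state_means * 0.5
    b_full <- as.matrix(simulate_bold(labs, cfg, seed = 200 + s))
    b_half <- as.matrix(simulate_bold(labs, cfg_half, seed = 200 + s))
    halved <- labs$trial %in% c(2, 4)
    b_full[halved, ] <- b_half[halved, ]
    pt <- per_trial_statistics(b_full, labs)
    mean(pt$t2[pt$trial %in% c(1, 3)]) - mean(pt$t2[pt$trial %in% c(2, 4)])
  })
  expect_gt(mean(diffs > 0), 0.8)
  expect_gt(mean(diffs), 0)
})

test_that("identical trials give identical per-trial T2", {
  lab1 <- c(rep("a", 4), rep("b", 4))
  labs <- dplyr::bind_rows(toy_labels(lab1, trial = 1L), toy_labels(lab1, trial = 2L))
  block <- matrix(rnorm(16), 8, 2)
  bold <- rbind(block, block)
  pt <- per_trial_statistics(bold, labs)
  expect_equal(pt$t2[1], pt$t2[2], tolerance = 1e-8)
})

test_that("memory-load grouping assigns the prescribed choice blocks", {
  labs <- simulate_task_labels(task_design(n_trials = 1), seed = 12)
  g <- choice_grouping(labs, "memory_load")
  cls <- setNames(g$class, g$choice_block)
  expect_equal(unname(cls[c("1", "2", "11", "12")]), rep("class_1", 4)) # low load
  expect_equal(unname(cls[c("5", "6", "7", "8")]), rep("class_2", 4))  # high load
  expect_equal(unname(cls[c("3", "4", "9", "10")]), rep("excluded", 4))
})

test_that("saliency grouping follows the landmark categories", {
  labs <- simulate_task_labels(task_design(n_trials = 1), seed = 13)
  g <- choice_grouping(labs, "visual_saliency")
  cls <- setNames(g$class, g$choice_block)
  high <- names(which(landmark_saliency(default_landmark_map()) == "high"))
  low <- names(which(landmark_saliency(default_landmark_map()) == "low"))
  neutral <- names(which(landmark_saliency(default_landmark_map()) == "neutral"))
  expect_equal(unname(cls[high]), rep("class_2", length(high)))
  expect_equal(unname(cls[low]), rep("class_1", length(low)))
  expect_equal(unname(cls[neutral]), rep("excluded", length(neutral)))
  labs_nolm <- dplyr::mutate(labs, landmark = NA_character_)
  expect_error(choice_grouping(labs_nolm, "visual_saliency"), "landmark")
})

test_that("random groupings draw ten disjoint 4+4 block sets deterministically", {
  labs <- simulate_task_labels(task_design(n_trials = 1), seed = 14)
  g <- choice_grouping(labs, "random", seed = 15)
  expect_equal(dplyr::n_distinct(g$instance), 10)
  for (i in unique(g$instance)) {
    gi <- g[g$instance == i, ]
    expect_equal(sum(gi$class == "class_1"), 4)
    expect_equal(sum(gi$class == "class_2"), 4)
    expect_length(intersect(gi$choice_block[gi$class == "class_1"],
                            gi$choice_block[gi$class == "class_2"]), 0)
  }
  expect_identical(g, choice_grouping(labs, "random", seed = 15))
})

test_that("grouping contrasts detect planted load structure and not its absence", {
  d <- small_design(3)
  labs <- simulate_task_labels(d, seed = 16)
  cfg <- generator_config(n_voxels = 16, effect_size = 0.5, ar = 0.3,
                          load_voxels = 1:8, load_delta = 2)
  bold <- simulate_bold(labs, cfg, seed = 17)
  g_mem <- choice_grouping(labs, "memory_load")
  g_rnd <- choice_grouping(labs, "random", seed = 18)
  r_mem <- grouping_contrast(bold, labs, g_mem, B = 60, seed = 19)
  r_rnd <- grouping_contrast(bold, labs, g_rnd, B = 60, seed = 20)
  expect_gt(r_mem$normalized, r_rnd$normalized)
  expect_lt(r_mem$p_value, 0.05)
  expect_equal(r_rnd$n_instances, 10)
  expect_length(r_rnd$bootstrap_values, 60) # averaged across instances, then pooled
})

test_that("identical class distributions give a near-null contrast", {
  # means identical across all labels: no class structure at choice points
  norm <- sapply(1:6, function(s) {
    labs <- simulate_task_labels(small_design(2), seed = 20 + s)
    mu <- matrix(0, length(unique(labs$label)), 4,
                 dimnames = list(sort(unique(labs$label)), NULL))
    bold <- simulate_bold(labs, generator_config(state_means = mu, noise_sd = 0.5),
                          seed = 40 + s)
    g <- choice_grouping(labs, "memory_load")
    grouping_contrast(bold, labs, g, B = 60, seed = 60 + s)$normalized
  })
  expect_gt(mean(norm), 0.75)
  expect_lt(mean(norm), 1.25)
  # exactly duplicated data in the two classes -> MD exactly 0
  gr_lab <- toy_labels(rep(c("choice_train", "choice_train"), 4),
                       choice_block = rep(c(1L, 5L), each = 4))
  x <- matrix(rep(rnorm(8), each = 2), 8, 2, byrow = FALSE)
  x[gr_lab$choice_block == 5, ] <- x[gr_lab$choice_block == 1, ]
  expect_equal(mahalanobis_distance(x, ifelse(gr_lab$choice_block == 1, "a", "b")),
               0, tolerance = 1e-8)
})

test_that("error choice blocks are excluded from contrasts", {
  labs <- simulate_task_labels(small_design(2), seed = 24)
  labs$error[labs$choice_block %in% c(1, 5)] <- TRUE
  g <- choice_grouping(labs, "memory_load")
  gr <- grouping_rows(labs, g[g$instance == 1, ])
  expect_false(any(gr$block %in% c(1, 5)))
  expect_setequal(unique(gr$block), c(2, 11, 12, 6, 7, 8))
})
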
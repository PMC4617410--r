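test_that("a one-state model reduces to the i.i.d. Gaussian fit", {
  set.seed(1)
  x <- matrix(rnorm(200 * 2, mean = 3, sd = 2), 200, 2)
  fit <- fit_hmm(x, 1, n_restarts = 1, seed = 2)
  expect_equal(as.numeric(fit$means), colMeans(x), tolerance = 1e-6)
  v_mle <- apply(x, 2, function(c) mean((c - mean(c))^2))
  expect_equal(as.numeric(fit$vars), v_mle, tolerance = 1e-5)
  ll_iid <- sum(dnorm(x, rep(colMeans(x), each = 200),
                      rep(sqrt(v_mle), each = 200), log = TRUE))
  expect_equal(fit$loglik, ll_iid, tolerance = 1e-4)
  expect_equal(fit$n_parameters, 0 + 0 + 2 * 1 * 2)
})

test_that("the EM log-likelihood is non-decreasing", {
  dat <- planted_hmm_data(3, 2, 300, mean_sd = 1.5, seed = 3)
  fit <- fit_hmm(dat$obs, 3, n_restarts = 2, seed = 4)
  expect_true(all(diff(fit$ll_path) >= -1e-8 * abs(fit$ll_path[-1])))
})

test_that("planted two-state means are recovered up to relabeling", {
  set.seed(5)
  z <- rep(sample(1:2, 50, replace = TRUE), each = 8)
  mu <- matrix(c(-3, 3), 2, 1)
  x <- matrix(mu[z, ] + rnorm(length(z)), ncol = 1)
  fit <- fit_hmm(x, 2, n_restarts = 3, seed = 6)
  est <- sort(as.numeric(fit$means))
  expect_lt(max(abs(est - c(-3, 3))), 0.2)
})

test_that("AIC follows the parameter-count formula", {
  dat <- planted_hmm_data(2, 1, 120, seed = 7)
  fit2 <- fit_hmm(dat$obs, 2, n_restarts = 2, seed = 8)
  expect_equal(fit2$n_parameters, 1 + 2 + 4) # (m-1) + m(m-1) + 2md = 7
  expect_equal(AIC(fit2), -2 * fit2$loglik + 2 * 7)
  fit1 <- fit_hmm(dat$obs, 1, n_restarts = 1, seed = 9)
  expect_equal(fit1$n_parameters, 2)
  # a hypothetical logL of -100 with m = 2, d = 1 gives AIC 214
  expect_equal(-2 * (-100) + 2 * 7, 214)
})

test_that("the forward log-likelihood matches brute-force path enumeration", {
  dat <- planted_hmm_data(2, 2, 60, seed = 10)
  fit <- fit_hmm(dat$obs, 2, n_restarts = 2, seed = 11)
  x <- dat$obs[1:7, , drop = FALSE] # tiny segment: 2^7 paths
  ll_fwd <- {
    logB <- stageseg:::hmm_log_emissions(x, fit$means, fit$vars)
    stageseg:::forward_backward(logB, fit$A, fit$pi)$loglik
  }
  paths <- as.matrix(expand.grid(rep(list(1:2), 7)))
  ll_paths <- apply(paths, 1, function(p) {
    lp <- log(fit$pi[p[1]]) +
      sum(log(fit$A[cbind(p[-length(p)], p[-1])])) +
      sum(sapply(seq_along(p), function(t) {
        sum(dnorm(x[t, ], fit$means[p[t], ], sqrt(fit$vars[p[t], ]), log = TRUE))
      }))
    lp
  })
  ll_brute <- max(ll_paths) + log(sum(exp(ll_paths - max(ll_paths))))
  expect_equal(ll_fwd, ll_brute, tolerance = 1e-8)
})

test_that("viterbi matches brute-force argmax and breaks ties to the lower state", {
  dat <- planted_hmm_data(2, 2, 60, seed = 12)
  fit <- fit_hmm(dat$obs, 2, n_restarts = 2, seed = 13)
  x <- dat$obs[1:7, , drop = FALSE]
  paths <- as.matrix(expand.grid(rep(list(1:2), 7)))
  score <- apply(paths, 1, function(p) {
    log(fit$pi[p[1]]) + sum(log(fit$A[cbind(p[-7], p[-1])])) +
      sum(sapply(1:7, function(t) {
        sum(dnorm(x[t, ], fit$means[p[t], ], sqrt(fit$vars[p[t], ]), log = TRUE))
      }))
  })
  vit <- viterbi_decode(fit, x)
  expect_equal(unname(vit), unname(paths[which.max(score), ]))
  # degenerate fully-tied model: all scores equal, path must be all state 1
  tied <- fit
  tied$means <- matrix(0, 2, 2)
  tied$vars <- matrix(1, 2, 2)
  tied$A <- matrix(0.5, 2, 2)
  tied$pi <- c(0.5, 0.5)
  expect_equal(viterbi_decode(tied, x), rep(1L, 7))
})

test_that("viterbi recovers noiseless well-separated sequences exactly", {
  dat <- planted_hmm_data(3, 2, 200, mean_sd = 6, seed = 14)
  fit <- fit_hmm(dat$obs, 3, n_restarts = 3, seed = 15)
  st <- viterbi_decode(fit, dat$obs)
  expect_gte(matching_index(st, as.character(dat$states))$matching_index, 99)
  fit1 <- fit_hmm(dat$obs, 1, n_restarts = 1, seed = 16)
  expect_equal(unique(viterbi_decode(fit1, dat$obs)), 1L)
})

test_that("the viterbi path scores at least as high as random paths", {
  dat <- planted_hmm_data(2, 2, 40, seed = 17)
  fit <- fit_hmm(dat$obs, 2, n_restarts = 2, seed = 18)
  path_score <- function(p, x) {
    log(fit$pi[p[1]]) + sum(log(fit$A[cbind(p[-length(p)], p[-1])])) +
      sum(sapply(seq_along(p), function(t) {
        sum(dnorm(x[t, ], fit$means[p[t], ], sqrt(fit$vars[p[t], ]), log = TRUE))
      }))
  }
  vit <- viterbi_decode(fit, dat$obs)
  s_vit <- path_score(vit, dat$obs)
  set.seed(19)
  for (i in 1:200) {
    expect_gte(s_vit, path_score(sample(1:2, 40, replace = TRUE), dat$obs))
  }
})

test_that("trial boundaries reset the state distribution", {
  dat <- planted_hmm_data(2, 2, 120, mean_sd = 4, seed = 20)
  trial <- rep(1:3, each = 40)
  fit <- fit_hmm(dat$obs, 2, trial = trial, n_restarts = 2, seed = 21)
  st_joint <- viterbi_decode(fit, dat$obs, trial = trial)
  expect_length(st_joint, 120)
  # decoding each trial separately gives the same result as the reset decode
  st_parts <- unlist(lapply(split(seq_len(120), trial), function(i) {
    viterbi_decode(fit, dat$obs[i, , drop = FALSE])
  }))
  expect_equal(unname(st_joint), unname(st_parts))
})

test_that("model selection returns the curve and respects degenerate ranges", {
  dat <- planted_hmm_data(2, 2, 150, seed = 22)
  sel1 <- model_selection(dat$obs, m_range = 3, n_restarts = 1, seed = 23)
  expect_equal(sel1$selected_m, 3L)
  sel <- model_selection(dat$obs, m_range = 1:4, n_restarts = 1, seed = 24)
  expect_equal(nrow(sel$curve), 4)
  expect_equal(sel$curve$m, 1:4)
  expect_s3_class(autoplot(sel), "ggplot")
  expect_error(model_selection(dat$obs, m_range = integer(0)), "non-empty")
})

test_that("smoothed-AIC selection finds a moderately separated 3-state structure", {
  hits <- sapply(1:5, function(s) {
    dat <- planted_hmm_data(3, 5, 600, mean_sd = 0.4, seed = 600 + s)
    model_selection(dat$obs, 1:6, n_restarts = 2, max_iter = 200,
                    seed = 650 + s)$selected_m
  })
  expect_gte(sum(hits == 3), 3)
})

test_that("invalid state counts are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_hmm(x, 0), "at least 1")
  expect_error(fit_hmm(x, 10), "below the number")
})
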
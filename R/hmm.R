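# Unsupervised dissection of time on task: Gaussian-emission hidden Markov
# models fitted by expectation-maximization, AIC-based selection of the
# state count, and Viterbi decoding. Trials are treated as independent
# sequences: the state distribution resets to pi at each trial start.

# Per-volume log emission densities (diagonal Gaussian), T x m.
hmm_log_emissions <- function(x, means, vars) {
  m <- nrow(means)
  Tn <- nrow(x)
  out <- matrix(0, Tn, m)
  for (j in seq_len(m)) {
    out[, j] <- -0.5 * sum(log(2 * pi * vars[j, ])) -
      0.5 * rowSums(sweep(x, 2, means[j, ], `-`)^2 %*% diag(1 / vars[j, ], ncol(x)))
  }
  out
}

# Scaled forward-backward over one sequence. Returns gamma, summed xi, and
# the sequence log-likelihood.
forward_backward <- function(logB, A, pi0) {
  Tn <- nrow(logB)
  m <- ncol(logB)
  Bm <- exp(logB - apply(logB, 1, max))
  alpha <- matrix(0, Tn, m)
  beta <- matrix(0, Tn, m)
  scl <- numeric(Tn)
  a <- pi0 * Bm[1, ]
  scl[1] <- sum(a)
  alpha[1, ] <- a / scl[1]
  for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% A) * Bm[t, ]
    scl[t] <- sum(a)
    alpha[t, ] <- a / scl[t]
  }
  beta[Tn, ] <- 1
  for (t in (Tn - 1):1) {
    b <- A %*% (Bm[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / scl[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, m, m)
  for (t in 1:(Tn - 1)) {
    x_t <- (alpha[t, ] %o% (Bm[t + 1, ] * beta[t + 1, ])) * A
    xi <- xi + x_t / sum(x_t)
  }
  loglik <- sum(log(scl)) + sum(apply(logB, 1, max))
  list(gamma = gamma, xi = xi, loglik = loglik)
}

hmm_em_once <- function(x, m, trial, max_iter, tol, var_floor) {
  Tn <- nrow(x)
  d <- ncol(x)
  # Random initialization: means at sampled observations, shared variances,
  # sticky transitions.
  means <- x[sample.int(Tn, m), , drop = FALSE] +
    matrix(rnorm(m * d, sd = 0.1), m, d)
  vars <- matrix(pmax(apply(x, 2, stats::var), var_floor), m, d, byrow = TRUE)
  A <- matrix(0.2 / max(m - 1, 1), m, m)
  diag(A) <- if (m > 1) 0.8 else 1
  pi0 <- rep(1 / m, m)
  seqs <- split(seq_len(Tn), trial)
  prev_ll <- -Inf
  ll_path <- numeric(0)
  for (iter in seq_len(max_iter)) {
    logB <- hmm_log_emissions(x, means, vars)
    gamma <- matrix(0, Tn, m)
    xi <- matrix(0, m, m)
    pi_acc <- rep(0, m)
    ll <- 0
    for (idx in seqs) {
      if (length(idx) < 2) {
        abort("Each trial needs at least 2 volumes for HMM fitting.")
      }
      fb <- forward_backward(logB[idx, , drop = FALSE], A, pi0)
      gamma[idx, ] <- fb$gamma
      xi <- xi + fb$xi
      pi_acc <- pi_acc + fb$gamma[1, ]
      ll <- ll + fb$loglik
    }
    if (!is.finite(ll)) abort("Non-finite likelihood during EM.")
    ll_path <- c(ll_path, ll)
    # M-step
    pi0 <- pi_acc / sum(pi_acc)
    if (m > 1) {
      A <- xi / pmax(rowSums(xi), .Machine$double.eps)
    }
    Ng <- colSums(gamma)
    means <- t(gamma) %*% x / Ng
    vars <- t(gamma) %*% x^2 / Ng - means^2
    vars <- pmax(vars, var_floor)
    if (is.finite(prev_ll) &&
        abs(ll - prev_ll) < tol * (abs(prev_ll) + .Machine$double.eps)) {
      break
    }
    prev_ll <- ll
  }
  list(A = A, pi = pi0, means = means, vars = vars,
       loglik = ll_path[length(ll_path)], ll_path = ll_path, iterations = iter)
}

#' Fit a Gaussian-emission hidden Markov model
#'
#' Baum-Welch (EM) estimation of an `m`-state HMM with diagonal-covariance
#' Gaussian emissions over the observed dimensions (typically a small set of
#' k-medoids representative voxels). Several random restarts are run and the
#' fit with the highest final log-likelihood is kept. Convergence is
#' declared when the relative log-likelihood change falls below `tol`;
#' variances are floored at `var_floor`. Trials (if given) are modeled as
#' independent sequences sharing parameters.
#'
#' @param x observations (matrix or tibble, time x dimensions).
#' @param m number of hidden states.
#' @param trial optional per-volume trial ids (or a label tibble whose
#'   `trial` column is used); state probabilities reset at trial starts.
#' @param n_restarts random initializations (default 5).
#' @param max_iter EM iteration cap (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-5).
#' @param var_floor lower bound on emission variances (default 1e-4).
#' @param seed integer seed.
#' @return an object of class `gauss_hmm`: transition matrix `A`, initial
#'   distribution `pi`, emission `means` and `vars` (m x d), `loglik`,
#'   `n_parameters`, `ll_path`, `iterations`.
#' @export
fit_hmm <- function(x, m, trial = NULL, n_restarts = 5, max_iter = 500,
                    tol = 1e-5, var_floor = 1e-4, seed = 1) {
  x <- as_bold_matrix(x)
  if (m < 1) abort("`m` must be at least 1.")
  if (m >= nrow(x)) abort("`m` must be below the number of volumes.")
  if (is.data.frame(trial)) trial <- trial$trial
  trial <- trial %||% rep(1L, nrow(x))
  if (length(trial) != nrow(x)) abort("`trial` must have one id per volume.")
  best <- NULL
  errors <- character(0)
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      with_seed(derive_seed(seed, "restart", r), {
        hmm_em_once(x, m, trial, max_iter, tol, var_floor)
      }),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      errors <- c(errors, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    abort(paste0("All EM restarts failed: ", paste(unique(errors), collapse = "; ")))
  }
  d <- ncol(x)
  structure(
    list(
      A = best$A, pi = best$pi, means = best$means, vars = best$vars,
      loglik = best$loglik, ll_path = best$ll_path,
      iterations = best$iterations, m = as.integer(m), d = as.integer(d),
      n_obs = nrow(x),
      n_parameters = (m - 1) + m * (m - 1) + 2 * m * d,
      converged = best$iterations < max_iter, seed = seed
    ),
    class = "gauss_hmm"
  )
}

#' @export
print.gauss_hmm <- function(x, ...) {
  cat(sprintf(
    "<gauss_hmm> %d states, %d dims, logLik = %.2f, AIC = %.2f (%d EM iterations%s)\n",
    x$m, x$d, x$loglik, stats::AIC(x), x$iterations,
    if (x$converged) "" else ", not converged"
  ))
  invisible(x)
}

#' @export
logLik.gauss_hmm <- function(object, ...) {
  structure(object$loglik, df = object$n_parameters, nobs = object$n_obs,
            class = "logLik")
}

#' @export
tidy.gauss_hmm <- function(x, ...) {
  tibble::tibble(
    state = rep(seq_len(x$m), each = x$d),
    dimension = rep(seq_len(x$d), times = x$m),
    mean = as.numeric(t(x$means)),
    variance = as.numeric(t(x$vars))
  )
}

#' @export
glance.gauss_hmm <- function(x, ...) {
  tibble::tibble(
    m = x$m, d = x$d, logLik = x$loglik, AIC = stats::AIC(x),
    n_parameters = x$n_parameters, iterations = x$iterations,
    converged = x$converged
  )
}

#' Select the number of hidden states by smoothed AIC
#'
#' Fits HMMs across `m_range`, computes each model's AIC
#' (`-2 logLik + 2 n_parameters`), smooths the AIC curve with a
#' least-squares third-order polynomial, and selects the state count
#' minimizing the smoothed curve on the integer grid (ties go to the
#' smallest m). The polynomial degree is reduced when fewer than four state
#' counts are available.
#'
#' @inheritParams fit_hmm
#' @param m_range candidate state counts (default 1:20).
#' @return an object of class `hmm_selection`: tibble `curve` (`m`, `aic`,
#'   `aic_smooth`), `selected_m`, and the refitted `best_model`.
#' @export
model_selection <- function(x, m_range = 1:20, trial = NULL, n_restarts = 5,
                            max_iter = 500, tol = 1e-5, var_floor = 1e-4,
                            seed = 1) {
  if (length(m_range) == 0) abort("`m_range` must be non-empty.")
  fits <- lapply(m_range, function(m) {
    tryCatch(
      fit_hmm(x, m, trial = trial, n_restarts = n_restarts,
              max_iter = max_iter, tol = tol, var_floor = var_floor,
              seed = derive_seed(seed, "m", m)),
      error = function(e) {
        warn(sprintf("HMM fit failed for m = %d: %s", m, conditionMessage(e)))
        NULL
      }
    )
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) abort("All HMM fits failed across `m_range`.")
  ms <- m_range[ok]
  aics <- vapply(fits[ok], function(f) stats::AIC(f), numeric(1))
  deg <- min(3, length(ms) - 1)
  smooth <- if (deg >= 1) {
    as.numeric(predict(stats::lm(aics ~ stats::poly(ms, deg))))
  } else {
    aics
  }
  sel <- ms[which.min(smooth)]
  structure(
    list(
      curve = tibble::tibble(m = as.integer(ms), aic = aics, aic_smooth = smooth),
      selected_m = as.integer(sel),
      best_model = fits[ok][[which(ms == sel)]]
    ),
    class = "hmm_selection"
  )
}

#' @export
print.hmm_selection <- function(x, ...) {
  cat(sprintf("<hmm_selection> m in [%d, %d], selected m = %d\n",
              min(x$curve$m), max(x$curve$m), x$selected_m))
  invisible(x)
}

#' @export
tidy.hmm_selection <- function(x, ...) x$curve

#' @export
autoplot.hmm_selection <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curve, c("aic", "aic_smooth"),
                            names_to = "curve", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$value,
                                   color = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_m, linetype = 2) +
    ggplot2::labs(x = "number of hidden states", y = "AIC")
}

#' Viterbi decoding
#'
#' Maximum a-posteriori hidden-state path by log-domain dynamic programming,
#' with ties broken toward the lower state index. Trials decode as
#' independent sequences.
#'
#' @param model a [fit_hmm()] model.
#' @param x observations (matrix or tibble) matching the model dimension.
#' @param trial optional per-volume trial ids (or label tibble).
#' @return integer vector of state indices (1..m), one per volume.
#' @export
viterbi_decode <- function(model, x, trial = NULL) {
  x <- as_bold_matrix(x)
  if (ncol(x) != model$d) abort("Observation dimension does not match the model.")
  if (is.data.frame(trial)) trial <- trial$trial
  trial <- trial %||% rep(1L, nrow(x))
  logB <- hmm_log_emissions(x, model$means, model$vars)
  logA <- log(pmax(model$A, .Machine$double.xmin))
  logpi <- log(pmax(model$pi, .Machine$double.xmin))
  out <- integer(nrow(x))
  for (idx in split(seq_len(nrow(x)), trial)) {
    n <- length(idx)
    m <- model$m
    delta <- matrix(-Inf, n, m)
    psi <- matrix(1L, n, m)
    delta[1, ] <- logpi + logB[idx[1], ]
    if (n > 1) {
      for (t in 2:n) {
        cand <- delta[t - 1, ] + logA # m x m: prev state x next state
        psi[t, ] <- apply(cand, 2, which.max)
        delta[t, ] <- cand[cbind(psi[t, ], seq_len(m))] + logB[idx[t], ]
      }
    }
    path <- integer(n)
    path[n] <- which.max(delta[n, ])
    if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
    out[idx] <- path
  }
  out
}
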
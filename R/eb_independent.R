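# Empirical-Bayes AUC prediction for independent pre-selected SNPs:
# EM fit of the point-normal prior on standardized effects z_m | delta_m ~
# N(delta_m / s_m, 1), closed-form spike-and-slab posterior of delta_m,
# and Monte-Carlo AUC draws.

#' Shared container for posterior AUC predictions
#'
#' @param auc_draws numeric vector of posterior AUC draws.
#' @param pi_hat,sigma_sq_hat estimated prior parameters.
#' @param extra named list merged into the result (sampler diagnostics).
#' @return list of class `"auc_prediction"` with `auc_draws`, `auc_mean`
#'   (posterior-mean point estimate), `auc_sd`, `ci` (2.5/97.5% draw
#'   quantiles), `pi_hat`, `sigma_sq_hat`.
#' @export
auc_prediction <- function(auc_draws, pi_hat = NA_real_,
                           sigma_sq_hat = NA_real_, extra = list()) {
  out <- c(list(auc_draws = auc_draws, auc_mean = mean(auc_draws),
                auc_sd = sd(auc_draws),
                ci = unname(quantile(auc_draws, c(0.025, 0.975))),
                pi_hat = pi_hat, sigma_sq_hat = sigma_sq_hat), extra)
  class(out) <- "auc_prediction"
  out
}

#' @export
print.auc_prediction <- function(x, ...) {
  cat(sprintf("Predicted AUC: %.4f (95%% interval %.4f-%.4f, sd %.4f)\n",
              x$auc_mean, x$ci[1], x$ci[2], x$auc_sd))
  if (is.finite(x$pi_hat))
    cat(sprintf("Prior fit: pi = %.4g, sigma^2 = %.4g\n",
                x$pi_hat, x$sigma_sq_hat))
  invisible(x)
}

# log marginal likelihood of z under the point-normal prior
pointnormal_loglik <- function(z, pi, sigma_sq) {
  v <- 1 + sigma_sq
  sum(log((1 - pi) * dnorm(z) + pi * dnorm(z / sqrt(v)) / sqrt(v)))
}

# posterior risk probability h_m for given (pi, sigma_sq)
posterior_h <- function(z, pi, sigma_sq) {
  v <- 1 + sigma_sq
  # log-domain for |z| large
  la <- log1p(-pi) + dnorm(z, log = TRUE)
  lb <- log(pi) + dnorm(z / sqrt(v), log = TRUE) - 0.5 * log(v)
  1 / (1 + exp(la - lb))
}

#' EM fit of the point-normal prior to z-scores
#'
#' Fits \eqn{\beta_m / s_m \sim (1-\pi)\delta_0 + \pi N(0, \sigma^2)} by
#' maximum marginal likelihood of the z-scores, for independent SNPs
#' (\eqn{z_m \sim (1-\pi) N(0,1) + \pi N(0, 1+\sigma^2)}). E-step:
#' posterior risk probabilities \eqn{h_m}; M-step: \eqn{\pi =
#' \sum h_m / M}, \eqn{\sigma^2 = \sum h_m z_m^2 / \sum h_m - 1}, floored
#' at zero. Iterates until both parameter changes fall below `tol`.
#'
#' @param z numeric z-score vector (length at least 2).
#' @param init_pi,init_sigma_sq starting values.
#' @param tol convergence tolerance on both parameter changes.
#' @param max_iter iteration cap; non-convergence yields a warning, not
#'   an error.
#' @return list of class `"prior_fit"`: `pi`, `sigma_sq`, `h` (posterior
#'   risk probabilities at the fit), `loglik_trace`, `n_iter`,
#'   `converged`.
#' @export
em_fit <- function(z, init_pi = 0.1, init_sigma_sq = 1, tol = 1e-6,
                   max_iter = 10000) {
  if (length(z) < 2) stop("em_fit: need at least 2 z-scores", call. = FALSE)
  if (any(!is.finite(z))) stop("em_fit: non-finite z-score", call. = FALSE)
  pi <- init_pi; sigma_sq <- init_sigma_sq
  M <- length(z)
  z2 <- z^2
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    h <- posterior_h(z, pi, sigma_sq)
    sh <- sum(h)
    pi_new <- sh / M
    sigma_new <- if (sh > 0) max(sum(h * z2) / sh - 1, .Machine$double.eps)
      else .Machine$double.eps
    trace[it] <- pointnormal_loglik(z, pi_new, sigma_new)
    if (abs(pi_new - pi) < tol && abs(sigma_new - sigma_sq) < tol) {
      pi <- pi_new; sigma_sq <- sigma_new
      converged <- TRUE
      break
    }
    pi <- pi_new; sigma_sq <- sigma_new
  }
  if (!converged)
    warning("em_fit: not converged after ", max_iter, " iterations",
            call. = FALSE)
  structure(list(pi = pi, sigma_sq = sigma_sq,
                 h = posterior_h(z, pi, sigma_sq),
                 loglik_trace = trace, n_iter = it, converged = converged),
            class = "prior_fit")
}

#' @export
print.prior_fit <- function(x, ...) {
  cat(sprintf("point-normal prior fit: pi = %.4g, sigma^2 = %.4g (%s in %d EM iterations)\n",
              x$pi, x$sigma_sq,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Closed-form posterior draws of allele-frequency differences
#'
#' Under the fitted prior, \eqn{\delta_m | z_m \sim (1-h_m)\delta_0 + h_m
#' N(\lambda z_m s_m, \lambda s_m^2)} with shrinkage factor
#' \eqn{\lambda = 1/(1 + 1/\sigma^2)}.
#'
#' @param fit a `"prior_fit"` from [em_fit()].
#' @param z,s aligned z-scores and standard errors of the observed
#'   allele-frequency differences.
#' @param n_draws number of Monte-Carlo draws (rows).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return list of class `"posterior_delta"`: `h`, `lambda`, and `draws`
#'   (`n_draws x M` matrix of delta samples).
#' @export
posterior_delta_draws <- function(fit, z, s, n_draws = 1000, seed = NULL) {
  stopifnot(inherits(fit, "prior_fit"), length(z) == length(s))
  if (n_draws < 1) stop("posterior_delta_draws: n_draws must be >= 1",
                        call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  M <- length(z)
  lambda <- 1 / (1 + 1 / fit$sigma_sq)
  h <- posterior_h(z, fit$pi, fit$sigma_sq)
  mu <- lambda * z * s
  sdv <- sqrt(lambda) * s
  ind <- matrix(rbinom(n_draws * M, 1L, rep(h, each = n_draws)),
                nrow = n_draws)
  eps <- matrix(rnorm(n_draws * M), nrow = n_draws)
  draws <- ind * (rep(mu, each = n_draws) + eps * rep(sdv, each = n_draws))
  structure(list(h = h, lambda = lambda, draws = draws),
            class = "posterior_delta")
}

#' Predict PRS AUC for independent pre-selected SNPs
#'
#' Runs the EM prior fit on the training z-scores, draws delta from the
#' closed-form posterior, and converts each draw to an AUC via
#' \eqn{\Phi(2\sum_m \omega_m \delta_m / \sqrt{\tau_0^2+\tau_1^2})} with
#' identity LD. Accepts one weight set or a list over a hyperparameter
#' grid; the prior fit and the delta draws are shared across the grid.
#'
#' @param ss a [sumstats] object (the pre-selected SNPs).
#' @param weights a [weightset] aligned to `ss`, or a list of such.
#' @param n_draws Monte-Carlo draws used for the posterior AUC.
#' @param seed optional integer seed.
#' @param fit optionally, a precomputed `"prior_fit"` to reuse.
#' @return an [auc_prediction] (or a list of them when `weights` is a
#'   list), each carrying `h` and `lambda` from the posterior.
#' @export
predict_auc_independent <- function(ss, weights, n_draws = 1000, seed = NULL,
                                    fit = NULL) {
  stopifnot(inherits(ss, "sumstats"))
  single <- inherits(weights, "weightset") || is.numeric(weights)
  wlist <- if (single) list(weights) else weights
  if (is.null(fit)) fit <- em_fit(ss$z)
  post <- posterior_delta_draws(fit, ss$z, ss$s, n_draws = n_draws,
                                seed = seed)
  s0 <- sqrt(ss$s0_sq); s1 <- sqrt(ss$s1_sq)
  res <- lapply(wlist, function(ws) {
    omega <- if (inherits(ws, "weightset")) ws$omega else as.numeric(ws)
    stopifnot(length(omega) == nrow(ss))
    denom <- tau_squared(omega, s0) + tau_squared(omega, s1)
    if (denom <= 0) {
      # all-zero weights: no discrimination, AUC is exactly 1/2
      auc <- rep(0.5, n_draws)
    } else {
      auc <- pnorm(2 * drop(post$draws %*% omega) / sqrt(denom))
    }
    auc_prediction(auc, pi_hat = fit$pi, sigma_sq_hat = fit$sigma_sq,
                   extra = list(h = post$h, lambda = post$lambda,
                                fit = fit))
  })
  if (single) res[[1]] else res
}
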
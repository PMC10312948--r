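# SAME (State-Augmentation for Marginal Estimation) Gibbs sampler for the
# point-normal prior under LD, and Monte-Carlo AUC prediction for
# correlated pre-selected SNPs. The number of artificial replicates D of
# the latent (beta, gamma) grows by one per outer iteration, so the
# sampled (pi, sigma^2) concentrate on their maximum-likelihood values.

#' Sampler schedule for the SAME algorithm
#'
#' @param d_max cap on the number of replicates D (outer iterations).
#' @param window width (in outer iterations) of the running-mean window
#'   used both for convergence checking and for the frozen
#'   \eqn{(\hat\pi, \hat\sigma^2)}.
#' @param tol relative change of consecutive window means of
#'   \eqn{\pi} and \eqn{\sigma^2} below which the sampler stops early.
#' @param n_auc_draws post-convergence sweeps collecting delta and AUC.
#' @param jitter diagonal jitter added to a block correlation matrix when
#'   its Cholesky factorization fails.
#' @param band_radius optional LD radius applied to the block matrices.
#' @return list of class `"same_schedule"`.
#' @export
same_schedule <- function(d_max = 100, window = 10, tol = 1e-3,
                          n_auc_draws = 500, jitter = 1e-6,
                          band_radius = NULL) {
  stopifnot(d_max >= 1, window >= 1, tol > 0, n_auc_draws >= 1)
  structure(list(d_max = as.integer(d_max), window = as.integer(window),
                 tol = tol, n_auc_draws = as.integer(n_auc_draws),
                 jitter = jitter, band_radius = band_radius),
            class = "same_schedule")
}

# Band, then ensure each block factorizes; grow jitter if needed.
regularize_blocks <- function(ld, schedule) {
  blocks <- ld$blocks
  for (k in seq_along(blocks)) {
    R <- blocks[[k]]$R
    if (!is.null(schedule$band_radius))
      R[abs(row(R) - col(R)) > schedule$band_radius] <- 0
    jit <- schedule$jitter
    ok <- FALSE
    # small jitter only: a block needing more than ~1000x the configured
    # jitter is genuinely indefinite and should be reported, not distorted
    for (try in 1:5) {
      ch <- tryCatch(chol(R + diag(if (try == 1) 0 else jit, nrow(R))),
                     error = function(e) NULL)
      if (!is.null(ch)) {
        if (try > 1) {
          R <- (R + diag(jit, nrow(R))) / (1 + jit)
          diag(R) <- 1
        }
        ok <- TRUE
        break
      }
      if (try > 1) jit <- jit * 10
    }
    if (!ok)
      stop("same_gibbs: block ", k, " is not positive semi-definite even ",
           "after jitter", call. = FALSE)
    blocks[[k]]$R <- R
  }
  blocks
}

#' SAME Gibbs sampler for the point-normal prior under LD
#'
#' Samples standardized effects \eqn{b_m = \beta_m/s_m}, risk indicators
#' \eqn{\gamma_m}, and prior parameters \eqn{(\pi, \sigma^2)} from the
#' replicated-augmentation posterior \eqn{\propto \prod_d P(z, \beta^{(d)},
#' \gamma^{(d)} | \pi, \sigma^2)} under the block model \eqn{z | b \sim
#' N(R b, R)}. Per SNP visit: residualized mean \eqn{\mu_m = \lambda(z_m -
#' \sum_{m'\ne m} R_{m m'} b_{m'})} with \eqn{\lambda = 1/(1+1/\sigma^2)};
#' slab draw \eqn{b_m \sim N(\mu_m, \lambda)}; spike-vs-slab odds
#' \eqn{r_m = \pi \sqrt{\lambda}/\sigma \cdot e^{\mu_m^2/(2\lambda)}}
#' (computed in the log domain), \eqn{h_m = r_m/(1-\pi+r_m)}. Replicates
#' are warm-started across outer iterations; after \eqn{(\pi, \sigma^2)}
#' converge they are frozen at their last window means and additional
#' sweeps collect \eqn{\delta = S R b} and one AUC draw per weight set.
#'
#' @param z,s z-scores and standard errors of the observed
#'   allele-frequency differences, aligned to the LD structure ordering.
#' @param ld an [ld_structure] covering all SNPs.
#' @param omega numeric matrix (`M x K`) of PRS weights, one column per
#'   weight set, or a single vector.
#' @param auc_denom length-`K` vector of \eqn{\sqrt{\tau_0^2+\tau_1^2}}
#'   denominators (0 allowed for all-zero weight sets, giving AUC 0.5).
#' @param schedule a [same_schedule()].
#' @param seed optional integer seed (`NULL` = current RNG state).
#' @param init_pi,init_sigma_sq starting prior parameters.
#' @return list with `pi_hat`, `sigma_sq_hat`, traces, `D`, `converged`,
#'   `auc_draws` (`n_auc_draws x K`), `delta_mean` and the final-replicate
#'   state.
#' @export
same_gibbs <- function(z, s, ld, omega, auc_denom, schedule = same_schedule(),
                       seed = NULL, init_pi = 0.1, init_sigma_sq = 1) {
  stopifnot(inherits(ld, "ld_structure"), length(z) == length(s))
  if (is.null(dim(omega))) omega <- matrix(omega, ncol = 1)
  stopifnot(nrow(omega) == length(z), length(auc_denom) == ncol(omega))
  if (number_of_snps(ld) != length(z))
    stop("same_gibbs: LD structure must cover every SNP exactly once",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  blocks <- regularize_blocks(ld, schedule)
  res <- .same_gibbs_cpp(as.numeric(z), as.numeric(s),
                         lapply(blocks, `[[`, "idx"),
                         lapply(blocks, `[[`, "R"),
                         init_pi, init_sigma_sq,
                         schedule$d_max, schedule$window, schedule$tol,
                         schedule$n_auc_draws, omega, as.numeric(auc_denom))
  res
}

#' Predict PRS AUC for LD-linked pre-selected SNPs
#'
#' Runs the SAME Gibbs sampler once on the training z-scores (the fit
#' depends only on `z`, `s` and the LD structure, not on the weights) and
#' converts the post-convergence delta draws into posterior AUC draws for
#' each supplied weight set. Weight sets must be harmonized with `ss`
#' (same SNPs, same order); every SNP must belong to exactly one LD block.
#'
#' @param ss a [sumstats] object over the pre-selected SNPs.
#' @param weights a [weightset], numeric vector, or list of either (one
#'   per hyperparameter value).
#' @param ld an [ld_structure] aligned to `ss`.
#' @param schedule a [same_schedule()].
#' @param seed optional integer seed.
#' @param init `"em"` (default) initializes \eqn{(\pi, \sigma^2)} at the
#'   EM estimates of the marginal (LD-free) z-score mixture before
#'   refining under LD — the replicate count D anneals quickly, so
#'   starting the chain near the likelihood mode matters; a numeric
#'   `c(pi, sigma_sq)` overrides.
#' @return an [auc_prediction], or a list of them when `weights` is a
#'   list; each carries the sampler diagnostics (`D`, `converged`,
#'   parameter traces) and the posterior mean `delta`.
#' @export
predict_auc_ld <- function(ss, weights, ld, schedule = same_schedule(),
                           seed = NULL, init = "em") {
  stopifnot(inherits(ss, "sumstats"))
  single <- inherits(weights, "weightset") || is.numeric(weights)
  wlist <- if (single) list(weights) else weights
  M <- nrow(ss)
  omega <- vapply(wlist, function(w)
    if (inherits(w, "weightset")) w$omega else as.numeric(w), numeric(M))
  omega <- matrix(omega, nrow = M)
  s0 <- sqrt(ss$s0_sq); s1 <- sqrt(ss$s1_sq)
  denom <- sqrt(apply(omega, 2, function(w)
    tau_squared(w, s0, ld) + tau_squared(w, s1, ld)))
  if (identical(init, "em")) {
    fit0 <- em_fit(ss$z)
    init <- c(max(min(fit0$pi, 0.999), 1e-4), max(fit0$sigma_sq, 1e-4))
  }
  res <- same_gibbs(ss$z, ss$s, ld, omega, denom, schedule = schedule,
                    seed = seed, init_pi = init[1], init_sigma_sq = init[2])
  preds <- lapply(seq_along(wlist), function(k)
    auc_prediction(res$auc_draws[, k],
                   pi_hat = res$pi_hat, sigma_sq_hat = res$sigma_sq_hat,
                   extra = list(D = res$D, converged = res$converged,
                                pi_trace = res$pi_trace,
                                sigma_sq_trace = res$sigma_sq_trace,
                                delta_mean = res$delta_mean)))
  if (single) preds[[1]] else preds
}
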
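# The summary-statistics AUC formula AUC = Phi(Delta) with
# Delta = 2 * sum(omega * delta) / sqrt(tau0^2 + tau1^2), its quadratic-form
# components, and the empirical Mann-Whitney AUC used for validation.

#' PRS variance quadratic form
#'
#' Computes \eqn{\tau_j^2 = \sum_m \omega_m^2 s_{j,m}^2 + 2 \sum_{m_1<m_2}
#' \omega_{m_1}\omega_{m_2} R_{m_1 m_2} s_{j,m_1} s_{j,m_2}}, the variance
#' of the PRS in group j, block-wise (cross-block correlation is zero).
#'
#' @param omega numeric weight vector.
#' @param group_sd per-SNP genotype standard deviations \eqn{s_{j,m}} for
#'   the group (i.e. `sqrt(s0_sq)` or `sqrt(s1_sq)`).
#' @param ld an [ld_structure], or `NULL` for independent SNPs (identity
#'   correlation), in which case the form reduces to
#'   \eqn{\sum_m \omega_m^2 s_{j,m}^2}.
#' @return scalar \eqn{\tau_j^2 \ge 0}, strictly positive unless
#'   `omega` is all zero.
#' @export
tau_squared <- function(omega, group_sd, ld = NULL) {
  stopifnot(length(omega) == length(group_sd))
  if (any(!is.finite(omega)))
    stop("tau_squared: non-finite weight", call. = FALSE)
  w <- omega * group_sd
  if (is.null(ld)) return(sum(w^2))
  stopifnot(inherits(ld, "ld_structure"))
  total <- 0
  covered <- rep(FALSE, length(omega))
  for (b in ld$blocks) {
    wb <- w[b$idx]
    total <- total + drop(crossprod(wb, b$R %*% wb))
    covered[b$idx] <- TRUE
  }
  # SNPs outside every block are treated as independent
  total + sum(w[!covered]^2)
}

#' AUC from allele-frequency differences
#'
#' \eqn{AUC = \Phi(\Delta)} with \eqn{\Delta = 2\sum_m \omega_m \delta_m /
#' \sqrt{\tau_0^2 + \tau_1^2}}.
#'
#' @param delta per-SNP case-control allele-frequency differences.
#' @param omega PRS weights aligned to `delta`.
#' @param tau0_sq,tau1_sq PRS variances in controls and cases (see
#'   [tau_squared()]).
#' @return AUC in (0, 1).
#' @export
auc_from_delta <- function(delta, omega, tau0_sq, tau1_sq) {
  denom <- tau0_sq + tau1_sq
  if (!is.finite(denom) || denom <= 0)
    stop("auc_from_delta: tau0^2 + tau1^2 must be positive; ",
         "is the weight vector empty or all zero?", call. = FALSE)
  pnorm(2 * sum(omega * delta) / sqrt(denom))
}

#' Empirical AUC (Mann-Whitney estimator)
#'
#' The probability that a random case score exceeds a random control
#' score, with ties counted one half.
#'
#' @param scores_cases,scores_controls numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(scores_cases, scores_controls) {
  n1 <- as.numeric(length(scores_cases))
  n0 <- as.numeric(length(scores_controls))
  if (n1 == 0 || n0 == 0)
    stop("empirical_auc: both groups must be non-empty", call. = FALSE)
  r <- rank(c(scores_cases, scores_controls))  # midranks handle ties
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score individuals with a PRS weight set
#'
#' Per-sample dot product of allele dosages and weights. Missing
#' genotypes contribute the SNP's mean observed dosage.
#'
#' @param panel a [genotype_panel], harmonized with `weights`.
#' @param weights a [weightset] aligned to the panel rows (same SNPs,
#'   same order), or a bare numeric vector.
#' @return numeric vector of PRS values, one per sample.
#' @export
score_prs <- function(panel, weights) {
  stopifnot(inherits(panel, "genotype_panel"))
  omega <- if (inherits(weights, "weightset")) weights$omega else
    as.numeric(weights)
  G <- panel$genotypes
  stopifnot(length(omega) == nrow(G))
  if (anyNA(G)) {
    mm <- rowMeans(G, na.rm = TRUE)
    nas <- which(is.na(G), arr.ind = TRUE)
    G[nas] <- mm[nas[, 1]]
  }
  drop(crossprod(G, omega))
}

#' Unadjusted plug-in AUC from training summary statistics
#'
#' Plugs the observed allele-frequency differences
#' \eqn{\hat\delta_m = z_m s_m} directly into the AUC formula. Because
#' large observed effects are overestimated in the training data, this
#' estimate is systematically inflated (overfitting); it is the baseline
#' the empirical-Bayes predictors improve on.
#'
#' @param ss a [sumstats] object.
#' @param ws a [weightset] aligned to `ss` (same SNPs, same order).
#' @param ld optional [ld_structure] for the \eqn{\tau^2} terms;
#'   `NULL` = independent SNPs.
#' @return AUC in (0, 1).
#' @export
plugin_auc <- function(ss, ws, ld = NULL) {
  stopifnot(inherits(ss, "sumstats"))
  omega <- if (inherits(ws, "weightset")) ws$omega else as.numeric(ws)
  stopifnot(length(omega) == nrow(ss))
  if (all(omega == 0)) return(0.5)  # a constant score discriminates nothing
  t0 <- tau_squared(omega, sqrt(ss$s0_sq), ld)
  t1 <- tau_squared(omega, sqrt(ss$s1_sq), ld)
  auc_from_delta(ss$z * ss$s, omega, t0, t1)
}
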
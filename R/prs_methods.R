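# Minimal PRS weight generators - P+T, C+T and a spike-and-slab
# (LDpred-style) Gibbs method - so the tuning loop can run end to end.
# They follow the standard recipes but are deliberately small; exact
# parity with the published software is not attempted. Weights are on
# the allele-frequency-difference (delta) scale throughout: the AUC
# formula is scale-free in omega, so any affine rescaling is irrelevant.

two_sided_p <- function(z) 2 * pnorm(-abs(z))

# per-SNP block and within-block position for pairwise correlation lookup
ld_index <- function(ld, M) {
  block <- integer(M)
  local <- integer(M)
  for (k in seq_along(ld$blocks)) {
    idx <- ld$blocks[[k]]$idx
    block[idx] <- k
    local[idx] <- seq_along(idx)
  }
  list(block = block, local = local)
}

ld_r <- function(ld, map, i, j) {
  if (map$block[i] != map$block[j] || map$block[i] == 0L) return(0)
  ld$blocks[[map$block[i]]]$R[map$local[i], map$local[j]]
}

#' Greedy LD pruning
#'
#' Walks SNPs in position (index) order and keeps a SNP unless its
#' squared correlation with an already-kept SNP within `radius` exceeds
#' `r2_threshold`. Association-agnostic, as required for the
#' pre-selection step of P+T.
#'
#' @param ss a [sumstats] object.
#' @param ld an [ld_structure] aligned to `ss`; `NULL` treats all SNPs as
#'   independent (everything is kept).
#' @param r2_threshold squared-correlation cutoff (default 0.1).
#' @param radius window in SNP index distance (default: the LD
#'   structure's band radius, or 10).
#' @return integer vector of kept (pruned-in) SNP indices.
#' @export
prune_snps <- function(ss, ld = NULL, r2_threshold = 0.1, radius = NULL) {
  M <- nrow(ss)
  if (is.null(ld)) return(seq_len(M))
  if (is.null(radius)) radius <- if (!is.null(ld$band_radius))
    ld$band_radius else 10L
  map <- ld_index(ld, M)
  kept_flag <- logical(M)
  for (m in seq_len(M)) {
    lo <- max(1L, m - radius)
    near <- (lo:m)[kept_flag[lo:m]]
    ok <- TRUE
    for (j in near)
      if (ld_r(ld, map, m, j)^2 > r2_threshold) { ok <- FALSE; break }
    kept_flag[m] <- ok
  }
  which(kept_flag)
}

#' P+T (pruning + thresholding) weights
#'
#' On a pre-pruned, approximately independent SNP set, assigns
#' \eqn{\omega_m = \hat\delta_m = z_m s_m} to SNPs whose two-sided
#' p-value falls below `p_threshold`; all other SNPs get weight zero.
#'
#' @param ss a [sumstats] object (typically already restricted to the
#'   pruned SNP set).
#' @param p_threshold p-value cutoff in (0, 1].
#' @param pruned optional integer vector of pruned-in SNP indices; SNPs
#'   outside it always get weight zero.
#' @return a [weightset] aligned to `ss`.
#' @export
pt_weights <- function(ss, p_threshold, pruned = NULL) {
  stopifnot(inherits(ss, "sumstats"), p_threshold > 0, p_threshold <= 1)
  sel <- two_sided_p(ss$z) < p_threshold
  if (p_threshold >= 1) sel <- rep(TRUE, nrow(ss))  # threshold 1 keeps all
  if (!is.null(pruned)) sel <- sel & seq_len(nrow(ss)) %in% pruned
  omega <- ifelse(sel, ss$z * ss$s, 0)
  weightset(ss$snp_id, ss$ref_allele, omega, method_label = "pt",
            hyperparameter = list(p_threshold = p_threshold))
}

#' C+T (clumping + thresholding) weights
#'
#' Greedy LD clumping: SNPs passing the p-value threshold are visited in
#' order of ascending p-value; a SNP is kept unless its squared
#' correlation with an already-kept SNP within `clump_radius` exceeds
#' `r2_clump`. Kept SNPs get \eqn{\omega_m = z_m s_m}, the rest zero.
#'
#' @param ss a [sumstats] object (genome-wide pre-selected SNPs).
#' @param ld an [ld_structure] aligned to `ss`.
#' @param p_threshold p-value cutoff in (0, 1].
#' @param r2_clump squared-correlation cutoff (default 0.1).
#' @param clump_radius window in SNP index distance (default: band
#'   radius of `ld`, or 10).
#' @return a [weightset] aligned to `ss`.
#' @export
ct_weights <- function(ss, ld, p_threshold, r2_clump = 0.1,
                       clump_radius = NULL) {
  stopifnot(inherits(ss, "sumstats"), p_threshold > 0, p_threshold <= 1)
  M <- nrow(ss)
  if (is.null(clump_radius)) clump_radius <- if (!is.null(ld$band_radius))
    ld$band_radius else 10L
  p <- two_sided_p(ss$z)
  passing <- if (p_threshold >= 1) seq_len(M) else which(p < p_threshold)
  map <- ld_index(ld, M)
  kept_flag <- logical(M)
  for (m in passing[order(p[passing])]) {
    lo <- max(1L, m - clump_radius); hi <- min(M, m + clump_radius)
    near <- (lo:hi)[kept_flag[lo:hi]]
    ok <- TRUE
    for (j in near)
      if (ld_r(ld, map, m, j)^2 > r2_clump) { ok <- FALSE; break }
    kept_flag[m] <- ok
  }
  kept <- which(kept_flag)
  omega <- numeric(M)
  omega[kept] <- ss$z[kept] * ss$s[kept]
  weightset(ss$snp_id, ss$ref_allele, omega, method_label = "ct",
            hyperparameter = list(p_threshold = p_threshold))
}

#' Spike-and-slab (LDpred-style) posterior-mean weights
#'
#' Gibbs sampling of standardized effects under a point-normal prior
#' with a user-fixed risk-SNP proportion `pi`; the slab variance is set
#' from a heritability-style scale as \eqn{\sigma^2 = c\,n/(M \pi)}, so
#' smaller `pi` concentrates the same signal in fewer SNPs. Weights are
#' the posterior-mean allele-frequency differences \eqn{\bar\delta =
#' S R \bar b}, averaged over post-burn-in sweeps.
#'
#' @param ss a [sumstats] object (genome-wide pre-selected SNPs).
#' @param ld an [ld_structure] aligned to `ss`.
#' @param pi fixed prior proportion of risk SNPs in (0, 1].
#' @param h2_style_scale scale constant `c` above (default 0.5).
#' @param n_iter total Gibbs sweeps (default 100).
#' @param burn_in discarded initial sweeps (default `n_iter %/% 4`).
#' @param seed optional integer seed.
#' @param jitter,band_radius block regularization, as in [same_schedule()].
#' @return a [weightset] aligned to `ss`.
#' @export
ldpred_like_weights <- function(ss, ld, pi, h2_style_scale = 0.5,
                                n_iter = 100, burn_in = n_iter %/% 4,
                                seed = NULL, jitter = 1e-6,
                                band_radius = NULL) {
  stopifnot(inherits(ss, "sumstats"), pi > 0, pi <= 1)
  if (!is.null(seed)) set.seed(seed)
  M <- nrow(ss)
  n <- stats::median(ss$n0 + ss$n1)
  sigma_sq <- h2_style_scale * n / (M * pi)
  pi_eff <- min(pi, 1 - 1e-9)
  blocks <- regularize_blocks(ld, same_schedule(jitter = jitter,
                                                band_radius = band_radius))
  res <- .gibbs_fixed_cpp(as.numeric(ss$z), as.numeric(ss$s),
                          lapply(blocks, `[[`, "idx"),
                          lapply(blocks, `[[`, "R"),
                          pi_eff, sigma_sq, as.integer(n_iter),
                          as.integer(burn_in))
  weightset(ss$snp_id, ss$ref_allele, res$delta_mean,
            method_label = "ldpred_like",
            hyperparameter = list(pi = pi, h2_style_scale = h2_style_scale))
}
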
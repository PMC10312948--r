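# P+T, C+T and the spike-and-slab weight generators.

p_to_z <- function(p) qnorm(1 - p / 2)

test_that("pt_weights thresholds two-sided p-values", {
  p <- c(0.001, 0.04, 0.2, 0.6, 0.9)
  z <- p_to_z(p)
  ss <- sumstats(paste0("rs", 1:5), n0 = 1000, n1 = 1000, z = z,
                 f_pooled = rep(0.5, 5))
  w05 <- pt_weights(ss, 0.05)
  expect_equal(sum(w05$omega != 0), 2)
  expect_equal(which(w05$omega != 0), 1:2)
  expect_equal(w05$omega[1], ss$z[1] * ss$s[1])
  # threshold 1 keeps everything, including p = 1 SNPs
  expect_true(all(pt_weights(ss, 1)$omega != 0 | ss$z == 0))
  # threshold below the minimum p zeroes all weights -> AUC exactly 1/2
  w0 <- pt_weights(ss, 1e-6)
  expect_true(all(w0$omega == 0))
  pred <- predict_auc_independent(ss, w0, n_draws = 50, seed = 1)
  expect_true(all(pred$auc_draws == 0.5))
})

test_that("pt and ct are deterministic and agree when SNPs are independent", {
  set.seed(51)
  z <- rnorm(40, 0, 2)
  ss <- sumstats(paste0("v", 1:40), n0 = 500, n1 = 500, z = z,
                 f_pooled = runif(40, 0.1, 0.9))
  ld <- ld_identity(40)
  for (th in c(1, 0.5, 0.05)) {
    expect_equal(ct_weights(ss, ld, th)$omega, pt_weights(ss, th)$omega)
  }
  expect_identical(ct_weights(ss, ld, 0.05), ct_weights(ss, ld, 0.05))
})

test_that("clumping keeps the smaller-p SNP of a perfectly correlated pair", {
  z <- c(3, 4)  # SNP 2 has the smaller p-value
  ss <- sumstats(c("a", "b"), n0 = 500, n1 = 500, z = z,
                 f_pooled = c(0.5, 0.5))
  ld <- ld_structure(list(list(idx = 1:2,
                               R = matrix(c(1, 1, 1, 1), 2) - diag(0, 2))))
  w <- ct_weights(ss, ld, 1, r2_clump = 0.1)
  expect_equal(w$omega[1], 0)
  expect_gt(abs(w$omega[2]), 0)
})

test_that("greedy clumping on a 6-SNP AR(1) block matches a hand trace", {
  # R = 0.6^|i-j|: r^2 = 0.36 (lag 1), 0.13 (lag 2), 0.047 (lag 3)
  # p-value order: SNP4 < SNP1 < SNP6 < SNP2 < SNP3 < SNP5
  # walk: keep 4; 1 (lag 3 from 4, r2 0.047 < 0.1) kept; 6 (lag 2 from 4,
  # r2 0.13 > 0.1) dropped; 2 (lag 1 from 1, lag 2 from 4) dropped;
  # 3 (lag 2 from 1, lag 1 from 4) dropped; 5 (lag 1 from 4) dropped.
  z <- c(3.0, 1.0, 0.8, 4.0, 0.5, 2.0)
  ss <- sumstats(paste0("s", 1:6), n0 = 500, n1 = 500, z = z,
                 f_pooled = rep(0.4, 6))
  ld <- ar1_ld_truth(6, 0.6, block_size = 6)
  w <- ct_weights(ss, ld, 1, r2_clump = 0.1, clump_radius = 5)
  expect_equal(which(w$omega != 0), c(1L, 4L))
})

test_that("LD pruning is association-agnostic and respects the radius", {
  ld <- ar1_ld_truth(6, 0.6, block_size = 6)
  ss <- sumstats(paste0("s", 1:6), n0 = 500, n1 = 500,
                 z = c(0, 5, 0, 5, 0, 5), f_pooled = rep(0.4, 6))
  kept <- prune_snps(ss, ld, r2_threshold = 0.1, radius = 5)
  # greedy in position order: 1 kept; 2 (r2 .36) and 3 (.13) dropped;
  # 4 (.047) kept; 5, 6 dropped relative to 4
  expect_equal(kept, c(1L, 4L))
})

test_that("single-SNP spike-and-slab weights match the closed-form posterior mean", {
  z <- 2.2
  ss <- sumstats("rs1", n0 = 1000, n1 = 1000, z = z, f_pooled = 0.3)
  ld <- ld_identity(1)
  pi <- 0.3; scale <- 0.5
  sig2 <- scale * 2000 / (1 * pi)
  w <- ldpred_like_weights(ss, ld, pi, h2_style_scale = scale,
                           n_iter = 40000, burn_in = 2000, seed = 12)
  closed <- closed_form_delta_mean(z, ss$s, pi, sig2)
  expect_equal(w$omega, closed, tolerance = 0.05)
})

test_that("pi = 1 gives ridge-style shrinkage, monotone in the slab scale", {
  set.seed(61)
  z <- rnorm(30, 0, 2)
  ss <- sumstats(paste0("v", 1:30), n0 = 1000, n1 = 1000, z = z,
                 f_pooled = runif(30, 0.2, 0.8))
  ld <- ld_identity(30)
  w_small <- ldpred_like_weights(ss, ld, 1, h2_style_scale = 0.005,
                                 n_iter = 3000, seed = 1)
  w_large <- ldpred_like_weights(ss, ld, 1, h2_style_scale = 5,
                                 n_iter = 3000, seed = 1)
  # shrunk toward zero, more strongly for the smaller scale
  expect_true(all(abs(w_small$omega) <= abs(ss$z * ss$s)))
  expect_gt(mean(abs(w_large$omega)), mean(abs(w_small$omega)))
  expect_gt(cor(w_large$omega, ss$z * ss$s), 0.95)
})

test_that("null z-scores produce near-zero spike-and-slab weights", {
  set.seed(71)
  M <- 100
  ss <- sumstats(paste0("v", 1:M), n0 = 1000, n1 = 1000,
                 z = rnorm(M, 0, 0.3), f_pooled = runif(M, 0.2, 0.8))
  w <- ldpred_like_weights(ss, ld_identity(M), 0.01, n_iter = 1000, seed = 2)
  expect_lt(max(abs(w$omega)), max(abs(ss$z * ss$s)) * 0.5)
})

test_that("weight generators are reproducible under a fixed seed", {
  set.seed(81)
  M <- 50
  ss <- sumstats(paste0("v", 1:M), n0 = 500, n1 = 500, z = rnorm(M),
                 f_pooled = runif(M, 0.2, 0.8))
  ld <- ar1_ld_truth(M, 0.2, block_size = 25)
  w1 <- ldpred_like_weights(ss, ld, 0.1, n_iter = 200, seed = 99)
  w2 <- ldpred_like_weights(ss, ld, 0.1, n_iter = 200, seed = 99)
  expect_identical(w1$omega, w2$omega)
})
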
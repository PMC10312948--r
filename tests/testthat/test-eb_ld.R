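# SAME Gibbs sampler under LD: closed-form and enumeration oracles,
# reductions to the independent path, numerical robustness.

test_that("single-SNP conditional sampler matches the closed-form posterior", {
  z <- 2.5; s <- 0.02; pi <- 0.1; sig2 <- 4
  set.seed(4)
  res <- prsauc:::.gibbs_fixed_cpp(z, s, list(1L), list(matrix(1, 1, 1)),
                                   pi, sig2, 20000L, 1000L)
  closed <- closed_form_delta_mean(z, s, pi, sig2)
  # draws are iid here (the collapsed update does not depend on b_m)
  se <- closed * 0.05 + 3e-4
  expect_equal(res$delta_mean, closed, tolerance = 3 * se / closed)
  expect_equal(res$gamma_mean, closed_form_h(z, pi, sig2), tolerance = 0.02)
})

test_that("two correlated SNPs: gamma posterior matches brute-force enumeration", {
  z <- c(1.8, 0.6); R <- matrix(c(1, 0.2, 0.2, 1), 2)
  pi <- 0.2; sig2 <- 4
  exact <- enum_gamma_posterior(z, R, pi, sig2)
  set.seed(6)
  res <- prsauc:::.gibbs_fixed_cpp(z, c(0.01, 0.01), list(1:2), list(R),
                                   pi, sig2, 60000L, 2000L)
  freq <- res$config_counts / res$n_kept
  n <- res$n_kept
  se <- sqrt(exact * (1 - exact) / n)
  # 3 SE plus a small allowance for sweep-to-sweep autocorrelation
  expect_true(all(abs(freq - exact) <= 3 * se + 0.01))
})

test_that("three-SNP long-run configuration frequencies match the 8-state posterior", {
  rho <- 0.3
  R <- rho^abs(outer(1:3, 1:3, "-"))
  z <- c(2.2, -0.5, 1.0); pi <- 0.15; sig2 <- 6
  exact <- enum_gamma_posterior(z, R, pi, sig2)
  set.seed(8)
  res <- prsauc:::.gibbs_fixed_cpp(z, rep(0.01, 3), list(1:3), list(R),
                                   pi, sig2, 80000L, 2000L)
  freq <- res$config_counts / res$n_kept
  se <- sqrt(exact * (1 - exact) / res$n_kept)
  expect_true(all(abs(freq - exact) <= 3 * se + 0.01))
})

test_that("SAME with singleton blocks agrees with the EM path", {
  set.seed(13)
  cfg <- sim_config(M = 1500, n = 6000, ld_mode = "independent")
  sim <- simulate_replicate(cfg)
  ss <- sim$sumstats
  w <- pt_weights(ss, 0.05)
  pred_em <- predict_auc_independent(ss, w, n_draws = 1000, seed = 3)
  ld <- ld_identity(nrow(ss))
  pred_same <- predict_auc_ld(ss, w, ld,
                              schedule = same_schedule(n_auc_draws = 1000),
                              seed = 3)
  expect_lt(abs(pred_same$auc_mean - pred_em$auc_mean), 0.02)
  expect_lt(abs(pred_same$pi_hat - pred_em$pi_hat), 0.03)
})

test_that("null z-scores give a predicted AUC of one half", {
  M <- 200
  ss <- make_tiny_ss(f0 = rep(0.4, M), f1 = rep(0.4, M))
  ld <- ar1_ld_truth(M, 0.2, block_size = 50)
  pred <- predict_auc_ld(ss, rep(1, M), ld,
                         schedule = same_schedule(d_max = 30,
                                                  n_auc_draws = 300),
                         seed = 10)
  expect_lt(abs(pred$auc_mean - 0.5), 0.01)
  expect_lt(pred$sigma_sq_hat * pred$pi_hat, 0.05)
})

test_that("the sampled (pi, sigma^2) trajectory concentrates as D grows", {
  set.seed(23)
  z <- simulate_z(2000, 0.05, 8)
  ld <- ld_identity(2000)
  res <- same_gibbs(z, rep(0.01, 2000), ld, matrix(0, 2000, 1), 0,
                    schedule = same_schedule(d_max = 60, tol = 1e-12,
                                             n_auc_draws = 1))
  tr <- res$pi_trace
  k <- length(tr)
  expect_gt(var(tr[1:15]), var(tr[(k - 14):k]))
})

test_that("block visiting order does not change the stationary AUC distribution", {
  set.seed(31)
  cfg <- sim_config(M = 400, n = 6000, ld_mode = "ar1", block_size = 50)
  sim <- simulate_replicate(cfg)
  ss <- sim$sumstats
  w <- ct_weights(ss, sim$ld_truth, 0.05, clump_radius = 5)
  sch <- same_schedule(d_max = 40, n_auc_draws = 400, band_radius = 5)
  p1 <- predict_auc_ld(ss, w, sim$ld_truth, schedule = sch, seed = 1)
  ld_perm <- sim$ld_truth
  ld_perm$blocks <- rev(ld_perm$blocks)
  p2 <- predict_auc_ld(ss, w, ld_perm, schedule = sch, seed = 2)
  ks <- suppressWarnings(stats::ks.test(p1$auc_draws, p2$auc_draws))
  expect_gt(ks$p.value, 0.01)
})

test_that("log-domain arithmetic survives extreme z-scores", {
  z <- c(50, -50, 0)
  ss <- make_tiny_ss(f0 = c(0.5, 0.5, 0.5), f1 = c(0.5, 0.5, 0.5))
  ld <- ld_identity(3)
  res <- same_gibbs(z, ss$s, ld, matrix(1, 3, 1), 1,
                    schedule = same_schedule(d_max = 20, n_auc_draws = 50),
                    seed = 2)
  expect_true(all(is.finite(res$pi_trace)))
  expect_true(all(is.finite(res$auc_draws)))
})

test_that("a non-PSD block is reported by name after jitter fails", {
  R <- matrix(c(1, 2, 2, 1), 2)  # correlation-like but indefinite
  expect_error(ld_structure(list(list(idx = 1:2, R = R))), NA)
  ld <- ld_structure(list(list(idx = 1:2, R = R)))
  expect_error(same_gibbs(c(0, 0), c(0.01, 0.01), ld, matrix(1, 2, 1), 1,
                          schedule = same_schedule(d_max = 5,
                                                   n_auc_draws = 10)),
               "block 1")
})

test_that("collected delta equals S R b computed densely", {
  set.seed(41)
  M <- 60
  ld <- ar1_ld_truth(M, 0.4, block_size = 30)
  s <- runif(M, 0.01, 0.02)
  z <- simulate_z(M, 0.3, 6)
  res <- prsauc:::.gibbs_fixed_cpp(z, s, lapply(ld$blocks, `[[`, "idx"),
                                   lapply(ld$blocks, `[[`, "R"),
                                   0.3, 6, 500L, 100L)
  R <- ld_as_matrix(ld, M)
  # collection is linear, so mean delta must equal S R (mean b) exactly
  expect_equal(res$delta_mean, drop(diag(s) %*% R %*% res$b_mean),
               tolerance = 1e-10)
  # spike states carry exactly zero effects
  same <- same_gibbs(z, s, ld, matrix(1, M, 1), 1,
                     schedule = same_schedule(d_max = 10, n_auc_draws = 20))
  expect_true(all(same$beta_final[same$gamma_final == 0] == 0))
})
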
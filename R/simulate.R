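# Synthetic GWAS generator for the two study designs used to validate
# the AUC predictors - independent SNPs and AR(1)-correlated SNPs - plus
# the rho_AUC / rd_AUC evaluation metrics and the replicated experiment
# driver.

#' Simulation configuration
#'
#' Defaults reproduce the two generative settings used throughout the
#' package's validation: independent SNPs with \eqn{\pi = 0.05},
#' \eqn{\sigma^2 = 0.001 n}, disease prevalence 1%, balanced training
#' GWAS, population allele frequencies U(0.05, 0.95); and AR(1)-linked
#' SNPs with adjacent genotype correlation \eqn{\rho = 0.2} and
#' \eqn{\sigma^2 = 0.0005 n}. Standardized risk effects scale with the
#' GWAS size because \eqn{s_m \propto 1/\sqrt{n}}.
#'
#' @param M number of SNPs.
#' @param n total training GWAS size (balanced: `n/2` cases, `n/2`
#'   controls).
#' @param pi_true proportion of risk SNPs.
#' @param sigma_sq_scale slab variance per unit `n`
#'   (\eqn{\sigma^2 = } `sigma_sq_scale * n`); default 0.001 for
#'   independent mode, 0.0005 for AR(1) mode.
#' @param prevalence disease prevalence \eqn{\kappa}.
#' @param ld_mode `"independent"` or `"ar1"`.
#' @param rho AR(1) adjacent-SNP genotype correlation.
#' @param n_test_cases,n_test_controls testing-cohort sizes.
#' @param n_ref reference-panel size for LD estimation (AR(1) mode).
#' @param block_size SNPs per simulator-defined LD block (AR(1) mode).
#' @param maf_range support of the population allele-frequency draw.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(M = 10000, n = 10000, pi_true = 0.05,
                       sigma_sq_scale = NULL, prevalence = 0.01,
                       ld_mode = c("independent", "ar1"), rho = 0.2,
                       n_test_cases = 1000, n_test_controls = 1000,
                       n_ref = 1000, block_size = 100,
                       maf_range = c(0.05, 0.95)) {
  ld_mode <- match.arg(ld_mode)
  if (is.null(sigma_sq_scale))
    sigma_sq_scale <- if (ld_mode == "independent") 0.001 else 0.0005
  stopifnot(M >= 2, n >= 4, n %% 2 == 0, pi_true >= 0, pi_true <= 1,
            prevalence > 0, prevalence < 1, abs(rho) < 1)
  structure(list(M = as.integer(M), n = as.integer(n), pi_true = pi_true,
                 sigma_sq_scale = sigma_sq_scale, prevalence = prevalence,
                 ld_mode = ld_mode, rho = rho,
                 n_test_cases = as.integer(n_test_cases),
                 n_test_controls = as.integer(n_test_controls),
                 n_ref = as.integer(n_ref), block_size = as.integer(block_size),
                 maf_range = maf_range),
            class = "sim_config")
}

# exact AR(1) matrix-vector product (R b)_m = sum_k rho^|m-k| b_k in O(M)
ar1_matvec <- function(b, rho) {
  M <- length(b)
  fwd <- numeric(M); bwd <- numeric(M)
  fwd[1] <- b[1]
  for (m in 2:M) fwd[m] <- b[m] + rho * fwd[m - 1]
  bwd[M] <- b[M]
  for (m in (M - 1):1) bwd[m] <- b[m] + rho * bwd[m + 1]
  fwd + bwd - b
}

# draw e ~ N(0, R) for AR(1) R via the stationary chain
ar1_noise <- function(M, rho) {
  e <- numeric(M)
  e[1] <- rnorm(1)
  innov <- rnorm(M - 1) * sqrt(1 - rho^2)
  for (m in 2:M) e[m] <- rho * e[m - 1] + innov[m - 1]
  e
}

#' True AR(1) LD structure over simulator-defined blocks
#'
#' @param M number of SNPs.
#' @param rho adjacent correlation.
#' @param block_size SNPs per block.
#' @return an [ld_structure] with `source = "simulated-truth"`.
#' @export
ar1_ld_truth <- function(M, rho, block_size = 100) {
  starts <- seq(1L, M, by = block_size)
  blocks <- lapply(starts, function(st) {
    idx <- st:min(st + block_size - 1L, M)
    p <- length(idx)
    list(idx = idx, R = rho^abs(outer(seq_len(p), seq_len(p), "-")))
  })
  ld_structure(blocks, source = "simulated-truth")
}

#' Simulator block partition (BED-convention intervals)
#'
#' SNP m sits at 1-based position m on chromosome "1"; blocks of
#' `block_size` consecutive SNPs become half-open 0-based intervals.
#'
#' @inheritParams ar1_ld_truth
#' @return a [block_partition].
#' @export
sim_block_partition <- function(M, block_size = 100) {
  starts <- seq(0L, M - 1L, by = block_size)
  block_partition("1", starts, pmin(starts + block_size, M))
}

#' Generate one simulation replicate
#'
#' Draws population allele frequencies \eqn{f_0 \sim U(0.05, 0.95)},
#' standardized risk effects \eqn{b_m = \beta_m/s_m} from the
#' point-normal prior, forms \eqn{\delta = \beta} (independent mode) or
#' \eqn{\delta = S R S^{-1} \beta} (AR(1) mode), clips the case
#' frequencies \eqn{f_1 = f_0 + \delta} into (0.01, 0.99), draws training
#' z-scores directly from the summary-statistics model \eqn{z \sim
#' N(S^{-1}\delta, R)}, and generates individual-level testing and
#' reference genotypes (binomial dosages, or paired first-order
#' correlated-Bernoulli haplotype chains with exact adjacent correlation
#' `rho`). The reference panel is drawn at the population frequency
#' \eqn{(1-\kappa) f_0 + \kappa f_1}.
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return list of class `"sim_replicate"`: `truth` (f0, f1, delta, b,
#'   gamma, clipped counts), `sumstats`, `test` ([genotype_panel]),
#'   `test_pheno` (1 = case), `ref` (panel, AR(1) mode), `ld_truth`,
#'   `partition`, `cfg`.
#' @export
simulate_replicate <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  M <- cfg$M
  n0 <- n1 <- cfg$n / 2
  snp_id <- sprintf("snp%06d", seq_len(M))

  f0 <- runif(M, cfg$maf_range[1], cfg$maf_range[2])
  sigma_sq <- cfg$sigma_sq_scale * cfg$n
  gamma <- rbinom(M, 1L, cfg$pi_true)
  b <- gamma * rnorm(M, 0, sqrt(sigma_sq))

  s_prov <- sqrt(2 * f0 * (1 - f0) * (1 / (4 * n1) + 1 / (4 * n0)))
  delta <- if (cfg$ld_mode == "independent") b * s_prov
    else s_prov * ar1_matvec(b, cfg$rho)

  f1 <- pmin(pmax(f0 + delta, 0.01), 0.99)
  n_clip_f1 <- sum(f1 != f0 + delta)
  if (n_clip_f1 > 0.01 * M)
    stop("simulate_replicate: clipping affected more than 1% of SNPs; ",
         "the effect-size scale is too large for these frequencies",
         call. = FALSE)
  delta <- f1 - f0
  # one recomputation of s from the realized frequencies (second-order)
  s0_sq <- 2 * f0 * (1 - f0)
  s1_sq <- 2 * f1 * (1 - f1)
  s <- sqrt(s1_sq / (4 * n1) + s0_sq / (4 * n0))

  noise <- if (cfg$ld_mode == "independent") rnorm(M)
    else ar1_noise(M, cfg$rho)
  z <- delta / s + noise

  # observed case frequency implied by the drawn z-score
  f1_obs <- pmin(pmax(f0 + z * s, 0.005), 0.995)
  n_clip_obs <- sum(f1_obs != f0 + z * s)
  ss <- sumstats(snp_id, n0 = n0, n1 = n1, f0_hat = f0, f1_hat = f1_obs,
                 chrom = "1", pos = seq_len(M),
                 ref_allele = "A", alt_allele = "G")

  draw_panel <- function(freq, n_ind, prefix) {
    if (cfg$ld_mode == "independent") {
      geno <- matrix(rbinom(M * n_ind, 2L, rep(freq, n_ind)), nrow = M)
      clip <- 0
    } else {
      res <- .ar1_genotypes_cpp(freq, cfg$rho, as.integer(n_ind))
      geno <- res$genotypes
      clip <- res$n_clipped
    }
    snps <- data.frame(snp_id = snp_id, chrom = "1", pos = seq_len(M),
                       ref_allele = "A", alt_allele = "G",
                       stringsAsFactors = FALSE)
    panel <- genotype_panel(geno, snps,
                            paste0(prefix, seq_len(n_ind)))
    attr(panel, "n_clipped") <- clip
    panel
  }
  cases <- draw_panel(f1, cfg$n_test_cases, "case")
  controls <- draw_panel(f0, cfg$n_test_controls, "ctrl")
  test <- genotype_panel(cbind(cases$genotypes, controls$genotypes),
                         cases$snps, c(cases$samples, controls$samples))
  test_pheno <- rep(c(1L, 0L), c(cfg$n_test_cases, cfg$n_test_controls))

  ref <- NULL
  ld_truth <- NULL
  partition <- NULL
  if (cfg$ld_mode == "ar1") {
    f_pop <- (1 - cfg$prevalence) * f0 + cfg$prevalence * f1
    ref <- draw_panel(f_pop, cfg$n_ref, "ref")
    ld_truth <- ar1_ld_truth(M, cfg$rho, cfg$block_size)
    partition <- sim_block_partition(M, cfg$block_size)
  }

  structure(list(truth = list(f0 = f0, f1 = f1, delta = delta, b = b,
                              gamma = gamma, sigma_sq = sigma_sq,
                              n_clip_f1 = n_clip_f1, n_clip_obs = n_clip_obs),
                 sumstats = ss, test = test, test_pheno = test_pheno,
                 ref = ref, ld_truth = ld_truth, partition = partition,
                 cfg = cfg),
            class = "sim_replicate")
}

#' Hyperparameter-tuning evaluation metrics
#'
#' `rho_auc` is the Pearson correlation between predicted and testing
#' AUC across the hyperparameter grid; `rd_auc` is the relative
#' shortfall of the testing AUC at the predicted-best hyperparameter
#' versus the best testing AUC,
#' \eqn{|AUC_{test}(\arg\max pred) - \max AUC_{test}| / \max AUC_{test}}.
#'
#' @param pred_auc,test_auc equal-length numeric vectors over the same
#'   hyperparameter grid.
#' @return list with `rho_auc` (NaN with a warning if either vector is
#'   constant) and `rd_auc` (nonnegative fraction).
#' @export
evaluate_metrics <- function(pred_auc, test_auc) {
  stopifnot(length(pred_auc) == length(test_auc), length(pred_auc) >= 1)
  rho <- if (sd(pred_auc) == 0 || sd(test_auc) == 0) {
    warning("evaluate_metrics: constant AUC vector; correlation undefined",
            call. = FALSE)
    NaN
  } else cor(pred_auc, test_auc)
  best_test <- max(test_auc)
  rd <- abs(test_auc[which.max(pred_auc)] - best_test) / best_test
  list(rho_auc = rho, rd_auc = rd)
}

#' Default hyperparameter grids
#'
#' P+T / C+T p-value thresholds and the LDpred-style risk-SNP proportion
#' grid used throughout the validation experiments.
#' @name default_grids
#' @export
pt_threshold_grid <- function() c(1, 5e-1, 5e-2, 5e-3, 5e-4, 5e-5, 5e-6)

#' @rdname default_grids
#' @export
ldpred_pi_grid <- function() c(1, 3e-1, 1e-1, 3e-2, 1e-2, 3e-3, 1e-3,
                               3e-4, 1e-4, 3e-5, 1e-5)

#' Run a replicated tuning experiment
#'
#' For each training sample size and replicate: simulate a replicate,
#' build PRS weights over each method's hyperparameter grid, predict the
#' AUC from the training summary statistics alone (EM path for
#' independent mode, SAME path for AR(1) mode using Ledoit-Wolf LD from
#' the simulated reference panel), compute the unadjusted plug-in AUC
#' and the testing-cohort Mann-Whitney AUC, and score the per-replicate
#' tuning metrics.
#'
#' @param cfg a [sim_config()] template; its `n` is overridden by
#'   `n_grid`.
#' @param n_grid training sample sizes to sweep.
#' @param n_reps replicates per sample size.
#' @param methods subset of `"pt"`, `"ct"`, `"ldpred"` (must match
#'   `cfg$ld_mode`: `"pt"` for independent, the others for AR(1)).
#' @param pt_thresholds,ldpred_pis hyperparameter grids.
#' @param schedule SAME sampler schedule (AR(1) mode).
#' @param ld_band_radius LD radius used for LD estimation and the
#'   samplers in AR(1) mode (default 5).
#' @param seed integer seed; the whole experiment is a single
#'   deterministic RNG stream.
#' @param verbose print per-replicate progress.
#' @return list with `results` (one row per n / replicate / method /
#'   hyperparameter: predicted, testing and unadjusted AUC) and
#'   `metrics` (per n and method: average `rho_auc` and `rd_auc` across
#'   replicates).
#' @export
run_experiment <- function(cfg, n_grid = cfg$n, n_reps = 2,
                           methods = if (cfg$ld_mode == "independent") "pt"
                             else c("ct", "ldpred"),
                           pt_thresholds = pt_threshold_grid(),
                           ldpred_pis = ldpred_pi_grid(),
                           schedule = same_schedule(),
                           ld_band_radius = 5, seed = 1, verbose = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$ld_mode == "independent" && !identical(methods, "pt"))
    stop("run_experiment: independent mode supports only the pt method",
         call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (n in n_grid) {
    cfg_n <- cfg
    cfg_n$n <- as.integer(n)
    for (rep in seq_len(n_reps)) {
      if (verbose) message("n = ", n, ", replicate ", rep)
      sim <- simulate_replicate(cfg_n)
      ss <- sim$sumstats

      if (cfg$ld_mode == "independent") {
        wlist <- lapply(pt_thresholds, function(th) pt_weights(ss, th))
        hyper <- pt_thresholds
        mlab <- rep("pt", length(wlist))
        fit <- em_fit(ss$z)
        preds <- predict_auc_independent(ss, wlist, fit = fit)
        ld_hat <- NULL
      } else {
        ld_hat <- estimate_ld(sim$ref, sim$partition,
                              band_radius = ld_band_radius)
        wlist <- list(); hyper <- numeric(0); mlab <- character(0)
        if ("ct" %in% methods) {
          wlist <- c(wlist, lapply(pt_thresholds, function(th)
            ct_weights(ss, ld_hat, th, clump_radius = ld_band_radius)))
          hyper <- c(hyper, pt_thresholds)
          mlab <- c(mlab, rep("ct", length(pt_thresholds)))
        }
        if ("ldpred" %in% methods) {
          wlist <- c(wlist, lapply(ldpred_pis, function(p)
            ldpred_like_weights(ss, ld_hat, p,
                                band_radius = ld_band_radius)))
          hyper <- c(hyper, ldpred_pis)
          mlab <- c(mlab, rep("ldpred", length(ldpred_pis)))
        }
        sch <- schedule
        sch$band_radius <- ld_band_radius
        preds <- predict_auc_ld(ss, wlist, ld_hat, schedule = sch)
      }

      # score all weight sets in one pass over the testing genotypes
      omega_mat <- vapply(wlist, `[[`, numeric(nrow(sim$sumstats)), "omega")
      scores <- crossprod(`storage.mode<-`(sim$test$genotypes, "double"),
                          omega_mat)
      for (k in seq_along(wlist)) {
        sc <- scores[, k]
        test_auc <- empirical_auc(sc[sim$test_pheno == 1L],
                                  sc[sim$test_pheno == 0L])
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, rep = rep, method = mlab[k], hyperparameter = hyper[k],
          pred_auc = preds[[k]]$auc_mean,
          pred_lo = preds[[k]]$ci[1], pred_hi = preds[[k]]$ci[2],
          test_auc = test_auc,
          unadjusted_auc = plugin_auc(ss, wlist[[k]], ld_hat),
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)

  metr <- list()
  for (n in unique(results$n)) for (ml in unique(results$method)) {
    sub <- results[results$n == n & results$method == ml, , drop = FALSE]
    per_rep <- lapply(split(sub, sub$rep), function(d)
      evaluate_metrics(d$pred_auc, d$test_auc))
    metr[[length(metr) + 1L]] <- data.frame(
      n = n, method = ml,
      rho_auc = mean(vapply(per_rep, `[[`, numeric(1), "rho_auc"),
                     na.rm = TRUE),
      rd_auc = mean(vapply(per_rep, `[[`, numeric(1), "rd_auc")),
      n_reps = length(per_rep), stringsAsFactors = FALSE)
  }
  list(results = results, metrics = do.call(rbind, metr))
}
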
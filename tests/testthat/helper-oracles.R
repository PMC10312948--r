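# Shared fixtures and independent oracles used across test files.

# tiny summary-statistics table with explicit frequencies
make_tiny_ss <- function(f0, f1, n0 = 1000, n1 = 1000,
                         ref = "A", alt = "G") {
  M <- length(f0)
  sumstats(snp_id = paste0("rs", seq_len(M)), n0 = n0, n1 = n1,
           f0_hat = f0, f1_hat = f1, chrom = "1", pos = seq_len(M),
           ref_allele = ref, alt_allele = alt)
}

# simulated z-scores from the two-component marginal (independent SNPs)
simulate_z <- function(M, pi, sigma_sq) {
  risk <- rbinom(M, 1, pi)
  rnorm(M, 0, 1) + risk * rnorm(M, 0, sqrt(sigma_sq))
}

# brute-force posterior over gamma configurations for <= 3 SNPs:
# z | b ~ N(R b, R), b_A ~ N(0, sigma^2 I) on the active set, so
# z | gamma ~ N(0, R diag(sigma^2 gamma) R + R)
enum_gamma_posterior <- function(z, R, pi, sigma_sq) {
  M <- length(z)
  configs <- as.matrix(expand.grid(rep(list(0:1), M)))
  logp <- apply(configs, 1, function(g) {
    V <- R %*% diag(sigma_sq * g, M) %*% R + R
    ldet <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
    quad <- drop(crossprod(z, solve(V, z)))
    -0.5 * (ldet + quad) + sum(g) * log(pi) + (M - sum(g)) * log(1 - pi)
  })
  p <- exp(logp - max(logp))
  p / sum(p)
}

# closed-form posterior quantities for a single independent SNP
closed_form_h <- function(z, pi, sigma_sq) {
  v <- 1 + sigma_sq
  num <- pi * dnorm(z / sqrt(v)) / sqrt(v)
  num / ((1 - pi) * dnorm(z) + num)
}
closed_form_delta_mean <- function(z, s, pi, sigma_sq) {
  lam <- 1 / (1 + 1 / sigma_sq)
  closed_form_h(z, pi, sigma_sq) * lam * z * s
}
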
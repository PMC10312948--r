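# Block-partitioned LD structure and its estimation from a reference
# genotype panel via the Ledoit-Wolf shrinkage estimator.

#' Construct an LD structure
#'
#' Holds per-block SNP correlation matrices over a single SNP ordering.
#' Cross-block correlation is treated as zero ("approximately independent"
#' blocks). Each block matrix must be a symmetric correlation matrix.
#'
#' @param blocks list; each element a list with `idx` (integer SNP indices
#'   into the global ordering) and `R` (correlation matrix, `length(idx)`
#'   square).
#' @param snp_id optional character vector naming the global SNP ordering.
#' @param band_radius optional integer; entries with index distance
#'   greater than the radius are zeroed ("LD radius").
#' @param source free-text provenance label (reference panel id or
#'   `"simulated-truth"`).
#' @return list of class `"ld_structure"`.
#' @export
ld_structure <- function(blocks, snp_id = NULL, band_radius = NULL,
                         source = "") {
  idx_all <- integer(0)
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    stopifnot(is.list(b), !is.null(b$idx), !is.null(b$R))
    b$idx <- as.integer(b$idx)
    b$R <- as.matrix(b$R)
    if (nrow(b$R) != length(b$idx) || ncol(b$R) != length(b$idx))
      stop("ld_structure: block ", k, " has mismatched idx/R dimensions",
           call. = FALSE)
    if (max(abs(b$R - t(b$R))) > 1e-8)
      stop("ld_structure: block ", k, " matrix is not symmetric", call. = FALSE)
    if (max(abs(diag(b$R) - 1)) > 1e-8)
      stop("ld_structure: block ", k, " matrix must have unit diagonal",
           call. = FALSE)
    if (!is.null(band_radius))
      b$R[abs(row(b$R) - col(b$R)) > band_radius] <- 0
    blocks[[k]] <- b
    idx_all <- c(idx_all, b$idx)
  }
  if (anyDuplicated(idx_all))
    stop("ld_structure: a SNP appears in more than one block", call. = FALSE)
  structure(list(blocks = blocks, snp_id = snp_id,
                 band_radius = band_radius, source = source),
            class = "ld_structure")
}

#' @export
print.ld_structure <- function(x, ...) {
  sizes <- vapply(x$blocks, function(b) length(b$idx), integer(1))
  cat("ld_structure:", length(sizes), "block(s),", sum(sizes), "SNPs",
      "(block sizes", min(sizes), "-", max(sizes), ")")
  if (!is.null(x$band_radius)) cat("; band radius", x$band_radius)
  if (nzchar(x$source)) cat("; source:", x$source)
  cat("\n")
  invisible(x)
}

#' Identity (independent-SNP) LD structure
#'
#' @param M number of SNPs.
#' @param snp_id optional SNP names.
#' @return an [ld_structure] with M singleton blocks.
#' @export
ld_identity <- function(M, snp_id = NULL) {
  blocks <- lapply(seq_len(M), function(m)
    list(idx = m, R = matrix(1, 1, 1)))
  ld_structure(blocks, snp_id = snp_id, source = "identity")
}

number_of_snps <- function(ld) sum(vapply(ld$blocks, function(b)
  length(b$idx), integer(1)))

#' Ledoit-Wolf shrinkage correlation estimate
#'
#' Closed-form plug-in shrinkage of the sample covariance of the columns
#' of `X` toward the scaled identity, renormalized to unit diagonal. With
#' the columns standardized, this is the shrinkage LD estimate used for
#' reference panels.
#'
#' @param X numeric matrix, samples x SNPs (columns are variables).
#' @param standardize center and scale columns first (default `TRUE`).
#' @return list with `R` (correlation matrix) and `alpha` (shrinkage
#'   intensity in `[0, 1]`).
#' @export
ledoit_wolf_corr <- function(X, standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("ledoit_wolf_corr: need at least 2 samples", call. = FALSE)
  if (standardize) {
    X <- scale(X)
    if (any(!is.finite(X)))
      stop("ledoit_wolf_corr: zero-variance column", call. = FALSE)
    X <- X * sqrt(n / (n - 1))  # population-style unit variance
  }
  S <- crossprod(X) / n
  mu <- mean(diag(S))
  d2 <- sum((S - diag(mu, p))^2) / p
  if (d2 < .Machine$double.eps) {
    return(list(R = diag(p), alpha = 1))
  }
  X2 <- X^2
  b2bar <- (sum(crossprod(X2)) - n * sum(S^2)) / (n^2 * p)
  b2 <- min(b2bar, d2)
  alpha <- b2 / d2
  Sig <- (1 - alpha) * S + alpha * diag(mu, p)
  dd <- sqrt(diag(Sig))
  R <- Sig / tcrossprod(dd)
  diag(R) <- 1
  list(R = R, alpha = alpha)
}

#' Estimate block-wise LD from a reference panel
#'
#' Per block: mean-impute missing dosages, standardize each SNP to mean 0
#' and variance 1, then estimate the correlation matrix with the
#' Ledoit-Wolf shrinkage estimator (`method = "ledoit_wolf"`) or the
#' plain sample correlation (`method = "sample"`). Zero-variance SNPs
#' cannot be correlated with anything; they are retained as isolated
#' rows/columns (identity) with a warning so SNP alignment is preserved.
#'
#' @param panel a [genotype_panel].
#' @param partition a [block_partition], or `NULL` to treat the whole
#'   panel as one block, or a precomputed integer vector of per-SNP block
#'   labels.
#' @param method `"ledoit_wolf"` (default) or `"sample"`.
#' @param band_radius optional LD radius; correlations beyond the radius
#'   (in SNP index distance) are set to zero.
#' @return an [ld_structure]; each block carries its shrinkage intensity
#'   as attribute `"alpha"`.
#' @export
estimate_ld <- function(panel, partition = NULL, method = c("ledoit_wolf",
                                                            "sample"),
                        band_radius = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  method <- match.arg(method)
  M <- nrow(panel$genotypes)
  labels <- if (is.null(partition)) rep(1L, M)
    else if (inherits(partition, "block_partition"))
      assign_blocks(panel$snps, partition)
    else as.integer(partition)

  blocks <- list()
  for (lab in sort(unique(labels))) {
    idx <- which(labels == lab)
    G <- t(panel$genotypes[idx, , drop = FALSE])  # samples x SNPs
    if (nrow(G) < 2)
      stop("estimate_ld: block ", lab, " has fewer than 2 samples",
           call. = FALSE)
    # mean-impute missing dosages per SNP
    if (anyNA(G)) {
      mm <- colMeans(G, na.rm = TRUE)
      nas <- which(is.na(G), arr.ind = TRUE)
      G[nas] <- mm[nas[, 2]]
    }
    v <- apply(G, 2, stats::var)
    live <- v > 0
    p <- length(idx)
    R <- diag(p)
    alpha <- NA_real_
    if (!all(live))
      warning("estimate_ld: ", sum(!live), " zero-variance SNP(s) in block ",
              lab, " kept as uncorrelated", call. = FALSE)
    if (sum(live) >= 2) {
      if (method == "ledoit_wolf") {
        lw <- ledoit_wolf_corr(G[, live, drop = FALSE])
        R[live, live] <- lw$R
        alpha <- lw$alpha
      } else {
        R[live, live] <- stats::cor(G[, live, drop = FALSE])
      }
    }
    b <- list(idx = idx, R = R)
    attr(b, "alpha") <- alpha
    blocks[[length(blocks) + 1L]] <- b
  }
  ld_structure(blocks, snp_id = panel$snps$snp_id,
               band_radius = band_radius,
               source = if (method == "ledoit_wolf")
                 "reference-panel (ledoit-wolf)" else "reference-panel (sample)")
}

#' Materialize an LD structure as a dense matrix
#'
#' Mainly for small-problem tests; cross-block entries are zero.
#'
#' @param ld an [ld_structure].
#' @param M total number of SNPs (default: inferred from block indices).
#' @return dense `M x M` correlation matrix.
#' @export
ld_as_matrix <- function(ld, M = NULL) {
  if (is.null(M)) M <- max(unlist(lapply(ld$blocks, `[[`, "idx")))
  R <- diag(M)
  for (b in ld$blocks) R[b$idx, b$idx] <- b$R
  R
}
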
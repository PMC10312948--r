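# Domain containers for case-control GWAS summary statistics, PRS weight
# vectors, genotype panels and genome block partitions, plus the allele
# harmonization that aligns them.

NUCLEOTIDES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct a case-control summary-statistics table
#'
#' Builds the per-SNP table used throughout the package: reference-allele
#' frequencies in controls (`f0_hat`) and cases (`f1_hat`), group sample
#' sizes, the per-group genotype variances \eqn{s_{j,m}^2 = 2 f_{j,m}(1 -
#' f_{j,m})}, the standard error of the allele-frequency difference
#' \eqn{s_m = \sqrt{s_{1,m}^2/(4 n_1) + s_{0,m}^2/(4 n_0)}} and the
#' z-score \eqn{z_m = (\hat f_{1,m} - \hat f_{0,m})/s_m}.
#'
#' Two construction paths are supported. If both group frequencies are
#' given, `z` is computed from them. If only `z` and a pooled frequency
#' `f_pooled` are available (common for meta-analysis files), the pooled
#' frequency is used for both group variances and the frequency difference
#' is reconstructed as `z * s`, split evenly around the pooled value.
#'
#' @param snp_id character vector of SNP identifiers.
#' @param n0,n1 control / case sample counts (scalar or per SNP).
#' @param f0_hat,f1_hat observed reference-allele frequency in controls and
#'   cases, strictly inside (0,1).
#' @param z allele-frequency-difference test z-scores (used when per-group
#'   frequencies are absent).
#' @param f_pooled pooled reference-allele frequency, required with `z`.
#' @param chrom,pos,ref_allele,alt_allele optional SNP metadata
#'   (`pos` 1-based). Frequencies refer to `ref_allele`.
#' @param maf_filter if `TRUE`, drop SNPs with minor allele frequency
#'   below `maf_min` in either group.
#' @param maf_min minor-allele-frequency cutoff used when `maf_filter` is
#'   set (default 0.05).
#' @return A `data.frame` of class `"sumstats"` with columns `snp_id`,
#'   `chrom`, `pos`, `ref_allele`, `alt_allele`, `f0_hat`, `f1_hat`, `n0`,
#'   `n1`, `s0_sq`, `s1_sq`, `s`, `z`. The number of rows dropped during
#'   validation is recorded in `attr(, "n_dropped")`.
#' @export
sumstats <- function(snp_id, n0, n1, f0_hat = NULL, f1_hat = NULL,
                     z = NULL, f_pooled = NULL,
                     chrom = NA_character_, pos = NA_integer_,
                     ref_allele = NA_character_, alt_allele = NA_character_,
                     maf_filter = FALSE, maf_min = 0.05) {
  M <- length(snp_id)
  n0 <- rep_len(as.numeric(n0), M)
  n1 <- rep_len(as.numeric(n1), M)
  if (any(!is.finite(n0)) || any(!is.finite(n1)) || any(n0 <= 0) || any(n1 <= 0))
    stop("sumstats: case and control sample sizes must be positive", call. = FALSE)

  if (!is.null(f0_hat) && !is.null(f1_hat)) {
    f0 <- as.numeric(f0_hat); f1 <- as.numeric(f1_hat)
    s0_sq <- 2 * f0 * (1 - f0)
    s1_sq <- 2 * f1 * (1 - f1)
    s <- sqrt(s1_sq / (4 * n1) + s0_sq / (4 * n0))
    zc <- (f1 - f0) / s
  } else if (!is.null(z) && !is.null(f_pooled)) {
    f <- as.numeric(f_pooled)
    zc <- as.numeric(z)
    s0_sq <- s1_sq <- 2 * f * (1 - f)
    s <- sqrt(s1_sq / (4 * n1) + s0_sq / (4 * n0))
    delta_hat <- zc * s
    f0 <- f - delta_hat / 2
    f1 <- f + delta_hat / 2
  } else {
    stop("sumstats: provide either (f0_hat, f1_hat) or (z, f_pooled)",
         call. = FALSE)
  }

  out <- data.frame(
    snp_id = as.character(snp_id),
    chrom = rep_len(as.character(chrom), M),
    pos = rep_len(as.integer(pos), M),
    ref_allele = rep_len(toupper(as.character(ref_allele)), M),
    alt_allele = rep_len(toupper(as.character(alt_allele)), M),
    f0_hat = f0, f1_hat = f1, n0 = n0, n1 = n1,
    s0_sq = s0_sq, s1_sq = s1_sq, s = s, z = zc,
    stringsAsFactors = FALSE
  )

  ok <- is.finite(out$f0_hat) & is.finite(out$f1_hat) &
    is.finite(out$z) & is.finite(out$s) & out$s > 0 &
    out$f0_hat > 0 & out$f0_hat < 1 & out$f1_hat > 0 & out$f1_hat < 1
  if (maf_filter) {
    maf <- pmin(out$f0_hat, 1 - out$f0_hat, out$f1_hat, 1 - out$f1_hat)
    ok <- ok & maf >= maf_min
  }
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message("sumstats: dropped ", n_dropped,
            " SNP(s) with non-finite, out-of-range or below-MAF values")
    out <- out[ok, , drop = FALSE]
  }

  dup <- duplicated(out$snp_id)
  if (any(dup)) {
    warning("sumstats: ", sum(dup),
            " duplicated SNP id(s); keeping first occurrence", call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a whitespace-, tab- or comma-delimited file with a header line
#' and maps its columns onto the canonical fields via `column_map`.
#' Mandatory fields: `snp_id`, `n0`, `n1`, plus either (`f0`, `f1`) or
#' (`z`, `f`). Optional: `chrom`, `pos`, `ref_allele`, `alt_allele`.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical field names
#'   (see above) to column names in the file; fields whose canonical name
#'   matches a file column need not be listed.
#' @param sep field separator passed to [utils::read.table()]; default
#'   `""` (any whitespace). Use `","` for CSV.
#' @inheritParams sumstats
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, column_map = NULL, sep = "",
                          maf_filter = FALSE, maf_min = 0.05) {
  if (!file.exists(path)) stop("read_sumstats: no such file: ", path, call. = FALSE)
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  get_col <- function(field, required = FALSE) {
    col <- if (!is.null(column_map) && field %in% names(column_map))
      column_map[[field]] else field
    if (col %in% names(tab)) return(tab[[col]])
    if (required)
      stop("read_sumstats: required column '", col, "' (field '", field,
           "') not found in ", path, call. = FALSE)
    NULL
  }
  snp_id <- get_col("snp_id", required = TRUE)
  n0 <- get_col("n0", required = TRUE)
  n1 <- get_col("n1", required = TRUE)
  f0 <- get_col("f0"); f1 <- get_col("f1")
  zz <- get_col("z");  fp <- get_col("f")
  has_freqs <- !is.null(f0) && !is.null(f1)
  if (!has_freqs && (is.null(zz) || is.null(fp)))
    stop("read_sumstats: need either columns (f0, f1) or (z, f); ",
         "neither pair found", call. = FALSE)
  opt <- function(field, default) {
    v <- get_col(field)
    if (is.null(v)) default else v
  }
  sumstats(
    snp_id = snp_id, n0 = n0, n1 = n1,
    f0_hat = if (has_freqs) f0 else NULL,
    f1_hat = if (has_freqs) f1 else NULL,
    z = if (has_freqs) NULL else zz,
    f_pooled = if (has_freqs) NULL else fp,
    chrom = opt("chrom", NA_character_), pos = opt("pos", NA_integer_),
    ref_allele = opt("ref_allele", NA_character_),
    alt_allele = opt("alt_allele", NA_character_),
    maf_filter = maf_filter, maf_min = maf_min
  )
}

#' Write summary statistics to a tab-delimited file
#'
#' @param ss a [sumstats] object.
#' @param path output file path.
#' @export
write_sumstats <- function(ss, path) {
  stopifnot(inherits(ss, "sumstats"))
  out <- as.data.frame(ss)[, c("snp_id", "chrom", "pos", "ref_allele",
                               "alt_allele", "f0_hat", "f1_hat",
                               "n0", "n1")]
  names(out)[names(out) == "f0_hat"] <- "f0"  # canonical read names
  names(out)[names(out) == "f1_hat"] <- "f1"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a PRS weight set
#'
#' A weight set holds the per-SNP weights \eqn{\omega} produced by a PRS
#' method at one hyperparameter value, on the allele-frequency-difference
#' scale so that the AUC formula consumes them directly.
#'
#' @param snp_id character vector of SNP identifiers.
#' @param effect_allele allele to which each weight refers.
#' @param omega numeric weights.
#' @param method_label short label of the generating PRS method.
#' @param hyperparameter named list describing the hyperparameter value
#'   (e.g. `list(p_threshold = 0.05)`).
#' @return A `data.frame` of class `"weightset"` with attributes
#'   `method_label` and `hyperparameter`.
#' @export
weightset <- function(snp_id, effect_allele, omega, method_label = "",
                      hyperparameter = list()) {
  stopifnot(length(snp_id) == length(omega))
  if (any(!is.finite(omega)))
    stop("weightset: non-finite weight", call. = FALSE)
  out <- data.frame(snp_id = as.character(snp_id),
                    effect_allele = toupper(rep_len(as.character(effect_allele),
                                                    length(snp_id))),
                    omega = as.numeric(omega), stringsAsFactors = FALSE)
  attr(out, "method_label") <- method_label
  attr(out, "hyperparameter") <- hyperparameter
  class(out) <- c("weightset", "data.frame")
  out
}

#' Read / write a PRS weight file
#'
#' Weight files are 3-column delimited text (SNP id, effect allele,
#' weight) with a header. Method label and hyperparameter values are kept
#' in `# key: value` comment lines above the header so they survive a
#' round trip.
#'
#' @param path file path.
#' @return [read_weights()] returns a [weightset].
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("read_weights: no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  method_label <- ""
  hyper <- list()
  for (ln in meta) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key == "method") method_label <- val
    else if (nzchar(key)) hyper[[key]] <- val
  }
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    stringsAsFactors = FALSE)
  weightset(tab[[1]], tab[[2]], tab[[3]], method_label = method_label,
            hyperparameter = hyper)
}

#' @rdname read_weights
#' @param ws a [weightset] object.
#' @export
write_weights <- function(ws, path) {
  stopifnot(inherits(ws, "weightset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method: ", attr(ws, "method_label")), con)
  hyper <- attr(ws, "hyperparameter")
  for (key in names(hyper))
    writeLines(paste0("# ", key, ": ", format(hyper[[key]])), con)
  write.table(as.data.frame(ws), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

is_strand_ambiguous <- function(a1, a2) {
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize summary statistics, PRS weights and a genotype panel
#'
#' Restricts all inputs to their common SNPs (in summary-statistics
#' order) and reconciles alleles into the summary-statistics frame:
#' weights whose effect allele is the sumstats reference allele have their
#' sign flipped; panel dosages counted on the opposite allele are flipped
#' to `2 - g`. Strand flips are resolved by complementing; strand-ambiguous
#' A/T and C/G SNPs in the weight set are dropped by default. SNPs whose
#' alleles cannot be reconciled are dropped. When allele metadata is
#' missing (`NA`), SNPs are matched by id alone.
#'
#' Applying `harmonize()` to already-harmonized inputs is a no-op.
#'
#' @param ss a [sumstats] object.
#' @param ws a [weightset] object.
#' @param panel optional [genotype_panel].
#' @param drop_ambiguous drop strand-ambiguous SNPs (default `TRUE`).
#' @return list with elements `sumstats`, `weights`, `panel` (NULL if not
#'   supplied) and `dropped`, a named integer vector of drop counts by
#'   reason.
#' @export
harmonize <- function(ss, ws, panel = NULL, drop_ambiguous = TRUE) {
  stopifnot(inherits(ss, "sumstats"), inherits(ws, "weightset"))
  dropped <- c(not_in_sumstats = 0L, strand_ambiguous = 0L,
               allele_mismatch = 0L, not_in_panel = 0L)

  idx_w <- match(ws$snp_id, ss$snp_id)
  dropped["not_in_sumstats"] <- sum(is.na(idx_w))
  keep <- !is.na(idx_w)
  ws2 <- ws[keep, , drop = FALSE]
  idx_w <- idx_w[keep]

  have_alleles <- !is.na(ss$ref_allele[idx_w]) & !is.na(ss$alt_allele[idx_w]) &
    !is.na(ws2$effect_allele)
  omega <- ws2$omega
  keep2 <- rep(TRUE, nrow(ws2))
  if (any(have_alleles)) {
    ref <- ss$ref_allele[idx_w]
    alt <- ss$alt_allele[idx_w]
    eff <- ws2$effect_allele
    amb <- have_alleles & is_strand_ambiguous(ref, alt)
    if (drop_ambiguous && any(amb)) {
      dropped["strand_ambiguous"] <- sum(amb)
      keep2 <- keep2 & !amb
    }
    # try direct match, then strand-complemented match
    ceff <- unname(COMPLEMENT[eff])
    same <- (eff == ref | (!amb & ceff == ref)) %in% TRUE
    swap <- (eff == alt | (!amb & ceff == alt)) %in% TRUE
    omega[have_alleles & !same & swap] <- -omega[have_alleles & !same & swap]
    bad <- have_alleles & !same & !swap
    dropped["allele_mismatch"] <- sum(bad & keep2)
    keep2 <- keep2 & !bad
  }
  ws2$omega <- omega
  ws2 <- ws2[keep2, , drop = FALSE]
  idx_w <- idx_w[keep2]

  if (!is.null(panel)) {
    idx_p <- match(ss$snp_id[idx_w], panel$snps$snp_id)
    dropped["not_in_panel"] <- sum(is.na(idx_p))
    keep3 <- !is.na(idx_p)
    ws2 <- ws2[keep3, , drop = FALSE]
    idx_w <- idx_w[keep3]
    idx_p <- idx_p[keep3]
  }

  if (length(idx_w) == 0)
    stop("harmonize: no SNPs shared between summary statistics and weights",
         call. = FALSE)

  ord <- order(idx_w)
  ws2 <- ws2[ord, , drop = FALSE]
  idx_w <- idx_w[ord]
  ss2 <- ss[idx_w, , drop = FALSE]
  rownames(ss2) <- rownames(ws2) <- NULL
  # weights are now expressed for the sumstats reference allele
  ws2$effect_allele <- ifelse(is.na(ss2$ref_allele), ws2$effect_allele,
                              ss2$ref_allele)
  class(ss2) <- class(ss)
  attr(ws2, "method_label") <- attr(ws, "method_label")
  attr(ws2, "hyperparameter") <- attr(ws, "hyperparameter")
  class(ws2) <- class(ws)

  panel2 <- NULL
  if (!is.null(panel)) {
    idx_p <- idx_p[ord]
    geno <- panel$genotypes[idx_p, , drop = FALSE]
    snps <- panel$snps[idx_p, , drop = FALSE]
    # flip dosages counted on the opposite allele
    if (!all(is.na(snps$ref_allele)) && !all(is.na(ss2$ref_allele))) {
      flip <- !is.na(snps$ref_allele) & !is.na(ss2$ref_allele) &
        (snps$ref_allele == ss2$alt_allele |
           unname(COMPLEMENT[snps$ref_allele]) == ss2$alt_allele)
      if (any(flip)) {
        geno[flip, ] <- 2L - geno[flip, , drop = FALSE]
        tmp <- snps$ref_allele[flip]
        snps$ref_allele[flip] <- snps$alt_allele[flip]
        snps$alt_allele[flip] <- tmp
      }
    }
    rownames(snps) <- NULL
    panel2 <- genotype_panel(geno, snps, panel$samples)
  }

  list(sumstats = ss2, weights = ws2, panel = panel2, dropped = dropped)
}
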
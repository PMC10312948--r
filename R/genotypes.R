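# Genotype panel container and PLINK 1 bed/bim/fam reader/writer.

#' Construct a genotype panel
#'
#' @param genotypes integer matrix, SNPs x samples, values in
#'   `{0, 1, 2, NA}`; each entry counts copies of the SNP's `ref_allele`.
#' @param snps `data.frame` with at least `snp_id`; optionally `chrom`,
#'   `pos`, `ref_allele` (counted allele), `alt_allele`.
#' @param samples character vector of sample ids.
#' @return list of class `"genotype_panel"` with elements `genotypes`,
#'   `snps` (including per-SNP `missing_frac`), `samples`.
#' @export
genotype_panel <- function(genotypes, snps, samples = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(genotypes)))
  if (is.character(snps)) snps <- data.frame(snp_id = snps,
                                             stringsAsFactors = FALSE)
  stopifnot(nrow(snps) == nrow(genotypes), length(samples) == ncol(genotypes))
  bad <- !is.na(genotypes) & (genotypes < 0L | genotypes > 2L)
  if (any(bad))
    stop("genotype_panel: genotype values must be 0, 1, 2 or NA", call. = FALSE)
  for (col in c("chrom", "pos", "ref_allele", "alt_allele"))
    if (is.null(snps[[col]])) snps[[col]] <- NA
  snps$missing_frac <- rowMeans(is.na(genotypes))
  structure(list(genotypes = genotypes, snps = snps,
                 samples = as.character(samples)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$genotypes), "SNPs x", ncol(x$genotypes),
      "samples;", sprintf("%.2f%%", 100 * mean(is.na(x$genotypes))),
      "missing\n")
  invisible(x)
}

#' Read a PLINK 1 bed/bim/fam fileset
#'
#' Reads the binary SNP-major `.bed` file together with its `.bim` and
#' `.fam` sidecars. Dosages count the A1 allele (PLINK's first, usually
#' minor, allele), which is stored as `ref_allele` in the panel metadata.
#' SNPs with all genotypes missing are excluded with a warning.
#'
#' @param bed_prefix path prefix; `<prefix>.bed/.bim/.fam` must exist.
#' @return a [genotype_panel].
#' @export
read_plink <- function(bed_prefix) {
  paths <- paste0(bed_prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("read_plink: missing file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE)
  names(bim) <- c("chrom", "snp_id", "cm", "pos", "a1", "a2")[seq_len(ncol(bim))]
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  n_snp <- nrow(bim)
  n_samp <- nrow(fam)

  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("read_plink: bad magic bytes; not a PLINK bed file", call. = FALSE)
  if (raw[3] != as.raw(0x01))
    stop("read_plink: only SNP-major bed files are supported", call. = FALSE)
  bytes_per_snp <- ceiling(n_samp / 4)
  if (length(raw) - 3L != n_snp * bytes_per_snp)
    stop("read_plink: bed size inconsistent with bim/fam dimensions",
         call. = FALSE)

  # 2-bit codes, little-endian within byte: 00 hom A1 (2), 10 het (1),
  # 11 hom A2 (0), 01 missing
  lookup <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  body <- as.integer(raw[-(1:3)])
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  codes <- matrix(codes, nrow = 4L * bytes_per_snp, ncol = n_snp)
  geno <- matrix(lookup[as.character(codes[seq_len(n_samp), , drop = FALSE])],
                 nrow = n_samp, ncol = n_snp)
  geno <- t(geno)

  snps <- data.frame(snp_id = bim$snp_id, chrom = as.character(bim$chrom),
                     pos = bim$pos, ref_allele = toupper(bim$a1),
                     alt_allele = toupper(bim$a2), stringsAsFactors = FALSE)
  all_missing <- rowSums(!is.na(geno)) == 0L
  if (any(all_missing)) {
    warning("read_plink: excluding ", sum(all_missing),
            " SNP(s) with all genotypes missing", call. = FALSE)
    geno <- geno[!all_missing, , drop = FALSE]
    snps <- snps[!all_missing, , drop = FALSE]
  }
  genotype_panel(geno, snps, samples = as.character(fam[[2]]))
}

#' Write a genotype panel as PLINK 1 bed/bim/fam
#'
#' @param panel a [genotype_panel].
#' @param bed_prefix output path prefix.
#' @export
write_plink <- function(panel, bed_prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  geno <- panel$genotypes
  n_snp <- nrow(geno)
  n_samp <- ncol(geno)
  bim <- data.frame(chrom = ifelse(is.na(panel$snps$chrom), "0",
                                   panel$snps$chrom),
                    snp_id = panel$snps$snp_id, cm = 0,
                    pos = ifelse(is.na(panel$snps$pos), 0L, panel$snps$pos),
                    a1 = ifelse(is.na(panel$snps$ref_allele), "A",
                                panel$snps$ref_allele),
                    a2 = ifelse(is.na(panel$snps$alt_allele), "G",
                                panel$snps$alt_allele))
  write.table(bim, paste0(bed_prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = panel$samples, iid = panel$samples,
                    pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  write.table(fam, paste0(bed_prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  code <- matrix(1L, nrow = n_snp, ncol = n_samp)  # missing
  code[!is.na(geno) & geno == 2L] <- 0L
  code[!is.na(geno) & geno == 1L] <- 2L
  code[!is.na(geno) & geno == 0L] <- 3L
  pad <- 4L * ceiling(n_samp / 4) - n_samp
  if (pad > 0) code <- cbind(code, matrix(3L, n_snp, pad))
  quads <- matrix(t(code), nrow = 4L)  # columns = bytes, SNP-major
  bytes <- as.raw(quads[1, ] + 4L * quads[2, ] + 16L * quads[3, ] +
                    64L * quads[4, ])
  con <- file(paste0(bed_prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), bytes), con)
  invisible(bed_prefix)
}
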
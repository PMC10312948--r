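# Genome block partitions (LDetect-style BED intervals) and SNP-to-block
# assignment.

#' Construct a genome block partition
#'
#' Intervals are half-open, 0-based `[start, end)` following the BED
#' convention; SNP positions are 1-based. Intervals on the same chromosome
#' must be disjoint; they are sorted on construction.
#'
#' @param chrom character vector of chromosome labels.
#' @param start,end integer interval bounds (0-based half-open).
#' @return `data.frame` of class `"block_partition"`.
#' @export
block_partition <- function(chrom, start, end) {
  out <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  if (any(out$end <= out$start))
    stop("block_partition: intervals must have end > start", call. = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  for (ch in unique(out$chrom)) {
    b <- out[out$chrom == ch, , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("block_partition: overlapping intervals on chromosome ", ch,
           call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("block_partition", "data.frame")
  out
}

#' Read a 3-column BED block partition
#'
#' @param path BED file (chrom, start, end; no header), e.g. an LDetect
#'   block list.
#' @return a [block_partition].
#' @export
read_blocks <- function(path) {
  if (!file.exists(path)) stop("read_blocks: no such file: ", path, call. = FALSE)
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  block_partition(tab[[1]], tab[[2]], tab[[3]])
}

#' Assign SNPs to partition blocks
#'
#' Maps each SNP by (chromosome, 1-based position) to the block whose
#' half-open interval contains it. A SNP at a block's `start + 1` (the
#' first covered base) belongs to that block. SNPs not covered by any
#' interval are assigned to the nearest block on their chromosome with a
#' warning.
#'
#' @param snps `data.frame` with columns `chrom` and `pos`.
#' @param partition a [block_partition].
#' @return integer vector of block indices (rows of `partition`).
#' @export
assign_blocks <- function(snps, partition) {
  stopifnot(inherits(partition, "block_partition"))
  idx <- rep(NA_integer_, nrow(snps))
  for (ch in unique(snps$chrom)) {
    rows <- which(snps$chrom == ch)
    brows <- which(partition$chrom == ch)
    if (!length(brows))
      stop("assign_blocks: no blocks on chromosome ", ch, call. = FALSE)
    pos0 <- snps$pos[rows] - 1L  # 0-based
    j <- findInterval(pos0, partition$start[brows])
    hit <- j >= 1 & pos0 < ifelse(j >= 1, partition$end[brows][pmax(j, 1)], 0L)
    idx[rows[hit]] <- brows[j[hit]]
    if (any(!hit)) {
      # nearest block by distance to interval bounds
      for (r in rows[!hit]) {
        p0 <- snps$pos[r] - 1L
        d <- pmax(partition$start[brows] - p0, p0 - (partition$end[brows] - 1L), 0L)
        idx[r] <- brows[which.min(d)]
      }
      warning("assign_blocks: ", sum(!hit), " SNP(s) on chromosome ", ch,
              " not covered by any block; assigned to nearest block",
              call. = FALSE)
    }
  }
  idx
}
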
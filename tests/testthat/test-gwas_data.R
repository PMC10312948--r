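# Summary statistics, weight files, genotype panels and harmonization.

test_that("sumstats derives s, s0_sq, s1_sq and z from group frequencies", {
  ss <- make_tiny_ss(f0 = 0.30, f1 = 0.35)
  expect_equal(ss$s0_sq, 0.42)
  expect_equal(ss$s1_sq, 0.455)
  s_hand <- sqrt(0.42 / 4000 + 0.455 / 4000)
  expect_equal(ss$s, s_hand, tolerance = 1e-12)
  expect_equal(ss$z, 0.05 / s_hand, tolerance = 1e-8)
  expect_equal(ss$z, 3.3806, tolerance = 1e-4)

  # type invariants on a larger random table
  set.seed(1)
  ss2 <- make_tiny_ss(f0 = runif(50, 0.1, 0.9),
                      f1 = runif(50, 0.1, 0.9), n0 = 800, n1 = 1200)
  expect_equal(ss2$s, sqrt(ss2$s1_sq / (4 * ss2$n1) + ss2$s0_sq / (4 * ss2$n0)),
               tolerance = 1e-12)
  expect_equal(ss2$z, (ss2$f1_hat - ss2$f0_hat) / ss2$s, tolerance = 1e-8)
})

test_that("a null SNP has z exactly zero", {
  ss <- make_tiny_ss(f0 = c(0.3, 0.5), f1 = c(0.3, 0.6))
  expect_identical(ss$z[1], 0)
})

test_that("duplicated SNP ids keep the first occurrence with a warning", {
  expect_warning(
    ss <- sumstats(c("rs1", "rs2", "rs1"), n0 = 100, n1 = 100,
                   f0_hat = c(0.3, 0.4, 0.5), f1_hat = c(0.35, 0.45, 0.55)),
    "duplicated")
  expect_equal(nrow(ss), 2)
  expect_equal(ss$f0_hat[ss$snp_id == "rs1"], 0.3)
})

test_that("z + pooled-frequency construction reconstructs the frequency difference", {
  ss <- sumstats("rs1", n0 = 2000, n1 = 2000, z = 2.5, f_pooled = 0.4)
  expect_equal(ss$s0_sq, 2 * 0.4 * 0.6)
  expect_equal(ss$f1_hat - ss$f0_hat, 2.5 * ss$s, tolerance = 1e-12)
})

test_that("invalid rows are dropped and counted; zero group sizes error", {
  expect_message(
    ss <- sumstats(c("a", "b", "c"), n0 = 500, n1 = 500,
                   f0_hat = c(0.3, NA, 0.5), f1_hat = c(0.31, 0.4, 1.2)),
    "dropped 2")
  expect_equal(nrow(ss), 1)
  expect_equal(attr(ss, "n_dropped"), 2)
  expect_error(sumstats("a", n0 = 0, n1 = 100, f0_hat = 0.3, f1_hat = 0.4),
               "positive")
})

test_that("the MAF filter removes low-frequency SNPs when flagged", {
  ss <- sumstats(c("a", "b"), n0 = 500, n1 = 500,
                 f0_hat = c(0.02, 0.3), f1_hat = c(0.025, 0.32),
                 maf_filter = TRUE)
  expect_equal(ss$snp_id, "b")
})

test_that("sumstats and weight files round-trip through disk", {
  dir <- withr::local_tempdir()
  ss <- make_tiny_ss(f0 = c(0.2, 0.4, 0.6), f1 = c(0.25, 0.38, 0.66))
  write_sumstats(ss, file.path(dir, "ss.tsv"))
  ss2 <- read_sumstats(file.path(dir, "ss.tsv"))
  expect_equal(ss2$z, ss$z, tolerance = 1e-10)
  expect_equal(ss2$snp_id, ss$snp_id)

  ws <- weightset(ss$snp_id, "A", c(0.1, -0.2, 0), method_label = "pt",
                  hyperparameter = list(p_threshold = 0.05))
  write_weights(ws, file.path(dir, "w.txt"))
  ws2 <- read_weights(file.path(dir, "w.txt"))
  expect_equal(ws2$omega, ws$omega)
  expect_equal(attr(ws2, "method_label"), "pt")
  expect_equal(attr(ws2, "hyperparameter")$p_threshold, "0.05")
})

test_that("read_sumstats names missing mandatory columns", {
  dir <- withr::local_tempdir()
  writeLines(c("snp_id\tf0\tf1", "rs1\t0.3\t0.4"), file.path(dir, "bad.tsv"))
  expect_error(read_sumstats(file.path(dir, "bad.tsv")), "n0")
})

test_that("harmonization flips swapped-allele weights and is idempotent", {
  ss <- make_tiny_ss(f0 = c(0.2, 0.4, 0.6), f1 = c(0.25, 0.38, 0.66))
  # rs2 weighted on the alternative allele: sign must flip
  ws <- weightset(c("rs1", "rs2", "rs3"), c("A", "G", "A"), c(0.5, 0.3, -0.1))
  h <- harmonize(ss, ws)
  expect_equal(h$weights$omega, c(0.5, -0.3, -0.1))
  expect_equal(h$sumstats$snp_id, c("rs1", "rs2", "rs3"))
  # idempotence: harmonizing the harmonized pair changes nothing
  h2 <- harmonize(h$sumstats, h$weights)
  expect_equal(h2$weights$omega, h$weights$omega)
  expect_equal(h2$sumstats, h$sumstats)
  # the AUC is invariant under the allele flip
  ws_same <- weightset(c("rs1", "rs2", "rs3"), "A", c(0.5, -0.3, -0.1))
  expect_equal(plugin_auc(h$sumstats, h$weights),
               plugin_auc(ss, ws_same))
})

test_that("harmonization drops strand-ambiguous SNPs and errors on disjoint sets", {
  ss <- sumstats(c("rs1", "rs2"), n0 = 500, n1 = 500,
                 f0_hat = c(0.3, 0.4), f1_hat = c(0.32, 0.42),
                 ref_allele = c("A", "A"), alt_allele = c("T", "G"))
  ws <- weightset(c("rs1", "rs2"), c("A", "A"), c(1, 2))
  h <- harmonize(ss, ws)
  expect_equal(h$sumstats$snp_id, "rs2")
  expect_equal(unname(h$dropped["strand_ambiguous"]), 1L)
  expect_error(harmonize(ss, weightset("rs9", "A", 1)), "no SNPs shared")
})

test_that("PLINK bed/bim/fam files round-trip exactly", {
  dir <- withr::local_tempdir()
  geno <- matrix(c(0L, 1L, 2L,
                   2L, NA, 0L), nrow = 2, byrow = TRUE)
  snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L),
                     ref_allele = c("A", "C"), alt_allele = c("G", "T"),
                     stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, snps, c("s1", "s2", "s3"))
  write_plink(panel, file.path(dir, "fix"))
  back <- read_plink(file.path(dir, "fix"))
  expect_identical(back$genotypes, panel$genotypes)
  expect_equal(back$snps$snp_id, snps$snp_id)
  expect_equal(back$samples, panel$samples)
  expect_equal(back$snps$missing_frac, c(0, 1 / 3))
})

test_that("read_plink rejects corrupt magic bytes and drops all-missing SNPs", {
  dir <- withr::local_tempdir()
  panel <- genotype_panel(matrix(c(1L, 0L, NA, NA), nrow = 2, byrow = TRUE),
                          data.frame(snp_id = c("rs1", "rs2")), c("s1", "s2"))
  write_plink(panel, file.path(dir, "p"))
  expect_warning(back <- read_plink(file.path(dir, "p")), "all genotypes missing")
  expect_equal(back$snps$snp_id, "rs1")

  writeBin(as.raw(c(0x00, 0x00, 0x01, 0xff)), file.path(dir, "p.bed"))
  expect_error(read_plink(file.path(dir, "p")), "magic")
})

test_that("dosage orientation survives a round trip", {
  # allele counts in the bed file must match the generating matrix
  dir <- withr::local_tempdir()
  set.seed(42)
  geno <- matrix(rbinom(50L, 2L, 0.3), nrow = 5)
  panel <- genotype_panel(geno, data.frame(snp_id = paste0("v", 1:5)))
  write_plink(panel, file.path(dir, "d"))
  back <- read_plink(file.path(dir, "d"))
  expect_identical(rowSums(back$genotypes), rowSums(geno))
  expect_identical(back$genotypes, panel$genotypes)
})

test_that("harmonization aligns and flips panel dosages", {
  ss <- make_tiny_ss(f0 = c(0.2, 0.4), f1 = c(0.25, 0.38))
  ws <- weightset(c("rs1", "rs2"), "A", c(1, 1))
  geno <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 2, byrow = TRUE)
  snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1", pos = 1:2,
                     ref_allele = c("A", "G"), alt_allele = c("G", "A"),
                     stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, snps)
  h <- harmonize(ss, ws, panel)
  # rs2 counted on G in the panel but frequencies refer to A: flipped
  expect_equal(h$panel$genotypes[2, ], c(0L, 1L, 2L))
  expect_equal(h$panel$genotypes[1, ], c(0L, 1L, 2L))
})
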
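test_that("dosage TSV round-trip preserves dosages and metadata", {
  g <- simulate_genotypes(c(A = 30), 2, 5, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path, format = "tsv")
  g2 <- read_genotypes(path, samples = g$samples)
  expect_equal(unname(g2$dosage), unname(g$dosage), tolerance = 1e-3)
  expect_equal(g2$variants$id, g$variants$id)
  expect_equal(g2$variants$pos, g$variants$pos)
  expect_equal(dim(g2$dosage), c(30, 10))
})

test_that("VCF round-trip works, GT is the fallback when DS is absent", {
  g <- simulate_genotypes(c(A = 12), 1, 4, seed = 6)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(g, path, format = "vcf")
  g2 <- read_genotypes(path, samples = g$samples)
  expect_equal(unname(g2$dosage), unname(g$dosage), tolerance = 1e-3)

  # GT-only record: 0/1 must become dosage 1
  gt_only <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1"
  )
  p2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(gt_only, p2)
  g3 <- read_genotypes(p2)
  expect_equal(as.numeric(g3$dosage), c(1, 2))
})

test_that("multiallelic VCF records are skipped with a warning", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "1\t200\tv2\tA\tG,T\t.\tPASS\t.\tGT\t1/2"
  )
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, p)
  expect_warning(g <- read_genotypes(p), "multiallelic")
  expect_equal(ncol(g$dosage), 1L)
})

test_that("MAF follows min(p, 1-p) of mean dosage and QC removes monomorphics", {
  dos <- cbind(v1 = c(0, 1, 1, 2), v2 = c(0, 0, 0, 0))
  vars <- data.frame(id = c("1:10:A:G", "1:20:A:G"), chrom = "1",
                     pos = c(10, 20), ref = "A", alt = "G", r2 = 1)
  vars$id <- c("v1", "v2")
  g <- genotype_matrix(dos, vars, data.frame(sample_id = paste0("s", 1:4),
                                             population = "A"))
  expect_equal(unname(maf(g)), c(0.5, 0))
  gq <- qc_filter(g, maf_min = 0.01, r2_min = 0, population = "ALL")
  expect_equal(colnames(gq$dosage), "v1")
  # idempotent
  gq2 <- qc_filter(gq, maf_min = 0.01, r2_min = 0, population = "ALL")
  expect_identical(gq$dosage, gq2$dosage)
})

test_that("ALL-mode QC requires imputation quality in every population", {
  set.seed(2)
  dos <- matrix(rbinom(40 * 2, 2, 0.4), 40, 2,
                dimnames = list(NULL, c("v1", "v2")))
  vars <- data.frame(id = c("v1", "v2"), chrom = "1", pos = c(10, 20),
                     ref = "A", alt = "G",
                     r2_P1 = c(0.9, 0.9), r2_P2 = c(0.9, 0.9),
                     r2_P3 = c(0.9, 0.9), r2_P4 = c(0.9, 0.7))
  samples <- data.frame(sample_id = paste0("s", 1:40),
                        population = rep(c("P1", "P2", "P3", "P4"), 10))
  g <- genotype_matrix(dos, vars, samples)
  g_all <- qc_filter(g, maf_min = 0.01, r2_min = 0.8, population = "ALL")
  expect_equal(colnames(g_all$dosage), "v1")
  g_p1 <- qc_filter(g, maf_min = 0.01, r2_min = 0.8, population = "P1")
  expect_setequal(colnames(g_p1$dosage), c("v1", "v2"))
  expect_true(all(g_p1$samples$population == "P1"))
})

test_that("MAF is symmetric under allele swap", {
  d <- c(0, 1, 2, 2, 1)
  vars <- function(id) data.frame(id = id, chrom = "1", pos = 10,
                                  ref = "A", alt = "G", r2 = 1)
  s <- data.frame(sample_id = paste0("s", 1:5), population = "A")
  g1 <- genotype_matrix(cbind(v = d), vars("v"), s)
  g2 <- genotype_matrix(cbind(v = 2 - d), vars("v"), s)
  expect_equal(maf(g1), maf(g2))
})

test_that("PCA separates differentiated populations and is deterministic", {
  g <- simulate_genotypes(c(P1 = 60, P2 = 60), 20, 10, fst_target = 0.3,
                          ld_decay = 0.3, seed = 13)
  pc <- genotype_pca(g, 2)
  s1 <- pc$scores[g$samples$population == "P1", 1]
  s2 <- pc$scores[g$samples$population == "P2", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1)
  # duplicate samples score identically
  g2 <- subset_genotypes(g, samples = c(1, 1, 2:60))
  pc2 <- genotype_pca(g2, 2)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ])
  # k = 0 is a no-op
  pc0 <- genotype_pca(g, 0)
  expect_equal(ncol(pc0$scores), 0L)
})

test_that("Hudson F_ST matches closed forms", {
  expect_lt(abs(fst_hudson(0.3, 0.3, 1e6, 1e6)), 1e-5)
  expect_equal(fst_hudson(0.1, 0.9, 1e9, 1e9), 0.64 / 0.82,
               tolerance = 1e-6)
  expect_equal(fst_hudson(0, 1, 1e9, 1e9), 1, tolerance = 1e-6)
  expect_true(is.na(fst_hudson(0, 0, 100, 100)))
})

test_that("Hudson and Weir-Cockerham agree on balanced simulated samples", {
  g <- simulate_genotypes(c(P1 = 300, P2 = 300), 50, 10, fst_target = 0.1,
                          ld_decay = 0.4, seed = 17)
  p1 <- colMeans(g$dosage[g$samples$population == "P1", ]) / 2
  p2 <- colMeans(g$dosage[g$samples$population == "P2", ]) / 2
  hud <- fst_mean(p1, p2, 300, 300)
  wc <- fst_weir_cockerham(p1, p2, 300, 300)
  expect_lt(abs(hud - wc), 0.02)
})
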
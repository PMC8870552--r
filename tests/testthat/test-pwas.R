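mk_model <- function(weights, vars, cov, strategy = "baseline") {
  structure(list(aptamer = "APT1", gene = "G1", population = "TRAIN",
                 strategy = strategy,
                 weights = data.frame(
                   variant_id = vars$id, chrom = vars$chrom, pos = vars$pos,
                   ref_allele = vars$ref, eff_allele = vars$alt,
                   weight = weights),
                 covariance = cov, rho = 0.5, p = 1e-5),
            class = "prediction_model")
}

mk_gwas <- function(vars, z, flip = rep(FALSE, nrow(vars))) {
  data.frame(variant_id = vars$id, chrom = vars$chrom, pos = vars$pos,
             effect_allele = ifelse(flip, vars$ref, vars$alt),
             other_allele = ifelse(flip, vars$alt, vars$ref),
             beta = z * 0.01, se = 0.01, z = z,
             p = 2 * pnorm(-abs(z)), n = 10000)
}

two_snp_vars <- data.frame(id = c("v1", "v2"), chrom = "1",
                           pos = c(100, 200), ref = "A", alt = "G")

test_that("GWAS harmonization aligns z to the model effect allele", {
  cov <- diag(c(0.5, 0.5)); dimnames(cov) <- list(c("v1", "v2"),
                                                  c("v1", "v2"))
  m <- mk_model(c(1, 1), two_snp_vars, cov)
  hz <- harmonize_gwas(mk_gwas(two_snp_vars, c(2.5, -1)), m)
  expect_equal(hz$z, c(2.5, -1))
  hz_f <- harmonize_gwas(mk_gwas(two_snp_vars, c(2.5, -1),
                                 flip = c(TRUE, FALSE)), m)
  expect_equal(hz_f$z, c(-2.5, -1))
  # mismatching allele pair dropped
  gw <- mk_gwas(two_snp_vars, c(2.5, -1))
  gw$effect_allele[1] <- "C"
  expect_message(hz_m <- harmonize_gwas(gw, m), "mismatch")
  expect_equal(hz_m$variant_id, "v2")
})

test_that("single-SNP association equals the SNP z-score", {
  vars <- two_snp_vars[1, ]
  cov <- matrix(0.48, 1, 1, dimnames = list("v1", "v1"))
  m <- mk_model(0.7, vars, cov)
  res <- spredixcan_assoc(m, mk_gwas(vars, 3.3))
  expect_equal(res$zscore, 3.3)
  # negative weight flips the protein-level direction
  m2 <- mk_model(-0.7, vars, cov)
  expect_equal(spredixcan_assoc(m2, mk_gwas(vars, 3.3))$zscore, -3.3)
})

test_that("the two-SNP hand example reproduces", {
  cov <- matrix(c(0.5, 0.25, 0.25, 0.5), 2,
                dimnames = list(c("v1", "v2"), c("v1", "v2")))
  m <- mk_model(c(1, 1), two_snp_vars, cov)
  res <- spredixcan_assoc(m, mk_gwas(two_snp_vars, c(4, 2)))
  expect_equal(res$zscore, sqrt(0.5) * 6 / sqrt(1.5), tolerance = 1e-12)
  expect_equal(round(res$zscore, 4), 3.4641)
  expect_equal(res$pvalue, 2 * pnorm(-res$zscore))
})

test_that("zero-weight variants and joint allele rewrites leave z unchanged", {
  cov <- matrix(c(0.5, 0.25, 0.25, 0.5), 2,
                dimnames = list(c("v1", "v2"), c("v1", "v2")))
  m <- mk_model(c(1, 0), two_snp_vars, cov)
  z_with <- spredixcan_assoc(m, mk_gwas(two_snp_vars, c(4, 2)))$zscore
  m1 <- mk_model(1, two_snp_vars[1, ],
                 matrix(0.5, 1, 1, dimnames = list("v1", "v1")))
  z_without <- spredixcan_assoc(m1, mk_gwas(two_snp_vars[1, ], 4))$zscore
  expect_equal(z_with, z_without)

  # rewrite both the model and the GWAS orientation for v1
  m_sw <- m
  m_sw$weights$ref_allele[1] <- "G"; m_sw$weights$eff_allele[1] <- "A"
  m_sw$weights$weight[1] <- -1
  z_sw <- spredixcan_assoc(m_sw, mk_gwas(two_snp_vars, c(4, 2)))$zscore
  expect_equal(abs(z_sw), abs(z_with), tolerance = 1e-12)
})

test_that("missing GWAS variants shrink the covariance submatrix consistently", {
  set.seed(10)
  n <- 2000
  X <- matrix(rbinom(n * 3, 2, 0.4), n, 3,
              dimnames = list(NULL, c("v1", "v2", "v3")))
  vars <- data.frame(id = colnames(X), chrom = "1", pos = c(1, 2, 3) * 100,
                     ref = "A", alt = "G")
  w <- c(0.5, -0.3, 0.2)
  cov <- cov(X); dimnames(cov) <- list(vars$id, vars$id)
  m <- mk_model(w, vars, cov)
  y <- as.numeric(X %*% w) + rnorm(n)
  gw <- summarize_gwas(X, y, vars)
  full <- spredixcan_assoc(m, gw)
  part <- spredixcan_assoc(m, gw[-2, ])
  expect_equal(part$n_snps_used, 2)
  expect_equal(part$n_snps_model, 3)
  expect_true(is.finite(part$zscore))
})

test_that("pooled Bonferroni thresholds are computed per strategy", {
  res <- data.frame(
    aptamer = paste0("A", 1:150), gene = "G", trait = rep(c("t1", "t2"), 75),
    population = rep(c("P1", "P2"), each = 75),
    strategy = c(rep("baseline", 100), rep("fm", 50)),
    zscore = rnorm(150), pvalue = runif(150)
  )
  out <- pooled_bonferroni(res)
  expect_equal(unique(out$bonferroni_threshold[out$strategy == "baseline"]),
               0.05 / 100)
  expect_equal(unique(out$bonferroni_threshold[out$strategy == "fm"]),
               0.05 / 50)
  # grouping by trait/population does not change the pooled threshold
  out2 <- pooled_bonferroni(res[order(res$trait, res$population), ])
  expect_equal(sort(out2$bonferroni_threshold),
               sort(out$bonferroni_threshold))
  expect_error(pooled_bonferroni(res[0, ]), "no association")
})

test_that("GWAS summary tables round-trip through TSV", {
  gw <- mk_gwas(two_snp_vars, c(1.2, -0.4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gwas(gw, path)
  gw2 <- read_gwas(path)
  expect_s3_class(gw2, "gwas_summary")
  expect_equal(gw2$z, gw$z)
  expect_equal(gw2$effect_allele, gw$effect_allele)
})

test_that("summary-based z is standard normal under the null", {
  set.seed(11)
  n <- 3000
  zs <- replicate(200, {
    X <- matrix(rbinom(n * 2, 2, 0.4), n, 2,
                dimnames = list(NULL, c("v1", "v2")))
    vars <- two_snp_vars
    cov <- cov(X); dimnames(cov) <- list(vars$id, vars$id)
    m <- mk_model(c(0.5, 0.3), vars, cov)
    y <- rnorm(n)
    spredixcan_assoc(m, summarize_gwas(X, y, vars))$zscore
  })
  expect_gt(ks.test(zs, "pnorm")$p.value, 0.01)
})
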
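test_that("F = 0 collapses the Balding-Nichols draw to the ancestral frequency", {
  g <- simulate_genotypes(c(A = 10, B = 10), 2, 5, fst_target = 0, seed = 1)
  tr <- attr(g, "truth")
  expect_identical(tr$pop_freq[, "A"], tr$ancestral_freq)
  expect_identical(tr$pop_freq[, "B"], tr$ancestral_freq)
})

test_that("dosages are hard calls in {0,1,2} and seeds reproduce bit-exactly", {
  g1 <- simulate_genotypes(c(A = 50, B = 30), 3, 8, 0.1, 0.6, seed = 9)
  g2 <- simulate_genotypes(c(A = 50, B = 30), 3, 8, 0.1, 0.6, seed = 9)
  expect_true(all(g1$dosage %in% 0:2))
  expect_identical(g1$dosage, g2$dosage)
  g3 <- simulate_genotypes(c(A = 50, B = 30), 3, 8, 0.1, 0.6, seed = 10)
  expect_false(identical(g1$dosage, g3$dosage))
})

test_that("invalid differentiation or LD parameters are rejected", {
  expect_error(simulate_genotypes(c(A = 5), 1, 2, fst_target = 1),
               "fst_target")
  expect_error(simulate_genotypes(c(A = 5), 1, 2, ld_decay = 1), "ld_decay")
})

test_that("achieved Hudson F_ST matches the Balding-Nichols target", {
  g <- simulate_genotypes(c(P1 = 500, P2 = 500), n_loci = 100,
                          snps_per_locus = 20, fst_target = 0.1,
                          ld_decay = 0.5, seed = 21)
  p1 <- colMeans(g$dosage[g$samples$population == "P1", ]) / 2
  p2 <- colMeans(g$dosage[g$samples$population == "P2", ]) / 2
  expect_lt(abs(fst_mean(p1, p2, 500, 500) - 0.1), 0.03)
})

test_that("LD decays geometrically along a locus and breaks across loci", {
  g <- simulate_genotypes(c(A = 900), 4, 12, fst_target = 0, ld_decay = 0.7,
                          seed = 5)
  cc <- cor(g$dosage)
  adj <- mean(diag(cc[2:12, 1:11])[1:11])
  lag3 <- mean(sapply(1:9, function(j) cc[j, j + 3]))
  expect_gt(adj, 0.4)
  expect_lt(lag3, adj)
  expect_gt(lag3, 0.05)
  # across-locus pair (last SNP of locus 1, first of locus 2)
  expect_lt(abs(cc[12, 13]), 0.15)
})

test_that("null cis architecture (h2 = 0) shows no dosage-abundance slope", {
  slopes <- replicate(20, {
    pan <- make_panel(n = 200, n_loci = 1, snps = 6, h2 = 0,
                      seed = sample.int(1e6, 1), beta_age = 0, beta_sex = 0,
                      miss2_rate = 0, n_timepoints = 1)
    at <- pan$prot$truth
    raw <- pan$prot$abundance
    y <- log(raw$value[raw$aptamer_id == "APT1"])
    x <- pan$g$dosage[match(raw$sample_id[raw$aptamer_id == "APT1"],
                            pan$g$samples$sample_id), 1]
    coef(lm(y ~ x))[2]
  })
  expect_lt(abs(mean(slopes)), 0.05)
})

test_that("realized heritability matches the h2 target on the latent scale", {
  set.seed(1)
  pan <- make_panel(n = 1000, n_loci = 3, snps = 10, h2 = 0.9, seed = 31,
                    beta_age = 0, beta_sex = 0, timepoint_sd = 0.05,
                    miss2_rate = 0)
  at <- pan$prot$truth$aptamers[["APT1"]]
  raw <- pan$prot$abundance
  raw <- raw[raw$aptamer_id == "APT1", ]
  m <- tapply(log(raw$value), raw$sample_id, mean)
  r2 <- cor(at$genetic_value, m[pan$g$samples$sample_id])^2
  expect_lt(abs(r2 - 0.9), 0.05)
})

test_that("artifact-driven aptamers carry no cis-genetic signal beyond the PAV", {
  pan <- make_panel(n = 300, n_loci = 6, snps = 8, h2 = 0.6, seed = 41,
                    pav_fraction = 0.99, artifact_sd = 1)
  for (at in pan$prot$truth$aptamers) {
    expect_true(at$artifact)
    expect_length(at$causal_ids, 0)
    expect_identical(at$genetic_value, rep(0, 300))
    expect_false(is.na(at$pav_id))
  }
})

test_that("PAV switches off cleanly: zero fraction reproduces the pure cis proteome", {
  g <- simulate_genotypes(c(A = 100), 2, 6, seed = 3)
  p1 <- simulate_proteome(g, h2 = 0.5, seed = 8)
  p2 <- simulate_proteome(g, h2 = 0.5, pav_fraction = 0, artifact_sd = 0,
                          seed = 8)
  expect_identical(p1$abundance, p2$abundance)
})

test_that("aptamers mapped to an absent locus raise an annotation error", {
  g <- simulate_genotypes(c(A = 50), 2, 4, seed = 2)
  ann <- data.frame(aptamer_id = "APTX", gene_id = "G99")
  expect_error(simulate_proteome(g, annotation = ann), "absent locus")
})

test_that("null GWAS (all gamma zero) yields calibrated z-scores", {
  pan <- make_panel(n = 100, n_loci = 10, snps = 10, h2 = 0.5, seed = 51)
  gw <- simulate_gwas_pair(pan$prot$truth,
                           c(APT1 = 0), 2000, 2000, seed = 52)
  z <- gw$discovery$z
  # z-scores within a cohort are LD-correlated, so the mean of 100 of
  # them is noisier than 1/sqrt(100)
  expect_lt(abs(mean(z)), 0.3)
  expect_lt(abs(sd(z) - 1), 0.2)
  expect_lt(abs(mean(gw$discovery$p < 0.05) - 0.05), 0.05)
})

test_that("strong mediation gives power and cross-cohort sign agreement at the causal SNP", {
  hits <- 0; agree <- 0; reps <- 100
  for (i in seq_len(reps)) {
    pan <- make_panel(n = 150, n_loci = 1, snps = 8, h2 = 0.9, seed = 600 + i,
                      beta_age = 0, beta_sex = 0)
    gw <- simulate_gwas_pair(pan$prot$truth, c(APT1 = 0.5), 50000, 50000,
                             seed = 700 + i)
    cid <- pan$prot$truth$aptamers[["APT1"]]$causal_ids[1]
    zd <- gw$discovery$z[gw$discovery$variant_id == cid]
    zr <- gw$replication$z[gw$replication$variant_id == cid]
    if (abs(zd) > 6) hits <- hits + 1
    if (sign(zd) == sign(zr)) agree <- agree + 1
  }
  expect_gt(hits / reps, 0.95)
  expect_gt(agree / reps, 0.95)
})
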
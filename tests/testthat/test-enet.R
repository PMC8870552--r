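test_that("univariate fit matches the closed-form soft-threshold solution", {
  set.seed(1)
  n <- 500
  x <- rnorm(n)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- rnorm(n)
  y <- y - mean(y)
  y <- y - x * mean(x * y) + 0.5 * x   # force x.y/n = 0.5 exactly
  X <- matrix(x, dimnames = list(NULL, "v1"))
  fit <- elastic_net_pf(X, y, c(v1 = 1), alpha = 0.5, lambda = 0.2)
  expect_equal(unname(fit$beta_std), 0.5 / 1.1 - 0.1 / 1.1, tolerance = 1e-9)
  expect_equal(round(unname(fit$beta_std), 5), 0.36364)
  # penalty factor 0 removes all shrinkage: OLS solution
  fit0 <- elastic_net_pf(X, y, c(v1 = 0), alpha = 0.5, lambda = 0.2)
  expect_equal(unname(fit0$beta_std), 0.5, tolerance = 1e-9)
})

test_that("lambda = 0 recovers least squares and every fit passes KKT", {
  set.seed(2)
  X <- matrix(rnorm(300 * 6), 300, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- as.numeric(X %*% c(1, -0.5, 0, 0, 0.3, 0) + rnorm(300))
  pens <- setNames(rep(1, 6), colnames(X))
  f0 <- elastic_net_pf(X, y, pens, alpha = 0.5, lambda = 0)
  ols <- coef(lm(y ~ X))[-1]
  expect_equal(unname(f0$weights), unname(ols), tolerance = 1e-6)
  for (lam in c(0.01, 0.05, 0.2)) {
    f <- elastic_net_pf(X, y, pens, alpha = 0.5, lambda = lam)
    expect_lt(kkt_violation(X, y, f), 1e-4)
  }
})

test_that("penalty-factor solutions agree with glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  n <- 400
  X <- matrix(rbinom(n * 8, 2, 0.3), n, 8,
              dimnames = list(NULL, paste0("v", 1:8)))
  y <- 0.6 * X[, 2] - 0.4 * X[, 5] + rnorm(n)
  pf <- c(1, 0.2, 1, 1, 0.5, 1, 1, 1)
  lam <- 0.08
  mine <- elastic_net_pf(X, y, setNames(pf, colnames(X)), 0.5, lam)
  gn <- glmnet::glmnet(X, y, alpha = 0.5, penalty.factor = pf,
                       lambda = lam * mean(pf), standardize = TRUE,
                       thresh = 1e-12)
  # glmnet rescales penalty factors to sum to p; compare after matching
  expect_equal(unname(mine$weights), as.numeric(gn$beta), tolerance = 5e-3)
})

test_that("nested CV finds perfect signal and ranks match the Spearman formula", {
  set.seed(4)
  # fractional (imputed-style) dosages avoid rank ties, so the noise-free
  # signal can reach rho near 1
  X <- matrix(runif(200 * 5, 0, 2), 200, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  y <- as.numeric(X[, 1])
  cv <- nested_cv_evaluate(X, y, setNames(rep(1, 5), colnames(X)))
  expect_gt(cv$rho, 0.95)
  expect_lt(cv$p, 1e-10)
  st <- spearman_test(c(3, 1, 2, 5, 4), c(1, 2, 3, 4, 5))
  expect_equal(st$rho, 0.6)
})

test_that("weak models are suppressed by the rho and p filter", {
  set.seed(5)
  X <- matrix(rbinom(120 * 6, 2, 0.3), 120, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  vars <- data.frame(id = colnames(X), chrom = "1", pos = 1:6 * 100,
                     ref = "A", alt = "G")
  y <- rnorm(120)
  m <- train_final_model(X, y, setNames(rep(1, 6), colnames(X)), vars,
                         aptamer = "APT1", gene = "G1")
  expect_null(m)
})

test_that("final models recover the causal variant and store the dosage covariance", {
  set.seed(6)
  n <- 500
  X <- matrix(rbinom(n * 6, 2, 0.35), n, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  y <- 1.0 * X[, 4] + rnorm(n, sd = 0.4)
  vars <- data.frame(id = colnames(X), chrom = "1", pos = 1:6 * 100,
                     ref = "A", alt = "G")
  m <- train_final_model(X, y, setNames(rep(1, 6), colnames(X)), vars,
                         aptamer = "APT1", gene = "G1")
  expect_s3_class(m, "prediction_model")
  top <- m$weights$variant_id[which.max(abs(m$weights$weight))]
  expect_equal(top, "v4")
  expect_true(all(m$weights$variant_id %in% rownames(m$covariance)))
  expect_true(all(eigen(m$covariance, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
  # hand-computed covariance of two dosage vectors
  expect_equal(cov(c(0, 1, 2, 1), c(0, 1, 1, 2)), 1 / 3)
  expect_equal(var(c(0, 1, 2, 1)), 2 / 3)
})

test_that("null proteins pass the significance filter at roughly the nominal rate", {
  set.seed(7)
  n_prot <- 60
  hits <- 0
  for (i in seq_len(n_prot)) {
    X <- matrix(rbinom(150 * 5, 2, 0.3), 150, 5,
                dimnames = list(NULL, paste0("v", 1:5)))
    y <- rnorm(150)
    cv <- nested_cv_evaluate(X, y, setNames(rep(1, 5), colnames(X)),
                             seed = i)
    if (is.finite(cv$rho) && cv$rho > 0.1 && cv$p < 0.05) hits <- hits + 1
  }
  expect_lte(hits / n_prot, 0.05 + 2 * sqrt(0.05 * 0.95 / n_prot))
})

test_that("PAV adjustment uses the 95% variance PC rule", {
  set.seed(8)
  y <- rnorm(200)
  # no PAVs: unchanged and flagged
  out0 <- pav_adjust(y, NULL)
  expect_identical(out0$y, y)
  expect_equal(out0$flag, "unadjusted")
  # constant PAV matrix treated as no PAVs
  outc <- pav_adjust(y, matrix(1, 200, 2))
  expect_equal(outc$flag, "unadjusted")
  # single PAV: one PC explains 100% of variance; residualize on it
  pav <- matrix(rbinom(200, 2, 0.3), dimnames = list(NULL, "pv"))
  out1 <- pav_adjust(y, pav)
  expect_equal(out1$n_pcs_used, 1L)
  expect_lt(abs(cor(out1$y, pav[, 1])), 1e-10)
})

test_that("PAV impact classification follows the delta-rho rules", {
  mk <- function(rho) structure(list(rho = rho, p = 1e-4),
                                class = "prediction_model")
  expect_equal(classify_pav_impact(mk(0.5), mk(0.45)), "marginal")
  expect_equal(classify_pav_impact(mk(0.5), mk(0.35)), "large_retained")
  expect_equal(classify_pav_impact(mk(0.5), NULL), "lost_significance")
  expect_equal(classify_pav_impact(mk(0.5), NULL, adjusted = FALSE),
               "unadjusted")
})

test_that("model bundles serialize to the two-table convention and covariance text", {
  set.seed(9)
  n <- 300
  X <- matrix(rbinom(n * 4, 2, 0.4), n, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  y <- X[, 1] * 0.8 + rnorm(n, sd = 0.5)
  vars <- data.frame(id = colnames(X), chrom = "1", pos = 1:4 * 50,
                     ref = "A", alt = "G")
  m <- train_final_model(X, y, setNames(rep(1, 4), colnames(X)), vars,
                         aptamer = "APT1", gene = "G1")
  prefix <- withr::local_tempfile()
  write_model_bundle(list(m), prefix)
  w <- read.delim(paste0(prefix, "_weights.tsv"))
  e <- read.delim(paste0(prefix, "_extra.tsv"))
  expect_setequal(names(w), c("gene", "rsid", "varID", "ref_allele",
                              "eff_allele", "weight"))
  expect_equal(e$n_snps_in_model, nrow(w))
  cv <- read.table(gzfile(paste0(prefix, "_covariances.txt.gz")),
                   header = TRUE)
  expect_equal(names(cv), c("GENE", "RSID1", "RSID2", "VALUE"))
  expect_equal(nrow(cv), nrow(w) * (nrow(w) + 1) / 2)
})
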
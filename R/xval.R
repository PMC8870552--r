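#' Predict protein abundance in an external cohort
#'
#' Matches model variants to the cohort by `chrom:pos`; when the cohort's
#' ref/alt orientation is swapped relative to the model, the dosage is
#' flipped (`2 - dosage`). Variants with alleles matching in neither
#' orientation are dropped with a message. Only matched variants that are
#' polymorphic (MAF > `maf_min`) in the test cohort contribute; a model
#' with no matched-and-polymorphic variant yields no prediction (`NULL`).
#' Unmatched model variants contribute 0.
#'
#' @param model `prediction_model`.
#' @param g test-cohort `genotype_matrix`.
#' @param maf_min polymorphism threshold in the test cohort (default
#'   0.01).
#' @return named numeric vector of predictions (one per cohort sample),
#'   or `NULL`.
#' @export
predict_external <- function(model, g, maf_min = 0.01) {
  w <- model$weights
  key_g <- paste(g$variants$chrom, g$variants$pos, sep = ":")
  key_m <- paste(w$chrom, w$pos, sep = ":")
  gi <- match(key_m, key_g)
  pred <- rep(0, nrow(g$dosage))
  test_maf <- maf(g)
  used <- 0L
  for (i in seq_len(nrow(w))) {
    j <- gi[i]
    if (is.na(j)) next
    same <- g$variants$ref[j] == w$ref_allele[i] &&
      g$variants$alt[j] == w$eff_allele[i]
    swap <- g$variants$ref[j] == w$eff_allele[i] &&
      g$variants$alt[j] == w$ref_allele[i]
    if (!same && !swap) {
      message("allele mismatch for ", w$variant_id[i], "; dropped")
      next
    }
    if (test_maf[j] <= maf_min) next
    d <- if (same) g$dosage[, j] else 2 - g$dosage[, j]
    pred <- pred + w$weight[i] * d
    used <- used + 1L
  }
  if (used == 0L) return(NULL)
  stats::setNames(pred, g$samples$sample_id)
}

#' Prediction accuracy as Spearman correlation
#'
#' @param predicted,observed aligned vectors, `n >= 10`.
#' @return list `rho`, `p`, `n`; `rho` is `NA` for a constant predicted
#'   vector.
#' @export
evaluate_prediction <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 10)
  spearman_test(predicted, observed)
}

#' Paired comparison of model performance (Wilcoxon signed-rank)
#'
#' Two-sided signed-rank test on paired Spearman correlations (typically
#' over the intersection of proteins predicted by both model sets). Zero
#' differences are dropped (Wilcoxon's rule); the null distribution is
#' exact by enumeration for up to 12 nonzero untied pairs, and a normal
#' approximation with continuity correction otherwise.
#'
#' @param rho_a,rho_b paired performance vectors.
#' @param exact_max largest n for which the exact null is used.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (on `rho_a - rho_b`).
#' @return list: `p`, `statistic` (V), `n` nonzero pairs.
#' @export
compare_paired <- function(rho_a, rho_b, exact_max = 12,
                           alternative = "two.sided") {
  stopifnot(length(rho_a) == length(rho_b))
  d <- rho_a - rho_b
  d <- d[is.finite(d) & d != 0]
  if (length(d) < 3) stop("fewer than 3 nonzero paired differences")
  exact <- length(d) <= exact_max && !anyDuplicated(abs(d))
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE,
                       alternative = alternative))
  list(p = wt$p.value, statistic = unname(wt$statistic), n = length(d))
}

#' Mann-Whitney rank-sum comparison of model F_ST between performance groups
#'
#' For each threshold `t`, splits models into large (`|delta rho| > t`)
#' and small (`|delta rho| <= t`) cross-population performance-difference
#' groups and tests whether their mean model F_ST distributions differ
#' (two-sided rank-sum; exact for small untied groups, normal
#' approximation otherwise).
#'
#' @param delta_rho per-protein performance difference between two
#'   training populations on the same test cohort.
#' @param model_fst per-protein mean model-SNP F_ST between training and
#'   test cohort.
#' @param thresholds numeric vector of `t` values.
#' @return data frame: `t, n_large, n_small, W, p, mean_fst_large,
#'   mean_fst_small`; thresholds with an empty group are skipped with a
#'   warning.
#' @export
fst_performance_groups <- function(delta_rho, model_fst,
                                   thresholds = c(0.05, 0.1, 0.2)) {
  stopifnot(length(delta_rho) == length(model_fst))
  out <- lapply(thresholds, function(t) {
    large <- abs(delta_rho) > t
    if (!any(large) || all(large)) {
      warning(sprintf("threshold t=%g leaves an empty group; skipped", t))
      return(NULL)
    }
    x <- model_fst[large]
    y <- model_fst[!large]
    exact <- length(x) + length(y) <= 20 && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    data.frame(t = t, n_large = length(x), n_small = length(y),
               W = unname(wt$statistic), p = wt$p.value,
               mean_fst_large = mean(x), mean_fst_small = mean(y))
  })
  do.call(rbind, out)
}

#' Mean model F_ST between a training and a test cohort
#'
#' Ratio-of-averages Hudson F_ST over the model's SNPs, from allele
#' frequencies in the two cohorts.
#'
#' @param model `prediction_model`.
#' @param g_train,g_test `genotype_matrix` objects.
#' @return scalar F_ST (NA when no model SNP is present in both).
#' @export
model_fst <- function(model, g_train, g_test) {
  ids <- model$weights$variant_id
  i1 <- match(ids, g_train$variants$id)
  i2 <- match(ids, g_test$variants$id)
  ok <- !is.na(i1) & !is.na(i2)
  if (!any(ok)) return(NA_real_)
  p1 <- colMeans(g_train$dosage[, i1[ok], drop = FALSE]) / 2
  p2 <- colMeans(g_test$dosage[, i2[ok], drop = FALSE]) / 2
  fst_mean(p1, p2, nrow(g_train$dosage), nrow(g_test$dosage))
}
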
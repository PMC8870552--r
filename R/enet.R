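# Internal: standardize to mean 0 and (1/n)-variance 1, recording the
# transform so weights can be reported on the raw dosage scale.
std_design <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sdn <- sqrt(colMeans(X^2) - mu^2)
  list(X = sweep(sweep(X, 2, mu), 2, pmax(sdn, .Machine$double.eps), "/"),
       mu = mu, sd = sdn)
}

#' Penalty-factor elastic net fit at a single lambda
#'
#' Cyclic coordinate descent for
#' `(1/2n) ||y - Xb||^2 + lambda * sum_j pf_j (alpha |b_j| + (1-alpha)/2 b_j^2)`.
#' Columns are standardized internally; returned weights are on the raw
#' dosage scale. A penalty factor of 0 leaves the feature unpenalized
#' (always kept); factor 1 is standard penalization. Only columns named in
#' `penalties` enter the design.
#'
#' @param X dosage matrix with named columns.
#' @param y response vector.
#' @param penalties named vector, variant -> penalty factor in `[0, 1]`;
#'   baseline models use 1 for every column.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param lambda penalty scale.
#' @param tol convergence tolerance on the maximum coefficient change
#'   (standardized scale).
#' @return list: `weights` (named, raw scale), `intercept`, `beta_std`
#'   (standardized scale, for KKT checks), `lambda`, `alpha`.
#' @export
elastic_net_pf <- function(X, y, penalties, alpha = 0.5, lambda,
                           tol = 1e-7) {
  X <- as.matrix(X)[, names(penalties), drop = FALSE]
  sd0 <- apply(X, 2, stats::sd) == 0
  if (any(sd0)) {
    X <- X[, !sd0, drop = FALSE]
    penalties <- penalties[!sd0]
  }
  if (ncol(X) == 0L) stop("no non-constant columns in the design")
  std <- std_design(X)
  yc <- y - mean(y)
  B <- enet_cd_path(std$X, yc, as.numeric(penalties), alpha,
                    as.numeric(lambda), tol = tol)
  beta_std <- B[, 1]
  w <- beta_std / std$sd
  out <- list(weights = stats::setNames(w, colnames(X)),
              intercept = mean(y) - sum(w * std$mu),
              beta_std = stats::setNames(beta_std, colnames(X)),
              lambda = lambda, alpha = alpha)
  attr(out, "pf") <- as.numeric(penalties)
  out
}

#' KKT subgradient residuals of an elastic-net solution
#'
#' On the standardized scale, optimality requires
#' `x_j' r / n = lambda alpha pf_j s_j + lambda (1-alpha) pf_j b_j` with
#' `s_j = sign(b_j)` for nonzero coefficients and `|s_j| <= 1` otherwise.
#' Returns the worst violation across coordinates (0 when all conditions
#' hold).
#'
#' @param X,y design and response as passed to [elastic_net_pf()].
#' @param fit result of [elastic_net_pf()].
#' @return maximum KKT violation (numeric scalar).
#' @export
kkt_violation <- function(X, y, fit) {
  X <- as.matrix(X)[, names(fit$beta_std), drop = FALSE]
  std <- std_design(X)
  yc <- y - mean(y)
  b <- fit$beta_std
  pf <- attr(fit, "pf")
  if (is.null(pf)) pf <- rep(1, length(b))
  r <- yc - std$X %*% b
  grad <- as.numeric(crossprod(std$X, r)) / nrow(X)
  lam <- fit$lambda
  a <- fit$alpha
  viol <- ifelse(
    b != 0,
    abs(grad - lam * a * pf * sign(b) - lam * (1 - a) * pf * b),
    pmax(abs(grad) - lam * a * pf, 0)
  )
  max(viol)
}

# lambda path: nlambda log-spaced points from lambda_max (the smallest
# lambda zeroing all pf>0 columns) down to ratio*lambda_max.
lambda_path <- function(Xs, yc, pf, alpha, nlambda = 100, ratio = 0.01) {
  n <- nrow(Xs)
  grad <- abs(as.numeric(crossprod(Xs, yc))) / n
  pos <- pf > 0
  if (!any(pos)) return(0)
  lmax <- max(grad[pos] / (alpha * pf[pos]))
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * ratio), length.out = nlambda))
}

# Inner k-fold CV over the lambda path; returns mean validation MSE per
# lambda. Fold labels are supplied by the caller (seeded there).
cv_mse_path <- function(X, y, pf, alpha, folds, lambdas) {
  as.numeric(cv_mse_path_cpp(as.matrix(X), y, as.numeric(pf), alpha,
                             as.integer(folds), as.numeric(lambdas)))
}

#' Nested cross-validated performance of a penalty-factor elastic net
#'
#' Outer folds (default 5) give out-of-fold predictions; within each outer
#' training set, the inner folds (default 10) choose the lambda minimizing
#' cross-validated MSE on a 100-point log-spaced path from `lambda_max`
#' down to `0.01 lambda_max`. Performance is the Spearman correlation
#' between the concatenated out-of-fold predictions and the observed
#' response, with the t-approximation p-value.
#'
#' @inheritParams elastic_net_pf
#' @param outer_folds,inner_folds fold counts.
#' @param seed seed for the fold assignments.
#' @param nlambda,lambda_min_ratio lambda path shape.
#' @return list: `rho`, `p`, `n`, per-fold chosen lambdas.
#' @export
nested_cv_evaluate <- function(X, y, penalties, alpha = 0.5,
                               outer_folds = 5, inner_folds = 10,
                               seed = 42, nlambda = 100,
                               lambda_min_ratio = 0.01) {
  X <- as.matrix(X)[, names(penalties), drop = FALSE]
  n <- nrow(X)
  stopifnot(n >= 25)
  pf <- as.numeric(penalties)
  set.seed(seed)
  fold <- sample(rep(seq_len(outer_folds), length.out = n))
  pred <- rep(NA_real_, n)
  lambda_used <- numeric(outer_folds)
  for (f in seq_len(outer_folds)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    keep <- apply(Xtr, 2, stats::sd) > 0
    if (!any(keep)) next
    std <- std_design(Xtr[, keep, drop = FALSE])
    lambdas <- lambda_path(std$X, ytr - mean(ytr), pf[keep], alpha,
                           nlambda, lambda_min_ratio)
    inner <- sample(rep(seq_len(inner_folds), length.out = sum(tr)))
    mse <- cv_mse_path(Xtr[, keep, drop = FALSE], ytr, pf[keep], alpha,
                       inner, lambdas)
    lam <- lambdas[which.min(mse)]
    lambda_used[f] <- lam
    fit <- elastic_net_pf(Xtr[, keep, drop = FALSE], ytr,
                          penalties[keep], alpha, lam)
    pred[!tr] <- X[!tr, names(fit$weights), drop = FALSE] %*% fit$weights +
      fit$intercept
  }
  ok <- !is.na(pred)
  st <- spearman_test(pred[ok], y[ok])
  list(rho = st$rho, p = st$p, n = st$n, lambda_used = lambda_used)
}

#' Train the final protein prediction model
#'
#' Evaluates the model by nested cross-validation; if the cross-validated
#' Spearman `rho > 0.1` and `p < 0.05`, refits on all data with lambda
#' chosen by 10-fold cross-validation and returns the weight set together
#' with the training-dosage covariance of the nonzero-weight variants
#' (denominator `n - 1`), the LD reference later used by the
#' summary-statistic association test.
#'
#' @inheritParams nested_cv_evaluate
#' @param variants data frame with `id, chrom, pos, ref, alt` for the
#'   design columns (matched by variant id).
#' @param aptamer,gene,population,strategy model metadata.
#' @param rho_min,p_max significance filter (defaults 0.1 and 0.05).
#' @return `prediction_model` (list with `weights` table, `covariance`,
#'   `rho`, `p`, `lambda`, `alpha`, `n_train`, metadata), or `NULL` when
#'   the model fails the filter or has no nonzero weights.
#' @export
train_final_model <- function(X, y, penalties, variants, alpha = 0.5,
                              seed = 42, aptamer = "", gene = "",
                              population = "ALL", strategy = "baseline",
                              rho_min = 0.1, p_max = 0.05) {
  if (!length(penalties)) return(NULL)
  X <- as.matrix(X)[, names(penalties), drop = FALSE]
  cv <- nested_cv_evaluate(X, y, penalties, alpha, seed = seed)
  if (!is.finite(cv$rho) || cv$rho <= rho_min || cv$p >= p_max) return(NULL)

  set.seed(seed + 1L)
  keep <- apply(X, 2, stats::sd) > 0
  Xk <- X[, keep, drop = FALSE]
  pf <- as.numeric(penalties)[keep]
  std <- std_design(Xk)
  lambdas <- lambda_path(std$X, y - mean(y), pf, alpha)
  folds <- sample(rep(1:10, length.out = nrow(Xk)))
  mse <- cv_mse_path(Xk, y, pf, alpha, folds, lambdas)
  lam <- lambdas[which.min(mse)]
  fit <- elastic_net_pf(Xk, y, penalties[keep], alpha, lam)
  nz <- names(fit$weights)[fit$weights != 0]
  if (!length(nz)) return(NULL)

  vi <- variants[match(nz, variants$id), , drop = FALSE]
  weights <- data.frame(
    variant_id = nz, chrom = vi$chrom, pos = vi$pos,
    ref_allele = vi$ref, eff_allele = vi$alt,
    weight = unname(fit$weights[nz]), stringsAsFactors = FALSE
  )
  covariance <- stats::cov(Xk[, nz, drop = FALSE])
  structure(list(
    aptamer = aptamer, gene = gene, population = population,
    strategy = strategy, weights = weights, covariance = covariance,
    rho = cv$rho, p = cv$p, lambda = lam, alpha = alpha,
    n_train = nrow(Xk), intercept = fit$intercept
  ), class = "prediction_model")
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf(
    "prediction_model %s (%s, %s/%s): %d SNPs, cv rho=%.3f p=%.2g\n",
    x$aptamer, x$gene, x$population, x$strategy, nrow(x$weights),
    x$rho, x$p))
  invisible(x)
}

#' Adjust abundance for protein-altering-variant genotypes
#'
#' PCA on the PAV dosage matrix; the response is residualized on the
#' smallest number of leading components whose cumulative explained
#' variance reaches 95%. With no (or constant) PAV genotypes the response
#' is returned unchanged and flagged `"unadjusted"`; the PAV columns are
#' meant to be removed from the prediction design by the caller.
#'
#' @param y abundance vector.
#' @param pav_genotypes dosage matrix of PAVs in the cis window (may have
#'   zero columns).
#' @param var_target cumulative explained-variance target (default 0.95).
#' @return list: `y` (possibly residualized), `n_pcs_used`, `flag`
#'   (`"adjusted"` or `"unadjusted"`).
#' @export
pav_adjust <- function(y, pav_genotypes, var_target = 0.95) {
  if (is.null(pav_genotypes) || NCOL(pav_genotypes) == 0L) {
    return(list(y = y, n_pcs_used = 0L, flag = "unadjusted"))
  }
  pav_genotypes <- as.matrix(pav_genotypes)
  keep <- apply(pav_genotypes, 2, stats::sd) > 0
  if (!any(keep)) {
    return(list(y = y, n_pcs_used = 0L, flag = "unadjusted"))
  }
  pc <- stats::prcomp(pav_genotypes[, keep, drop = FALSE], center = TRUE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= var_target)[1]
  list(y = residualize(y, pc$x[, seq_len(k), drop = FALSE]),
       n_pcs_used = k, flag = "adjusted")
}

#' Classify the impact of PAV adjustment on a model
#'
#' @param before significant `prediction_model` trained without PAV
#'   adjustment.
#' @param after PAV-adjusted `prediction_model`, or `NULL` when the
#'   adjusted model failed the significance filter.
#' @param adjusted whether any PAV adjustment was applied (`FALSE` when no
#'   PAV was present in the window).
#' @return one of `"unadjusted"`, `"marginal"` (delta rho < 0.1),
#'   `"large_retained"` (delta rho >= 0.1, still significant),
#'   `"lost_significance"`.
#' @export
classify_pav_impact <- function(before, after, adjusted = TRUE) {
  stopifnot(inherits(before, "prediction_model"))
  if (!adjusted) return("unadjusted")
  if (is.null(after)) return("lost_significance")
  if (before$rho - after$rho < 0.1) "marginal" else "large_retained"
}

#' Write prediction models as a PredictDB-convention text bundle
#'
#' Two relational tables -- `weights` (gene, rsid, varID
#' `chr_pos_ref_alt_b38`, ref_allele, eff_allele, weight) and `extra`
#' (gene, genename, n_snps_in_model, pred_perf_rho, pred_perf_pval,
#' strategy, population) -- written as TSV, plus the training LD bundle as
#' gzipped whitespace text `GENE RSID1 RSID2 VALUE`.
#'
#' @param models list of `prediction_model`s.
#' @param prefix output path prefix; writes `<prefix>_weights.tsv`,
#'   `<prefix>_extra.tsv`, `<prefix>_covariances.txt.gz`.
#' @return prefix, invisibly.
#' @export
write_model_bundle <- function(models, prefix) {
  models <- Filter(Negate(is.null), models)
  weights <- do.call(rbind, lapply(models, function(m) {
    data.frame(gene = m$gene, rsid = m$weights$variant_id,
               varID = paste(paste0("chr", m$weights$chrom), m$weights$pos,
                             m$weights$ref_allele, m$weights$eff_allele,
                             "b38", sep = "_"),
               ref_allele = m$weights$ref_allele,
               eff_allele = m$weights$eff_allele,
               weight = m$weights$weight, stringsAsFactors = FALSE)
  }))
  extra <- do.call(rbind, lapply(models, function(m) {
    data.frame(gene = m$gene, genename = m$aptamer,
               n_snps_in_model = nrow(m$weights), pred_perf_rho = m$rho,
               pred_perf_pval = m$p, strategy = m$strategy,
               population = m$population, stringsAsFactors = FALSE)
  }))
  data.table::fwrite(weights, paste0(prefix, "_weights.tsv"), sep = "\t")
  data.table::fwrite(extra, paste0(prefix, "_extra.tsv"), sep = "\t")
  con <- gzfile(paste0(prefix, "_covariances.txt.gz"), "w")
  writeLines("GENE RSID1 RSID2 VALUE", con)
  for (m in models) {
    ids <- rownames(m$covariance)
    for (i in seq_along(ids)) for (j in i:length(ids)) {
      writeLines(paste(m$gene, ids[i], ids[j],
                       format(m$covariance[i, j], digits = 8)), con)
    }
  }
  close(con)
  invisible(prefix)
}
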
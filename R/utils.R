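#' Log-sum-exp
#'
#' Numerically stable `log(sum(exp(x)))`, used wherever Bayes factors are
#' combined on the log scale.
#'
#' @param x numeric vector of log values (may contain `-Inf`).
#' @return scalar `log(sum(exp(x)))`.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Spearman correlation with t-approximation p-value
#'
#' Spearman's rho with average ranks, and the two-sided p-value from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df.
#'
#' @param predicted,observed aligned numeric vectors.
#' @return list with `rho`, `p` and `n`. `rho` is `NA` when either vector is
#'   constant (rank correlation undefined).
#' @export
spearman_test <- function(predicted, observed) {
  keep <- is.finite(predicted) & is.finite(observed)
  predicted <- predicted[keep]
  observed <- observed[keep]
  n <- length(predicted)
  if (n < 3L || stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(predicted, observed, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Least-squares residuals against a covariate matrix
#'
#' Residualizes `y` on an intercept plus the supplied covariates. Collinear
#' covariate columns are dropped (pivoted QR) with a warning, so the fit is
#' always full rank.
#'
#' @param y numeric response vector.
#' @param covariates numeric matrix (rows aligned with `y`), or `NULL` for
#'   intercept-only centering.
#' @return residual vector; orthogonal to every retained covariate column.
#' @export
residualize <- function(y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    return(y - mean(y))
  }
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == length(y))
  X <- cbind(`(Intercept)` = 1, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X)), keep)
    warning(sprintf("dropping %d collinear covariate column(s)", length(dropped)))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  as.numeric(qr.resid(qrX, y))
}

#' Variant key chrom:pos:ref:alt
#' @keywords internal
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
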
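#' Rank inverse-normal transformation
#'
#' `qnorm((rank - 0.5) / n)` with average ranks for ties. The transformed
#' values are standard-normal quantiles, mean zero by symmetry for
#' all-distinct inputs.
#'
#' @param values numeric vector (>= 3 finite values, not all identical).
#' @return transformed vector, same order as input.
#' @export
rank_inverse_normalize <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 3L) stop("need at least 3 finite values")
  if (stats::sd(values[ok]) == 0) stop("all values identical; ranks degenerate")
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.5) / sum(ok))
  out
}

#' Prepare adjusted protein abundance
#'
#' The full preparation chain for aptamer abundances, applied in this
#' order: natural log of each timepoint; per-timepoint residualization on
#' the covariates (age and sex by default); mean across available
#' timepoints (a sample measured at only one timepoint keeps that
#' timepoint's adjusted value as its mean); rank inverse-normal
#' transformation; residualization on the first `n_pcs` genotype principal
#' components.
#'
#' @param raw long-format abundance data frame (`sample_id`, `aptamer_id`,
#'   `timepoint`, `value`), values strictly positive.
#' @param covariates data frame with `sample_id` and the columns named in
#'   `covariate_names`.
#' @param pcs sample x component score matrix (rownames = sample ids), or
#'   `NULL` when `n_pcs = 0`.
#' @param n_pcs number of leading components to adjust for (default 10).
#' @param covariate_names per-timepoint adjustment covariates
#'   (default `c("age", "sex")`; an external-cohort convention with a
#'   different covariate list reuses this argument).
#' @return `abundance_matrix`: list with `values` (samples x aptamers,
#'   adjusted stage, no missing values), `stage = "adjusted"`, and the
#'   covariate table.
#' @export
prepare_abundance <- function(raw, covariates, pcs = NULL, n_pcs = 10,
                              covariate_names = c("age", "sex")) {
  stopifnot(all(c("sample_id", "aptamer_id", "timepoint", "value") %in%
                  names(raw)))
  bad <- which(!is.finite(raw$value) | raw$value <= 0)
  if (length(bad)) {
    stop(sprintf("nonpositive abundance for sample %s, aptamer %s",
                 raw$sample_id[bad[1]], raw$aptamer_id[bad[1]]))
  }
  if (n_pcs > 0) {
    if (is.null(pcs)) stop("n_pcs > 0 but no PC scores supplied")
    if (n_pcs > ncol(pcs)) stop("n_pcs exceeds available components")
  }
  samples <- unique(raw$sample_id)
  aptamers <- unique(raw$aptamer_id)
  cov_idx <- match(samples, covariates$sample_id)
  if (anyNA(cov_idx)) stop("covariates missing for some samples")
  covmat <- as.matrix(covariates[cov_idx, covariate_names, drop = FALSE])

  # per-timepoint: log then residualize on covariates, for all aptamers
  tps <- sort(unique(raw$timepoint))
  acc <- matrix(0, length(samples), length(aptamers),
                dimnames = list(samples, aptamers))
  cnt <- matrix(0L, length(samples), length(aptamers),
                dimnames = list(samples, aptamers))
  for (tp in tps) {
    sub <- raw[raw$timepoint == tp, , drop = FALSE]
    si <- match(sub$sample_id, samples)
    ai <- match(sub$aptamer_id, aptamers)
    lv <- log(sub$value)
    for (a in seq_along(aptamers)) {
      rows <- which(ai == a)
      if (!length(rows)) next
      res <- residualize(lv[rows], covmat[si[rows], , drop = FALSE])
      acc[cbind(si[rows], a)] <- acc[cbind(si[rows], a)] + res
      cnt[cbind(si[rows], a)] <- cnt[cbind(si[rows], a)] + 1L
    }
  }
  if (any(cnt == 0L)) stop("some sample x aptamer pairs have no measurement")
  mean_adj <- acc / cnt

  int <- apply(mean_adj, 2, rank_inverse_normalize)
  if (n_pcs > 0) {
    pc_sub <- pcs[match(samples, rownames(pcs)), seq_len(n_pcs), drop = FALSE]
    if (anyNA(pc_sub)) stop("PC scores missing for some samples")
    int <- apply(int, 2, residualize, covariates = pc_sub)
  }
  dimnames(int) <- list(samples, aptamers)
  structure(list(values = int, stage = "adjusted",
                 covariates = covariates[cov_idx, , drop = FALSE]),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix (%s): %d samples x %d aptamers\n",
              x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write / read an adjusted abundance matrix as wide TSV
#' @param a `abundance_matrix`.
#' @param path TSV file.
#' @return `path` invisibly / `abundance_matrix`.
#' @export
write_abundance <- function(a, path) {
  out <- data.frame(sample_id = rownames(a$values), a$values,
                    check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  values <- as.matrix(dt[, -1, drop = FALSE])
  rownames(values) <- dt[[1]]
  structure(list(values = values, stage = "adjusted", covariates = NULL),
            class = "abundance_matrix")
}
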
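#' Log Bayes factor of a variant subset under a Zellner g-prior
#'
#' Compares the linear model of `y` on the (standardized) columns of
#' `X_subset` against the intercept-only model:
#' `log BF = ((n-1-k)/2) log(1+g) - ((n-1)/2) log(1 + g (1 - R^2))`
#' with `k` the number of linearly independent predictors and `R^2` from
#' least squares on the subset. Perfectly collinear columns are dropped
#' (smallest index retained) with a message.
#'
#' @param y response vector.
#' @param X_subset matrix of one or more predictor columns.
#' @param g_prior scalar g (default `length(y)`, the unit-information
#'   choice).
#' @return scalar natural-log Bayes factor.
#' @export
model_log_bf <- function(y, X_subset, g_prior = length(y)) {
  X_subset <- as.matrix(X_subset)
  n <- length(y)
  stopifnot(nrow(X_subset) == n, ncol(X_subset) >= 1, n > ncol(X_subset) + 1)
  Xs <- scale(X_subset)
  qrX <- qr(Xs)
  if (qrX$rank < ncol(Xs)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    message(sprintf("dropping %d collinear column(s) from subset",
                    ncol(Xs) - length(keep)))
    Xs <- Xs[, keep, drop = FALSE]
  }
  k <- ncol(Xs)
  yc <- y - mean(y)
  fit <- stats::lm.fit(Xs, yc)
  r2 <- 1 - sum(fit$residuals^2) / sum(yc^2)
  zellner_log_bf(n, k, r2, g_prior)
}

zellner_log_bf <- function(n, k, r2, g) {
  ((n - 1 - k) / 2) * log(1 + g) - ((n - 1) / 2) * log(1 + g * (1 - r2))
}

#' Exhaustive Bayesian fine-mapping of a cis locus
#'
#' Enumerates all variant subsets of size at most `K` (plus the null
#' model), scores each with the g-prior Bayes factor and the independence
#' prior `pi^|S| (1-pi)^(p-|S|)`, normalizes to posterior model
#' probabilities, and reports per-variant posterior inclusion
#' probabilities (PIPs). Variants are then grouped into LD signal
#' clusters: seeds are taken in descending PIP order (ties broken by
#' smaller genomic position) and unassigned variants join a seed's cluster
#' when their `r^2` with the seed is at least `cluster_r2`.
#'
#' When the subset count `sum_(k<=K) C(p, k)` exceeds `max_models`, the
#' locus is screened to the most marginally correlated variants so that
#' enumeration stays under the cap; screened-out variants receive PIP 0.
#'
#' @param y adjusted abundance vector.
#' @param X_locus dosage matrix for the locus (columns named by variant).
#' @param prior_pi per-variant prior inclusion probability (default
#'   `1/p`, one expected causal variant per locus).
#' @param K maximum model size (default 3).
#' @param cluster_r2 LD threshold for cluster membership (default 0.25).
#' @param max_models enumeration cap before marginal screening kicks in.
#' @param positions optional genomic positions for tie-breaking.
#' @return `fine_map_result`: list with `variants` (data frame `id, pip,
#'   cluster, cluster_pip, prior`), `prior_pi`, `K`, `log_norm`, and
#'   `models` (top 50 models with log BF and posterior, for audit).
#' @export
enumerate_posteriors <- function(y, X_locus, prior_pi = NULL, K = 3,
                                 cluster_r2 = 0.25, max_models = 2e5,
                                 positions = NULL) {
  X_locus <- as.matrix(X_locus)
  p <- ncol(X_locus)
  if (p == 0L) stop("locus has no variants")
  stopifnot(K >= 1)
  n <- nrow(X_locus)
  ids <- colnames(X_locus)
  if (is.null(ids)) ids <- paste0("v", seq_len(p))
  if (is.null(prior_pi)) prior_pi <- 1 / p
  if (is.null(positions)) positions <- seq_len(p)

  sds <- apply(X_locus, 2, stats::sd)
  usable <- which(sds > 0)
  yc <- (y - mean(y)) / stats::sd(y)
  Xs <- scale(X_locus[, usable, drop = FALSE])
  cy <- as.numeric(crossprod(Xs, yc)) / (n - 1)

  n_models <- function(np) sum(choose(np, seq_len(min(K, np))))
  active <- seq_along(usable)
  if (n_models(length(usable)) > max_models) {
    ord <- order(-abs(cy))
    m_keep <- length(usable)
    while (m_keep > 1 && n_models(m_keep) > max_models) m_keep <- m_keep - 1
    active <- sort(ord[seq_len(m_keep)])
  }
  Xa <- Xs[, active, drop = FALSE]
  ca <- cy[active]
  pa <- length(active)
  C <- stats::cor(Xa)
  g <- n

  # log posterior weight for a model of size k with fit r2
  lw <- function(k, r2) {
    zellner_log_bf(n, k, r2, g) + k * log(prior_pi) +
      (p - k) * log1p(-prior_pi)
  }

  subsets_by_k <- list()   # k -> k x n_k matrix of column indices into Xa
  lw_by_k <- list()        # k -> model log posterior weights
  r2_1 <- pmin(ca^2, 1)
  subsets_by_k[["1"]] <- matrix(seq_len(pa), nrow = 1)
  lw_by_k[["1"]] <- lw(1L, r2_1)
  if (K >= 2 && pa >= 2) {
    pairs <- utils::combn(pa, 2)
    rho <- C[t(pairs)]
    c1 <- ca[pairs[1, ]]; c2 <- ca[pairs[2, ]]
    denom <- 1 - rho^2
    r2_2 <- ifelse(denom > 1e-12,
                   (c1^2 + c2^2 - 2 * c1 * c2 * rho) / denom,
                   pmax(c1^2, c2^2))
    subsets_by_k[["2"]] <- pairs
    lw_by_k[["2"]] <- lw(2L, pmin(pmax(r2_2, 0), 1))
  }
  if (K >= 3 && pa >= 3) {
    for (k in 3:min(K, pa)) {
      subs <- utils::combn(pa, k)
      r2k <- vapply(seq_len(ncol(subs)),
                    function(m) subset_r2(C, ca, subs[, m]), numeric(1))
      subsets_by_k[[as.character(k)]] <- subs
      lw_by_k[[as.character(k)]] <- lw(k, r2k)
    }
  }

  lw_null <- p * log1p(-prior_pi)
  model_lw <- c(lw_null, unlist(lw_by_k, use.names = FALSE))
  lz <- logsumexp(model_lw)
  post <- exp(model_lw - lz)

  pip_active <- numeric(pa)
  off <- 1L  # skip null
  for (k in names(subsets_by_k)) {
    subs <- subsets_by_k[[k]]
    pk <- post[off + seq_len(ncol(subs))]
    sums <- rowsum(rep(pk, each = nrow(subs)), as.integer(subs))
    pip_active[as.integer(rownames(sums))] <-
      pip_active[as.integer(rownames(sums))] + as.numeric(sums)
    off <- off + ncol(subs)
  }
  pip <- numeric(p)
  pip[usable[active]] <- pmin(pip_active, 1)

  # LD signal clusters, greedy by descending PIP
  cluster <- rep(NA_integer_, p)
  r2mat <- matrix(0, p, p)
  r2mat[usable, usable] <- stats::cor(X_locus[, usable, drop = FALSE])^2
  ord <- order(-pip, positions)
  cl <- 0L
  for (j in ord) {
    if (!is.na(cluster[j])) next
    if (pip[j] == 0) break
    cl <- cl + 1L
    members <- which(is.na(cluster) & r2mat[j, ] >= cluster_r2)
    members <- union(j, members)
    cluster[members] <- cl
  }
  cluster_pip <- vapply(seq_len(p), function(j) {
    if (is.na(cluster[j])) pip[j] else sum(pip[cluster == cluster[j]],
                                           na.rm = TRUE)
  }, numeric(1))

  # audit trail: the top posterior models with their log BFs
  sizes <- c(0L, unlist(lapply(names(subsets_by_k), function(k)
    rep(as.integer(k), ncol(subsets_by_k[[k]])))))
  member_str <- c("", unlist(lapply(names(subsets_by_k), function(k)
    apply(subsets_by_k[[k]], 2, function(S)
      paste(ids[usable[active]][S], collapse = ",")))))
  top <- order(-post)[seq_len(min(50, length(post)))]
  models <- data.frame(
    members = member_str[top],
    log_bf = model_lw[top] - (sizes[top] * log(prior_pi) +
                                (p - sizes[top]) * log1p(-prior_pi)),
    posterior = post[top], stringsAsFactors = FALSE
  )

  structure(list(
    variants = data.frame(id = ids, pip = pip, cluster = cluster,
                          cluster_pip = cluster_pip, prior = prior_pi,
                          pos = positions, stringsAsFactors = FALSE),
    prior_pi = prior_pi, K = K, log_norm = lz, models = models
  ), class = "fine_map_result")
}

# R^2 of y on a subset, from the correlation matrix; pseudo-inverse path
# for (near-)collinear subsets.
subset_r2 <- function(C, cy, S) {
  CS <- C[S, S, drop = FALSE]
  cS <- cy[S]
  b <- tryCatch(solve(CS, cS), error = function(e) NULL)
  if (is.null(b)) {
    eg <- eigen(CS, symmetric = TRUE)
    keep <- eg$values > 1e-10
    b <- eg$vectors[, keep, drop = FALSE] %*%
      ((crossprod(eg$vectors[, keep, drop = FALSE], cS)) / eg$values[keep])
  }
  min(max(sum(b * cS), 0), 1)
}

#' Elastic-net penalty factors from fine-mapping PIPs
#'
#' Reduces each LD cluster to its top-PIP member (when `cluster_filter` is
#' set), keeps variants with `PIP > pip_threshold`, and assigns penalty
#' `1 - PIP` to each: PIP 1 gives penalty 0 (the variant is always kept by
#' the elastic net), low PIPs are penalized nearly as usual. Variants
#' failing the threshold are excluded from the design entirely.
#'
#' @param fm `fine_map_result`.
#' @param pip_threshold minimum PIP (exclusive); the conventional choices
#'   are 0, 0.001 and 0.01.
#' @param cluster_filter keep only the top-PIP variant of each cluster.
#' @return named numeric vector, variant id -> penalty in `[0, 1]`; empty
#'   when no variant is eligible.
#' @export
penalty_factors <- function(fm, pip_threshold = 0.001, cluster_filter = TRUE) {
  v <- fm$variants
  eligible <- rep(TRUE, nrow(v))
  if (cluster_filter) {
    for (cl in unique(v$cluster[!is.na(v$cluster)])) {
      idx <- which(v$cluster == cl & !is.na(v$cluster))
      top <- idx[order(-v$pip[idx], v$pos[idx])][1]
      eligible[setdiff(idx, top)] <- FALSE
    }
  }
  eligible <- eligible & v$pip > pip_threshold
  stats::setNames(1 - v$pip[eligible], v$id[eligible])
}

#' Write fine-mapping results to TSV
#' @param fm `fine_map_result`.
#' @param path output file.
#' @param locus locus label column.
#' @export
write_finemap <- function(fm, path, locus = "locus") {
  out <- cbind(locus = locus, fm$variants)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
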
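# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration and plain lm() fits.

# Exact two-sided signed-rank p by exhaustive enumeration of all 2^n sign
# assignments of the absolute differences (no zeros, no ties assumed).
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  ev <- n * (n + 1) / 4
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-12)
}

# Exact two-sided rank-sum p by exhaustive enumeration of all C(n1+n2, n1)
# group assignments.
oracle_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  r <- rank(all_v)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(all_v), n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  ev <- n1 * length(y) / 2
  mean(abs(w_all - ev) >= abs(w_obs - ev) - 1e-12)
}

# Brute-force fine-mapping: every subset of size <= K scored with the
# g-prior BF computed from a plain lm() fit; posteriors normalized
# directly. Independent of the package's correlation-matrix shortcut.
oracle_finemap_pips <- function(y, X, prior_pi, K, g = length(y)) {
  p <- ncol(X)
  n <- length(y)
  Xs <- scale(X)
  yc <- y - mean(y)
  log_bf <- function(S) {
    k <- length(S)
    fit <- lm(yc ~ Xs[, S, drop = FALSE])
    r2 <- 1 - sum(residuals(fit)^2) / sum(yc^2)
    ((n - 1 - k) / 2) * log(1 + g) - ((n - 1) / 2) * log(1 + g * (1 - r2))
  }
  sets <- list(integer(0))
  for (k in seq_len(K)) {
    sets <- c(sets, utils::combn(p, k, simplify = FALSE))
  }
  lw <- vapply(sets, function(S) {
    bf <- if (length(S)) log_bf(S) else 0
    bf + length(S) * log(prior_pi) + (p - length(S)) * log(1 - prior_pi)
  }, numeric(1))
  post <- exp(lw - max(lw))
  post <- post / sum(post)
  pip <- numeric(p)
  for (i in seq_along(sets)) pip[sets[[i]]] <- pip[sets[[i]]] + post[i]
  pip
}

# Small training panel + proteome used by several tests.
make_panel <- function(n = 400, n_loci = 5, snps = 10, h2 = 0.5,
                       seed = 11, fst = 0.05, ld = 0.7, n_causal = 1, ...) {
  g <- simulate_genotypes(c(TRAIN = n), n_loci, snps, fst_target = fst,
                          ld_decay = ld, seed = seed)
  prot <- simulate_proteome(g, h2 = h2, n_causal = n_causal,
                            seed = seed + 1, ...)
  list(g = g, prot = prot)
}
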
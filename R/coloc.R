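#' Wakefield approximate Bayes factor
#'
#' For a variant with association z-score `z` and standard error `se`,
#' under a normal effect prior with scale `prior_sd`: with shrinkage
#' factor `W/(W + V)` (written `r` below), `V = se^2`, `W = prior_sd^2`,
#' `log ABF = 0.5 log(1 - r) + z^2 r / 2`. Computed and returned on the
#' natural-log scale, stable for |z| up to several tens.
#'
#' @param z z-score(s).
#' @param se standard error(s), > 0.
#' @param prior_sd prior effect-size scale (same units as the betas).
#' @return vector of log ABFs (`NA` where `se <= 0`).
#' @export
wakefield_abf <- function(z, se, prior_sd = 0.15) {
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  out <- 0.5 * log1p(-r) + z^2 * r / 2
  out[!is.finite(se) | se <= 0] <- NA_real_
  out
}

#' Colocalization posteriors from two sets of per-variant log ABFs
#'
#' Standard single-causal-variant-per-trait enumeration over a shared
#' variant set: with per-variant ABFs `A1` (trait 1, e.g. pQTL) and `A2`
#' (trait 2, e.g. GWAS) and priors `p1, p2` (single-trait causality) and
#' `p12` (shared causal variant),
#' `L0 = 1`, `L1 = p1 sum(A1)`, `L2 = p2 sum(A2)`,
#' `L3 = p1 p2 (sum(A1) sum(A2) - sum(A1 A2))`, `L4 = p12 sum(A1 A2)`,
#' normalized to the posteriors P0..P4. All sums use log-sum-exp.
#'
#' @param abf1,abf2 per-variant natural-log ABFs over the identical
#'   (harmonized) variant set; names are variant ids.
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @return `coloc_result`: list with `posteriors` (named P0..P4, summing
#'   to 1), `n_snps`, `top_variant` (largest per-variant joint ABF).
#' @export
coloc_posteriors <- function(abf1, abf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  ok <- is.finite(abf1) & is.finite(abf2)
  abf1 <- abf1[ok]; abf2 <- abf2[ok]
  if (!length(abf1)) stop("no shared variants with finite ABFs")
  stopifnot(length(abf1) == length(abf2))
  ls1 <- logsumexp(abf1)
  ls2 <- logsumexp(abf2)
  ls12 <- logsumexp(abf1 + abf2)
  # log(sum A1 * sum A2 - sum A1A2), guarding the single-variant case
  # where the difference is exactly zero
  gap <- ls12 - (ls1 + ls2)
  l3_core <- if (gap >= 0) -Inf else ls1 + ls2 + log1p(-exp(gap))
  lh <- c(
    H0 = 0,
    H1 = log(p1) + ls1,
    H2 = log(p2) + ls2,
    H3 = log(p1) + log(p2) + l3_core,
    H4 = log(p12) + ls12
  )
  post <- exp(lh - logsumexp(lh))
  names(post) <- paste0("P", 0:4)
  joint <- abf1 + abf2
  top <- if (!is.null(names(joint))) names(joint)[which.max(joint)]
         else as.character(which.max(joint))
  structure(list(posteriors = post, n_snps = length(abf1),
                 top_variant = top), class = "coloc_result")
}

#' Colocalization of a pQTL locus with a GWAS signal
#'
#' Convenience wrapper: harmonizes the GWAS to the pQTL table's effect
#' alleles over the shared variants of one aptamer-gene locus, computes
#' Wakefield log ABFs on both sides (pQTL from in-sample t and se; GWAS
#' from z and se) and returns the five colocalization posteriors.
#'
#' @param pqtl rows of a `pqtl_table` for one aptamer-gene pair.
#' @param gwas `gwas_summary`.
#' @param prior_sd_pqtl,prior_sd_gwas Wakefield prior scales (defaults
#'   0.15, intended for traits on roughly unit scale).
#' @param p1,p2,p12 coloc priors.
#' @return `coloc_result` as in [coloc_posteriors()], or `NULL` when no
#'   variant is shared.
#' @export
coloc_locus <- function(pqtl, gwas, prior_sd_pqtl = 0.15,
                        prior_sd_gwas = 0.15,
                        p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  key_p <- paste(pqtl$chrom, pqtl$pos, sep = ":")
  key_g <- paste(gwas$chrom, gwas$pos, sep = ":")
  gi <- match(key_p, key_g)
  ok <- !is.na(gi)
  if (!any(ok)) return(NULL)
  pq <- pqtl[ok, , drop = FALSE]
  gw <- gwas[gi[ok], , drop = FALSE]
  same <- toupper(gw$effect_allele) == toupper(pq$alt) &
    toupper(gw$other_allele) == toupper(pq$ref)
  swap <- toupper(gw$effect_allele) == toupper(pq$ref) &
    toupper(gw$other_allele) == toupper(pq$alt)
  keep <- same | swap
  if (!any(keep)) return(NULL)
  pq <- pq[keep, , drop = FALSE]
  gw <- gw[keep, , drop = FALSE]
  a1 <- wakefield_abf(pq$t, pq$se, prior_sd_pqtl)
  a2 <- wakefield_abf(gw$z, gw$se, prior_sd_gwas)
  names(a1) <- names(a2) <- pq$variant_id
  coloc_posteriors(a1, a2, p1, p2, p12)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("coloc_result over", x$n_snps, "variants:\n")
  print(round(x$posteriors, 4))
  invisible(x)
}
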
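#' Read / write GWAS summary statistics TSV
#'
#' Columns: `variant_id, chrom, pos, effect_allele, other_allele, beta,
#' se, z, p, n`.
#'
#' @param path TSV file.
#' @return `gwas_summary` data frame.
#' @export
read_gwas <- function(path) {
  gw <- data.table::fread(path, sep = "\t", data.table = FALSE)
  req <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele")
  if (!all(req %in% names(gw))) {
    stop("GWAS table must have columns: ", paste(req, collapse = ", "))
  }
  if (!"z" %in% names(gw) && all(c("beta", "se") %in% names(gw))) {
    gw$z <- gw$beta / gw$se
  }
  class(gw) <- c("gwas_summary", "data.frame")
  gw
}

#' @rdname read_gwas
#' @param gwas `gwas_summary` data frame.
#' @export
write_gwas <- function(gwas, path) {
  data.table::fwrite(gwas, path, sep = "\t")
  invisible(path)
}

#' Harmonize GWAS summary statistics to a model's effect alleles
#'
#' Matches variants by `chrom:pos`; when the GWAS effect allele equals the
#' model's non-effect allele (and vice versa) the z-score sign is flipped.
#' Allele pairs matching in neither orientation are dropped (count
#' logged).
#'
#' @param gwas `gwas_summary` data frame.
#' @param model `prediction_model`.
#' @return data frame `variant_id, z, se` aligned to the model's effect
#'   alleles (rows only for matched variants).
#' @export
harmonize_gwas <- function(gwas, model) {
  w <- model$weights
  key_g <- paste(gwas$chrom, gwas$pos, sep = ":")
  key_m <- paste(w$chrom, w$pos, sep = ":")
  gi <- match(key_m, key_g)
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(w))) {
    j <- gi[i]
    if (is.na(j)) next
    ea <- toupper(gwas$effect_allele[j]); oa <- toupper(gwas$other_allele[j])
    same <- ea == w$eff_allele[i] && oa == w$ref_allele[i]
    swap <- ea == w$ref_allele[i] && oa == w$eff_allele[i]
    if (!same && !swap) { dropped <- dropped + 1L; next }
    z <- if ("z" %in% names(gwas) && is.finite(gwas$z[j])) gwas$z[j]
         else gwas$beta[j] / gwas$se[j]
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = w$variant_id[i],
      z = if (same) z else -z,
      se = gwas$se[j], stringsAsFactors = FALSE)
  }
  if (dropped > 0) message(dropped, " variant(s) dropped: allele mismatch")
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' S-PrediXcan protein-trait association from summary statistics
#'
#' The summary-statistic association z-score
#' `z_protein = sum_l w_l sigma_l z_l / sigma_protein`, with
#' `sigma_l = sqrt(Gamma_ll)` and `sigma_protein^2 = w' Gamma w` over the
#' matched variants, where `Gamma` is the training-cohort dosage
#' covariance stored with the model. Model variants absent from the GWAS
#' are dropped from both the numerator and the covariance submatrix.
#'
#' @param model `prediction_model` (carries its covariance bundle).
#' @param gwas `gwas_summary` for the trait.
#' @param trait trait label for the output.
#' @return `association_result` (one-row data frame: `aptamer, gene,
#'   trait, population, strategy, zscore, pvalue, direction, n_snps_used,
#'   n_snps_model`), or `NULL` when no variant matches or the predicted
#'   variance is numerically zero.
#' @export
spredixcan_assoc <- function(model, gwas, trait = "trait") {
  hz <- harmonize_gwas(gwas, model)
  if (is.null(hz)) {
    message("no GWAS overlap for ", model$aptamer, "; skipped")
    return(NULL)
  }
  w <- model$weights$weight[match(hz$variant_id, model$weights$variant_id)]
  G <- model$covariance[hz$variant_id, hz$variant_id, drop = FALSE]
  sig2 <- as.numeric(t(w) %*% G %*% w)
  if (!is.finite(sig2) || sig2 <= 1e-12) {
    message("zero predicted variance for ", model$aptamer, "; skipped")
    return(NULL)
  }
  z <- sum(w * sqrt(diag(G)) * hz$z) / sqrt(sig2)
  out <- data.frame(
    aptamer = model$aptamer, gene = model$gene, trait = trait,
    population = model$population, strategy = model$strategy,
    zscore = z, pvalue = 2 * stats::pnorm(-abs(z)),
    direction = sign(z), n_snps_used = nrow(hz),
    n_snps_model = nrow(model$weights), stringsAsFactors = FALSE
  )
  class(out) <- c("association_result", "data.frame")
  out
}

#' Pooled Bonferroni threshold per model-building strategy
#'
#' All association tests of one strategy -- across populations and traits
#' -- are pooled and the significance threshold is `0.05 / n_tests`,
#' computed independently for each strategy.
#'
#' @param results association results (rows from [spredixcan_assoc()],
#'   bound together).
#' @param alpha_total family-wise error budget (default 0.05).
#' @return the input with columns `bonferroni_threshold` and
#'   `bonferroni_flag` added (per row, from its strategy's pooled count).
#' @export
pooled_bonferroni <- function(results, alpha_total = 0.05) {
  if (is.null(results) || nrow(results) == 0L) stop("no association results")
  thr <- tapply(results$pvalue, results$strategy,
                function(p) alpha_total / length(p))
  results$bonferroni_threshold <- as.numeric(thr[results$strategy])
  results$bonferroni_flag <- results$pvalue < results$bonferroni_threshold
  results
}
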
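#' Cis-pQTL association scan
#'
#' For every aptamer-gene pair and every QC-passing variant within 1 Mb of
#' the gene's TSS, fits the simple linear regression of adjusted abundance
#' on dosage and reports beta, se, `t = beta/se` and the two-sided p-value
#' on `n - 2` df. Aptamers mapping to several genes are scanned once per
#' gene with identical response values (each aptamer-gene pair is an
#' independent phenotype). Benjamini-Hochberg q-values are pooled across
#' all tests in the table.
#'
#' @param g QC-filtered `genotype_matrix`.
#' @param a adjusted-stage `abundance_matrix`.
#' @param ann aptamer annotation (`aptamer_id`, `gene_id`, `chrom`, `tss`).
#' @param window cis half-width in bp (default 1 Mb).
#' @param population label stored with the output rows.
#' @return `pqtl_table` data frame: `aptamer_id, gene_id, variant_id,
#'   chrom, pos, ref, alt, beta, se, t, p, q, population`. Aptamer-gene
#'   pairs with no variant in the window are skipped with a message.
#' @export
map_cis_pqtl <- function(g, a, ann, window = 1e6, population = "ALL") {
  stopifnot(inherits(g, "genotype_matrix"), inherits(a, "abundance_matrix"))
  if (!identical(a$stage, "adjusted")) stop("abundance must be adjusted stage")
  common <- intersect(rownames(a$values), g$samples$sample_id)
  dos <- g$dosage[match(common, g$samples$sample_id), , drop = FALSE]
  vals <- a$values[match(common, rownames(a$values)), , drop = FALSE]
  out <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    apt <- ann$aptamer_id[i]
    if (!apt %in% colnames(vals)) next
    win <- cis_window(ann$tss[i], window)
    in_win <- which(g$variants$chrom == ann$chrom[i] &
                      g$variants$pos >= win[1] & g$variants$pos <= win[2])
    if (!length(in_win)) {
      message("no cis variants for ", apt, " / ", ann$gene_id[i], "; skipped")
      next
    }
    y <- vals[, apt]
    res <- marginal_gwas(dos[, in_win, drop = FALSE], y,
                         g$variants[in_win, , drop = FALSE])
    out[[i]] <- data.frame(
      aptamer_id = apt, gene_id = ann$gene_id[i],
      variant_id = res$variant_id, chrom = res$chrom, pos = res$pos,
      ref = res$other_allele, alt = res$effect_allele,
      beta = res$beta, se = res$se, t = res$z, p = res$p,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, out)
  if (is.null(tab)) stop("no aptamer-gene pair produced any test")
  bad <- !is.finite(tab$p)
  if (any(bad)) {
    message(sum(bad), " monomorphic variant test(s) dropped")
    tab <- tab[!bad, , drop = FALSE]
  }
  tab$q <- bh_fdr(tab$p)
  tab$population <- population
  class(tab) <- c("pqtl_table", "data.frame")
  tab
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values `q_i = min over {j : p_j >= p_i} of p_j * n / rank_j`,
#' monotone in p. Delegates to [stats::p.adjust()] with `method = "BH"`,
#' which implements exactly this.
#'
#' @param pvalues numeric vector in `(0, 1]`.
#' @return q-values in input order; empty input gives empty output.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  stopifnot(all(pvalues > 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Write a pQTL table to TSV
#' @param tab `pqtl_table`.
#' @param path output file.
#' @export
write_pqtl <- function(tab, path) {
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
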
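#' Construct a genotype matrix container
#'
#' @param dosage numeric samples x variants matrix, entries in `[0, 2]`
#'   (imputed dosages may be fractional).
#' @param variants data frame with at least `id, chrom, pos, ref, alt`;
#'   optional imputation quality as a single `r2` column or per-population
#'   `r2_<pop>` columns.
#' @param samples data frame with `sample_id` and `population`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, samples) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(dosage) == nrow(samples), ncol(dosage) == nrow(variants))
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  ord <- order(variants$chrom, variants$pos)
  if (any(ord != seq_along(ord))) {
    variants <- variants[ord, , drop = FALSE]
    dosage <- dosage[, ord, drop = FALSE]
  }
  if (anyDuplicated(paste(variants$chrom, variants$pos))) {
    stop("positions must be strictly increasing within chromosome")
  }
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants; populations: %s\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$samples$population), collapse = ", ")))
  invisible(x)
}

#' Subset a genotype matrix by samples and/or variants
#'
#' @param g `genotype_matrix`.
#' @param samples logical/integer/character index into samples.
#' @param variants logical/integer/character index into variants.
#' @return subsetted `genotype_matrix` (truth attribute preserved).
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  truth <- attr(g, "truth")
  if (is.null(samples)) samples <- seq_len(nrow(g$dosage))
  if (is.null(variants)) variants <- seq_len(ncol(g$dosage))
  if (is.character(samples)) samples <- match(samples, g$samples$sample_id)
  if (is.character(variants)) variants <- match(variants, g$variants$id)
  out <- structure(list(
    dosage = g$dosage[samples, variants, drop = FALSE],
    variants = g$variants[variants, , drop = FALSE],
    samples = g$samples[samples, , drop = FALSE]
  ), class = "genotype_matrix")
  attr(out, "truth") <- truth
  out
}

#' Minor allele frequency per variant
#'
#' `min(p_hat, 1 - p_hat)` with `p_hat = mean(dosage) / 2`; symmetric under
#' allele swap.
#'
#' @param g `genotype_matrix`.
#' @param population restrict to one population label, or `"ALL"`.
#' @return named numeric vector of MAFs.
#' @export
maf <- function(g, population = "ALL") {
  dos <- g$dosage
  if (!identical(population, "ALL")) {
    dos <- dos[g$samples$population == population, , drop = FALSE]
  }
  p <- colMeans(dos, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' QC-filter variants on MAF and imputation quality
#'
#' In per-population mode (a population label), keeps variants with
#' `MAF > maf_min` computed within that population and imputation
#' `R^2 > r2_min` for that population, and restricts the samples to the
#' population. In `"ALL"` mode, keeps variants passing `R^2 > r2_min` in
#' every population and `MAF > maf_min` computed on the combined sample,
#' retaining all samples.
#'
#' @param g `genotype_matrix`.
#' @param maf_min MAF threshold in `[0, 0.5]` (exclusive comparison).
#' @param r2_min imputation quality threshold in `[0, 1]`.
#' @param population a population label, or `"ALL"`.
#' @return filtered `genotype_matrix`; empty result is valid (warning).
#' @export
qc_filter <- function(g, maf_min = 0.01, r2_min = 0.8, population = "ALL") {
  stopifnot(maf_min >= 0, maf_min <= 0.5, r2_min >= 0, r2_min <= 1)
  pops <- unique(g$samples$population)
  r2_for <- function(pop) {
    col <- paste0("r2_", pop)
    if (col %in% names(g$variants)) g$variants[[col]]
    else if ("r2" %in% names(g$variants)) g$variants$r2
    else rep(1, nrow(g$variants))
  }
  if (identical(population, "ALL")) {
    r2_pass <- Reduce(`&`, lapply(pops, function(p) r2_for(p) > r2_min))
    keep <- r2_pass & maf(g, "ALL") > maf_min
    out <- subset_genotypes(g, variants = which(keep))
  } else {
    if (!population %in% pops) stop("unknown population: ", population)
    keep <- r2_for(population) > r2_min & maf(g, population) > maf_min
    out <- subset_genotypes(g,
                            samples = which(g$samples$population == population),
                            variants = which(keep))
  }
  if (ncol(out$dosage) == 0L) warning("qc_filter removed all variants")
  out
}

#' Principal components of a genotype matrix
#'
#' Plain PCA on centered, unit-variance-scaled dosages (monomorphic
#' variants dropped).
#'
#' @param g `genotype_matrix`.
#' @param k number of components.
#' @return list with `scores` (samples x k) and `explained` (variance
#'   fractions, non-increasing). `k = 0` returns a zero-column score
#'   matrix.
#' @export
genotype_pca <- function(g, k = 10) {
  n <- nrow(g$dosage)
  if (k == 0L) {
    return(list(scores = matrix(0, n, 0,
                                dimnames = list(g$samples$sample_id, NULL)),
                explained = numeric(0)))
  }
  stopifnot(n >= k + 1)
  sds <- apply(g$dosage, 2, stats::sd)
  X <- g$dosage[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  if (k > length(pc$sdev)) stop("k exceeds the rank of the genotype matrix")
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- g$samples$sample_id
  list(scores = scores, explained = ev[seq_len(k)])
}

#' Hudson F_ST estimator
#'
#' Per-variant Hudson estimator
#' `[(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)] / [p1(1-p2) + p2(1-p1)]`.
#' Vectorized over variants. Undefined (both populations fixed for the same
#' allele) values are returned as `NA`.
#'
#' @param p1,p2 allele frequencies in `[0, 1]` (vectors allowed).
#' @param n1,n2 sample sizes (>= 2).
#' @return numeric vector of per-variant estimates.
#' @seealso [fst_mean()] for the model-level ratio-of-averages summary.
#' @export
fst_hudson <- function(p1, p2, n1, n2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1), n1 >= 2, n2 >= 2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(den == 0, NA_real_, num / den)
}

#' Model-level F_ST summary over a set of variants
#'
#' Ratio of averages (sum of Hudson numerators over sum of denominators),
#' the standard multi-locus combination; a per-variant average is available
#' as an option.
#'
#' @param p1,p2 per-variant frequencies.
#' @param n1,n2 sample sizes.
#' @param method `"ratio_of_averages"` (default) or `"average_of_ratios"`.
#' @return scalar F_ST.
#' @export
fst_mean <- function(p1, p2, n1, n2,
                     method = c("ratio_of_averages", "average_of_ratios")) {
  method <- match.arg(method)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- den > 0
  if (!any(ok)) return(NA_real_)
  if (method == "ratio_of_averages") {
    sum(num[ok]) / sum(den[ok])
  } else {
    mean(num[ok] / den[ok])
  }
}

#' Weir-Cockerham two-population F_ST (theta-hat)
#'
#' Provided as an alternative estimator for cross-checks against Hudson.
#'
#' @inheritParams fst_mean
#' @return scalar estimate (ratio of averages over variants).
#' @export
fst_weir_cockerham <- function(p1, p2, n1, n2) {
  n_bar <- (n1 + n2) / 2
  nc <- (2 * n_bar - (n1^2 + n2^2) / (2 * n_bar)) / 1  # r - 1 = 1
  p_bar <- (n1 * p1 + n2 * p2) / (2 * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / n_bar
  # heterozygosity term from HWE expectation (dosage data are unphased)
  h_bar <- (n1 * 2 * p1 * (1 - p1) + n2 * 2 * p2 * (1 - p2)) / (2 * n_bar)
  a <- n_bar / nc * (s2 - (p_bar * (1 - p_bar) - s2 / 2 - h_bar / 4) / (n_bar - 1))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - s2 / 2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  c_ <- h_bar / 2
  ok <- (a + b + c_) > 0
  if (!any(ok)) return(NA_real_)
  sum(a[ok]) / sum(a[ok] + b[ok] + c_[ok])
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF v4.2: the `DS` FORMAT field is used when present, otherwise `GT` is
#' converted to an alternate-allele count. Multiallelic records are skipped
#' with a warning. Dosage TSV dialect: first column `variant id`
#' (`chr:pos:ref:alt`), remaining columns one per sample, rows one per
#' variant.
#'
#' @param path input file.
#' @param format `"vcf"` or `"tsv"`; guessed from the extension by default.
#' @param samples optional data frame (`sample_id`, `population`) supplying
#'   population labels; defaults to a single `"ALL"` label.
#' @return `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           samples = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi)) {
      warning(sprintf("skipping %d multiallelic record(s)", sum(multi)))
      vcf <- vcf[!multi, ]
      fix <- fix[!multi, , drop = FALSE]
    }
    ds <- try(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE),
              silent = TRUE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt_dosage <- matrix(
      sapply(strsplit(gsub("\\|", "/", gt), "/"),
             function(a) sum(a != "0" & a != ".")),
      nrow = nrow(gt), dimnames = dimnames(gt))
    dosage <- if (inherits(ds, "try-error") || all(is.na(ds))) {
      gt_dosage
    } else {
      ifelse(is.na(ds), gt_dosage, ds)
    }
    r2 <- suppressWarnings(
      as.numeric(vcfR::extract.info(vcf, element = "R2")))
    variants <- data.frame(
      id = ifelse(is.na(fix$ID) | fix$ID == ".",
                  variant_key(fix$CHROM, fix$POS, fix$REF, fix$ALT), fix$ID),
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT,
      r2 = ifelse(is.na(r2), 1, r2),
      stringsAsFactors = FALSE
    )
    dosage <- t(dosage)
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t",
                            data.table = FALSE)
    parts <- strsplit(dt[[1]], ":", fixed = TRUE)
    bad <- which(lengths(parts) != 4L)
    if (length(bad)) {
      stop(sprintf("malformed variant id at line %d: %s", bad[1] + 1L,
                   dt[[1]][bad[1]]))
    }
    variants <- data.frame(
      id = dt[[1]],
      chrom = vapply(parts, `[`, "", 1L),
      pos = as.integer(vapply(parts, `[`, "", 2L)),
      ref = vapply(parts, `[`, "", 3L),
      alt = vapply(parts, `[`, "", 4L),
      r2 = 1, stringsAsFactors = FALSE
    )
    dosage <- t(as.matrix(dt[, -1, drop = FALSE]))
    colnames(dosage) <- variants$id
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = rownames(dosage), population = "ALL",
                          stringsAsFactors = FALSE)
  } else {
    samples <- samples[match(rownames(dosage), samples$sample_id), ,
                       drop = FALSE]
  }
  genotype_matrix(dosage, variants, samples)
}

#' Write genotypes to VCF or dosage TSV
#'
#' @param g `genotype_matrix`.
#' @param path output file.
#' @param format `"vcf"` (v4.2, one ALT per record, `DS` in FORMAT) or
#'   `"tsv"` (dialect of [read_genotypes()]). Dosages are written with 3
#'   decimals.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- data.frame(variant = g$variants$id,
                      round(t(g$dosage), 3), check.names = FALSE)
    colnames(out) <- c("variant", g$samples$sample_id)
    data.table::fwrite(out, path, sep = "\t")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", g$samples$sample_id), collapse = "\t")
    ), con)
    gt_of <- function(d) c("0/0", "0/1", "1/1")[pmin(round(d), 2) + 1L]
    for (j in seq_len(ncol(g$dosage))) {
      d <- g$dosage[, j]
      fields <- paste0(gt_of(d), ":", formatC(d, digits = 3, format = "f"))
      writeLines(paste(c(
        g$variants$chrom[j], g$variants$pos[j], g$variants$id[j],
        g$variants$ref[j], g$variants$alt[j], ".", "PASS",
        sprintf("R2=%.4f", g$variants$r2[j]), "GT:DS", fields
      ), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read an aptamer annotation table
#'
#' TSV columns: `aptamer_id, gene_id, chrom, tss` and optional `pav_ids`,
#' `pav_consequences` (comma-separated within a cell). An aptamer may map
#' to several genes (one row per aptamer-gene pair); each pair is treated
#' downstream as an independent phenotype with identical values.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_annotation <- function(path) {
  ann <- data.table::fread(path, sep = "\t", data.table = FALSE)
  req <- c("aptamer_id", "gene_id", "chrom", "tss")
  if (!all(req %in% names(ann))) {
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  }
  ann
}

#' Cis window around a TSS
#'
#' Closed interval `[tss - window, tss + window]`, clipped at 1.
#'
#' @param tss 1-based transcription start position.
#' @param window half-width in bp (default 1 Mb).
#' @return length-2 numeric `c(start, end)`.
#' @export
cis_window <- function(tss, window = 1e6) {
  c(max(1, tss - window), tss + window)
}
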
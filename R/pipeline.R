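#' Train prediction models for every aptamer-gene pair
#'
#' For each annotation row, takes the QC-passing variants in the 1 Mb cis
#' window as the design. Under the `"baseline"` strategy every variant
#' gets penalty factor 1; under `"fm"` the locus is fine-mapped first
#' ([enumerate_posteriors()]) and the design is reduced to the eligible
#' variants with penalties `1 - PIP` ([penalty_factors()]). With
#' `pav = TRUE`, the response is first residualized on the leading
#' principal components of the locus's PAV genotypes (95% variance rule)
#' and the PAVs are removed from the design.
#'
#' @param g QC-filtered `genotype_matrix` (training population only).
#' @param a adjusted `abundance_matrix` for the same samples.
#' @param ann aptamer annotation (may include `pav_ids`, comma-separated).
#' @param strategy `"baseline"` or `"fm"`.
#' @param pip_threshold,cluster_filter fine-mapping penalty options.
#' @param pav apply PAV adjustment.
#' @param alpha elastic-net mixing parameter.
#' @param seed fold seed.
#' @param window cis half-width.
#' @param population label recorded on each model.
#' @param K,prior_pi fine-mapping settings (defaults: model size cap 3,
#'   prior `1/p`).
#' @return named list of `prediction_model`s (entries `NULL`-dropped);
#'   attribute `pav_flags` records per-aptamer adjustment flags.
#' @export
train_protein_models <- function(g, a, ann, strategy = c("baseline", "fm"),
                                 pip_threshold = 0.001,
                                 cluster_filter = TRUE, pav = FALSE,
                                 alpha = 0.5, seed = 42, window = 1e6,
                                 population = "ALL", K = 3,
                                 prior_pi = NULL) {
  strategy <- match.arg(strategy)
  common <- intersect(rownames(a$values), g$samples$sample_id)
  dos <- g$dosage[match(common, g$samples$sample_id), , drop = FALSE]
  models <- list()
  pav_flags <- character(0)
  strategy_tag <- if (strategy == "fm") {
    sprintf("fm_pip%s%s", format(pip_threshold),
            if (cluster_filter) "_clusterfilter" else "")
  } else "baseline"
  if (pav) strategy_tag <- paste0(strategy_tag, "_pav")

  for (i in seq_len(nrow(ann))) {
    apt <- ann$aptamer_id[i]
    if (!apt %in% colnames(a$values)) next
    win <- cis_window(ann$tss[i], window)
    in_win <- which(g$variants$chrom == ann$chrom[i] &
                      g$variants$pos >= win[1] & g$variants$pos <= win[2])
    if (!length(in_win)) next
    X <- dos[, in_win, drop = FALSE]
    y <- a$values[match(common, rownames(a$values)), apt]
    vinfo <- g$variants[in_win, , drop = FALSE]

    flag <- "unadjusted"
    if (pav) {
      pav_ids <- character(0)
      if ("pav_ids" %in% names(ann) && !is.na(ann$pav_ids[i])) {
        pav_ids <- intersect(
          trimws(strsplit(ann$pav_ids[i], ",")[[1]]), colnames(X))
      }
      if (length(pav_ids)) {
        adj <- pav_adjust(y, X[, pav_ids, drop = FALSE])
        y <- adj$y
        flag <- adj$flag
        if (adj$flag == "adjusted") {
          keep <- setdiff(colnames(X), pav_ids)
          X <- X[, keep, drop = FALSE]
          vinfo <- vinfo[match(keep, vinfo$id), , drop = FALSE]
        }
      }
    }
    pav_flags[apt] <- flag
    if (ncol(X) == 0L) next

    if (strategy == "fm") {
      fm <- enumerate_posteriors(y, X, prior_pi = prior_pi, K = K,
                                 positions = vinfo$pos)
      pen <- penalty_factors(fm, pip_threshold, cluster_filter)
      if (!length(pen)) next
    } else {
      pen <- stats::setNames(rep(1, ncol(X)), colnames(X))
    }
    m <- train_final_model(X, y, pen, vinfo, alpha = alpha, seed = seed,
                           aptamer = apt, gene = ann$gene_id[i],
                           population = population,
                           strategy = strategy_tag)
    if (!is.null(m)) models[[paste(apt, ann$gene_id[i], sep = "|")]] <- m
  }
  attr(models, "pav_flags") <- pav_flags
  models
}

#' Run the full synthetic discovery-to-triage pipeline once
#'
#' Generates a training panel, an aptamer proteome with one (or more)
#' trait-mediating proteins, and paired discovery/replication GWAS
#' cohorts; prepares abundances; maps cis-pQTLs; trains baseline and
#' fine-mapped models; runs the summary-statistic association test against
#' both cohorts; colocalizes the discovery hits; and triages through the
#' Bonferroni / colocalization / replication criteria.
#'
#' @param seed master seed (all stages derive from it).
#' @param n_train training-panel size.
#' @param n_loci,snps_per_locus panel shape (one aptamer per locus).
#' @param h2 true cis heritability of each aptamer.
#' @param n_causal causal variants per aptamer.
#' @param mediated_aptamers names (e.g. `"APT1"`) of trait-mediating
#'   proteins.
#' @param gamma mediation effect per mediated protein.
#' @param n_gwas discovery and replication cohort size.
#' @param strategies which model sets to build.
#' @param n_pcs genotype PCs adjusted in abundance preparation.
#' @param ld_decay neighbour LD of the panel.
#' @return list: `triage` (records/headline/counts), `assoc` (discovery
#'   associations with Bonferroni flags), `models`, `pqtl`, `gwas`,
#'   `truth`.
#' @export
pwas_pipeline <- function(seed = 1, n_train = 500, n_loci = 50,
                          snps_per_locus = 12, h2 = 0.5, n_causal = 2,
                          mediated_aptamers = "APT1", gamma = 0.35,
                          n_gwas = 10000,
                          strategies = c("baseline", "fm"),
                          n_pcs = 5, ld_decay = 0.7) {
  g <- simulate_genotypes(c(TRAIN = n_train), n_loci, snps_per_locus,
                          fst_target = 0.05, ld_decay = ld_decay,
                          seed = seed)
  prot <- simulate_proteome(g, h2 = h2, n_causal = n_causal,
                            seed = seed + 1L)
  pcs <- genotype_pca(g, k = n_pcs)
  a <- prepare_abundance(prot$abundance, prot$covariates, pcs$scores,
                         n_pcs = n_pcs)
  gq <- qc_filter(g, maf_min = 0.01, r2_min = 0.8, population = "ALL")
  pq <- map_cis_pqtl(gq, a, prot$annotation, population = "TRAIN")

  gam <- stats::setNames(rep(gamma, length(mediated_aptamers)),
                         mediated_aptamers)
  gw <- simulate_gwas_pair(prot$truth, gam, n_gwas, n_gwas,
                           population = "TRAIN", seed = seed + 2L)

  models <- list()
  for (s in strategies) {
    models <- c(models, train_protein_models(
      gq, a, prot$annotation, strategy = s, population = "TRAIN",
      seed = seed + 3L))
  }

  assoc_of <- function(gwas) {
    rows <- lapply(models, spredixcan_assoc, gwas = gwas, trait = "trait1")
    do.call(rbind, Filter(Negate(is.null), rows))
  }
  disc <- assoc_of(gw$discovery)
  if (is.null(disc)) stop("no model produced an association test")
  disc <- pooled_bonferroni(disc)
  repl <- assoc_of(gw$replication)

  hits <- unique(disc[disc$bonferroni_flag, c("aptamer", "gene")])
  colocs <- NULL
  if (nrow(hits)) {
    colocs <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
      sub <- pq[pq$aptamer_id == hits$aptamer[i] &
                  pq$gene_id == hits$gene[i], , drop = FALSE]
      cr <- coloc_locus(sub, gw$discovery)
      if (is.null(cr)) return(NULL)
      data.frame(aptamer = hits$aptamer[i], gene = hits$gene[i],
                 trait = "trait1", p4 = unname(cr$posteriors["P4"]),
                 stringsAsFactors = FALSE)
    }))
  }
  tri <- triage_associations(disc, colocs, repl)
  list(triage = tri, assoc = disc, models = models, pqtl = pq, gwas = gw,
       truth = prot$truth)
}
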
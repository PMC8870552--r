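#' Simulate multi-population genotype dosages
#'
#' Draws per-population allele frequencies around shared ancestral
#' frequencies under the Balding-Nichols model, then generates haplotypes
#' locus by locus with a first-order Markov chain so that linkage
#' disequilibrium between neighbouring variants decays geometrically.
#'
#' For differentiation parameter `F > 0`, each population's allele frequency
#' at a variant with ancestral frequency `p` is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose expectation is `p` and whose
#' variance is `F p (1-p)` -- so `F` is approximately the Hudson F_ST
#' between any two populations. At `F = 0` every population uses the
#' ancestral frequency exactly.
#'
#' Within a locus, haplotype alleles share the latent uniform of the
#' previous variant with probability `ld_decay`, giving pairwise
#' correlation that decays as roughly `ld_decay^distance`; chains restart
#' at locus boundaries so loci are unlinked.
#'
#' @param n_per_population named integer vector, samples per population
#'   (e.g. `c(AFA = 183, EUR = 416)`).
#' @param n_loci number of independent cis loci (one gene per locus).
#' @param snps_per_locus variants per locus.
#' @param fst_target Balding-Nichols `F` in `[0, 1)`; either a scalar
#'   (all populations) or a named per-population vector, allowing panels
#'   where populations sit at different differentiation from the
#'   ancestral pool. Two populations drawn at the same `F` have pairwise
#'   Hudson F_ST close to `F`; a population at `F` versus one at 0 sits
#'   near `F / 2`.
#' @param ld_decay neighbour allele correlation in `[0, 1)`.
#' @param seed integer RNG seed; identical seeds reproduce the matrix
#'   bit-exactly.
#' @param chrom chromosome label for all loci.
#' @param locus_spacing bp between locus starts (default 3 Mb, so the
#'   1 Mb cis windows of adjacent loci never overlap).
#' @param snp_spacing bp between variants within a locus.
#' @param maf_range range ancestral frequencies are drawn from
#'   (uniform; default keeps variants away from monomorphism).
#' @param fst_heterogeneity locus-level spread of differentiation in
#'   `[0, 1)`: each locus draws its own `F` uniformly from
#'   `fst_target * (1 - h, 1 + h)`. Real genomes show strong locus-to-locus
#'   variation in F_ST (drift and selection are not uniform), and
#'   cross-model contrasts of mean F_ST rely on that spread; 0 (default)
#'   applies the same `F` everywhere.
#' @return a list with class `genotype_matrix` (fields `dosage` --
#'   samples x variants matrix with entries in `{0,1,2}`, `variants`,
#'   `samples`) and a `truth` attribute of class `sim_truth` recording
#'   ancestral and per-population frequencies, the locus table and the
#'   generator settings.
#' @export
simulate_genotypes <- function(n_per_population, n_loci, snps_per_locus,
                               fst_target = 0.1, ld_decay = 0.7, seed = 1,
                               chrom = "1", locus_spacing = 3e6,
                               snp_spacing = 1500,
                               maf_range = c(0.05, 0.95),
                               fst_heterogeneity = 0) {
  stopifnot(length(n_per_population) >= 1, all(n_per_population >= 1),
            n_loci >= 1, snps_per_locus >= 1)
  if (any(fst_target < 0) || any(fst_target >= 1)) {
    stop("fst_target must lie in [0, 1)")
  }
  if (ld_decay < 0 || ld_decay >= 1) {
    stop("ld_decay must lie in [0, 1)")
  }
  if (is.null(names(n_per_population))) {
    names(n_per_population) <- paste0("POP", seq_along(n_per_population))
  }
  set.seed(seed)
  pops <- names(n_per_population)
  if (length(fst_target) == 1L) {
    fst_target <- stats::setNames(rep(fst_target, length(pops)), pops)
  }
  stopifnot(all(pops %in% names(fst_target)))
  m <- n_loci * snps_per_locus
  locus_of <- rep(seq_len(n_loci), each = snps_per_locus)
  pos <- (locus_of - 1L) * locus_spacing + 1e6 +
    (seq_len(m) - (locus_of - 1L) * snps_per_locus - 1L) * snp_spacing
  ids <- variant_key(chrom, pos, "A", "G")

  # within-locus frequencies cluster around a locus base frequency so the
  # Markov chain's realized neighbour correlation tracks ld_decay
  base <- stats::runif(n_loci, maf_range[1] + 0.1, maf_range[2] - 0.1)
  p_anc <- pmin(pmax(base[locus_of] + stats::runif(m, -0.1, 0.1),
                     maf_range[1]), maf_range[2])
  stopifnot(fst_heterogeneity >= 0, fst_heterogeneity < 1)
  pop_freq <- sapply(pops, function(pop) {
    fp <- fst_target[[pop]]
    if (fp > 0) {
      f_locus <- if (fst_heterogeneity > 0) {
        stats::runif(n_loci, fp * (1 - fst_heterogeneity),
                     fp * (1 + fst_heterogeneity))
      } else rep(fp, n_loci)
      f_snp <- pmin(f_locus[locus_of], 0.95)
      f <- stats::rbeta(m, p_anc * (1 - f_snp) / f_snp,
                        (1 - p_anc) * (1 - f_snp) / f_snp)
      # keep Beta draws off the exact boundary so loci stay segregating
      pmin(pmax(f, 1e-6), 1 - 1e-6)
    } else {
      p_anc
    }
  })

  dosage <- matrix(NA_real_, nrow = sum(n_per_population), ncol = m)
  sample_ids <- character(sum(n_per_population))
  sample_pop <- character(sum(n_per_population))
  offset <- 0L
  for (pop in pops) {
    n <- n_per_population[[pop]]
    h1 <- markov_haplotypes(2L * n, pop_freq[, pop], ld_decay, locus_of)
    rows <- offset + seq_len(n)
    dosage[rows, ] <- h1[seq_len(n), , drop = FALSE] +
      h1[n + seq_len(n), , drop = FALSE]
    sample_ids[rows] <- sprintf("%s_%04d", pop, seq_len(n))
    sample_pop[rows] <- pop
    offset <- offset + n
  }
  dimnames(dosage) <- list(sample_ids, ids)

  variants <- data.frame(
    id = ids, chrom = chrom, pos = pos, ref = "A", alt = "G",
    r2 = 1, locus = paste0("G", locus_of),
    stringsAsFactors = FALSE
  )
  loci <- data.frame(
    locus = paste0("G", seq_len(n_loci)), chrom = chrom,
    tss = pos[match(seq_len(n_loci), locus_of)],
    stringsAsFactors = FALSE
  )
  samples <- data.frame(sample_id = sample_ids, population = sample_pop,
                        stringsAsFactors = FALSE)

  g <- genotype_matrix(dosage, variants, samples)
  truth <- structure(list(
    ancestral_freq = stats::setNames(p_anc, ids),
    pop_freq = `rownames<-`(pop_freq, ids),
    fst_target = fst_target, ld_decay = ld_decay,
    loci = loci, variants = variants, seed = seed
  ), class = "sim_truth")
  attr(g, "truth") <- truth
  g
}

# Haplotypes with locus-restarting first-order Markov LD: each variant
# reuses the previous variant's latent uniform with probability r.
markov_haplotypes <- function(n_hap, freqs, r, locus_of) {
  m <- length(freqs)
  U <- matrix(stats::runif(n_hap * m), n_hap, m)
  if (r > 0 && m > 1L) {
    copy <- matrix(stats::runif(n_hap * m) < r, n_hap, m)
    for (j in 2:m) {
      if (locus_of[j] != locus_of[j - 1L]) next
      idx <- copy[, j]
      U[idx, j] <- U[idx, j - 1L]
    }
  }
  (U < matrix(freqs, n_hap, m, byrow = TRUE)) + 0
}

#' Simulate an aptamer proteome over a genotype panel
#'
#' Each aptamer maps to one simulated gene/locus and receives a sparse cis
#' architecture: `n_causal` variants with normal effects, scaled so the
#' genetic value explains `h2` of the latent (person-level) variance. A
#' fraction of aptamers is flagged artifact-driven: their abundance carries
#' no true cis-genetic signal, only a protein-altering-variant (PAV)
#' binding-affinity term proportional to the PAV dosage. Optionally, inert
#' ("neutral") PAVs are annotated in the windows of genuinely cis-regulated
#' aptamers without contributing to abundance. Raw abundances are emitted on
#' the positive measurement scale (`exp` of the latent scale) per timepoint,
#' with age, sex and timepoint noise added, and a configurable
#' missing-at-second-timepoint rate.
#'
#' @param genotypes `genotype_matrix` from [simulate_genotypes()].
#' @param annotation optional aptamer-to-gene table (`aptamer_id`,
#'   `gene_id`); defaults to one aptamer per simulated locus. Every
#'   `gene_id` must be a locus of the panel.
#' @param n_causal causal variants per aptamer.
#' @param h2 true cis heritability in `[0, 1]` of non-artifact aptamers.
#' @param pav_fraction fraction of aptamers whose signal is purely a PAV
#'   binding artifact.
#' @param artifact_sd magnitude (latent-scale units per dosage) of the PAV
#'   artifact effect.
#' @param neutral_pav_fraction fraction of non-artifact aptamers that get an
#'   annotated but inert PAV linked to the causal variant.
#' @param n_timepoints measurement timepoints (default 2).
#' @param miss2_rate fraction of samples missing at timepoints after the
#'   first.
#' @param beta_age,beta_sex covariate effects on the measured level.
#' @param timepoint_sd per-timepoint measurement noise SD.
#' @param seed integer RNG seed.
#' @return list with class `sim_proteome`: `abundance` (long data frame:
#'   `sample_id`, `aptamer_id`, `timepoint`, `value`, positive scale),
#'   `covariates` (`sample_id`, `age`, `sex`, `population`), `annotation`
#'   (aptamer, gene, chrom, tss, PAV ids/consequences), and `truth`
#'   (per-aptamer causal ids, scaled effects, true genetic values, h2,
#'   artifact flags and effects).
#' @export
simulate_proteome <- function(genotypes, annotation = NULL, n_causal = 1,
                              h2 = 0.5, pav_fraction = 0, artifact_sd = 1,
                              neutral_pav_fraction = 0, n_timepoints = 2,
                              miss2_rate = 0.2, beta_age = 0.01,
                              beta_sex = 0.2, timepoint_sd = 0.5, seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            h2 >= 0, h2 <= 1, n_timepoints >= 1)
  truth <- attr(genotypes, "truth")
  if (is.null(truth)) stop("genotypes carry no sim_truth attribute")
  loci <- truth$loci
  if (is.null(annotation)) {
    annotation <- data.frame(
      aptamer_id = sub("^G", "APT", loci$locus),
      gene_id = loci$locus, stringsAsFactors = FALSE
    )
  }
  missing_locus <- setdiff(annotation$gene_id, loci$locus)
  if (length(missing_locus)) {
    stop("annotation maps aptamer(s) to absent locus: ",
         paste(missing_locus, collapse = ", "))
  }
  if (n_causal > sum(truth$variants$locus == loci$locus[1])) {
    stop("n_causal exceeds snps_per_locus")
  }
  set.seed(seed)
  dos <- genotypes$dosage
  n <- nrow(dos)
  n_apt <- nrow(annotation)

  covariates <- data.frame(
    sample_id = genotypes$samples$sample_id,
    age = stats::runif(n, 45, 85),
    sex = stats::rbinom(n, 1, 0.5),
    population = genotypes$samples$population,
    stringsAsFactors = FALSE
  )

  is_artifact <- stats::runif(n_apt) < pav_fraction
  has_neutral_pav <- !is_artifact & stats::runif(n_apt) < neutral_pav_fraction

  apt_truth <- vector("list", n_apt)
  latent <- matrix(0, n, n_apt)
  ann_rows <- vector("list", n_apt)
  for (a in seq_len(n_apt)) {
    gene <- annotation$gene_id[a]
    apt <- annotation$aptamer_id[a]
    vidx <- which(truth$variants$locus == gene)
    vids <- truth$variants$id[vidx]
    pav_id <- NA_character_
    pav_conseq <- NA_character_
    if (is_artifact[a]) {
      # binding-affinity artifact: no true cis effect on abundance
      pav_j <- sample(vids, 1)
      a_eff <- artifact_sd * sample(c(-1, 1), 1)
      latent[, a] <- a_eff * dos[, pav_j] + stats::rnorm(n)
      apt_truth[[a]] <- list(causal_ids = character(0),
                             effects = numeric(0), h2 = 0,
                             genetic_value = rep(0, n),
                             artifact = TRUE, pav_id = pav_j,
                             artifact_effect = a_eff)
      pav_id <- pav_j
      pav_conseq <- "missense variant"
    } else {
      causal <- sample(vids, n_causal)
      eff <- stats::rnorm(n_causal)
      gval <- as.numeric(dos[, causal, drop = FALSE] %*% eff)
      if (h2 > 0 && stats::sd(gval) > 0) {
        scl <- sqrt(h2) / stats::sd(gval)
        eff <- eff * scl
        gval <- gval * scl
        noise_sd <- sqrt(1 - h2)
      } else {
        eff <- rep(0, n_causal)
        gval <- rep(0, n)
        noise_sd <- 1
      }
      latent[, a] <- gval + stats::rnorm(n, sd = noise_sd)
      if (has_neutral_pav[a]) {
        # annotate an inert PAV adjacent to the causal variant (in LD)
        ci <- match(causal[1], vids)
        pav_j <- vids[if (ci < length(vids)) ci + 1L else ci - 1L]
        pav_id <- pav_j
        pav_conseq <- "missense variant"
      }
      apt_truth[[a]] <- list(causal_ids = causal, effects = eff, h2 = h2,
                             genetic_value = gval, artifact = FALSE,
                             pav_id = pav_id, artifact_effect = 0)
    }
    ann_rows[[a]] <- data.frame(
      aptamer_id = apt, gene_id = gene,
      chrom = loci$chrom[match(gene, loci$locus)],
      tss = loci$tss[match(gene, loci$locus)],
      pav_ids = pav_id, pav_consequences = pav_conseq,
      stringsAsFactors = FALSE
    )
  }
  names(apt_truth) <- annotation$aptamer_id
  ann <- do.call(rbind, ann_rows)

  age_c <- covariates$age - mean(covariates$age)
  rows <- vector("list", n_timepoints)
  for (tp in seq_len(n_timepoints)) {
    present <- if (tp == 1L) rep(TRUE, n) else stats::runif(n) >= miss2_rate
    meas <- latent +
      matrix(beta_age * age_c + beta_sex * covariates$sex, n, n_apt) +
      matrix(stats::rnorm(n * n_apt, sd = timepoint_sd), n, n_apt)
    rows[[tp]] <- data.frame(
      sample_id = rep(covariates$sample_id[present], n_apt),
      aptamer_id = rep(annotation$aptamer_id, each = sum(present)),
      timepoint = tp,
      value = exp(as.numeric(meas[present, , drop = FALSE])),
      stringsAsFactors = FALSE
    )
  }
  abundance <- do.call(rbind, rows)

  truth$aptamers <- apt_truth
  structure(list(
    abundance = abundance, covariates = covariates, annotation = ann,
    truth = truth
  ), class = "sim_proteome")
}

#' Simulate paired discovery and replication GWAS cohorts
#'
#' Draws two independent individual-level cohorts from the same generative
#' frequencies as the training panel, builds a quantitative trait partially
#' mediated by the true genetic protein values
#' (`trait = sum_a gamma_a * g_a + noise`), and summarizes each cohort by
#' per-variant marginal regression (beta, se, z, p).
#'
#' @param truth `sim_truth` (with `aptamers`) as produced by
#'   [simulate_proteome()] (the `truth` element).
#' @param protein_effects named numeric vector: mediation effect `gamma`
#'   per aptamer (trait units per latent protein unit); aptamers not named
#'   get 0.
#' @param n_discovery,n_replication cohort sizes (each >= 100).
#' @param noise_sd trait environmental noise SD.
#' @param population which generative frequencies to use: `"ancestral"` or
#'   a population name from the panel.
#' @param seed integer RNG seed.
#' @return list with elements `discovery` and `replication`, each a
#'   `gwas_summary` data frame with columns `variant_id, chrom, pos,
#'   effect_allele, other_allele, beta, se, z, p, n` (effect allele = ALT).
#' @export
simulate_gwas_pair <- function(truth, protein_effects, n_discovery,
                               n_replication, noise_sd = 1,
                               population = "ancestral", seed = 1) {
  stopifnot(inherits(truth, "sim_truth"), n_discovery >= 100,
            n_replication >= 100)
  if (is.null(truth$aptamers)) {
    stop("truth lacks aptamer architecture; run simulate_proteome first")
  }
  stopifnot(all(is.finite(protein_effects)))
  set.seed(seed)
  freqs <- if (identical(population, "ancestral")) {
    truth$ancestral_freq
  } else {
    truth$pop_freq[, population]
  }
  locus_of <- match(truth$variants$locus, truth$loci$locus)
  one_cohort <- function(n) {
    h <- markov_haplotypes(2L * n, freqs, truth$ld_decay, locus_of)
    dos <- h[seq_len(n), , drop = FALSE] + h[n + seq_len(n), , drop = FALSE]
    colnames(dos) <- truth$variants$id
    y <- stats::rnorm(n, sd = noise_sd)
    for (apt in names(protein_effects)) {
      gam <- protein_effects[[apt]]
      if (gam == 0) next
      at <- truth$aptamers[[apt]]
      if (is.null(at)) stop("unknown aptamer in protein_effects: ", apt)
      if (length(at$causal_ids)) {
        y <- y + gam * as.numeric(
          dos[, at$causal_ids, drop = FALSE] %*% at$effects)
      }
    }
    marginal_gwas(dos, y, truth$variants)
  }
  list(discovery = one_cohort(n_discovery),
       replication = one_cohort(n_replication))
}

#' Summarize an individual-level cohort into GWAS summary statistics
#'
#' Vectorized per-variant simple linear regression of the trait on
#' dosage: beta, se, `z = beta/se`, two-sided p on `n - 2` df. The ALT
#' allele is the effect allele.
#'
#' @param dos samples x variants dosage matrix (columns named by variant).
#' @param y trait vector.
#' @param variants variant metadata (`id, chrom, pos, ref, alt`).
#' @return `gwas_summary` data frame.
#' @export
summarize_gwas <- function(dos, y, variants) {
  marginal_gwas(dos, y, variants)
}

marginal_gwas <- function(dos, y, variants) {
  n <- length(y)
  yc <- y - mean(y)
  xm <- colMeans(dos)
  sxx <- colSums(dos^2) - n * xm^2
  sxy <- as.numeric(crossprod(dos, yc))
  syy <- sum(yc^2)
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss <- syy - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  z <- beta / se
  p <- 2 * stats::pt(-abs(z), df = n - 2)
  out <- data.frame(
    variant_id = variants$id, chrom = variants$chrom, pos = variants$pos,
    effect_allele = variants$alt, other_allele = variants$ref,
    beta = beta, se = se, z = z, p = p, n = n,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gwas_summary", "data.frame")
  out
}
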
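---
title: "Methods: proteome prediction models and summary-statistic PWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome prediction models and summary-statistic PWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the statistical machinery it
implements, the assumptions behind each stage, the defaults and why they
were chosen, and what the synthetic-data generator can and cannot tell
you about behavior on real cohorts.

## 1. Abundance preparation

Aptamer abundances arrive as positive measurements per sample and
timepoint. `prepare_abundance()` applies, in this order: natural log;
per-timepoint residualization on age and sex; mean over available
timepoints (a participant measured at one timepoint keeps that value as
their mean); rank inverse-normal transformation (INT) with offset
`(rank - 0.5)/n` and average ranks for ties; residualization on the
leading genotype principal components (default 10 when available).

The INT offset is the simple symmetric choice; alternatives
(Blom, Tukey) differ by a monotone rescaling and do not change rank-based
downstream statistics. The same operations express an external cohort's
convention by swapping the covariate list — there is no separate code
path. Natural log is used throughout; a base change is absorbed by the
INT. Nonpositive raw values are an error rather than silently dropped,
because they indicate an upstream assay problem.

## 2. Cis-pQTL scan and FDR

For each aptamer-gene pair, every QC-passing variant within the closed
1 Mb window around the TSS is tested by simple linear regression of the
adjusted abundance on dosage (`t = beta/se`, df `n - 2`). Covariates are
removed during preparation, not refit per SNP, so the response is
identical across variants of a window. Aptamers mapping to several
genes are scanned once per gene with identical response values — each
aptamer-gene pair is an independent phenotype. Benjamini–Hochberg
q-values are pooled across all tests of a population's table
(`stats::p.adjust`). Monomorphic-in-sample variants yield undefined
tests and are dropped with a message.

## 3. Fine-mapping

Per locus, all variant subsets of size at most `K` (default 3, plus the
null model) are scored by

* Bayes factor: Zellner g-prior with `g = n` (unit information),
  `log BF = ((n-1-k)/2) log(1+g) - ((n-1)/2) log(1 + g(1-R²))`,
  with `R²` computed from the locus correlation matrix (a
  pseudo-inverse path handles collinear subsets);
* prior: independence `pi^|S| (1-pi)^(p-|S|)` with `pi = 1/p` by
  default — one expected causal variant per locus. Enrichment-based
  priors are a configuration override, not an estimation step.

Posteriors are normalized by log-sum-exp; the PIP of a variant is the
posterior mass of models containing it. When `sum_k C(p,k)` exceeds the
enumeration cap (default 2e5), the locus is screened to its most
marginally correlated variants and screened-out variants get PIP 0;
with the default panel shapes (8–20 variants per locus) the cap never
binds, and the exhaustive path is the one verified against a brute-force
`lm()` oracle to 1e-9.

LD signal clusters are formed greedily: seeds in descending PIP order
(ties broken by smaller genomic position), members joining when
`r² >= 0.25` with the seed. A cluster's PIP is the sum over members; it
estimates the expected number of causal variants tagged by the cluster
and can exceed 1 when a locus carries several signals in partial LD.

Penalty factors for the elastic net are `1 - PIP` over the eligible
variants: optionally reduced to each cluster's top-PIP member, then
thresholded (`PIP > 0`, `> 0.001`, `> 0.01`). Ineligible variants are
excluded from the design entirely, not just penalized.

## 4. Penalty-factor elastic net

The core fit minimizes

```
(1/2n) ||y - Xb||² + λ Σ_j pf_j ( α|b_j| + ((1-α)/2) b_j² ),  α = 0.5
```

by cyclic coordinate descent in compiled C++ with the update
`b_j ← S(x_jᵀr/n + b_j, λ α pf_j) / (1 + λ (1-α) pf_j)` on columns
standardized to mean 0 and (1/n)-variance 1. Convergence is a maximum
coefficient change below 1e-7 per sweep; every fit can be audited with
`kkt_violation()`, which checks the subgradient conditions directly.
Weights are reported on the raw dosage scale. The inner
cross-validation loop uses a covariance-update variant (gradients
maintained from the p×p Gram matrix), which is exact and fast for the
narrow cis designs this package fits; the two code paths produce
identical solutions and the single-λ path is additionally cross-checked
against glmnet in the test suite.

Nested cross-validation: 5 outer folds for performance, 10 inner folds
for λ on a 100-point log-spaced path from `λ_max` (the smallest λ
zeroing all penalized columns) down to `0.01 λ_max`. The reported
performance is the Spearman ρ between concatenated out-of-fold
predictions and the observed response, with the t-approximation
p-value; models are emitted only when ρ > 0.1 and p < 0.05. The final
model refits all data at the λ chosen by 10-fold CV and stores the
training dosage covariance (denominator `n - 1`) of its nonzero-weight
variants — the LD reference for the summary-statistic association.
Fold assignments are seeded (default 42).

Two deliberate calibration facts, verified in the tests: (i) the λ-path
floor of `0.01 λ_max` never binds at the panel sizes used, so the path
design does not cost performance; (ii) at `h2 = 0.5`, `n = 400`, the
mean cross-validated ρ over noiselessly measured proteins is ≈ 0.57,
not `sqrt(0.5) ≈ 0.71` — the gap decomposes into the Spearman-versus-
Pearson difference on bivariate normal data (≈ 0.02) and finite-sample
estimation loss, and is reproduced exactly by glmnet's own nested CV on
identical data. Recovery of `sqrt(h2)` is therefore asserted with a
±0.15 band.

## 5. PAV adjustment

Protein-altering variants may change aptamer binding rather than true
abundance. `pav_adjust()` performs PCA on the locus's PAV dosages,
residualizes the response on the smallest number of leading components
reaching 95% cumulative variance, and the training wrapper removes the
PAVs from the design. Model impact is classified as `unadjusted` (no
PAV in the window), `marginal` (Δρ < 0.1), `large_retained` (Δρ ≥ 0.1,
still significant; equality binned here), or `lost_significance`. A
loss of significance is evidence the signal ran through the PAVs — it
cannot by itself distinguish a binding artifact from a PAV that is
causal for abundance.

## 6. External prediction and population transfer

Variants are matched to an external cohort by `chrom:pos`, with
ref/alt-swapped records handled by dosage flipping; alleles matching in
neither orientation are dropped. No strand flipping is attempted
(synthetic data has known strand; for real data, strand-ambiguous
variants are the user's responsibility). A model contributes a
prediction only if at least one matched variant is polymorphic
(MAF > 0.01) in the test cohort; unmatched model variants contribute 0.

Model-set comparisons use the Wilcoxon signed-rank test on paired
Spearman ρ over the intersection of predicted proteins (exact null by
enumeration up to 12 untied pairs, normal approximation with continuity
correction beyond; zero differences dropped). The F_ST analysis
computes each model's mean Hudson F_ST (ratio of averages over its
SNPs) between training and test cohorts and contrasts models with large
versus small cross-population performance differences by Mann–Whitney
rank-sum.

A mechanism worth stating explicitly, because it shapes both the tests
and expectations on real data: cross-population transfer loss requires
*tag-based* prediction. When a single strong causal variant is common
in both cohorts, the elastic net selects it and the regression slope
transfers losslessly across any allele-frequency difference. Decay
appears when models lean on LD proxies — modest heritability spread
over several causals, tight LD, small training panels — because
proxy-causal LD and allele frequencies drift together with F. The
transfer experiments therefore use `h2 = 0.3`, three causal variants,
`ld_decay = 0.85` and training panels of 250, with locus-level
differentiation heterogeneity (`fst_heterogeneity = 0.9`) supplying the
cross-model F_ST spread that the group contrast measures.

## 7. Summary-statistic association, colocalization, triage

`spredixcan_assoc()` computes
`z_protein = Σ_l w_l σ_l z_l / sqrt(wᵀ Γ w)` with `σ_l = sqrt(Γ_ll)`
and `Γ` the stored training covariance; GWAS z-scores are first
harmonized to the model's effect alleles (sign flips for swapped
pairs, mismatches dropped). Model variants absent from the GWAS are
removed from both the numerator and the covariance submatrix. The
defining property — equality with the z of regressing the trait on the
genotype-predicted abundance in the same cohort — is verified to
Pearson r > 0.99 and slope 1 ± 0.05 on a 5,000-sample cohort with 200
aptamers.

Discovery significance is pooled Bonferroni, `0.05 / n_tests`, with
tests pooled across populations and traits *within* each model-building
strategy. Colocalization uses Wakefield log ABFs
(`0.5 log(1-r) + z² r/2`, `r = W/(W+V)`, prior effect scale 0.15 on
both sides by default; the pQTL side uses in-sample standard errors)
and the standard single-causal-per-trait enumeration with priors
`p1 = p2 = 1e-4`, `p12 = 1e-5`, all in log space (stable beyond
|z| = 50). Replication requires the replication-cohort association to
pass that set's own per-strategy Bonferroni threshold *and* to have the
same direction of effect. `triage_associations()` stages the three
criteria (counts are monotone non-increasing by construction), and the
headline table keeps the lowest-discovery-p record per distinct
(aptamer, trait) pair.

## 8. The synthetic-data generator

What it emulates: multi-population allele frequencies under the
Balding–Nichols model (per-population `F` targets; optional locus-level
heterogeneity, since real genomes' F_ST varies strongly across loci);
first-order Markov LD within loci (pairwise correlation decays
geometrically with distance; chains restart across loci so loci are
unlinked); sparse cis architectures scaled to an exact latent
heritability; PAV binding artifacts (artifact-driven aptamers carry no
true cis signal beyond the PAV term; optionally inert annotated PAVs
linked to the causal variant); age and sex effects; two timepoints with
independent noise (sd 0.5) and a 20% missing-at-second-timepoint rate;
paired GWAS cohorts drawn at the individual level from the same
generative frequencies, with the trait partially mediated by the true
genetic protein values, then summarized by exact per-SNP regression.

What it does not emulate: recombination-map LD and haplotype blocks of
realistic length, admixture tracts, relatedness, trans-QTLs,
plate/batch structure, genotyping or imputation error (imputation R² is
metadata, set to 1 in simulated panels), assay nonlinearity. Passing
tests therefore demonstrate the correctness and calibration of the
statistical machinery under a faithful but simplified genome — not
performance claims about any real cohort.

Default generator parameters: ancestral frequencies uniform within
loci around a locus base frequency in [0.15, 0.85] (keeps variants
segregating and lets realized neighbor correlation track `ld_decay`);
age ~ Uniform(45, 85) with effect 0.01 per year; sex ~ Bernoulli(0.5)
with effect 0.2; `ld_decay = 0.7`. The end-to-end pipeline default is a
training panel of 500, 50 loci × 12 SNPs, `h2 = 0.5`, two causal
variants per aptamer, one trait-mediating protein (γ = 0.35), and
discovery/replication cohorts of 10,000 — at these sizes the mediated
protein's causal SNPs reach |z| ≈ 25, so discovery power is saturated
and the interesting behavior is in colocalization and triage, not in
marginal power.

## 9. Problem sizes and runtimes

The test suite runs the full acceptance battery at: exhaustive
fine-mapping oracle on 10-variant loci; 200-aptamer summary-vs-
individual equivalence at cohort size 5,000; 50 colocalization
replicates at GWAS size 50,000 (single locus); 50-protein heritability
recovery at n = 400; 50 PAV-robustness replicates per arm; transfer
analysis pooled over three 100-locus panels; 25 end-to-end pipeline
runs; 20 global-null FDR simulations. The whole suite completes in a
few minutes on one CPU; `scripts/acceptance.R` takes about 90 seconds.

## 10. Known limitations

- The fine-mapper is exhaustive-enumeration with a marginal screen
  fallback; it does not implement adaptive shotgun search, so very
  large loci (hundreds of variants) with many signals are outside its
  comfortable range.
- Colocalization is the single-configuration approximate-Bayes-factor
  form: one causal variant per trait per locus, no conditional
  masking of secondary signals.
- The PCA used for population structure is plain PCA; related samples
  would leak structure into the components.
- Model serialization writes the two-table PredictDB-style schema as
  TSV plus gzipped covariance text, one bundle per model set.
- The Spearman p-value uses the t approximation; for n below ~10 it is
  rough, and `evaluate_prediction()` requires n ≥ 10 for that reason.
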
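#' Replication flags for a discovered association
#'
#' An association replicates when its replication-cohort test passes the
#' replication Bonferroni threshold AND has the same direction of effect
#' as the discovery result.
#'
#' @param discovery,replication one-row `association_result`s for the same
#'   aptamer/trait pairing (replication may be `NULL`/missing).
#' @param threshold replication p-value threshold.
#' @return list: `replicated` (logical), `p_pass`, `direction_concordant`,
#'   `status` (`"replicated"`, `"not_replicated"` or `"untested"`).
#' @export
replication_test <- function(discovery, replication, threshold) {
  if (is.null(replication) || nrow(replication) == 0L) {
    return(list(replicated = FALSE, p_pass = NA, direction_concordant = NA,
                status = "untested"))
  }
  p_pass <- replication$pvalue < threshold
  concord <- sign(discovery$zscore) == sign(replication$zscore)
  list(replicated = p_pass && concord, p_pass = p_pass,
       direction_concordant = concord,
       status = if (p_pass && concord) "replicated" else "not_replicated")
}

#' Three-criteria triage of protein-trait associations
#'
#' Staged filtering: (A) discovery associations passing the pooled
#' Bonferroni threshold of their strategy; (B) of those, associations
#' whose locus colocalizes (max P4 > `p4_min`); (C) of those, associations
#' that replicate (replication Bonferroni within strategy, same direction
#' of effect). Records join on aptamer-gene x trait x population x
#' strategy. The headline table keeps, per distinct (aptamer, trait) pair,
#' the record with the lowest discovery p.
#'
#' @param assocs discovery association results (rows from
#'   [spredixcan_assoc()], after [pooled_bonferroni()]).
#' @param colocs data frame `aptamer, gene, trait, p4` (max P4 per locus
#'   x trait); associations without a coloc row are flagged
#'   `coloc_missing` and excluded from stage B.
#' @param replications replication-cohort association results (same
#'   columns as `assocs`); the replication Bonferroni threshold is
#'   computed per strategy over this set.
#' @param p4_min colocalization cutoff (default 0.5).
#' @return list: `records` (per-association `triage_record` rows with
#'   flags and `verdict` in `discovered`, `discovered+colocalized`,
#'   `discovered+colocalized+replicated`, `not_significant`), `headline`
#'   (deduplicated per aptamer-trait), `counts` (stage A/B/C counts per
#'   population x strategy).
#' @export
triage_associations <- function(assocs, colocs, replications,
                                p4_min = 0.5) {
  stopifnot(nrow(assocs) >= 1)
  if (!"bonferroni_flag" %in% names(assocs)) {
    assocs <- pooled_bonferroni(assocs)
  }
  repl_thr <- if (!is.null(replications) && nrow(replications)) {
    tapply(replications$pvalue, replications$strategy,
           function(p) 0.05 / length(p))
  } else numeric(0)

  key <- function(d) paste(d$aptamer, d$gene, d$trait, d$population,
                           d$strategy, sep = "|")
  ckey <- function(d) paste(d$aptamer, d$gene, d$trait, sep = "|")
  rk <- if (!is.null(replications) && nrow(replications)) key(replications)
        else character(0)
  ck <- if (!is.null(colocs) && nrow(colocs)) ckey(colocs) else character(0)

  rec <- assocs
  rec$coloc_p4 <- NA_real_
  rec$coloc_flag <- FALSE
  rec$coloc_missing <- FALSE
  rec$repl_z <- NA_real_
  rec$repl_p <- NA_real_
  rec$repl_status <- "untested"
  rec$verdict <- "not_significant"
  for (i in seq_len(nrow(rec))) {
    if (!rec$bonferroni_flag[i]) next
    rec$verdict[i] <- "discovered"
    ci <- match(ckey(rec[i, ]), ck)
    if (is.na(ci)) {
      rec$coloc_missing[i] <- TRUE
      next
    }
    rec$coloc_p4[i] <- colocs$p4[ci]
    rec$coloc_flag[i] <- colocs$p4[ci] > p4_min
    if (!rec$coloc_flag[i]) next
    rec$verdict[i] <- "discovered+colocalized"
    ri <- match(key(rec[i, ]), rk)
    if (is.na(ri)) next
    rec$repl_z[i] <- replications$zscore[ri]
    rec$repl_p[i] <- replications$pvalue[ri]
    rt <- replication_test(rec[i, ], replications[ri, ],
                           repl_thr[[rec$strategy[i]]])
    rec$repl_status[i] <- rt$status
    if (rt$replicated) rec$verdict[i] <- "discovered+colocalized+replicated"
  }

  # headline: lowest discovery p per distinct (aptamer, trait) pair
  disc <- rec[rec$verdict != "not_significant", , drop = FALSE]
  headline <- NULL
  if (nrow(disc)) {
    pair <- paste(disc$aptamer, disc$trait, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(disc)), pair), function(idx)
      idx[which.min(disc$pvalue[idx])]))
    headline <- disc[sort(keep), , drop = FALSE]
  }

  grp <- interaction(rec$population, rec$strategy, drop = TRUE)
  counts <- do.call(rbind, lapply(levels(grp), function(gl) {
    sub <- rec[grp == gl, , drop = FALSE]
    data.frame(
      population = sub$population[1], strategy = sub$strategy[1],
      n_discovered = sum(sub$bonferroni_flag),
      n_colocalized = sum(sub$bonferroni_flag & sub$coloc_flag),
      n_replicated = sum(sub$verdict == "discovered+colocalized+replicated"),
      stringsAsFactors = FALSE
    )
  }))
  list(records = rec, headline = headline, counts = counts)
}
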
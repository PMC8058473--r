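# Local-vs-commercial group comparisons, resilience indices (LN/HN) and
# accession rankings.

#' Welch t-test between local and commercial accession means
#'
#' Unequal-variance (Welch) two-sided t-test; the pooled-variance
#' variant is inconsistent with the published group contrasts, which the
#' Welch statistic reproduces from the printed summary statistics.
#'
#' @param values_local,values_commercial Accession means per group
#'   (each length >= 2).
#' @return Data frame: group means and SEs, `t`, `df`, `p`,
#'   `flagged` (TRUE when a group has zero variance and n < 3, in which
#'   case the test is still reported but should be read with care).
#' @export
group_ttest <- function(values_local, values_commercial) {
  if (length(values_local) < 2 || length(values_commercial) < 2)
    stop("each group needs at least 2 accession means")
  flagged <- (stats::sd(values_local) == 0 && length(values_local) < 3) ||
    (stats::sd(values_commercial) == 0 && length(values_commercial) < 3)
  if (stats::sd(values_local) == 0 && stats::sd(values_commercial) == 0) {
    eq <- mean(values_local) == mean(values_commercial)
    tt <- list(statistic = if (eq) 0 else Inf, parameter = NA_real_,
               p.value = if (eq) 1 else 0)
  } else {
    tt <- stats::t.test(values_local, values_commercial,
                        var.equal = FALSE)
  }
  data.frame(mean_local = mean(values_local),
             se_local = stats::sd(values_local) / sqrt(length(values_local)),
             mean_commercial = mean(values_commercial),
             se_commercial = stats::sd(values_commercial) /
               sqrt(length(values_commercial)),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Welch t statistic from summary statistics
#'
#' Reconstructs the Welch test from group means, standard errors and
#' sizes — useful when only published summaries are available.
#'
#' @param mean1,se1,n1,mean2,se2,n2 Group summaries.
#' @return List with `t`, `df`, `p`.
#' @export
welch_from_summary <- function(mean1, se1, n1, mean2, se2, n2) {
  t <- (mean1 - mean2) / sqrt(se1^2 + se2^2)
  df <- (se1^2 + se2^2)^2 /
    (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  list(t = t, df = df,
       p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Local-vs-commercial comparison across traits and treatments
#'
#' Runs [group_ttest()] on accession means for every trait under each
#' treatment and flags traits whose group difference is significant
#' under both treatments ("stable" differences).
#'
#' @param table A [trial_table()] whose accessions carry local /
#'   commercial classes.
#' @param alpha Significance level (default 0.05).
#' @return Data frame, one row per trait x treatment, with group
#'   summaries, test results, `significant` and `stable`.
#' @export
group_comparison <- function(table, alpha = 0.05) {
  am <- accession_means(table)
  if (length(unique(am$class)) < 2)
    stop("need both local and commercial accessions")
  out <- do.call(rbind, lapply(unique(am$trait), function(tc) {
    do.call(rbind, lapply(c("LN", "HN"), function(tr) {
      sub <- am[am$trait == tc & am$treatment == tr, ]
      res <- group_ttest(sub$value[sub$class == "local"],
                         sub$value[sub$class == "commercial"])
      cbind(data.frame(trait = tc, treatment = tr,
                       stringsAsFactors = FALSE), res)
    }))
  }))
  out$significant <- out$p < alpha
  stable <- tapply(out$significant, out$trait, all)
  out$stable <- as.logical(stable[out$trait])
  rownames(out) <- NULL
  out
}

#' Resilience index
#'
#' Ratio of an accession's trait mean under low nitrogen to its mean
#' under high nitrogen (LN/HN); values above 1 indicate better
#' performance under the restrictive treatment.
#'
#' @param mean_LN,mean_HN Treatment means; `mean_HN > 0`.
#' @return `mean_LN / mean_HN`.
#' @export
resilience_index <- function(mean_LN, mean_HN) {
  if (any(mean_HN <= 0)) stop("high-N mean must be positive")
  mean_LN / mean_HN
}

#' Per-accession resilience indices with ranks
#'
#' Accessions whose high-nitrogen mean is not positive (possible for
#' simulated concentration traits, impossible for real ones) have no
#' defined ratio: their index and rank are `NA` and a warning is issued;
#' the remaining accessions are ranked 1..n.
#'
#' @param table A [trial_table()].
#' @param traits Traits to include (default all).
#' @return Data frame: `accession`, `trait`, `index`, `rank` (1 =
#'   highest index; ties broken by accession ID).
#' @export
resilience_table <- function(table, traits = NULL) {
  am <- accession_means(table)
  if (is.null(traits)) traits <- unique(am$trait)
  out <- do.call(rbind, lapply(traits, function(tc) {
    sub <- am[am$trait == tc, ]
    ln <- sub[sub$treatment == "LN", ]
    hn_val <- sub$value[sub$treatment == "HN"][
      match(ln$accession, sub$accession[sub$treatment == "HN"])]
    ok <- hn_val > 0
    if (!all(ok))
      warning(sprintf(
        "trait '%s': %d accession(s) with non-positive HN mean excluded from resilience",
        tc, sum(!ok)))
    idx <- rep(NA_real_, nrow(ln))
    idx[ok] <- resilience_index(ln$value[ok], hn_val[ok])
    rk <- rank_accessions(stats::setNames(idx[ok], ln$accession[ok]))
    res <- data.frame(accession = c(rk$accession, ln$accession[!ok]),
                      trait = tc,
                      index = c(rk$value, rep(NA_real_, sum(!ok))),
                      rank = c(rk$rank, rep(NA_integer_, sum(!ok))),
                      stringsAsFactors = FALSE)
    res
  }))
  rownames(out) <- NULL
  out
}

#' Rank accessions by a per-accession value
#'
#' Deterministic dense ranking, 1 = best. Ties are broken by accession
#' ID in lexicographic order so rankings are reproducible.
#'
#' @param values Named numeric vector (names = accession IDs).
#' @param direction `"desc"` (default; largest value ranks first) or
#'   `"asc"`.
#' @return Data frame `accession`, `value`, `rank`, sorted by rank.
#' @export
rank_accessions <- function(values, direction = c("desc", "asc")) {
  direction <- match.arg(direction)
  if (anyDuplicated(names(values))) stop("duplicate accession IDs")
  ord <- order(if (direction == "desc") -values else values,
               names(values))
  data.frame(accession = names(values)[ord], value = unname(values)[ord],
             rank = seq_along(values), stringsAsFactors = FALSE)
}

#' Top-k accessions of a ranking
#'
#' @param ranking A [rank_accessions()] result.
#' @param k Number of rows to keep.
#' @return The first `k` rows.
#' @export
top_k <- function(ranking, k) ranking[seq_len(min(k, nrow(ranking))), ]

#' Ranking table of the best accessions for a lead trait
#'
#' Ranks accessions by `by` under one treatment, keeps the top `k`, and
#' annotates each with its value and whole-collection rank position for
#' the other traits — the structure of the published top-10 tables.
#'
#' @param table A [trial_table()].
#' @param by Lead trait (default `"y"`, yield).
#' @param treatment Treatment to rank within.
#' @param k Number of accessions to keep.
#' @param traits Annotation traits (default all others present).
#' @return Data frame with one row per top accession: lead value and
#'   rank, then `<trait>` / `<trait>_rank` columns.
#' @export
yield_ranking <- function(table, by = "y", treatment = c("LN", "HN"),
                          k = 10, traits = NULL) {
  treatment <- match.arg(treatment)
  am <- accession_means(table)
  am <- am[am$treatment == treatment, ]
  if (is.null(traits)) traits <- setdiff(unique(am$trait), by)
  lead <- am[am$trait == by, ]
  rk <- top_k(rank_accessions(stats::setNames(lead$value,
                                              lead$accession)), k)
  out <- data.frame(accession = rk$accession, stringsAsFactors = FALSE)
  out[[by]] <- rk$value
  out[[paste0(by, "_rank")]] <- rk$rank
  for (tc in traits) {
    sub <- am[am$trait == tc, ]
    full <- rank_accessions(stats::setNames(sub$value, sub$accession))
    m <- match(out$accession, full$accession)
    out[[tc]] <- full$value[m]
    out[[paste0(tc, "_rank")]] <- full$rank[m]
  }
  out
}
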
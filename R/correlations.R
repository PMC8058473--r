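# Phenotypic vs environmental correlation decomposition: trait-trait
# Pearson correlations over accession means (genetic plus average
# environment) and over model residuals (within-cell environment), with
# family-wise Bonferroni control.

.cor_p <- function(r, n) {
  # two-sided p from the t transform of a Pearson correlation
  t <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
}

.cor_with_p <- function(m) {
  # zero-SD warnings from cor() are superseded by the explicit mask below
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(m))
  p <- .cor_p(r, n)
  diag(p) <- 0
  const <- apply(m, 2, function(v) stats::sd(v, na.rm = TRUE)) == 0
  if (any(const)) {
    r[const, ] <- NA; r[, const] <- NA
    p[const, ] <- NA; p[, const] <- NA
    diag(r)[!const] <- 1
    warning("constant trait(s) masked: ",
            paste(colnames(m)[const], collapse = ", "))
  }
  list(r = r, p = p, n = n)
}

#' Phenotypic correlations from accession means
#'
#' Pearson correlations between traits over accession-level mean
#' profiles. By default the unit of observation is the accession x
#' treatment combination (n = g * 2); alternatively the per-accession
#' overall mean (n = g).
#'
#' @param table A [trial_table()].
#' @param basis `"accession_treatment"` (default) or `"accession"`.
#' @return List with matrices `r`, `p`, effective sample sizes `n`, and
#'   the basis used.
#' @export
phenotypic_correlations <- function(table,
                                    basis = c("accession_treatment",
                                              "accession")) {
  basis <- match.arg(basis)
  m <- mean_matrix(table)
  if (basis == "accession") {
    acc <- sub(":.*$", "", rownames(m))
    m <- apply(m, 2, function(v) tapply(v, acc, mean))
  }
  if (nrow(m) < 3) stop("need at least 3 observation units")
  out <- .cor_with_p(m)
  out$basis <- basis
  out
}

#' Environmental correlations from model residuals
#'
#' Pearson correlations between traits over the replicate-level
#' residuals of the bifactorial model, aligned by (accession, treatment,
#' block). Residuals can be supplied (long data frame as returned by
#' [residuals.gn_trial()]) or are computed from the table.
#'
#' @param x A [trial_table()], a [gn_trial()] fit, or a long residual
#'   data frame with columns `trait`, `accession`, `treatment`, `block`,
#'   `residual`.
#' @return List with matrices `r`, `p` and sample sizes `n`.
#' @export
environmental_correlations <- function(x) {
  if (inherits(x, "gn_trial")) {
    res <- residuals(x)
  } else if (inherits(x, "trial_table")) {
    res <- residuals(gn_trial(x))
  } else {
    res <- as.data.frame(x)
    need <- c("trait", "accession", "treatment", "block", "residual")
    miss <- setdiff(need, names(res))
    if (length(miss))
      stop("residual table lacks column(s): ", paste(miss, collapse = ", "))
  }
  res$unit <- paste(res$accession, res$treatment, res$block, sep = ":")
  units <- sort(unique(res$unit))
  traits <- unique(res$trait)
  per_trait <- split(res, res$trait)
  counts <- vapply(per_trait, nrow, integer(1))
  if (length(unique(counts)) > 1)
    stop("misaligned residual tables: unequal record counts per trait")
  m <- matrix(NA_real_, length(units), length(traits),
              dimnames = list(units, traits))
  m[cbind(match(res$unit, units), match(res$trait, traits))] <- res$residual
  if (anyNA(m)) stop("misaligned residual tables: missing cells")
  .cor_with_p(m)
}

#' Bonferroni significance mask for a correlation matrix
#'
#' A pair is significant when its p-value is below `alpha / m` with
#' `m = T(T-1)/2` trait pairs (406 for the 29-trait panel).
#'
#' @param p Symmetric matrix of p-values.
#' @param alpha Family-wise level (default 0.05).
#' @return Logical matrix (diagonal `FALSE`; `NA` entries stay `NA`).
#' @export
bonferroni_mask <- function(p, alpha = 0.05) {
  T <- ncol(p)
  m <- T * (T - 1) / 2
  out <- p < alpha / m
  diag(out) <- FALSE
  out
}

#' Paired phenotypic and environmental correlation analysis
#'
#' Runs both correlation decompositions on a trial and applies the
#' Bonferroni mask to each — the two triangles of the published
#' correlogram.
#'
#' @param table A [trial_table()] (or a [gn_trial()] fit, from which the
#'   underlying means and residuals are reused).
#' @param alpha Family-wise significance level.
#' @param basis Basis for the phenotypic side, see
#'   [phenotypic_correlations()].
#' @return Object of class `correlation_pair`: list with `traits`,
#'   `r_pheno`, `p_pheno`, `sig_pheno`, `r_env`, `p_env`, `sig_env`,
#'   `alpha`.
#' @export
correlation_pair <- function(table, alpha = 0.05,
                             basis = "accession_treatment") {
  ph <- phenotypic_correlations(table, basis = basis)
  en <- environmental_correlations(table)
  common <- intersect(colnames(ph$r), colnames(en$r))
  structure(list(traits = common,
                 r_pheno = ph$r[common, common],
                 p_pheno = ph$p[common, common],
                 sig_pheno = bonferroni_mask(ph$p[common, common], alpha),
                 r_env = en$r[common, common],
                 p_env = en$p[common, common],
                 sig_env = bonferroni_mask(en$p[common, common], alpha),
                 alpha = alpha), class = "correlation_pair")
}

#' @export
print.correlation_pair <- function(x, ...) {
  cat(sprintf(
    "Correlation pair over %d traits: %d significant phenotypic, %d significant environmental (Bonferroni, alpha = %g)\n",
    length(x$traits), sum(x$sig_pheno, na.rm = TRUE) / 2,
    sum(x$sig_env, na.rm = TRUE) / 2, x$alpha))
  invisible(x)
}
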
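# Per-trait bifactorial ANOVA with block removal. On a balanced design the
# sequential sums of squares of y ~ block + G + N + G:N coincide with the
# partial ones, and fitting the block term first is exactly the "block
# effect removed" adjustment of the reference analysis.

#' Bifactorial genotype x nitrogen ANOVA for one trait
#'
#' Fits \code{value ~ block + accession + treatment +
#' accession:treatment} on the balanced replicate-level data of one
#' trait and returns the ANOVA decomposition. All F-tests use the
#' residual mean square by default; for the nitrogen main effect the
#' interaction mean square can be chosen as denominator instead
#' (appropriate when genotypes are regarded as random).
#'
#' @param table A [trial_table()].
#' @param trait_code Trait to analyse.
#' @param n_denominator Denominator for the nitrogen F-test:
#'   `"residual"` (default) or `"interaction"`.
#' @return Object of class `gn_anova`: list with `trait`, `table` (data
#'   frame with rows block/G/N/GxN/residual and columns SS, df, MS, F,
#'   p, stars), `design`, `residuals` (replicate-level, aligned with the
#'   input rows), `cell_means`, `degenerate` (TRUE when the residual SS
#'   is numerically zero).
#' @export
gn_anova <- function(table, trait_code,
                     n_denominator = c("residual", "interaction")) {
  n_denominator <- match.arg(n_denominator)
  df <- as.data.frame(table)
  df <- df[df$trait == trait_code, ]
  if (!nrow(df)) stop("trait not present: ", trait_code)
  d <- list(g = length(unique(df$accession)),
            delta = length(unique(df$treatment)),
            r = length(unique(df$block)))
  if (d$g < 2 || d$delta < 2 || d$r < 2)
    stop("each factor needs at least 2 levels")
  dat <- data.frame(y = df$value,
                    G = factor(df$accession),
                    N = factor(df$treatment, c("LN", "HN")),
                    B = factor(df$block))
  fit <- stats::lm(y ~ B + G + N + G:N, data = dat)
  # perfect-fit warnings are redundant: degeneracy is flagged explicitly
  an <- suppressWarnings(stats::anova(fit))
  rn <- rownames(an)
  pick <- function(term) which(rn == term)
  ord <- c(pick("B"), pick("G"), pick("N"), pick("G:N"), pick("Residuals"))
  out <- data.frame(term = c("block", "G", "N", "GxN", "residual"),
                    SS = an$`Sum Sq`[ord], df = an$Df[ord],
                    MS = an$`Mean Sq`[ord], stringsAsFactors = FALSE)
  # scale-aware zero: SS below this share of the total is numerical noise
  tot_ss <- sum(out$SS)
  zero_tol <- 1e-10 * max(tot_ss, .Machine$double.xmin)
  degenerate <- out$SS[out$term == "residual"] <= zero_tol
  fnum <- out$term %in% c("block", "G", "N", "GxN")
  out$F <- NA_real_; out$p <- NA_real_
  for (i in which(fnum)) {
    den_term <- if (out$term[i] == "N" && n_denominator == "interaction")
      "GxN" else "residual"
    den_ss <- out$SS[out$term == den_term]
    den_ms <- out$MS[out$term == den_term]
    den_df <- out$df[out$term == den_term]
    if (den_ss > zero_tol) {
      out$F[i] <- out$MS[i] / den_ms
      out$p[i] <- stats::pf(out$F[i], out$df[i], den_df,
                            lower.tail = FALSE)
    } else {
      # degenerate denominator: infinite F when the numerator is non-null
      null_num <- out$SS[i] <= zero_tol
      out$F[i] <- if (null_num) 0 else Inf
      out$p[i] <- if (null_num) 1 else 0
    }
  }
  out$stars <- significance_stars(out$p)
  res <- stats::residuals(fit)
  structure(list(trait = trait_code, table = out, design = d,
                 residuals = data.frame(accession = df$accession,
                                        treatment = df$treatment,
                                        block = df$block,
                                        residual = unname(res),
                                        stringsAsFactors = FALSE),
                 n_denominator = n_denominator,
                 degenerate = degenerate),
            class = "gn_anova")
}

#' @export
print.gn_anova <- function(x, ...) {
  cat(sprintf("G x N ANOVA for '%s' (g=%d, treatments=%d, r=%d%s)\n",
              x$trait, x$design$g, x$design$delta, x$design$r,
              if (x$degenerate) ", degenerate residual" else ""))
  tab <- x$table
  tab$SS <- signif(tab$SS, 6); tab$MS <- signif(tab$MS, 6)
  tab$F <- signif(tab$F, 4); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Significance stars at the 0.05 / 0.01 / 0.001 levels
#'
#' @param p Vector of p-values.
#' @return Character vector: `"***"`, `"**"`, `"*"` or `""`.
#' @export
significance_stars <- function(p) {
  out <- ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
  out
}

#' Replicate-level residuals of the bifactorial model
#'
#' Residuals after removing block, genotype, nitrogen and interaction
#' effects — the environmental deviations used by
#' [environmental_correlations()]. Within every genotype-by-treatment
#' cell they sum to zero.
#'
#' @param table A [trial_table()].
#' @param trait_code Trait to analyse.
#' @return Data frame `accession`, `treatment`, `block`, `residual`.
#' @export
residual_table <- function(table, trait_code) {
  gn_anova(table, trait_code)$residuals
}

#' Per-accession low-vs-high nitrogen follow-up contrasts
#'
#' For each accession, tests its LN vs HN replicate means with an
#' LSD-type contrast against the pooled residual mean square of the full
#' bifactorial model (t with the residual degrees of freedom). This
#' per-accession test is a reconstruction: the reference analysis
#' reports which accessions responded to nitrogen but does not name the
#' test used. Percent change is reported relative to the HN mean.
#'
#' @param table A [trial_table()].
#' @param trait_code Trait to analyse.
#' @param alpha Significance level (default 0.05).
#' @return Data frame: `accession`, `mean_LN`, `mean_HN`,
#'   `percent_change`, `t`, `p`, `significant`.
#' @export
interaction_followup <- function(table, trait_code, alpha = 0.05) {
  fit <- gn_anova(table, trait_code)
  if (fit$design$r < 2) stop("need at least 2 replicates")
  df <- as.data.frame(table)
  df <- df[df$trait == trait_code, ]
  ms_res <- fit$table$MS[fit$table$term == "residual"]
  df_res <- fit$table$df[fit$table$term == "residual"]
  r <- fit$design$r
  se <- sqrt(ms_res * 2 / r)
  acc <- sort(unique(df$accession))
  ln <- tapply(df$value[df$treatment == "LN"],
               factor(df$accession[df$treatment == "LN"], acc), mean)
  hn <- tapply(df$value[df$treatment == "HN"],
               factor(df$accession[df$treatment == "HN"], acc), mean)
  tval <- if (se > 0) (ln - hn) / se else ifelse(ln == hn, 0, Inf)
  p <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  data.frame(accession = acc, mean_LN = as.numeric(ln),
             mean_HN = as.numeric(hn),
             percent_change = 100 * (ln - hn) / hn,
             t = as.numeric(tval), p = as.numeric(p),
             significant = as.numeric(p) < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
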
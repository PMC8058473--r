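#' Fit the genotype-by-nitrogen trial model to every trait
#'
#' The package's central fitting function. For each trait in a balanced
#' replicate-level [trial_table()] it fits the bifactorial model
#' \code{value ~ block + accession + treatment + accession:treatment}
#' ([gn_anova()]), extracts variance components from the expected mean
#' squares, and computes broad-sense heritability and the genotypic and
#' phenotypic coefficients of variation with Delta-method standard
#' errors ([genetic_params()]).
#'
#' @param data A [trial_table()] (or a data frame coercible to one).
#' @param traits Trait codes to fit; default all traits present.
#' @param n_denominator Denominator of the nitrogen F-test, passed to
#'   [gn_anova()].
#' @return Object of class `gn_trial` with components `anova` (named
#'   list of [gn_anova()] fits), `genetics` (per-trait data frame of
#'   variance components, H2 and CVs with SEs), `means`
#'   (accession-by-treatment means), `design`, and the call.
#' @seealso [summary.gn_trial()], [coef.gn_trial()],
#'   [residuals.gn_trial()], [simulate.gn_trial()], [plot.gn_trial()]
#' @export
#' @examples
#' tab <- generate_trial(paperlike_config(traits = c("frw", "ssc"), seed = 3))
#' fit <- gn_trial(tab)
#' summary(fit)
gn_trial <- function(data, traits = NULL,
                     n_denominator = c("residual", "interaction")) {
  n_denominator <- match.arg(n_denominator)
  if (!inherits(data, "trial_table")) data <- trial_table(data)
  present <- unique(data$trait)
  if (is.null(traits)) traits <- present
  miss <- setdiff(traits, present)
  if (length(miss))
    stop("trait(s) not in data: ", paste(miss, collapse = ", "))
  fits <- lapply(traits, function(tc)
    gn_anova(data, tc, n_denominator = n_denominator))
  names(fits) <- traits
  df <- as.data.frame(data)
  gen <- do.call(rbind, lapply(traits, function(tc) {
    genetic_params(fits[[tc]], mu = mean(df$value[df$trait == tc]))
  }))
  structure(list(anova = fits, genetics = gen,
                 means = accession_means(data),
                 design = attr(data, "design"),
                 accessions = attr(data, "accessions"),
                 n_denominator = n_denominator,
                 call = match.call()),
            class = "gn_trial")
}

#' @export
print.gn_trial <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "Genotype x nitrogen trial fit: %d accessions x %d treatments x %d blocks, %d trait(s)\n",
    d["g"], d["delta"], d["r"], length(x$anova)))
  cat("Traits:", paste(names(x$anova), collapse = ", "), "\n")
  invisible(x)
}

#' Summarise a fitted genotype-by-nitrogen trial
#'
#' @param object A [gn_trial()] fit.
#' @param ... Unused.
#' @return Object of class `summary.gn_trial` holding the F-ratio table
#'   (per trait: F and significance stars for genotype, nitrogen and
#'   interaction) and the genetic-parameter table (H2, CV_G, CV_P with
#'   standard errors).
#' @export
summary.gn_trial <- function(object, ...) {
  ftab <- do.call(rbind, lapply(object$anova, function(f) {
    tb <- f$table
    data.frame(trait = f$trait,
               F_G = tb$F[tb$term == "G"], sig_G = tb$stars[tb$term == "G"],
               F_N = tb$F[tb$term == "N"], sig_N = tb$stars[tb$term == "N"],
               F_GN = tb$F[tb$term == "GxN"],
               sig_GN = tb$stars[tb$term == "GxN"],
               stringsAsFactors = FALSE)
  }))
  rownames(ftab) <- NULL
  structure(list(f_ratios = ftab, genetics = object$genetics,
                 design = object$design), class = "summary.gn_trial")
}

#' @export
print.summary.gn_trial <- function(x, ...) {
  cat("F-ratios (residual-denominator tests):\n")
  f <- x$f_ratios
  f$F_G <- round(f$F_G, 2); f$F_N <- round(f$F_N, 2)
  f$F_GN <- round(f$F_GN, 2)
  print(f, row.names = FALSE)
  cat("\nGenetic parameters (H2 and CVs with Delta-method SEs):\n")
  g <- x$genetics[c("trait", "H2", "se_H2", "cvg", "se_cvg", "cvp",
                    "se_cvp")]
  g[-1] <- lapply(g[-1], round, 2)
  print(g, row.names = FALSE)
  invisible(x)
}

#' Variance components of a fitted trial
#'
#' @param object A [gn_trial()] fit.
#' @param ... Unused.
#' @return Matrix of variance components (rows: traits; columns:
#'   sigma2_G, sigma2_GN, sigma2_e, sigma2_P).
#' @export
coef.gn_trial <- function(object, ...) {
  g <- object$genetics
  m <- as.matrix(g[c("sigma2_G", "sigma2_GN", "sigma2_e", "sigma2_P")])
  rownames(m) <- g$trait
  m
}

#' Replicate-level residuals of a fitted trial
#'
#' @param object A [gn_trial()] fit.
#' @param ... Unused.
#' @return Long data frame: `trait`, `accession`, `treatment`, `block`,
#'   `residual`.
#' @export
residuals.gn_trial <- function(object, ...) {
  out <- do.call(rbind, lapply(object$anova, function(f)
    cbind(trait = f$trait, f$residuals)))
  rownames(out) <- NULL
  out
}

#' Fitted accession-by-treatment means
#'
#' @param object A [gn_trial()] fit.
#' @param ... Unused.
#' @return Long data frame of accession-by-treatment trait means.
#' @export
fitted.gn_trial <- function(object, ...) object$means

#' Simulate new trials from the fitted variance components
#'
#' Parametric resimulation: each simulated trial is drawn from the
#' generative model of [sim_config()] with the estimated variance
#' components, grand means and treatment effects of the fit.
#'
#' @param object A [gn_trial()] fit.
#' @param nsim Number of trials.
#' @param seed Integer seed for the first trial; subsequent trials use
#'   `seed + 1, ...`.
#' @param ... Unused.
#' @return A list of [trial_table()]s (length `nsim`).
#' @export
simulate.gn_trial <- function(object, nsim = 1, seed = 1L, ...) {
  g <- object$genetics
  mm <- object$means
  d_hn <- vapply(g$trait, function(tc) {
    sub <- mm[mm$trait == tc, ]
    mean(sub$value[sub$treatment == "HN"]) -
      mean(sub$value[sub$treatment == "LN"])
  }, numeric(1))
  trt <- data.frame(trait = g$trait, mu = g$mu, d_HN = unname(d_hn),
                    sigma2_G = g$sigma2_G, sigma2_GN = g$sigma2_GN,
                    sigma2_B = 0, sigma2_e = g$sigma2_e,
                    stringsAsFactors = FALSE)
  ncom <- sum(object$accessions$class == "commercial")
  lapply(seq_len(nsim), function(i)
    generate_trial(sim_config(g = object$design[["g"]],
                              r = object$design[["r"]], traits = trt,
                              seed = seed + i - 1L,
                              n_commercial = ncom)))
}

#' Plot heritability estimates of a fitted trial
#'
#' Dot plot of broad-sense heritability per trait with one-standard-
#' error bars.
#'
#' @param x A [gn_trial()] fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.gn_trial <- function(x, ...) {
  g <- x$genetics[order(x$genetics$H2), ]
  n <- nrow(g)
  graphics::plot(g$H2, seq_len(n), xlim = c(0, 1), yaxt = "n",
                 xlab = expression(H^2), ylab = "",
                 pch = 19, ...)
  graphics::axis(2, at = seq_len(n), labels = g$trait, las = 1,
                 cex.axis = 0.7)
  graphics::segments(pmax(g$H2 - g$se_H2, 0), seq_len(n),
                     pmin(g$H2 + g$se_H2, 1), seq_len(n))
  invisible(x)
}
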
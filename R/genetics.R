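# Variance components from expected mean squares, broad-sense
# heritability with Delta-method standard errors, and coefficients of
# variation. Notation: M1, M2, M3 are the genotype, interaction and
# residual mean squares; delta the number of treatments, r the number of
# replicate blocks.

#' Variance components from balanced two-factor mean squares
#'
#' Expected-mean-square inversion for the balanced genotype x treatment
#' design:
#' \deqn{\sigma^2_G = (M_1 - M_2)/(\delta r), \quad
#'       \sigma^2_{GN} = (M_2 - M_3)/r, \quad \sigma^2_e = M_3}
#' Negative estimates are truncated to zero for reporting (with a flag);
#' untruncated values are retained for standard-error propagation.
#'
#' @param M1,M2,M3 Genotype, interaction and residual mean squares.
#' @param delta Number of treatments (>= 2).
#' @param r Number of replicates (>= 2).
#' @return List with `sigma2_G`, `sigma2_GN`, `sigma2_e`, `sigma2_P`
#'   (their sum), `raw` (untruncated components) and `truncated`
#'   (logical flags).
#' @export
#' @examples
#' variance_components(10, 4, 2, delta = 2, r = 3)
variance_components <- function(M1, M2, M3, delta, r) {
  if (delta < 2 || r < 2) stop("delta and r must be at least 2")
  if (any(c(M1, M2, M3) < 0)) stop("mean squares must be non-negative")
  raw <- c(sigma2_G = (M1 - M2) / (delta * r),
           sigma2_GN = (M2 - M3) / r,
           sigma2_e = M3)
  trunc <- raw < 0
  comp <- pmax(raw, 0)
  list(sigma2_G = comp[["sigma2_G"]], sigma2_GN = comp[["sigma2_GN"]],
       sigma2_e = comp[["sigma2_e"]], sigma2_P = sum(comp),
       raw = raw, truncated = trunc)
}

#' Broad-sense heritability
#'
#' \eqn{H^2 = \sigma^2_G / \sigma^2_P} with
#' \eqn{\sigma^2_P = \sigma^2_G + \sigma^2_{GN} + \sigma^2_e} (the
#' executable phenotypic-variance definition implied by the
#' mean-square decomposition).
#'
#' @param vc A [variance_components()] result.
#' @return H-squared in `[0, 1]`.
#' @export
heritability <- function(vc) {
  if (vc$sigma2_P <= 0) stop("zero phenotypic variance: H2 undefined")
  vc$sigma2_G / vc$sigma2_P
}

#' Delta-method standard error of broad-sense heritability
#'
#' First-order propagation of the mean-square sampling variances
#' \eqn{V_i = 2 M_i^2/(df_i + 2)} through the ratio
#' \eqn{H^2 = A/B} with \eqn{A = (M_1 - M_2)/(\delta r)} and
#' \eqn{B = M_1/(\delta r) + M_2 (\delta - 1)/(\delta r) +
#' M_3 (r - 1)/r}:
#' \deqn{SE(H^2) = H^2 \sqrt{\sigma^2_a/A^2 + \sigma^2_b/B^2 -
#'   2\,cov(A,B)/(AB)}}
#' with \eqn{\sigma^2_a = (V_1 + V_2)/(\delta r)^2},
#' \eqn{\sigma^2_b = V_1/(\delta r)^2 + V_2 ((\delta-1)/(\delta r))^2 +
#' V_3 ((r-1)/r)^2} and, from the same linear expansions,
#' \eqn{cov(A,B) = (V_1 - (\delta - 1) V_2)/(\delta r)^2}. The
#' computation uses the algebraically equivalent stable form
#' \eqn{SE^2 = (\sigma^2_a + h^2 \sigma^2_b - 2 h\,cov(A,B))/B^2} with
#' \eqn{h = A/B} untruncated, which stays finite when \eqn{A \le 0}
#' (reported heritability 0 with a positive standard error).
#'
#' @param M1,M2,M3 Mean squares.
#' @param dfM1,dfM2,dfM3 Their degrees of freedom.
#' @param delta,r Design dimensions.
#' @return Standard error (>= 0).
#' @export
se_heritability <- function(M1, M2, M3, dfM1, dfM2, dfM3, delta, r) {
  if (any(c(dfM1, dfM2, dfM3) <= 0)) stop("degrees of freedom must be positive")
  if (delta < 2 || r < 2) stop("delta and r must be at least 2")
  V1 <- 2 * M1^2 / (dfM1 + 2)
  V2 <- 2 * M2^2 / (dfM2 + 2)
  V3 <- 2 * M3^2 / (dfM3 + 2)
  dr <- delta * r
  A <- (M1 - M2) / dr
  B <- M1 / dr + M2 * (delta - 1) / dr + M3 * (r - 1) / r
  if (B <= 0) stop("non-positive phenotypic variance")
  s2a <- (V1 + V2) / dr^2
  s2b <- V1 / dr^2 + V2 * ((delta - 1) / dr)^2 + V3 * ((r - 1) / r)^2
  cab <- (V1 - (delta - 1) * V2) / dr^2
  h <- A / B
  sqrt(pmax(s2a + h^2 * s2b - 2 * h * cab, 0)) / B
}

#' Coefficient of variation with standard error
#'
#' \eqn{CV = 100 \sqrt{\sigma^2}/\mu} and
#' \eqn{SE(CV) = CV \sqrt{(1 + 2 (CV/100)^2) / (2N)}}, where `N` is the
#' number of individuals behind the estimate (the 44 accessions in the
#' reference design).
#'
#' @param sigma2 Variance component (>= 0).
#' @param mu Trait mean (> 0).
#' @param N Count used in the SE (>= 2).
#' @return List with `cv` and `se` (both in percent).
#' @export
#' @examples
#' cv_with_se(sigma2 = (26.90 * 71.55 / 100)^2, mu = 71.55, N = 44)
cv_with_se <- function(sigma2, mu, N) {
  if (mu <= 0) stop("mean must be positive")
  if (N < 2) stop("N must be at least 2")
  if (sigma2 < 0) stop("variance must be non-negative")
  cv <- 100 * sqrt(sigma2) / mu
  se <- cv * sqrt((1 + 2 * (cv / 100)^2) / (2 * N))
  list(cv = cv, se = se)
}

#' Standard error of a coefficient of variation given as a percent
#'
#' Convenience wrapper applying the SE(CV) formula directly to a printed
#' CV value.
#'
#' @param cv Coefficient of variation, percent.
#' @param N Count used in the estimate.
#' @return Standard error, percent.
#' @export
#' @examples
#' se_cv(26.90, 44)  # 3.07
se_cv <- function(cv, N) {
  if (N < 2) stop("N must be at least 2")
  cv * sqrt((1 + 2 * (cv / 100)^2) / (2 * N))
}

#' Genetic parameters of one trait from its ANOVA
#'
#' Assembles variance components, broad-sense heritability with its
#' Delta-method standard error, and genotypic/phenotypic coefficients of
#' variation with standard errors, from a fitted [gn_anova()].
#'
#' @param fit A [gn_anova()] object.
#' @param mu Trait grand mean (computed from the data the fit came from,
#'   or supplied).
#' @param N Count used in SE(CV); defaults to the number of genotypes.
#' @return One-row data frame: `trait`, `sigma2_G`, `sigma2_GN`,
#'   `sigma2_e`, `sigma2_P`, `H2`, `se_H2`, `cvg`, `se_cvg`, `cvp`,
#'   `se_cvp`, `mu`, plus truncation flags.
#' @export
genetic_params <- function(fit, mu, N = fit$design$g) {
  stopifnot(inherits(fit, "gn_anova"))
  tab <- fit$table
  M1 <- tab$MS[tab$term == "G"]
  M2 <- tab$MS[tab$term == "GxN"]
  M3 <- tab$MS[tab$term == "residual"]
  d1 <- tab$df[tab$term == "G"]
  d2 <- tab$df[tab$term == "GxN"]
  d3 <- tab$df[tab$term == "residual"]
  delta <- fit$design$delta; r <- fit$design$r
  vc <- variance_components(M1, M2, M3, delta, r)
  H2 <- heritability(vc)
  seH2 <- se_heritability(M1, M2, M3, d1, d2, d3, delta, r)
  cvg <- cv_with_se(vc$sigma2_G, mu, N)
  cvp <- cv_with_se(vc$sigma2_P, mu, N)
  data.frame(trait = fit$trait, sigma2_G = vc$sigma2_G,
             sigma2_GN = vc$sigma2_GN, sigma2_e = vc$sigma2_e,
             sigma2_P = vc$sigma2_P, H2 = H2, se_H2 = seH2,
             cvg = cvg$cv, se_cvg = cvg$se, cvp = cvp$cv,
             se_cvp = cvp$se, mu = mu,
             G_truncated = vc$truncated[["sigma2_G"]],
             GN_truncated = vc$truncated[["sigma2_GN"]],
             stringsAsFactors = FALSE)
}
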
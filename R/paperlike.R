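# Published summary statistics of the 44-accession 'de penjar' collection
# (accession-mean basis, two nitrogen treatments), used as the default
# simulation preset and as the printed-quantity inputs for derived-trait
# reproduction. Columns: collection mean/SD/range per treatment, paired
# HN - LN difference, ANOVA F-ratios, heritability and CV estimates.

#' Published collection statistics of the 'de penjar' reference trial
#'
#' Per-trait summary statistics of the reference 44-accession x 2-nitrogen
#' trial, on the accession-mean basis: mean, SD and range under low (LN)
#' and high (HN) nitrogen, mean paired HN - LN difference, F-ratios of
#' the genotype, treatment and interaction terms, and broad-sense
#' heritability and genotypic/phenotypic coefficients of variation with
#' standard errors. These are the quantities from which
#' [paperlike_config()] back-fills a simulation configuration. The
#' vitamin C heritability row was typeset ambiguously in the source
#' table; its stored values are the evident reading and are not used as
#' a numeric anchor anywhere.
#'
#' @return Data frame, one row per trait.
#' @export
depenjar_reference <- function() {
  txt <- "
trait mean_LN sd_LN min_LN max_LN mean_HN sd_HN min_HN max_HN paired_diff F_G F_N F_GN H2 se_H2 cvg se_cvg cvp se_cvp
spad 49.64 3.54 40.67 56.25 48.98 5.41 36.38 60.90 -0.67 4.15 0.15 1.23 0.31 0.08 6.82 0.73 12.23 1.32
y 2.20 0.47 0.96 3.18 1.98 0.46 1.23 3.90 -0.22 3.64 0.66 0.83 0.33 0.07 17.70 1.95 30.77 3.58
frw 72.7 19.9 29.0 132.5 70.4 20.3 29.3 134.6 -2.3 19.04 2.13 0.82 0.76 0.04 26.90 3.07 30.78 3.58
L 36.57 2.95 32.01 43.29 35.50 2.09 31.23 40.42 -1.07 4.16 1.04 1.64 0.26 0.08 4.68 0.50 9.23 0.99
chroma 21.50 3.45 14.69 32.28 21.58 3.28 15.30 33.23 0.08 5.80 0.00 1.17 0.42 0.07 12.74 1.38 19.60 2.17
hue 40.00 5.91 30.53 51.32 37.78 4.19 29.27 46.11 -2.22 4.70 16.86 1.11 0.37 0.07 10.36 1.12 17.12 1.88
Nf 21.1 1.9 17.2 25.4 19.9 2.2 14.6 26.6 -1.2 3.25 3.77 0.94 0.30 0.07 7.51 0.80 14.14 1.54
Cf 408.0 3.1 402.3 416.3 405.8 4.6 390.5 416.7 -2.26 3.32 4.87 1.54 0.40 0.15 0.58 0.06 1.29 0.14
pH 4.13 0.17 3.83 4.63 4.11 0.18 3.83 4.50 -0.02 2.27 0.42 1.32 0.12 0.07 2.22 0.24 6.28 0.67
ssc 5.52 0.57 4.28 6.58 5.69 0.70 4.02 6.87 0.16 4.68 0.90 0.91 0.39 0.07 9.36 1.01 14.94 1.63
ta 0.57 0.13 0.34 0.96 0.58 0.12 0.37 0.85 0.01 5.04 0.02 0.91 0.41 0.07 18.21 2.00 28.27 3.25
cit 6.73 1.77 4.22 12.28 6.30 1.62 4.31 12.66 -0.43 5.37 0.54 1.28 0.38 0.08 20.44 2.27 32.99 3.88
mal 1.30 0.36 0.73 2.00 1.33 0.33 0.83 2.36 0.03 10.44 0.96 1.33 0.58 0.07 23.19 2.60 30.52 3.54
tacid 8.03 1.78 5.22 13.60 7.62 1.60 5.55 13.98 -0.41 4.51 0.45 1.33 0.32 0.08 15.96 1.74 28.08 3.22
citmalr 5.71 2.25 2.69 10.02 5.14 1.99 2.75 9.44 -0.57 11.31 1.40 1.10 0.62 0.06 35.53 4.24 45.05 5.69
fru 18.83 2.41 13.69 22.77 21.28 2.46 16.31 27.50 2.45 3.83 53.25 1.25 0.28 0.07 8.60 0.92 16.13 1.76
glu 15.47 3.02 9.57 21.52 18.37 3.06 10.99 24.93 2.90 4.40 10.90 1.35 0.31 0.08 13.09 1.42 23.39 2.63
tsug 34.30 5.17 24.27 42.87 39.65 5.29 28.96 52.07 5.35 4.19 23.70 1.27 0.31 0.08 10.36 1.12 18.64 2.05
fruglur 1.26 0.18 1.01 1.88 1.19 0.15 1.02 1.93 -0.06 3.93 1.39 2.19 0.17 0.09 7.24 0.78 17.46 1.92
tsi 4.00 0.56 2.86 4.94 4.59 0.58 3.43 5.97 0.59 4.09 32.16 1.25 0.28 0.07 9.69 1.04 17.59 1.93
ssctar 10.54 2.65 5.74 19.27 10.63 2.38 6.84 16.41 0.09 4.64 0.01 0.93 0.39 0.07 19.43 2.15 31.20 3.64
tsugtacidr 4.64 1.21 2.29 7.79 5.57 1.15 3.11 8.70 0.92 3.78 2.40 0.88 0.33 0.07 18.24 2.01 31.54 3.68
tsitar 7.68 2.14 4.14 14.40 8.63 2.10 5.21 13.65 0.95 4.83 1.19 0.96 0.20 0.04 21.29 2.37 33.85 4.00
vitc 0.27 0.04 0.15 0.39 0.29 0.04 0.21 0.38 0.02 2.39 0.91 0.91 0.20 0.06 9.48 1.02 21.10 2.35
lyc 7.99 2.22 3.64 15.87 7.64 2.84 3.34 14.50 -0.34 1.80 0.40 2.23 0.00 0.07 0.00 0.00 46.20 5.88
bcar 3.45 0.84 2.00 5.72 3.17 0.80 1.96 5.15 -0.28 2.69 2.40 2.04 0.07 0.08 9.05 0.97 33.22 3.91
tcar 15.41 4.15 7.51 29.71 14.58 5.04 6.79 26.01 -0.83 1.92 0.71 2.25 0.00 0.08 0.00 0.00 43.08 5.38
gluta 3.42 1.08 1.73 7.01 3.83 0.78 2.34 5.61 0.41 2.29 0.23 1.22 0.14 0.07 14.34 1.56 37.97 4.59
aspa 0.76 0.21 0.33 1.33 0.90 0.19 0.51 1.40 0.14 2.66 0.78 1.03 0.21 0.07 16.26 1.78 35.31 4.21
"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

#' Simulation preset emulating the reference 'de penjar' trial
#'
#' Back-fills a [sim_config()] from the published collection statistics
#' ([depenjar_reference()]): 44 genotypes x 2 nitrogen treatments x 3
#' blocks, per-trait grand mean set to the average of the LN and HN
#' collection means, a fixed treatment effect matching the paired
#' HN - LN difference, genotypic variance \eqn{(CV_G \mu / 100)^2} and
#' phenotypic variance \eqn{(CV_P \mu / 100)^2}. The non-genotypic
#' remainder is split between interaction and residual using the
#' published interaction F-ratio through its expected-mean-square
#' relation \eqn{E[F_{GN}] \approx (r \sigma^2_{GN} + \sigma^2_e) /
#' \sigma^2_e}; interaction variance is set to zero where that F-ratio
#' does not exceed 1. Block variance is not recoverable from the
#' published tables and defaults to zero (blocks are still simulated and
#' fitted).
#'
#' @param traits Trait codes to include; default all 29.
#' @param seed Seed stored in the configuration.
#' @return A [sim_config()].
#' @export
paperlike_config <- function(traits = NULL, seed = 1L) {
  ref <- depenjar_reference()
  if (!is.null(traits)) {
    bad <- setdiff(traits, ref$trait)
    if (length(bad)) stop("unknown trait(s): ", paste(bad, collapse = ", "))
    ref <- ref[ref$trait %in% traits, ]
  }
  r <- 3L
  mu <- (ref$mean_LN + ref$mean_HN) / 2
  s2G <- (ref$cvg * mu / 100)^2
  s2P <- (ref$cvp * mu / 100)^2
  rem <- pmax(s2P - s2G, 0)
  f <- ref$F_GN
  s2e <- ifelse(f > 1, rem / (1 + (f - 1) / r), rem)
  s2GN <- rem - s2e
  sim_config(
    g = 44L, r = r, seed = seed, n_commercial = 5L,
    traits = data.frame(trait = ref$trait, mu = mu,
                        d_HN = ref$paired_diff,
                        sigma2_G = s2G, sigma2_GN = s2GN,
                        sigma2_B = 0, sigma2_e = s2e,
                        stringsAsFactors = FALSE))
}
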
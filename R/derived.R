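# Derived fruit-quality traits: sums, ratios, sweetness index, carotenoid
# quantification from spectrophotometric absorbances, and the relative
# summary statistics (percent changes, fold ranges).

#' Total sweetness index
#'
#' Perceived-sweetness proxy weighting the two reducing sugars,
#' 0.76 x glucose + 1.50 x fructose, with concentrations expressed in
#' g per 100 g. Inputs are in the trial's native g kg-1 fresh weight and
#' are divided by 10 first; this scaling is what puts the index on the
#' published scale (collection means near 4).
#'
#' @param glu,fru Glucose and fructose concentrations, g kg-1 fw.
#' @return Dimensionless index.
#' @export
#' @examples
#' total_sweetness_index(15.47, 18.83)  # 4.00
total_sweetness_index <- function(glu, fru) {
  if (any(glu < 0) || any(fru < 0))
    stop("sugar concentrations must be non-negative")
  0.76 * glu / 10 + 1.50 * fru / 10
}

#' Sum of two component traits
#'
#' Used for total sugars (fructose + glucose), total acids
#' (citric + malic) and vitamin C (ascorbic + dehydroascorbic).
#'
#' @param a,b Component concentrations, same units.
#' @return `a + b`.
#' @export
sum_trait <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("components must be non-negative")
  a + b
}

#' Ratio of two traits
#'
#' Computed per replicate, before any averaging: collection values of
#' e.g. the fructose:glucose ratio are means of per-replicate ratios,
#' not ratios of means.
#'
#' @param num,den Numerator and denominator values.
#' @return `num / den`.
#' @export
ratio_trait <- function(num, den) {
  if (any(den <= 0))
    stop("ratio denominator must be positive (zero indicates a data problem)")
  num / den
}

#' Carotenoid concentrations from absorbance readings
#'
#' Converts hexane-phase absorbances at 510, 452 and 485 nm of an
#' ethanol:hexane extract of freeze-dried fruit powder into lycopene,
#' beta-carotene and total carotenoid concentrations (mg kg-1):
#' \deqn{lyc = A_{510} \cdot 537 \cdot 2.7 / (m \cdot 172) \cdot 100}
#' \deqn{bcar = [A_{452} - 0.9285 A_{510}] \cdot 533.85 \cdot 2.7 / (m \cdot 139) \cdot 100}
#' \deqn{tcar = A_{485} \cdot 2.7 / (m \cdot 181) \cdot 100}
#' with m the sample mass in mg (reference protocol: 30 mg) and 2.7 the
#' solvent volume. The beta-carotene bracket can go negative with noisy
#' readings; it is floored at zero with a warning.
#'
#' @param A452,A485,A510 Absorbance readings (>= 0).
#' @param mass Sample mass, mg dry powder.
#' @return Data frame with columns `lyc`, `bcar`, `tcar` (mg kg-1).
#' @export
#' @examples
#' carotenoids_from_absorbance(0.25, 0.4, 0.1, mass = 30)
carotenoids_from_absorbance <- function(A452, A485, A510, mass = 30) {
  if (any(mass <= 0)) stop("sample mass must be positive")
  if (any(A452 < 0) || any(A485 < 0) || any(A510 < 0))
    stop("absorbances must be non-negative")
  lyc <- A510 * 537 * 2.7 / (mass * 172) * 100
  bracket <- A452 - A510 * 0.9285
  if (any(bracket < 0))
    warning("negative beta-carotene bracket floored at 0")
  bcar <- pmax(bracket, 0) * 533.85 * 2.7 / (mass * 139) * 100
  tcar <- A485 * 2.7 / (mass * 181) * 100
  data.frame(lyc = lyc, bcar = bcar, tcar = tcar)
}

#' Percent change of the low-N mean relative to the high-N mean
#'
#' @param mean_LN,mean_HN Trait means under the two treatments.
#' @param reference Which mean is the denominator; the published
#'   convention takes high N as the reference.
#' @return Percent change, `100 * (mean_LN - mean_HN) / reference`.
#' @export
#' @examples
#' percent_change_LN_vs_HN(18.83, 21.28)  # -11.5 (fructose)
percent_change_LN_vs_HN <- function(mean_LN, mean_HN,
                                    reference = c("HN", "LN")) {
  reference <- match.arg(reference)
  ref <- if (reference == "HN") mean_HN else mean_LN
  if (any(ref == 0)) stop("zero reference mean")
  100 * (mean_LN - mean_HN) / ref
}

#' Relative difference between a reference group and another group
#'
#' How much higher the reference (local) group's mean is, as a percent of
#' the reference mean: `100 * (mean_ref - mean_other) / mean_ref`. This
#' reference convention is the one consistent with the published
#' local-vs-commercial contrasts (e.g. 30.0% for ssctar under HN).
#'
#' @param mean_ref Reference-group mean (> 0).
#' @param mean_other Other group's mean.
#' @return Percent difference.
#' @export
group_relative_difference <- function(mean_ref, mean_other) {
  if (any(mean_ref <= 0)) stop("reference mean must be positive")
  100 * (mean_ref - mean_other) / mean_ref
}

#' Relative range of variation
#'
#' @param max,min Range endpoints, `min > 0`.
#' @return Fold range `max / min`.
#' @export
relative_range <- function(max, min) {
  if (any(min <= 0)) stop("minimum must be positive")
  max / min
}

#' Compute all derived traits at replicate level
#'
#' Adds, for each (accession, treatment, block) cell, every derived trait
#' whose components are present and not already recorded: tacid, tsug,
#' citmalr, fruglur, tsi, ssctar, tsugtacidr, tsitar. Ratios are taken
#' within the replicate; only afterwards may results be averaged.
#'
#' @param table A [trial_table()].
#' @return A [trial_table()] with the derived records appended.
#' @export
derive_traits <- function(table) {
  df <- as.data.frame(table)
  have <- unique(df$trait)
  wide <- stats::reshape(df, idvar = c("accession", "class", "treatment",
                                       "block"),
                         timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  add <- list(
    tacid = function(w) sum_trait(w$cit, w$mal),
    tsug = function(w) sum_trait(w$fru, w$glu),
    tsi = function(w) total_sweetness_index(w$glu, w$fru),
    citmalr = function(w) ratio_trait(w$cit, w$mal),
    fruglur = function(w) ratio_trait(w$fru, w$glu),
    ssctar = function(w) ratio_trait(w$ssc, w$ta),
    tsugtacidr = function(w) ratio_trait(w$tsug, w$tacid),
    tsitar = function(w) ratio_trait(w$tsi, w$ta)
  )
  deps <- list(tacid = c("cit", "mal"), tsug = c("fru", "glu"),
               tsi = c("glu", "fru"), citmalr = c("cit", "mal"),
               fruglur = c("fru", "glu"), ssctar = c("ssc", "ta"),
               tsugtacidr = c("tsug", "tacid"), tsitar = c("tsi", "ta"))
  for (tc in names(add)) {
    if (tc %in% have) next
    if (!all(deps[[tc]] %in% names(wide))) next
    wide[[tc]] <- add[[tc]](wide)
    have <- c(have, tc)
  }
  long <- stats::reshape(
    wide, idvar = c("accession", "class", "treatment", "block"),
    varying = setdiff(names(wide),
                      c("accession", "class", "treatment", "block")),
    v.names = "value", timevar = "trait",
    times = setdiff(names(wide),
                    c("accession", "class", "treatment", "block")),
    direction = "long")
  rownames(long) <- NULL
  trial_table(long[c("accession", "class", "treatment", "block",
                     "trait", "value")])
}
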
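#' Registry of vegetative and fruit-quality traits
#'
#' Returns the catalogue of the 29 traits handled by the package: SPAD value
#' and yield on the plant side, and 27 fruit composition and quality traits.
#' Derived traits (sums, ratios, the total sweetness index and the
#' spectrophotometric carotenoid concentrations) carry a `formula_id`
#' resolving to the corresponding derivation rule in [derive_traits()].
#'
#' @return A data frame with columns `code`, `name`, `units`, `derived`
#'   (logical) and `formula_id` (`NA` for measured traits).
#' @seealso [derive_traits()], [paperlike_config()]
#' @export
#' @examples
#' reg <- trait_registry()
#' subset(reg, derived)$code
trait_registry <- function() {
  reg <- data.frame(
    code = c("spad", "y", "frw", "L", "chroma", "hue", "Nf", "Cf", "pH",
             "ssc", "ta", "cit", "mal", "tacid", "citmalr", "fru", "glu",
             "tsug", "fruglur", "tsi", "ssctar", "tsugtacidr", "tsitar",
             "vitc", "lyc", "bcar", "tcar", "gluta", "aspa"),
    name = c("SPAD value", "Yield", "Fruit mean weight", "Lightness",
             "Chroma", "Hue", "Fruit nitrogen content",
             "Fruit carbon content", "pH", "Soluble solid content",
             "Titratable acidity", "Citric acid content",
             "Malic acid content", "Total acid content",
             "Citric:malic acid ratio", "Fructose content",
             "Glucose content", "Total sugar content",
             "Fructose:glucose ratio", "Total sweetness index",
             "Soluble solid content:titratable acidity ratio",
             "Total sugar:total acid ratio",
             "Total sweetness index:titratable acidity ratio",
             "Vitamin C content", "Lycopene content",
             "beta-Carotene content", "Total carotenoid content",
             "Glutamic acid content", "Aspartic acid content"),
    units = c("-", "kg plant-1", "g", "-", "-", "deg", "g kg-1 dm",
              "g kg-1 dm", "-", "%", "%", "g kg-1 fw", "g kg-1 fw",
              "g kg-1 fw", "-", "g kg-1 fw", "g kg-1 fw", "g kg-1 fw",
              "-", "-", "-", "-", "-", "g kg-1 fw", "mg kg-1 fw",
              "mg kg-1 fw", "mg kg-1 fw", "g kg-1 fw", "g kg-1 fw"),
    derived = FALSE,
    formula_id = NA_character_,
    stringsAsFactors = FALSE
  )
  rules <- c(tacid = "sum:cit+mal", tsug = "sum:fru+glu",
             citmalr = "ratio:cit/mal", fruglur = "ratio:fru/glu",
             tsi = "tsi:glu,fru", ssctar = "ratio:ssc/ta",
             tsugtacidr = "ratio:tsug/tacid", tsitar = "ratio:tsi/ta",
             lyc = "carotenoid:lyc", bcar = "carotenoid:bcar",
             tcar = "carotenoid:tcar")
  hit <- match(names(rules), reg$code)
  reg$derived[hit] <- TRUE
  reg$formula_id[hit] <- unname(rules)
  # concentration-like traits cannot be negative in valid data
  reg$concentration <- reg$units != "-" | reg$code %in%
    c("citmalr", "fruglur", "tsi", "ssctar", "tsugtacidr", "tsitar")
  reg
}

#' Construct a balanced replicate-level trial table
#'
#' A `trial_table` holds one row per (accession, treatment, block, trait)
#' measurement of a balanced genotype-by-nitrogen trial. The constructor
#' validates the treatment labels, checks that every trait is observed in
#' every design cell, and records the design dimensions (g genotypes,
#' delta treatments, r blocks).
#'
#' @param records Data frame with columns `accession`, `class`
#'   (`"local"`/`"commercial"`), `treatment` (`"LN"`/`"HN"`), `block`
#'   (integer), `trait`, `value`.
#' @param require_known_traits Reject trait codes absent from
#'   [trait_registry()] (default `TRUE`).
#' @return An object of class `trial_table`: the records plus a `design`
#'   attribute `c(g, delta, r)` and an `accessions` attribute with the
#'   accession-to-class map.
#' @export
trial_table <- function(records, require_known_traits = TRUE) {
  needed <- c("accession", "class", "treatment", "block", "trait", "value")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[needed]
  if (!is.numeric(records$value))
    stop("'value' must be numeric; coerce and check the source file")
  bad_tr <- setdiff(unique(records$treatment), c("LN", "HN"))
  if (length(bad_tr))
    stop("unknown treatment labels: ", paste(bad_tr, collapse = ", "),
         " (expected LN/HN; remap on input)")
  if (require_known_traits) {
    bad <- setdiff(unique(records$trait), trait_registry()$code)
    if (length(bad))
      stop("unknown trait code(s): ", paste(bad, collapse = ", "))
  }
  bad_cl <- setdiff(unique(records$class), c("local", "commercial"))
  if (length(bad_cl))
    stop("unknown variety class: ", paste(bad_cl, collapse = ", "))

  acc <- sort(unique(records$accession))
  trt <- c("LN", "HN")
  blk <- sort(unique(records$block))
  g <- length(acc); r <- length(blk)
  # balance: every (accession, treatment, block) present once per trait
  for (tc in unique(records$trait)) {
    sub <- records[records$trait == tc, ]
    tab <- table(factor(sub$accession, acc), factor(sub$treatment, trt),
                 factor(sub$block, blk))
    if (any(tab != 1L)) {
      hole <- which(tab != 1L, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "unbalanced design for trait '%s': cell (accession=%s, treatment=%s, block=%s) has %d value(s)",
        tc, acc[hole[1]], trt[hole[2]], blk[hole[3]],
        tab[hole[1], hole[2], hole[3]]))
    }
  }
  cls <- unique(records[c("accession", "class")])
  if (anyDuplicated(cls$accession))
    stop("accession assigned to more than one variety class")
  structure(records, class = c("trial_table", "data.frame"),
            design = c(g = g, delta = 2L, r = r),
            accessions = cls[order(cls$accession), ])
}

#' @export
print.trial_table <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf(
    "Balanced G x N trial: %d accessions x %d treatments x %d blocks, %d traits (%d records)\n",
    d["g"], d["delta"], d["r"], length(unique(x$trait)), nrow(x)))
  invisible(x)
}

#' Read a replicate-level trial from CSV
#'
#' Long-format CSV, one row per measurement, decimal point ".". Column
#' names and treatment labels can be remapped through `dialect`.
#'
#' @param path CSV file path.
#' @param dialect Optional named list: `columns` (named character vector
#'   mapping standard names `accession`, `class`, `treatment`, `block`,
#'   `trait`, `value` to the file's column names) and `treatment_labels`
#'   (named character vector mapping file labels to `"LN"`/`"HN"`).
#' @return A [trial_table()].
#' @export
read_trial <- function(path, dialect = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c(accession = "accession", class = "class",
            treatment = "treatment", block = "block",
            trait = "trait", value = "value")
  if (!is.null(dialect$columns))
    cols[names(dialect$columns)] <- unlist(dialect$columns)
  miss <- setdiff(unname(cols), names(raw))
  if (length(miss))
    stop("file lacks column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(accession = as.character(raw[[cols["accession"]]]),
                   class = as.character(raw[[cols["class"]]]),
                   treatment = as.character(raw[[cols["treatment"]]]),
                   block = raw[[cols["block"]]],
                   trait = as.character(raw[[cols["trait"]]]),
                   value = raw[[cols["value"]]],
                   stringsAsFactors = FALSE)
  if (!is.null(dialect$treatment_labels)) {
    m <- dialect$treatment_labels
    df$treatment <- ifelse(df$treatment %in% names(m),
                           unname(m[df$treatment]), df$treatment)
  }
  if (!is.numeric(df$value)) {
    suppressWarnings(v <- as.numeric(df$value))
    if (anyNA(v) & !anyNA(df$value))
      stop("non-numeric value at row ", which(is.na(v))[1])
    df$value <- v
  }
  if (anyNA(df$value))
    stop("non-numeric or missing value at row ", which(is.na(df$value))[1])
  trial_table(df)
}

#' Write a trial table to CSV
#'
#' @param table A [trial_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a summary table as TSV
#'
#' Fixed column order, numeric columns rounded to `digits` decimals
#' (2 by default, the precision of the published summary tables).
#'
#' @param table Rectangular data frame.
#' @param path Output path.
#' @param digits Decimal places for numeric columns.
#' @return `path`, invisibly.
#' @export
write_summary <- function(table, path, digits = 2) {
  out <- as.data.frame(table)
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- round(out[[j]], digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-treatment collection summary of a trial
#'
#' Accession means are computed first (over blocks); the summary reports,
#' per trait, the mean, SD and range of those accession means under each
#' treatment and the mean paired HN - LN difference.
#'
#' @param table A [trial_table()].
#' @return Data frame with columns `trait`, `mean_LN`, `sd_LN`,
#'   `min_LN`, `max_LN`, `mean_HN`, `sd_HN`, `min_HN`, `max_HN`,
#'   `paired_diff`.
#' @export
collection_summary <- function(table) {
  am <- accession_means(table)
  traits <- unique(am$trait)
  out <- lapply(traits, function(tc) {
    sub <- am[am$trait == tc, ]
    ln <- sub$value[sub$treatment == "LN"]
    hn <- sub$value[sub$treatment == "HN"]
    # pair by accession for the HN - LN difference
    sln <- sub[sub$treatment == "LN", ]
    shn <- sub[sub$treatment == "HN", ]
    d <- shn$value[match(sln$accession, shn$accession)] - sln$value
    data.frame(trait = tc, mean_LN = mean(ln), sd_LN = stats::sd(ln),
               min_LN = min(ln), max_LN = max(ln), mean_HN = mean(hn),
               sd_HN = stats::sd(hn), min_HN = min(hn), max_HN = max(hn),
               paired_diff = mean(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Accession-by-treatment trait means
#'
#' @param table A [trial_table()].
#' @return Long data frame: `accession`, `class`, `treatment`, `trait`,
#'   `value` (mean over blocks).
#' @export
accession_means <- function(table) {
  df <- as.data.frame(table)
  agg <- stats::aggregate(value ~ accession + class + treatment + trait,
                          data = df, FUN = mean)
  agg[order(agg$trait, agg$treatment, agg$accession), ]
}

#' Accession-by-treatment mean matrix (wide)
#'
#' Rows are accession:treatment combinations, columns traits — the input
#' shape for [trial_pca()] and [phenotypic_correlations()].
#'
#' @param table A [trial_table()].
#' @return Numeric matrix with rownames `accession:treatment` and an
#'   attribute `treatment` giving each row's treatment.
#' @export
mean_matrix <- function(table) {
  am <- accession_means(table)
  am$unit <- paste(am$accession, am$treatment, sep = ":")
  units <- sort(unique(am$unit))
  traits <- unique(am$trait)
  m <- matrix(NA_real_, length(units), length(traits),
              dimnames = list(units, traits))
  m[cbind(match(am$unit, units), match(am$trait, traits))] <- am$value
  structure(m, treatment = sub("^.*:", "", units))
}
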
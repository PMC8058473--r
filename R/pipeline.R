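# One-call pipeline: simulate or read a trial, derive traits, fit the
# bifactorial model, and emit the published table structures as TSVs.

#' Run the full trial-analysis pipeline
#'
#' Chains data input (or simulation), derived traits, the
#' genotype-by-nitrogen fit, correlations, PCA, group comparisons and
#' rankings, writing one TSV per published table analogue plus a
#' plain-text provenance log. Deterministic for a fixed configuration.
#'
#' @param config Either the path to a YAML file or a list with entries:
#'   `input` (CSV path) or `simulate` (`TRUE` to use
#'   [paperlike_config()]), `seed` (integer, simulation only), `out_dir`
#'   (output directory), `alpha` (default 0.05), `stages` (character
#'   subset of `c("anova", "genetics", "correlations", "pca",
#'   "groups", "ranking", "resilience")`; default all), and options
#'   `n_denominator`, `pheno_corr_basis`.
#' @return Invisibly, a list with the fitted objects and the paths of
#'   the written files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(simulate = TRUE, seed = 1L, out_dir = "gn_out", alpha = 0.05,
         stages = c("anova", "genetics", "correlations", "pca",
                    "groups", "ranking", "resilience"),
         n_denominator = "residual",
         pheno_corr_basis = "accession_treatment"),
    config)
  ok_stage <- c("anova", "genetics", "correlations", "pca", "groups",
                "ranking", "resilience")
  bad <- setdiff(cfg$stages, ok_stage)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(tab, name) {
    p <- file.path(cfg$out_dir, name)
    write_summary(tab, p)
    paths[[name]] <<- p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  table <- stage("input", {
    if (!is.null(cfg$input)) read_trial(cfg$input)
    else generate_trial(paperlike_config(seed = cfg$seed))
  })
  table <- stage("derive", derive_traits(table))
  out <- list(table = table)

  summ <- stage("summary", collection_summary(table))
  emit(summ, "table3_summary.tsv")

  fit <- stage("anova", gn_trial(table, n_denominator = cfg$n_denominator))
  out$fit <- fit
  if ("anova" %in% cfg$stages)
    emit(summary(fit)$f_ratios, "table2_fratios.tsv")
  if ("genetics" %in% cfg$stages)
    emit(fit$genetics[c("trait", "H2", "se_H2", "cvg", "se_cvg", "cvp",
                        "se_cvp")], "table5_genetics.tsv")
  if ("correlations" %in% cfg$stages) {
    cp <- stage("correlations",
                correlation_pair(table, alpha = cfg$alpha,
                                 basis = cfg$pheno_corr_basis))
    out$correlations <- cp
    idx <- which(upper.tri(cp$r_pheno), arr.ind = TRUE)
    long <- data.frame(traitA = cp$traits[idx[, 1]],
                       traitB = cp$traits[idx[, 2]],
                       r_pheno = cp$r_pheno[idx],
                       sig_pheno = cp$sig_pheno[idx],
                       r_env = cp$r_env[idx], sig_env = cp$sig_env[idx],
                       stringsAsFactors = FALSE)
    emit(long, "fig2_correlations.tsv")
  }
  if ("pca" %in% cfg$stages) {
    pca <- stage("pca", trial_pca(mean_matrix(table), k = 2))
    out$pca <- pca
    sc <- data.frame(unit = rownames(pca$scores),
                     treatment = pca$treatment, pca$scores,
                     stringsAsFactors = FALSE)
    emit(sc, "fig3_pca_scores.tsv")
    ld <- data.frame(trait = rownames(pca$loadings), pca$loadings,
                     stringsAsFactors = FALSE)
    emit(ld, "fig3_pca_loadings.tsv")
  }
  if ("groups" %in% cfg$stages) {
    gc <- stage("groups", group_comparison(table, alpha = cfg$alpha))
    out$groups <- gc
    emit(gc[gc$stable, ], "table4_groups.tsv")
  }
  if ("ranking" %in% cfg$stages) {
    t6 <- stage("ranking", rbind(
      cbind(treatment = "LN", yield_ranking(table, treatment = "LN")),
      cbind(treatment = "HN", yield_ranking(table, treatment = "HN"))))
    out$ranking <- t6
    emit(t6, "table6_yield_ranking.tsv")
  }
  if ("resilience" %in% cfg$stages) {
    res <- stage("resilience", resilience_table(table))
    out$resilience <- res
    top <- res[res$trait == "y" & res$rank <= 10, ]
    emit(top, "table7_resilience.tsv")
  }

  log <- c(sprintf("gntrial pipeline run %s", format(Sys.time(), "%Y-%m-%d")),
           sprintf("seed: %s", cfg$seed),
           sprintf("records: %d", nrow(table)),
           sprintf("traits: %s", paste(unique(table$trait), collapse = ",")),
           sprintf("stages: %s", paste(cfg$stages, collapse = ",")),
           "config:",
           paste0("  ", strsplit(yaml::as.yaml(
             cfg[setdiff(names(cfg), "stages")]), "\n")[[1]]))
  writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  out$paths <- paths
  invisible(out)
}
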
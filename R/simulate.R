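# Synthetic balanced G x N trials with known variance structure, plus
# instrument-level absorbance fixtures for the carotenoid conversions.
# Every random effect is normal with the configured variance, so the
# expected-mean-square relations used downstream are exact.

#' Simulation configuration for a balanced G x N trial
#'
#' Defines the design (g genotypes, 2 treatments, r blocks) and, per
#' trait, the generative model
#' \deqn{y_{ijk} = \mu + G_i + N_j + (GN)_{ij} + B_k + \epsilon_{ijk}}
#' with independent zero-mean normal \eqn{G_i \sim N(0, \sigma^2_G)},
#' \eqn{(GN)_{ij} \sim N(0, \sigma^2_{GN})}, \eqn{B_k \sim N(0,
#' \sigma^2_B)}, \eqn{\epsilon \sim N(0, \sigma^2_e)}. The nitrogen
#' main effect is fixed: the LN and HN treatment means differ by `d_HN`
#' (HN minus LN), applied symmetrically around `mu`.
#'
#' @param g Number of genotypes (>= 2).
#' @param r Number of replicate blocks (>= 2).
#' @param traits Data frame with columns `trait`, `mu`, `d_HN`,
#'   `sigma2_G`, `sigma2_GN`, `sigma2_B`, `sigma2_e`.
#' @param seed Integer seed used by [generate_trial()].
#' @param n_commercial How many of the `g` accessions are labelled
#'   commercial (`C1`, `C2`, ...); the rest are local (`L01`, ...).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(g, r, traits, seed = 1L, n_commercial = 0L) {
  stopifnot(g >= 2, r >= 2, n_commercial >= 0, n_commercial < g)
  need <- c("trait", "mu", "d_HN", "sigma2_G", "sigma2_GN", "sigma2_B",
            "sigma2_e")
  miss <- setdiff(need, names(traits))
  if (length(miss))
    stop("trait table lacks column(s): ", paste(miss, collapse = ", "))
  v <- as.matrix(traits[c("sigma2_G", "sigma2_GN", "sigma2_B", "sigma2_e")])
  if (any(v < 0)) stop("variance components must be non-negative")
  if (anyDuplicated(traits$trait)) stop("duplicate trait codes")
  structure(list(g = as.integer(g), delta = 2L, r = as.integer(r),
                 traits = as.data.frame(traits), seed = as.integer(seed),
                 n_commercial = as.integer(n_commercial)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d genotypes x 2 treatments x %d blocks, %d trait(s), seed %d\n",
              x$g, x$r, nrow(x$traits), x$seed))
  invisible(x)
}

.accession_ids <- function(g, n_commercial) {
  n_local <- g - n_commercial
  ids <- sprintf("L%02d", seq_len(n_local))
  if (n_commercial > 0) ids <- c(ids, sprintf("C%d", seq_len(n_commercial)))
  ids
}

#' Generate a balanced replicate-level trial
#'
#' Draws one value per (accession, treatment, block, trait) from the
#' model in [sim_config()]. Traits are generated independently. Output
#' is identical for identical configuration (the seed is part of the
#' configuration).
#'
#' @param cfg A [sim_config()].
#' @return A [trial_table()].
#' @export
#' @examples
#' tab <- generate_trial(paperlike_config(traits = "frw", seed = 7))
#' nrow(tab)  # 264
generate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  g <- cfg$g; r <- cfg$r
  ids <- .accession_ids(g, cfg$n_commercial)
  cls <- c(rep("local", g - cfg$n_commercial),
           rep("commercial", cfg$n_commercial))
  grid <- expand.grid(block = seq_len(r), treatment = c("LN", "HN"),
                      accession = ids, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$class <- cls[match(grid$accession, ids)]
  out <- vector("list", nrow(cfg$traits))
  for (k in seq_len(nrow(cfg$traits))) {
    p <- cfg$traits[k, ]
    Gi <- stats::rnorm(g, 0, sqrt(p$sigma2_G))
    GNij <- matrix(stats::rnorm(g * 2, 0, sqrt(p$sigma2_GN)), g, 2)
    Bk <- stats::rnorm(r, 0, sqrt(p$sigma2_B))
    eps <- stats::rnorm(nrow(grid), 0, sqrt(p$sigma2_e))
    i <- match(grid$accession, ids)
    j <- ifelse(grid$treatment == "HN", 2L, 1L)
    tau <- ifelse(j == 2L, p$d_HN / 2, -p$d_HN / 2)
    y <- p$mu + tau + Gi[i] + GNij[cbind(i, j)] + Bk[grid$block] + eps
    out[[k]] <- data.frame(accession = grid$accession, class = grid$class,
                           treatment = grid$treatment, block = grid$block,
                           trait = p$trait, value = y,
                           stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  trial_table(rec, require_known_traits =
                all(rec$trait %in% trait_registry()$code))
}

#' Generate absorbance triplets consistent with target carotenoid levels
#'
#' Inverts the spectrophotometric equations of
#' [carotenoids_from_absorbance()]: target concentrations are drawn
#' uniformly within the supplied ranges, converted to the noise-free
#' absorbances that would produce them, and Gaussian instrument noise is
#' added (floored at zero absorbance). With `noise_sd = 0` the forward
#' conversion recovers the targets exactly.
#'
#' @param n Number of samples.
#' @param mass Sample mass, mg (reference protocol 30 mg).
#' @param lyc_range,bcar_range,tcar_range Target concentration ranges,
#'   mg kg-1.
#' @param noise_sd Absorbance noise SD (>= 0).
#' @param seed Integer seed.
#' @return Data frame with columns `A452`, `A485`, `A510`, `mass`,
#'   `true_lyc`, `true_bcar`, `true_tcar`.
#' @export
generate_absorbances <- function(n, mass = 30,
                                 lyc_range = c(3.64, 15.87),
                                 bcar_range = c(2.00, 5.72),
                                 tcar_range = c(7.51, 29.71),
                                 noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (mass <= 0) stop("mass must be positive")
  set.seed(seed)
  if (n == 0)
    return(data.frame(A452 = numeric(0), A485 = numeric(0),
                      A510 = numeric(0), mass = numeric(0),
                      true_lyc = numeric(0), true_bcar = numeric(0),
                      true_tcar = numeric(0)))
  lyc <- stats::runif(n, lyc_range[1], lyc_range[2])
  bcar <- stats::runif(n, bcar_range[1], bcar_range[2])
  tcar <- stats::runif(n, tcar_range[1], tcar_range[2])
  A510 <- lyc * mass * 172 / (537 * 2.7 * 100)
  A452 <- bcar * mass * 139 / (533.85 * 2.7 * 100) + 0.9285 * A510
  A485 <- tcar * mass * 181 / (2.7 * 100)
  if (noise_sd > 0) {
    A510 <- pmax(A510 + stats::rnorm(n, 0, noise_sd), 0)
    A452 <- pmax(A452 + stats::rnorm(n, 0, noise_sd), 0)
    A485 <- pmax(A485 + stats::rnorm(n, 0, noise_sd), 0)
  }
  data.frame(A452 = A452, A485 = A485, A510 = A510, mass = mass,
             true_lyc = lyc, true_bcar = bcar, true_tcar = tcar)
}

#' Generate a two-trait trial with planted correlations
#'
#' Validation instrument for the correlation decomposition: genotype
#' effects of the two traits are drawn from a bivariate normal with
#' correlation chosen so that the accession-by-treatment means carry the
#' requested phenotypic correlation, while replicate residuals are
#' bivariate normal with the requested environmental correlation. No
#' interaction or block effects are simulated.
#'
#' @param g,r Design dimensions.
#' @param rho_pheno Target correlation of accession-by-treatment means.
#' @param rho_env Target residual (environmental) correlation.
#' @param sigma2_G,sigma2_e Variance components shared by both traits.
#' @param mu Grand means, length 2.
#' @param seed Integer seed.
#' @return A [trial_table()] with traits `"tA"` and `"tB"`.
#' @export
simulate_correlated_pair <- function(g = 44, r = 3, rho_pheno = 0.3,
                                     rho_env = 0.6, sigma2_G = 1,
                                     sigma2_e = 1, mu = c(10, 10),
                                     seed = 1L) {
  stopifnot(abs(rho_pheno) < 1, abs(rho_env) < 1)
  # mean-level correlation mixes genotypic and averaged-residual parts:
  # rho_P = (rho_G s2G + rho_E s2e/r) / (s2G + s2e/r)  =>  solve rho_G
  rho_G <- (rho_pheno * (sigma2_G + sigma2_e / r) -
              rho_env * sigma2_e / r) / sigma2_G
  if (abs(rho_G) > 1)
    stop("requested correlations unattainable with these components")
  set.seed(seed)
  ids <- .accession_ids(g, 0)
  .bvn <- function(n, s2, rho) {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    sqrt(s2) * cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
  }
  G <- .bvn(g, sigma2_G, rho_G)
  grid <- expand.grid(block = seq_len(r), treatment = c("LN", "HN"),
                      accession = ids, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  E <- .bvn(nrow(grid), sigma2_e, rho_env)
  i <- match(grid$accession, ids)
  rec <- rbind(
    data.frame(accession = grid$accession, class = "local",
               treatment = grid$treatment, block = grid$block,
               trait = "tA", value = mu[1] + G[i, 1] + E[, 1],
               stringsAsFactors = FALSE),
    data.frame(accession = grid$accession, class = "local",
               treatment = grid$treatment, block = grid$block,
               trait = "tB", value = mu[2] + G[i, 2] + E[, 2],
               stringsAsFactors = FALSE))
  trial_table(rec, require_known_traits = FALSE)
}
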
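test_that("degenerate noise collapses to mu plus the treatment effect", {
  st <- data.frame(trait = "ssc", mu = 5.5, d_HN = 0.4, sigma2_G = 0,
                   sigma2_GN = 0, sigma2_B = 0, sigma2_e = 0)
  tab <- generate_trial(sim_config(g = 4, r = 3, traits = st, seed = 1))
  df <- as.data.frame(tab)
  expect_equal(unique(df$value[df$treatment == "LN"]), 5.3)
  expect_equal(unique(df$value[df$treatment == "HN"]), 5.7)
})

test_that("identical configurations give identical tables", {
  cfg <- paperlike_config(traits = c("frw", "ssc"), seed = 99)
  t1 <- generate_trial(cfg)
  t2 <- generate_trial(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- generate_trial(paperlike_config(traits = c("frw", "ssc"),
                                        seed = 100))
  expect_false(identical(as.data.frame(t1)$value,
                         as.data.frame(t3)$value))
})

test_that("negative variances are rejected", {
  st <- data.frame(trait = "ssc", mu = 5, d_HN = 0, sigma2_G = -0.1,
                   sigma2_GN = 0, sigma2_B = 0, sigma2_e = 1)
  expect_error(sim_config(g = 4, r = 3, traits = st), "non-negative")
})

test_that("between-genotype variance of genotype means matches its expectation", {
  # var of genotype means = sigma2_G + sigma2_e / (delta r)
  st <- data.frame(trait = "ssc", mu = 5.5, d_HN = 0, sigma2_G = 0.2,
                   sigma2_GN = 0, sigma2_B = 0, sigma2_e = 0.3)
  tab <- generate_trial(sim_config(g = 44, r = 3, traits = st, seed = 42))
  df <- as.data.frame(tab)
  v <- var(tapply(df$value, df$accession, mean))
  expected <- 0.2 + 0.3 / 6
  mc_tol <- 3 * sqrt(2 / 43) * expected
  expect_lt(abs(v - expected), mc_tol)
})

test_that("estimated variance components are unbiased over replicates", {
  st <- data.frame(trait = "ssc", mu = 10, d_HN = 0.5, sigma2_G = 0.8,
                   sigma2_GN = 0.3, sigma2_B = 0.2, sigma2_e = 1.0)
  nsim <- 200
  est <- matrix(NA_real_, nsim, 3)
  for (i in seq_len(nsim)) {
    tab <- generate_trial(sim_config(g = 12, r = 3, traits = st,
                                     seed = 5000 + i))
    tb <- gn_anova(tab, "ssc")$table
    M <- tb$MS[match(c("G", "GxN", "residual"), tb$term)]
    vc <- variance_components(M[1], M[2], M[3], delta = 2, r = 3)
    est[i, ] <- vc$raw
  }
  truth <- c(0.8, 0.3, 1.0)
  for (k in 1:3) {
    mc_se <- sd(est[, k]) / sqrt(nsim)
    expect_lt(abs(mean(est[, k]) - truth[k]), 3 * mc_se)
  }
})

test_that("noise-free absorbances invert the carotenoid equations exactly", {
  abs <- generate_absorbances(20, mass = 30, noise_sd = 0, seed = 3)
  got <- carotenoids_from_absorbance(abs$A452, abs$A485, abs$A510,
                                     mass = abs$mass)
  expect_equal(got$lyc, abs$true_lyc, tolerance = 1e-12)
  expect_equal(got$bcar, abs$true_bcar, tolerance = 1e-12)
  expect_equal(got$tcar, abs$true_tcar, tolerance = 1e-12)
  # targets drawn on the collection's lycopene range stay inside it
  expect_true(all(got$lyc >= 3.64 & got$lyc <= 15.87))
})

test_that("absorbance generator edge cases behave", {
  expect_equal(nrow(generate_absorbances(0)), 0)
  expect_error(generate_absorbances(5, noise_sd = -1), "non-negative")
  noisy <- generate_absorbances(200, noise_sd = 0.05, seed = 4)
  expect_true(all(noisy$A452 >= 0 & noisy$A485 >= 0 & noisy$A510 >= 0))
})

test_that("paperlike preset encodes the published component structure", {
  cfg <- paperlike_config()
  expect_equal(nrow(cfg$traits), 29)
  p <- cfg$traits
  ref <- depenjar_reference()
  # phenotypic variance never below genotypic by construction
  expect_true(all(p$sigma2_GN >= 0 & p$sigma2_e >= 0))
  frw <- p[p$trait == "frw", ]
  expect_equal(sqrt(frw$sigma2_G), 26.90 * (72.7 + 70.4) / 2 / 100,
               tolerance = 1e-9)
  # interaction variance only where the published F-ratio exceeds 1
  f_gn <- ref$F_GN[match(p$trait, ref$trait)]
  expect_true(all(p$sigma2_GN[f_gn <= 1] == 0))
  expect_true(all(p$sigma2_GN[f_gn > 1 & p$sigma2_e > 0] > 0))
})

test_that("full pipeline on the paperlike preset recovers heritability", {
  cfg <- paperlike_config(traits = c("frw", "mal"), seed = 2024)
  fit <- gn_trial(generate_trial(cfg))
  ref <- depenjar_reference()
  for (tc in c("frw", "mal")) {
    truth <- (ref$cvg[ref$trait == tc] / ref$cvp[ref$trait == tc])^2
    est <- fit$genetics$H2[fit$genetics$trait == tc]
    se <- fit$genetics$se_H2[fit$genetics$trait == tc]
    expect_lt(abs(est - truth), 3 * se)
  }
})

test_that("correlated-pair generator hits its planted correlations in one large draw", {
  tab <- simulate_correlated_pair(g = 400, r = 3, rho_pheno = 0.3,
                                  rho_env = 0.6, seed = 8)
  ph <- phenotypic_correlations(tab)
  en <- environmental_correlations(tab)
  expect_lt(abs(ph$r["tA", "tB"] - 0.3), 0.12)  # ~3.5 sampling SDs at n=800
  expect_lt(abs(en$r["tA", "tB"] - 0.6), 0.06)
})
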
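test_that("variance components invert the expected mean squares", {
  vc <- variance_components(10, 4, 2, delta = 2, r = 3)
  expect_equal(vc$sigma2_G, 1)
  expect_equal(vc$sigma2_GN, 2 / 3)
  expect_equal(vc$sigma2_e, 2)
  expect_equal(vc$sigma2_P, 11 / 3)
  expect_false(any(vc$truncated))
  # equal mean squares: nothing but residual variance
  vc0 <- variance_components(1, 1, 1, delta = 2, r = 3)
  expect_equal(c(vc0$sigma2_G, vc0$sigma2_GN, vc0$sigma2_e), c(0, 0, 1))
})

test_that("negative component estimates are truncated and flagged", {
  vc <- variance_components(1, 4, 2, delta = 2, r = 3)
  expect_equal(vc$sigma2_G, 0)
  expect_true(vc$truncated[["sigma2_G"]])
  expect_lt(vc$raw[["sigma2_G"]], 0)
  expect_gte(vc$sigma2_P, vc$sigma2_G)
  expect_error(variance_components(1, 1, 1, delta = 1, r = 3),
               "at least 2")
})

test_that("heritability is the genotypic share of phenotypic variance", {
  vc <- variance_components(10, 4, 2, delta = 2, r = 3)
  expect_equal(heritability(vc), 3 / 11)
  # truncated genotypic variance gives H2 = 0
  expect_equal(heritability(variance_components(1, 4, 2, 2, 3)), 0)
  # no interaction or residual variance gives H2 = 1
  vc1 <- list(sigma2_G = 2, sigma2_GN = 0, sigma2_e = 0, sigma2_P = 2)
  expect_equal(heritability(vc1), 1)
  vc_zero <- list(sigma2_G = 0, sigma2_GN = 0, sigma2_e = 0, sigma2_P = 0)
  expect_error(heritability(vc_zero), "undefined")
})

test_that("H2 is nondecreasing in the genotype mean square", {
  h <- vapply(seq(2, 20, by = 0.5), function(m1)
    heritability(variance_components(m1, 2, 1.5, 2, 3)), numeric(1))
  expect_true(all(diff(h) >= 0))
})

test_that("the Delta-method SE stays finite when A crosses zero", {
  # M2 = M1: zero heritability but a positive standard error
  se0 <- se_heritability(2, 2, 1.5, 43, 43, 174, delta = 2, r = 3)
  expect_gt(se0, 0)
  expect_true(is.finite(se0))
  # continuous through the truncation point
  se_eps <- se_heritability(2 + 1e-9, 2, 1.5, 43, 43, 174, 2, 3)
  expect_equal(se0, se_eps, tolerance = 1e-6)
  expect_error(se_heritability(2, 2, 1.5, 0, 43, 174, 2, 3), "positive")
})

test_that("Delta-method SE agrees with a parametric bootstrap", {
  # 20,000 draws of each mean square from its scaled chi-square
  boot_se <- function(M, df, delta, r, B = 20000, seed = 1) {
    set.seed(seed)
    m1 <- M[1] * rchisq(B, df[1]) / df[1]
    m2 <- M[2] * rchisq(B, df[2]) / df[2]
    m3 <- M[3] * rchisq(B, df[3]) / df[3]
    A <- (m1 - m2) / (delta * r)
    Bv <- m1 / (delta * r) + m2 * (delta - 1) / (delta * r) +
      m3 * (r - 1) / r
    sd(A / Bv)
  }
  cases <- list(list(M = c(10, 2, 1.5), df = c(43, 43, 174)),
                list(M = c(3, 2, 1.8), df = c(43, 43, 174)),
                list(M = c(8, 5, 3), df = c(20, 20, 80)))
  for (cs in cases) {
    del <- se_heritability(cs$M[1], cs$M[2], cs$M[3], cs$df[1],
                           cs$df[2], cs$df[3], delta = 2, r = 3)
    bt <- boot_se(cs$M, cs$df, delta = 2, r = 3)
    expect_lt(abs(del - bt) / bt, 0.10)
  }
})

test_that("CV and its SE reproduce the published fruit-weight row", {
  expect_equal(round(se_cv(26.90, 44), 2), 3.07)
  expect_equal(round(se_cv(30.78, 44), 2), 3.58)
  mu <- 71.55
  got <- cv_with_se((26.90 * mu / 100)^2, mu, 44)
  expect_equal(round(got$cv, 2), 26.90)
  expect_equal(round(got$se, 2), 3.07)
  zero <- cv_with_se(0, 10, 44)
  expect_equal(c(zero$cv, zero$se), c(0, 0))
  expect_error(cv_with_se(1, 0, 44), "positive")
  expect_error(cv_with_se(1, 10, 1), "at least 2")
})

test_that("phenotypic CV never falls below genotypic CV", {
  set.seed(5)
  for (i in 1:25) {
    M <- sort(rexp(3, 0.3))  # M3 <= M2 <= M1 not guaranteed; use any order
    vc <- variance_components(M[3], M[2], M[1], delta = 2, r = 3)
    mu <- runif(1, 1, 100)
    cvg <- cv_with_se(vc$sigma2_G, mu, 44)$cv
    cvp <- cv_with_se(vc$sigma2_P, mu, 44)$cv
    expect_gte(cvp, cvg)
  }
})

test_that("genetic_params assembles a coherent per-trait row", {
  tab <- generate_trial(paperlike_config(traits = "mal", seed = 77))
  fit <- gn_anova(tab, "mal")
  mu <- mean(as.data.frame(tab)$value)
  gp <- genetic_params(fit, mu = mu)
  expect_equal(gp$sigma2_P,
               gp$sigma2_G + gp$sigma2_GN + gp$sigma2_e)
  expect_true(gp$H2 >= 0 && gp$H2 <= 1)
  expect_gte(gp$cvp, gp$cvg)
  expect_true(all(c(gp$se_H2, gp$se_cvg, gp$se_cvp) >= 0))
  # H2 equals the component ratio
  expect_equal(gp$H2, gp$sigma2_G / gp$sigma2_P)
})
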
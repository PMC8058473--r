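# The derived-trait identities below use the published collection means
# as fixed numeric inputs; sums of two 2-decimal roundings can be off by
# one unit in the last place relative to a sum computed on unrounded
# data, so the HN acid sum is checked to 0.011.

test_that("total sweetness index reproduces the collection means", {
  expect_equal(round(total_sweetness_index(15.47, 18.83), 2), 4.00)
  expect_equal(round(total_sweetness_index(18.37, 21.28), 2), 4.59)
  expect_equal(total_sweetness_index(0, 0), 0)
  expect_error(total_sweetness_index(-1, 5), "non-negative")
})

test_that("sum traits reproduce total sugars and total acids", {
  expect_equal(sum_trait(18.83, 15.47), 34.30)
  expect_equal(sum_trait(21.28, 18.37), 39.65)
  expect_equal(sum_trait(6.73, 1.30), 8.03)
  expect_equal(sum_trait(6.30, 1.33), 7.62, tolerance = 0.011 / 7.62)
  expect_equal(sum_trait(0, 0), 0)
  expect_error(sum_trait(-0.1, 1), "non-negative")
})

test_that("ratio traits divide per replicate and guard the denominator", {
  expect_equal(ratio_trait(18.83, 15.47), 18.83 / 15.47)
  expect_equal(ratio_trait(7, 7), 1)
  expect_error(ratio_trait(1, 0), "positive")
  expect_error(ratio_trait(1, -2), "positive")
})

test_that("carotenoid equations match hand arithmetic and scale linearly", {
  # lyc = A510 * 537 * 2.7 / (mass * 172) * 100
  # (A452 = 0 with positive A510 also floors the beta-carotene bracket)
  got <- suppressWarnings(carotenoids_from_absorbance(0, 0, 0.1,
                                                      mass = 30))
  expect_equal(got$lyc, 0.1 * 537 * 2.7 / (30 * 172) * 100,
               tolerance = 1e-12)
  expect_equal(got$lyc, 2.80988, tolerance = 1e-5)
  zero <- carotenoids_from_absorbance(0, 0, 0, mass = 30)
  expect_equal(unlist(zero), c(lyc = 0, bcar = 0, tcar = 0))
  # homogeneity: degree 1 in absorbance, degree -1 in mass
  one <- carotenoids_from_absorbance(0.4, 0.3, 0.1, mass = 30)
  two <- carotenoids_from_absorbance(0.8, 0.6, 0.2, mass = 30)
  half <- carotenoids_from_absorbance(0.4, 0.3, 0.1, mass = 60)
  expect_equal(unlist(two), 2 * unlist(one), tolerance = 1e-12)
  expect_equal(unlist(half), unlist(one) / 2, tolerance = 1e-12)
  expect_error(carotenoids_from_absorbance(0.1, 0.1, 0.1, mass = 0),
               "positive")
})

test_that("a negative beta-carotene bracket is floored at zero", {
  expect_warning(
    got <- carotenoids_from_absorbance(0.05, 0.2, 0.1, mass = 30),
    "floored")
  expect_equal(got$bcar, 0)
  expect_gt(got$lyc, 0)
})

test_that("percent change supports both reference conventions", {
  expect_equal(round(percent_change_LN_vs_HN(18.83, 21.28), 1), -11.5)
  expect_equal(round(percent_change_LN_vs_HN(15.47, 18.37), 1), -15.8)
  expect_equal(round(percent_change_LN_vs_HN(34.30, 39.65), 1), -13.5)
  # hue: 5.9% against the HN reference, 5.6% against the LN mean
  expect_equal(round(percent_change_LN_vs_HN(40.00, 37.78), 1), 5.9)
  expect_equal(percent_change_LN_vs_HN(40.00, 37.78, reference = "LN"),
               5.55, tolerance = 1e-3)
  expect_equal(percent_change_LN_vs_HN(3, 3), 0)
  expect_error(percent_change_LN_vs_HN(1, 0), "zero reference")
})

test_that("group differences use the local mean as denominator", {
  expect_equal(round(group_relative_difference(10.76, 8.78), 1), 18.4)
  expect_equal(round(group_relative_difference(11.00, 7.70), 1), 30.0)
  expect_equal(round(group_relative_difference(7.87, 6.14), 1), 22.0)
  expect_equal(round(group_relative_difference(8.92, 6.35), 1), 28.8)
  expect_equal(round(group_relative_difference(0.28, 0.21), 1), 25.0)
  expect_equal(round(group_relative_difference(0.29, 0.24), 1), 17.2)
  expect_equal(group_relative_difference(5, 5), 0)
  expect_error(group_relative_difference(0, 1), "positive")
})

test_that("relative ranges reproduce the published fold values", {
  expect_equal(round(relative_range(132.5, 29.0), 2), 4.57)
  expect_equal(round(relative_range(15.87, 3.64), 2), 4.36)
  expect_equal(round(relative_range(134.6, 29.3), 2), 4.59)
  expect_equal(round(relative_range(14.50, 3.34), 2), 4.34)
  expect_equal(relative_range(7, 7), 1)
  expect_error(relative_range(5, 0), "positive")
})

test_that("derived traits are computed per replicate, then averaged", {
  # asymmetric fixture: mean of ratios differs from ratio of means
  fru <- c(10, 30, 10, 30, 10, 30, 10, 30)
  glu <- c(10, 10, 10, 10, 10, 10, 10, 10)
  base <- rbind(
    transform(as.data.frame(make_mini_trial(g = 2, r = 2, trait = "fru",
                                            values = fru))),
    transform(as.data.frame(make_mini_trial(g = 2, r = 2, trait = "glu",
                                            values = glu))))
  tab <- derive_traits(trial_table(base))
  df <- as.data.frame(tab)
  fg <- df$value[df$trait == "fruglur"]
  expect_equal(sort(unique(fg)), c(1, 3))
  mean_of_ratios <- mean(fg)                 # 2
  ratio_of_means <- mean(fru) / mean(glu)    # 2 as well here, so use cells
  cell <- df[df$trait == "fruglur" & df$accession == "A01" &
               df$treatment == "LN", "value"]
  expect_equal(mean(cell), mean(c(1, 3)))
  expect_false(isTRUE(all.equal(mean(cell), 30 / 10)))
  # every derived record keeps the design balanced
  expect_equal(unname(attr(tab, "design")), c(2L, 2L, 2L))
  expect_setequal(unique(df$trait), c("fru", "glu", "tsug", "fruglur",
                                      "tsi"))
})

test_that("derived sums and indices agree with their components rowwise", {
  cfg <- paperlike_config(traits = c("fru", "glu", "cit", "mal", "ssc",
                                     "ta"), seed = 21)
  tab <- derive_traits(generate_trial(cfg))
  df <- as.data.frame(tab)
  wide <- reshape(df, idvar = c("accession", "treatment", "block"),
                  timevar = "trait", direction = "wide",
                  drop = "class")
  names(wide) <- sub("^value\\.", "", names(wide))
  expect_equal(wide$tsug, wide$fru + wide$glu, tolerance = 1e-12)
  expect_equal(wide$tacid, wide$cit + wide$mal, tolerance = 1e-12)
  expect_equal(wide$tsi, 0.76 * wide$glu / 10 + 1.5 * wide$fru / 10,
               tolerance = 1e-12)
  expect_equal(wide$tsitar, wide$tsi / wide$ta, tolerance = 1e-12)
})
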
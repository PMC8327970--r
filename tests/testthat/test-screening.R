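# reference values computed with an independent implementation of the
# same standardized moment tests (D'Agostino skewness, Anscombe-Glynn
# kurtosis), frozen here
test_that("moment tests match independently computed reference values", {
  x1 <- c(0.31, -1.24, 0.52, 2.14, -0.73, 0.11, 1.42, -0.38, 0.87, -1.93,
          2.55, 0.21, 0.94, -0.41, 1.13)
  s1 <- skewness_test(x1)
  expect_equal(s1$g1, -0.025402407607, tolerance = 1e-10)
  expect_equal(s1$z, -0.051630777560, tolerance = 1e-10)
  expect_equal(s1$p, 0.958822895091, tolerance = 1e-10)
  k1 <- kurtosis_test(x1)
  expect_equal(k1$g2, -0.472426835432, tolerance = 1e-10)
  expect_equal(k1$z, 0.086709353487, tolerance = 1e-9)
  expect_equal(k1$p, 0.930902541416, tolerance = 1e-9)

  x2 <- c(5.2, 5.3, 5.1, 5.25, 5.4, 9.9, 5.15, 5.05, 5.35, 5.2, 5.3, 5.12)
  s2 <- skewness_test(x2)
  expect_equal(s2$z, 4.293541492955, tolerance = 1e-9)
  expect_equal(s2$p, 0.000017584543, tolerance = 1e-6)
  k2 <- kurtosis_test(x2)
  expect_equal(k2$z, 3.842637950780, tolerance = 1e-9)
  # strongly leptokurtic: the platykurtic one-sided p is near 1
  expect_gt(k2$p_platy, 0.999)
})

test_that("Grubbs flagging finds planted outliers and is affine-invariant", {
  set.seed(21)
  x <- rnorm(50)
  x[17] <- 8
  flagged <- grubbs_outliers(x)
  expect_true(17 %in% flagged)
  expect_identical(grubbs_outliers(100 + 5 * x), flagged)
  expect_identical(grubbs_outliers(-x), flagged)
  # iterative: two planted outliers on opposite sides
  y <- rnorm(50)
  y[c(3, 40)] <- c(-9, 7)
  expect_setequal(grubbs_outliers(y)[1:2], c(3, 40))
})

test_that("screening flags planted DA, AS and size dependency", {
  # planted mean-shift DA at delta = 2 sigma
  tm_da <- build_trait_matrices(simulate_dataset(
    synthetic_config(n_individuals = 200, n_replicates = 2,
                     sigma_fa = 0.04, da_offset = 0.08, sigma_me = 0.005,
                     seed = 31)))[[1]]
  s_da <- screen_trait(tm_da)
  expect_true(s_da$da_flag)
  expect_identical(s_da$verdict, "DA")
  expect_lt(s_da$mean_d_p, 0.001)

  # antisymmetric two-point mixture at delta = 3 sigma: platykurtic
  tm_as <- build_trait_matrices(simulate_dataset(
    synthetic_config(n_individuals = 200, n_replicates = 2,
                     sigma_fa = 0.04, as_delta = 0.12, as_prob = 1,
                     sigma_me = 0.005, seed = 32)))[[1]]
  s_as <- screen_trait(tm_as)
  expect_lt(s_as$excess_kurtosis, 0)
  expect_true(s_as$as_flag)
  expect_identical(s_as$verdict, "AS")

  # FA deviation scaling with trait size
  tm_sd <- build_trait_matrices(simulate_dataset(
    synthetic_config(n_individuals = 200, n_replicates = 2,
                     size_dep_gamma = 8, seed = 33)))[[1]]
  s_sd <- screen_trait(tm_sd, da_rule = "t")
  expect_true(s_sd$size_dep_flag)
  expect_gt(s_sd$size_dependency_rho, 0)
})

test_that("DA rule configuration switches between skew and t criteria", {
  # a pure mean shift moves the t-test, not the skew test
  tm <- build_trait_matrices(simulate_dataset(
    synthetic_config(n_individuals = 200, n_replicates = 2,
                     sigma_fa = 0.04, da_offset = 0.08, sigma_me = 0.005,
                     seed = 34)))[[1]]
  expect_true(screen_trait(tm, da_rule = "t")$da_flag)
  expect_true(screen_trait(tm, da_rule = "either")$da_flag)
  expect_false(screen_trait(tm, da_rule = "skew")$da_flag)
})

test_that("small or degenerate traits are reported not-evaluable", {
  tm_small <- build_trait_matrices(simulate_dataset(
    synthetic_config(n_individuals = 5, n_replicates = 2, seed = 35)))[[1]]
  expect_warning(s <- screen_trait(tm_small), "not evaluable")
  expect_false(s$evaluable)
  expect_identical(s$verdict, "clean")

  tm_const <- trait_matrix(matrix(10, 10, 2), matrix(10.5, 10, 2))
  expect_warning(s2 <- screen_trait(tm_const), "constant")
  expect_false(s2$evaluable)
})

test_that("elimination rules reproduce the study's ledger pattern", {
  # screening table with flags exactly matching the study's five
  # eliminations over the full 36-variable roster
  roster <- expand.grid(sex = c("female", "male"),
                        metric = c("length", "breadth"),
                        tooth = study_teeth(), stringsAsFactors = FALSE)
  scr <- data.frame(roster,
                    da_flag = FALSE, as_flag = FALSE, size_dep_flag = FALSE,
                    stringsAsFactors = FALSE)
  da <- scr$metric == "length" & scr$tooth %in% c("MNM1", "MNM2")
  scr$da_flag[da] <- TRUE
  scr$size_dep_flag[scr$sex == "male" & scr$metric == "length" &
                      scr$tooth == "MXP3"] <- TRUE
  el <- apply_elimination(scr)
  expect_equal(nrow(el$eliminated), 5L)
  expect_equal(sum(el$eliminated$reason == "DA"), 4L)
  expect_equal(sum(el$eliminated$reason == "size_dependent"), 1L)
  counts <- table(el$retained$sex, el$retained$metric)
  expect_equal(counts["female", "breadth"], 9L, ignore_attr = TRUE)
  expect_equal(counts["female", "length"], 7L, ignore_attr = TRUE)
  expect_equal(counts["male", "breadth"], 9L, ignore_attr = TRUE)
  expect_equal(counts["male", "length"], 6L, ignore_attr = TRUE)

  # no flags: everything retained
  clean <- scr
  clean$da_flag <- clean$size_dep_flag <- FALSE
  el2 <- apply_elimination(clean)
  expect_equal(nrow(el2$eliminated), 0L)
  expect_equal(nrow(el2$retained), 36L)

  # everything flagged: empty roster with warning
  allbad <- scr
  allbad$da_flag <- TRUE
  expect_warning(el3 <- apply_elimination(allbad), "eliminated")
  expect_equal(nrow(el3$retained), 0L)
})

test_that("replicate scan reports zero ME on noise-free data", {
  cfgs <- study_configs(n_individuals = 8, n_replicates = 10,
                        sigma_me = 0, teeth = c("MXM1", "MNM3"))
  rec <- simulate_study(cfgs, seed = 41)
  scan <- replicate_scan(rec, list(1:10, 2:9, 9:10))
  expect_equal(scan$mean, rep(0, 3))
  expect_equal(scan$me3_pooled, rep(0, 3))
  expect_equal(scan$range, rep(0, 3))
})

test_that("replicate scan localizes noisy trials", {
  # trials 9-10 carry 4x the measurement-error variance (2x SD)
  me <- c(rep(0.01, 8), rep(0.02, 2))
  cfgs <- study_configs(n_individuals = 40, n_replicates = 10,
                        sigma_me = me, teeth = c("MXM1", "MNM3", "MXP4"))
  rec <- simulate_study(cfgs, seed = 42)
  scan <- replicate_scan(rec, list(1:8, 9:10))
  expect_gt(scan$mean[scan$subset_label == "9-10"],
            scan$mean[scan$subset_label == "1-8"])
  expect_equal(scan$range, scan$maximum - scan$minimum)
})

test_that("replicate scan validates its subsets", {
  rec <- simulate_dataset(synthetic_config(n_individuals = 4,
                                           n_replicates = 3, seed = 43))
  expect_error(replicate_scan(rec, list(1:5)), "1-5")
  expect_error(replicate_scan(rec, list(2)), "fewer than 2")
})
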
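test_that("side means and signed differences follow hand arithmetic", {
  tm <- trait_matrix(
    left = rbind(c(10, 11), c(12, 13), c(9, 9)),
    right = rbind(c(11, 12), c(12, 12), c(10, 11))
  )
  sm <- side_means(tm)
  expect_equal(sm$left_mean, c(10.5, 12.5, 9))
  expect_equal(sm$right_mean, c(11.5, 12, 10.5))
  expect_equal(sm$d, c(1, -0.5, 1.5))  # right minus left
  expect_equal(sm$s, c(11, 12.25, 9.75))

  tm2 <- trait_matrix(left = matrix(10, 4, 2), right = matrix(12, 4, 2))
  expect_equal(side_means(tm2)$d, rep(2, 4))
  expect_equal(side_means(tm2)$s, rep(11, 4))
})

test_that("degenerate strata give zero mean squares", {
  # identical replicates within each cell: no measurement-error stratum
  L <- matrix(rep(c(10, 11, 12), 2), 3, 2)
  R <- matrix(rep(c(10.2, 11.1, 12.4), 2), 3, 2)
  a <- fit_sides_anova(trait_matrix(L, R))
  expect_equal(a$ms_error, 0)
  # perfect symmetry and no error: only individuals vary
  b <- fit_sides_anova(trait_matrix(L, L))
  expect_equal(b$ms_sides, 0)
  expect_equal(b$ms_interaction, 0)
  expect_gt(b$ms_individuals, 0)
})

test_that("single-replicate and single-individual designs are rejected", {
  expect_error(fit_sides_anova(trait_matrix(matrix(1:3), matrix(4:6))),
               "replicate stratum")
  expect_error(trait_matrix(matrix(1, 1, 2), matrix(1, 1, 2)), "J >= 2")
})

test_that("mean squares match the brute-force summation oracle", {
  set.seed(42)
  for (r in 1:20) {
    tm <- random_trait_matrix(J = sample(2:6, 1), M = sample(2:4, 1))
    a <- fit_sides_anova(tm)
    o <- oracle_sides_anova(tm)
    expect_equal(a$ms_sides, o$ms_sides, tolerance = 1e-10)
    expect_equal(a$ms_individuals, o$ms_individuals, tolerance = 1e-10)
    expect_equal(a$ms_interaction, o$ms_interaction, tolerance = 1e-10)
    expect_equal(a$ms_error, o$ms_error, tolerance = 1e-10)
    # conservation: stratum sums of squares add up to the total
    expect_equal(a$ss_sides + a$ss_individuals + a$ss_interaction +
                   a$ss_error, a$ss_total, tolerance = 1e-10)
  }
})

test_that("variance components follow the mean-square contrasts, with clamping", {
  a <- structure(list(ms_interaction = 0.5, ms_error = 0.1, M = 2),
                 class = "sides_anova")
  vc <- variance_components(a)
  expect_equal(vc$sigma2_i, 0.2)
  expect_equal(vc$sigma2_m, 0.1)
  expect_false(vc$clamped)

  b <- structure(list(ms_interaction = 0.1, ms_error = 0.5, M = 2),
                 class = "sides_anova")
  vb <- variance_components(b)
  expect_equal(vb$sigma2_i, 0)
  expect_true(vb$clamped)
})

test_that("index formulas hold on their components", {
  set.seed(9)
  tm <- random_trait_matrix(6, 3)
  fi <- fa_indices(tm)
  vc <- variance_components(fit_sides_anova(tm))
  d <- side_means(tm)$d
  k <- sqrt(2 / pi)
  expect_equal(fi$fa1, mean(abs(d)))
  expect_equal(fi$fa4a, k * sd(d))
  expect_equal(fi$fa10a, k * sqrt(2 * vc$sigma2_i))
  expect_equal(fi$me3_percent,
               100 * vc$sigma2_m / (vc$sigma2_i + vc$sigma2_m))
  expect_equal(fi$repeatability, 1 - fi$me3_percent / 100)
  expect_equal(fi$n, 6L)
})

test_that("noise-free symmetric data has zero indices and undefined ME3", {
  L <- matrix(rep(c(10, 11, 12, 13), 2), 4, 2)
  tm <- trait_matrix(L, L)
  expect_warning(fi <- fa_indices(tm), "undefined")
  expect_equal(fi$fa1, 0)
  expect_equal(fi$fa4a, 0)
  expect_equal(fi$fa10a, 0)
  expect_true(is.na(fi$me3_percent))
})

test_that("FA10a is shift-invariant and scales linearly", {
  set.seed(14)
  tm <- random_trait_matrix(8, 3)
  base <- fa_indices(tm)$fa10a
  shifted <- trait_matrix(tm$left + 5, tm$right + 5)
  scaled <- trait_matrix(tm$left * 3, tm$right * 3)
  expect_equal(fa_indices(shifted)$fa10a, base, tolerance = 1e-8)
  expect_equal(fa_indices(scaled)$fa10a, 3 * base, tolerance = 1e-8)
})

test_that("variance components are recovered from simulated data", {
  # var(R - L) = 0.02, so the planted interaction component is
  # sigma2_i = var(d)/2 = 0.01 (the signed deviation splits across the
  # two sides); sigma2_m = 0.05^2 = 0.0025; J = 200, M = 10
  cfg <- synthetic_config(n_individuals = 200, n_replicates = 10,
                          sigma_fa = sqrt(0.02), sigma_me = 0.05, seed = 101)
  tm <- build_trait_matrices(simulate_dataset(cfg))[[1]]
  vc <- variance_components(fit_sides_anova(tm))
  expect_lt(abs(vc$sigma2_i - 0.01) / 0.01, 0.20)
  expect_lt(abs(vc$sigma2_m - 0.0025) / 0.0025, 0.20)
})

test_that("measurement error inflates FA4a but not FA10a", {
  # same underlying asymmetries with and without measurement noise
  set.seed(77)
  J <- 500
  d_true <- rnorm(J, 0, 0.04)
  size <- rnorm(J, 10, 0.5)
  clean <- trait_matrix(cbind(size - d_true / 2, size - d_true / 2),
                        cbind(size + d_true / 2, size + d_true / 2))
  noisy <- trait_matrix(clean$left + rnorm(2 * J, 0, 0.04),
                        clean$right + rnorm(2 * J, 0, 0.04))
  fc <- fa_indices(clean)
  fn <- fa_indices(noisy)
  # noise-free: both indices estimate the same quantity
  expect_lt(abs(fc$fa4a - fc$fa10a) / fc$fa10a, 0.05)
  # with ME: FA4a inflates, FA10a stays near the noise-free value
  expect_gt(fn$fa4a, 1.2 * fc$fa4a)
  expect_lt(abs(fn$fa10a - fc$fa10a) / fc$fa10a, 0.25)
  # closed form: FA10a estimates E|d| = 0.798 * sd(d) = 0.798 * 0.04
  expect_lt(abs(fn$fa10a - sqrt(2 / pi) * 0.04) /
              (sqrt(2 / pi) * 0.04), 0.15)
})

test_that("FA report serializes with the published table's leading columns", {
  rec <- simulate_study(study_configs(n_individuals = 10, n_replicates = 2,
                                      teeth = c("MXM1", "MNM3")), seed = 2)
  rep_tab <- fa_report_table(build_trait_matrices(rec))
  expect_equal(nrow(rep_tab), 8L)
  path <- tempfile(fileext = ".tsv")
  write_fa_report(rep_tab, path)
  back <- read.delim(path)
  expect_equal(names(back)[1:5], c("sex", "metric", "tooth", "fa10a", "n"))
})
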
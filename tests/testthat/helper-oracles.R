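# independent oracles and fixture builders used across test files

# brute-force sides-by-individuals ANOVA: explicit summation over all
# 2*J*M observations of the cell-means decomposition, no shared code with
# fit_sides_anova()
oracle_sides_anova <- function(tm) {
  J <- nrow(tm$left)
  M <- ncol(tm$left)
  y <- array(NA_real_, c(2, J, M))
  y[1, , ] <- tm$left
  y[2, , ] <- tm$right
  grand <- mean(y)
  ss_sides <- 0
  for (s in 1:2) ss_sides <- ss_sides + J * M * (mean(y[s, , ]) - grand)^2
  ss_ind <- 0
  for (i in 1:J) ss_ind <- ss_ind + 2 * M * (mean(y[, i, ]) - grand)^2
  ss_int <- 0
  for (s in 1:2) {
    for (i in 1:J) {
      ss_int <- ss_int +
        M * (mean(y[s, i, ]) - mean(y[s, , ]) - mean(y[, i, ]) + grand)^2
    }
  }
  ss_err <- 0
  for (s in 1:2) {
    for (i in 1:J) {
      for (k in 1:M) ss_err <- ss_err + (y[s, i, k] - mean(y[s, i, ]))^2
    }
  }
  list(
    ms_sides = ss_sides / 1,
    ms_individuals = ss_ind / (J - 1),
    ms_interaction = ss_int / (J - 1),
    ms_error = ss_err / (2 * J * (M - 1)),
    ss = c(sides = ss_sides, individuals = ss_ind,
           interaction = ss_int, error = ss_err),
    ss_total = sum((y - grand)^2)
  )
}

random_trait_matrix <- function(J, M) {
  trait_matrix(
    left = matrix(runif(J * M, 8, 12), J, M),
    right = matrix(runif(J * M, 8, 12), J, M)
  )
}

# a trait_matrix carrying prescribed per-individual side means (M = 1)
tm_from_sides <- function(left, right, ...) {
  trait_matrix(matrix(left, ncol = 1), matrix(right, ncol = 1), ...)
}

# one-way ANOVA on absolute deviations via lm(), as an in-suite
# cross-check route distinct from levene_test()'s explicit sums
oracle_levene_lm <- function(values, groups, center) {
  g <- factor(groups)
  cfun <- if (center == "median") stats::median else mean
  z <- abs(values - ave(values, g, FUN = cfun))
  a <- anova(lm(z ~ g))
  list(F = a$`F value`[1], df = a$Df, p = a$`Pr(>F)`[1])
}

published_suite <- data.frame(
  model = c("FA10~Tooth", "FA10~Class", "FA10~Arcade", "FA10~Metric",
            "FA10~Sex", "FA10:M1~Tooth Type", "FA10:M1~Tooth Type*Sex",
            "FA10:M3~Tooth Type", "FA10:M3~Tooth Type*Sex"),
  F = c(1.78, 0.19, 0.26, 8.48, 10.602, 1.670, 6.696, 0.064, 4.313),
  df_between = c(8L, 1L, 1L, 1L, 1L, 1L, 3L, 1L, 3L),
  p = c(0.14, 0.67, 0.61, 0.01, 0.003, 0.207, 0.002, 0.802, 0.013),
  stringsAsFactors = FALSE
)
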
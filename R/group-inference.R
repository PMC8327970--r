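#' Levene / Brown-Forsythe test for equality of variance
#'
#' One-way ANOVA F on the absolute deviations of each value from its
#' group center. Because an FA index is itself a variance-like quantity,
#' equality of FA across groups is a homogeneity-of-variance question,
#' and this is the package's group-level test. `center = "median"`
#' (Brown-Forsythe, the default of the standard R implementation) is
#' robust; `center = "mean"` is the classical Levene form.
#'
#' @param values numeric vector of index values.
#' @param groups group labels, same length as `values`.
#' @param center `"median"` (default) or `"mean"`.
#' @param model_label optional label carried into the result.
#' @return object of class `levene_test`: list with `model_label`, `F`,
#'   `df_between`, `df_within`, `p`, `center`, and `groups`, a data.frame
#'   of group label, n and member count.
#' @export
levene_test <- function(values, groups, center = c("median", "mean"),
                        model_label = NULL) {
  center <- match.arg(center)
  values <- as.numeric(values)
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2L) stop("levene_test needs at least 2 groups")
  n_g <- table(groups)
  if (any(n_g < 2L)) {
    stop("group(s) with fewer than 2 values: ",
         paste(names(n_g)[n_g < 2], collapse = ", "))
  }
  cfun <- if (center == "median") stats::median else mean
  centers <- tapply(values, groups, cfun)
  z <- abs(values - centers[as.integer(groups)])

  # one-way ANOVA on the deviation scores, by explicit sums
  k <- nlevels(groups)
  N <- length(z)
  zbar <- mean(z)
  zbar_g <- tapply(z, groups, mean)
  ss_between <- sum(n_g * (zbar_g - zbar)^2)
  ss_within <- sum((z - zbar_g[as.integer(groups)])^2)
  df_between <- k - 1L
  df_within <- N - k
  f <- (ss_between / df_between) / (ss_within / df_within)
  p <- stats::pf(f, df_between, df_within, lower.tail = FALSE)

  structure(
    list(
      model_label = if (is.null(model_label)) "FA10~group" else model_label,
      F = f, df_between = df_between, df_within = df_within, p = p,
      center = center,
      groups = data.frame(label = levels(groups), n = as.integer(n_g),
                          stringsAsFactors = FALSE)
    ),
    class = "levene_test"
  )
}

#' @export
print.levene_test <- function(x, ...) {
  cat(sprintf("%s: Levene F = %.3f, df = %d/%d, p = %.4g (%s-centred)\n",
              x$model_label, x$F, x$df_between, x$df_within, x$p, x$center))
  invisible(x)
}

#' Build grouping labels for the hypothesis contrasts
#'
#' Maps FA-index rows (one row per trait variable, with `sex`, `metric`,
#' `tooth` columns) to the grouping factors of the group-level tests.
#' Plain factors label rows by the corresponding field (`tooth` uses the
#' arcade-specific trait code, 9 levels in the study roster; `class` and
#' `arcade` are derived from the code). The life-history contrasts pool
#' arcades and metrics: `m1_vs_rest` labels first-molar rows (MNM1 and
#' MXM1) `"M1"` against `"other"`; `m3_vs_rest` analogously for third
#' molars. `interact_sex` crosses the chosen factor with sex.
#'
#' @param rows data.frame of FA-index rows with `sex`, `metric`, `tooth`.
#' @param contrast one of `"sex"`, `"metric"`, `"tooth"`, `"class"`,
#'   `"arcade"`, `"m1_vs_rest"`, `"m3_vs_rest"`.
#' @param interact_sex cross the contrast with sex (default `FALSE`).
#' @return character vector of group labels, one per row.
#' @export
build_contrast_groups <- function(rows,
                                  contrast = c("sex", "metric", "tooth",
                                               "class", "arcade",
                                               "m1_vs_rest", "m3_vs_rest"),
                                  interact_sex = FALSE) {
  contrast <- match.arg(contrast)
  info <- tooth_info(rows$tooth)
  labels <- switch(contrast,
    sex = as.character(rows$sex),
    metric = as.character(rows$metric),
    tooth = as.character(rows$tooth),
    class = info$tooth_class,
    arcade = info$arcade,
    m1_vs_rest = ifelse(info$tooth_type == "M1", "M1", "other"),
    m3_vs_rest = ifelse(info$tooth_type == "M3", "M3", "other")
  )
  if (interact_sex && contrast != "sex") {
    labels <- paste(labels, rows$sex, sep = ":")
  }
  if (length(unique(labels)) < 2L) {
    stop("contrast '", contrast, "' yields fewer than 2 non-empty groups")
  }
  labels
}

#' The nine group-level hypothesis tests
#'
#' Runs the full suite of Levene-type tests on a table of FA10a index
#' values (one value per retained trait variable): the four
#' data-exploration factors (tooth, tooth class, arcade, metric), the sex
#' contrast, and the two life-history contrasts — first molar (weaning
#' proxy) and third molar (reproductive-maturity proxy) against all
#' other teeth, each alone and crossed with sex.
#'
#' @param rows data.frame with `sex`, `metric`, `tooth`, `fa10a`.
#' @param center `"median"` (default) or `"mean"`; passed to
#'   [levene_test()].
#' @return data.frame with one row per model: `model`, `F`, `df_between`,
#'   `df_within`, `p`, `center`. The full `levene_test` objects are
#'   attached as attribute `"tests"`.
#' @export
run_hypothesis_suite <- function(rows, center = c("median", "mean")) {
  center <- match.arg(center)
  stopifnot(all(c("sex", "metric", "tooth", "fa10a") %in% names(rows)))
  if (length(unique(rows$sex)) < 2L || length(unique(rows$metric)) < 2L) {
    stop("hypothesis suite needs rows covering both sexes and both metrics")
  }
  specs <- list(
    list(label = "FA10~Tooth", contrast = "tooth", interact = FALSE),
    list(label = "FA10~Class", contrast = "class", interact = FALSE),
    list(label = "FA10~Arcade", contrast = "arcade", interact = FALSE),
    list(label = "FA10~Metric", contrast = "metric", interact = FALSE),
    list(label = "FA10~Sex", contrast = "sex", interact = FALSE),
    list(label = "FA10:M1~Tooth Type", contrast = "m1_vs_rest",
         interact = FALSE),
    list(label = "FA10:M1~Tooth Type*Sex", contrast = "m1_vs_rest",
         interact = TRUE),
    list(label = "FA10:M3~Tooth Type", contrast = "m3_vs_rest",
         interact = FALSE),
    list(label = "FA10:M3~Tooth Type*Sex", contrast = "m3_vs_rest",
         interact = TRUE)
  )
  tests <- lapply(specs, function(s) {
    g <- build_contrast_groups(rows, s$contrast, interact_sex = s$interact)
    levene_test(rows$fa10a, g, center = center, model_label = s$label)
  })
  out <- data.frame(
    model = vapply(tests, `[[`, character(1), "model_label"),
    F = vapply(tests, `[[`, numeric(1), "F"),
    df_between = vapply(tests, `[[`, integer(1), "df_between"),
    df_within = vapply(tests, `[[`, integer(1), "df_within"),
    p = vapply(tests, `[[`, numeric(1), "p"),
    center = center,
    stringsAsFactors = FALSE
  )
  attr(out, "tests") <- tests
  out
}

#' Mean FA10a by factor level
#'
#' Arithmetic mean of the index per level of a grouping field, reported
#' at full precision together with a 2-decimal display column.
#'
#' @param rows data.frame with `fa10a` and the grouping field.
#' @param field `"metric"`, `"sex"`, or `"tooth"`.
#' @return data.frame with `level`, `mean_fa10a`, `mean_fa10a_2dp`, `n`.
#' @export
summarize_by <- function(rows, field = c("metric", "sex", "tooth")) {
  field <- match.arg(field)
  stopifnot(nrow(rows) > 0)
  g <- factor(rows[[field]])
  m <- tapply(rows$fa10a, g, mean)
  data.frame(
    level = levels(g),
    mean_fa10a = as.numeric(m),
    mean_fa10a_2dp = round(as.numeric(m), 2),
    n = as.integer(table(g)),
    stringsAsFactors = FALSE
  )
}
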
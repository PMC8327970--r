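#' Per-individual side means and signed asymmetry
#'
#' Averages each individual's replicates within a side and returns the
#' side means together with the signed side difference d = R - L (the
#' right-minus-left convention is used throughout the package) and the
#' individual trait size s = (R + L) / 2.
#'
#' @param tm a [trait_matrix()].
#' @return data.frame with one row per individual: `individual`,
#'   `left_mean`, `right_mean`, `d` (mm, R - L), `s` (mm, trait size).
#' @export
side_means <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  L <- rowMeans(tm$left)
  R <- rowMeans(tm$right)
  data.frame(
    individual = tm$individuals,
    left_mean = L, right_mean = R,
    d = R - L, s = (R + L) / 2,
    stringsAsFactors = FALSE
  )
}

#' Sides-by-individuals mixed-model ANOVA
#'
#' Fits the balanced two-way crossed ANOVA with sides (2 levels, fixed)
#' and individuals (J levels, random) and M replicate measurements per
#' cell. The four strata partition the total variation into directional
#' asymmetry (sides), individual size variation (individuals),
#' nondirectional asymmetry (sides x individuals interaction) and
#' measurement error (among replicates within cells). Sums of squares
#' are the standard balanced-design cell/marginal-mean sums.
#'
#' @param tm a [trait_matrix()] with M >= 2 (a replicate error stratum
#'   requires repeated measurements).
#' @return object of class `sides_anova`: list with sums of squares
#'   (`ss_sides`, `ss_individuals`, `ss_interaction`, `ss_error`,
#'   `ss_total`), mean squares (`ms_*`), degrees of freedom (`df_*`),
#'   and `J`, `M`.
#' @export
fit_sides_anova <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  J <- tm$J
  M <- tm$M
  if (J < 2L) stop("sides-by-individuals ANOVA requires J >= 2")
  if (M < 2L) stop("no replicate stratum: M >= 2 replicates required")

  # cell means: J x 2 (columns L, R)
  cellL <- rowMeans(tm$left)
  cellR <- rowMeans(tm$right)
  ind_mean <- (cellL + cellR) / 2
  side_mean <- c(L = mean(cellL), R = mean(cellR))
  grand <- mean(ind_mean)

  ss_sides <- J * M * sum((side_mean - grand)^2)
  ss_individuals <- 2 * M * sum((ind_mean - grand)^2)
  ss_interaction <- M * sum((cellL - ind_mean - side_mean["L"] + grand)^2 +
                              (cellR - ind_mean - side_mean["R"] + grand)^2)
  ss_error <- sum((tm$left - cellL)^2) + sum((tm$right - cellR)^2)
  ss_total <- sum((tm$left - grand)^2) + sum((tm$right - grand)^2)

  df_sides <- 1L
  df_individuals <- J - 1L
  df_interaction <- J - 1L
  df_error <- 2L * J * (M - 1L)

  structure(
    list(
      ss_sides = ss_sides, ss_individuals = ss_individuals,
      ss_interaction = ss_interaction, ss_error = ss_error,
      ss_total = ss_total,
      ms_sides = ss_sides / df_sides,
      ms_individuals = ss_individuals / df_individuals,
      ms_interaction = ss_interaction / df_interaction,
      ms_error = ss_error / df_error,
      df_sides = df_sides, df_individuals = df_individuals,
      df_interaction = df_interaction, df_error = df_error,
      J = J, M = M
    ),
    class = "sides_anova"
  )
}

#' @export
print.sides_anova <- function(x, ...) {
  tab <- data.frame(
    stratum = c("sides", "individuals", "sides:individuals", "error"),
    df = c(x$df_sides, x$df_individuals, x$df_interaction, x$df_error),
    SS = c(x$ss_sides, x$ss_individuals, x$ss_interaction, x$ss_error),
    MS = c(x$ms_sides, x$ms_individuals, x$ms_interaction, x$ms_error)
  )
  cat(sprintf("sides-by-individuals ANOVA (J = %d, M = %d)\n", x$J, x$M))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Variance components of nondirectional asymmetry and measurement error
#'
#' Method-of-moments estimators from the sides-by-individuals mean
#' squares: the nondirectional between-sides (FA) component is
#' sigma2_i = (MS_interaction - MS_error) / M and the measurement-error
#' component is sigma2_m = MS_error. A negative raw sigma2_i estimate
#' (sampling noise when FA is small relative to ME) is clamped to zero
#' and flagged.
#'
#' @param a a `sides_anova` fit.
#' @return list with `sigma2_i`, `sigma2_m`, `clamped`.
#' @export
variance_components <- function(a) {
  stopifnot(inherits(a, "sides_anova"))
  raw <- (a$ms_interaction - a$ms_error) / a$M
  clamped <- raw < 0
  list(sigma2_i = max(0, raw), sigma2_m = a$ms_error, clamped = clamped)
}

#' FA and measurement-error indices for one trait
#'
#' Computes the index family for a single balanced trait matrix, all from
#' one sides-by-individuals decomposition:
#' \describe{
#'   \item{FA1}{mean absolute side difference, mean(|d_i|), in mm.}
#'   \item{FA4a}{0.798 * sqrt(var(d_i)); inflated by measurement error,
#'     since var(d_i) includes 2 sigma2_m / M.}
#'   \item{FA10a}{0.798 * sqrt(2 sigma2_i): the expected mean absolute
#'     asymmetry of a normal FA distribution *after* the measurement-error
#'     component has been parsed out; 0.798 = sqrt(2/pi).}
#'   \item{ME3}{100 * sigma2_m / (sigma2_i + sigma2_m): the percentage of
#'     nondirectional between-sides variance attributable to measurement
#'     error, a unit-free repeatability descriptor.}
#' }
#' Repeatability is reported as 1 - ME3/100. When sigma2_i + sigma2_m = 0
#' (degenerate, noise-free symmetric data) ME3 is undefined and returned
#' as `NA` with a warning.
#'
#' @param tm a [trait_matrix()] with J >= 2, M >= 2.
#' @return one-row data.frame of class `fa_report`: `sex`, `metric`,
#'   `tooth`, `fa1`, `fa4a`, `fa10a`, `me3_percent`, `repeatability`,
#'   `sigma2_i`, `sigma2_m`, `clamped`, `n`.
#' @export
fa_indices <- function(tm) {
  a <- fit_sides_anova(tm)
  vc <- variance_components(a)
  sm <- side_means(tm)
  k <- sqrt(2 / pi)
  fa1 <- mean(abs(sm$d))
  fa4a <- k * stats::sd(sm$d)
  fa10a <- k * sqrt(2 * vc$sigma2_i)
  tot <- vc$sigma2_i + vc$sigma2_m
  if (tot <= 0) {
    warning("sigma2_i + sigma2_m = 0: ME3 undefined for trait ",
            paste(tm$sex, tm$tooth, tm$metric))
    me3 <- NA_real_
  } else {
    me3 <- 100 * vc$sigma2_m / tot
  }
  out <- data.frame(
    sex = tm$sex, metric = tm$metric, tooth = tm$tooth,
    fa1 = fa1, fa4a = fa4a, fa10a = fa10a,
    me3_percent = me3, repeatability = 1 - me3 / 100,
    sigma2_i = vc$sigma2_i, sigma2_m = vc$sigma2_m,
    clamped = vc$clamped, n = tm$J,
    stringsAsFactors = FALSE
  )
  class(out) <- c("fa_report", "data.frame")
  out
}

#' FA report for a collection of traits
#'
#' Applies [fa_indices()] to every trait matrix in a list (as produced by
#' [build_trait_matrices()]) and binds the one-row reports.
#'
#' @param tms named list of `trait_matrix` objects.
#' @return data.frame with one row per trait, class `fa_report`.
#' @export
fa_report_table <- function(tms) {
  stopifnot(length(tms) > 0)
  out <- do.call(rbind, lapply(tms, fa_indices))
  rownames(out) <- NULL
  class(out) <- c("fa_report", "data.frame")
  out
}

#' Serialize an FA report to TSV
#'
#' Column order mirrors the published index table (sex, metric, tooth,
#' fa10a, n) followed by the supplementary indices.
#'
#' @param report an `fa_report` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fa_report <- function(report, path) {
  cols <- c("sex", "metric", "tooth", "fa10a", "n",
            "fa1", "fa4a", "me3_percent", "repeatability")
  utils::write.table(report[intersect(cols, names(report))], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
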
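#' D'Agostino test of skewness
#'
#' Standardized skewness test: the sample skewness g1 = m3 / m2^(3/2) is
#' transformed to an approximately standard-normal Z (D'Agostino's
#' formulation). Requires n >= 8 for the approximation to hold.
#'
#' @param x numeric vector, n >= 8.
#' @return list with `g1`, `z`, `p` (two-sided).
#' @export
skewness_test <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("skewness test requires n >= 8")
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  if (m2 <= 0) stop("zero variance: skewness undefined")
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z <- delta * asinh(y / alpha)
  list(g1 = g1, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Anscombe-Glynn test of kurtosis
#'
#' Standardized kurtosis test: the sample kurtosis b2 = m4 / m2^2 is
#' transformed to an approximately standard-normal Z (Anscombe-Glynn
#' formulation). The one-sided platykurtic p-value (`p_platy`) tests for
#' kurtosis *below* the normal value, the signature of antisymmetry.
#'
#' @param x numeric vector, n >= 8.
#' @return list with `g2` (excess kurtosis b2 - 3), `z`, `p` (two-sided),
#'   `p_platy` (one-sided, platykurtic alternative).
#' @export
kurtosis_test <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("kurtosis test requires n >= 8")
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  if (m2 <= 0) stop("zero variance: kurtosis undefined")
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  denom <- 1 + xx * sqrt(2 / (a - 4))
  if (denom <= 0) {
    # beyond the domain of the cube-root normalization: kurtosis is so
    # far below the normal value that the evidence is effectively
    # infinite (platykurtic)
    z <- -Inf
  } else {
    term <- ((1 - 2 / a) / denom)^(1 / 3)
    z <- (1 - 2 / (9 * a) - term) / sqrt(2 / (9 * a))
  }
  list(g2 = b2 - 3, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       p_platy = stats::pnorm(z))
}

#' Iterative Grubbs outlier flagging
#'
#' Applies the two-sided Grubbs test repeatedly: at each step the most
#' extreme observation is tested against the t-based critical value at
#' level `alpha`; if significant it is set aside and the test repeats on
#' the remainder, until no outlier is found or fewer than 3 points
#' remain. Flagged observations are reported; removal is the caller's
#' choice.
#'
#' @param x numeric vector.
#' @param alpha significance level per step (default 0.05).
#' @return integer vector of indices into `x` flagged as outliers
#'   (possibly empty), in flagging order.
#' @export
grubbs_outliers <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  idx <- seq_along(x)
  flagged <- integer(0)
  repeat {
    n <- length(x)
    if (n < 3L) break
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    g <- dev[i] / s
    tcrit <- stats::qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
    gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (g <= gcrit) break
    flagged <- c(flagged, idx[i])
    x <- x[-i]
    idx <- idx[-i]
  }
  flagged
}

#' Confounder screening for one trait
#'
#' Runs the data-inspection battery on a trait's signed side differences
#' d_i = R_i - L_i (side means): directional asymmetry (DA) by the
#' skewness test and by the supplementary one-sample t-test of mean(d)
#' against 0; antisymmetry (AS) by the one-sided platykurtosis test;
#' trait-size dependency by Spearman rank correlation of |d_i| with the
#' individual trait size s_i; and outliers by iterative Grubbs flagging.
#'
#' The DA flag rule is configurable: the study criterion is a significant
#' skew (`"skew"`), the conventional criterion is a significant mean
#' shift (`"t"`); the default `"either"` flags on either test. The AS
#' flag requires a significant platykurtosis test *and* negative excess
#' kurtosis. With fewer than 8 individuals the moment tests are not
#' evaluable and the trait is reported clean with a warning.
#'
#' @param tm a [trait_matrix()].
#' @param alpha significance level for every screen (default 0.05).
#' @param da_rule `"either"` (default), `"skew"`, or `"t"`.
#' @return one-row data.frame: trait key, J, the statistics and p-values
#'   of each screen, `outliers` (comma-separated individual ids),
#'   flags `da_flag`, `as_flag`, `size_dep_flag`, `evaluable`, and
#'   `verdict` in `{"clean", "DA", "AS", "size_dependent"}` (priority
#'   DA > AS > size_dependent).
#' @export
screen_trait <- function(tm, alpha = 0.05, da_rule = c("either", "skew", "t")) {
  da_rule <- match.arg(da_rule)
  sm <- side_means(tm)
  d <- sm$d
  J <- length(d)
  res <- data.frame(
    sex = tm$sex, metric = tm$metric, tooth = tm$tooth, J = J,
    skewness = NA_real_, skew_p = NA_real_,
    excess_kurtosis = NA_real_, kurtosis_p = NA_real_,
    mean_d_t = NA_real_, mean_d_p = NA_real_,
    size_dependency_rho = NA_real_, size_dependency_p = NA_real_,
    outliers = "", da_flag = FALSE, as_flag = FALSE,
    size_dep_flag = FALSE, evaluable = TRUE, verdict = "clean",
    stringsAsFactors = FALSE
  )
  if (stats::var(d) == 0) {
    warning("constant side differences for trait ",
            paste(tm$sex, tm$tooth, tm$metric), ": screens not evaluable")
    res$evaluable <- FALSE
    return(res)
  }
  if (J < 8L) {
    warning("J = ", J, " < 8 for trait ", paste(tm$sex, tm$tooth, tm$metric),
            ": moment tests not evaluable, verdict clean-with-warning")
    res$evaluable <- FALSE
    return(res)
  }

  sk <- skewness_test(d)
  ku <- kurtosis_test(d)
  tt <- stats::t.test(d, mu = 0)
  ct <- suppressWarnings(
    stats::cor.test(abs(d), sm$s, method = "spearman", exact = FALSE)
  )
  out_idx <- grubbs_outliers(d, alpha)

  res$skewness <- sk$g1
  res$skew_p <- sk$p
  res$excess_kurtosis <- ku$g2
  res$kurtosis_p <- ku$p_platy
  res$mean_d_t <- unname(tt$statistic)
  res$mean_d_p <- tt$p.value
  res$size_dependency_rho <- unname(ct$estimate)
  res$size_dependency_p <- ct$p.value
  res$outliers <- paste(tm$individuals[out_idx], collapse = ",")

  res$da_flag <- switch(da_rule,
    skew = sk$p < alpha,
    t = tt$p.value < alpha,
    either = sk$p < alpha || tt$p.value < alpha
  )
  res$as_flag <- ku$p_platy < alpha && ku$g2 < 0
  res$size_dep_flag <- ct$p.value < alpha
  res$verdict <- if (res$da_flag) "DA" else if (res$as_flag) "AS" else
    if (res$size_dep_flag) "size_dependent" else "clean"
  res
}

#' Screen a collection of traits
#'
#' @param tms named list of `trait_matrix` objects.
#' @inheritParams screen_trait
#' @return data.frame with one [screen_trait()] row per trait.
#' @export
screen_traits <- function(tms, alpha = 0.05,
                          da_rule = c("either", "skew", "t")) {
  da_rule <- match.arg(da_rule)
  out <- do.call(rbind, lapply(tms, screen_trait, alpha = alpha,
                               da_rule = da_rule))
  rownames(out) <- NULL
  out
}

#' Apply variable-elimination rules to screening results
#'
#' Eliminates trait variables whose screening flags indicate a
#' non-FA asymmetry signal, with one reason per variable in priority
#' order DA > AS > size_dependent (mirroring the screening verdict).
#' Which flags eliminate is configurable; by default all three do.
#'
#' @param screening data.frame from [screen_traits()].
#' @param eliminate character vector of verdicts that eliminate,
#'   subset of `c("DA", "AS", "size_dependent")`.
#' @return list with `retained` (data.frame of kept trait keys) and
#'   `eliminated` (ledger data.frame: sex, metric, tooth, reason). A
#'   warning is raised if nothing is retained.
#' @export
apply_elimination <- function(screening,
                              eliminate = c("DA", "AS", "size_dependent")) {
  eliminate <- match.arg(eliminate, several.ok = TRUE)
  reason <- rep(NA_character_, nrow(screening))
  if ("DA" %in% eliminate) reason[is.na(reason) & screening$da_flag] <- "DA"
  if ("AS" %in% eliminate) reason[is.na(reason) & screening$as_flag] <- "AS"
  if ("size_dependent" %in% eliminate) {
    reason[is.na(reason) & screening$size_dep_flag] <- "size_dependent"
  }
  keep <- is.na(reason)
  keys <- screening[c("sex", "metric", "tooth")]
  eliminated <- cbind(keys[!keep, , drop = FALSE],
                      reason = reason[!keep])
  rownames(eliminated) <- NULL
  retained <- keys[keep, , drop = FALSE]
  rownames(retained) <- NULL
  if (nrow(retained) == 0L) warning("all trait variables eliminated")
  list(retained = retained, eliminated = eliminated)
}

#' Measurement-error scan across replicate subsets
#'
#' For each contiguous replicate subset, rebuilds per-trait balanced
#' matrices, computes each trait's ME3 percentage, and summarizes across
#' traits. Two aggregations are reported: `me3_pooled`, the
#' variance-weighted pooled percentage 100 * sum(sigma2_m) /
#' sum(sigma2_i + sigma2_m) over traits, and the mean/median/min/max/
#' range of the per-trait ME3 values.
#'
#' @param records validated measurement data.frame.
#' @param subsets list of contiguous integer ranges (e.g.
#'   `list(1:10, 2:9, 9:10)`); each must lie within the replicates
#'   present in `records` and contain at least 2 trials.
#' @return data.frame with one row per subset: `subset_label`,
#'   `me3_pooled`, `mean`, `median`, `minimum`, `maximum`, `range`,
#'   `n_traits` (all ME3 figures in percent).
#' @export
replicate_scan <- function(records, subsets) {
  max_rep <- max(records$replicate)
  rows <- lapply(subsets, function(subset) {
    subset <- sort(unique(as.integer(subset)))
    label <- paste0(min(subset), "-", max(subset))
    if (min(subset) < 1L || max(subset) > max_rep) {
      stop("replicate subset ", label, " outside available replicates 1..",
           max_rep)
    }
    if (length(subset) < 2L) {
      stop("replicate subset ", label, " has fewer than 2 trials")
    }
    tms <- suppressWarnings(build_trait_matrices(records, subset))
    vcs <- lapply(tms, function(tm) variance_components(fit_sides_anova(tm)))
    me3 <- vapply(vcs, function(v) {
      tot <- v$sigma2_i + v$sigma2_m
      if (tot <= 0) NA_real_ else 100 * v$sigma2_m / tot
    }, numeric(1))
    s2m <- vapply(vcs, `[[`, numeric(1), "sigma2_m")
    s2i <- vapply(vcs, `[[`, numeric(1), "sigma2_i")
    pooled_tot <- sum(s2i) + sum(s2m)
    data.frame(
      subset_label = label,
      me3_pooled = if (pooled_tot <= 0) 0 else 100 * sum(s2m) / pooled_tot,
      mean = mean(me3, na.rm = TRUE),
      median = stats::median(me3, na.rm = TRUE),
      minimum = min(me3, na.rm = TRUE),
      maximum = max(me3, na.rm = TRUE),
      range = max(me3, na.rm = TRUE) - min(me3, na.rm = TRUE),
      n_traits = length(tms),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
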
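#' Configuration for a synthetic replicated bilateral trait
#'
#' Parameters of the generative model used throughout the package's
#' calibration and recovery tests. Per individual i, a true trait size
#' T_i ~ N(trait_mean, trait_sd^2) is split into sides around a signed
#' asymmetry A_i = da_offset + FA_i + AS_i, where FA_i ~ N(0, sigma_fa^2)
#' is the fluctuating-asymmetry deviation, and AS_i = +/- as_delta (sign
#' fair-coin) with probability as_prob (else 0) is an antisymmetric
#' two-point admixture. True sides are R_i = T_i + A_i/2 and
#' L_i = T_i - A_i/2; each of the M replicate measurements per side adds
#' independent N(0, sigma_me^2) error. Whole (individual, side) cells are
#' dropped with probability missing_rate, emulating unmeasurable teeth.
#'
#' `size_dep_gamma` plants trait-size dependency: the FA deviation's SD
#' is scaled by (T_i / trait_mean)^gamma, so |d_i| correlates with trait
#' size when gamma > 0 (0, the default, disables this).
#'
#' Defaults mirror the baboon dental study's conditions: J = 25
#' individuals per trait (the published per-variable n runs 14-35),
#' M = 10 replicate measurements, crown dimensions near 10 mm with
#' ~0.8 mm between-individual SD, an FA deviation SD of 0.035 mm (giving
#' FA10a indices in the published 0.01-0.10 mm range) and a 0.01 mm
#' single-measurement error SD (per-variable ME3 near 8%).
#'
#' @param n_individuals J, individuals per trait.
#' @param n_replicates M, replicate measurements per side.
#' @param trait_mean,trait_sd mm; between-individual size distribution.
#' @param sigma_fa mm; SD of the signed FA deviation (sqrt of sigma2_i).
#' @param da_offset mm; mean of R - L (directional asymmetry).
#' @param as_delta mm; half-separation of the antisymmetric mixture.
#' @param as_prob mixture weight in `[0, 1]`.
#' @param sigma_me mm; single-measurement error SD. A scalar, or a
#'   length-M vector of per-trial SDs for heterogeneous-trial scans.
#' @param missing_rate probability in `[0, 1)` that an (individual, side)
#'   cell is unmeasurable.
#' @param size_dep_gamma exponent of the FA-size scaling (0 = none).
#' @param sex,tooth,metric trait labels stamped on the records.
#' @param seed optional integer seed (`NULL` uses the current RNG state).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals = 25, n_replicates = 10,
                             trait_mean = 10, trait_sd = 0.8,
                             sigma_fa = 0.035, da_offset = 0,
                             as_delta = 0, as_prob = 0,
                             sigma_me = 0.01, missing_rate = 0,
                             size_dep_gamma = 0,
                             sex = "female", tooth = "MXM1",
                             metric = "breadth", seed = NULL) {
  stopifnot(
    n_individuals >= 2, n_replicates >= 1,
    trait_sd >= 0, sigma_fa >= 0, as_delta >= 0,
    as_prob >= 0, as_prob <= 1, all(sigma_me >= 0),
    missing_rate >= 0, missing_rate < 1,
    length(sigma_me) == 1L || length(sigma_me) == n_replicates
  )
  structure(
    list(n_individuals = n_individuals, n_replicates = n_replicates,
         trait_mean = trait_mean, trait_sd = trait_sd,
         sigma_fa = sigma_fa, da_offset = da_offset,
         as_delta = as_delta, as_prob = as_prob, sigma_me = sigma_me,
         missing_rate = missing_rate, size_dep_gamma = size_dep_gamma,
         sex = sex, tooth = tooth, metric = metric, seed = seed),
    class = "synthetic_config"
  )
}

#' Simulate one trait's replicated bilateral measurements
#'
#' Draws a dataset from the generative model described in
#' [synthetic_config()] and returns it in the canonical long record
#' format, ready for [build_trait_matrices()].
#'
#' @param cfg a [synthetic_config()].
#' @return validated measurement data.frame (J x 2 x M rows minus any
#'   missing cells).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  J <- cfg$n_individuals
  M <- cfg$n_replicates

  size <- stats::rnorm(J, cfg$trait_mean, cfg$trait_sd)
  fa_sd <- cfg$sigma_fa
  if (cfg$size_dep_gamma != 0) {
    fa_sd <- fa_sd * pmax(size / cfg$trait_mean, 0.05)^cfg$size_dep_gamma
  }
  fa <- stats::rnorm(J, 0, fa_sd)
  as_on <- stats::runif(J) < cfg$as_prob
  as_sign <- ifelse(stats::runif(J) < 0.5, -1, 1)
  asym <- cfg$da_offset + fa + ifelse(as_on, as_sign * cfg$as_delta, 0)
  right <- size + asym / 2
  left <- size - asym / 2

  me <- if (length(cfg$sigma_me) == 1L) rep(cfg$sigma_me, M) else cfg$sigma_me
  # measurement cells: rows interleaved (L_1, R_1, L_2, R_2, ...), one
  # column per replicate trial; per-trial error SD me[k]
  truth <- as.vector(rbind(left, right))
  obs <- matrix(NA_real_, 2 * J, M)
  for (k in seq_len(M)) {
    obs[, k] <- truth + stats::rnorm(2 * J, 0, me[k])
  }
  keep_cell <- stats::runif(2 * J) >= cfg$missing_rate

  # ids are sex-prefixed so that a multi-trait, two-sex study satisfies
  # the global (individual, tooth, metric, side, replicate) uniqueness
  # invariant while the same individuals recur across a sex's traits
  ids <- sprintf("%s%03d", substr(cfg$sex, 1, 1), seq_len(J))
  info <- tooth_info(cfg$tooth)
  cell <- rep(seq_len(2 * J), times = M)
  replicate <- rep(seq_len(M), each = 2 * J)
  indiv <- (cell + 1L) %/% 2L
  rec <- data.frame(
    individual_id = ids[indiv],
    sex = cfg$sex,
    tooth = cfg$tooth,
    arcade = info$arcade,
    tooth_class = info$tooth_class,
    metric = cfg$metric,
    side = ifelse(cell %% 2L == 1L, "L", "R"),
    replicate = replicate,
    value_mm = obs[cbind(cell, replicate)],
    stringsAsFactors = FALSE
  )
  rec <- rec[keep_cell[cell], , drop = FALSE]
  rownames(rec) <- NULL
  validate_measurements(rec)
}

trait_key <- function(sex, tooth, metric) paste(sex, tooth, metric, sep = ".")

# deterministic 31-bit substream seed for a trait key
trait_substream_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

#' Build a study-shaped roster of synthetic trait configurations
#'
#' Creates one [synthetic_config()] per (sex, tooth, metric) combination
#' over the study roster (2 sexes x 9 teeth x 2 metrics = 36 candidate
#' variables), with optional planted effects: `da_traits` receive a
#' directional-asymmetry offset, `size_dep_traits` receive trait-size
#' dependency, and `sigma_fa_male` allows a sex difference in FA
#' magnitude (emulating the male-female difference of the study).
#'
#' @param n_individuals,n_replicates design size per trait.
#' @param sigma_fa_female,sigma_fa_male mm; FA deviation SD per sex.
#' @param da_traits character vector of `"sex.TOOTH.metric"` keys given
#'   `da_offset`.
#' @param da_offset mm; planted DA offset for `da_traits`.
#' @param size_dep_traits keys given `size_dep_gamma`.
#' @param size_dep_gamma planted size-dependency exponent.
#' @param teeth trait codes (default [study_teeth()]).
#' @param ... further arguments passed to every [synthetic_config()].
#' @return named list of configs keyed `"sex.TOOTH.metric"`.
#' @export
study_configs <- function(n_individuals = 25, n_replicates = 10,
                          sigma_fa_female = 0.035,
                          sigma_fa_male = 0.035,
                          da_traits = character(0), da_offset = 0.3,
                          size_dep_traits = character(0),
                          size_dep_gamma = 3,
                          teeth = study_teeth(), ...) {
  cfgs <- list()
  for (sex in c("female", "male")) {
    for (tooth in teeth) {
      for (metric in c("length", "breadth")) {
        key <- trait_key(sex, tooth, metric)
        cfgs[[key]] <- synthetic_config(
          n_individuals = n_individuals, n_replicates = n_replicates,
          sigma_fa = if (sex == "male") sigma_fa_male else sigma_fa_female,
          da_offset = if (key %in% da_traits) da_offset else 0,
          size_dep_gamma = if (key %in% size_dep_traits) size_dep_gamma else 0,
          sex = sex, tooth = tooth, metric = metric, ...
        )
      }
    }
  }
  cfgs
}

#' Simulate a multi-trait study
#'
#' Concatenates one simulated dataset per trait configuration. A single
#' global seed drives a deterministic per-trait substream, so each
#' trait's records are reproducible independently of roster order or
#' composition.
#'
#' @param configs named list of [synthetic_config()] objects; names (or
#'   the configs' own sex/tooth/metric labels) must form unique trait
#'   keys.
#' @param seed integer global seed.
#' @return validated measurement data.frame covering all traits.
#' @export
simulate_study <- function(configs, seed = 1L) {
  keys <- vapply(configs, function(cfg) {
    trait_key(cfg$sex, cfg$tooth, cfg$metric)
  }, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate trait key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  parts <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    cfg$seed <- trait_substream_seed(seed, keys[i])
    simulate_dataset(cfg)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
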
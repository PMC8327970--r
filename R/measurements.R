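MEASUREMENT_COLUMNS <- c(
  "individual_id", "sex", "tooth", "arcade", "tooth_class",
  "metric", "side", "replicate", "value_mm"
)

#' Validate a table of replicated bilateral measurements
#'
#' Checks a long-format measurement table against the canonical data
#' model: one row per (individual, trait, side, replicate) with a
#' positive, finite measurement in millimetres. Rows violating row-level
#' invariants are dropped with a warning that lists their row numbers;
#' structural problems (missing columns, duplicated keys) are errors.
#'
#' @param records data.frame with columns `individual_id`, `sex`
#'   (`"female"`/`"male"`), `tooth` (trait code), `arcade`, `tooth_class`,
#'   `metric` (`"length"`/`"breadth"`), `side` (`"L"`/`"R"`), `replicate`
#'   (integer >= 1), `value_mm` (positive mm).
#' @return the validated data.frame, with attributes `n_read` and
#'   `n_dropped` recording row counts.
#' @export
validate_measurements <- function(records) {
  missing <- setdiff(MEASUREMENT_COLUMNS, names(records))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  records <- records[MEASUREMENT_COLUMNS]
  n_read <- nrow(records)
  records$individual_id <- as.character(records$individual_id)
  records$sex <- tolower(as.character(records$sex))
  records$tooth <- toupper(as.character(records$tooth))
  records$metric <- tolower(as.character(records$metric))
  records$side <- toupper(as.character(records$side))
  records$replicate <- as.integer(records$replicate)
  records$value_mm <- as.numeric(records$value_mm)

  bad <- !is.finite(records$value_mm) | records$value_mm <= 0
  bad <- bad | !(records$sex %in% c("female", "male"))
  bad <- bad | !(records$side %in% c("L", "R"))
  bad <- bad | !(records$metric %in% c("length", "breadth"))
  bad <- bad | is.na(records$replicate) | records$replicate < 1L
  bad <- bad | !grepl("^(MN|MX)(P[34]|M[123])$", records$tooth)
  if (any(bad)) {
    warning(sum(bad), " row(s) dropped by validation: rows ",
            paste(utils::head(which(bad), 20), collapse = ", "),
            if (sum(bad) > 20) ", ..." else "")
    records <- records[!bad, , drop = FALSE]
  }

  # derived fields must agree with the trait code
  info <- tooth_info(records$tooth)
  mismatch <- tolower(records$arcade) != info$arcade |
    tolower(records$tooth_class) != info$tooth_class
  if (any(mismatch)) {
    stop("arcade/tooth_class disagree with tooth code in ",
         sum(mismatch), " row(s), e.g. row ", which(mismatch)[1])
  }

  key <- paste(records$individual_id, records$tooth, records$metric,
               records$side, records$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (individual, tooth, metric, side, replicate) key, e.g. row ",
         which(duplicated(key))[1])
  }
  rownames(records) <- NULL
  attr(records, "n_read") <- n_read
  attr(records, "n_dropped") <- n_read - nrow(records)
  records
}

#' Read replicated bilateral measurements from CSV
#'
#' Reads the canonical long-format CSV dialect (UTF-8, comma separated,
#' header required) and validates it with [validate_measurements()].
#'
#' @param path path to a CSV file with the nine canonical columns.
#' @return validated measurement data.frame (see [validate_measurements()]).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  validate_measurements(records)
}

#' Write measurements to the canonical CSV dialect
#'
#' @param records measurement data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  utils::write.csv(records[MEASUREMENT_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a balanced trait matrix
#'
#' A `trait_matrix` holds one trait's measurements as two aligned J x M
#' matrices (left and right antimere, J individuals by M replicates), the
#' substrate of the sides-by-individuals ANOVA. Rows of `left` and
#' `right` refer to the same individuals, in the same order.
#'
#' @param left,right numeric J x M matrices of measurements (mm).
#' @param individuals character vector of J individual ids.
#' @param sex,tooth,metric trait key labels (may be `NA` for toy data).
#' @return object of class `trait_matrix`.
#' @export
trait_matrix <- function(left, right, individuals = NULL,
                         sex = NA_character_, tooth = NA_character_,
                         metric = NA_character_) {
  left <- as.matrix(left)
  right <- as.matrix(right)
  if (!all(dim(left) == dim(right))) {
    stop("left and right matrices must have identical dimensions")
  }
  if (nrow(left) < 2L) stop("a trait matrix needs J >= 2 individuals")
  if (ncol(left) < 1L) stop("a trait matrix needs M >= 1 replicates")
  if (anyNA(left) || anyNA(right)) stop("trait matrices must be complete (no NA)")
  if (is.null(individuals)) individuals <- as.character(seq_len(nrow(left)))
  stopifnot(length(individuals) == nrow(left))
  structure(
    list(left = unname(left), right = unname(right),
         individuals = as.character(individuals),
         J = nrow(left), M = ncol(left),
         sex = sex, tooth = tooth, metric = metric),
    class = "trait_matrix"
  )
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %s %s %s  (J = %d individuals, M = %d replicates)\n",
              x$sex, x$tooth, x$metric, x$J, x$M))
  invisible(x)
}

#' Build per-trait balanced matrices from long-format records
#'
#' Splits records by (sex, tooth, metric) and assembles one balanced
#' [trait_matrix()] per trait. Completeness is judged per trait: an
#' individual enters a trait's matrix only if it has both antimeres and
#' every replicate in `replicate_subset` on both sides; individuals with
#' partial dentitions remain in every other trait they are complete for.
#' Traits with fewer than two complete individuals are skipped with a
#' warning.
#'
#' @param records validated measurement data.frame.
#' @param replicate_subset non-empty integer vector of replicate indices
#'   to use (any subset of the trials present, e.g. `1:10`, `2:5`,
#'   `c(1, 10)`); replicates outside it are simply unused.
#' @return named list of `trait_matrix` objects, keyed
#'   `"<sex>.<tooth>.<metric>"`, in deterministic key order.
#' @export
build_trait_matrices <- function(records, replicate_subset = NULL) {
  if (is.null(replicate_subset)) {
    replicate_subset <- seq_len(max(records$replicate))
  }
  replicate_subset <- sort(unique(as.integer(replicate_subset)))
  if (length(replicate_subset) == 0L) stop("replicate_subset is empty")

  records <- records[records$replicate %in% replicate_subset, , drop = FALSE]
  M <- length(replicate_subset)
  keys <- sort(unique(paste(records$sex, records$tooth, records$metric,
                            sep = ".")))
  out <- list()
  for (key in keys) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sub <- records[records$sex == parts[1] & records$tooth == parts[2] &
                     records$metric == parts[3], , drop = FALSE]
    # complete-case per trait: both sides, all subset replicates
    counts <- table(sub$individual_id)
    complete <- names(counts)[counts == 2L * M]
    complete <- sort(complete)
    if (length(complete) < 2L) {
      warning("trait ", key, " skipped: fewer than 2 complete individuals")
      next
    }
    sub <- sub[sub$individual_id %in% complete, , drop = FALSE]
    i <- match(sub$individual_id, complete)
    k <- match(sub$replicate, replicate_subset)
    left <- matrix(NA_real_, length(complete), M)
    right <- matrix(NA_real_, length(complete), M)
    isL <- sub$side == "L"
    left[cbind(i[isL], k[isL])] <- sub$value_mm[isL]
    right[cbind(i[!isL], k[!isL])] <- sub$value_mm[!isL]
    if (anyNA(left) || anyNA(right)) {
      # an individual counted as complete must have had a duplicate side;
      # validate_measurements() precludes this, guard anyway
      stop("internal error: incomplete cell for trait ", key)
    }
    out[[key]] <- trait_matrix(left, right, complete,
                               sex = parts[1], tooth = parts[2],
                               metric = parts[3])
  }
  out
}

#' Published baboon FA10a index table
#'
#' Loads the bundled table of 31 published FA10a index values (with the
#' per-variable sample size n underlying each index) from the study of
#' dental fluctuating asymmetry in wild Nigerian olive baboons: 9 female
#' breadth, 7 female length, 9 male breadth and 6 male length variables,
#' after the study's confounder-based eliminations. This table is the
#' input to the group-level hypothesis tests reproduced by
#' [run_hypothesis_suite()].
#'
#' @return data.frame with columns `sex`, `metric`, `tooth`, `fa10a`, `n`.
#' @export
load_baboon_fa10a <- function() {
  path <- system.file("extdata", "baboon_fa10a_published.csv",
                      package = "flucasym", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$sex <- tolower(df$sex)
  df$metric <- tolower(df$metric)
  stopifnot(nrow(df) == 31L, all(df$fa10a >= 0), all(df$n >= 2))
  df
}
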
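#' Dental trait codes
#'
#' Trait codes follow the `MN`/`MX` + tooth scheme used for baboon
#' postcanine dentition: `MN` = mandibular, `MX` = maxillary, followed by
#' `P3`/`P4` (third/fourth premolar) or `M1`/`M2`/`M3` (molars). Arcade
#' and tooth class are derivable from the code and are validated against
#' it on input.
#'
#' @param tooth character vector of trait codes (e.g. `"MNM1"`, `"MXP4"`).
#' @return `tooth_info()` returns a data.frame with columns `tooth`,
#'   `arcade` (`"mandible"`/`"maxilla"`), `tooth_class`
#'   (`"premolar"`/`"molar"`) and `tooth_type` (`"P3"`, `"P4"`, `"M1"`,
#'   `"M2"`, `"M3"`); invalid codes raise an error.
#' @examples
#' tooth_info(c("MNM1", "MXP4"))
#' @export
tooth_info <- function(tooth) {
  tooth <- toupper(as.character(tooth))
  ok <- grepl("^(MN|MX)(P[34]|M[123])$", tooth)
  if (!all(ok)) {
    stop("invalid tooth code(s): ", paste(unique(tooth[!ok]), collapse = ", "))
  }
  data.frame(
    tooth = tooth,
    arcade = ifelse(substr(tooth, 1, 2) == "MN", "mandible", "maxilla"),
    tooth_class = ifelse(substr(tooth, 3, 3) == "P", "premolar", "molar"),
    tooth_type = substr(tooth, 3, 4),
    stringsAsFactors = FALSE
  )
}

#' Study trait roster
#'
#' The nine postcanine trait codes measurable in the baboon study sample.
#' The mandibular third premolar is excluded: in cercopithecoids it is the
#' sectorial (canine-honing) tooth and its crown does not yield comparable
#' maximum length/breadth measurements.
#'
#' @return character vector of nine trait codes.
#' @export
study_teeth <- function() {
  c("MNM1", "MNM2", "MNM3", "MNP4", "MXM1", "MXM2", "MXM3", "MXP3", "MXP4")
}
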
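#' Packaged experiment fixtures
#'
#' Tables packaged with hkbright:
#' \describe{
#'   \item{`table2`}{the 30 chromatic test stimuli of the laser-projector
#'     brightness-matching experiment: luminance `L` (cd/m2), chromaticity
#'     `x`, `y`, and `matched_L`, the mean luminance of the achromatic
#'     stimulus the 16 observers matched to it (cd/m2).}
#'   \item{`table3`}{the published per-observer interobserver-agreement CVs
#'     (percent) of the same experiment.}
#'   \item{`primaries_laser`, `primaries_bt2020`, `primaries_8ktv`}{display
#'     primary chromaticities, as in [display_primaries()].}
#' }
#'
#' @param name Fixture name.
#' @return A tibble.
#' @examples
#' hk_dataset("table2")
#' @export
hk_dataset <- function(name = c("table2", "table3", "primaries_laser",
                                "primaries_bt2020", "primaries_8ktv")) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("table2", "table3", "primaries_laser",
                   "primaries_bt2020", "primaries_8ktv")) {
    abort(paste("unknown fixture; available: table2, table3,",
                "primaries_laser, primaries_bt2020, primaries_8ktv"))
  }
  if (name %in% c("primaries_laser", "primaries_bt2020", "primaries_8ktv")) {
    return(display_primaries(sub("primaries_", "", name)))
  }
  file <- switch(name,
    table2 = "table2_stimuli.csv",
    table3 = "table3_observer_cv.csv"
  )
  path <- system.file("extdata", file, package = "hkbright", mustWork = TRUE)
  out <- as_tibble(read.csv(path))
  if (name == "table2") check_stimuli(out)
  out
}

check_stimuli <- function(data, need_match = TRUE) {
  cols <- c("L", "x", "y", if (need_match) "matched_L")
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    abort(paste("stimulus table is missing column(s):", paste(miss, collapse = ", ")))
  }
  if (any(data$L <= 0)) abort("stimulus luminance must be positive")
  if (need_match && any(data$matched_L <= 0)) {
    abort("matched luminance must be positive")
  }
  invisible(data)
}

#' Read a stimulus table from CSV
#'
#' CSV dialect: header `id,L,x,y,matched_L`, UTF-8, '.' decimal separator.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the stimulus records.
#' @export
read_stimuli <- function(path) {
  out <- as_tibble(read.csv(path))
  check_stimuli(out)
  out
}
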
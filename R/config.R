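conditions_keys <- c("white_x", "white_y", "white_L", "La", "Yb", "surround")

#' Read viewing conditions from a key-value config file
#'
#' The file is YAML with (a subset of) the keys `white_x`, `white_y`,
#' `white_L`, `La`, `Yb`, `surround`; missing keys take the
#' [cam16_conditions()] defaults and unknown keys are an error.
#'
#' @param path Path to the config file.
#' @return A [cam16_conditions()] object.
#' @export
read_conditions <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("config must be a key-value mapping")
  unknown <- setdiff(names(cfg), conditions_keys)
  if (length(unknown)) {
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  do.call(cam16_conditions, cfg)
}

#' Write viewing conditions to a key-value config file
#'
#' @param vc A [cam16_conditions()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conditions <- function(vc, path) {
  stopifnot(inherits(vc, "cam16_conditions"))
  yaml::write_yaml(
    list(white_x = vc$white_x, white_y = vc$white_y, white_L = vc$white_L,
         La = vc$La, Yb = vc$Yb, surround = vc$surround),
    path)
  invisible(path)
}

#' Serialize fitted parameters to a key-value config
#'
#' @param params An [hk_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hk_params <- function(params, path) {
  stopifnot(inherits(params, "hk_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Read fitted parameters from a key-value config
#'
#' @param path Path written by [write_hk_params()] (keys alpha1..alpha4,
#'   gamma).
#' @return An [hk_params()] object.
#' @export
read_hk_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("alpha1", "alpha2", "alpha3", "alpha4", "gamma")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    abort(paste("params config missing key(s):", paste(miss, collapse = ", ")))
  }
  unknown <- setdiff(names(cfg), need)
  if (length(unknown)) {
    abort(paste("unknown params key(s):", paste(unknown, collapse = ", ")))
  }
  do.call(hk_params, cfg[need])
}
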
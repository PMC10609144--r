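#' Parameters of the Helmholtz-Kohlrausch brightness compensation
#'
#' The corrected lightness is
#' \deqn{J_{HK} = J + f_1(J) f_2(h) C^\gamma,\quad
#'   f_1(J) = \alpha_1 + \alpha_2 J,\quad
#'   f_2(h) = \alpha_3 + \alpha_4 (1 - \sin(h/2))}
#' with the hue angle h in degrees (so f_2 has period 720 degrees with a
#' single minimum at h = 180).
#'
#' @param alpha1,alpha2 Coefficients of the lightness factor f1.
#' @param alpha3,alpha4 Coefficients of the hue factor f2.
#' @param gamma Chroma exponent, > 0.
#' @return An object of class `hk_params`.
#' @seealso [hk_params_profile()] for the published fitted values.
#' @export
hk_params <- function(alpha1, alpha2, alpha3, alpha4, gamma) {
  if (gamma <= 0) abort("gamma must be > 0")
  structure(
    list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
         alpha4 = alpha4, gamma = gamma),
    class = "hk_params"
  )
}

#' Named parameter profiles
#'
#' `"zhu2023"` is the parameter set fitted to the 30-stimulus laser
#' projector brightness-matching experiment:
#' (alpha1, alpha2, alpha3, alpha4, gamma) =
#' (1.52, -0.013, 0.65, 0.11, 0.867).
#'
#' @param name Profile name.
#' @return An [hk_params()] object.
#' @export
hk_params_profile <- function(name = "zhu2023") {
  switch(name,
    zhu2023 = hk_params(1.52, -0.013, 0.65, 0.11, 0.867),
    abort(sprintf("unknown profile '%s' (available: zhu2023)", name))
  )
}

#' @export
print.hk_params <- function(x, ...) {
  cat(sprintf(
    "<hk_params> f1(J) = %.4g + %.4g J | f2(h) = %.4g + %.4g (1 - sin(h/2)) | gamma = %.4g\n",
    x$alpha1, x$alpha2, x$alpha3, x$alpha4, x$gamma))
  invisible(x)
}

#' Lightness factor f1(J) of the compensation term
#' @param J Lightness, >= 0.
#' @param params An [hk_params()] object.
#' @return alpha1 + alpha2 * J.
#' @export
hk_f1 <- function(J, params = hk_params_profile()) {
  if (any(J < 0)) abort("lightness must be >= 0")
  params$alpha1 + params$alpha2 * J
}

#' Hue factor f2(h) of the compensation term
#'
#' `sin(h/2)` is taken with h in degrees, giving a single minimum of f2 at
#' h = 180 degrees. This reading is isolated here so an alternative
#' convention is a one-line change.
#'
#' @param h Hue angle in degrees.
#' @param params An [hk_params()] object.
#' @return alpha3 + alpha4 * (1 - sin(h/2)).
#' @export
hk_f2 <- function(h, params = hk_params_profile()) {
  params$alpha3 + params$alpha4 * (1 - sin(h / 2 * pi / 180))
}

#' Helmholtz-Kohlrausch corrected lightness
#'
#' @param J CAM16 lightness.
#' @param C CAM16 chroma, >= 0.
#' @param h CAM16 hue angle in degrees.
#' @param params An [hk_params()] object.
#' @return Corrected lightness J_HK = J + f1(J) f2(h) C^gamma.
#' @export
hk_lightness <- function(J, C, h, params = hk_params_profile()) {
  if (any(C < 0)) abort("chroma must be >= 0")
  jhk <- J + hk_f1(J, params) * hk_f2(h, params) * C^params$gamma
  if (any(jhk < 0)) {
    abort("corrected lightness is negative: pathological parameter set")
  }
  jhk
}

#' Hellwig-form corrected lightness
#'
#' The generic additive chroma correction \eqn{J_{HK} = J + f_h(h)
#' C^{\gamma_H}} with a user-supplied hue-dependence function. No default
#' coefficients ship with the package: `f_h` and `gamma_H` must be given
#' (e.g. transcribed from a published Hellwig-model profile).
#'
#' @param J,C,h CAM16 lightness, chroma and hue angle (degrees).
#' @param f_h A function of the hue angle in degrees returning the hue
#'   weight, or a single number for a hue-independent weight.
#' @param gamma_H Chroma exponent.
#' @return Corrected lightness.
#' @export
hellwig_lightness <- function(J, C, h, f_h, gamma_H) {
  if (any(C < 0)) abort("chroma must be >= 0")
  if (missing(f_h) || missing(gamma_H)) {
    abort("hellwig_lightness needs explicit f_h and gamma_H (no defaults ship)")
  }
  w <- if (is.function(f_h)) f_h(h) else rep_len(f_h, length(J))
  J + w * C^gamma_H
}

#' Predict brightness of chromatic stimuli under a given model
#'
#' Runs the CAM16 forward model on each stimulus row and appends the
#' model's brightness prediction:
#' \describe{
#'   \item{`proposed`}{Helmholtz-Kohlrausch compensated CAM16: columns
#'     `J_HK` and `Q_HK`, plus `L_pred`, the luminance of the achromatic
#'     stimulus predicted to match (CAM16 brightness inverted at the white
#'     chromaticity).}
#'   \item{`cam16`}{plain CAM16 brightness: `Q` and its achromatic match
#'     `L_pred`.}
#'   \item{`hellwig`}{Hellwig-form correction (requires `f_h`, `gamma_H`):
#'     `J_HK`, `Q_HK`, `L_pred`.}
#'   \item{`vac`, `vcc`}{Nayatani equivalent luminance: column `L_eq` (and
#'     `L_pred = L_eq`).}
#' }
#'
#' @param data Data frame with stimulus columns `x`, `y`, `L` (cd/m2).
#' @param vc A [cam16_conditions()] object.
#' @param model Model name.
#' @param params An [hk_params()] object (proposed model).
#' @param f_h,gamma_H Hellwig-model hue weight and chroma exponent.
#' @param invert If `TRUE` (default) also compute `L_pred` for the
#'   CAM16-family models (a root-find per row).
#' @return `data` with appearance correlates and prediction columns
#'   appended.
#' @examples
#' vc <- cam16_conditions()
#' predict_brightness(hk_dataset("table2")[1:3, ], vc)
#' @export
predict_brightness <- function(data, vc, model = c("proposed", "cam16", "hellwig", "vac", "vcc"),
                               params = hk_params_profile(),
                               f_h = NULL, gamma_H = NULL, invert = TRUE) {
  model <- match.arg(model)
  if (nrow(data) == 0) abort("empty stimulus table")
  if (model %in% c("vac", "vcc")) {
    ctx <- nayatani_context(vc$white_x, vc$white_y, vc$La)
    out <- as_tibble(data)
    out$ratio <- nayatani_ratio(data$x, data$y, ctx,
                                method = toupper(model))
    out$L_eq <- out$ratio * data$L
    out$L_pred <- out$L_eq
    return(out)
  }
  app <- cam16_appearance(data, vc)
  if (model == "proposed") {
    app$J_HK <- hk_lightness(app$J, app$C, app$h, params)
    app$Q_HK <- cam16_brightness(app$J_HK, vc)
    q <- app$Q_HK
  } else if (model == "hellwig") {
    app$J_HK <- hellwig_lightness(app$J, app$C, app$h, f_h, gamma_H)
    app$Q_HK <- cam16_brightness(app$J_HK, vc)
    q <- app$Q_HK
  } else {
    q <- app$Q
  }
  if (invert) app$L_pred <- achromatic_luminance(q, vc)
  app
}
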
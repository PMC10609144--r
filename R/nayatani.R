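#' Nayatani model context
#'
#' The adopted white chromaticity and adapting luminance the Nayatani
#' equivalent-luminance model is evaluated under.
#'
#' @param white_x,white_y Chromaticity of the adopted white (default D65).
#' @param La Adapting luminance in cd/m2.
#' @return A list with `white_uv` (u'v' of the white) and `La`.
#' @export
nayatani_context <- function(white_x = 0.3127, white_y = 0.3290, La = 50) {
  if (La < 0) abort("adapting luminance must be >= 0")
  uv <- xy_to_uv(white_x, white_y)
  list(white_uv = c(up = uv$up, vp = uv$vp), La = La)
}

#' Hue-quadrature factor q(theta) of the Nayatani model
#'
#' The 9-term Fourier series describing how the Helmholtz-Kohlrausch effect
#' varies with the u'v' hue angle about the white point.
#'
#' @param theta Hue angle in radians.
#' @return Numeric vector, same length as `theta`.
#' @export
nayatani_q <- function(theta) {
  -0.01585 -
    0.03017 * cos(theta) - 0.04556 * cos(2 * theta) -
    0.02667 * cos(3 * theta) - 0.00295 * cos(4 * theta) +
    0.14592 * sin(theta) + 0.05084 * sin(2 * theta) -
    0.01900 * sin(3 * theta) - 0.00764 * sin(4 * theta)
}

#' Adapting-luminance factor K_Br of the Nayatani model
#'
#' Strictly increasing in the adapting luminance; equals 1 near
#' La = 63.66 cd/m2 and saturates at 0.2717 x 6.362 for very bright
#' adaptation.
#'
#' @param La Adapting luminance in cd/m2, >= 0.
#' @return Numeric vector, same length as `La`.
#' @export
nayatani_kbr <- function(La) {
  if (any(La < 0)) abort("adapting luminance must be >= 0")
  0.2717 * (6.469 + 6.362 * La^0.4495) / (6.469 + La^0.4495)
}

#' Nayatani chromatic saturation s_uv
#'
#' \eqn{13 \sqrt{(u' - u'_w)^2 + (v' - v'_w)^2}}: 13 times the Euclidean
#' distance from the white point in the u'v' diagram.
#'
#' @param x,y Stimulus chromaticity (CIE 1931).
#' @param ctx A [nayatani_context()].
#' @return Saturation, >= 0; zero iff the stimulus sits at the white point.
#' @export
nayatani_suv <- function(x, y, ctx) {
  uv <- xy_to_uv(x, y)
  13 * sqrt((uv$up - ctx$white_uv[["up"]])^2 + (uv$vp - ctx$white_uv[["vp"]])^2)
}

#' Nayatani equivalent-luminance ratio (VAC / VCC)
#'
#' Ratio of the equivalent achromatic luminance to the photometric
#' luminance, \eqn{L_{eq}/L}. The variable-achromatic-color (VAC) method
#' (the achromatic side is adjusted during matching) uses hue coefficient
#' -0.1340, the variable-chromatic-color (VCC) method -0.8660:
#' \deqn{L_{eq}/L = 0.4462 [1 + (q_{coef} q(\theta) + 0.0872 K_{Br})
#'   s_{uv} + 0.3086]^3}
#' For an achromatic stimulus (s_uv = 0) the ratio is 1 to within the
#' rounding of the published coefficients.
#'
#' @param x,y Stimulus chromaticity.
#' @param ctx A [nayatani_context()].
#' @param method `"VAC"` (default) or `"VCC"`.
#' @return The ratio L_eq / L (dimensionless, positive).
#' @examples
#' ctx <- nayatani_context()
#' nayatani_ratio(0.7077, 0.2834, ctx) # deep red: well above 1
#' @export
nayatani_ratio <- function(x, y, ctx, method = c("VAC", "VCC")) {
  method <- match.arg(method)
  coef <- if (method == "VAC") -0.1340 else -0.8660
  uv <- xy_to_uv(x, y)
  du <- uv$up - ctx$white_uv[["up"]]
  dv <- uv$vp - ctx$white_uv[["vp"]]
  theta <- atan2(dv, du)
  suv <- 13 * sqrt(du^2 + dv^2)
  kbr <- nayatani_kbr(ctx$La)
  0.4462 * (1 + (coef * nayatani_q(theta) + 0.0872 * kbr) * suv + 0.3086)^3
}
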
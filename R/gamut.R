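#' Display primary sets packaged with hkbright
#'
#' Chromaticity coordinates of the red, green and blue primaries of the
#' trichromatic laser projector used for the brightness-matching experiment,
#' the BT.2020 (Rec. 2020) UHD standard, and the 8K laser TV prototype.
#'
#' @param name One of `"laser"`, `"bt2020"`, `"8ktv"`.
#' @return A tibble with columns `name`, `x`, `y` (three rows: red, green,
#'   blue).
#' @examples
#' display_primaries("bt2020")
#' @export
display_primaries <- function(name = c("laser", "bt2020", "8ktv")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("primaries_", name, ".csv"),
                      package = "hkbright", mustWork = TRUE)
  read_primaries(path)
}

#' Read a primary set from a 3-row CSV (name, x, y)
#'
#' @param path Path to a CSV file with columns `name`, `x`, `y`.
#' @return A tibble with columns `name`, `x`, `y`.
#' @export
read_primaries <- function(path) {
  p <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  check_primaries(p)
  p
}

check_primaries <- function(p) {
  if (!all(c("x", "y") %in% names(p)) || nrow(p) != 3) {
    abort("a primary set needs columns x, y and exactly 3 rows")
  }
  if (any(p$x < 0 | p$y <= 0 | p$x + p$y > 1)) {
    abort("primaries must satisfy x >= 0, y > 0, x + y <= 1")
  }
  invisible(p)
}

# shoelace area of a polygon given coordinate vectors
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Area of a primary triangle in the xy chromaticity diagram
#'
#' Shoelace formula on the three primary chromaticities.
#'
#' @param primaries Data frame with columns `x`, `y` (3 rows), e.g. from
#'   [display_primaries()].
#' @return Area in xy-diagram units.
#' @examples
#' triangle_area(display_primaries("laser"))
#' @export
triangle_area <- function(primaries) {
  check_primaries(primaries)
  a <- polygon_area(primaries$x, primaries$y)
  if (a <= 1e-12) abort("primaries are collinear: zero-area gamut")
  a
}

#' Area of the visible gamut in the xy chromaticity diagram
#'
#' Shoelace area of the polygon bounded by the spectral locus (sampled from
#' the embedded CIE 1931 2-degree observer table, see [spectral_locus()])
#' and the straight purple line. This is the denominator of
#' [gamut_coverage()].
#'
#' @param step Locus sampling step in nm.
#' @return Area in xy-diagram units (about 0.3325 under the package's
#'   locus convention).
#' @export
visible_gamut_area <- function(step = 1) {
  key <- paste0("vga_", step)
  if (is.null(.hk_cache[[key]])) {
    locus <- spectral_locus(step)
    .hk_cache[[key]] <- polygon_area(locus$x, locus$y)
  }
  .hk_cache[[key]]
}

#' Gamut coverage of the visible chromaticity diagram
#'
#' Percentage of the visible-gamut polygon area covered by a display's
#' primary triangle, computed in CIE 1931 xy.
#'
#' @inheritParams triangle_area
#' @param step Locus sampling step passed to [visible_gamut_area()].
#' @return Coverage in percent.
#' @examples
#' gamut_coverage(display_primaries("laser")) # about 67.9
#' @export
gamut_coverage <- function(primaries, step = 1) {
  100 * triangle_area(primaries) / visible_gamut_area(step)
}

# Sutherland-Hodgman clipping of a convex subject polygon by a convex clip
# polygon; both as lists of coordinate vectors. Clip vertices must be in a
# consistent winding; we normalize to counter-clockwise.
ccw <- function(p) {
  n <- length(p$x)
  j <- c(n, seq_len(n - 1))
  if (sum(p$x[j] * p$y - p$x * p$y[j]) < 0) list(x = rev(p$x), y = rev(p$y)) else p
}

clip_convex <- function(subject, clip) {
  subject <- ccw(subject)
  clip <- ccw(clip)
  out <- subject
  nc <- length(clip$x)
  for (i in seq_len(nc)) {
    if (length(out$x) == 0) break
    ax <- clip$x[i]; ay <- clip$y[i]
    bx <- clip$x[i %% nc + 1]; by <- clip$y[i %% nc + 1]
    # signed distance to the directed edge a->b (positive = inside for CCW)
    side <- function(px, py) (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    nx <- numeric(0); ny <- numeric(0)
    np <- length(out$x)
    for (j in seq_len(np)) {
      cx <- out$x[j]; cy <- out$y[j]
      dxp <- out$x[j %% np + 1]; dyp <- out$y[j %% np + 1]
      sc <- side(cx, cy); sd <- side(dxp, dyp)
      if (sc >= 0) { nx <- c(nx, cx); ny <- c(ny, cy) }
      if ((sc > 0 && sd < 0) || (sc < 0 && sd > 0)) {
        t <- sc / (sc - sd)
        nx <- c(nx, cx + t * (dxp - cx))
        ny <- c(ny, cy + t * (dyp - cy))
      }
    }
    out <- list(x = nx, y = ny)
  }
  out
}

#' Coverage of one primary triangle by another
#'
#' Percentage of triangle `b`'s area covered by triangle `a`, via convex
#' polygon intersection (iterative half-plane clipping) in CIE 1931 xy.
#'
#' @param a,b Primary sets (data frames with columns `x`, `y`, 3 rows each).
#' @return Percent of `b`'s area inside `a`.
#' @examples
#' gamut_overlap(display_primaries("laser"), display_primaries("bt2020"))
#' @export
gamut_overlap <- function(a, b) {
  area_b <- triangle_area(b)
  area_a <- triangle_area(a) # validates a
  inter <- clip_convex(list(x = a$x, y = a$y), list(x = b$x, y = b$y))
  ai <- if (length(inter$x) < 3) 0 else polygon_area(inter$x, inter$y)
  100 * min(ai, min(area_a, area_b)) / area_b
}
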
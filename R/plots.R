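#' Plot primary triangles on the chromaticity diagram
#'
#' Draws the spectral-locus horseshoe (closed by the purple line) and one
#' or more display primary triangles in CIE 1931 xy.
#'
#' @param ... Named primary sets (data frames with columns `x`, `y`), e.g.
#'   `plot_gamut(laser = display_primaries("laser"))`.
#' @param locus_step Locus sampling step in nm.
#' @return A ggplot object.
#' @examples
#' plot_gamut(laser = display_primaries("laser"),
#'            bt2020 = display_primaries("bt2020"))
#' @export
plot_gamut <- function(..., locus_step = 1) {
  sets <- list(...)
  if (length(sets) && is.null(names(sets))) {
    names(sets) <- paste0("gamut", seq_along(sets))
  }
  locus <- spectral_locus(locus_step)
  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = locus, ggplot2::aes(x = .data$x, y = .data$y),
      fill = "grey92", color = "grey40", linewidth = 0.3) +
    ggplot2::coord_equal(xlim = c(0, 0.8), ylim = c(0, 0.9)) +
    ggplot2::labs(x = "x", y = "y") +
    ggplot2::theme_minimal()
  if (length(sets)) {
    tri <- dplyr::bind_rows(
      purrr::imap(sets, function(s, nm) tibble(set = nm, x = s$x, y = s$y)))
    p <- p +
      ggplot2::geom_polygon(
        data = tri,
        ggplot2::aes(x = .data$x, y = .data$y, color = .data$set),
        fill = NA, linewidth = 0.6) +
      ggplot2::labs(color = NULL)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter of reference vs predicted brightness for a model evaluation
#'
#' Each point is one chromatic stimulus: the observed (reference) value
#' against the model's f-rescaled prediction; the identity line is the
#' ideal model. Points below the line mean the model under-predicts the
#' Helmholtz-Kohlrausch lift for that stimulus.
#'
#' @param object An [evaluate_brightness_model()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hk_eval <- function(object, ...) {
  d <- object$stimuli
  d$pred_scaled <- object$f * d$pred
  lim <- range(c(d$ref, d$pred_scaled))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ref, y = .data$pred_scaled)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey40") +
    ggplot2::geom_point(color = "#2166ac", size = 2) +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    ggplot2::labs(
      x = "observed (reference)",
      y = "model prediction (rescaled)",
      title = sprintf("model '%s', mode '%s': CV = %.1f%%",
                      object$model, object$mode, object$cv)) +
    ggplot2::theme_minimal()
}
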
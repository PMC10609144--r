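#' Least-squares scale factor between two brightness series
#'
#' The factor f that brings a prediction series onto the scale of a
#' reference series in the least-squares sense,
#' \eqn{f = \sum_i r_i p_i / \sum_i p_i^2}.
#'
#' @param ref Reference series.
#' @param pred Prediction series, same length.
#' @return The scalar f.
#' @examples
#' scale_factor(c(1, 2), c(2, 4)) # 0.5
#' @export
scale_factor <- function(ref, pred) {
  if (length(ref) != length(pred) || length(ref) < 1) {
    abort("ref and pred must have equal length >= 1")
  }
  sp2 <- sum(pred^2)
  if (sp2 <= 0) abort("prediction series is all zero")
  sum(ref * pred) / sp2
}

#' Coefficient of variation between two brightness series
#'
#' The scale-adjusted RMS disagreement used throughout brightness-matching
#' psychophysics:
#' \deqn{CV = 100 \sqrt{\frac{1}{n}\sum_i (r_i - f p_i)^2 / \bar r^2}}
#' where f is the least-squares [scale_factor()] and \eqn{\bar r} the
#' arithmetic mean of the reference. CV = 0 means perfect agreement after a
#' global rescaling; the statistic is invariant to the overall scale of
#' `pred` and equivariant under joint rescaling of both series.
#'
#' @inheritParams scale_factor
#' @return An object of class `cv_result`: list with `cv` (percent), `f`
#'   and `n`.
#' @examples
#' agreement_cv(c(100, 120, 150), c(50, 60, 75))$cv # 0: proportional
#' @export
agreement_cv <- function(ref, pred) {
  f <- scale_factor(ref, pred)
  mr <- mean(ref)
  if (mr <= 0) abort("reference series must have positive mean")
  cv <- 100 * sqrt(mean((ref - f * pred)^2) / mr^2)
  structure(list(cv = cv, f = f, n = length(ref)), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> CV = %.2f%% (f = %.4g, n = %d)\n", x$cv, x$f, x$n))
  invisible(x)
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble(cv = x$cv, f = x$f, n = x$n)
}

#' Evaluate a brightness model against matching data
#'
#' Scores a model's brightness predictions for the chromatic stimuli
#' against the achromatic stimuli the observers matched to them, with the
#' [agreement_cv()] statistic. Three comparison conventions are available:
#' \describe{
#'   \item{`matched_luminance` (default)}{the prediction is the luminance
#'     of the achromatic stimulus the model itself predicts to match (model
#'     brightness inverted at the white chromaticity; for the Nayatani
#'     models this is the equivalent luminance directly), and the reference
#'     is the observed matched luminance. Both series are in cd/m2, the
#'     units the experiment records, commensurate with the interobserver
#'     CV.}
#'   \item{`appearance`}{the prediction is the model's brightness of the
#'     chromatic stimulus and the reference is the base-model (CAM16)
#'     brightness of the achromatic stimulus at the observed matched
#'     luminance; for VAC/VCC the comparison is L_eq against the matched
#'     luminance.}
#'   \item{`luminance`}{the prediction is the model's raw brightness value
#'     and the reference the observed matched luminance, relying on the
#'     f-rescaling to reconcile the units.}
#' }
#'
#' @param data Stimulus table with columns `x`, `y`, `L`, `matched_L` (e.g.
#'   [hk_dataset()]`("table2")` or [simulate_matching_experiment()]
#'   records).
#' @param vc A [cam16_conditions()] object.
#' @param model,params,f_h,gamma_H Passed to [predict_brightness()].
#' @param mode Comparison convention (above).
#' @return A `cv_result` with the per-stimulus table attached as
#'   `$stimuli` (columns `ref` and `pred` alongside the predictions).
#' @examples
#' vc <- cam16_conditions()
#' evaluate_brightness_model(hk_dataset("table2"), vc)
#' @export
evaluate_brightness_model <- function(data, vc,
                                      model = c("proposed", "cam16", "hellwig", "vac", "vcc"),
                                      mode = c("matched_luminance", "appearance", "luminance"),
                                      params = hk_params_profile(),
                                      f_h = NULL, gamma_H = NULL) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  if (is.list(data) && !is.data.frame(data) && !is.null(data$records)) {
    data <- data$records
  }
  check_stimuli(data)
  if (nrow(data) == 0) abort("empty dataset")
  nayatani <- model %in% c("vac", "vcc")
  pred_tab <- predict_brightness(data, vc, model, params, f_h, gamma_H,
                                 invert = (mode == "matched_luminance") && !nayatani)
  if (mode == "matched_luminance") {
    ref <- data$matched_L
    pred <- pred_tab$L_pred
  } else if (mode == "appearance") {
    if (nayatani) {
      ref <- data$matched_L
      pred <- pred_tab$L_eq
    } else {
      ref <- cam16_appearance(
        data.frame(x = vc$white_x, y = vc$white_y, L = data$matched_L), vc)$Q
      pred <- if (model == "cam16") pred_tab$Q else pred_tab$Q_HK
    }
  } else {
    ref <- data$matched_L
    pred <- if (nayatani) pred_tab$L_eq
            else if (model == "cam16") pred_tab$Q else pred_tab$Q_HK
  }
  out <- agreement_cv(ref, pred)
  pred_tab$ref <- ref
  pred_tab$pred <- pred
  out$stimuli <- pred_tab
  out$model <- model
  out$mode <- mode
  class(out) <- c("hk_eval", class(out))
  out
}

#' @export
print.hk_eval <- function(x, ...) {
  cat(sprintf("<hk_eval> model '%s', mode '%s': CV = %.2f%% (f = %.4g, n = %d)\n",
              x$model, x$mode, x$cv, x$f, x$n))
  invisible(x)
}

#' @export
tidy.hk_eval <- function(x, ...) {
  x$stimuli
}

#' @export
glance.hk_eval <- function(x, ...) {
  tibble(model = x$model, mode = x$mode, cv = x$cv, f = x$f, n = x$n)
}

#' Per-observer interobserver agreement
#'
#' Computes the per-observer CV of a matching dataset with individual
#' observer matches: for each observer, the reference series is the
#' geometric mean of all observers' matched luminances per stimulus and
#' the prediction series is that observer's matches ([agreement_cv()], so
#' an observer who is uniformly scaled relative to the panel still scores
#' CV = 0).
#'
#' @param data A matching dataset with a `per_observer` matrix (observers
#'   in rows, stimuli in columns), e.g. from
#'   [simulate_matching_experiment()].
#' @return A tibble with columns `observer` and `cv`, plus attribute
#'   `mean_cv`.
#' @export
interobserver_cv <- function(data) {
  m <- data$per_observer
  if (is.null(m)) abort("dataset has no per-observer matches")
  geo <- exp(colMeans(log(m)))
  cvs <- vapply(seq_len(nrow(m)), function(i) agreement_cv(geo, m[i, ])$cv,
                numeric(1))
  out <- tibble(observer = seq_len(nrow(m)), cv = cvs)
  attr(out, "mean_cv") <- mean(cvs)
  out
}
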
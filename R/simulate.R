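#' Simulate a brightness-matching experiment
#'
#' Generates per-observer achromatic matches for a set of chromatic
#' stimuli, emulating the protocol in which each observer adjusts the
#' luminance of an achromatic half-field until it looks as bright as the
#' chromatic one. The noise-free match for a stimulus is the luminance at
#' which the achromatic stimulus has the same model brightness as the
#' chromatic stimulus (the generating model's equivalent achromatic
#' luminance). Each observer's match multiplies it by an independent
#' lognormal factor with median 1 and coefficient of variation `noise_cv`
#' (matching errors scale with magnitude, Weber-like), and the reported
#' `matched_L` is the geometric mean across observers, so the noise-free
#' match is the central tendency.
#'
#' @param stimuli Data frame with columns `x`, `y`, `L` (cd/m2); an `id`
#'   column is kept if present.
#' @param vc A [cam16_conditions()] object.
#' @param model,params,f_h,gamma_H Generating model, as in
#'   [predict_brightness()].
#' @param n_observers Number of simulated observers (>= 1).
#' @param noise_cv Interobserver coefficient of variation of the
#'   multiplicative matching error, as a fraction (default 0.16, the level
#'   seen in the 16-observer laser-projector experiment).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return An object of class `matching_dataset`: list with `records` (a
#'   stimulus tibble with `matched_L`) and `per_observer` (an
#'   `n_observers` x `n_stimuli` matrix of individual matches).
#' @examples
#' vc <- cam16_conditions()
#' sim <- simulate_matching_experiment(hk_dataset("table2")[1:5, ], vc,
#'                                     n_observers = 4, seed = 42)
#' sim$records
#' @export
simulate_matching_experiment <- function(stimuli, vc,
                                         model = "proposed",
                                         params = hk_params_profile(),
                                         f_h = NULL, gamma_H = NULL,
                                         n_observers = 16, noise_cv = 0.16,
                                         seed = 1) {
  check_stimuli(stimuli, need_match = FALSE)
  if (n_observers < 1) abort("need at least one observer")
  if (noise_cv < 0) abort("noise_cv must be >= 0")

  pred <- tryCatch(
    predict_brightness(stimuli, vc, model, params, f_h, gamma_H, invert = TRUE),
    error = function(e) {
      abort(paste("could not invert the model brightness for these stimuli:",
                  conditionMessage(e)))
    }
  )
  true_L <- pred$L_pred
  n_stim <- length(true_L)

  sdlog <- sqrt(log(1 + noise_cv^2))
  eps <- with_seed(seed, {
    matrix(stats::rlnorm(n_observers * n_stim, meanlog = 0, sdlog = sdlog),
           nrow = n_observers)
  })
  per_obs <- sweep(eps, 2, true_L, `*`)
  matched <- exp(colMeans(log(per_obs)))

  records <- as_tibble(stimuli[, intersect(c("id", "L", "x", "y"), names(stimuli))])
  if (!"id" %in% names(records)) records$id <- seq_len(n_stim)
  records$matched_L <- matched
  colnames(per_obs) <- records$id

  structure(
    list(records = records, per_observer = per_obs,
         noise_cv = noise_cv, model = model, seed = seed),
    class = "matching_dataset"
  )
}

#' @export
print.matching_dataset <- function(x, ...) {
  cat(sprintf(
    "<matching_dataset> %d stimuli x %d observers (model '%s', noise CV %.3g, seed %d)\n",
    ncol(x$per_observer), nrow(x$per_observer), x$model, x$noise_cv, x$seed))
  print(x$records)
  invisible(x)
}
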
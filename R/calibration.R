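#' Construct a count-to-energy-expenditure calibration model
#'
#' An `ee_calibration` object maps accelerometer output (counts/min) and body
#' mass (kg) to energy expenditure (kcal/min) through the linear model
#' \deqn{EE = \beta_c \cdot counts + \beta_m \cdot mass + \beta_0.}
#' Use [fit_calibration()] to estimate one from data; use this constructor to
#' hold a published or otherwise externally supplied set of coefficients.
#'
#' @param count_coef kcal/min per (counts/min).
#' @param mass_coef kcal/min per kg.
#' @param intercept kcal/min.
#' @param r_squared,see,n_obs optional fit diagnostics (coefficient of
#'   determination, standard error of estimation in kcal/min, number of
#'   observations used in the fit).
#' @return an object of class `ee_calibration`.
#' @seealso [published_calibration()] for the validated smartphone equation.
#' @export
calibration_model <- function(count_coef, mass_coef, intercept,
                              r_squared = NA_real_, see = NA_real_,
                              n_obs = NA_integer_) {
  stopifnot(is.numeric(count_coef), is.numeric(mass_coef), is.numeric(intercept))
  if (!is.na(see) && see < 0) stop_invalid("'see' must be non-negative")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop_invalid("'r_squared' must lie in [0, 1]")
  structure(
    list(count_coef = as.numeric(count_coef),
         mass_coef = as.numeric(mass_coef),
         intercept = as.numeric(intercept),
         r_squared = as.numeric(r_squared),
         see = as.numeric(see),
         n_obs = as.integer(n_obs),
         fit = NULL),
    class = "ee_calibration")
}

#' Published smartphone count-to-EE calibration equation
#'
#' The validated two-predictor equation relating smartphone activity counts
#' and body mass to energy expenditure:
#' `EE (kcal/min) = 0.00063 * counts/min + 0.121 * mass_kg - 5.66`
#' (fit diagnostics r^2 = 0.83, SEE = 1.94 kcal/min, n = 21 participants).
#'
#' @return an `ee_calibration` object.
#' @export
published_calibration <- function() {
  calibration_model(0.00063, 0.121, -5.66,
                    r_squared = 0.83, see = 1.94, n_obs = 21L)
}

#' Fit a count-to-EE calibration model by ordinary least squares
#'
#' Regresses measured energy expenditure on activity counts and body mass.
#' This is the standard accelerometer calibration design: per-bout (or
#' per-minute) steady-state means of counts and criterion EE, pooled across
#' participants, with mass as the anthropometric covariate.
#'
#' @param obs data frame with numeric columns `counts_per_min`, `mass_kg`,
#'   `ee_kcal_min`.
#' @return an `ee_calibration` object. `see` is
#'   `sqrt(SS_resid / (n - 3))`; `r_squared` the coefficient of
#'   determination. The underlying [stats::lm] fit is kept in `$fit`.
#' @examples
#' d <- generate_calibration_dataset(200, published_calibration(),
#'                                   residual_sd = 1.94, seed = 1)
#' fit <- fit_calibration(d)
#' coef(fit)
#' @export
fit_calibration <- function(obs) {
  req <- c("counts_per_min", "mass_kg", "ee_kcal_min")
  if (!all(req %in% names(obs)))
    stop_invalid("'obs' must have columns ", paste(req, collapse = ", "))
  obs <- as.data.frame(obs)[req]
  if (nrow(obs) < 4L)
    stop_invalid("need at least 4 observations to fit 3 parameters (got ",
                 nrow(obs), ")")
  for (v in c("counts_per_min", "mass_kg")) {
    if (stats::var(obs[[v]]) == 0)
      stop_invalid("degenerate design: predictor '", v, "' is constant")
  }
  fit <- stats::lm(ee_kcal_min ~ counts_per_min + mass_kg, data = obs)
  if (any(is.na(stats::coef(fit))))
    stop_invalid("degenerate design: predictors are collinear")
  cf <- stats::coef(fit)
  n <- nrow(obs)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((obs$ee_kcal_min - mean(obs$ee_kcal_min))^2)
  out <- calibration_model(
    count_coef = cf[["counts_per_min"]],
    mass_coef = cf[["mass_kg"]],
    intercept = cf[["(Intercept)"]],
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    see = sqrt(rss / (n - 3L)),
    n_obs = n)
  out$fit <- fit
  out
}

#' Predict energy expenditure from activity counts
#'
#' @param model an `ee_calibration` object.
#' @param counts_per_min non-negative activity counts per minute (vectorised).
#' @param mass_kg body mass in kg (> 0; recycled against counts).
#' @return predicted EE in kcal/min. Predictions can be negative when
#'   extrapolating below the calibration range (e.g. low counts and low body
#'   mass); they are returned unmodified.
#' @export
predict_ee <- function(model, counts_per_min, mass_kg) {
  stopifnot(inherits(model, "ee_calibration"))
  if (any(counts_per_min < 0, na.rm = TRUE))
    stop_invalid("'counts_per_min' must be non-negative")
  if (any(mass_kg <= 0, na.rm = TRUE))
    stop_invalid("'mass_kg' must be positive")
  model$count_coef * counts_per_min + model$mass_coef * mass_kg + model$intercept
}

#' MET / kcal-per-minute conversion
#'
#' Converts between metabolic equivalents and absolute energy expenditure.
#' The default convention is the compendium definition
#' 1 MET = 1 kcal per kg body mass per hour. The alternative `"vo2"`
#' convention uses 1 MET = 3.5 mL O2/kg/min with 5 kcal per litre O2
#' (kcal/min = MET x mass x 0.0175).
#'
#' @param met,ee_kcal_min value to convert (vectorised).
#' @param mass_kg body mass in kg (> 0).
#' @param convention `"kcal_kg_hr"` (default) or `"vo2"`.
#' @return the converted value; the two functions are mutual inverses.
#' @export
met_to_kcal <- function(met, mass_kg, convention = c("kcal_kg_hr", "vo2")) {
  convention <- match.arg(convention)
  if (any(mass_kg <= 0)) stop_invalid("'mass_kg' must be positive")
  switch(convention,
         kcal_kg_hr = met * mass_kg / 60,
         vo2 = met * mass_kg * 3.5 * 5 / 1000)
}

#' @rdname met_to_kcal
#' @export
kcal_to_met <- function(ee_kcal_min, mass_kg, convention = c("kcal_kg_hr", "vo2")) {
  convention <- match.arg(convention)
  if (any(mass_kg <= 0)) stop_invalid("'mass_kg' must be positive")
  switch(convention,
         kcal_kg_hr = ee_kcal_min * 60 / mass_kg,
         vo2 = ee_kcal_min / (mass_kg * 3.5 * 5 / 1000))
}

#' Intensity classification cut-points in counts/min
#'
#' Holds the ordered lower edges of the moderate, hard, and very-hard bands.
#' Counts strictly below the first boundary are light. Boundaries are
#' interpreted with inclusive lower bounds: a count exactly at a boundary
#' falls in the higher category.
#'
#' @param boundaries strictly increasing numeric vector of band lower edges
#'   (counts/min), one fewer than `labels`.
#' @param labels category labels, lowest intensity first.
#' @param met_boundaries optional MET values the boundaries correspond to.
#' @return an object of class `intensity_thresholds`.
#' @seealso [published_thresholds()], [derive_thresholds()],
#'   [classify_intensity()]
#' @export
intensity_thresholds <- function(boundaries,
                                 labels = c("light", "moderate", "hard", "very hard"),
                                 met_boundaries = NULL) {
  boundaries <- as.numeric(boundaries)
  if (length(labels) != length(boundaries) + 1L)
    stop_invalid("need exactly one more label than boundary")
  if (any(diff(boundaries) <= 0))
    stop_invalid("'boundaries' must be strictly increasing")
  structure(list(boundaries = boundaries, labels = as.character(labels),
                 met_boundaries = met_boundaries),
            class = "intensity_thresholds")
}

#' Published smartphone intensity cut-points
#'
#' The frozen cut-point table used by default for classification:
#' light < 1253, moderate 1253-1272, hard 1273-6987, very hard > 6987
#' counts/min, anchored at the 3/6/9 MET intensity boundaries. These
#' published bands are treated as authoritative; they are *not* exactly
#' reproducible by inverting the published calibration equation (see
#' [derive_thresholds()] and the package vignette), which is why they are
#' shipped as a constant rather than derived at run time.
#'
#' @return an `intensity_thresholds` object.
#' @export
published_thresholds <- function() {
  intensity_thresholds(c(1253, 1273, 6988), met_boundaries = c(3, 6, 9))
}

#' Derive intensity cut-points by inverting a calibration model
#'
#' For each MET boundary m, the target EE is `met_to_kcal(m, ref_mass_kg)`
#' and the corresponding counts/min threshold solves the calibration
#' equation: `(target_ee - mass_coef * ref_mass - intercept) / count_coef`.
#' Negative solutions are clamped to zero with a warning.
#'
#' @param model an `ee_calibration` with `count_coef > 0`.
#' @param met_boundaries strictly increasing MET boundary values.
#' @param ref_mass_kg reference body mass; defaults to 70.5 kg, the
#'   calibration sample mean.
#' @param convention MET convention passed to [met_to_kcal()].
#' @return an `intensity_thresholds` object.
#' @export
derive_thresholds <- function(model, met_boundaries = c(3, 6, 9),
                              ref_mass_kg = 70.5,
                              convention = c("kcal_kg_hr", "vo2")) {
  stopifnot(inherits(model, "ee_calibration"))
  convention <- match.arg(convention)
  if (any(diff(met_boundaries) <= 0))
    stop_invalid("'met_boundaries' must be strictly increasing")
  if (!is.finite(model$count_coef) || model$count_coef <= 0)
    stop_invalid("invalid model: 'count_coef' must be positive to invert ",
                 "EE into counts")
  target_ee <- met_to_kcal(met_boundaries, ref_mass_kg, convention)
  thr <- (target_ee - model$mass_coef * ref_mass_kg - model$intercept) /
    model$count_coef
  if (any(thr < 0)) {
    warning("negative count threshold(s) clamped to 0", call. = FALSE)
    thr <- pmax(thr, 0)
  }
  labs <- if (length(met_boundaries) == 3L) {
    c("light", "moderate", "hard", "very hard")
  } else {
    c(sprintf("<%g MET", met_boundaries[1L]),
      sprintf(">=%g MET", met_boundaries))
  }
  intensity_thresholds(thr, labels = labs, met_boundaries = met_boundaries)
}

#' Scale correction between smartphone and reference activity counts
#'
#' Smartphone-derived counts sit on a smaller scale than the reference
#' accelerometer's; multiplying by the congruence factor (default 2121)
#' places both on a comparable scale. Set `factor = 1/scale_correction_factor()`
#' to apply the correction in the opposite direction if the source scales are
#' reversed.
#'
#' @param counts numeric counts (any epoch length).
#' @param factor positive scale factor; default [scale_correction_factor()].
#' @return corrected counts.
#' @export
apply_scale_correction <- function(counts, factor = scale_correction_factor()) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop_invalid("'factor' must be a single positive number")
  counts * factor
}

#' @rdname apply_scale_correction
#' @export
scale_correction_factor <- function() 2121

#' Cross-validate a calibration model on an independent sample
#'
#' Applies a fitted (or published) model to held-out observations without
#' re-estimating anything. Because no parameters are fit on `obs`, the
#' standard error of estimation is the plain root-mean-square residual, and
#' `r_squared` is the squared Pearson correlation between observed and
#' predicted EE.
#'
#' @param model an `ee_calibration` object.
#' @param obs independent data frame with columns `counts_per_min`,
#'   `mass_kg`, `ee_kcal_min`.
#' @return list with `see` (kcal/min), `r_squared` (NA with a warning when
#'   observed EE is constant), and `n`.
#' @export
cross_validate <- function(model, obs) {
  stopifnot(inherits(model, "ee_calibration"))
  req <- c("counts_per_min", "mass_kg", "ee_kcal_min")
  if (!all(req %in% names(obs)))
    stop_invalid("'obs' must have columns ", paste(req, collapse = ", "))
  if (nrow(obs) == 0L) stop_invalid("'obs' is empty")
  pred <- predict_ee(model, obs$counts_per_min, obs$mass_kg)
  resid <- obs$ee_kcal_min - pred
  r2 <- NA_real_
  if (nrow(obs) >= 2L && stats::var(obs$ee_kcal_min) > 0 && stats::var(pred) > 0) {
    r2 <- stats::cor(obs$ee_kcal_min, pred)^2
  } else {
    warning("r_squared undefined (constant observed or predicted EE)",
            call. = FALSE)
  }
  list(see = sqrt(mean(resid^2)), r_squared = r2, n = nrow(obs))
}

# ---- S3 methods for ee_calibration --------------------------------------

#' @export
print.ee_calibration <- function(x, ...) {
  cat("Count-to-EE calibration model\n")
  cat(sprintf("  EE (kcal/min) = %.5g x counts/min + %.4g x mass_kg + %.4g\n",
              x$count_coef, x$mass_coef, x$intercept))
  if (!is.na(x$r_squared) || !is.na(x$see))
    cat(sprintf("  r^2 = %.3f, SEE = %.3f kcal/min, n = %s\n",
                x$r_squared, x$see,
                ifelse(is.na(x$n_obs), "?", x$n_obs)))
  invisible(x)
}

#' @export
coef.ee_calibration <- function(object, ...) {
  c(intercept = object$intercept,
    count_coef = object$count_coef,
    mass_coef = object$mass_coef)
}

#' @export
summary.ee_calibration <- function(object, ...) {
  out <- list(coefficients = coef(object),
              r_squared = object$r_squared,
              see = object$see,
              n_obs = object$n_obs,
              lm_summary = if (!is.null(object$fit)) summary(object$fit))
  class(out) <- "summary.ee_calibration"
  out
}

#' @export
print.summary.ee_calibration <- function(x, ...) {
  cat("Count-to-EE calibration model\n\nCoefficients:\n")
  print(x$coefficients)
  cat(sprintf("\nr^2 = %.4f, SEE = %.4f kcal/min, n = %s\n",
              x$r_squared, x$see, ifelse(is.na(x$n_obs), "?", x$n_obs)))
  if (!is.null(x$lm_summary)) {
    cat("\nCoefficient table (OLS):\n")
    stats::printCoefmat(x$lm_summary$coefficients)
  }
  invisible(x)
}

#' @export
predict.ee_calibration <- function(object, newdata, ...) {
  predict_ee(object, newdata$counts_per_min, newdata$mass_kg)
}

#' @export
residuals.ee_calibration <- function(object, ...) {
  if (is.null(object$fit))
    stop_invalid("model was not fitted from data; no residuals available")
  stats::residuals(object$fit)
}

#' @export
fitted.ee_calibration <- function(object, ...) {
  if (is.null(object$fit))
    stop_invalid("model was not fitted from data; no fitted values available")
  stats::fitted(object$fit)
}

#' Simulate calibration observations from a model
#'
#' Draws `nsim` replicate calibration datasets from the model treated as the
#' data-generating truth, with additive Gaussian residual noise at the
#' model's SEE (or `sd`).
#'
#' @param object an `ee_calibration` object.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param n rows per dataset.
#' @param sd residual SD; defaults to the model SEE (0 if unknown).
#' @param ... unused.
#' @return list of data frames as from [generate_calibration_dataset()].
#' @export
simulate.ee_calibration <- function(object, nsim = 1, seed = NULL, n = 100,
                                    sd = NULL, ...) {
  sd <- sd %||% (if (is.na(object$see)) 0 else object$see)
  seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  lapply(seq_len(nsim), function(i) {
    generate_calibration_dataset(n, object, residual_sd = sd,
                                 seed = seed + i - 1L)
  })
}

#' @export
plot.ee_calibration <- function(x, ...) {
  if (is.null(x$fit))
    stop_invalid("model was not fitted from data; nothing to plot")
  obs <- stats::model.frame(x$fit)
  graphics::plot(stats::fitted(x$fit), obs[[1L]],
                 xlab = "Predicted EE (kcal/min)",
                 ylab = "Measured EE (kcal/min)",
                 main = "Calibration model fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
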
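#' The five classical release-kinetics models
#'
#' @return Character vector of model names understood by
#'   [linearize_release()] and [fit_kinetic_model()].
#' @export
kinetic_models <- function() {
  c("zero_order", "first_order", "higuchi", "korsmeyer_peppas", "hixson_crowell")
}

#' Linearize a release segment under a kinetic model
#'
#' Transforms a (time, cumulative fraction) segment to the coordinates in
#' which the named model is a straight line:
#' \describe{
#'   \item{zero_order}{\eqn{Q_t = k_0 t}: x = t, y = Q.}
#'   \item{first_order}{printed form \eqn{\log Q_t = k t / 2.303}:
#'     x = t, y = log10(Q). The conventional first-order law regresses the
#'     log of the remaining amount instead; set `first_order = "remaining"`
#'     for y = log10(1 - Q).}
#'   \item{higuchi}{\eqn{Q_t = k_H \sqrt{t}}: x = sqrt(t), y = Q.}
#'   \item{korsmeyer_peppas}{\eqn{M_t/M_\infty = K t^n}: x = log10(t),
#'     y = log10(Q), t > 0 only, and by default only points with
#'     Q <= `kp_max_fraction` (the conventional 60% validity window).}
#'   \item{hixson_crowell}{\eqn{W_0^{1/3} - W_t^{1/3} = k t} with
#'     \eqn{W_0 = 1}, \eqn{W_t = 1 - Q}: x = t, y = 1 - (1-Q)^(1/3).}
#' }
#' Points where a log or cube-root difference is undefined (Q <= 0, Q >= 1
#' for logs of remaining, t <= 0 for log-time) are dropped; the count of
#' dropped points is returned.
#'
#' @param model one of [kinetic_models()].
#' @param times times in hours, >= 0.
#' @param fraction cumulative released fraction.
#' @param kp_max_fraction Korsmeyer-Peppas validity window (default 0.6);
#'   set to `Inf` to disable.
#' @param first_order `"log_released"` (the printed form, default) or
#'   `"remaining"` (conventional first-order on the remaining amount).
#' @return A list with `x`, `y`, `kept` (logical index into the input) and
#'   `n_dropped`.
#' @export
linearize_release <- function(model, times, fraction,
                              kp_max_fraction = 0.6,
                              first_order = c("log_released", "remaining")) {
  model <- match.arg(model, kinetic_models())
  first_order <- match.arg(first_order)
  stopifnot(is.numeric(times), is.numeric(fraction),
            length(times) == length(fraction))
  if (any(times < 0)) stop("'times' must be >= 0")
  keep <- rep(TRUE, length(times))
  if (model == "first_order") {
    keep <- if (first_order == "log_released") fraction > 0 else fraction < 1
  } else if (model == "korsmeyer_peppas") {
    keep <- times > 0 & fraction > 0 & fraction <= kp_max_fraction
  } else if (model == "hixson_crowell") {
    keep <- fraction <= 1
  }
  tk <- times[keep]; qk <- fraction[keep]
  xy <- switch(model,
    zero_order = list(x = tk, y = qk),
    first_order = if (first_order == "log_released")
      list(x = tk, y = log10(qk)) else list(x = tk, y = log10(1 - qk)),
    higuchi = list(x = sqrt(tk), y = qk),
    korsmeyer_peppas = list(x = log10(tk), y = log10(qk)),
    hixson_crowell = list(x = tk, y = 1 - (1 - qk)^(1 / 3)))
  if (sum(keep) < 3)
    stop("fewer than 3 usable points after filtering for model '", model, "'")
  c(xy, list(kept = keep, n_dropped = sum(!keep)))
}

#' Fit a classical kinetic model by linear least squares
#'
#' Ordinary least squares on the linearized coordinates of
#' [linearize_release()], with a free intercept (stage-local segments need
#' not start at zero release). The reported model constant is the slope,
#' mapped back to the model's natural parameters; for Korsmeyer-Peppas the
#' release exponent is the slope and the rate constant is
#' \eqn{K = 10^{intercept}}; for the printed first-order form the constant
#' is \eqn{k = 2.303 \times slope}.
#'
#' @inheritParams linearize_release
#' @param ... passed to [linearize_release()].
#' @return An object of class `"kinetic_fit"`: a list with `model`,
#'   `params` (named numeric), `intercept`, `slope`, `r_squared`,
#'   `n_points`, `n_dropped` and the linearization options used.
#' @export
#' @examples
#' t <- 1:6
#' fit_kinetic_model(t, 0.05 * t, "zero_order")
fit_kinetic_model <- function(times, fraction, model, ...) {
  model <- match.arg(model, kinetic_models())
  lin <- linearize_release(model, times, fraction, ...)
  if (stats::var(lin$x) == 0)
    stop("degenerate linearized abscissa (zero variance) for model '", model, "'")
  fit <- stats::lm(y ~ x, data = list(x = lin$x, y = lin$y))
  cf <- stats::coef(fit)
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  sst <- sum((lin$y - mean(lin$y))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sst
  params <- switch(model,
    zero_order = c(k0 = slope),
    first_order = c(k = 2.303 * slope),
    higuchi = c(kH = slope),
    korsmeyer_peppas = c(K = 10^intercept, n = slope),
    hixson_crowell = c(k_hc = slope))
  opts <- list(...)
  structure(list(model = model, params = params,
                 intercept = intercept, slope = slope,
                 r_squared = r2, n_points = length(lin$x),
                 n_dropped = lin$n_dropped, options = opts),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic model fit:", x$model, "\n")
  cat("  ", paste(names(x$params), signif(x$params, 6), sep = " = ",
                  collapse = ", "), "\n")
  cat("  r-squared (linearized):", signif(x$r_squared, 6),
      " on", x$n_points, "points")
  if (x$n_dropped > 0) cat(" (", x$n_dropped, "dropped )")
  cat("\n")
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) object$params

#' Predict cumulative fractions from a fitted kinetic model
#'
#' Forward evaluation of the fitted linearized model (including its
#' intercept), mapped back to the cumulative-fraction scale. Round-trips
#' [fit_kinetic_model()] on noise-free model-generated data.
#'
#' @param object a `"kinetic_fit"`.
#' @param times times in hours, >= 0 (> 0 where the model's transform
#'   demands, e.g. log-time for Korsmeyer-Peppas).
#' @param ... unused.
#' @return Predicted cumulative fractions.
#' @export
predict.kinetic_fit <- function(object, times, ...) {
  stopifnot(is.numeric(times))
  if (any(times < 0)) stop("'times' must be >= 0")
  a <- object$intercept; b <- object$slope
  fo <- object$options$first_order
  remaining <- identical(fo, "remaining")
  switch(object$model,
    zero_order = a + b * times,
    first_order = if (remaining) 1 - 10^(a + b * times)
                  else 10^(a + b * times),
    higuchi = a + b * sqrt(times),
    korsmeyer_peppas = {
      if (any(times <= 0)) stop("'times' must be > 0 for korsmeyer_peppas")
      10^(a + b * log10(times))
    },
    hixson_crowell = 1 - (1 - (a + b * times))^3)
}

#' @rdname predict.kinetic_fit
#' @export
predict_kinetic <- function(object, times, ...) predict(object, times, ...)

#' Stage-wise model-adequacy report
#'
#' Fits the five classical models to each stage of a release profile and
#' reports the linear-fit r-squared with an adequacy flag. Each stage is
#' fitted as an incremental release on a stage-local time axis: times are
#' taken relative to the stage's start boundary and the fraction released
#' before the stage (the previous stage's terminal observed value) is
#' subtracted, the same splicing convention used by the multifractal
#' per-stage calibration. The Korsmeyer-Peppas validity window is disabled
#' here (stage-local increments are not the global released fraction).
#'
#' @param profile a [release_profile()] for one formulation.
#' @param partition a [stage_partition()].
#' @param threshold adequacy threshold on r-squared (default 0.90).
#' @param isotonic apply isotonic cleanup to the replicate-averaged curve.
#' @param ... passed to [fit_kinetic_model()].
#' @return A data frame with one row per model x stage: columns
#'   `formulation`, `stage`, `model`, `param_names`, `param_values`,
#'   `r_squared`, `n_points`, `adequate` (NA where a cell was not
#'   evaluable).
#' @export
stagewise_model_report <- function(profile, partition = stage_partition(),
                                   threshold = 0.90, isotonic = FALSE, ...) {
  profile <- validate_release_profile(profile)
  form <- unique(profile$formulation)
  if (length(form) != 1L) stop("'profile' must contain a single formulation")
  avg <- average_replicates(profile, isotonic = isotonic)
  seg <- segment_stages_curve(avg, partition)
  rows <- list()
  for (stage in 1:3) {
    s <- seg[[stage]]
    local_t <- s$time_h - seg$t_start[stage]
    inc <- s$cumulative_fraction - seg$offset[stage]
    for (model in kinetic_models()) {
      row <- data.frame(formulation = form, stage = stage, model = model,
                        param_names = NA_character_, param_values = NA_character_,
                        r_squared = NA_real_, n_points = nrow(s),
                        adequate = NA, stringsAsFactors = FALSE)
      fit <- tryCatch(
        fit_kinetic_model(local_t, inc, model, kp_max_fraction = Inf, ...),
        error = function(e) NULL)
      if (!is.null(fit)) {
        row$param_names <- paste(names(fit$params), collapse = ";")
        row$param_values <- paste(signif(fit$params, 8), collapse = ";")
        row$r_squared <- fit$r_squared
        row$n_points <- fit$n_points
        row$adequate <- fit$r_squared >= threshold
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}
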
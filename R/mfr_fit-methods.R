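#' @export
print.mfr_fit <- function(x, ...) {
  cat("Stage-wise multifractal release model\n")
  cat("Formulation:", x$formulation, "\n")
  cat(sprintf("Stage boundaries (h): %g, %g, %g\n",
              x$partition$t_burst_end, x$partition$t_slow_end,
              x$partition$t_final))
  cm <- coef(x)
  print(signif(cm, 6))
  cat("Fractality trajectory:", x$trajectory$verdict, "\n")
  invisible(x)
}

#' @export
summary.mfr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mfr_fit")
}

#' @export
print.summary.mfr_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-stage detail:\n")
  for (k in 1:3) print(f$stages[[k]])
  tr <- f$trajectory
  if (!anyNA(tr$f_alpha))
    cat(sprintf("\nf(alpha): %.4g > %.4g > %.4g is %s\n",
                tr$f_alpha[1], tr$f_alpha[2], tr$f_alpha[3],
                ifelse(isTRUE(tr$decreasing), "TRUE", "FALSE")))
  invisible(x)
}

#' @export
coef.mfr_fit <- function(object, ...) {
  rows <- t(vapply(object$stages, function(s) {
    if (is.null(s$params))
      c(mu = NA_real_, phi = NA_real_, m0_bar = NA_real_,
        f_alpha = NA_real_, rmse = NA_real_)
    else
      c(mu = s$params$mu, phi = s$params$phi, m0_bar = s$params$m0_bar,
        f_alpha = s$f_alpha, rmse = s$rmse)
  }, numeric(5)))
  rownames(rows) <- paste0("stage", 1:3)
  rows
}

# Piecewise evaluation of the fitted model at absolute times (hours).
predict_mfr_times <- function(object, times) {
  out <- rep(NA_real_, length(times))
  idx <- stage_index(times, object$partition)
  for (k in 1:3) {
    s <- object$stages[[k]]
    sel <- which(idx == k)
    if (!length(sel) || is.null(s$params)) next
    eta <- (times[sel] - s$t_start) / object$scale$tau0
    out[sel] <- s$offset + cumulative_release(s$params, eta)
  }
  out
}

#' Predict from a stage-wise multifractal release model
#'
#' Evaluates the fitted piecewise release curve (stage offset plus the
#' stage's calibrated multifractal release law) at new times.
#'
#' @param object an `"mfr_fit"`.
#' @param times absolute times in hours; defaults to the fitted data's times.
#' @param ... unused.
#' @return Predicted cumulative released fractions (NA beyond `t_final` or
#'   where a stage fit is unavailable).
#' @export
predict.mfr_fit <- function(object, times = object$data$time_h, ...) {
  stopifnot(is.numeric(times))
  if (any(times < 0)) stop("'times' must be >= 0")
  predict_mfr_times(object, times)
}

#' @export
fitted.mfr_fit <- function(object, ...) {
  predict_mfr_times(object, object$data$time_h)
}

#' @export
residuals.mfr_fit <- function(object, ...) {
  object$data$cumulative_fraction - fitted(object)
}

#' Plot a stage-wise multifractal release fit
#'
#' Observed replicate-averaged cumulative release (points) with the fitted
#' piecewise multifractal release curve (line) and the stage boundaries
#' (dotted verticals).
#'
#' @param x an `"mfr_fit"`.
#' @param log_time plot time on a log axis (default FALSE).
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.mfr_fit <- function(x, log_time = FALSE, ...) {
  d <- x$data
  tt <- seq(min(d$time_h), max(d$time_h), length.out = 400)
  graphics::plot(d$time_h, d$cumulative_fraction,
                 xlab = "time (h)", ylab = "cumulative released fraction",
                 main = paste("Multifractal release fit:", x$formulation),
                 log = if (log_time) "x" else "",
                 pch = 19, cex = 0.6, ...)
  graphics::lines(tt, predict_mfr_times(x, tt), col = "red3", lwd = 2)
  graphics::abline(v = c(x$partition$t_burst_end, x$partition$t_slow_end),
                   lty = 3, col = "grey40")
  invisible(x)
}
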
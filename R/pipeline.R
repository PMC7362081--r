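#' Three-stage partition of a release timeline
#'
#' Fixed calendar boundaries of the three release stages: a burst stage
#' `[0, t_burst_end]`, a slower diffusive stage `(t_burst_end, t_slow_end]`
#' and an erosion-driven tail `(t_slow_end, t_final]`. Defaults follow the
#' three-stage narrative of the urea-release experiments: burst over the
#' first 5 h, slower release over the next 11 days (through 269 h), then
#' slow release to day 35 (840 h).
#'
#' @param t_burst_end end of the burst stage, hours.
#' @param t_slow_end end of the second stage, hours.
#' @param t_final end of the observation window, hours.
#' @return An object of class `"stage_partition"`.
#' @export
stage_partition <- function(t_burst_end = 5, t_slow_end = 269, t_final = 840) {
  stopifnot(is.numeric(t_burst_end), is.numeric(t_slow_end), is.numeric(t_final))
  if (!(0 < t_burst_end && t_burst_end < t_slow_end && t_slow_end < t_final))
    stop("need 0 < t_burst_end < t_slow_end < t_final")
  structure(list(t_burst_end = t_burst_end, t_slow_end = t_slow_end,
                 t_final = t_final),
            class = "stage_partition")
}

stage_index <- function(time_h, partition) {
  ifelse(time_h <= partition$t_burst_end, 1L,
         ifelse(time_h <= partition$t_slow_end, 2L,
                ifelse(time_h <= partition$t_final, 3L, NA_integer_)))
}

#' Assign profile observations to release stages
#'
#' Partitions the observations of a release profile into the three stages by
#' the half-open intervals `[0, t1]`, `(t1, t2]`, `(t2, t_final]`. Every
#' observation with `time_h <= t_final` lands in exactly one stage;
#' observations beyond `t_final` are dropped with a warning.
#'
#' @param profile a [release_profile()].
#' @param partition a [stage_partition()].
#' @return A list of three `release_profile` subsets (possibly empty, in
#'   which case attribute `"empty_stages"` flags them).
#' @export
segment_stages <- function(profile, partition = stage_partition()) {
  profile <- validate_release_profile(profile)
  if (nrow(profile) == 0L) stop("empty profile")
  if (max(profile$time_h) <= partition$t_burst_end)
    warning("profile does not extend beyond the burst stage; stages 2-3 empty")
  idx <- stage_index(profile$time_h, partition)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " observation(s) beyond t_final dropped")
    profile <- profile[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  out <- lapply(1:3, function(k) profile[idx == k, , drop = FALSE])
  names(out) <- paste0("stage", 1:3)
  attr(out, "empty_stages") <- which(vapply(out, nrow, 0L) == 0L)
  attr(out, "partition") <- partition
  out
}

# Segment a replicate-averaged curve (time_h, cumulative_fraction) and
# attach the stage-local conventions: stage start times and additive offsets
# (the previous stage's terminal observed release; 0 for stage 1).
segment_stages_curve <- function(avg, partition) {
  idx <- stage_index(avg$time_h, partition)
  keep <- !is.na(idx)
  avg <- avg[keep, , drop = FALSE]; idx <- idx[keep]
  segs <- lapply(1:3, function(k) avg[idx == k, , drop = FALSE])
  t_start <- c(0, partition$t_burst_end, partition$t_slow_end)
  offset <- numeric(3)
  for (k in 2:3) {
    prev <- avg$cumulative_fraction[idx < k]
    offset[k] <- if (length(prev)) prev[length(prev)] else 0
  }
  c(segs, list(t_start = t_start, offset = offset))
}

#' Mass-balance correction for withdrawal/replacement sampling
#'
#' In the release protocol a fixed sample volume is withdrawn at each
#' sampling time and replaced with fresh medium, so measured concentrations
#' underestimate the cumulative released mass. The exact mass balance gives
#' cumulative released mass at sampling time i as
#' \deqn{M_i = V\,C_i + V_s \sum_{j<i} C_j,}
#' with medium volume V and sample volume V_s: the current dissolved mass
#' plus everything previously carried out of the vial.
#'
#' @param conc measured concentrations (mg/mL), one per sampling time, in
#'   chronological order.
#' @param medium_ml medium volume V (default 10 mL).
#' @param sample_ml withdrawn/replaced volume V_s (default 1 mL), < medium_ml.
#' @return Cumulative released mass (mg) at each sampling time.
#' @export
#' @examples
#' correct_sampling(c(1, 1))    # 10, 11
#' correct_sampling(c(1, 0.9))  # 10, 10: dilution exactly cancelled
correct_sampling <- function(conc, medium_ml = 10, sample_ml = 1) {
  stopifnot(is.numeric(conc), is.numeric(medium_ml), is.numeric(sample_ml))
  if (medium_ml <= 0 || sample_ml <= 0) stop("volumes must be > 0")
  if (sample_ml >= medium_ml) stop("'sample_ml' must be < 'medium_ml'")
  if (any(conc < 0)) stop("negative concentration")
  medium_ml * conc + sample_ml * c(0, cumsum(conc)[-length(conc)])
}

#' Calibrate the multifractal release law on one stage
#'
#' Nonlinear least squares of the multifractal cumulative-release law
#' [cumulative_release()] against the observed incremental release of one
#' stage. Times are taken stage-locally (`eta = (t - t_start)/tau0`) and the
#' observed fraction is reduced by `offset`, the release accumulated before
#' the stage, so each stage is fitted as an incremental release starting
#' from zero. Parameters `(mu, phi, m0_bar)` are estimated by bounded
#' Levenberg-Marquardt least squares with a deterministic multi-start grid;
#' among starts whose final RMSE ties (relative 1e-8), the lowest fitted
#' `mu` wins. The fitted `mu` is converted to a fractality degree via the
#' scale relation (sigma = mu * alpha^2 / tau0, then
#' [fractality_from_sigma()]); `f_alpha` is `NA` when `mu` is 0 or the
#' implied fractal dimension is outside (0, Inf).
#'
#' @param times observation times in hours (absolute).
#' @param fraction observed cumulative released fraction at `times`.
#' @param t_start stage start time in hours (stage-local origin).
#' @param offset release fraction accumulated before this stage.
#' @param scale a [scale_config()]; supplies tau0 for the eta scaling and
#'   (lam, dt, alpha) for the fractality conversion.
#' @param xi_obs observation coordinate of the release law (default 0).
#' @param lower,upper parameter bounds, order (mu, phi, m0_bar).
#' @param starts numeric vector of multi-start values per parameter
#'   (clipped into the bounds and deduplicated per parameter); the default
#'   `c(0.1, 1, 10, 100)` spans the bounds, including the upper bound of
#'   `phi`, where the optimum of slow stages often sits.
#' @param stage_id optional stage label carried into the result.
#' @return An object of class `"mf_stage_fit"`: fitted
#'   [release_model_params()], `f_alpha`, `rmse`, `converged`, `n_points`,
#'   plus the stage-local data used.
#' @export
fit_multifractal_stage <- function(times, fraction, t_start = 0, offset = 0,
                                   scale = scale_config(), xi_obs = 0,
                                   lower = c(0, 1e-8, 1e-8),
                                   upper = c(100, 100, 1.5),
                                   starts = c(0.1, 1, 10, 100),
                                   stage_id = NA_integer_) {
  stopifnot(is.numeric(times), is.numeric(fraction),
            length(times) == length(fraction),
            inherits(scale, "scale_config"))
  if (length(times) < 4) stop("need at least 4 points in the stage segment")
  eta <- (times - t_start) / scale$tau0
  if (any(eta < 0)) stop("times before the stage start")
  y <- fraction - offset

  resid_fun <- function(par) {
    p <- list(mu = par[1], phi = par[2], m0_bar = par[3], xi_obs = xi_obs)
    class(p) <- "release_model_params"
    cumulative_release(p, eta) - y
  }

  clip_starts <- function(j) unique(pmin(pmax(starts, lower[j]), upper[j]))
  grid <- expand.grid(mu = clip_starts(1), phi = clip_starts(2),
                      m0 = clip_starts(3))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    par0 <- as.numeric(grid[i, ])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(resid_fun(fit$par)^2))
    ok <- fit$info %in% 1:4
    cand <- list(par = fit$par, rmse = rmse, converged = ok)
    if (is.null(best) ||
        rmse < best$rmse * (1 - 1e-8) ||
        (abs(rmse - best$rmse) <= 1e-8 * max(best$rmse, .Machine$double.eps) &&
         fit$par[1] < best$par[1])) {
      best <- cand
    }
  }
  if (is.null(best)) {
    return(structure(list(stage_id = stage_id, params = NULL,
                          f_alpha = NA_real_, rmse = NA_real_,
                          converged = FALSE, n_points = length(eta),
                          eta = eta, y = y, offset = offset,
                          t_start = t_start, scale = scale),
                     class = "mf_stage_fit"))
  }
  params <- release_model_params(mu = best$par[1], phi = best$par[2],
                                 m0_bar = best$par[3], xi_obs = xi_obs)
  sigma <- params$mu * scale$alpha^2 / scale$tau0
  f_alpha <- if (sigma > 0)
    tryCatch(fractality_from_sigma(sigma, scale$lam, scale$dt),
             error = function(e) NA_real_)
  else NA_real_
  structure(list(stage_id = stage_id, params = params, f_alpha = f_alpha,
                 rmse = best$rmse, converged = best$converged,
                 n_points = length(eta), eta = eta, y = y,
                 offset = offset, t_start = t_start, scale = scale),
            class = "mf_stage_fit")
}

#' @export
print.mf_stage_fit <- function(x, ...) {
  cat("Multifractal stage fit",
      if (!is.na(x$stage_id)) paste0("(stage ", x$stage_id, ")"), "\n")
  if (is.null(x$params)) {
    cat("  not converged\n")
    return(invisible(x))
  }
  cat(sprintf("  mu = %.6g, phi = %.6g, m0_bar = %.6g\n",
              x$params$mu, x$params$phi, x$params$m0_bar))
  cat(sprintf("  f(alpha) = %.6g, rmse = %.3e, converged = %s, n = %d\n",
              x$f_alpha, x$rmse, x$converged, x$n_points))
  invisible(x)
}

#' Fit the stage-wise multifractal release model
#'
#' The main model-fitting entry point: segments a single-formulation release
#' profile into the three release stages, calibrates the multifractal
#' release law on each stage (see [fit_multifractal_stage()]) and derives
#' the fractality trajectory across stages. Replicates are averaged before
#' fitting.
#'
#' @param profile a [release_profile()] for one formulation.
#' @param partition a [stage_partition()].
#' @param scale a [scale_config()].
#' @param isotonic apply isotonic cleanup to the averaged curve.
#' @param ... passed to [fit_multifractal_stage()].
#' @return An object of class `"mfr_fit"` with components `stages` (list of
#'   three `mf_stage_fit`), `trajectory` (see [fractality_trajectory()]),
#'   `formulation`, `partition`, `scale`, `data` (the averaged curve) and
#'   `call`. Supports `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals` and `plot`.
#' @export
#' @examples
#' cfg <- generator_config(noise_rel = 0)
#' panel <- generate_panel(cfg, seed = 1)
#' prof <- panel$profiles[panel$profiles$formulation == "2-U1", ]
#' fit <- fit_release(prof)
#' fit
fit_release <- function(profile, partition = stage_partition(),
                        scale = scale_config(), isotonic = FALSE, ...) {
  cl <- match.call()
  profile <- validate_release_profile(profile)
  form <- unique(profile$formulation)
  if (length(form) != 1L)
    stop("'profile' must contain a single formulation; see fit_release_panel()")
  avg <- average_replicates(profile, isotonic = isotonic)
  seg <- segment_stages_curve(avg, partition)
  stages <- vector("list", 3L)
  for (k in 1:3) {
    s <- seg[[k]]
    stages[[k]] <- if (nrow(s) >= 4) {
      fit_multifractal_stage(s$time_h, s$cumulative_fraction,
                             t_start = seg$t_start[k], offset = seg$offset[k],
                             scale = scale, stage_id = k, ...)
    } else {
      structure(list(stage_id = k, params = NULL, f_alpha = NA_real_,
                     rmse = NA_real_, converged = FALSE, n_points = nrow(s),
                     eta = numeric(0), y = numeric(0),
                     offset = seg$offset[k], t_start = seg$t_start[k],
                     scale = scale),
                class = "mf_stage_fit")
    }
  }
  names(stages) <- paste0("stage", 1:3)
  structure(list(stages = stages,
                 trajectory = fractality_trajectory(stages),
                 formulation = form, partition = partition, scale = scale,
                 data = avg, call = cl),
            class = "mfr_fit")
}

#' Fractality trajectory across release stages
#'
#' Collects the fitted fractality degrees of the three stage fits and
#' reports whether they decrease strictly, the signature of a release that
#' starts highly energetic (high fractality) and slows down. The verdict is
#' `"indeterminate"` when any stage fit is unconverged or has an undefined
#' fractality degree.
#'
#' @param fits a list of three `mf_stage_fit` objects (or an `"mfr_fit"`).
#' @return A list with `f_alpha` (length 3), `mu` (length 3, model-native
#'   fractality parameters), `decreasing` (logical or NA) and `verdict`
#'   (`"decreasing"`, `"not decreasing"` or `"indeterminate"`).
#' @export
fractality_trajectory <- function(fits) {
  if (inherits(fits, "mfr_fit")) fits <- fits$stages
  stopifnot(length(fits) == 3L)
  f <- vapply(fits, function(s) if (is.null(s$f_alpha)) NA_real_ else s$f_alpha,
              0)
  mu <- vapply(fits, function(s) if (is.null(s$params)) NA_real_ else s$params$mu,
               0)
  conv <- vapply(fits, function(s) isTRUE(s$converged), TRUE)
  if (any(!conv) || anyNA(f)) {
    return(list(f_alpha = f, mu = mu, decreasing = NA,
                verdict = "indeterminate"))
  }
  dec <- f[1] > f[2] && f[2] > f[3]
  list(f_alpha = f, mu = mu, decreasing = dec,
       verdict = if (dec) "decreasing" else "not decreasing")
}

#' Stage-3 load independence across formulations
#'
#' Dispersion of the stage-3 fractality degree across formulations with
#' different initial urea loads. A small coefficient of variation indicates
#' that the late, erosion-driven release no longer depends on the initial
#' load. The population coefficient of variation (sd with divisor n over
#' the mean) is used.
#'
#' @param fits a list of `"mfr_fit"` objects (>= 2), or a numeric vector of
#'   stage-3 fractality degrees.
#' @param threshold independence threshold on the CV (default 0.15).
#' @return A list with `f_alpha`, `cv` and `independent`.
#' @export
load_independence_stage3 <- function(fits, threshold = 0.15) {
  f <- if (is.numeric(fits)) fits
       else vapply(fits, function(x) x$stages$stage3$f_alpha, 0)
  if (length(f) < 2) stop("need stage-3 fits from at least 2 formulations")
  if (anyNA(f)) stop("stage-3 fractality degree missing for some formulation")
  m <- mean(f)
  sd_pop <- sqrt(mean((f - m)^2))
  cv <- sd_pop / m
  list(f_alpha = f, cv = cv, independent = cv < threshold)
}

#' Fit the multifractal model to every formulation of a panel
#'
#' @param profiles a [release_profile()] data frame with one or more
#'   formulations.
#' @param ... passed to [fit_release()].
#' @return A named list of `"mfr_fit"` objects, one per formulation.
#' @export
fit_release_panel <- function(profiles, ...) {
  lapply(split_formulations(profiles), fit_release, ...)
}
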
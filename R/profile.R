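#' Construct a release profile
#'
#' A release profile is a long-format data frame of cumulative released
#' fraction over time, one row per (formulation, replicate, time) with
#' strictly increasing times within each replicate. Fractions slightly above
#' 1 (up to 1.05) are tolerated as measurement overshoot.
#'
#' @param formulation formulation code (recycled).
#' @param replicate replicate label (recycled).
#' @param time_h sampling times in hours, >= 0.
#' @param cumulative_fraction cumulative released fraction, in [0, 1.05].
#' @return A data frame of class `"release_profile"`.
#' @export
release_profile <- function(formulation, replicate, time_h, cumulative_fraction) {
  d <- data.frame(formulation = as.character(formulation),
                  replicate = as.character(replicate),
                  time_h = as.numeric(time_h),
                  cumulative_fraction = as.numeric(cumulative_fraction),
                  stringsAsFactors = FALSE)
  validate_release_profile(d)
}

validate_release_profile <- function(d) {
  need <- c("formulation", "replicate", "time_h", "cumulative_fraction")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d$formulation <- as.character(d$formulation)
  d$replicate <- as.character(d$replicate)
  d$time_h <- as.numeric(d$time_h)
  d$cumulative_fraction <- as.numeric(d$cumulative_fraction)
  if (any(!is.finite(d$time_h)) || any(d$time_h < 0))
    stop("'time_h' must be finite and >= 0")
  if (any(!is.finite(d$cumulative_fraction)) ||
      any(d$cumulative_fraction < 0) || any(d$cumulative_fraction > 1.05))
    stop("'cumulative_fraction' must lie in [0, 1.05]")
  d <- d[order(d$formulation, d$replicate, d$time_h), , drop = FALSE]
  key <- paste(d$formulation, d$replicate, d$time_h)
  if (anyDuplicated(key))
    stop("duplicated (formulation, replicate, time_h) row(s): ",
         paste(utils::head(key[duplicated(key)], 3L), collapse = "; "))
  rownames(d) <- NULL
  class(d) <- c("release_profile", "data.frame")
  d
}

#' Replicate-averaged release curve
#'
#' Averages the cumulative fraction across replicates at each time point of
#' a single-formulation profile. Optionally applies an isotonic
#' (pool-adjacent-violators) cleanup so the averaged curve is nondecreasing.
#'
#' @param profile a [release_profile()] for a single formulation.
#' @param isotonic apply isotonic regression cleanup (default FALSE).
#' @return A data frame with columns `time_h` and `cumulative_fraction`.
#' @export
average_replicates <- function(profile, isotonic = FALSE) {
  profile <- validate_release_profile(profile)
  if (length(unique(profile$formulation)) != 1L)
    stop("'profile' must contain a single formulation")
  agg <- stats::aggregate(cumulative_fraction ~ time_h, data = profile, FUN = mean)
  agg <- agg[order(agg$time_h), , drop = FALSE]
  if (isotonic) {
    iso <- stats::isoreg(agg$time_h, agg$cumulative_fraction)
    agg$cumulative_fraction <- iso$yf
  }
  rownames(agg) <- NULL
  agg[, c("time_h", "cumulative_fraction")]
}

split_formulations <- function(profiles) {
  profiles <- validate_release_profile(profiles)
  split(profiles, profiles$formulation)
}
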
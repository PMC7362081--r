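#' Printed urea percentage of a formulation
#'
#' Urea weight percent of the total formulation,
#' `100 * urea / (matrix + urea)`, rounded to the nearest integer as printed
#' in the composition table - except for the doubled-urea rows whose exact
#' ratio is 2/3 (66.67%): those are printed truncated as 66, and the same
#' convention is applied here so the table is reproduced bit-exactly.
#'
#' @param urea_mg urea mass (mg), >= 0.
#' @param matrix_mg matrix (chitosan + salicylaldehyde) mass (mg), > 0.
#' @return Integer percentage.
#' @export
#' @examples
#' formulation_percent(141, 141)  # 50
#' formulation_percent(282, 141)  # 66 (exact 2/3, printed truncated)
formulation_percent <- function(urea_mg, matrix_mg) {
  stopifnot(is.numeric(urea_mg), is.numeric(matrix_mg))
  if (any(urea_mg < 0)) stop("'urea_mg' must be >= 0")
  if (any(matrix_mg <= 0)) stop("'matrix_mg' must be > 0")
  total <- matrix_mg + urea_mg
  pct <- 100 * urea_mg / total
  out <- floor(pct + 0.5)
  two_thirds <- abs(3 * urea_mg - 2 * total) < 1e-9 * total
  out[two_thirds] <- 66
  as.integer(out)
}

#' The eight urea-release formulations
#'
#' Composition table of the eight chitosan/salicylaldehyde/urea formulations:
#' two crosslinking ratios (NH2/CHO = 1.5 and 2) times four urea loadings
#' (none, half, equal and double the matrix mass). The matrix mass is the
#' chitosan plus salicylaldehyde mass; the percentage column follows the
#' printed convention of [formulation_percent()].
#'
#' @return A data frame with columns `code`, `nh2_cho_ratio`, `chitosan_mg`,
#'   `sa_mg`, `matrix_mg`, `urea_mg`, `urea_percent`, `formulation_mg`.
#' @export
table1_formulations <- function() {
  d <- data.frame(
    code = c("1.5-U0", "1.5-U0.5", "1.5-U1", "1.5-U2",
             "2-U0", "2-U0.5", "2-U1", "2-U2"),
    nh2_cho_ratio = c(1.5, 1.5, 1.5, 1.5, 2, 2, 2, 2),
    chitosan_mg = rep(100, 8),
    sa_mg = c(41, 41, 41, 41, 31, 31, 31, 31),
    urea_mg = c(0, 70.5, 141, 282, 0, 65, 131, 262),
    stringsAsFactors = FALSE)
  d$matrix_mg <- d$chitosan_mg + d$sa_mg
  d$urea_percent <- ifelse(d$urea_mg == 0, 0L,
                           formulation_percent(d$urea_mg, d$matrix_mg))
  d$formulation_mg <- d$matrix_mg + d$urea_mg
  d[, c("code", "nh2_cho_ratio", "chitosan_mg", "sa_mg", "matrix_mg",
        "urea_mg", "urea_percent", "formulation_mg")]
}

#' Synthetic release-experiment configuration
#'
#' Parameters of the synthetic in vitro release experiment: the three-stage
#' release milestones (burst to `F1` at `t1`, slower release to `F2` at
#' `t2`, near-complete release `F_final` at `t_final`), the stage shape
#' constants, the withdrawal/replacement protocol volumes, the measurement
#' noise level and the replicate count. The default milestones encode a
#' burst to 46% in 5 h, 75% released after 11 further days (269 h) and 99%
#' by day 35 (840 h); each formulation vial is loaded with 50 mg urea.
#'
#' Stage shapes: stage 1 is a first-order burst with rate `k1`; stage 2 is a
#' Higuchi-type square-root-of-time filling; stage 3 is a heterogeneous-
#' erosion tail with Hill-type saturation in stage-local time,
#' \eqn{w(u) = u^q / (u^q + K^q)} (power-law onset with exponent
#' `stage3_exponent` = q, half-saturation at `stage3_half_time` = K hours,
#' heavy tail), rescaled to end at the final milestone. All three stages are
#' anchored so the milestones are hit exactly.
#'
#' @param t1,F1 end of burst stage (h) and fraction released there.
#' @param t2,F2 end of second stage (h) and fraction released there.
#' @param t_final,F_final end of observation (h) and final fraction.
#' @param k1 burst first-order rate constant (1/h).
#' @param stage3_exponent Hill exponent q of the erosion tail, > 0.
#' @param stage3_half_time Hill half-saturation time K of the erosion tail
#'   (hours of stage-local time), > 0.
#' @param noise_rel relative (multiplicative Gaussian) measurement noise sd.
#' @param n_replicates replicates per formulation.
#' @param medium_ml release-medium volume (mL).
#' @param sample_ml withdrawn/replaced volume per sampling (mL).
#' @param urea_loading_mg urea load per vial (mg).
#' @param ratio_factor speed multiplier for the higher-crosslinked (1.5-Ux)
#'   series.
#' @param urea_factors named list of speed multipliers by urea percent
#'   (names "33", "50", "66").
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(t1 = 5, F1 = 0.46,
                             t2 = 269, F2 = 0.75,
                             t_final = 840, F_final = 0.99,
                             k1 = 0.15, stage3_exponent = 0.7,
                             stage3_half_time = 200,
                             noise_rel = 0.03, n_replicates = 2,
                             medium_ml = 10, sample_ml = 1,
                             urea_loading_mg = 50,
                             ratio_factor = 1.1,
                             urea_factors = list("33" = 0.9, "50" = 1.0,
                                                 "66" = 1.15)) {
  stopifnot(0 < F1, F1 < F2, F2 < F_final, F_final <= 1,
            0 < t1, t1 < t2, t2 < t_final,
            k1 > 0, stage3_exponent > 0, stage3_half_time > 0,
            noise_rel >= 0, n_replicates >= 1,
            medium_ml > 0, sample_ml > 0, sample_ml < medium_ml,
            urea_loading_mg > 0, ratio_factor > 0,
            all(unlist(urea_factors) > 0),
            all(c("33", "50", "66") %in% names(urea_factors)))
  structure(list(t1 = t1, F1 = F1, t2 = t2, F2 = F2,
                 t_final = t_final, F_final = F_final,
                 k1 = k1, stage3_exponent = stage3_exponent,
                 stage3_half_time = stage3_half_time,
                 noise_rel = noise_rel, n_replicates = as.integer(n_replicates),
                 medium_ml = medium_ml, sample_ml = sample_ml,
                 urea_loading_mg = urea_loading_mg,
                 ratio_factor = ratio_factor,
                 urea_factors = urea_factors),
            class = "generator_config")
}

#' Formulation-specific release-speed multiplier
#'
#' Encodes the observed ordering of the release speeds across formulations:
#' the higher-crosslinked series (NH2/CHO = 1.5) releases slightly faster,
#' and formulations with more (larger) urea crystals release faster than
#' lightly loaded ones. The multiplier scales the burst rate `k1` and the
#' stage-2 time scale. Blank matrices (0% urea) have nothing to release and
#' get `NA`.
#'
#' @param formulation one row of [table1_formulations()] (or any list with
#'   `nh2_cho_ratio` and `urea_percent`).
#' @param cfg a [generator_config()].
#' @return A positive multiplier, or `NA` for blank matrices.
#' @export
formulation_modifiers <- function(formulation, cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  ratio <- formulation$nh2_cho_ratio
  pct <- formulation$urea_percent
  if (pct == 0) return(NA_real_)
  a <- if (ratio == 1.5) cfg$ratio_factor else 1.0
  b <- cfg$urea_factors[[as.character(pct)]]
  if (is.null(b) || is.na(b))
    stop("no urea speed factor configured for ", pct, "%")
  a * b
}

#' Noise-free true release curve
#'
#' Continuous, nondecreasing three-stage cumulative release fraction with
#' the configured milestones hit exactly: a first-order burst on `[0, t1]`,
#' a square-root-of-time stage on `(t1, t2]` and a Hill-type
#' heterogeneous-erosion tail on `(t2, t_final]`. A formulation-speed
#' `modifier` scales
#' the burst rate and the stage-2 elapsed time (capped at the stage-2
#' milestone); the erosion tail always starts from the value reached at
#' `t2` and ends at `F_final` exactly.
#'
#' @param t times in hours, >= 0. Times beyond `t_final` are clamped to the
#'   final fraction with a warning.
#' @param cfg a [generator_config()].
#' @param modifier formulation speed multiplier (default 1, the reference).
#' @return Cumulative released fractions.
#' @export
true_release_curve <- function(t, cfg = generator_config(), modifier = 1) {
  stopifnot(inherits(cfg, "generator_config"), is.numeric(t),
            is.numeric(modifier), length(modifier) == 1L, modifier > 0)
  if (any(t < 0)) stop("'t' must be >= 0")
  if (any(t > cfg$t_final)) {
    warning("times beyond t_final clamped to the final fraction")
    t <- pmin(t, cfg$t_final)
  }
  k1 <- cfg$k1 * modifier
  f_at_t2 <- cfg$F1 + (cfg$F2 - cfg$F1) * min(1, sqrt(modifier))
  stage1 <- function(tt) cfg$F1 * (1 - exp(-k1 * tt)) / (1 - exp(-k1 * cfg$t1))
  stage2 <- function(tt) cfg$F1 + (cfg$F2 - cfg$F1) *
    pmin(1, sqrt(modifier * (tt - cfg$t1) / (cfg$t2 - cfg$t1)))
  hill <- function(u) {
    uq <- u^cfg$stage3_exponent
    uq / (uq + cfg$stage3_half_time^cfg$stage3_exponent)
  }
  stage3 <- function(tt) f_at_t2 + (cfg$F_final - f_at_t2) *
    hill(tt - cfg$t2) / hill(cfg$t_final - cfg$t2)
  out <- numeric(length(t))
  i1 <- t <= cfg$t1
  i2 <- t > cfg$t1 & t <= cfg$t2
  i3 <- t > cfg$t2
  out[i1] <- stage1(t[i1])
  out[i2] <- stage2(t[i2])
  out[i3] <- stage3(t[i3])
  out
}

#' Sampling schedule of the release protocol
#'
#' Hourly sampling through the first day (hours 1-24), then daily samples at
#' 24-hour multiples through day 35 (hours 48, 72, ..., 840): 58 sampling
#' times in total.
#'
#' @return Strictly increasing sampling times in hours.
#' @export
sampling_schedule <- function() {
  c(1:24, seq(48, 840, by = 24))
}

# Deterministic sub-seed per (panel seed, formulation index, replicate).
sub_seed <- function(seed, form_idx, replicate) {
  (as.integer(seed) %% 100000L) * 10000L + form_idx * 100L + replicate
}

#' Simulate the withdrawal/replacement sampling protocol
#'
#' Simulates measured supernatant concentrations for one formulation under
#' the release protocol: urea dissolves into `medium_ml` of water following
#' the true release curve; at each sampling time `sample_ml` of supernatant
#' is withdrawn (removing its share of dissolved urea) and replaced with
#' water. The measured concentration is the true concentration times
#' `(1 + e)` with independent Gaussian relative error `e` of sd
#' `noise_rel` per observation per replicate. Withdrawals remove mass at
#' the true concentration; noise is purely observational. Deterministic for
#' a fixed seed, with distinct per-replicate substreams.
#'
#' @param cfg a [generator_config()].
#' @param formulation optional row of [table1_formulations()]; used to derive
#'   the speed modifier. `NULL` (default) simulates the reference speed
#'   (modifier 1).
#' @param seed integer seed.
#' @param times sampling times in hours (default [sampling_schedule()]).
#' @return A data frame with columns `replicate`, `time_h`,
#'   `conc_mg_per_ml` (measured), plus attribute `"true_cumulative_mg"`
#'   (the noise-free cumulative released mass at `times`).
#' @export
simulate_sampling <- function(cfg = generator_config(), formulation = NULL,
                              seed = 1, times = sampling_schedule()) {
  stopifnot(inherits(cfg, "generator_config"), is.numeric(times),
            all(diff(times) > 0), all(times >= 0))
  modifier <- if (is.null(formulation)) 1
              else formulation_modifiers(formulation, cfg)
  if (is.na(modifier))
    stop("blank matrix (0% urea): nothing to release, simulation skipped")
  frac <- true_release_curve(times, cfg, modifier)
  released_mg <- cfg$urea_loading_mg * frac

  out <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    set.seed(sub_seed(seed, 0L, r))
    eps <- stats::rnorm(length(times), 0, cfg$noise_rel)
    withdrawn <- 0
    conc <- numeric(length(times))
    for (i in seq_along(times)) {
      dissolved <- released_mg[i] - withdrawn
      c_true <- dissolved / cfg$medium_ml
      conc[i] <- c_true * (1 + eps[i])
      withdrawn <- withdrawn + cfg$sample_ml * c_true
    }
    out[[r]] <- data.frame(replicate = paste0("R", r), time_h = times,
                           conc_mg_per_ml = conc, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "true_cumulative_mg") <- released_mg
  res
}

#' Generate a full synthetic release panel
#'
#' Simulates the complete experiment: every urea-bearing formulation of
#' [table1_formulations()] (six of eight; the two blank matrices have
#' nothing to release and are skipped) times `n_replicates` replicates,
#' passed through the withdrawal/replacement protocol, the mass-balance
#' correction [correct_sampling()] and conversion to cumulative released
#' fraction. A manifest records the generator truth for recovery testing.
#'
#' @param cfg a [generator_config()].
#' @param seed integer master seed; all randomness flows from it.
#' @return A list with `profiles` (a [release_profile()] data frame over all
#'   formulations and replicates), `concentrations` (the raw measured
#'   concentration records) and `manifest` (config echo, seed, per-
#'   formulation speed modifiers).
#' @export
generate_panel <- function(cfg = generator_config(), seed = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  tab <- table1_formulations()
  tab <- tab[tab$urea_mg > 0, , drop = FALSE]
  profs <- list(); concs <- list(); mods <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    f <- tab[i, ]
    mods[i] <- formulation_modifiers(f, cfg)
    sim <- simulate_sampling(cfg, f, seed = sub_seed(seed, i, 0L))
    sim$formulation <- f$code
    concs[[i]] <- sim
    for (r in unique(sim$replicate)) {
      s <- sim[sim$replicate == r, ]
      mass <- correct_sampling(s$conc_mg_per_ml, cfg$medium_ml, cfg$sample_ml)
      profs[[length(profs) + 1L]] <- data.frame(
        formulation = f$code, replicate = r, time_h = s$time_h,
        cumulative_fraction = mass / cfg$urea_loading_mg,
        stringsAsFactors = FALSE)
    }
  }
  profiles <- validate_release_profile(do.call(rbind, profs))
  manifest <- list(config = unclass(cfg), seed = seed,
                   formulations = data.frame(code = tab$code,
                                             urea_percent = tab$urea_percent,
                                             modifier = mods,
                                             stringsAsFactors = FALSE),
                   package_version = as.character(utils::packageVersion("mfrelease")))
  list(profiles = profiles,
       concentrations = do.call(rbind, concs),
       manifest = manifest)
}
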
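# FNV-1a hash of a string, reported as 8 hex digits. Used to stamp output
# files with a configuration fingerprint without external dependencies.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h >= 2^31)), b)
    h <- (as.numeric(h %% 2^32) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Strip S3 classes recursively so configuration objects serialize plainly.
unclass_all <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_all) else x
}

config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(unclass_all(config), auto_unbox = TRUE,
                              digits = NA, null = "null"))
}

output_header <- function(config) {
  sprintf("# mfrelease %s config_hash=%s",
          as.character(utils::packageVersion("mfrelease")),
          config_hash(if (is.null(config)) list() else unclass(config)))
}

#' Run configuration
#'
#' Collects every tunable of a reproducible run: the scale constants, the
#' stage partition, the generator configuration, the optimizer grid, the
#' adequacy and load-independence thresholds, and the seed. Unknown keys are
#' rejected by name, so configuration typos fail loudly. The object is
#' fully JSON-serializable and is echoed verbatim into run reports.
#'
#' @param ... overrides of the default fields: `scale` ([scale_config()]),
#'   `partition` ([stage_partition()]), `generator` ([generator_config()]),
#'   `seed` (integer), `adequacy_threshold`, `cv_threshold`, `starts`,
#'   `input`, `outdir`.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(...) {
  defaults <- list(scale = scale_config(),
                   partition = stage_partition(),
                   generator = generator_config(),
                   seed = 1L,
                   adequacy_threshold = 0.90,
                   cv_threshold = 0.15,
                   starts = c(0.1, 1, 10),
                   input = NULL,
                   outdir = NULL)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "run_config")
}

#' Read release profiles from CSV
#'
#' Reads a long-format release CSV with the exact header
#' `formulation, replicate, time_h, value, value_type`, where `value_type`
#' is `cumulative_fraction` or `conc_mg_per_ml` per row (uniform within a
#' replicate). Concentration rows are routed through [correct_sampling()]
#' using the protocol volumes and converted to cumulative fraction with the
#' vial loading. Lines starting with `#` are ignored. Malformed rows are
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @param medium_ml,sample_ml protocol volumes for concentration inputs.
#' @param urea_loading_mg vial loading used to convert mass to fraction.
#' @return A [release_profile()] data frame.
#' @export
read_release_csv <- function(path, medium_ml = 10, sample_ml = 1,
                             urea_loading_mg = 50) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("formulation", "replicate", "time_h", "value", "value_type")
  if (!identical(sort(names(d)), sort(need)))
    stop("header must be exactly {", paste(need, collapse = ", "),
         "}; got {", paste(names(d), collapse = ", "), "}")
  line_no <- seq_len(nrow(d)) + 1L  # header is line 1 (comments excluded)
  bad_type <- !d$value_type %in% c("cumulative_fraction", "conc_mg_per_ml")
  if (any(bad_type))
    stop("unknown value_type at line(s): ",
         paste(utils::head(line_no[bad_type], 5L), collapse = ", "))
  bad_val <- !is.finite(d$value) | d$value < 0
  if (any(bad_val))
    stop("negative or non-numeric value at line(s): ",
         paste(utils::head(line_no[bad_val], 5L), collapse = ", "))
  key <- paste(d$formulation, d$replicate, d$time_h)
  if (anyDuplicated(key))
    stop("duplicated (formulation, replicate, time_h) at line(s): ",
         paste(utils::head(line_no[duplicated(key)], 5L), collapse = ", "))

  parts <- split(d, paste(d$formulation, d$replicate))
  rows <- lapply(parts, function(p) {
    p <- p[order(p$time_h), , drop = FALSE]
    vt <- unique(p$value_type)
    if (length(vt) != 1L)
      stop("mixed value_type within replicate ", p$replicate[1],
           " of formulation ", p$formulation[1])
    frac <- if (vt == "cumulative_fraction") p$value
            else correct_sampling(p$value, medium_ml, sample_ml) / urea_loading_mg
    data.frame(formulation = p$formulation, replicate = p$replicate,
               time_h = p$time_h, cumulative_fraction = frac,
               stringsAsFactors = FALSE)
  })
  validate_release_profile(do.call(rbind, rows))
}

#' Write release profiles to CSV
#'
#' Writes profiles in the long format read back by [read_release_csv()],
#' with a `#` header comment carrying the package version and a
#' configuration hash.
#'
#' @param profiles a [release_profile()] data frame.
#' @param path output CSV path.
#' @param config optional configuration echoed into the header hash.
#' @return `path`, invisibly.
#' @export
write_release_csv <- function(profiles, path, config = NULL) {
  profiles <- validate_release_profile(profiles)
  out <- data.frame(formulation = profiles$formulation,
                    replicate = profiles$replicate,
                    time_h = profiles$time_h,
                    value = profiles$cumulative_fraction,
                    value_type = "cumulative_fraction",
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Write a per-stage multifractal fit table to CSV
#'
#' @param fits a named list of `"mfr_fit"` objects (as returned by
#'   [fit_release_panel()]).
#' @param path output CSV path.
#' @param config optional configuration echoed into the header hash.
#' @return The fit table data frame, invisibly.
#' @export
write_stage_fit_csv <- function(fits, path, config = NULL) {
  rows <- list()
  for (f in fits) {
    cm <- coef(f)
    for (k in 1:3) {
      rows[[length(rows) + 1L]] <- data.frame(
        formulation = f$formulation, stage = k,
        mu = cm[k, "mu"], phi = cm[k, "phi"], m0_bar = cm[k, "m0_bar"],
        f_alpha = cm[k, "f_alpha"], rmse = cm[k, "rmse"],
        converged = isTRUE(f$stages[[k]]$converged),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(tab)
}

#' Write a stage-by-model kinetics report to CSV
#'
#' @param report a data frame from [stagewise_model_report()] (rows from
#'   several formulations may be rbind-ed together).
#' @param path output CSV path.
#' @param config optional configuration echoed into the header hash.
#' @return `path`, invisibly.
#' @export
write_kinetics_csv <- function(report, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config), con)
  utils::write.csv(report, con, row.names = FALSE)
  invisible(path)
}

#' Consolidated JSON run report
#'
#' Writes a machine-readable report of a full analysis run: the verbatim
#' configuration echo with its hash, the seed, per-formulation multifractal
#' fit tables and fractality-trajectory verdicts, the stage-3
#' load-independence summary, and any warnings collected.
#'
#' @param fits a named list of `"mfr_fit"` objects.
#' @param config a [run_config()].
#' @param path output JSON path.
#' @param warnings character vector of warnings to embed.
#' @return The report list, invisibly.
#' @export
write_run_report <- function(fits, config, path, warnings = character()) {
  stopifnot(inherits(config, "run_config"))
  per_form <- lapply(fits, function(f) {
    cm <- coef(f)
    list(coefficients = as.data.frame(cbind(stage = 1:3, cm)),
         trajectory = f$trajectory$verdict,
         f_alpha = f$trajectory$f_alpha)
  })
  indep <- tryCatch(load_independence_stage3(fits, config$cv_threshold),
                    error = function(e) list(cv = NA, independent = NA,
                                             note = conditionMessage(e)))
  report <- list(package_version = as.character(utils::packageVersion("mfrelease")),
                 config = unclass_all(config),
                 config_hash = config_hash(config),
                 seed = config$seed,
                 formulations = per_form,
                 stage3_load_independence = indep,
                 warnings = warnings)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(report)
}
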
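# Compendium-style MET constants used by both scoring paths.

# week geometry, fixed by the minute-epoch design
MINUTES_PER_DAY <- 1440L
MINUTES_PER_WEEK <- 10080L
HOURS_PER_WEEK <- 168

#' MET constants for questionnaire scoring and stream fusion
#'
#' Returns the immutable registry of MET (metabolic equivalent of task)
#' values and intensity thresholds used throughout the package: the
#' compendium-derived intensities assigned to questionnaire domains
#' (occupational light/moderate/vigorous = 2/3/4 MET, household chores
#' 2.5/3.5/4.5 MET, active transport 4 MET, motorized transport 1.5 MET,
#' eating 1.8 MET, sleeping 0.9 MET, residual inactive leisure 1.5 MET),
#' the imputation constants for non-wear during personal care (2 MET) and
#' swimming (6 MET), and the intensity-class thresholds (sedentary at or
#' below 1.8 MET; moderate at least 3 and below 6 MET; vigorous at least
#' 6 MET; bouts require 10 consecutive minutes).
#'
#' Alternative compendium values can be supplied explicitly, but never by
#' mutation: the returned list is a fresh copy each call.
#'
#' @param overrides named list of constants to replace; names must be a
#'   subset of the default registry.
#' @return a named list of class `met_constants`.
#' @examples
#' met_constants()$active_transport
#' met_constants(list(eating = 1.5))$eating
#' @export
met_constants <- function(overrides = NULL) {
  x <- list(
    job_light = 2, job_moderate = 3, job_vigorous = 4,
    household_light = 2.5, household_moderate = 3.5, household_vigorous = 4.5,
    active_transport = 4, motorized_transport = 1.5,
    eating = 1.8, sleeping = 0.9,
    residual_leisure = 1.5,
    personal_care_impute = 2, swimming_impute = 6,
    sedentary_ceiling = 1.8,
    moderate_lower = 3, moderate_upper = 6, vigorous_lower = 6,
    bout_min_minutes = 10
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    bad <- setdiff(names(overrides), names(x))
    if (length(bad)) {
      stop("unknown MET constant(s): ", paste(bad, collapse = ", "))
    }
    x[names(overrides)] <- lapply(overrides, as.numeric)
  }
  structure(x, class = "met_constants")
}

#' Minimum minutes of data for a valid monitoring day
#'
#' A monitoring day is valid when it holds at least 95% of a 24-hour
#' period of worn or imputed minute data.
#'
#' @return integer number of minutes (1368).
#' @export
valid_day_minutes <- function() {
  as.integer(round(0.95 * MINUTES_PER_DAY))
}

#' Write / read MET constants as a plain-text config
#'
#' Serializes the constant registry to a `key: value` YAML file, and reads
#' one back. A round trip reproduces the registry exactly.
#'
#' @param constants a `met_constants` object.
#' @param path file path.
#' @return `read_met_config` returns a `met_constants` object.
#' @export
write_met_config <- function(constants, path) {
  stopifnot(inherits(constants, "met_constants"))
  yaml::write_yaml(unclass(constants), path, precision = 15)
  invisible(path)
}

#' @rdname write_met_config
#' @export
read_met_config <- function(path) {
  met_constants(yaml::read_yaml(path))
}
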
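# Shared domain types: subjects, age groups, and the 20-parameter
# activity profile produced by both measurement paths.

#' Age group labels used for subgroup analyses
#' @export
AGE_GROUPS <- c("20-34", "35-49", "50-64")

#' The twenty activity parameters, in reporting order
#'
#' Times are hours per week; energy expenditures (`*_ee`, `total_ee`) are
#' METhours per week; `pal` (physical activity level) is dimensionless MET.
#' @export
PROFILE_PARAMETERS <- c(
  "pal", "total_ee", "moderate_pa", "vigorous_pa", "sedentary",
  "job_time", "job_ee", "sports_time", "sports_ee", "screen_time",
  "household_time", "household_ee",
  "active_transport_time", "active_transport_ee",
  "motorized_time", "motorized_ee",
  "eating_time", "eating_ee", "sleeping_time", "sleeping_ee"
)

#' Assign an adult age to its analysis age group
#'
#' Brackets are closed on both ends (20-34, 35-49, 50-64); ages are whole
#' years so the brackets partition 20..64.
#'
#' @param age_years integer vector of ages in years, each within 20..64.
#' @return character vector of age-group labels (see [AGE_GROUPS]).
#' @examples
#' age_group_of(c(34, 35, 64))
#' @export
age_group_of <- function(age_years) {
  if (!is.numeric(age_years) || any(is.na(age_years))) {
    stop("age_years must be numeric and non-missing")
  }
  if (any(age_years != floor(age_years))) {
    stop("age_years must be whole years")
  }
  if (any(age_years < 20 | age_years > 64)) {
    stop("age out of range: valid ages are 20 to 64 years")
  }
  AGE_GROUPS[findInterval(age_years, c(20, 35, 50))]
}

#' Construct a subject record
#'
#' @param subject_id identifier (coerced to character).
#' @param gender `"male"` or `"female"`.
#' @param age_years age in whole years, 20..64.
#' @return a list of class `subject` with a derived `age_group`.
#' @export
subject <- function(subject_id, gender, age_years) {
  gender <- match.arg(gender, c("male", "female"))
  structure(
    list(
      subject_id = as.character(subject_id),
      gender = gender,
      age_years = as.integer(age_years),
      age_group = age_group_of(age_years)
    ),
    class = "subject"
  )
}

#' Construct a 20-parameter activity profile
#'
#' The shared output type of both scoring paths: the questionnaire scorer
#' and the sensor-diary fusion both produce one profile per subject.
#' Validation enforces non-negative times bounded by the 168-hour week and
#' the identity `pal = total_ee / 168`.
#'
#' @param values named numeric vector or list holding all twenty
#'   parameters named as in [PROFILE_PARAMETERS].
#' @param validate check invariants (default `TRUE`).
#' @return named numeric vector of class `activity_profile`, ordered as
#'   [PROFILE_PARAMETERS].
#' @export
activity_profile <- function(values, validate = TRUE) {
  values <- unlist(values)
  missing <- setdiff(PROFILE_PARAMETERS, names(values))
  if (length(missing)) {
    stop("missing profile parameter(s): ", paste(missing, collapse = ", "))
  }
  x <- as.numeric(values[PROFILE_PARAMETERS])
  names(x) <- PROFILE_PARAMETERS
  if (validate) {
    times <- x[c("moderate_pa", "vigorous_pa", "sedentary", "job_time",
                 "sports_time", "screen_time", "household_time",
                 "active_transport_time", "motorized_time",
                 "eating_time", "sleeping_time")]
    if (any(times < -1e-9)) stop("activity times must be non-negative")
    if (any(times > HOURS_PER_WEEK + 1e-9)) {
      stop("activity times cannot exceed 168 hours per week")
    }
    if (abs(x[["pal"]] * HOURS_PER_WEEK - x[["total_ee"]]) >
        1e-9 * max(1, abs(x[["total_ee"]]))) {
      stop("profile violates pal = total_ee / 168")
    }
  }
  structure(x, class = "activity_profile")
}

# Bind a list of profiles (plus subjects) into one data.frame row per subject.
#' Combine per-subject activity profiles into a table
#'
#' @param profiles named list of `activity_profile` objects; names are
#'   subject ids.
#' @return data.frame with `subject_id` plus the twenty parameter columns.
#' @export
profile_table <- function(profiles) {
  stopifnot(length(profiles) > 0)
  m <- do.call(rbind, lapply(profiles, as.numeric))
  colnames(m) <- PROFILE_PARAMETERS
  ids <- names(profiles)
  if (is.null(ids)) ids <- as.character(seq_along(profiles))
  data.frame(subject_id = ids, m, row.names = NULL,
             stringsAsFactors = FALSE)
}
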
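# Plain-text (tab-delimited) input and output for the three data
# streams and the derived profiles. Missing MET values are written as
# empty fields.

#' Read / write minute-epoch MET streams
#'
#' Columns: `subject_id`, `minute_index` (0..10079), `met` (empty when
#' missing), `worn` (0/1).
#'
#' @param path tab-delimited file with a header row.
#' @return `read_minutes`: named list of per-subject data.frames.
#' @export
read_minutes <- function(path) {
  df <- utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "minute_index", "met") %in% names(df)))
  df$worn <- if ("worn" %in% names(df)) as.logical(df$worn) else !is.na(df$met)
  split(df[c("minute_index", "met", "worn")], df$subject_id)
}

#' @rdname read_minutes
#' @param streams named list of per-subject minute data.frames.
#' @export
write_minutes <- function(streams, path) {
  df <- do.call(rbind, lapply(names(streams), function(id) {
    cbind(subject_id = id, streams[[id]][c("minute_index", "met", "worn")])
  }))
  df$worn <- as.integer(df$worn)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write activity diaries
#'
#' Columns: `subject_id`, `start_minute`, `end_minute` (half-open
#' interval), `category`, `subcategory` (empty where not applicable).
#'
#' @param path tab-delimited file with a header row.
#' @return `read_diary`: named list of per-subject data.frames.
#' @export
read_diary <- function(path) {
  df <- utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "start_minute", "end_minute", "category")
                %in% names(df)))
  if (is.null(df$subcategory)) df$subcategory <- NA_character_
  split(df[c("start_minute", "end_minute", "category", "subcategory")],
        df$subject_id)
}

#' @rdname read_diary
#' @param diaries named list of per-subject diary data.frames.
#' @export
write_diary <- function(diaries, path) {
  df <- do.call(rbind, lapply(names(diaries), function(id) {
    cbind(subject_id = id,
          diaries[[id]][c("start_minute", "end_minute", "category",
                          "subcategory")])
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

# flat column order for questionnaire tables
.Q_NUMERIC_FIELDS <- c(
  "sitting_weekday_h", "sitting_weekend_h",
  "moderate_days", "moderate_h_per_day", "vigorous_days", "vigorous_h_per_day",
  "job_main_h", "job_main_pct_light", "job_main_pct_moderate",
  "job_main_pct_vigorous",
  "job_add_h", "job_add_pct_light", "job_add_pct_moderate",
  "job_add_pct_vigorous",
  "screen_weekday_h", "screen_weekend_h",
  "household_light_h", "household_moderate_h", "household_vigorous_h",
  "walk_commute_main_days", "walk_commute_main_h",
  "walk_commute_add_days", "walk_commute_add_h",
  "cycle_commute_main_days", "cycle_commute_main_h",
  "cycle_commute_add_days", "cycle_commute_add_h",
  "walk_leisure_weekday_h", "walk_leisure_weekend_h",
  "cycle_leisure_weekday_h", "cycle_leisure_weekend_h",
  "motor_commute_main_days", "motor_commute_main_h",
  "motor_commute_add_days", "motor_commute_add_h",
  "motor_leisure_weekday_h", "motor_leisure_weekend_h",
  "eating_h_per_day", "sleeping_h_per_night"
)

#' Read / write questionnaire tables
#'
#' One row per subject: `subject_id`, `gender`, `age_years`, the numeric
#' response fields of [questionnaire_record()], and up to three sports as
#' `sportK_name`, `sportK_met`, `sportK_h` (annualized weekly hours).
#'
#' @param path tab-delimited file with a header row.
#' @return `read_questionnaires`: named list of `questionnaire_record`s.
#' @export
read_questionnaires <- function(path) {
  df <- utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "gender", "age_years") %in% names(df)))
  out <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    args <- list(subject = subject(row$subject_id, row$gender, row$age_years))
    for (f in intersect(.Q_NUMERIC_FIELDS, names(df))) {
      v <- row[[f]]
      args[[f]] <- if (is.na(v)) 0 else v
    }
    sports <- list()
    for (k in 1:3) {
      nm <- row[[paste0("sport", k, "_name")]]
      if (!is.null(nm) && !is.na(nm) && nzchar(nm)) {
        sports[[length(sports) + 1]] <- list(
          name = nm,
          met_value = row[[paste0("sport", k, "_met")]],
          hours_per_week_annualized = row[[paste0("sport", k, "_h")]]
        )
      }
    }
    args$sports <- sports
    out[[row$subject_id]] <- do.call(questionnaire_record, args)
  }
  out
}

#' @rdname read_questionnaires
#' @param records named list of `questionnaire_record`s.
#' @export
write_questionnaires <- function(records, path) {
  rows <- lapply(records, function(r) {
    base <- data.frame(subject_id = r$subject$subject_id,
                       gender = r$subject$gender,
                       age_years = r$subject$age_years,
                       stringsAsFactors = FALSE)
    for (f in .Q_NUMERIC_FIELDS) base[[f]] <- r[[f]]
    for (k in 1:3) {
      s <- if (k <= length(r$sports)) r$sports[[k]] else NULL
      base[[paste0("sport", k, "_name")]] <- if (is.null(s)) NA else s$name
      base[[paste0("sport", k, "_met")]] <- if (is.null(s)) NA else s$met_value
      base[[paste0("sport", k, "_h")]] <-
        if (is.null(s)) NA else s$hours_per_week_annualized
    }
    base
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write / read activity-profile tables
#'
#' One row per subject: `subject_id` plus the twenty parameter columns in
#' reporting order.
#'
#' @param profiles data.frame from [profile_table()].
#' @param path tab-delimited file.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles[c("subject_id", PROFILE_PARAMETERS)], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a generated cohort as the three input files
#'
#' Emits `questionnaires.tsv`, `minutes.tsv` and `diary.tsv` in the
#' dialects consumed by [read_questionnaires()], [read_minutes()] and
#' [read_diary()], plus `generation.yml` logging the master seed.
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param seed master seed to log.
#' @return the directory, invisibly.
#' @export
write_cohort_files <- function(cohort, dir, seed = NA) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- vapply(cohort, function(s) s$subject$subject_id, "")
  write_questionnaires(stats::setNames(lapply(cohort, `[[`, "questionnaire"),
                                       ids),
                       file.path(dir, "questionnaires.tsv"))
  write_minutes(stats::setNames(lapply(cohort, `[[`, "minutes"), ids),
                file.path(dir, "minutes.tsv"))
  write_diary(stats::setNames(lapply(cohort, `[[`, "diary"), ids),
              file.path(dir, "diary.tsv"))
  yaml::write_yaml(list(n_subjects = length(cohort), master_seed = seed),
                   file.path(dir, "generation.yml"))
  invisible(dir)
}
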
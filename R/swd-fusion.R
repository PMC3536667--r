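# Fusion of a 7-day minute-epoch MET stream with an electronic activity
# diary: imputation of non-wear, wear-time validation, intensity bouts,
# domain aggregation and six-day weekly extrapolation.
#
# The week is indexed in minutes 0..10079 starting Monday 00:00; day d
# covers minutes [1440*d, 1440*(d+1)), so Saturday is day 5 and Sunday
# day 6.

# diary controlled vocabulary ------------------------------------------------

DIARY_CATEGORIES <- c("sleeping_resting", "personal_care", "eating_drinking",
                      "job", "leisure", "transport", "household")
DIARY_SUBCATEGORIES <- list(
  leisure = c("sports", "swimming", "tv", "computer", "other"),
  transport = c("walk", "bike", "motorized"),
  household = c("in_house", "garden")
)

# internal integer codes for fast per-minute work
.CODE_JOB <- 1L; .CODE_SPORTS <- 2L; .CODE_SCREEN <- 3L; .CODE_HOUSEHOLD <- 4L
.CODE_ACTIVE <- 5L; .CODE_MOTOR <- 6L; .CODE_EATING <- 7L; .CODE_SLEEP <- 8L
.CODE_PCARE <- 9L; .CODE_OTHER <- 10L; .CODE_SWIM <- 11L; .CODE_NONE <- 0L

# map one (category, subcategory) pair to its internal code
.diary_code <- function(category, subcategory) {
  if (is.na(subcategory)) subcategory <- ""
  switch(category,
    job = .CODE_JOB,
    sleeping_resting = .CODE_SLEEP,
    personal_care = .CODE_PCARE,
    eating_drinking = .CODE_EATING,
    leisure = switch(subcategory,
      sports = .CODE_SPORTS, swimming = .CODE_SWIM,
      tv = .CODE_SCREEN, computer = .CODE_SCREEN,
      other = .CODE_OTHER,
      stop("unknown leisure subcategory: ", subcategory)),
    transport = switch(subcategory,
      walk = .CODE_ACTIVE, bike = .CODE_ACTIVE, motorized = .CODE_MOTOR,
      stop("unknown transport subcategory: ", subcategory)),
    household = .CODE_HOUSEHOLD,
    stop("unknown diary category: ", category)
  )
}

# expand a diary to a per-minute code vector of length 10080, checking the
# diary invariants (bounds, ordering, non-overlap)
diary_minute_codes <- function(diary) {
  stopifnot(all(c("start_minute", "end_minute", "category") %in% names(diary)))
  if (!nrow(diary)) return(rep(.CODE_NONE, MINUTES_PER_WEEK))
  if (any(diary$start_minute >= diary$end_minute)) {
    stop("diary intervals must satisfy start < end")
  }
  if (any(diary$start_minute < 0) || any(diary$end_minute > MINUTES_PER_WEEK)) {
    stop("diary intervals must lie within minutes 0..10080")
  }
  o <- order(diary$start_minute)
  diary <- diary[o, , drop = FALSE]
  if (any(diary$start_minute[-1] < diary$end_minute[-nrow(diary)])) {
    stop("diary intervals overlap")
  }
  sub <- if ("subcategory" %in% names(diary)) diary$subcategory else
    rep(NA_character_, nrow(diary))
  per_entry <- mapply(.diary_code, diary$category, sub, USE.NAMES = FALSE)
  codes <- rep(.CODE_NONE, MINUTES_PER_WEEK)
  idx <- sequence(diary$end_minute - diary$start_minute,
                  from = diary$start_minute + 1L)
  codes[idx] <- rep(per_entry, diary$end_minute - diary$start_minute)
  codes
}

# normalize a minute-record data.frame into aligned week-long vectors
.week_vectors <- function(minutes) {
  stopifnot(all(c("minute_index", "met") %in% names(minutes)))
  if (anyDuplicated(minutes$minute_index)) {
    stop("minute_index must be unique per subject")
  }
  if (any(minutes$minute_index < 0 | minutes$minute_index >= MINUTES_PER_WEEK)) {
    stop("minute_index must lie within 0..10079")
  }
  met <- rep(NA_real_, MINUTES_PER_WEEK)
  worn <- rep(FALSE, MINUTES_PER_WEEK)
  i <- minutes$minute_index + 1L
  met[i] <- minutes$met
  if ("worn" %in% names(minutes)) worn[i] <- as.logical(minutes$worn)
  else worn[i] <- !is.na(minutes$met)
  if (any(!is.na(met) & met <= 0)) stop("MET values must be positive")
  list(met = met, worn = worn)
}

# ---- operations ----

#' Impute missing minutes from the diary
#'
#' Minutes without sensor data (non-wear) are filled where the diary
#' licenses it: minutes inside sleeping/resting intervals get the
#' subject's mean observed sleeping MET; personal-care minutes get the
#' constant 2 MET; swimming minutes the constant 6 MET. All other missing
#' minutes stay missing and count against day validity.
#'
#' @param minutes data.frame with `minute_index` (0..10079), `met`
#'   (`NA` when missing) and optional `worn`.
#' @param diary data.frame with `start_minute`, `end_minute`, `category`,
#'   `subcategory`.
#' @param constants [met_constants()].
#' @return `minutes` with one row per week minute and imputed `met`; the
#'   logical column `imputed` marks filled values.
#' @export
impute_missing <- function(minutes, diary, constants = met_constants()) {
  wv <- .week_vectors(minutes)
  codes <- diary_minute_codes(diary)
  met <- wv$met
  miss <- is.na(met)
  fill_sleep <- miss & codes == .CODE_SLEEP
  if (any(fill_sleep)) {
    obs <- met[!miss & codes == .CODE_SLEEP]
    if (!length(obs)) {
      stop("cannot impute sleep: no observed sleeping minutes for this subject")
    }
    met[fill_sleep] <- mean(obs)
  }
  met[miss & codes == .CODE_PCARE] <- constants$personal_care_impute
  met[miss & codes == .CODE_SWIM] <- constants$swimming_impute
  data.frame(minute_index = 0:(MINUTES_PER_WEEK - 1L),
             met = met, worn = wv$worn,
             imputed = miss & !is.na(met))
}

#' Wear-time validity report for one monitored week
#'
#' A day is valid with at least 1368 minutes of data (95% of 24 h;
#' imputed minutes count as data). A subject is valid with at least six
#' valid days including the Saturday and the Sunday.
#'
#' @param minutes minute data.frame (ideally after [impute_missing()]).
#' @return list of class `validity_report`: `day_minutes` (length 7,
#'   Monday first), `day_valid`, `n_valid_days`, `weekend_complete`,
#'   `subject_valid`.
#' @export
validate_week <- function(minutes) {
  met <- .week_vectors(minutes)$met
  day_minutes <- colSums(!is.na(matrix(met, nrow = MINUTES_PER_DAY)))
  day_valid <- day_minutes >= valid_day_minutes()
  weekend_complete <- day_valid[6] && day_valid[7]
  structure(list(
    day_minutes = as.integer(day_minutes),
    day_valid = day_valid,
    n_valid_days = sum(day_valid),
    weekend_complete = weekend_complete,
    subject_valid = sum(day_valid) >= 6 && weekend_complete
  ), class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  days <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  cat("week validity:", if (x$subject_valid) "VALID" else "INVALID",
      sprintf("(%d valid days%s)\n", x$n_valid_days,
              if (x$weekend_complete) ", weekend complete"
              else ", weekend incomplete"))
  cat(paste(sprintf("%s %d%s", days, x$day_minutes,
                    ifelse(x$day_valid, "", "*")), collapse = "  "), "\n")
  invisible(x)
}

# logical mask of minutes that belong to qualifying bouts
bout_minutes <- function(met, lower, upper = Inf, min_len = 10L) {
  in_band <- !is.na(met) & met >= lower & met < upper
  r <- rle(in_band)
  keep <- r$values & r$lengths >= min_len
  rep(keep, r$lengths)
}

#' Bouted time in an intensity band
#'
#' Sums maximal runs of at least `min_len` consecutive minutes whose MET
#' lies in `[lower, upper)`. Runs are strict: a single minute below the
#' band (or missing) terminates the run. Bouts may span midnight — the
#' scan is over the continuous week-long series.
#'
#' @param met numeric MET series (minute epochs; `NA` = missing).
#' @param lower,upper intensity band bounds (upper exclusive, may be
#'   `Inf`).
#' @param min_len minimum bout length in minutes (default 10).
#' @return hours accumulated in qualifying bouts.
#' @export
detect_bouts <- function(met, lower, upper = Inf, min_len = 10L) {
  stopifnot(lower < upper, min_len >= 1)
  sum(bout_minutes(met, lower, upper, min_len)) / 60
}

#' Sedentary time: low-intensity awake minutes
#'
#' Counts minutes at or below the sedentary ceiling (1.8 MET) that are
#' not inside diary sleeping/resting intervals.
#'
#' @param minutes minute data.frame (after imputation).
#' @param diary diary data.frame.
#' @param constants [met_constants()].
#' @return hours per week.
#' @export
sedentary_time <- function(minutes, diary, constants = met_constants()) {
  met <- .week_vectors(minutes)$met
  codes <- diary_minute_codes(diary)
  sum(!is.na(met) & met <= constants$sedentary_ceiling &
        codes != .CODE_SLEEP) / 60
}

#' Per-domain time and energy expenditure
#'
#' Time comes from the diary interval lengths; energy expenditure is the
#' sum of minute MET values inside the domain's intervals, divided by 60.
#' Screen = TV plus leisure computer; household = in-house plus garden;
#' active transport = on foot plus by bike; sports includes swimming.
#' Minutes outside the eight reported domains (personal care, other
#' leisure, uncovered) are returned as `uncategorized` so that domain
#' totals plus the uncategorized remainder reproduce the week totals.
#'
#' @param minutes minute data.frame (after imputation).
#' @param diary diary data.frame.
#' @return data.frame with columns `domain`, `time` (h/week), `ee`
#'   (METh/week).
#' @export
domain_aggregate <- function(minutes, diary) {
  met <- .week_vectors(minutes)$met
  codes <- diary_minute_codes(diary)
  .domain_aggregate_vec(met, codes)
}

.DOMAIN_CODES <- list(
  job = .CODE_JOB, sports = c(.CODE_SPORTS, .CODE_SWIM),
  screen = .CODE_SCREEN, household = .CODE_HOUSEHOLD,
  active_transport = .CODE_ACTIVE, motorized = .CODE_MOTOR,
  eating = .CODE_EATING, sleeping = .CODE_SLEEP,
  uncategorized = c(.CODE_PCARE, .CODE_OTHER, .CODE_NONE)
)

.domain_aggregate_vec <- function(met, codes) {
  met0 <- ifelse(is.na(met), 0, met)
  # counts and MET sums per code in one pass
  n_by_code <- tabulate(codes + 1L, nbins = 12L)
  # restrict time to diary-covered minutes except the uncovered bucket,
  # which only counts minutes that carry data
  n_by_code[1L] <- sum(codes == .CODE_NONE & !is.na(met))
  ee_by_code <- vapply(0:11, function(cd) sum(met0[codes == cd]), 0)
  data.frame(
    domain = names(.DOMAIN_CODES),
    time = vapply(.DOMAIN_CODES, function(cd) sum(n_by_code[cd + 1L]), 0) / 60,
    ee = vapply(.DOMAIN_CODES, function(cd) sum(ee_by_code[cd + 1L]), 0) / 60,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Week totals: energy expenditure and activity level
#'
#' Total EE is the sum of minute MET values over the entire week divided
#' by 60; PAL is the average minute MET.
#'
#' @param minutes minute data.frame (after imputation).
#' @return named numeric: `total_ee` (METh/week), `pal` (MET).
#' @export
totals <- function(minutes) {
  met <- .week_vectors(minutes)$met
  c(total_ee = sum(met, na.rm = TRUE) / 60, pal = mean(met, na.rm = TRUE))
}

#' Weekly value from six valid days
#'
#' For subjects with exactly six valid days (four valid weekdays plus
#' Saturday and Sunday) the weekly value of a per-day-decomposable
#' parameter is `mean(valid weekdays) * 5 + Saturday + Sunday`. With all
#' seven days valid the plain weekly sum is returned, which the formula
#' reduces to when every weekday is equal.
#'
#' @param per_day numeric length 7, Monday first.
#' @param valid_mask logical length 7 marking valid days.
#' @return weekly value.
#' @export
weekly_extrapolate <- function(per_day, valid_mask) {
  stopifnot(length(per_day) == 7, length(valid_mask) == 7)
  if (all(valid_mask)) return(sum(per_day))
  if (sum(valid_mask) < 6 || !valid_mask[6] || !valid_mask[7]) {
    stop("weekly extrapolation needs >= 6 valid days including Saturday and Sunday")
  }
  wk <- valid_mask[1:5]
  mean(per_day[1:5][wk]) * 5 + per_day[6] + per_day[7]
}

#' Fuse a minute MET stream and diary into an activity profile
#'
#' Runs the full objective pipeline: non-wear imputation, wear-time
#' validation (invalid subjects are rejected), bout detection on the
#' continuous series, sedentary and domain aggregation, and — for
#' subjects with six valid days — weekly extrapolation of every per-day
#' decomposable parameter. PAL is the extrapolated total EE divided by
#' 168.
#'
#' @param minutes minute data.frame (`minute_index`, `met`, `worn`).
#' @param diary diary data.frame.
#' @param constants [met_constants()].
#' @param strict reject weeks with worn minutes not covered by any diary
#'   entry (default `FALSE`: such minutes enter totals and intensity
#'   classes but no domain).
#' @return an [activity_profile()].
#' @export
fuse <- function(minutes, diary, constants = met_constants(), strict = FALSE) {
  imp <- impute_missing(minutes, diary, constants)
  met <- imp$met
  codes <- diary_minute_codes(diary)
  if (strict && any(!is.na(met) & codes == .CODE_NONE)) {
    stop("strict mode: worn minutes not covered by any diary entry")
  }
  rep_v <- validate_week(imp)
  if (!rep_v$subject_valid) {
    stop("subject is not valid: needs >= 6 valid days (1368+ min) ",
         "including Saturday and Sunday")
  }

  has <- !is.na(met)
  met0 <- ifelse(has, met, 0)

  per_day_sum <- function(mask) {
    colSums(matrix(mask, nrow = MINUTES_PER_DAY))
  }
  per_day_ee <- function(mask) {
    colSums(matrix(met0 * mask, nrow = MINUTES_PER_DAY))
  }

  mod_mask <- bout_minutes(met, constants$moderate_lower,
                           constants$moderate_upper, constants$bout_min_minutes)
  vig_mask <- bout_minutes(met, constants$vigorous_lower, Inf,
                           constants$bout_min_minutes)
  sed_mask <- has & met <= constants$sedentary_ceiling & codes != .CODE_SLEEP

  dom_time_mask <- function(cds) {
    if (identical(cds, .CODE_NONE)) codes == .CODE_NONE & has
    else codes %in% cds
  }

  # per-day values (minutes or MET-minutes) for every decomposable parameter
  pd <- list(
    moderate_pa = per_day_sum(mod_mask),
    vigorous_pa = per_day_sum(vig_mask),
    sedentary = per_day_sum(sed_mask),
    total_ee = per_day_ee(has)
  )
  for (d in setdiff(names(.DOMAIN_CODES), "uncategorized")) {
    mask <- dom_time_mask(.DOMAIN_CODES[[d]])
    pd[[paste0(d, "_time")]] <- per_day_sum(mask)
    pd[[paste0(d, "_ee")]] <- per_day_ee(mask & has)
  }

  weekly <- vapply(pd, weekly_extrapolate, 0, valid_mask = rep_v$day_valid) / 60
  total_ee <- weekly[["total_ee"]]

  activity_profile(c(
    pal = total_ee / HOURS_PER_WEEK,
    total_ee = total_ee,
    moderate_pa = weekly[["moderate_pa"]],
    vigorous_pa = weekly[["vigorous_pa"]],
    sedentary = weekly[["sedentary"]],
    job_time = weekly[["job_time"]], job_ee = weekly[["job_ee"]],
    sports_time = weekly[["sports_time"]], sports_ee = weekly[["sports_ee"]],
    screen_time = weekly[["screen_time"]],
    household_time = weekly[["household_time"]],
    household_ee = weekly[["household_ee"]],
    active_transport_time = weekly[["active_transport_time"]],
    active_transport_ee = weekly[["active_transport_ee"]],
    motorized_time = weekly[["motorized_time"]],
    motorized_ee = weekly[["motorized_ee"]],
    eating_time = weekly[["eating_time"]], eating_ee = weekly[["eating_ee"]],
    sleeping_time = weekly[["sleeping_time"]],
    sleeping_ee = weekly[["sleeping_ee"]]
  ))
}
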
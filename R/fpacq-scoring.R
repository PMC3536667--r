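# Questionnaire scoring: converts one questionnaire record into the
# twenty weekly activity parameters.
#
# Weekly totals for daily questions use the usual-week weighting of
# 5 weekdays + 2 weekend days; occupational, household and sports
# questions are already weekly.

#' Construct a questionnaire record
#'
#' One subject's responses to the physical-activity questionnaire, already
#' converted to numeric hours/days (see [response_bands()] for the banded
#' answer conversion). All durations default to zero, so partial records
#' describe respondents who skip a domain.
#'
#' @param subject optional [subject()] object.
#' @param sitting_weekday_h,sitting_weekend_h usual sitting hours per
#'   weekday / weekend day.
#' @param moderate_days,moderate_h_per_day days per week with bouted
#'   moderate activity (0..7) and usual hours on such a day.
#' @param vigorous_days,vigorous_h_per_day same, for vigorous activity.
#' @param job_main_h,job_add_h weekly hours of main / additional occupation.
#' @param job_main_pct_light,job_main_pct_moderate,job_main_pct_vigorous
#'   fractions of main-occupation time at each intensity; must sum to 1
#'   when `job_main_h > 0`.
#' @param job_add_pct_light,job_add_pct_moderate,job_add_pct_vigorous
#'   fractions for the additional occupation.
#' @param sports list of up to three entries from [sport_entry()].
#' @param screen_weekday_h,screen_weekend_h screen hours per weekday /
#'   weekend day.
#' @param household_light_h,household_moderate_h,household_vigorous_h
#'   weekly hours of light / moderate / vigorous home and garden chores.
#' @param walk_commute_main_days,walk_commute_main_h days per week and
#'   hours per such day walking to and from the main occupation.
#' @param walk_commute_add_days,walk_commute_add_h same for the additional
#'   occupation.
#' @param cycle_commute_main_days,cycle_commute_main_h,cycle_commute_add_days,cycle_commute_add_h
#'   cycling commute pattern, main and additional occupation.
#' @param walk_leisure_weekday_h,walk_leisure_weekend_h leisure-time
#'   transport on foot, hours per weekday / weekend day.
#' @param cycle_leisure_weekday_h,cycle_leisure_weekend_h leisure-time
#'   transport by bike.
#' @param motor_commute_main_days,motor_commute_main_h,motor_commute_add_days,motor_commute_add_h
#'   motorized commute pattern.
#' @param motor_leisure_weekday_h,motor_leisure_weekend_h leisure-time
#'   motorized transport.
#' @param eating_h_per_day usual daily eating hours.
#' @param sleeping_h_per_night usual nightly sleeping hours.
#' @return list of class `questionnaire_record`.
#' @export
questionnaire_record <- function(subject = NULL,
                                 sitting_weekday_h = 0, sitting_weekend_h = 0,
                                 moderate_days = 0, moderate_h_per_day = 0,
                                 vigorous_days = 0, vigorous_h_per_day = 0,
                                 job_main_h = 0,
                                 job_main_pct_light = 1,
                                 job_main_pct_moderate = 0,
                                 job_main_pct_vigorous = 0,
                                 job_add_h = 0,
                                 job_add_pct_light = 1,
                                 job_add_pct_moderate = 0,
                                 job_add_pct_vigorous = 0,
                                 sports = list(),
                                 screen_weekday_h = 0, screen_weekend_h = 0,
                                 household_light_h = 0,
                                 household_moderate_h = 0,
                                 household_vigorous_h = 0,
                                 walk_commute_main_days = 0, walk_commute_main_h = 0,
                                 walk_commute_add_days = 0, walk_commute_add_h = 0,
                                 cycle_commute_main_days = 0, cycle_commute_main_h = 0,
                                 cycle_commute_add_days = 0, cycle_commute_add_h = 0,
                                 walk_leisure_weekday_h = 0, walk_leisure_weekend_h = 0,
                                 cycle_leisure_weekday_h = 0, cycle_leisure_weekend_h = 0,
                                 motor_commute_main_days = 0, motor_commute_main_h = 0,
                                 motor_commute_add_days = 0, motor_commute_add_h = 0,
                                 motor_leisure_weekday_h = 0, motor_leisure_weekend_h = 0,
                                 eating_h_per_day = 0,
                                 sleeping_h_per_night = 0) {
  rec <- as.list(environment())
  num <- rec[setdiff(names(rec), c("subject", "sports"))]
  if (any(unlist(num) < 0)) stop("questionnaire durations must be non-negative")
  for (f in grep("_days$", names(num), value = TRUE)) {
    if (rec[[f]] > 7) stop(f, " cannot exceed 7 days per week")
  }
  if (length(sports) > 3) stop("at most 3 sports entries are allowed")
  for (occ in c("main", "add")) {
    h <- rec[[paste0("job_", occ, "_h")]]
    s <- rec[[paste0("job_", occ, "_pct_light")]] +
      rec[[paste0("job_", occ, "_pct_moderate")]] +
      rec[[paste0("job_", occ, "_pct_vigorous")]]
    if (h > 0 && abs(s - 1) > 1e-9) {
      stop("intensity fractions for the ", occ,
           " occupation must sum to 1 (got ", format(s), ")")
    }
  }
  structure(rec, class = "questionnaire_record")
}

#' Construct a sports entry
#'
#' Annualizes the in-season weekly duration: the reported hours per week
#' during the practicing months are averaged over twelve months. The MET
#' value is looked up in the shipped compendium subset when a known sport
#' name is given; unknown sports require an explicit `met_value`.
#'
#' @param name sport name (used for the compendium lookup).
#' @param hours_per_week hours per week while the sport is practiced.
#' @param months_per_year months per year of practice (1..12).
#' @param met_value MET intensity; defaults to the compendium value.
#' @return list with `name`, `met_value` and annualized
#'   `hours_per_week_annualized`.
#' @export
sport_entry <- function(name, hours_per_week, months_per_year = 12,
                        met_value = NULL) {
  stopifnot(hours_per_week >= 0, months_per_year >= 1, months_per_year <= 12)
  if (is.null(met_value)) {
    comp <- sports_compendium()
    i <- match(tolower(name), comp$name)
    if (is.na(i)) {
      stop("sport '", name, "' is not in the shipped compendium subset; ",
           "supply met_value explicitly")
    }
    met_value <- comp$met[i]
  }
  if (met_value <= 0) stop("met_value must be positive")
  list(name = name, met_value = met_value,
       hours_per_week_annualized = hours_per_week * months_per_year / 12)
}

#' Shipped MET compendium subset for named sports
#'
#' @return data.frame with columns `name`, `met`.
#' @export
sports_compendium <- function() {
  path <- system.file("extdata", "sports_met.csv", package = "actagree")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# ---- individual scoring operations (weekly parameters) ----

#' Weekly sedentary time from daily sitting questions
#'
#' @param sitting_weekday_h,sitting_weekend_h sitting hours per weekday /
#'   weekend day.
#' @return hours per week: `weekday * 5 + weekend * 2`.
#' @export
score_sedentary <- function(sitting_weekday_h, sitting_weekend_h) {
  if (sitting_weekday_h < 0 || sitting_weekend_h < 0) {
    stop("sitting hours must be non-negative")
  }
  sitting_weekday_h * 5 + sitting_weekend_h * 2
}

#' Weekly bouted activity from days-times-duration questions
#'
#' Used for both the moderate and the vigorous activity items.
#'
#' @param days days per week with such activity (0..7).
#' @param h_per_day usual hours on one of those days.
#' @return hours per week: `days * h_per_day`.
#' @export
score_bouted_pa <- function(days, h_per_day) {
  if (days < 0 || days > 7) stop("days must be within 0..7")
  if (h_per_day < 0) stop("h_per_day must be non-negative")
  days * h_per_day
}

#' Occupational time and energy expenditure
#'
#' Each occupation's weekly hours are split into light / moderate /
#' vigorous fractions scored at 2 / 3 / 4 MET.
#'
#' @param record a [questionnaire_record()].
#' @param constants [met_constants()].
#' @return named numeric: `job_time` (h/week), `job_ee` (METh/week).
#' @export
score_job <- function(record, constants = met_constants()) {
  ee <- 0
  for (occ in c("main", "add")) {
    h <- record[[paste0("job_", occ, "_h")]]
    if (h > 0) {
      s <- record[[paste0("job_", occ, "_pct_light")]] +
        record[[paste0("job_", occ, "_pct_moderate")]] +
        record[[paste0("job_", occ, "_pct_vigorous")]]
      if (abs(s - 1) > 1e-9) {
        stop("intensity fractions for the ", occ, " occupation must sum to 1")
      }
    }
    ee <- ee + h * (record[[paste0("job_", occ, "_pct_light")]] * constants$job_light +
                    record[[paste0("job_", occ, "_pct_moderate")]] * constants$job_moderate +
                    record[[paste0("job_", occ, "_pct_vigorous")]] * constants$job_vigorous)
  }
  c(job_time = record$job_main_h + record$job_add_h, job_ee = ee)
}

#' Sports time and energy expenditure
#'
#' @param sports list of up to three [sport_entry()] items.
#' @return named numeric: `sports_time`, `sports_ee`.
#' @export
score_sports <- function(sports) {
  if (length(sports) > 3) stop("at most 3 sports entries are allowed")
  time <- 0
  ee <- 0
  for (s in sports) {
    if (s$met_value <= 0) stop("sport MET values must be positive")
    time <- time + s$hours_per_week_annualized
    ee <- ee + s$hours_per_week_annualized * s$met_value
  }
  c(sports_time = time, sports_ee = ee)
}

#' Household-chore time and energy expenditure
#'
#' Light / moderate / vigorous home and garden chores at 2.5 / 3.5 / 4.5
#' MET.
#'
#' @param light_h,moderate_h,vigorous_h weekly hours per intensity.
#' @param constants [met_constants()].
#' @return named numeric: `household_time`, `household_ee`.
#' @export
score_household <- function(light_h, moderate_h, vigorous_h,
                            constants = met_constants()) {
  if (min(light_h, moderate_h, vigorous_h) < 0) {
    stop("household hours must be non-negative")
  }
  c(household_time = light_h + moderate_h + vigorous_h,
    household_ee = light_h * constants$household_light +
      moderate_h * constants$household_moderate +
      vigorous_h * constants$household_vigorous)
}

#' Transport time and energy expenditure
#'
#' Active transport (walking and cycling, commuting plus leisure) is
#' scored at 4 MET; motorized transport at 1.5 MET. Commute items are
#' days-per-week times hours-per-day; leisure items are per-weekday /
#' per-weekend-day hours weighted 5 and 2.
#'
#' @param record a [questionnaire_record()].
#' @param constants [met_constants()].
#' @return named numeric: `active_transport_time`, `active_transport_ee`,
#'   `motorized_time`, `motorized_ee`.
#' @export
score_transport <- function(record, constants = met_constants()) {
  active_time <-
    record$walk_commute_main_days * record$walk_commute_main_h +
    record$walk_commute_add_days * record$walk_commute_add_h +
    record$cycle_commute_main_days * record$cycle_commute_main_h +
    record$cycle_commute_add_days * record$cycle_commute_add_h +
    (record$walk_leisure_weekday_h + record$cycle_leisure_weekday_h) * 5 +
    (record$walk_leisure_weekend_h + record$cycle_leisure_weekend_h) * 2
  motor_time <-
    record$motor_commute_main_days * record$motor_commute_main_h +
    record$motor_commute_add_days * record$motor_commute_add_h +
    record$motor_leisure_weekday_h * 5 +
    record$motor_leisure_weekend_h * 2
  if (active_time < 0 || motor_time < 0) {
    stop("transport durations must be non-negative")
  }
  c(active_transport_time = active_time,
    active_transport_ee = active_time * constants$active_transport,
    motorized_time = motor_time,
    motorized_ee = motor_time * constants$motorized_transport)
}

#' Screen, eating and sleeping parameters
#'
#' Screen time is the 5/2-weighted weekly sum of the weekday and weekend
#' questions; eating and sleeping scale the daily/nightly answer by 7 and
#' are scored at 1.8 and 0.9 MET.
#'
#' @param weekday_h,weekend_h screen hours per weekday / weekend day.
#' @return `score_screen`: hours per week.
#' @export
score_screen <- function(weekday_h, weekend_h) {
  if (weekday_h < 0 || weekend_h < 0) stop("screen hours must be non-negative")
  weekday_h * 5 + weekend_h * 2
}

#' @rdname score_screen
#' @param h_per_day usual daily eating hours.
#' @param constants [met_constants()].
#' @export
score_eating <- function(h_per_day, constants = met_constants()) {
  if (h_per_day < 0) stop("eating hours must be non-negative")
  time <- h_per_day * 7
  c(eating_time = time, eating_ee = time * constants$eating)
}

#' @rdname score_screen
#' @param h_per_night usual nightly sleeping hours.
#' @export
score_sleeping <- function(h_per_night, constants = met_constants()) {
  if (h_per_night < 0) stop("sleeping hours must be non-negative")
  time <- h_per_night * 7
  c(sleeping_time = time, sleeping_ee = time * constants$sleeping)
}

#' Total weekly energy expenditure and physical activity level
#'
#' The remaining inactive leisure time (168 hours minus the seven
#' time-accounted domains: job, sports, household chores, active and
#' motorized transport, eating, sleeping) is scored at the residual MET of
#' 1.5; total EE is the sum of the seven domain EEs plus this residual
#' term, and PAL is total EE divided by 168.
#'
#' @param domain_times named numeric with `job_time`, `sports_time`,
#'   `household_time`, `active_transport_time`, `motorized_time`,
#'   `eating_time`, `sleeping_time` (hours/week).
#' @param domain_ees named numeric with the corresponding `*_ee` values.
#' @param constants [met_constants()].
#' @param clamp_residual when reported domain times sum past 168 h, clamp
#'   the residual at zero with a warning (`TRUE`, default) or reject the
#'   record (`FALSE`).
#' @return named numeric: `total_ee`, `pal`, `residual_time`.
#' @export
score_total <- function(domain_times, domain_ees,
                        constants = met_constants(),
                        clamp_residual = TRUE) {
  needed <- c("job_time", "sports_time", "household_time",
              "active_transport_time", "motorized_time",
              "eating_time", "sleeping_time")
  stopifnot(all(needed %in% names(domain_times)))
  residual <- HOURS_PER_WEEK - sum(domain_times[needed])
  if (residual < -1e-9) {
    if (!clamp_residual) {
      stop("reported domain times exceed 168 hours per week: ",
           paste(sprintf("%s=%.2f", needed, domain_times[needed]),
                 collapse = ", "))
    }
    warning(sprintf(
      "domain times sum to %.2f h > 168 h; residual leisure clamped at 0",
      sum(domain_times[needed])))
    residual <- 0
  }
  residual <- max(residual, 0)
  total <- sum(domain_ees) + residual * constants$residual_leisure
  c(total_ee = total, pal = total / HOURS_PER_WEEK, residual_time = residual)
}

#' Score a full questionnaire record into an activity profile
#'
#' Pure composition of the per-domain scoring operations; idempotent and a
#' pure function of the record.
#'
#' @param record a [questionnaire_record()].
#' @param constants [met_constants()].
#' @param clamp_residual see [score_total()].
#' @return an [activity_profile()].
#' @export
score_all <- function(record, constants = met_constants(),
                      clamp_residual = TRUE) {
  stopifnot(inherits(record, "questionnaire_record"))
  job <- score_job(record, constants)
  sp <- score_sports(record$sports)
  hh <- score_household(record$household_light_h, record$household_moderate_h,
                        record$household_vigorous_h, constants)
  tr <- score_transport(record, constants)
  eat <- score_eating(record$eating_h_per_day, constants)
  slp <- score_sleeping(record$sleeping_h_per_night, constants)
  times <- c(job["job_time"], sp["sports_time"], hh["household_time"],
             tr["active_transport_time"], tr["motorized_time"],
             eat["eating_time"], slp["sleeping_time"])
  ees <- c(job["job_ee"], sp["sports_ee"], hh["household_ee"],
           tr["active_transport_ee"], tr["motorized_ee"],
           eat["eating_ee"], slp["sleeping_ee"])
  tot <- score_total(times, ees, constants, clamp_residual)
  activity_profile(c(
    pal = unname(tot["pal"]), total_ee = unname(tot["total_ee"]),
    moderate_pa = score_bouted_pa(record$moderate_days, record$moderate_h_per_day),
    vigorous_pa = score_bouted_pa(record$vigorous_days, record$vigorous_h_per_day),
    sedentary = score_sedentary(record$sitting_weekday_h, record$sitting_weekend_h),
    job, sp,
    screen_time = score_screen(record$screen_weekday_h, record$screen_weekend_h),
    hh, tr, eat, slp
  ))
}

# ---- banded responses ----

#' Numeric conversion table for banded questionnaire answers
#'
#' The questionnaire presents many items as ordered response bands (for
#' example sitting time from under 30 minutes to 10 or more hours per
#' day). This table maps each band to a single number: the band midpoint,
#' with open-ended top bands valued at their stated bound. The table is
#' data, not code — edit the shipped CSV (or pass another file) to use a
#' different convention.
#'
#' @param path CSV with columns `item`, `lower`, `upper`, `value`.
#' @return data.frame of bands, strictly increasing within each item.
#' @export
response_bands <- function(path = system.file("extdata", "response_bands.csv",
                                              package = "actagree")) {
  bands <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("item", "lower", "upper", "value") %in% names(bands)))
  for (it in unique(bands$item)) {
    b <- bands[bands$item == it, ]
    if (any(diff(b$value) <= 0) || any(b$lower >= b$upper)) {
      stop("response bands for item '", it, "' are not strictly increasing")
    }
  }
  bands
}

#' Snap a continuous answer to its response-band value
#'
#' @param item band item name (see the shipped `response_bands.csv`).
#' @param x numeric answer(s) on the item's natural scale.
#' @param bands band table from [response_bands()].
#' @return numeric: the value of the band containing each `x` (values
#'   below the first band clamp to it; at or above the last lower bound,
#'   to the last).
#' @export
apply_band <- function(item, x, bands = response_bands()) {
  b <- bands[bands$item == item, ]
  if (!nrow(b)) stop("no response bands defined for item '", item, "'")
  i <- findInterval(x, b$lower)
  i[i < 1] <- 1
  i[i > nrow(b)] <- nrow(b)
  b$value[i]
}
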
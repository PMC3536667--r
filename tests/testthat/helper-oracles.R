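# Independent brute-force reimplementations used as oracles. These are
# deliberately naive (explicit loops, no shared helpers with the package)
# so they check the vectorized implementations from a different angle.

# explicit run scan for bouted time in [lower, upper)
oracle_bouts_hours <- function(met, lower, upper = Inf, min_len = 10) {
  total <- 0
  run <- 0
  for (i in seq_along(met)) {
    ok <- !is.na(met[i]) && met[i] >= lower && met[i] < upper
    if (ok) {
      run <- run + 1
    } else {
      if (run >= min_len) total <- total + run
      run <- 0
    }
  }
  if (run >= min_len) total <- total + run
  total / 60
}

# straight-line questionnaire arithmetic, written directly from the
# per-parameter formulas
oracle_score <- function(r) {
  sed <- r$sitting_weekday_h * 5 + r$sitting_weekend_h * 2
  mod <- r$moderate_days * r$moderate_h_per_day
  vig <- r$vigorous_days * r$vigorous_h_per_day
  job_time <- r$job_main_h + r$job_add_h
  job_ee <- r$job_main_h * (r$job_main_pct_light * 2 +
                              r$job_main_pct_moderate * 3 +
                              r$job_main_pct_vigorous * 4) +
    r$job_add_h * (r$job_add_pct_light * 2 + r$job_add_pct_moderate * 3 +
                     r$job_add_pct_vigorous * 4)
  sports_time <- 0
  sports_ee <- 0
  for (s in r$sports) {
    sports_time <- sports_time + s$hours_per_week_annualized
    sports_ee <- sports_ee + s$hours_per_week_annualized * s$met_value
  }
  screen <- r$screen_weekday_h * 5 + r$screen_weekend_h * 2
  hh_time <- r$household_light_h + r$household_moderate_h + r$household_vigorous_h
  hh_ee <- r$household_light_h * 2.5 + r$household_moderate_h * 3.5 +
    r$household_vigorous_h * 4.5
  at <- r$walk_commute_main_days * r$walk_commute_main_h +
    r$walk_commute_add_days * r$walk_commute_add_h +
    r$cycle_commute_main_days * r$cycle_commute_main_h +
    r$cycle_commute_add_days * r$cycle_commute_add_h +
    (r$walk_leisure_weekday_h + r$cycle_leisure_weekday_h) * 5 +
    (r$walk_leisure_weekend_h + r$cycle_leisure_weekend_h) * 2
  mt <- r$motor_commute_main_days * r$motor_commute_main_h +
    r$motor_commute_add_days * r$motor_commute_add_h +
    r$motor_leisure_weekday_h * 5 + r$motor_leisure_weekend_h * 2
  eat_time <- r$eating_h_per_day * 7
  sleep_time <- r$sleeping_h_per_night * 7
  residual <- max(0, 168 - job_time - sports_time - hh_time - at - mt -
                    eat_time - sleep_time)
  total <- job_ee + sports_ee + hh_ee + at * 4 + mt * 1.5 +
    eat_time * 1.8 + sleep_time * 0.9 + residual * 1.5
  c(pal = total / 168, total_ee = total, moderate_pa = mod,
    vigorous_pa = vig, sedentary = sed,
    job_time = job_time, job_ee = job_ee,
    sports_time = sports_time, sports_ee = sports_ee, screen_time = screen,
    household_time = hh_time, household_ee = hh_ee,
    active_transport_time = at, active_transport_ee = at * 4,
    motorized_time = mt, motorized_ee = mt * 1.5,
    eating_time = eat_time, eating_ee = eat_time * 1.8,
    sleeping_time = sleep_time, sleeping_ee = sleep_time * 0.9)
}

# per-minute loop aggregation of time and EE by diary domain
oracle_domain <- function(met, diary) {
  dom_of <- function(category, subcategory) {
    if (category == "job") return("job")
    if (category == "sleeping_resting") return("sleeping")
    if (category == "eating_drinking") return("eating")
    if (category == "household") return("household")
    if (category == "personal_care") return("uncategorized")
    if (category == "leisure") {
      if (subcategory %in% c("sports", "swimming")) return("sports")
      if (subcategory %in% c("tv", "computer")) return("screen")
      return("uncategorized")
    }
    if (category == "transport") {
      if (subcategory %in% c("walk", "bike")) return("active_transport")
      return("motorized")
    }
    stop("bad category")
  }
  doms <- c("job", "sports", "screen", "household", "active_transport",
            "motorized", "eating", "sleeping", "uncategorized")
  time <- stats::setNames(numeric(9), doms)
  ee <- stats::setNames(numeric(9), doms)
  covered <- rep(NA_character_, length(met))
  for (i in seq_len(nrow(diary))) {
    d <- dom_of(diary$category[i], diary$subcategory[i])
    for (m in (diary$start_minute[i] + 1):diary$end_minute[i]) covered[m] <- d
  }
  for (m in seq_along(met)) {
    d <- covered[m]
    if (is.na(d)) {
      if (!is.na(met[m])) {
        time["uncategorized"] <- time["uncategorized"] + 1
        ee["uncategorized"] <- ee["uncategorized"] + met[m]
      }
    } else {
      time[d] <- time[d] + 1
      if (!is.na(met[m])) ee[d] <- ee[d] + met[m]
    }
  }
  list(time = time / 60, ee = ee / 60)
}

# random questionnaire record with all domains active
random_record <- function() {
  sports <- list()
  for (k in seq_len(sample(0:3, 1))) {
    sports[[k]] <- sport_entry(paste0("custom", k),
                               hours_per_week = runif(1, 0, 4),
                               months_per_year = sample(1:12, 1),
                               met_value = runif(1, 3, 12))
  }
  l1 <- runif(1); m1 <- runif(1, 0, 1 - l1)
  l2 <- runif(1); m2 <- runif(1, 0, 1 - l2)
  questionnaire_record(
    sitting_weekday_h = runif(1, 0, 10), sitting_weekend_h = runif(1, 0, 10),
    moderate_days = sample(0:7, 1), moderate_h_per_day = runif(1, 0, 2),
    vigorous_days = sample(0:7, 1), vigorous_h_per_day = runif(1, 0, 2),
    job_main_h = runif(1, 0, 50),
    job_main_pct_light = l1, job_main_pct_moderate = m1,
    job_main_pct_vigorous = 1 - l1 - m1,
    job_add_h = runif(1, 0, 10),
    job_add_pct_light = l2, job_add_pct_moderate = m2,
    job_add_pct_vigorous = 1 - l2 - m2,
    sports = sports,
    screen_weekday_h = runif(1, 0, 5), screen_weekend_h = runif(1, 0, 6),
    household_light_h = runif(1, 0, 8), household_moderate_h = runif(1, 0, 5),
    household_vigorous_h = runif(1, 0, 3),
    walk_commute_main_days = sample(0:5, 1), walk_commute_main_h = runif(1, 0, 1),
    cycle_commute_main_days = sample(0:5, 1), cycle_commute_main_h = runif(1, 0, 1),
    walk_leisure_weekday_h = runif(1, 0, 1), walk_leisure_weekend_h = runif(1, 0, 1),
    cycle_leisure_weekday_h = runif(1, 0, 1), cycle_leisure_weekend_h = runif(1, 0, 1),
    motor_commute_main_days = sample(0:5, 1), motor_commute_main_h = runif(1, 0, 1.5),
    motor_leisure_weekday_h = runif(1, 0, 1), motor_leisure_weekend_h = runif(1, 0, 2),
    eating_h_per_day = runif(1, 0, 2), sleeping_h_per_night = runif(1, 5, 9)
  )
}

# a small hand-specified day: complete minute stream + diary covering 1440 min
fixture_day <- function() {
  diary <- data.frame(
    start_minute = c(0, 420, 450, 480, 960, 1020, 1380),
    end_minute = c(420, 450, 480, 960, 1020, 1380, 1440),
    category = c("sleeping_resting", "personal_care", "eating_drinking",
                 "job", "household", "leisure", "sleeping_resting"),
    subcategory = c(NA, NA, NA, NA, "in_house", "tv", NA),
    stringsAsFactors = FALSE
  )
  met <- c(rep(0.9, 420), rep(1.5, 30), rep(1.8, 30), rep(2.5, 480),
           rep(3.5, 60), rep(1.3, 360), rep(0.9, 60))
  list(minutes = data.frame(minute_index = 0:1439, met = met, worn = TRUE),
       diary = diary, met = met)
}

# a complete 7-day minute stream + diary built from one repeated fixture day
fixture_week <- function() {
  day <- fixture_day()
  diary <- do.call(rbind, lapply(0:6, function(d) {
    x <- day$diary
    x$start_minute <- x$start_minute + 1440 * d
    x$end_minute <- x$end_minute + 1440 * d
    x
  }))
  met <- rep(day$met, 7)
  list(minutes = data.frame(minute_index = 0:10079, met = met, worn = TRUE),
       diary = diary, met = met)
}
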
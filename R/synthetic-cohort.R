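# Synthetic paired-cohort generator.
#
# Every subject starts from a latent weekly schedule: ordered activity
# intervals covering all 10080 minutes, each carrying a true MET level.
# Both instruments observe that truth — the questionnaire through a
# recall-bias model, the sensor stream through a noise/non-wear model,
# and the diary as the intervals themselves. Latent MET levels equal the
# compendium constants the questionnaire scorer assigns, so with an
# unbiased reporter and a noiseless sensor the two measurement paths
# recover identical parameters.

#' Self-report bias model
#'
#' Multiplicative distortions applied to recalled durations and shifts of
#' reported occupational intensity, motivated by the recall mechanisms of
#' self-report instruments: vigorous activity is over-reported, routine
#' light-to-moderate activity (household chores, moderate bouts, sitting,
#' motorized travel) under-reported, and occupational intensity inflated.
#' All factors at 1 with zero noise is the unbiased reporter.
#'
#' @param vigorous_overreport_factor multiplies recalled vigorous time.
#' @param moderate_underreport_factor multiplies recalled moderate time.
#' @param household_underreport_factor multiplies recalled chore hours.
#' @param sedentary_underreport_factor multiplies recalled sitting hours.
#' @param motorized_underreport_factor multiplies recalled motorized
#'   travel.
#' @param job_overreport_factor multiplies recalled weekly job hours.
#' @param job_intensity_inflation fraction of reported occupational time
#'   shifted one intensity level upward (light toward moderate, moderate
#'   toward vigorous); 0..1.
#' @param recall_noise_sd sd of lognormal multiplicative noise applied to
#'   every recalled duration.
#' @param banding snap recalled answers to the questionnaire response
#'   bands ([response_bands()]).
#' @return list of class `bias_model`.
#' @export
bias_model <- function(vigorous_overreport_factor = 1,
                       moderate_underreport_factor = 1,
                       household_underreport_factor = 1,
                       sedentary_underreport_factor = 1,
                       motorized_underreport_factor = 1,
                       job_overreport_factor = 1,
                       job_intensity_inflation = 0,
                       recall_noise_sd = 0,
                       banding = FALSE) {
  x <- as.list(environment())
  f <- unlist(x[grep("_factor$", names(x))])
  if (any(f <= 0)) stop("bias factors must be positive")
  stopifnot(job_intensity_inflation >= 0, job_intensity_inflation < 1,
            recall_noise_sd >= 0, is.logical(banding))
  structure(x, class = "bias_model")
}

#' Sensor noise model for the minute MET stream
#'
#' @param met_noise_sd sd of additive Gaussian noise per minute; the
#'   resulting MET is floored at 0.9 (resting).
#' @param nonwear_rate expected non-wear episodes per day.
#' @param nonwear_duration_mean mean episode duration in minutes
#'   (geometric).
#' @param underestimate_vigorous_factor multiplier (at or below 1) on
#'   true MET above 6, emulating the monitor's compression of very
#'   vigorous intensities.
#' @return list of class `sensor_model`.
#' @export
sensor_model <- function(met_noise_sd = 0,
                         nonwear_rate = 0,
                         nonwear_duration_mean = 45,
                         underestimate_vigorous_factor = 1) {
  stopifnot(met_noise_sd >= 0, nonwear_rate >= 0, nonwear_duration_mean >= 1,
            underestimate_vigorous_factor > 0,
            underestimate_vigorous_factor <= 1)
  structure(as.list(environment()), class = "sensor_model")
}

#' Cohort generation configuration
#'
#' Demographics, weekly-schedule distributions and the two observation
#' models. Durations are drawn per subject from truncated normal or
#' uniform distributions emulating a working-adult week: roughly 8 h
#' sleep, a 38-hour week at mostly light occupational intensity,
#' commuting, household chores concentrated in the weekend, up to two
#' sports, and evening screen time.
#'
#' @param p_female probability a subject is female.
#' @param age_range inclusive integer age range sampled uniformly.
#' @param p_employed probability a subject has a (single, main)
#'   occupation.
#' @param job_h_mean,job_h_sd weekly occupation hours (truncated 20..50).
#' @param sleep_h_mean,sleep_h_sd nightly sleep hours (truncated 6..9.5).
#' @param bias a [bias_model()], or a list with elements `male` and
#'   `female` for gender-specific reporting bias.
#' @param sensor a [sensor_model()].
#' @param diary_dropout_p probability that a diary entry shorter than 15
#'   minutes (other than sleep) is forgotten.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(p_female = 0.52,
                          age_range = c(20L, 64L),
                          p_employed = 0.95,
                          job_h_mean = 38, job_h_sd = 5,
                          sleep_h_mean = 8, sleep_h_sd = 0.4,
                          bias = bias_model(),
                          sensor = sensor_model(),
                          diary_dropout_p = 0) {
  stopifnot(p_female >= 0, p_female <= 1,
            age_range[1] >= 20, age_range[2] <= 64,
            age_range[1] <= age_range[2],
            diary_dropout_p >= 0, diary_dropout_p <= 1)
  if (inherits(bias, "bias_model")) bias <- list(male = bias, female = bias)
  stopifnot(inherits(bias$male, "bias_model"),
            inherits(bias$female, "bias_model"))
  stopifnot(inherits(sensor, "sensor_model"))
  structure(as.list(environment()), class = "cohort_config")
}

#' Reporting-bias preset reflecting typical self-report distortions
#'
#' Bias magnitudes set from the direction and rough size of questionnaire
#' vs sensor-diary discrepancies reported for working-age adults:
#' vigorous activity over-reported severalfold, moderate activity and
#' sitting under-reported, household chores and motorized travel
#' under-reported, job hours slightly over-reported and occupational
#' intensity inflated; paired with a moderately noisy sensor that
#' compresses very vigorous MET.
#'
#' @param banding snap questionnaire answers to response bands.
#' @return a [cohort_config()].
#' @export
reporting_bias_reference <- function(banding = FALSE) {
  cohort_config(
    bias = bias_model(
      vigorous_overreport_factor = 3.4,
      moderate_underreport_factor = 0.32,
      household_underreport_factor = 0.68,
      sedentary_underreport_factor = 0.60,
      motorized_underreport_factor = 0.70,
      job_overreport_factor = 1.14,
      job_intensity_inflation = 0.25,
      recall_noise_sd = 0.20,
      banding = banding
    ),
    sensor = sensor_model(
      met_noise_sd = 0.25,
      nonwear_rate = 0.25,
      nonwear_duration_mean = 40,
      underestimate_vigorous_factor = 0.90
    ),
    diary_dropout_p = 0.15
  )
}

# ---- RNG scoping -----------------------------------------------------------

# run expr under a local seed without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# per-subject substream: counter-derived, always below 2^31
subject_seed <- function(master_seed, k) {
  as.integer((as.numeric(master_seed) + 7919 * as.numeric(k)) %% 2147483647)
}

# ---- latent week construction ---------------------------------------------

rtnorm1 <- function(mean, sd, lo, hi) min(hi, max(lo, stats::rnorm(1, mean, sd)))
rtnorm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

# split `total` integer minutes across days proportional to weights
alloc_minutes <- function(total, weights) {
  if (total <= 0) return(integer(length(weights)))
  raw <- total * weights / sum(weights)
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    o <- order(raw - out, decreasing = TRUE)
    out[o[seq_len(rem)]] <- out[o[seq_len(rem)]] + 1
  }
  as.integer(out)
}

# Draw one subject's latent weekly plan as integer minutes per day.
# All downstream artifacts (diary, stream, questionnaire truth) are
# derived from these integers, so the two measurement paths share one
# exact ground truth.
draw_week_plan <- function(config) {
  sleep_min <- as.integer(round(60 * rtnorm(7, config$sleep_h_mean,
                                            config$sleep_h_sd, 6, 9.5)))
  pcare_min <- as.integer(round(60 * rtnorm(7, 0.75, 0.1, 0.5, 1)))
  eat_mean <- rtnorm1(1.2, 0.2, 0.7, 1.8)
  eat_min <- as.integer(round(60 * rtnorm(7, eat_mean, 0.08, 0.5, 2)))

  employed <- stats::runif(1) < config$p_employed
  job_min <- integer(7)
  job_frac <- c(light = 1, moderate = 0, vigorous = 0)
  commute_mode <- "none"
  commute_min <- integer(7)
  if (employed) {
    wk <- as.integer(round(60 * rtnorm1(config$job_h_mean, config$job_h_sd,
                                        20, 50)))
    job_min[1:5] <- alloc_minutes(wk, rep(1, 5))
    l <- stats::runif(1, 0.45, 0.75)
    v <- stats::runif(1, 0, 0.15)
    job_frac <- c(light = l, moderate = 1 - l - v, vigorous = v)
    commute_mode <- sample(c("motorized", "bike", "walk", "none"), 1,
                           prob = c(0.55, 0.20, 0.10, 0.15))
    if (commute_mode != "none") {
      commute_min[1:5] <- as.integer(2 * round(stats::runif(1, 10, 40)))
    }
  }
  # per-day occupational intensity minutes (remainder to light)
  job_int <- t(vapply(job_min, function(m) {
    mv <- as.integer(round(m * job_frac[c("moderate", "vigorous")]))
    c(light = m - sum(mv), moderate = mv[[1]], vigorous = mv[[2]])
  }, c(light = 0, moderate = 0, vigorous = 0)))

  hh_weights <- c(rep(0.5 / 5, 5), 0.25, 0.25)
  hh_light <- alloc_minutes(round(60 * rtnorm1(5, 2, 0, 10)), hh_weights)
  hh_mod <- alloc_minutes(round(60 * rtnorm1(3, 1.5, 0, 7)), hh_weights)
  hh_vig <- alloc_minutes(round(60 * rtnorm1(1, 0.8, 0, 4)), hh_weights)

  comp <- sports_compendium()
  n_sports <- sample(0:2, 1, prob = c(0.35, 0.45, 0.20))
  sports <- NULL
  sports_min <- matrix(0L, nrow = n_sports, ncol = 7)
  if (n_sports > 0) {
    rows <- sample(nrow(comp), n_sports)
    sports <- comp[rows, , drop = FALSE]
    for (i in seq_len(n_sports)) {
      sessions <- sample(1:3, 1)
      len <- as.integer(round(stats::runif(1, 45, 90)))
      days <- sample(7, sessions)
      sports_min[i, days] <- len
    }
  }

  screen_wd <- as.integer(round(60 * rtnorm1(1.8, 0.6, 0.5, 4)))
  screen_we <- as.integer(round(60 * rtnorm1(2.8, 0.8, 0.5, 5)))
  screen_min <- c(rep(screen_wd, 5), rep(screen_we, 2))
  walk_leis <- c(rep(as.integer(round(60 * stats::runif(1, 0, 0.3))), 5),
                 rep(as.integer(round(60 * stats::runif(1, 0, 0.8))), 2))
  cycle_leis <- c(rep(as.integer(round(60 * stats::runif(1, 0, 0.2))), 5),
                  rep(as.integer(round(60 * stats::runif(1, 0, 0.5))), 2))
  motor_leis <- c(rep(as.integer(round(60 * stats::runif(1, 0.1, 0.7))), 5),
                  rep(as.integer(round(60 * stats::runif(1, 0.3, 1.2))), 2))

  plan <- list(sleep_min = sleep_min, pcare_min = pcare_min, eat_min = eat_min,
               job_int = job_int, commute_mode = commute_mode,
               commute_min = commute_min,
               hh_light = hh_light, hh_mod = hh_mod, hh_vig = hh_vig,
               sports = sports, sports_min = sports_min,
               screen_min = screen_min, walk_leis = walk_leis,
               cycle_leis = cycle_leis, motor_leis = motor_leis)

  # fit each day into 1440 minutes: cap the job, then shrink flexible
  # items proportionally so a filler of other leisure always remains
  for (d in 1:7) {
    fixed_other <- plan$sleep_min[d] + plan$pcare_min[d] + plan$eat_min[d] +
      plan$commute_min[d]
    job_d <- sum(plan$job_int[d, ])
    if (fixed_other + job_d > 1400) {
      newj <- max(0L, 1400L - fixed_other)
      plan$job_int[d, ] <- alloc_minutes(newj, pmax(plan$job_int[d, ], 1e-9))
      job_d <- newj
    }
    free <- 1440L - fixed_other - job_d
    flex <- c(plan$hh_light[d], plan$hh_mod[d], plan$hh_vig[d],
              if (nrow(sports_min)) plan$sports_min[, d] else integer(0),
              plan$screen_min[d], plan$walk_leis[d], plan$cycle_leis[d],
              plan$motor_leis[d])
    if (sum(flex) > free - 10) {
      f <- max(0, free - 10) / max(sum(flex), 1)
      shrink <- function(x) as.integer(floor(x * f))
      plan$hh_light[d] <- shrink(plan$hh_light[d])
      plan$hh_mod[d] <- shrink(plan$hh_mod[d])
      plan$hh_vig[d] <- shrink(plan$hh_vig[d])
      if (nrow(sports_min)) {
        plan$sports_min[, d] <- shrink(plan$sports_min[, d])
      }
      plan$screen_min[d] <- shrink(plan$screen_min[d])
      plan$walk_leis[d] <- shrink(plan$walk_leis[d])
      plan$cycle_leis[d] <- shrink(plan$cycle_leis[d])
      plan$motor_leis[d] <- shrink(plan$motor_leis[d])
    }
  }
  plan
}

# assemble the plan into ordered week-covering intervals
# returns data.frame(category, subcategory, met, len) with sum(len) = 10080
plan_to_intervals <- function(plan, constants = met_constants()) {
  rows <- vector("list", 7)
  commute_sub <- switch(plan$commute_mode, walk = "walk", bike = "bike",
                        motorized = "motorized", NA_character_)
  commute_met <- switch(plan$commute_mode,
                        walk = constants$active_transport,
                        bike = constants$active_transport,
                        motorized = constants$motorized_transport, 0)
  for (d in 1:7) {
    iv <- list()
    add <- function(category, subcategory, met, len) {
      if (len > 0) iv[[length(iv) + 1]] <<- list(category, subcategory, met, len)
    }
    eat1 <- plan$eat_min[d] %/% 3
    eat2 <- plan$eat_min[d] %/% 3
    eat3 <- plan$eat_min[d] - eat1 - eat2
    half_commute <- plan$commute_min[d] %/% 2
    jl <- plan$job_int[d, "light"]
    jm <- plan$job_int[d, "moderate"]
    jv <- plan$job_int[d, "vigorous"]

    add("sleeping_resting", NA, constants$sleeping, plan$sleep_min[d] - 60L)
    add("personal_care", NA, constants$residual_leisure, plan$pcare_min[d])
    add("eating_drinking", NA, constants$eating, eat1)
    if (half_commute > 0) {
      add("transport", commute_sub, commute_met, half_commute)
    }
    add("job", NA, constants$job_light, jl %/% 2)
    add("job", NA, constants$job_moderate, jm)
    add("eating_drinking", NA, constants$eating, eat2)
    add("job", NA, constants$job_vigorous, jv)
    add("job", NA, constants$job_light, jl - jl %/% 2)
    if (half_commute > 0) {
      add("transport", commute_sub, commute_met,
          plan$commute_min[d] - half_commute)
    }
    add("household", "in_house", constants$household_light, plan$hh_light[d])
    add("household", "in_house", constants$household_moderate, plan$hh_mod[d])
    add("household", "garden", constants$household_vigorous, plan$hh_vig[d])
    add("eating_drinking", NA, constants$eating, eat3)
    if (!is.null(plan$sports)) {
      for (i in seq_len(nrow(plan$sports))) {
        sub <- if (identical(plan$sports$name[i], "swimming")) "swimming"
               else "sports"
        add("leisure", sub, plan$sports$met[i], plan$sports_min[i, d])
      }
    }
    add("transport", "walk", constants$active_transport, plan$walk_leis[d])
    add("transport", "bike", constants$active_transport, plan$cycle_leis[d])
    add("transport", "motorized", constants$motorized_transport,
        plan$motor_leis[d])
    add("leisure", "tv", constants$residual_leisure, plan$screen_min[d])
    used <- sum(vapply(iv, function(r) r[[4]], 0)) + 60L
    add("leisure", "other", constants$residual_leisure, 1440L - used)
    add("sleeping_resting", NA, constants$sleeping, 60L)
    rows[[d]] <- iv
  }
  iv <- do.call(c, rows)
  data.frame(
    category = vapply(iv, `[[`, "", 1),
    subcategory = vapply(iv, function(r) as.character(r[[2]]), ""),
    met = vapply(iv, `[[`, 0, 3),
    len = as.integer(vapply(iv, `[[`, 0, 4)),
    stringsAsFactors = FALSE
  )
}

# merge adjacent intervals with the same diary label into diary entries
intervals_to_diary <- function(intervals) {
  lab <- paste(intervals$category, intervals$subcategory, sep = "\r")
  grp <- cumsum(c(TRUE, lab[-1] != lab[-length(lab)]))
  len <- as.vector(tapply(intervals$len, grp, sum))
  first <- !duplicated(grp)
  end <- cumsum(len)
  data.frame(
    start_minute = end - len,
    end_minute = end,
    category = intervals$category[first],
    subcategory = intervals$subcategory[first],
    stringsAsFactors = FALSE
  )
}

# ---- observation models ----------------------------------------------------

apply_sensor <- function(true_met, sensor) {
  met <- true_met
  hi <- met > 6
  met[hi] <- met[hi] * sensor$underestimate_vigorous_factor
  if (sensor$met_noise_sd > 0) {
    met <- pmax(0.9, met + stats::rnorm(length(met), 0, sensor$met_noise_sd))
  }
  worn <- rep(TRUE, length(met))
  n_ep <- stats::rpois(1, sensor$nonwear_rate * 7)
  if (n_ep > 0) {
    for (i in seq_len(n_ep)) {
      dur <- min(stats::rgeom(1, 1 / sensor$nonwear_duration_mean) + 1L, 600L)
      start <- sample(length(met) - dur, 1)
      worn[start:(start + dur - 1L)] <- FALSE
    }
    met[!worn] <- NA_real_
  }
  list(met = met, worn = worn)
}

# questionnaire truth + bias -> questionnaire_record
derive_questionnaire <- function(subj, true_met, codes, plan, bias,
                                 constants = met_constants(),
                                 bands = NULL) {
  noise <- function() {
    if (bias$recall_noise_sd > 0) stats::rlnorm(1, 0, bias$recall_noise_sd)
    else 1
  }
  band <- function(item, x) {
    if (bias$banding) apply_band(item, x, bands) else x
  }
  wd <- 1:5; we <- 6:7

  # intensity classes from the true stream, same definitions as fusion
  sleep_mask <- codes == .CODE_SLEEP
  sed_mask <- true_met <= constants$sedentary_ceiling & !sleep_mask
  sed_day <- colSums(matrix(sed_mask, nrow = MINUTES_PER_DAY)) / 60
  sit_wd <- band("sitting_h_per_day",
                 sum(sed_day[wd]) / 5 * bias$sedentary_underreport_factor * noise())
  sit_we <- band("sitting_h_per_day",
                 sum(sed_day[we]) / 2 * bias$sedentary_underreport_factor * noise())

  recall_bouts <- function(lower, upper, factor) {
    bm <- bout_minutes(true_met, lower, upper, constants$bout_min_minutes)
    per_day <- colSums(matrix(bm, nrow = MINUTES_PER_DAY)) / 60
    days <- sum(per_day > 0)
    h <- if (days > 0) sum(per_day) / days * factor * noise() else 0
    list(days = days, h = band("activity_h_per_day", h))
  }
  mod <- recall_bouts(constants$moderate_lower, constants$moderate_upper,
                      bias$moderate_underreport_factor)
  vig <- recall_bouts(constants$vigorous_lower, Inf,
                      bias$vigorous_overreport_factor)

  job_total <- sum(plan$job_int)
  if (job_total > 0) {
    frac <- colSums(plan$job_int) / job_total
  } else {
    frac <- c(light = 1, moderate = 0, vigorous = 0)
  }
  s <- bias$job_intensity_inflation
  frac_rep <- c(light = frac[["light"]] * (1 - s),
                moderate = frac[["moderate"]] * (1 - s) + frac[["light"]] * s,
                vigorous = frac[["vigorous"]] + frac[["moderate"]] * s)
  job_h <- band("job_h_per_week",
                job_total / 60 * bias$job_overreport_factor * noise())

  sports <- list()
  if (!is.null(plan$sports)) {
    for (i in seq_len(nrow(plan$sports))) {
      h <- sum(plan$sports_min[i, ]) / 60 * noise()
      if (h > 0) {
        sports[[length(sports) + 1]] <- sport_entry(
          plan$sports$name[i], hours_per_week = h, months_per_year = 12,
          met_value = plan$sports$met[i])
      }
    }
  }

  screen_wd <- band("screen_h_per_day", sum(plan$screen_min[wd]) / 60 / 5 * noise())
  screen_we <- band("screen_h_per_day", sum(plan$screen_min[we]) / 60 / 2 * noise())

  hh <- function(x) {
    band("household_h_per_week",
         sum(x) / 60 * bias$household_underreport_factor * noise())
  }

  commute_days <- sum(plan$commute_min > 0)
  commute_h <- if (commute_days > 0) {
    sum(plan$commute_min) / 60 / commute_days
  } else 0
  cw <- c(days = 0, h = 0); cb <- c(days = 0, h = 0); cm <- c(days = 0, h = 0)
  if (plan$commute_mode == "walk") {
    cw <- c(days = commute_days, h = band("activity_h_per_day", commute_h * noise()))
  } else if (plan$commute_mode == "bike") {
    cb <- c(days = commute_days, h = band("activity_h_per_day", commute_h * noise()))
  } else if (plan$commute_mode == "motorized") {
    cm <- c(days = commute_days,
            h = band("activity_h_per_day",
                     commute_h * bias$motorized_underreport_factor * noise()))
  }

  questionnaire_record(
    subject = subj,
    sitting_weekday_h = sit_wd, sitting_weekend_h = sit_we,
    moderate_days = mod$days, moderate_h_per_day = mod$h,
    vigorous_days = vig$days, vigorous_h_per_day = vig$h,
    job_main_h = job_h,
    job_main_pct_light = frac_rep[["light"]],
    job_main_pct_moderate = frac_rep[["moderate"]],
    job_main_pct_vigorous = frac_rep[["vigorous"]],
    sports = sports,
    screen_weekday_h = screen_wd, screen_weekend_h = screen_we,
    household_light_h = hh(plan$hh_light),
    household_moderate_h = hh(plan$hh_mod),
    household_vigorous_h = hh(plan$hh_vig),
    walk_commute_main_days = cw[["days"]], walk_commute_main_h = cw[["h"]],
    cycle_commute_main_days = cb[["days"]], cycle_commute_main_h = cb[["h"]],
    walk_leisure_weekday_h = band("activity_h_per_day",
                                  sum(plan$walk_leis[wd]) / 60 / 5 * noise()),
    walk_leisure_weekend_h = band("activity_h_per_day",
                                  sum(plan$walk_leis[we]) / 60 / 2 * noise()),
    cycle_leisure_weekday_h = band("activity_h_per_day",
                                   sum(plan$cycle_leis[wd]) / 60 / 5 * noise()),
    cycle_leisure_weekend_h = band("activity_h_per_day",
                                   sum(plan$cycle_leis[we]) / 60 / 2 * noise()),
    motor_commute_main_days = cm[["days"]], motor_commute_main_h = cm[["h"]],
    motor_leisure_weekday_h = band(
      "activity_h_per_day",
      sum(plan$motor_leis[wd]) / 60 / 5 * bias$motorized_underreport_factor * noise()),
    motor_leisure_weekend_h = band(
      "activity_h_per_day",
      sum(plan$motor_leis[we]) / 60 / 2 * bias$motorized_underreport_factor * noise()),
    eating_h_per_day = band("activity_h_per_day",
                            sum(plan$eat_min) / 60 / 7 * noise()),
    sleeping_h_per_night = band("sleeping_h_per_night",
                                sum(plan$sleep_min) / 60 / 7 * noise())
  )
}

# ---- public generation API -------------------------------------------------

#' Generate one synthetic subject with paired measurements
#'
#' Draws a latent weekly activity schedule and observes it three ways:
#' a questionnaire record (truth distorted by the configured recall-bias
#' model), a minute-level MET stream (truth distorted by the sensor
#' model) and an electronic diary (the latent intervals, optionally with
#' short entries forgotten). Deterministic given `(config, seed)`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed for this subject.
#' @param subject_id identifier for the generated subject.
#' @return list with elements `subject`, `schedule` (`intervals`,
#'   `true_met`, `plan`), `questionnaire`, `minutes`, `diary`.
#' @export
generate_subject <- function(config = cohort_config(), seed = 1,
                             subject_id = "S1") {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(seed, {
    gender <- if (stats::runif(1) < config$p_female) "female" else "male"
    age <- sample(config$age_range[1]:config$age_range[2], 1)
    subj <- subject(subject_id, gender, age)

    plan <- draw_week_plan(config)
    intervals <- plan_to_intervals(plan)
    true_met <- rep(intervals$met, intervals$len)
    full_diary <- intervals_to_diary(intervals)
    codes <- diary_minute_codes(full_diary)

    bias <- config$bias[[gender]]
    bands <- if (bias$banding) response_bands() else NULL
    q <- derive_questionnaire(subj, true_met, codes, plan, bias,
                              bands = bands)

    obs <- apply_sensor(true_met, config$sensor)
    minutes <- data.frame(minute_index = 0:(MINUTES_PER_WEEK - 1L),
                          met = obs$met, worn = obs$worn)

    diary <- full_diary
    if (config$diary_dropout_p > 0) {
      short <- diary$end_minute - diary$start_minute < 15 &
        diary$category != "sleeping_resting"
      drop <- short & stats::runif(nrow(diary)) < config$diary_dropout_p
      diary <- diary[!drop, , drop = FALSE]
    }

    list(subject = subj,
         schedule = list(intervals = intervals, true_met = true_met,
                         plan = plan),
         questionnaire = q, minutes = minutes, diary = diary)
  })
}

#' Generate a cohort of paired synthetic subjects
#'
#' Subjects are independent; each uses a counter-derived seed from the
#' master seed, so cohorts are reproducible and order-independent.
#'
#' @param n number of subjects (at least 1).
#' @param config a [cohort_config()].
#' @param seed master seed.
#' @return list of subjects as from [generate_subject()].
#' @export
generate_cohort <- function(n, config = cohort_config(), seed = 1) {
  if (n < 1) stop("n must be at least 1")
  lapply(seq_len(n), function(k) {
    generate_subject(config, subject_seed(seed, k),
                     subject_id = sprintf("S%03d", k))
  })
}

#' Score both measurement paths for a generated cohort
#'
#' Runs the questionnaire scorer and the sensor-diary fusion for every
#' subject; subjects whose monitored week fails the wear-time validity
#' rules are dropped (as in a real cohort).
#'
#' @param cohort list from [generate_cohort()].
#' @param constants [met_constants()].
#' @return a [paired_cohort()].
#' @export
profile_cohort <- function(cohort, constants = met_constants()) {
  fp <- list(); sw <- list(); keep <- list()
  for (s in cohort) {
    swd <- tryCatch(fuse(s$minutes, s$diary, constants), error = function(e) NULL)
    if (is.null(swd)) next
    id <- s$subject$subject_id
    fp[[id]] <- score_all(s$questionnaire, constants)
    sw[[id]] <- swd
    keep[[id]] <- s$subject
  }
  if (!length(keep)) stop("no subject passed wear-time validation")
  subjects <- data.frame(
    subject_id = vapply(keep, `[[`, "", "subject_id"),
    gender = vapply(keep, `[[`, "", "gender"),
    age_years = vapply(keep, function(x) as.numeric(x$age_years), 0),
    age_group = vapply(keep, `[[`, "", "age_group"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  paired_cohort(subjects, profile_table(fp), profile_table(sw))
}
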
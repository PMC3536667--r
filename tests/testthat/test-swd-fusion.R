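test_that("diary-guided imputation fills sleep, personal care and swimming", {
  wk <- fixture_week()
  # no missing minutes: identity
  imp0 <- impute_missing(wk$minutes, wk$diary)
  expect_equal(imp0$met, wk$met)
  expect_false(any(imp0$imputed))

  # knock out one personal-care minute, one sleep minute, and leave one
  # uncovered minute missing
  m <- wk$minutes
  m$met[c(431, 100, 990)] <- NA  # minute_index 430 (pcare), 99 (sleep), 989 (household)
  imp <- impute_missing(m, wk$diary)
  expect_equal(imp$met[431], 2)        # personal-care constant
  expect_equal(imp$met[100], 0.9)      # mean of observed sleep (constant 0.9)
  expect_true(is.na(imp$met[990]))     # household minutes are not imputable
  expect_true(imp$imputed[431] && imp$imputed[100])

  # swimming minutes get the 6-MET constant
  d <- wk$diary
  d$category[6] <- "leisure"; d$subcategory[6] <- "swimming"
  m2 <- wk$minutes
  m2$met[1025] <- NA  # inside the interval now labelled swimming
  imp2 <- impute_missing(m2, d)
  expect_equal(imp2$met[1025], 6)

  # subject with no observed sleep at all cannot impute sleep
  m3 <- wk$minutes
  sleep_idx <- unlist(lapply(0:6, function(d) {
    c(1440 * d + 1:420, 1440 * d + 1381:1440)
  }))
  m3$met[sleep_idx] <- NA
  expect_error(impute_missing(m3, wk$diary), "no observed sleep")
})

test_that("day and subject validity follow the 1368-minute and weekend rules", {
  wk <- fixture_week()
  r <- validate_week(wk$minutes)
  expect_true(r$subject_valid)
  expect_equal(r$n_valid_days, 7)
  expect_equal(r$day_minutes, rep(1440L, 7))

  # one weekday at 1367 minutes: day invalid, subject still valid
  m <- wk$minutes
  m$met[2 * 1440 + 1:73] <- NA  # Wednesday loses 73 minutes -> 1367
  r2 <- validate_week(m)
  expect_false(r2$day_valid[3])
  expect_equal(r2$n_valid_days, 6)
  expect_true(r2$subject_valid)

  # exactly 1368 minutes is still a valid day
  m3 <- wk$minutes
  m3$met[2 * 1440 + 1:72] <- NA
  expect_true(validate_week(m3)$day_valid[3])

  # an incomplete Saturday invalidates the subject even with 6 valid days
  m4 <- wk$minutes
  m4$met[5 * 1440 + 1:440] <- NA
  r4 <- validate_week(m4)
  expect_equal(r4$n_valid_days, 6)
  expect_false(r4$subject_valid)
})

test_that("bout detection honours the 10-minute minimum and strict runs", {
  pad <- function(x) c(rep(1, 5), x, rep(1, 5))
  expect_equal(detect_bouts(pad(rep(4, 9)), 3, 6), 0)
  expect_equal(detect_bouts(pad(rep(4, 10)), 3, 6), 10 / 60)
  # a single interrupting minute splits a run into two sub-threshold halves
  expect_equal(detect_bouts(pad(c(rep(4, 9), 1, rep(4, 9))), 3, 6), 0)
  # missing minutes break runs too
  expect_equal(detect_bouts(pad(c(rep(4, 9), NA, rep(4, 9))), 3, 6), 0)
  # band is half-open: 6 MET is not moderate, it is vigorous
  expect_equal(detect_bouts(rep(6, 10), 3, 6), 0)
  expect_equal(detect_bouts(rep(6, 10), 6), 10 / 60)
})

test_that("bout detection matches the exhaustive run-scanning oracle", {
  set.seed(403)
  for (i in 1:1000) {
    n <- sample(50:300, 1)
    met <- sample(c(0.9, 1.5, 2.9, 3, 4.5, 5.99, 6, 9, NA),
                  n, replace = TRUE)
    expect_equal(detect_bouts(met, 3, 6), oracle_bouts_hours(met, 3, 6))
    expect_equal(detect_bouts(met, 6), oracle_bouts_hours(met, 6))
  }
})

test_that("adding a qualifying bout never decreases bouted hours", {
  set.seed(404)
  for (i in 1:50) {
    met <- sample(c(1, 2, 4, 7), 500, replace = TRUE)
    before <- detect_bouts(met, 3, 6)
    extended <- c(met, rep(4, 10))
    expect_gte(detect_bouts(extended, 3, 6), before)
  }
})

test_that("moderate and vigorous bout minutes are disjoint", {
  set.seed(405)
  met <- runif(2000, 0.9, 9)
  m <- actagree:::bout_minutes(met, 3, 6)
  v <- actagree:::bout_minutes(met, 6, Inf)
  expect_false(any(m & v))
})

test_that("sedentary time counts low-MET awake minutes only", {
  # a full week of diary sleep at 0.9 MET yields zero sedentary time
  all_sleep <- data.frame(start_minute = 0, end_minute = 10080,
                          category = "sleeping_resting", subcategory = NA)
  m <- data.frame(minute_index = 0:10079, met = rep(0.9, 10080), worn = TRUE)
  expect_equal(sedentary_time(m, all_sleep), 0)

  # 60 awake minutes at exactly 1.8 MET count (inclusive ceiling)
  wk <- fixture_week()
  # per day: personal care 30 min at 1.5, eating 30 min at exactly 1.8
  # (inclusive ceiling), tv 360 min at 1.3
  expected_sed <- 7 * (30 + 30 + 360) / 60
  expect_equal(sedentary_time(wk$minutes, wk$diary), expected_sed)
  m2 <- wk$minutes
  m2$met[481:540] <- 1.8  # one hour of Monday's job block at the ceiling
  expect_equal(sedentary_time(m2, wk$diary), expected_sed + 1)
})

test_that("domain aggregation matches the per-minute oracle and conserves totals", {
  set.seed(406)
  cats <- list(
    c("sleeping_resting", NA), c("personal_care", NA),
    c("eating_drinking", NA), c("job", NA),
    c("leisure", "sports"), c("leisure", "swimming"), c("leisure", "tv"),
    c("leisure", "computer"), c("leisure", "other"),
    c("transport", "walk"), c("transport", "bike"), c("transport", "motorized"),
    c("household", "in_house"), c("household", "garden")
  )
  for (i in 1:200) {
    # random day: random interval partition with a random uncovered gap
    cuts <- sort(sample(1:1439, sample(5:12, 1)))
    bounds <- c(0, cuts, 1440)
    n_iv <- length(bounds) - 1
    pick <- sample(length(cats), n_iv, replace = TRUE)
    diary <- data.frame(
      start_minute = bounds[-length(bounds)], end_minute = bounds[-1],
      category = vapply(cats[pick], `[`, "", 1),
      subcategory = vapply(cats[pick], `[`, "", 2),
      stringsAsFactors = FALSE
    )
    gap <- sample(nrow(diary), 1)
    diary_gappy <- diary[-gap, , drop = FALSE]
    met <- runif(1440, 0.9, 10)
    met[sample(1440, 50)] <- NA
    minutes <- data.frame(minute_index = 0:1439, met = met)

    got <- domain_aggregate(minutes, diary_gappy)
    want <- oracle_domain(met, diary_gappy)
    expect_equal(stats::setNames(got$time, got$domain), want$time,
                 tolerance = 1e-12)
    expect_equal(stats::setNames(got$ee, got$domain), want$ee,
                 tolerance = 1e-12)

    # conservation: domains + uncategorized reproduce the week totals
    tot <- totals(minutes)
    expect_equal(sum(got$ee), unname(tot["total_ee"]), tolerance = 1e-9)
  }
})

test_that("week totals and PAL follow the minute-sum definitions", {
  m <- data.frame(minute_index = 0:10079, met = rep(1.62, 10080))
  tot <- totals(m)
  expect_equal(unname(tot["total_ee"]), 1.62 * 168)
  expect_equal(unname(tot["pal"]), 1.62)

  m1 <- data.frame(minute_index = 0:10079, met = rep(1, 10080))
  expect_equal(unname(totals(m1)), c(168, 1))

  set.seed(407)
  m2 <- data.frame(minute_index = 0:10079, met = runif(10080, 0.9, 8))
  tot2 <- totals(m2)
  expect_equal(unname(tot2["pal"] * 168), unname(tot2["total_ee"]))
})

test_that("six-day weekly extrapolation matches the printed formula", {
  expect_equal(weekly_extrapolate(rep(3, 7), rep(TRUE, 7)), 21)
  # four valid weekdays of 2, Saturday 3, Sunday 1
  pd <- c(2, 2, 2, 2, 99, 3, 1)
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(weekly_extrapolate(pd, mask), 2 * 5 + 3 + 1)
  set.seed(408)
  for (i in 1:50) {
    pd <- runif(7, 0, 10)
    drop <- sample(1:5, 1)
    mask <- rep(TRUE, 7); mask[drop] <- FALSE
    expect_equal(weekly_extrapolate(pd, mask),
                 mean(pd[1:5][-drop]) * 5 + pd[6] + pd[7])
  }
  expect_error(weekly_extrapolate(rep(1, 7), c(rep(TRUE, 5), FALSE, TRUE)),
               "Saturday and Sunday")
})

test_that("fusion reproduces a hand-computed fixture week", {
  wk <- fixture_week()
  p <- fuse(wk$minutes, wk$diary)
  # hand arithmetic for the repeated day (see fixture_day): job 480 min at
  # 2.5 MET, household 60 min at 3.5, tv 360 at 1.3, eating 30 at 1.8,
  # personal care 30 at 1.5, sleep 480 at 0.9
  expect_equal(p[["job_time"]], 7 * 8)
  expect_equal(p[["job_ee"]], 7 * 8 * 2.5)
  expect_equal(p[["household_time"]], 7)
  expect_equal(p[["household_ee"]], 7 * 3.5)
  expect_equal(p[["screen_time"]], 7 * 6)
  expect_equal(p[["sleeping_time"]], 7 * 8)
  expect_equal(p[["sleeping_ee"]], 7 * 8 * 0.9)
  expect_equal(p[["eating_time"]], 7 * 0.5)
  expect_equal(p[["moderate_pa"]], 7)        # the 60-min 3.5-MET block
  expect_equal(p[["vigorous_pa"]], 0)
  expect_equal(p[["sedentary"]], 7 * 7)  # pcare 0.5 + eating 0.5 + tv 6 h/day
  expect_equal(p[["total_ee"]],
               7 * (480 * 0.9 + 30 * 1.5 + 30 * 1.8 + 480 * 2.5 +
                      60 * 3.5 + 360 * 1.3) / 60)
  expect_equal(p[["pal"]], p[["total_ee"]] / 168)
})

test_that("an all-sleep week fuses to zero sedentary and 168 h sleep", {
  all_sleep <- data.frame(start_minute = 0, end_minute = 10080,
                          category = "sleeping_resting", subcategory = NA)
  m <- data.frame(minute_index = 0:10079, met = rep(0.9, 10080), worn = TRUE)
  p <- fuse(m, all_sleep)
  expect_equal(p[["sedentary"]], 0)
  expect_equal(p[["sleeping_time"]], 168)
  expect_equal(p[["total_ee"]], 168 * 0.9)
})

test_that("fusion rejects invalid weeks and extrapolates six-day weeks", {
  wk <- fixture_week()
  # invalidate Thursday (weekday) by removing 100 non-imputable job
  # minutes: fusion must use the 6-day formula, which for identical days
  # equals the full-week value
  m <- wk$minutes
  m$met[3 * 1440 + 481:580] <- NA
  expect_false(validate_week(impute_missing(m, wk$diary))$day_valid[4])
  p6 <- fuse(m, wk$diary)
  p7 <- fuse(wk$minutes, wk$diary)
  expect_equal(as.numeric(p6), as.numeric(p7), tolerance = 1e-9)

  # invalidate a weekend day: subject rejected
  m2 <- wk$minutes
  m2$met[6 * 1440 + 481:580] <- NA
  expect_error(fuse(m2, wk$diary), "not valid")

  # two invalid weekdays: rejected
  m3 <- wk$minutes
  m3$met[481:580] <- NA
  m3$met[1440 + 481:580] <- NA
  expect_error(fuse(m3, wk$diary), "not valid")
})

test_that("strict fusion rejects diary gaps, lenient mode keeps them uncategorized", {
  wk <- fixture_week()
  d <- wk$diary[-5, , drop = FALSE]  # remove one household entry (Monday)
  expect_error(fuse(wk$minutes, d, strict = TRUE), "strict")
  p <- fuse(wk$minutes, d)
  expect_equal(p[["household_time"]], 6)  # six remaining days
  # the uncovered hour still contributes to total EE
  expect_equal(p[["total_ee"]], fuse(wk$minutes, wk$diary)[["total_ee"]])
})
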
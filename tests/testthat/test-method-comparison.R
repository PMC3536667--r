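test_that("paired t-test matches hand computation and handles degeneracy", {
  # d = (1, 2, 3): mean 2, sd 1, t = 2 / (1 / sqrt(3))
  res <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$mean_diff, 2)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)

  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(same[c("mean_diff", "t", "p")]), c(mean_diff = 0, t = 0, p = 1))

  shifted <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_equal(shifted$mean_diff, 1)
  expect_true(is.infinite(shifted$t))
  expect_lt(shifted$p, 1e-15)

  expect_error(paired_t(1, 2), "n >= 2")
})

test_that("paired t-test recovers a configured shift on synthetic data", {
  set.seed(409)
  x <- rnorm(300)
  y <- x - 0.8 + rnorm(300, sd = 0.3)
  res <- paired_t(x, y)
  expect_lt(abs(res$mean_diff - 0.8), 3 * 0.3 / sqrt(300))
  expect_lt(res$p, 1e-10)
})

test_that("pearson correlation behaves on exact, null and latent-correlation data", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x), 1)
  expect_error(pearson_r(x, rep(1, 4)), "zero-variance")
  expect_error(pearson_r(1:2, 2:3), "n >= 3")

  set.seed(410)
  n <- 2000
  a <- rnorm(n); b <- rnorm(n)
  expect_lt(abs(pearson_r(a, b)), 3 / sqrt(n))

  rho <- 0.6
  c1 <- rnorm(n)
  c2 <- rho * c1 + sqrt(1 - rho^2) * rnorm(n)
  expect_lt(abs(pearson_r(c1, c2) - rho), 0.06)
})

test_that("Bland-Altman analysis returns classical bias and limits", {
  x <- c(1, 2, 3, 4)
  id <- bland_altman(x, x)
  expect_equal(id$bias, 0)
  expect_equal(c(id$lower_limit, id$upper_limit), c(0, 0))

  set.seed(411)
  n <- 50000
  avg_level <- runif(n, 100, 400)
  d <- rnorm(n, mean = 25.26, sd = 41.54)
  ba <- bland_altman(avg_level + d / 2, avg_level - d / 2)
  # closed form: limits are mu +/- 1.96 sigma
  expect_lt(abs(ba$bias - 25.26), 0.6)
  expect_lt(abs(ba$lower_limit - (25.26 - 1.96 * 41.54)), 1.5)
  expect_lt(abs(ba$upper_limit - (25.26 + 1.96 * 41.54)), 1.5)
  expect_lt(abs(mean(ba$differences >= ba$lower_limit &
                       ba$differences <= ba$upper_limit) - 0.95), 0.01)

  # proportional bias shows up as a positive trend slope
  x2 <- runif(500, 0, 100)
  y2 <- x2 * 0.8 + rnorm(500, sd = 2)
  prop <- bland_altman(x2, y2)
  expect_gt(prop$trend_slope, 0.1)

  expect_error(bland_altman(1:2, 2:3), "n >= 3")
})

test_that("difference table reproduces identities and the unbiased null", {
  coh <- suppressWarnings(profile_cohort(generate_cohort(40, cohort_config(),
                                                         seed = 21)))
  dt <- difference_table(coh)
  expect_equal(dt$mean_diff, dt$fpacq_mean - dt$swd_mean)
  # identical profiles on both sides: all differences zero
  same <- paired_cohort(coh$subjects, coh$fpacq, coh$fpacq)
  dt0 <- difference_table(same)
  expect_true(all(dt0$mean_diff == 0))
  expect_error(paired_cohort(coh$subjects[0, ], coh$fpacq, coh$swd), "empty")

  # difference_table mean difference == paired_t mean difference,
  # bland_altman bias == both
  for (p in c("total_ee", "sedentary", "job_ee")) {
    pt <- paired_t(coh$fpacq[[p]], coh$swd[[p]])
    ba <- bland_altman(coh$fpacq[[p]], coh$swd[[p]])
    expect_equal(dt$mean_diff[dt$parameter == p], pt$mean_diff)
    expect_equal(ba$bias, pt$mean_diff)
  }
})

test_that("paired-t p-values are uniform under the unbiased null", {
  set.seed(412)
  n_sim <- 1000
  p <- replicate(n_sim, {
    x <- rnorm(25); y <- rnorm(25)
    paired_t(x, y)$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("two-way ANOVA matches hand-computed sums of squares on a balanced fixture", {
  # balanced 2x3 with 4 per cell and known cell means
  cell_means <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 2, byrow = TRUE)
  set.seed(413)
  rows <- list()
  for (g in 1:2) for (a in 1:3) {
    rows[[length(rows) + 1]] <- data.frame(
      g = c("male", "female")[g], a = AGE_GROUPS[a],
      d = cell_means[g, a] + c(-0.3, -0.1, 0.1, 0.3))
  }
  df <- do.call(rbind, rows)
  subjects <- data.frame(subject_id = as.character(seq_len(nrow(df))),
                         gender = df$g, age_years = 30,
                         age_group = df$a, stringsAsFactors = FALSE)
  prof0 <- as.data.frame(stats::setNames(as.list(rep(0, 20)), PROFILE_PARAMETERS))
  fp <- cbind(subject_id = subjects$subject_id,
              prof0[rep(1, nrow(df)), , drop = FALSE])
  fp$total_ee <- df$d
  sw <- fp
  sw$total_ee <- 0
  coh <- paired_cohort(subjects, fp, sw)
  res <- subgroup_anova(coh, "total_ee")

  # brute-force sums of squares for the balanced design
  n <- nrow(df); r <- 4
  grand <- mean(df$d)
  mg <- tapply(df$d, df$g, mean)
  ma <- tapply(df$d, df$a, mean)
  mcell <- tapply(df$d, list(df$g, df$a), mean)
  ss_g <- 12 * sum((mg - grand)^2)
  ss_a <- 8 * sum((ma - grand)^2)
  ss_cell <- 4 * sum((mcell - outer(mg - grand, rep(1, 3)) -
                        outer(rep(1, 2), ma - grand) - grand)^2)
  ss_e <- sum((df$d - mcell[cbind(df$g, df$a)])^2)
  f_g <- (ss_g / 1) / (ss_e / (n - 6))
  f_a <- (ss_a / 2) / (ss_e / (n - 6))
  f_ga <- (ss_cell / 2) / (ss_e / (n - 6))
  expect_equal(res$effects$F[res$effects$term == "gender"], f_g,
               tolerance = 1e-9)
  expect_equal(res$effects$F[res$effects$term == "age_group"], f_a,
               tolerance = 1e-9)
  expect_equal(res$effects$F[res$effects$term == "interaction"], f_ga,
               tolerance = 1e-9)
  expect_equal(res$cell_means[cbind(df$g, df$a)][seq(1, 24, by = 4)],
               unname(mcell[cbind(df$g, df$a)][seq(1, 24, by = 4)]))

  # grand mean of difference scores equals weighted mean of cell means
  expect_equal(mean(df$d), sum(res$cell_means * 4) / 24)
})

test_that("ANOVA degeneracies: equal scores give F = 0; Tukey never flags equal cells", {
  subjects <- data.frame(
    subject_id = as.character(1:12),
    gender = rep(c("male", "female"), each = 6),
    age_years = 30,
    age_group = rep(AGE_GROUPS, 4), stringsAsFactors = FALSE)
  prof0 <- as.data.frame(stats::setNames(as.list(rep(0, 20)), PROFILE_PARAMETERS))
  fp <- cbind(subject_id = subjects$subject_id, prof0[rep(1, 12), ])
  fp$total_ee <- 5  # identical difference everywhere
  sw <- fp; sw$total_ee <- 0
  res <- subgroup_anova(paired_cohort(subjects, fp, sw), "total_ee")
  expect_equal(res$effects$F, c(0, 0, 0))
  expect_null(res$tukey_age)

  # age effect present but two of the three age-group means equal:
  # the equal pair must not be flagged
  fp2 <- fp
  fp2$total_ee <- ifelse(subjects$age_group == "50-64", 10, 5) +
    rep(c(-0.1, 0.1), 6)
  res2 <- subgroup_anova(paired_cohort(subjects, fp2, sw), "total_ee")
  expect_false(is.null(res2$tukey_age))
  pair_equal <- res2$tukey_age$comparison == "35-49-20-34"
  expect_false(any(res2$tukey_age$significant[pair_equal]))
  expect_true(any(res2$tukey_age$significant[!pair_equal]))

  # an empty cell is rejected with the cell named
  subjects3 <- subjects
  subjects3$age_group[subjects3$gender == "male" &
                        subjects3$age_group == "50-64"] <- "35-49"
  expect_error(subgroup_anova(paired_cohort(subjects3, fp2, sw), "total_ee"),
               "male x 50-64")
})

test_that("a gender-specific reporting bias is detected by the subgroup ANOVA", {
  # simulated difference scores: males shifted by 0.5 sd
  set.seed(414)
  detect <- replicate(30, {
    n <- 400
    gender <- sample(c("male", "female"), n, replace = TRUE)
    age <- sample(20:64, n, replace = TRUE)
    d <- rnorm(n) + ifelse(gender == "male", 0.5, 0)
    subjects <- data.frame(subject_id = as.character(1:n), gender = gender,
                           age_years = age, stringsAsFactors = FALSE)
    prof0 <- as.data.frame(stats::setNames(as.list(rep(0, 20)),
                                           PROFILE_PARAMETERS))
    fp <- cbind(subject_id = subjects$subject_id, prof0[rep(1, n), ])
    fp$total_ee <- d
    sw <- fp; sw$total_ee <- 0
    res <- subgroup_anova(paired_cohort(subjects, fp, sw), "total_ee")
    res$effects$p[res$effects$term == "gender"] < 0.05
  })
  expect_gt(mean(detect), 0.8)
})

test_that("the shipped reference means feed the worked-example arithmetic", {
  means <- reference_cohort_means()
  expect_equal(means$parameter, PROFILE_PARAMETERS)
  dt <- difference_table(means_as_cohort(means))
  expect_equal(dt$mean_diff, means$fpacq_mean - means$swd_mean)
  expect_true(all(is.na(dt$p_value)))
})
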
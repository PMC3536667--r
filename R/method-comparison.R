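# Agreement statistics over paired activity profiles: paired t-tests,
# Pearson correlations, Bland-Altman analysis and gender-by-age ANOVA of
# difference scores.

#' Assemble a paired cohort
#'
#' Couples the questionnaire-derived and fusion-derived profile tables of
#' the same subjects.
#'
#' @param subjects data.frame with `subject_id`, `gender`, `age_years`
#'   and/or `age_group`.
#' @param fpacq,swd profile tables ([profile_table()]-style data.frames)
#'   with identical subject sets.
#' @return list of class `paired_cohort`.
#' @export
paired_cohort <- function(subjects, fpacq, swd) {
  stopifnot(is.data.frame(subjects), is.data.frame(fpacq), is.data.frame(swd))
  if (!nrow(subjects)) stop("paired cohort is empty")
  if (!identical(sort(subjects$subject_id), sort(fpacq$subject_id)) ||
      !identical(sort(subjects$subject_id), sort(swd$subject_id))) {
    stop("subject sets of the two profile tables must match")
  }
  fpacq <- fpacq[match(subjects$subject_id, fpacq$subject_id), , drop = FALSE]
  swd <- swd[match(subjects$subject_id, swd$subject_id), , drop = FALSE]
  if (is.null(subjects$age_group) && !is.null(subjects$age_years)) {
    subjects$age_group <- age_group_of(subjects$age_years)
  }
  structure(list(subjects = subjects, fpacq = fpacq, swd = swd),
            class = "paired_cohort")
}

#' Paired t-test on two method readings
#'
#' @param x,y equal-length paired samples (method 1 and method 2).
#' @return list with `mean_diff` (mean of `x - y`), `t`, `p` (two-sided),
#'   `n`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("paired t-test needs n >= 2")
  d <- x - y
  if (stats::sd(d) == 0) {
    # degenerate: constant differences
    if (mean(d) == 0) return(list(mean_diff = 0, t = 0, p = 1, n = length(d)))
    return(list(mean_diff = mean(d), t = sign(mean(d)) * Inf, p = 1e-16,
                n = length(d)))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       p = tt$p.value, n = length(d))
}

#' Pearson product-moment correlation
#'
#' @param x,y paired samples, `n >= 3`, each with positive variance.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("pearson_r needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r is undefined for a zero-variance sample")
  }
  stats::cor(x, y)
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean difference `x - y`; the 95% limits of agreement are
#' bias plus/minus 1.96 times the SD of the differences. A least-squares
#' slope of difference on average flags proportional (systematic) bias.
#'
#' @param x,y paired samples (`n >= 3`).
#' @return list of class `bland_altman`: `differences`, `averages`,
#'   `bias`, `sd_diff`, `lower_limit`, `upper_limit`, `trend_slope`, `n`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("bland_altman needs n >= 3")
  d <- x - y
  a <- (x + y) / 2
  s <- stats::sd(d)
  slope <- if (stats::var(a) > 0) {
    unname(stats::coef(stats::lm(d ~ a))[2])
  } else 0
  structure(list(differences = d, averages = a,
                 bias = mean(d), sd_diff = s,
                 lower_limit = mean(d) - 1.96 * s,
                 upper_limit = mean(d) + 1.96 * s,
                 trend_slope = slope, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, 95%% limits [%.3f, %.3f], n = %d\n",
              x$bias, x$lower_limit, x$upper_limit, x$n))
  cat(sprintf("trend slope (difference on average): %.4f\n", x$trend_slope))
  invisible(x)
}

#' Per-parameter comparison table for a paired cohort
#'
#' One row per activity parameter: means and SDs under each method, the
#' mean difference (questionnaire minus sensor-diary), the paired-t
#' p-value and the Pearson correlation. With fewer than two (three)
#' subjects the p-value (correlation) is `NA`.
#'
#' @param cohort a [paired_cohort()].
#' @param parameters parameters to tabulate (default all twenty).
#' @return data.frame.
#' @export
difference_table <- function(cohort, parameters = PROFILE_PARAMETERS) {
  stopifnot(inherits(cohort, "paired_cohort"))
  n <- nrow(cohort$subjects)
  if (!n) stop("paired cohort is empty")
  rows <- lapply(parameters, function(p) {
    x <- cohort$fpacq[[p]]
    y <- cohort$swd[[p]]
    pt <- if (n >= 2) paired_t(x, y) else NULL
    r <- if (n >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0) {
      pearson_r(x, y)
    } else NA_real_
    data.frame(parameter = p,
               fpacq_mean = mean(x), fpacq_sd = stats::sd(x),
               swd_mean = mean(y), swd_sd = stats::sd(y),
               mean_diff = mean(x) - mean(y),
               p_value = if (is.null(pt)) NA_real_ else pt$p,
               pearson_r = r,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-way gender-by-age ANOVA on difference scores
#'
#' Fits difference scores (questionnaire minus sensor-diary, one
#' parameter) against gender, age group and their interaction with Type
#' III sums of squares under sum-to-zero contrasts, and — when the age
#' main effect is significant at 0.05 — runs Tukey HSD post-hoc
#' comparisons across the three age groups.
#'
#' @param cohort a [paired_cohort()].
#' @param parameter one parameter name from [PROFILE_PARAMETERS].
#' @param alpha significance level gating the post-hoc tests.
#' @return list of class `subgroup_anova`: `parameter`, `cell_means`
#'   (gender x age group), `effects` (data.frame with F and p for gender,
#'   age group, interaction), `tukey_age` (data.frame or `NULL`).
#' @export
subgroup_anova <- function(cohort, parameter, alpha = 0.05) {
  stopifnot(inherits(cohort, "paired_cohort"),
            parameter %in% PROFILE_PARAMETERS)
  df <- data.frame(
    d = cohort$fpacq[[parameter]] - cohort$swd[[parameter]],
    gender = factor(cohort$subjects$gender, levels = c("male", "female")),
    age_group = factor(cohort$subjects$age_group, levels = AGE_GROUPS)
  )
  df <- droplevels(df)
  counts <- table(df$gender, df$age_group)
  if (any(counts < 2)) {
    bad <- which(counts < 2, arr.ind = TRUE)[1, ]
    stop("subgroup ANOVA needs >= 2 subjects per cell; cell ",
         rownames(counts)[bad[1]], " x ", colnames(counts)[bad[2]],
         " has ", counts[bad[1], bad[2]])
  }
  fit <- stats::lm(d ~ gender * age_group, data = df,
                   contrasts = list(gender = "contr.sum",
                                    age_group = "contr.sum"))
  rss <- sum(stats::residuals(fit)^2)
  if (rss > 1e-10 * max(1, sum(df$d^2))) {
    a3 <- car::Anova(fit, type = 3)
  } else {
    # degenerate noiseless data: Type III sums of squares by explicit
    # term deletion; zero-SS effects get F = 0, nonzero ones F = Inf
    d1 <- suppressWarnings(stats::drop1(fit, . ~ ., test = "F"))
    a3 <- data.frame("Sum Sq" = d1[["Sum of Sq"]],
                     "F value" = ifelse(d1[["Sum of Sq"]] < 1e-12, 0, Inf),
                     "Pr(>F)" = ifelse(d1[["Sum of Sq"]] < 1e-12, 1, 0),
                     row.names = rownames(d1), check.names = FALSE)
  }
  pick <- function(term) {
    i <- match(term, rownames(a3))
    ss <- a3[i, "Sum Sq"]
    f <- a3[i, "F value"]
    p <- a3[i, "Pr(>F)"]
    if (!is.na(ss) && ss < 1e-12) { f <- 0; p <- 1 }  # no effect at all
    c(F = f, p = p)
  }
  eff <- rbind(gender = pick("gender"), age_group = pick("age_group"),
               interaction = pick("gender:age_group"))
  effects <- data.frame(term = rownames(eff), F = eff[, "F"], p = eff[, "p"],
                        row.names = NULL, stringsAsFactors = FALSE)

  cell_means <- tapply(df$d, list(df$gender, df$age_group), mean)

  tukey_age <- NULL
  if (!is.na(effects$p[effects$term == "age_group"]) &&
      effects$p[effects$term == "age_group"] < alpha &&
      nlevels(df$age_group) > 1) {
    aovfit <- stats::aov(d ~ gender * age_group, data = df)
    tk <- stats::TukeyHSD(aovfit, which = "age_group")$age_group
    tukey_age <- data.frame(
      comparison = rownames(tk),
      diff = tk[, "diff"], p_adj = tk[, "p adj"],
      significant = !is.na(tk[, "p adj"]) & tk[, "p adj"] < alpha &
        abs(tk[, "diff"]) > 1e-12,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(parameter = parameter, cell_means = cell_means,
                 effects = effects, tukey_age = tukey_age,
                 n = nrow(df)),
            class = "subgroup_anova")
}

#' @export
print.subgroup_anova <- function(x, ...) {
  cat("Two-way ANOVA of difference scores:", x$parameter,
      sprintf("(n = %d)\n", x$n))
  print(x$effects, row.names = FALSE)
  cat("cell means (gender x age group):\n")
  print(round(x$cell_means, 3))
  if (!is.null(x$tukey_age)) {
    cat("Tukey HSD, age groups:\n")
    print(x$tukey_age, row.names = FALSE)
  }
  invisible(x)
}

#' Published reference-cohort means for the twenty parameters
#'
#' Mean and SD of every parameter under both methods from a published
#' comparison cohort of 442 Flemish adults, shipped for worked examples
#' and consistency checks of the scoring constants.
#'
#' @return data.frame with `parameter`, `fpacq_mean`, `fpacq_sd`,
#'   `swd_mean`, `swd_sd`.
#' @export
reference_cohort_means <- function() {
  utils::read.csv(system.file("extdata", "reference_cohort_means.csv",
                              package = "actagree"),
                  stringsAsFactors = FALSE)
}

#' Degenerate paired cohort from published group means
#'
#' Wraps a table of per-method group means (as from
#' [reference_cohort_means()]) as a single-"subject" paired cohort, so
#' that [difference_table()] reproduces the published mean-difference
#' arithmetic.
#'
#' @param means data.frame with `parameter`, `fpacq_mean`, `swd_mean`.
#' @return a [paired_cohort()] with one row per side.
#' @export
means_as_cohort <- function(means = reference_cohort_means()) {
  fp <- as.data.frame(as.list(stats::setNames(means$fpacq_mean,
                                              means$parameter)))
  sw <- as.data.frame(as.list(stats::setNames(means$swd_mean,
                                              means$parameter)))
  fp$subject_id <- "group_mean"
  sw$subject_id <- "group_mean"
  subjects <- data.frame(subject_id = "group_mean", gender = "female",
                         age_years = 41, stringsAsFactors = FALSE)
  paired_cohort(subjects, fp, sw)
}
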
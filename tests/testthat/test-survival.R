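test_that("onset is dated halfway between the bracketing visits", {
  expect_equal(onset_time(4, 7), 5.5)
  expect_equal(onset_time(0, 2), 1)
  expect_error(onset_time(2, 2), "last_normal")
  expect_error(onset_time(4, 2), "last_normal")
  # shifting both visit dates shifts the onset by the same amount
  set.seed(30)
  a <- runif(20, 0, 4)
  b <- a + runif(20, 0.5, 3)
  d <- runif(20, 0, 5)
  expect_equal(onset_time(a + d, b + d), onset_time(a, b) + d)
})

test_that("survival records encode events, deaths and dropouts", {
  co <- tiny_cohort()
  # add a death and a zero-exposure dropout to the hand-built cohort
  b <- co$baseline
  v <- co$visits
  b <- rbind(b,
             tiny_baseline_row("D01", 74, 1, 0.5, 0.1, 0.05, death_time = 3),
             tiny_baseline_row("Z01", 75, 1, 0.5, 0.1, 0.05,
                               dropout_time = 1))
  v <- rbind(v, tiny_visits("D01", c(0, 2), c("normal", "normal")),
             tiny_visits("Z01", 0, "normal"))
  co2 <- wml_cohort(b, v)
  expect_message(rec <- build_survival_records(co2), "zero exposure")
  rownames(rec) <- rec$subject_id
  # incident case at the year-2 visit: onset placed at year 1
  expect_true(rec["T01", "event"])
  expect_equal(rec["T01", "exit_age"], rec["T01", "entry_age"] + 1)
  expect_identical(rec["T01", "event_type"], "mci")
  # death without MCI/dementia censors at the age of death
  expect_false(rec["D01", "event"])
  expect_equal(rec["D01", "exit_age"], 74 + 3)
  # no post-baseline visit: censored at entry, flagged
  expect_true(rec["Z01", "zero_exposure"])
  expect_equal(rec["Z01", "exit_age"], rec["Z01", "entry_age"])
  # everyone else censored at the last attended visit
  expect_equal(rec["L01", "exit_age"], rec["L01", "entry_age"] + 7)
})

test_that("incidence denominators conserve person-years exactly", {
  expect_equal(rate_per_1000(11, 2637), 1000 * 11 / 2637)
  expect_equal(round(rate_per_1000(11, 2637), 1), 4.2)
  expect_equal(round(rate_per_1000(100, 2637)), 38)
  expect_equal(rate_per_1000(0, 100), 0)
  expect_error(rate_per_1000(5, 0), "person_years")
  co <- generate_cohort(cohort_config(n_subjects = 200L), seed = 12)
  rec <- suppressMessages(build_survival_records(co))
  inc <- incidence_rate(rec)
  expect_equal(inc$person_years, sum(rec$exit_age - rec$entry_age))
  expect_equal(inc$events, sum(rec$event))
  expect_equal(incidence_rate(rec, "mci")$events +
                 incidence_rate(rec, "dementia")$events, inc$events)
})

test_that("delayed-entry fits match an independent Newton implementation", {
  for (seed in 1:50) {
    d <- random_cox_data(n = 40, seed = seed, p = 2)
    fit <- cox_delayed_entry(d, covariates = c("x1", "x2"))
    want <- oracle_cox_coef(d$entry_age, d$exit_age, d$event,
                            d[, c("x1", "x2")])
    expect_equal(fit$table$coef, unname(want), tolerance = 1e-6)
  }
})

test_that("late-entering censored subjects leave the fit untouched", {
  d <- random_cox_data(n = 30, seed = 900, p = 1)
  extra <- d[1, ]
  extra$entry_age <- max(d$exit_age) + 1  # enters after every event age
  extra$exit_age <- extra$entry_age + 2
  extra$event <- FALSE
  fit1 <- cox_delayed_entry(d, covariates = "x1")
  fit2 <- cox_delayed_entry(rbind(d, extra), covariates = "x1")
  expect_equal(fit1$table$coef, fit2$table$coef, tolerance = 1e-9)
})

test_that("the Wald test keeps its size under a null covariate", {
  set.seed(31)
  reject <- logical(200)
  for (i in 1:200) {
    n <- 200
    entry <- 65 + runif(n, 0, 10)
    x <- rbinom(n, 1, 0.5)
    gap <- rexp(n, 0.15)
    cens <- runif(n, 1, 7)
    d <- data.frame(entry_age = entry, exit_age = entry + pmin(gap, cens),
                    event = gap <= cens, zero_exposure = FALSE, x1 = x)
    fit <- cox_delayed_entry(d, covariates = "x1")
    reject[i] <- fit$table$p[fit$table$term == "x1"] < 0.05
  }
  expect_gt(mean(reject), 0.015)
  expect_lt(mean(reject), 0.095)
})

test_that("hazard ratios are coherent under a reference switch", {
  co <- generate_cohort(cohort_config(), seed = 14)
  pat <- assign_pattern(wml_features(co), fixed_consensus())
  rec <- suppressMessages(build_survival_records(co, pat))
  f1 <- cox_delayed_entry(rec, model = 5, reference = "pattern1")
  f2 <- cox_delayed_entry(rec, model = 5, reference = "pattern2")
  hr31 <- f1$table$hr[f1$table$term == "patternpattern3"]
  hr21 <- f1$table$hr[f1$table$term == "patternpattern2"]
  hr32 <- f2$table$hr[f2$table$term == "patternpattern3"]
  expect_equal(hr32, hr31 / hr21, tolerance = 1e-6)
  # CI bounds are exp(coef +/- 1.96 se) by construction
  row <- f1$table[f1$table$term == "patternpattern3", ]
  expect_equal(row$lower, exp(row$coef - 1.96 * row$se))
  expect_equal(row$upper, exp(row$coef + 1.96 * row$se))
  expect_gt(row$hr, 0)
})

test_that("model-5 covariates drop subjects with missing MRI measures", {
  co <- generate_cohort(cohort_config(), seed = 15)
  pat <- assign_pattern(wml_features(co), fixed_consensus())
  rec <- suppressMessages(build_survival_records(co, pat))
  f5 <- cox_delayed_entry(rec, model = 5)
  complete <- stats::complete.cases(
    rec[, c("hippocampal_volume", "silent_brain_infarcts")])
  expect_equal(f5$n, sum(complete & !rec$zero_exposure))
  expect_identical(cox_model_covariates(1), c("sex", "education"))
  expect_length(cox_model_covariates(5), 10)
})
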
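test_that("cohort files round-trip field for field and byte-stably", {
  co <- tiny_cohort()
  bf <- withr::local_tempfile(fileext = ".csv")
  vf <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, bf, vf)
  back <- read_cohort(bf, vf)
  expect_equal(back$baseline, co$baseline)
  expect_equal(back$visits, co$visits)
  b2 <- withr::local_tempfile(fileext = ".csv")
  v2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, b2, v2)
  expect_identical(readLines(bf), readLines(b2))
  expect_identical(readLines(vf), readLines(v2))
})

test_that("a generated cohort survives read/write/read unchanged", {
  co <- generate_cohort(cohort_config(n_subjects = 120L), seed = 11)
  bf <- withr::local_tempfile()
  vf <- withr::local_tempfile()
  tf <- withr::local_tempfile()
  write_cohort(co, bf, vf, truth_file = tf)
  back <- read_cohort(bf, vf)
  expect_equal(back$baseline, co$baseline)
  expect_equal(back$visits, co$visits)
  # missing optional fields written as the empty sentinel, restored as NA
  expect_true(anyNA(back$baseline$hippocampal_volume) ||
                anyNA(back$baseline$silent_brain_infarcts) ||
                anyNA(back$baseline$death_time))
  expect_true(file.exists(tf))
})

test_that("rows violating invariants are rejected with diagnostics", {
  co <- tiny_cohort()
  bf <- withr::local_tempfile()
  vf <- withr::local_tempfile()
  write_cohort(co, bf, vf)
  # corrupt subject L01's stored total so the regions no longer add up
  lines <- readLines(bf)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  fields <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  fields <- c(fields, rep("", length(header) - length(fields)))
  fields[header == "wml_total"] <- "1.0"
  lines[2] <- paste(fields, collapse = ",")
  writeLines(lines, bf)
  expect_warning(kept <- read_cohort(bf, vf), "additivity|sum to")
  expect_equal(nrow(kept$baseline), nrow(co$baseline) - 1L)
  expect_false("L01" %in% kept$baseline$subject_id)
  # a missing mandatory column is a schema error, not a row rejection
  writeLines(sub("^subject_id,", "id,", readLines(vf)), vf)
  expect_error(read_cohort(bf, vf), "schema error")
})

test_that("constructor enforces visit ordering and censoring exclusivity", {
  co <- tiny_cohort()
  b <- co$baseline
  v <- co$visits
  v2 <- v
  v2$time[v2$subject_id == "L01"] <- c(0, 2, 2, 7)
  expect_error(wml_cohort(b, v2), "strictly increasing")
  v3 <- v[!(v$subject_id == "L02" & v$time == 0), ]
  expect_error(wml_cohort(b, v3), "first visit not at time 0")
  b2 <- b
  b2$death_time[1] <- 5
  b2$dropout_time[1] <- 6
  expect_error(wml_cohort(b2, v), "both death_time and dropout_time")
  b3 <- b
  b3$death_time[1] <- 3  # visits at 4 and 7 would postdate the death
  expect_error(wml_cohort(b3, v), "after death/dropout")
  v4 <- v
  v4$diagnosis[v4$subject_id == "T01"] <- c("normal", "mci", "normal", "mci")
  expect_error(wml_cohort(b, v4), "recovers")
})

test_that("the MCI-R rule needs a complaint plus one impaired test", {
  cfg <- cohort_config()
  norms <- generate_norms(cfg)
  cuts <- vapply(c("benton", "isaacs", "five_word_immediate",
                   "five_word_delayed"), function(test) {
    norms$cutoff[norms$test == test & norms$age_band == "70-74" &
                   norms$education_band == "primary"]
  }, numeric(1))
  low <- cuts - 1
  high <- cuts + 1
  # impaired scores without a complaint stay normal
  expect_identical(mci_r_diagnosis(FALSE, low, norms, "70-74", "primary"),
                   "normal")
  # complaint without any impaired test stays normal
  expect_identical(mci_r_diagnosis(TRUE, high, norms, "70-74", "primary"),
                   "normal")
  # a score exactly at the 20th-percentile cutoff counts as impaired
  one_at <- high
  one_at["isaacs"] <- cuts[["isaacs"]]
  expect_identical(mci_r_diagnosis(TRUE, one_at, norms, "70-74", "primary"),
                   "mci")
  expect_error(mci_r_diagnosis(TRUE, high[-1], norms, "70-74", "primary"),
               "missing test score")
  expect_error(mci_r_diagnosis(TRUE, high, norms, "70-74", "doctorate"),
               "no normative cutoff")
})

test_that("lowering a score never flips an mci call back to normal", {
  cfg <- cohort_config()
  norms <- generate_norms(cfg)
  set.seed(42)
  tests <- c("benton", "isaacs", "five_word_immediate", "five_word_delayed")
  for (rep in 1:50) {
    band <- sample(c("65-69", "70-74", "75+"), 1)
    edu <- sample(c("none", "primary", "secondary", "higher"), 1)
    sc <- vapply(tests, function(t) {
      norms$cutoff[norms$test == t & norms$age_band == band &
                     norms$education_band == edu] + rnorm(1, 0, 2)
    }, numeric(1))
    base <- mci_r_diagnosis(TRUE, sc, norms, band, edu)
    worse <- sc
    j <- sample(4, 1)
    worse[j] <- worse[j] - abs(rnorm(1, 2, 1))
    after <- mci_r_diagnosis(TRUE, worse, norms, band, edu)
    if (base == "mci") expect_identical(after, "mci")
  }
})

test_that("recorded visit diagnoses reproduce from scores and norms", {
  cfg <- cohort_config(n_subjects = 150L)
  co <- generate_cohort(cfg, seed = 5)
  norms <- generate_norms(cfg)
  b <- co$baseline
  v <- co$visits[co$visits$time > 0, ]
  idx <- match(v$subject_id, b$subject_id)
  tests <- c("benton", "isaacs", "five_word_immediate", "five_word_delayed")
  for (i in seq_len(nrow(v))) {
    band <- age_band(b$age_baseline[idx[i]] + v$time[i])
    rule <- mci_r_diagnosis(v$cognitive_complaint[i],
                            unlist(v[i, tests]), norms, band,
                            b$education[idx[i]])
    if (v$diagnosis[i] == "dementia") {
      # dementia supersedes the MCI call the scores alone would produce
      expect_identical(rule, "mci")
    } else {
      expect_identical(rule, v$diagnosis[i])
    }
  }
})

test_that("percentile norms must cover every band combination", {
  norms <- generate_norms(cohort_config())
  expect_s3_class(norms, "percentile_norms")
  expect_error(percentile_norms(norms$test[-1], norms$age_band[-1],
                                norms$education_band[-1], norms$cutoff[-1]),
               "must be present")
})
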
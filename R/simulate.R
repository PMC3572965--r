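# Synthetic longitudinal cohort generator.
#
# Emulates the statistical structure the pattern analysis assumes: an
# elderly MRI sub-cohort (baseline age 65-79) with right-skewed regional
# WML volumes calibrated to the study's baseline marginals, a planted
# three-pattern WML geography (total volume and temporal share
# thresholds), a pattern-dependent MCI/dementia hazard on the age
# timescale observed only at scheduled visits (years 0/2/4/7, hence
# interval censoring), and competing death / loss-to-follow-up
# censoring. The latent truth (pattern, onset age) is exported alongside
# the cohort for oracle-based testing; analysis stages never read it.

#' Generator configuration
#'
#' All tunable parameters of the synthetic cohort, with defaults set to
#' the study conditions the analysis is meant to recover:
#'
#' * Regional WML volume means (ml) `frontal 1.15, parietal 0.56,
#'   temporal 0.05, occipital 0.03`; the total WML volume is log-normal
#'   with mean equal to their sum (1.79 ml) and SD 3.56 ml, with a mild
#'   log-linear age trend. Temporal and occipital shares are
#'   zero-inflated log-normal: temporal/occipital involvement is
#'   all-or-nothing (a point mass of subjects with no lesion there, and
#'   a continuous component bounded away from zero, as when a single
#'   minimal detectable lesion already contributes a fraction of a
#'   percent of the total); the zero masses and log-scales are chosen so
#'   the regional volume means AND standard deviations reproduce the
#'   emulated baseline table. The frontal/parietal split of the
#'   remainder is Beta, with frontal > parietal (antero-posterior
#'   gradient). Shares are drawn independently of the total, so total
#'   volume and temporal WMLr are uncorrelated by construction.
#' * Planted pattern thresholds: total WML `1.587` ml, temporal WMLr
#'   `0.65` %. Pattern 3 (at or above both) has log hazard ratio
#'   `log(2.28)`; pattern 2 none.
#' * Hazard: piecewise-constant on age, with 2-year pieces whose
#'   multipliers follow the epidemiological age gradient of MCI/dementia
#'   incidence (incidence doubling roughly every 5.5 years of age);
#'   `baseline_hazard` is the pattern-1 rate near the cohort's mean age.
#'   `baseline_hazard = 0.026` makes the default 426-subject cohort
#'   produce on the order of 110 detected events over the 7-year
#'   schedule.
#' * Censoring: death and loss to follow-up, independent of the event
#'   process given age, with age-graded piecewise-constant hazards
#'   (`0.0055`/py and `0.032`/py near the mean age), calibrated to ~3%
#'   deaths and ~20% lost to follow-up, with the older (hence more
#'   lesioned) subjects over-represented among them.
#' * Covariates: prevalences and normal moments for the baseline
#'   covariates; hypertension and depressive symptomatology depend on
#'   the latent pattern (patterns 2/3 more hypertensive; pattern 2 more
#'   depressive symptomatology).
#' * Cognitive score model: per-test normal distributions whose means
#'   shift with age band and education level; after latent onset, scores
#'   drop by `score_decline_sd` reference SDs and a cognitive complaint
#'   is always present, so the recorded visit diagnoses are exactly
#'   reproducible from the scores by the MCI-R rule.
#'
#' @param n_subjects cohort size (default 426).
#' @param seed default RNG seed used by [generate_cohort()].
#' @param regional_means named regional WML volume means, ml.
#' @param total_sd SD of the total WML volume, ml.
#' @param share_zero_mass,share_sdlog zero-inflation mass and log-scale
#'   SD of the temporal/occipital share distributions.
#' @param frontal_share_conc Beta concentration of the frontal/parietal
#'   split.
#' @param age_mean,age_sd,age_range truncated-normal baseline age model.
#' @param log_total_age_slope increase of log total WML per year of age.
#' @param true_total_threshold,true_temporal_wmlr_threshold planted
#'   pattern thresholds (ml, %).
#' @param baseline_hazard pattern-1 event hazard below age 75, per
#'   person-year.
#' @param hazard_age_knots,hazard_age_multipliers piecewise-constant age
#'   profile of the baseline hazard.
#' @param log_hazard_pattern2,log_hazard_pattern3 planted log hazard
#'   ratios.
#' @param dementia_fraction probability that an incident case is
#'   dementia rather than MCI.
#' @param visit_times scheduled visit times, years since baseline,
#'   strictly increasing from 0.
#' @param death_rate,dropout_rate censoring rates per person-year near
#'   the cohort's mean age.
#' @param death_age_multipliers,dropout_age_multipliers age profiles of
#'   the censoring hazards (same 2-year pieces as the event hazard):
#'   mortality doubles roughly every 8 years of age and dropout every 10,
#'   so subjects who die or are lost are older — and, through the
#'   age-WML coupling, carry more lesions — than those who stay.
#' @param p_female,education_probs,p_vascular,p_apoe4 covariate model.
#' @param p_hypertension,p_depression per-pattern prevalences.
#' @param brain_volume_mean,brain_volume_sd,atrophy_mean,atrophy_sd,hippocampus_mean,hippocampus_sd
#'   normal models for the volumetric covariates.
#' @param p_missing_hippocampus,p_missing_sbi,p_sbi missingness and
#'   prevalence of the optional covariates.
#' @param p_complaint probability of a cognitive complaint at a visit
#'   before any latent onset.
#' @param score_model per-test list(mean, sd, age_slope, edu_slope).
#' @param score_decline_sd post-onset score drop in reference-SD units.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 426L,
                          seed = 1L,
                          regional_means = c(frontal = 1.15, parietal = 0.56,
                                             temporal = 0.05, occipital = 0.03),
                          total_sd = 3.56,
                          share_zero_mass = c(temporal = 0.35, occipital = 0.35),
                          share_sdlog = c(temporal = 0.5, occipital = 0.68),
                          frontal_share_conc = 7,
                          age_mean = 71.1, age_sd = 4.0,
                          age_range = c(65, 80),
                          log_total_age_slope = 0.12,
                          true_total_threshold = 1.587,
                          true_temporal_wmlr_threshold = 0.65,
                          baseline_hazard = 0.026,
                          hazard_age_knots = seq(67, 79, by = 2),
                          hazard_age_multipliers = 2^((seq(66, 80, by = 2) -
                                                         71.1) / 5.5),
                          log_hazard_pattern2 = 0,
                          log_hazard_pattern3 = log(2.28),
                          dementia_fraction = 11 / 111,
                          visit_times = c(0, 2, 4, 7),
                          death_rate = 0.0036,
                          dropout_rate = 0.026,
                          death_age_multipliers = 2^((seq(66, 80, by = 2) -
                                                        71.1) / 8),
                          dropout_age_multipliers = 2^((seq(66, 80, by = 2) -
                                                          71.1) / 10),
                          p_female = 0.55,
                          education_probs = c(none = 0.20, primary = 0.35,
                                              secondary = 0.30, higher = 0.15),
                          p_hypertension = c(pattern1 = 0.35, pattern2 = 0.55,
                                             pattern3 = 0.55),
                          p_vascular = 0.30,
                          p_apoe4 = 0.20,
                          p_depression = c(pattern1 = 0.12, pattern2 = 0.30,
                                           pattern3 = 0.15),
                          brain_volume_mean = 1017, brain_volume_sd = 101,
                          atrophy_mean = 15.2, atrophy_sd = 2.4,
                          hippocampus_mean = 5.8, hippocampus_sd = 0.8,
                          p_missing_hippocampus = 2 / 426,
                          p_missing_sbi = 8 / 426,
                          p_sbi = 0.20,
                          p_complaint = 0.20,
                          score_model = default_score_model(),
                          score_decline_sd = 3) {
  cfg <- as.list(environment())
  if (cfg$n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (any(cfg$regional_means < 0) || cfg$total_sd <= 0) {
    stop("degenerate WML distribution parameters", call. = FALSE)
  }
  if (cfg$true_total_threshold <= 0 ||
      cfg$true_temporal_wmlr_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  rates <- c(cfg$baseline_hazard, cfg$death_rate, cfg$dropout_rate)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (cfg$visit_times[1L] != 0 || any(diff(cfg$visit_times) <= 0)) {
    stop("visit_times must be strictly increasing and start at 0",
         call. = FALSE)
  }
  probs <- c(cfg$p_female, cfg$education_probs, cfg$p_hypertension,
             cfg$p_vascular, cfg$p_apoe4, cfg$p_depression, cfg$p_sbi,
             cfg$p_complaint, cfg$share_zero_mass, cfg$dementia_fraction,
             cfg$p_missing_hippocampus, cfg$p_missing_sbi)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$share_sdlog <= 0) || cfg$frontal_share_conc <= 0 ||
      cfg$age_sd <= 0 || cfg$total_sd <= 0) {
    stop("scale parameters must be positive", call. = FALSE)
  }
  for (mf in c("hazard_age_multipliers", "death_age_multipliers",
               "dropout_age_multipliers")) {
    if (length(cfg[[mf]]) != length(cfg$hazard_age_knots) + 1L ||
        any(cfg[[mf]] < 0)) {
      stop(mf, " must have one more element than hazard_age_knots",
           call. = FALSE)
    }
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Default cognitive score model
#'
#' Per-test normal reference distributions: `mean` and `sd` for the
#' youngest band / no formal education; the mean shifts by `age_slope`
#' per age band and `edu_slope` per education level. Values are
#' synthetic but sized like the short cognitive battery the diagnosis
#' uses (Benton visual retention, Isaacs set test, five-word immediate
#' and delayed recall).
#'
#' @return Named list, one entry per test.
#' @export
default_score_model <- function() {
  list(benton = list(mean = 12, sd = 2, age_slope = -0.5, edu_slope = 0.5),
       isaacs = list(mean = 33, sd = 6, age_slope = -2, edu_slope = 2),
       five_word_immediate = list(mean = 9.4, sd = 0.8, age_slope = -0.15,
                                  edu_slope = 0.15),
       five_word_delayed = list(mean = 8.8, sd = 1.2, age_slope = -0.3,
                                edu_slope = 0.3))
}

# per-band mean of one test's reference distribution
.score_band_mean <- function(spec, band_idx, edu_idx) {
  spec$mean + spec$age_slope * (band_idx - 1L) + spec$edu_slope * (edu_idx - 1L)
}

#' Normative cutoffs implied by the score model
#'
#' The 20th-percentile cutoff of every (test, age band, education band)
#' reference distribution, computed in closed form from the generator's
#' normal score model. Deterministic (independent of the seed): the
#' cutoffs are the exact quantiles, so the expected per-test impairment
#' rate among unimpaired subjects is exactly 20% in every band.
#'
#' @param config a [cohort_config].
#' @return A [percentile_norms] table.
#' @export
generate_norms <- function(config = cohort_config()) {
  grid <- expand.grid(test = COGNITIVE_TESTS, age_band = AGE_BANDS,
                      education_band = EDUCATION_LEVELS,
                      stringsAsFactors = FALSE)
  cutoff <- mapply(function(test, ab, eb) {
    spec <- config$score_model[[test]]
    stats::qnorm(0.2, .score_band_mean(spec, match(ab, AGE_BANDS),
                                       match(eb, EDUCATION_LEVELS)), spec$sd)
  }, grid$test, grid$age_band, grid$education_band)
  percentile_norms(grid$test, grid$age_band, grid$education_band, cutoff)
}

#' Draw raw (unimpaired) test scores
#'
#' Samples from the reference score distribution of each subject's band,
#' with no diagnostic conditioning — the distribution against which the
#' normative cutoffs of [generate_norms()] are defined. Used for
#' large-sample calibration checks of the norms.
#'
#' @param config a [cohort_config].
#' @param age,education vectors defining each subject's band.
#' @return Matrix (subjects x tests) of scores.
#' @export
draw_reference_scores <- function(config, age, education) {
  n <- length(age)
  band_idx <- match(age_band(age), AGE_BANDS)
  edu_idx <- match(education, EDUCATION_LEVELS)
  out <- matrix(NA_real_, n, length(COGNITIVE_TESTS),
                dimnames = list(NULL, COGNITIVE_TESTS))
  for (t in COGNITIVE_TESTS) {
    spec <- config$score_model[[t]]
    out[, t] <- stats::rnorm(n, .score_band_mean(spec, band_idx, edu_idx),
                             spec$sd)
  }
  out
}

# truncated normal on [lo, hi) by rejection
.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x >= hi)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] >= hi]
  }
  x
}

# E[exp(slope * (A - age_mean))] over the truncated age distribution,
# used to keep the total-WML mean calibrated despite the age trend
.age_trend_correction <- function(config) {
  if (config$log_total_age_slope == 0) return(0)
  f <- function(a) {
    exp(config$log_total_age_slope * (a - config$age_mean)) *
      stats::dnorm(a, config$age_mean, config$age_sd)
  }
  mass <- stats::pnorm(config$age_range[2L], config$age_mean, config$age_sd) -
    stats::pnorm(config$age_range[1L], config$age_mean, config$age_sd)
  log(stats::integrate(f, config$age_range[1L],
                       config$age_range[2L])$value / mass)
}

# first event age for a piecewise-constant hazard on age, starting at entry
.sample_onset_age <- function(entry, rate, knots, mults) {
  n <- length(entry)
  out <- rep(Inf, n)
  if (all(rate == 0)) return(out)
  rem <- stats::rexp(n)
  cur <- entry
  done <- rep(FALSE, n)
  bp <- c(knots, Inf)
  for (j in seq_along(mults)) {
    r <- rate * mults[j]
    width <- pmax(0, bp[j] - cur)
    hz <- ifelse(r > 0, r * width, 0)
    take <- !done & rem <= hz & r > 0
    out[take] <- cur[take] + rem[take] / r[take]
    done <- done | take
    rem <- rem - hz
    cur <- pmax(cur, bp[j])
  }
  out
}

# truncated-normal score draw via the probability integral transform:
# u ~ U(plo, phi), x = qnorm(u)
.rnorm_band <- function(mean, sd, plo, phi) {
  stats::qnorm(stats::runif(length(mean), plo, phi), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort under a [cohort_config]: baseline covariates and
#' regional WML volumes (additive by construction: the stored total is
#' the exact sum of the four regions), a latent onset age from the
#' pattern-dependent piecewise-constant hazard on the age timescale,
#' competing death/dropout times, and the visit history. Onsets are
#' observed only at the first attended scheduled visit after the latent
#' onset (interval censoring); the recorded visit diagnoses are exactly
#' consistent with the MCI-R rule applied to the drawn complaint and
#' test scores under [generate_norms()] (dementia visits also satisfy
#' the rule but are recorded as dementia, which supersedes MCI).
#'
#' @param config a [cohort_config].
#' @param seed RNG seed; defaults to `config$seed`. Identical config and
#'   seed give an identical cohort.
#' @param baseline_only if `TRUE`, skip visit histories (baseline visit
#'   only, no outcomes) — cheap cohorts for marginal calibration checks.
#' @return A [wml_cohort] whose `truth` element records each subject's
#'   latent pattern, onset age, event type and censoring times.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed,
                            baseline_only = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_subjects
  width <- max(4L, nchar(as.character(n)))
  ids <- sprintf(paste0("S%0", width, "d"), seq_len(n))

  age <- .rnorm_trunc(n, config$age_mean, config$age_sd,
                      config$age_range[1L], config$age_range[2L])
  sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  education <- sample(EDUCATION_LEVELS, n, replace = TRUE,
                      prob = config$education_probs)
  vascular <- stats::runif(n) < config$p_vascular
  apoe4 <- stats::runif(n) < config$p_apoe4
  brain_vol <- stats::rnorm(n, config$brain_volume_mean,
                            config$brain_volume_sd)
  atrophy <- stats::rnorm(n, config$atrophy_mean, config$atrophy_sd)
  hippo <- stats::rnorm(n, config$hippocampus_mean, config$hippocampus_sd)
  hippo[stats::runif(n) < config$p_missing_hippocampus] <- NA_real_
  sbi <- stats::runif(n) < config$p_sbi
  sbi[stats::runif(n) < config$p_missing_sbi] <- NA

  # total WML: log-normal with mean = sum of regional means, SD = total_sd,
  # and a log-linear age trend whose mean effect is integrated out
  m_total <- sum(config$regional_means)
  sdlog2 <- log(1 + (config$total_sd / m_total)^2)
  mulog <- log(m_total) - sdlog2 / 2 - .age_trend_correction(config)
  total <- stats::rlnorm(n, mulog +
                           config$log_total_age_slope * (age - config$age_mean),
                         sqrt(sdlog2))

  # regional shares, independent of the total
  share_mean <- config$regional_means / m_total
  draw_share <- function(m, region) {
    zm <- config$share_zero_mass[[region]]
    sl <- config$share_sdlog[[region]]
    meanlog <- log(share_mean[[region]] / (1 - zm)) - sl^2 / 2
    (stats::runif(m) >= zm) * stats::rlnorm(m, meanlog, sl)
  }
  s_t <- draw_share(n, "temporal")
  s_o <- draw_share(n, "occipital")
  bad <- which(s_t + s_o > 0.5)
  while (length(bad) > 0L) {
    s_t[bad] <- draw_share(length(bad), "temporal")
    s_o[bad] <- draw_share(length(bad), "occipital")
    bad <- bad[s_t[bad] + s_o[bad] > 0.5]
  }
  m_f <- (share_mean[["frontal"]]) /
    (1 - share_mean[["temporal"]] - share_mean[["occipital"]])
  b_split <- stats::rbeta(n, config$frontal_share_conc * m_f,
                          config$frontal_share_conc * (1 - m_f))
  frontal <- (1 - s_t - s_o) * b_split * total
  parietal <- (1 - s_t - s_o) * (1 - b_split) * total
  temporal <- s_t * total
  occipital <- s_o * total
  wml_total <- frontal + parietal + temporal + occipital  # exact additivity

  # latent pattern from the planted thresholds (boundary goes up)
  tw_r <- ifelse(wml_total > 0, 100 * temporal / wml_total, 0)
  pattern <- ifelse(wml_total < config$true_total_threshold, 1L,
                    ifelse(tw_r < config$true_temporal_wmlr_threshold, 2L, 3L))

  hypertension <- stats::runif(n) < config$p_hypertension[pattern]
  depression <- stats::runif(n) < config$p_depression[pattern]

  log_hr <- c(0, config$log_hazard_pattern2, config$log_hazard_pattern3)
  rate <- config$baseline_hazard * exp(log_hr[pattern])
  onset_age <- .sample_onset_age(age, rate, config$hazard_age_knots,
                                 config$hazard_age_multipliers)
  severe <- stats::runif(n) < config$dementia_fraction

  end_adm <- max(config$visit_times)
  death_lat <- .sample_onset_age(age, rep(config$death_rate, n),
                                 config$hazard_age_knots,
                                 config$death_age_multipliers) - age
  dropout_lat <- .sample_onset_age(age, rep(config$dropout_rate, n),
                                   config$hazard_age_knots,
                                   config$dropout_age_multipliers) - age
  death_time <- ifelse(death_lat <= end_adm & death_lat < dropout_lat,
                       death_lat, NA_real_)
  dropout_time <- ifelse(dropout_lat < end_adm & dropout_lat <= death_lat,
                         dropout_lat, NA_real_)

  baseline <- data.frame(
    subject_id = ids, age_baseline = age, sex = sex, education = education,
    hypertension = hypertension, vascular_history = vascular, apoe4 = apoe4,
    depressive_symptomatology = depression, total_brain_volume = brain_vol,
    brain_atrophy = atrophy, hippocampal_volume = hippo,
    silent_brain_infarcts = sbi,
    wml_frontal = frontal, wml_parietal = parietal, wml_temporal = temporal,
    wml_occipital = occipital, wml_total = wml_total,
    death_time = death_time, dropout_time = dropout_time,
    stringsAsFactors = FALSE)

  truth <- data.frame(
    subject_id = ids, true_pattern = PATTERN_LEVELS[pattern],
    onset_age = onset_age,
    latent_event_type = ifelse(severe, "dementia", "mci"),
    latent_death_time = death_lat, latent_dropout_time = dropout_lat,
    stringsAsFactors = FALSE)

  visit_times <- if (baseline_only) 0 else config$visit_times
  visit_list <- vector("list", length(visit_times))
  for (vi in seq_along(visit_times)) {
    t <- visit_times[vi]
    attended <- if (t == 0) rep(TRUE, n) else t < pmin(death_lat, dropout_lat)
    idx <- which(attended)
    m <- length(idx)
    post <- t > 0 & onset_age[idx] <= age[idx] + t
    diagnosis <- ifelse(post, ifelse(severe[idx], "dementia", "mci"), "normal")
    complaint <- post | stats::runif(m) < config$p_complaint
    band_idx <- match(age_band(age[idx] + t), AGE_BANDS)
    edu_idx <- match(education[idx], EDUCATION_LEVELS)
    scores <- matrix(NA_real_, m, length(COGNITIVE_TESTS),
                     dimnames = list(NULL, COGNITIVE_TESTS))
    for (tn in COGNITIVE_TESTS) {
      spec <- config$score_model[[tn]]
      mu <- .score_band_mean(spec, band_idx, edu_idx)
      x <- stats::rnorm(m, mu, spec$sd)
      # complaining but unimpaired subjects must score above every cutoff
      # (the cutoff is the exact 20th percentile, so truncate to (0.2, 1))
      keep_normal <- complaint & !post
      x[keep_normal] <- .rnorm_band(mu[keep_normal], spec$sd, 0.2, 1)
      # post-onset: centre shifted down by score_decline_sd reference SDs
      x[post] <- stats::rnorm(sum(post),
                              mu[post] - config$score_decline_sd * spec$sd,
                              spec$sd)
      scores[, tn] <- x
    }
    if (any(post)) {
      # the MCI-R rule needs >= 1 impaired test: force the first test below
      # its cutoff for the (rare) post-onset rows where none is
      cuts <- vapply(COGNITIVE_TESTS, function(tn) {
        spec <- config$score_model[[tn]]
        stats::qnorm(0.2, .score_band_mean(spec, band_idx, edu_idx), spec$sd)
      }, numeric(m))
      cuts <- matrix(cuts, nrow = m)
      none_low <- post & rowSums(scores <= cuts) == 0L
      if (any(none_low)) {
        spec <- config$score_model[[COGNITIVE_TESTS[1L]]]
        mu1 <- .score_band_mean(spec, band_idx, edu_idx)
        scores[none_low, 1L] <- .rnorm_band(mu1[none_low], spec$sd, 0, 0.2)
      }
    }
    visit_list[[vi]] <- data.frame(
      subject_id = ids[idx], time = t, cognitive_complaint = complaint,
      benton = scores[, "benton"], isaacs = scores[, "isaacs"],
      five_word_immediate = scores[, "five_word_immediate"],
      five_word_delayed = scores[, "five_word_delayed"],
      diagnosis = diagnosis, stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, visit_list)
  wml_cohort(baseline, visits, truth = truth)
}

#' Latent-truth patterns of a generated cohort
#'
#' @param cohort a generated [wml_cohort] with a truth table.
#' @return Factor of true patterns in baseline order.
#' @export
true_patterns <- function(cohort) {
  stopifnot(!is.null(cohort$truth))
  factor(cohort$truth$true_pattern[match(cohort$baseline$subject_id,
                                         cohort$truth$subject_id)],
         levels = PATTERN_LEVELS)
}
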
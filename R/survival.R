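# Onset dating, censoring, person-years, and delayed-entry Cox models.
#
# Age is the basic timescale with birth as the origin: a subject enters
# the risk set at the baseline age and leaves it at the exit age. Onsets
# are interval-censored by the visit schedule and dated by the midpoint
# rule; deaths censor at the age of death; subjects who attended no
# post-baseline visit are censored at entry with zero exposure and
# flagged; everyone else is censored at the last attended visit.

#' Midpoint onset date
#'
#' The onset of MCI/dementia is set halfway between the last follow-up
#' visit at which the subject was classified normal and the visit of
#' diagnosis.
#'
#' @param last_normal_visit,diagnosis_visit times in years since baseline
#'   (vectors of equal length); `diagnosis_visit` must be strictly later.
#' @return Midpoint time(s) in years since baseline.
#' @examples
#' onset_time(4, 7)  # 5.5
#' onset_time(0, 2)  # 1
#' @export
onset_time <- function(last_normal_visit, diagnosis_visit) {
  if (any(is.na(last_normal_visit)) || any(is.na(diagnosis_visit)) ||
      any(last_normal_visit < 0) ||
      any(diagnosis_visit <= last_normal_visit)) {
    stop("need diagnosis_visit > last_normal_visit >= 0", call. = FALSE)
  }
  (last_normal_visit + diagnosis_visit) / 2
}

#' Build delayed-entry survival records
#'
#' Converts a cohort (plus assigned WML patterns) into one record per
#' subject for the age-timescale Cox models: `entry_age` is the baseline
#' age; for incident cases `exit_age` is the entry age plus the midpoint
#' onset time and `event` is `TRUE`; subjects who died event-free are
#' censored at the age of death; subjects with no post-baseline visit
#' and no recorded death are censored at entry with zero exposure and
#' flagged (`zero_exposure`); all remaining subjects are censored at the
#' last attended visit.
#'
#' @param cohort a [wml_cohort].
#' @param patterns factor of assigned patterns in baseline order (from
#'   [assign_pattern()]), or `NULL` to omit the pattern column.
#' @return Data frame with `subject_id`, `entry_age`, `exit_age`,
#'   `event`, `event_type` (`none`/`mci`/`dementia`), `zero_exposure`,
#'   `pattern` (when supplied) and the baseline covariates.
#' @export
build_survival_records <- function(cohort, patterns = NULL) {
  stopifnot(inherits(cohort, "wml_cohort"))
  b <- cohort$baseline
  n <- nrow(b)
  if (!is.null(patterns)) stopifnot(length(patterns) == n)
  vs <- split(cohort$visits, factor(cohort$visits$subject_id,
                                    levels = b$subject_id))
  exit_time <- numeric(n)
  event <- logical(n)
  event_type <- rep("none", n)
  zero_exposure <- logical(n)
  for (i in seq_len(n)) {
    v <- vs[[i]]
    ev_idx <- which(v$diagnosis != "normal")
    if (length(ev_idx) > 0L) {
      j <- ev_idx[1L]
      if (j == 1L) {
        stop("subject ", b$subject_id[i],
             ": event at baseline; cohort must be incident-only",
             call. = FALSE)
      }
      exit_time[i] <- onset_time(v$time[j - 1L], v$time[j])
      event[i] <- TRUE
      event_type[i] <- v$diagnosis[j]
    } else if (!is.na(b$death_time[i])) {
      exit_time[i] <- b$death_time[i]
    } else {
      last <- max(v$time)
      exit_time[i] <- last
      if (last == 0) zero_exposure[i] <- TRUE
    }
  }
  out <- data.frame(subject_id = b$subject_id,
                    entry_age = b$age_baseline,
                    exit_age = b$age_baseline + exit_time,
                    event = event,
                    event_type = event_type,
                    zero_exposure = zero_exposure,
                    stringsAsFactors = FALSE)
  if (!is.null(patterns)) out$pattern <- factor(patterns, levels = PATTERN_LEVELS)
  covs <- c("sex", "education", "hypertension", "vascular_history", "apoe4",
            "depressive_symptomatology", "total_brain_volume",
            "brain_atrophy", "hippocampal_volume", "silent_brain_infarcts")
  out <- cbind(out, b[, covs, drop = FALSE])
  rownames(out) <- NULL
  if (any(zero_exposure)) {
    message(sum(zero_exposure),
            " subject(s) with no follow-up information: censored at entry",
            " with zero exposure (flagged)")
  }
  out
}

#' Incidence rate per 1000 person-years
#'
#' @param events number of events.
#' @param person_years total person-years at risk (must be positive).
#' @return `1000 * events / person_years`.
#' @examples
#' rate_per_1000(11, 2637)   # ~4.2
#' rate_per_1000(100, 2637)  # ~38
#' @export
rate_per_1000 <- function(events, person_years) {
  stopifnot(events >= 0, person_years > 0)
  1000 * events / person_years
}

#' Incidence of MCI/dementia in a record set
#'
#' Person-years are the exact sum of `exit_age - entry_age` over all
#' records (so incidence denominators are conserved by construction);
#' events can be restricted by type.
#'
#' @param records output of [build_survival_records()].
#' @param type `"all"`, `"mci"` or `"dementia"`.
#' @return List with `events`, `person_years` and `rate` (per 1000
#'   person-years).
#' @export
incidence_rate <- function(records, type = c("all", "mci", "dementia")) {
  type <- match.arg(type)
  ev <- records$event
  if (type != "all") ev <- ev & records$event_type == type
  py <- sum(records$exit_age - records$entry_age)
  list(events = sum(ev), person_years = py,
       rate = rate_per_1000(sum(ev), py))
}

#' Covariate sets of the nested Cox models
#'
#' Model 1 adjusts for sex and education (age is handled by the
#' delayed-entry age timescale, not duplicated as a covariate); models
#' 2-5 successively add vascular history and hypertension; APOE e4 and
#' depressive symptomatology; total brain volume; and hippocampal
#' volume, brain atrophy and silent brain infarcts.
#'
#' @param model integer 1-5.
#' @return Character vector of covariate column names.
#' @export
cox_model_covariates <- function(model) {
  stopifnot(model %in% 1:5)
  sets <- list(
    c("sex", "education"),
    c("vascular_history", "hypertension"),
    c("apoe4", "depressive_symptomatology"),
    c("total_brain_volume"),
    c("hippocampal_volume", "brain_atrophy", "silent_brain_infarcts"))
  unlist(sets[seq_len(model)])
}

#' Delayed-entry Cox proportional-hazards fit
#'
#' Fits the left-truncated Cox model on the age timescale: the risk set
#' at an event age `t` is every record with `entry_age < t <= exit_age`.
#' Pattern membership enters as two indicators against a configurable
#' reference level, so all three pairwise hazard-ratio contrasts can be
#' read off by switching the reference. Ties are handled with the Efron
#' approximation (event ages synchronised by the visit schedule produce
#' many ties). Records with missing covariate values are dropped (the
#' fully adjusted model loses the subjects without hippocampal volume or
#' silent-brain-infarct assessment), as are zero-exposure records.
#'
#' @param records output of [build_survival_records()] (with a `pattern`
#'   column).
#' @param model integer 1-5, see [cox_model_covariates()].
#' @param reference pattern level used as the hazard-ratio reference.
#' @param covariates optional explicit covariate vector overriding
#'   `model`.
#' @return Object of class `cox_fit`: list with `model`, `reference`,
#'   `n`, `n_events`, `table` (term, coef, se, hr, lower, upper, p; CI
#'   bounds `exp(coef +/- 1.96 se)`) and the underlying
#'   [survival::coxph] fit.
#' @export
cox_delayed_entry <- function(records, model = 5L, reference = "pattern1",
                              covariates = NULL) {
  if (is.null(covariates)) covariates <- cox_model_covariates(model)
  has_pattern <- "pattern" %in% names(records)
  if (has_pattern) stopifnot(reference %in% PATTERN_LEVELS)
  d <- records[!records$zero_exposure, , drop = FALSE]
  d <- d[stats::complete.cases(d[, covariates, drop = FALSE]), , drop = FALSE]
  if (sum(d$event) < 2L) stop("need at least 2 events", call. = FALSE)
  if (has_pattern) {
    d$pattern <- stats::relevel(droplevels(factor(d$pattern,
                                                  levels = PATTERN_LEVELS)),
                                ref = reference)
  }
  if ("education" %in% names(d)) {
    d$education <- factor(d$education, levels = EDUCATION_LEVELS)
  }
  if ("sex" %in% names(d)) d$sex <- factor(d$sex, levels = c("female", "male"))
  fml <- stats::reformulate(c(if (has_pattern) "pattern", covariates),
                            response = "survival::Surv(entry_age, exit_age, event)")
  fit <- survival::coxph(fml, data = d, ties = "efron",
                         control = survival::coxph.control(
                           eps = 1e-12, toler.chol = 1e-13, iter.max = 100))
  coefs <- stats::coef(fit)
  if (anyNA(coefs)) stop("Cox model did not converge (NA coefficients)",
                         call. = FALSE)
  if (any(abs(coefs) > 15)) {
    warning("very large coefficient: possible complete separation",
            call. = FALSE)
  }
  se <- sqrt(diag(fit$var))
  tab <- data.frame(term = names(coefs), coef = unname(coefs),
                    se = unname(se), hr = exp(unname(coefs)),
                    lower = exp(unname(coefs) - 1.96 * unname(se)),
                    upper = exp(unname(coefs) + 1.96 * unname(se)),
                    p = 2 * stats::pnorm(-abs(unname(coefs) / unname(se))),
                    stringsAsFactors = FALSE)
  structure(list(model = if (is.null(model)) NA_integer_ else model,
                 reference = reference, n = fit$n, n_events = fit$nevent,
                 table = tab, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> model %s, reference %s: n = %d, events = %d\n",
              as.character(x$model), x$reference, x$n, x$n_events))
  tab <- x$table
  tab$hr <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$lower, tab$upper)
  print(tab[, c("term", "hr", "p")], row.names = FALSE, digits = 2)
  invisible(x)
}

#' Hazard ratio of one pattern contrast
#'
#' Convenience accessor: the hazard ratio (and CI and p-value) of
#' `pattern` versus the fit's reference level.
#'
#' @param fit a `cox_fit`.
#' @param pattern pattern level of interest.
#' @return One-row data frame from the fit's coefficient table.
#' @export
pattern_hr <- function(fit, pattern = "pattern3") {
  row <- fit$table[fit$table$term == paste0("pattern", pattern), , drop = FALSE]
  if (nrow(row) == 0L) {
    row <- fit$table[fit$table$term == pattern, , drop = FALSE]
  }
  if (nrow(row) == 0L) stop("contrast not in model: ", pattern, call. = FALSE)
  row
}
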
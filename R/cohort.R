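# Domain types and file dialect for the longitudinal WML cohort.
#
# A cohort is a pair of tables: one baseline row per subject (regional WML
# volumes in ml, covariates, and the observed death/dropout times in years
# since baseline, if any) and a long-format visit table (scheduled follow-ups
# at years 0/2/4/7 with cognitive test scores and the panel diagnosis).

WML_REGIONS <- c("frontal", "parietal", "temporal", "occipital")

COGNITIVE_TESTS <- c("benton", "isaacs", "five_word_immediate", "five_word_delayed")

EDUCATION_LEVELS <- c("none", "primary", "secondary", "higher")

AGE_BANDS <- c("65-69", "70-74", "75+")

DIAGNOSIS_LEVELS <- c("normal", "mci", "dementia")

PATTERN_LEVELS <- c("pattern1", "pattern2", "pattern3")

WML_FEATURE_NAMES <- c("total_wml", "frontal_wmlr", "parietal_wmlr",
                       "temporal_wmlr", "occipital_wmlr")

# volumes must add up to the stored total within this absolute tolerance (ml)
ADDITIVITY_TOL <- 1e-9

baseline_columns <- function() {
  c("subject_id", "age_baseline", "sex", "education", "hypertension",
    "vascular_history", "apoe4", "depressive_symptomatology",
    "total_brain_volume", "brain_atrophy", "hippocampal_volume",
    "silent_brain_infarcts",
    paste0("wml_", WML_REGIONS), "wml_total",
    "death_time", "dropout_time")
}

visit_columns <- function() {
  c("subject_id", "time", "cognitive_complaint", COGNITIVE_TESTS, "diagnosis")
}

# column -> storage type for the file dialect
.baseline_types <- function() {
  c(subject_id = "character", age_baseline = "numeric", sex = "character",
    education = "character", hypertension = "logical",
    vascular_history = "logical", apoe4 = "logical",
    depressive_symptomatology = "logical", total_brain_volume = "numeric",
    brain_atrophy = "numeric", hippocampal_volume = "numeric",
    silent_brain_infarcts = "logical",
    wml_frontal = "numeric", wml_parietal = "numeric",
    wml_temporal = "numeric", wml_occipital = "numeric",
    wml_total = "numeric", death_time = "numeric", dropout_time = "numeric")
}

.visit_types <- function() {
  c(subject_id = "character", time = "numeric",
    cognitive_complaint = "logical",
    benton = "numeric", isaacs = "numeric",
    five_word_immediate = "numeric", five_word_delayed = "numeric",
    diagnosis = "character")
}

#' Construct a validated WML cohort
#'
#' Bundles the one-row-per-subject baseline table and the long-format visit
#' table into a `wml_cohort` object, after checking every structural
#' invariant of the study design: regional volumes must add up to the stored
#' total (within `1e-9` ml), baseline ages must lie in `[65, 80)`, each
#' subject's visits must start at time 0 and be strictly increasing, the
#' diagnosis sequence must be monotone (no recovery from `mci`/`dementia`
#' back to `normal`), at most one of death/dropout may end a record, and no
#' visit may occur at or after that terminating time.
#'
#' @param baseline data frame with the columns of [baseline_columns()].
#' @param visits data frame with the columns of [visit_columns()].
#' @param truth optional per-subject latent-truth table produced by the
#'   synthetic generator (true pattern, latent onset age). It is carried
#'   along for oracle-based testing only; no analysis stage reads it.
#' @return An object of class `wml_cohort`: a list with elements `baseline`,
#'   `visits` (sorted by subject then time) and `truth` (possibly `NULL`).
#' @seealso [read_cohort()], [write_cohort()], [generate_cohort()]
#' @export
wml_cohort <- function(baseline, visits, truth = NULL) {
  problems <- check_cohort(baseline, visits)
  if (length(problems) > 0L) {
    stop("invalid cohort:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  ord <- order(match(visits$subject_id, baseline$subject_id), visits$time)
  visits <- visits[ord, visit_columns(), drop = FALSE]
  rownames(baseline) <- NULL
  rownames(visits) <- NULL
  structure(list(baseline = baseline[, baseline_columns(), drop = FALSE],
                 visits = visits, truth = truth),
            class = "wml_cohort")
}

#' Check cohort invariants
#'
#' Validates a candidate baseline/visit table pair and returns a character
#' vector of human-readable problems (empty when the cohort is valid). Used
#' by [wml_cohort()] (which turns problems into an error) and by
#' [read_cohort()] (which rejects the offending subjects row by row).
#'
#' @inheritParams wml_cohort
#' @return Character vector of diagnostics, one per violated invariant,
#'   each naming the subject and baseline row concerned.
#' @export
check_cohort <- function(baseline, visits) {
  problems <- character(0)
  miss_b <- setdiff(baseline_columns(), names(baseline))
  miss_v <- setdiff(visit_columns(), names(visits))
  if (length(miss_b) > 0L || length(miss_v) > 0L) {
    return(sprintf("missing mandatory column(s): %s",
                   paste(c(miss_b, miss_v), collapse = ", ")))
  }
  if (anyDuplicated(baseline$subject_id)) {
    problems <- c(problems, sprintf(
      "duplicated subject_id: %s",
      paste(unique(baseline$subject_id[duplicated(baseline$subject_id)]),
            collapse = ", ")))
  }
  orphan <- setdiff(visits$subject_id, baseline$subject_id)
  if (length(orphan) > 0L) {
    problems <- c(problems, sprintf(
      "visit rows for unknown subject(s): %s", paste(orphan, collapse = ", ")))
  }
  ids <- baseline$subject_id
  tag <- sprintf("subject %s (baseline row %d)", ids, seq_along(ids))
  add_problem <- function(problems, bad, msg) {
    c(problems, if (any(bad)) paste0(tag[bad], ": ", msg) else character(0))
  }
  regions <- as.matrix(baseline[, paste0("wml_", WML_REGIONS)])
  total <- baseline$wml_total
  miss_wml <- rowSums(is.na(regions)) > 0L | is.na(total)
  problems <- add_problem(problems, miss_wml, "missing WML volume")
  neg <- !miss_wml & (rowSums(regions < 0) > 0L | total < 0)
  problems <- add_problem(problems, neg, "negative WML volume")
  nonadd <- !miss_wml & abs(rowSums(regions) - total) > ADDITIVITY_TOL
  if (any(nonadd)) {
    problems <- c(problems, sprintf(
      "%s: regional volumes sum to %.9g but wml_total is %.9g",
      tag[nonadd], rowSums(regions)[nonadd], total[nonadd]))
  }
  bad_age <- is.na(baseline$age_baseline) | baseline$age_baseline < 65 |
    baseline$age_baseline >= 80
  problems <- add_problem(problems, bad_age, "age_baseline outside [65, 80)")
  both_end <- !is.na(baseline$death_time) & !is.na(baseline$dropout_time)
  problems <- add_problem(problems, both_end,
                          "both death_time and dropout_time recorded")
  end_time <- pmin(ifelse(is.na(baseline$death_time), Inf,
                          baseline$death_time),
                   ifelse(is.na(baseline$dropout_time), Inf,
                          baseline$dropout_time))
  vsplit <- split(visits[, c("time", "diagnosis")],
                  factor(visits$subject_id, levels = ids))
  for (i in seq_along(ids)) {
    v <- vsplit[[i]]
    if (nrow(v) == 0L) {
      problems <- c(problems, paste0(tag[i], ": no visits (baseline required)"))
      next
    }
    v <- v[order(v$time), , drop = FALSE]
    if (v$time[1L] != 0) {
      problems <- c(problems, paste0(tag[i], ": first visit not at time 0"))
    }
    if (any(diff(v$time) <= 0)) {
      problems <- c(problems,
                    paste0(tag[i], ": visit times not strictly increasing"))
    }
    if (is.finite(end_time[i]) && any(v$time >= end_time[i])) {
      problems <- c(problems,
                    paste0(tag[i], ": visit at or after death/dropout time"))
    }
    if (!all(v$diagnosis %in% DIAGNOSIS_LEVELS)) {
      problems <- c(problems, paste0(tag[i], ": unknown diagnosis value"))
    } else {
      sev <- match(v$diagnosis, DIAGNOSIS_LEVELS)
      if (any(sev < cummax(sev))) {
        problems <- c(problems,
                      paste0(tag[i], ": diagnosis recovers after mci/dementia"))
      }
    }
  }
  problems
}

#' Read a cohort from its two delimited text files
#'
#' Parses the baseline and visit tables (UTF-8 delimited text, comma by
#' default, empty field as the missing-value sentinel) and validates every
#' subject. Subjects violating a structural invariant (regional additivity,
#' visit ordering, ...) are rejected with a row-level diagnostic issued as a
#' warning; a missing mandatory column or an unparseable numeric field is an
#' error.
#'
#' @param baseline_file,visits_file paths to the two tables.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @return A validated [wml_cohort] containing the accepted subjects.
#' @export
read_cohort <- function(baseline_file, visits_file, sep = ",") {
  baseline <- .read_typed(baseline_file, .baseline_types(), sep)
  visits <- .read_typed(visits_file, .visit_types(), sep)
  problems <- check_cohort(baseline, visits)
  if (length(problems) > 0L) {
    bad <- unique(sub("^subject (\\S+) .*$", "\\1",
                      grep("^subject ", problems, value = TRUE)))
    if (any(!grepl("^subject ", problems))) {
      stop("cohort file error:\n  ",
           paste(problems[!grepl("^subject ", problems)], collapse = "\n  "),
           call. = FALSE)
    }
    warning("rejected ", length(bad), " subject(s):\n  ",
            paste(problems, collapse = "\n  "), call. = FALSE)
    baseline <- baseline[!(baseline$subject_id %in% bad), , drop = FALSE]
    visits <- visits[!(visits$subject_id %in% bad), , drop = FALSE]
  }
  wml_cohort(baseline, visits)
}

.read_typed <- function(path, types, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = "",
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(names(types), names(raw))
  if (length(miss) > 0L) {
    stop("schema error in ", path, ": missing mandatory column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- raw[, names(types), drop = FALSE]
  for (col in names(types)) {
    x <- out[[col]]
    if (types[[col]] == "numeric") {
      conv <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(conv))
      if (length(bad) > 0L) {
        stop(sprintf("parse error in %s, column %s, line %d: %s",
                     path, col, bad[1L] + 1L, x[bad[1L]]), call. = FALSE)
      }
      out[[col]] <- conv
    } else if (types[[col]] == "logical") {
      conv <- rep(NA, length(x))
      conv[!is.na(x) & x == "TRUE"] <- TRUE
      conv[!is.na(x) & x == "FALSE"] <- FALSE
      bad <- which(!is.na(x) & is.na(conv))
      if (length(bad) > 0L) {
        stop(sprintf("parse error in %s, column %s, line %d: %s",
                     path, col, bad[1L] + 1L, x[bad[1L]]), call. = FALSE)
      }
      out[[col]] <- conv
    }
  }
  out
}

#' Write a cohort to its two delimited text files
#'
#' Serialises a [wml_cohort] in the fixed column order of the file dialect,
#' with missing optional fields written as empty fields and numeric values
#' written losslessly (`%.17g`), so that
#' `read_cohort(write_cohort(x)) == x` field for field and repeated writes
#' are byte-identical.
#'
#' @param cohort a [wml_cohort].
#' @param baseline_file,visits_file output paths.
#' @param truth_file optional path for the generator's latent-truth table;
#'   written only when the cohort carries one. Downstream analysis stages
#'   never read this file.
#' @param sep field delimiter.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, baseline_file, visits_file,
                         truth_file = NULL, sep = ",") {
  stopifnot(inherits(cohort, "wml_cohort"))
  if (any(grepl(sep, cohort$baseline$subject_id, fixed = TRUE))) {
    stop("subject_id must not contain the field delimiter", call. = FALSE)
  }
  .write_typed(cohort$baseline, .baseline_types(), baseline_file, sep)
  .write_typed(cohort$visits, .visit_types(), visits_file, sep)
  if (!is.null(truth_file) && !is.null(cohort$truth)) {
    tt <- cohort$truth
    types <- vapply(tt, function(x) {
      if (is.numeric(x)) "numeric" else if (is.logical(x)) "logical" else "character"
    }, character(1))
    .write_typed(tt, types, truth_file, sep)
  }
  invisible(cohort)
}

.write_typed <- function(df, types, path, sep) {
  df <- df[, names(types), drop = FALSE]
  cols <- lapply(names(types), function(col) {
    x <- df[[col]]
    out <- switch(types[[col]],
                  numeric = sprintf("%.17g", as.numeric(x)),
                  logical = ifelse(x, "TRUE", "FALSE"),
                  as.character(x))
    out[is.na(x)] <- ""
    out
  })
  lines <- c(paste(names(types), collapse = sep),
             do.call(paste, c(cols, sep = sep)))
  writeLines(lines, path)
}

#' Age band used by the normative tables
#'
#' Maps an age in years to the 5-year band of the cognitive normative
#' tables (`65-69`, `70-74`, `75+`; the last band is open-ended so that it
#' also covers ages attained during follow-up).
#'
#' @param age numeric vector of ages in years (>= 65).
#' @return Character vector of band labels.
#' @export
age_band <- function(age) {
  stopifnot(all(age >= 65))
  AGE_BANDS[pmin(findInterval(age, c(65, 70, 75)), 3L)]
}

#' Normative percentile table
#'
#' Builds a `percentile_norms` object: for every (test, age band,
#' education level) combination, the score at the 20th percentile of the
#' corresponding reference distribution. [mci_r_diagnosis()] classifies a
#' test as impaired when the observed score is at or below this cutoff.
#'
#' @param test,age_band,education_band,cutoff vectors of equal length
#'   describing each cell of the table.
#' @return A data frame of class `percentile_norms`.
#' @export
percentile_norms <- function(test, age_band, education_band, cutoff) {
  df <- data.frame(test = test, age_band = age_band,
                   education_band = education_band, cutoff = cutoff,
                   stringsAsFactors = FALSE)
  full <- expand.grid(test = COGNITIVE_TESTS, age_band = AGE_BANDS,
                      education_band = EDUCATION_LEVELS,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$test, d$age_band, d$education_band)
  if (!all(key(full) %in% key(df))) {
    stop("percentile_norms: every (test, age band, education band) ",
         "combination must be present", call. = FALSE)
  }
  if (any(!is.finite(df$cutoff))) {
    stop("percentile_norms: cutoffs must be finite", call. = FALSE)
  }
  class(df) <- c("percentile_norms", "data.frame")
  df
}

norm_cutoff <- function(norms, test, age_band, education_band) {
  i <- which(norms$test == test & norms$age_band == age_band &
               norms$education_band == education_band)
  if (length(i) != 1L) {
    stop(sprintf("no normative cutoff for (%s, %s, %s)",
                 test, age_band, education_band), call. = FALSE)
  }
  norms$cutoff[i]
}

#' MCI-R diagnostic rule
#'
#' Applies the revised MCI algorithm: a subject is classified `mci` if and
#' only if a cognitive complaint is present AND at least one of the four
#' test scores (Benton visual retention, Isaacs set test, five-word
#' immediate and delayed recall) lies within the 20th percentile of the
#' age- and education-matched reference group. "Within the 20th
#' percentile" is read inclusively: a score exactly at the cutoff counts
#' as impaired.
#'
#' @param complaint logical, presence of a cognitive complaint.
#' @param scores named numeric vector (or list) with one score per test in
#'   `COGNITIVE_TESTS`; no score may be missing.
#' @param norms a [percentile_norms] table.
#' @param age_band,education_band the subject's bands at the time of
#'   testing (see [age_band()]; education is one of
#'   `none`/`primary`/`secondary`/`higher`).
#' @return `"mci"` or `"normal"`.
#' @export
mci_r_diagnosis <- function(complaint, scores, norms, age_band,
                            education_band) {
  stopifnot(is.logical(complaint), length(complaint) == 1L, !is.na(complaint))
  scores <- unlist(scores)
  miss <- setdiff(COGNITIVE_TESTS, names(scores))
  if (length(miss) > 0L || anyNA(scores[COGNITIVE_TESTS])) {
    stop("mci_r_diagnosis: missing test score(s): ",
         paste(c(miss, COGNITIVE_TESTS[is.na(scores[COGNITIVE_TESTS])]),
               collapse = ", "), call. = FALSE)
  }
  if (!complaint) return("normal")
  impaired <- vapply(COGNITIVE_TESTS, function(t) {
    scores[[t]] <= norm_cutoff(norms, t, age_band, education_band)
  }, logical(1))
  if (any(impaired)) "mci" else "normal"
}

#' @export
print.wml_cohort <- function(x, ...) {
  n <- nrow(x$baseline)
  nv <- nrow(x$visits)
  ev <- subject_event_labels(x)
  cat(sprintf("<wml_cohort> %d subjects, %d visit records, %d with incident MCI/dementia\n",
              n, nv, sum(ev)))
  cat(sprintf("  mean total WML %.2f ml (SD %.2f); baseline age %.1f (SD %.1f)\n",
              mean(x$baseline$wml_total), stats::sd(x$baseline$wml_total),
              mean(x$baseline$age_baseline), stats::sd(x$baseline$age_baseline)))
  if (!is.null(x$truth)) cat("  latent truth table attached\n")
  invisible(x)
}

#' Outcome labels for the pattern search
#'
#' One label per subject (in baseline order): `TRUE` when the subject has an
#' incident MCI or dementia diagnosis at any follow-up visit, `FALSE`
#' otherwise (including subjects censored by death or loss to follow-up).
#'
#' @param cohort a [wml_cohort].
#' @return Named logical vector.
#' @export
subject_event_labels <- function(cohort) {
  ev <- tapply(cohort$visits$diagnosis != "normal", cohort$visits$subject_id,
               any)
  out <- as.logical(ev[cohort$baseline$subject_id])
  names(out) <- cohort$baseline$subject_id
  out
}
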
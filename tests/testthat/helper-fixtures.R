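# Hand-built micro-cohorts with fully known arithmetic.

# One subject's baseline row; regional volumes given, total is their sum.
tiny_baseline_row <- function(id, age, frontal, parietal, temporal,
                              occipital, death_time = NA_real_,
                              dropout_time = NA_real_) {
  data.frame(subject_id = id, age_baseline = age, sex = "female",
             education = "primary", hypertension = FALSE,
             vascular_history = FALSE, apoe4 = FALSE,
             depressive_symptomatology = FALSE, total_brain_volume = 1000,
             brain_atrophy = 15, hippocampal_volume = 5.8,
             silent_brain_infarcts = FALSE,
             wml_frontal = frontal, wml_parietal = parietal,
             wml_temporal = temporal, wml_occipital = occipital,
             wml_total = frontal + parietal + temporal + occipital,
             death_time = death_time, dropout_time = dropout_time,
             stringsAsFactors = FALSE)
}

# visit rows with neutral scores; diagnosis sequence given per time
tiny_visits <- function(id, times, diagnoses,
                        complaint = diagnoses != "normal") {
  data.frame(subject_id = id, time = times,
             cognitive_complaint = complaint,
             benton = 12, isaacs = 33, five_word_immediate = 9.4,
             five_word_delayed = 8.8, diagnosis = diagnoses,
             stringsAsFactors = FALSE)
}

# 12 subjects separable only by the two-level structure: 6 low-total
# (never ill, with temporal shares straddling the high-load cases'), 4
# high-total with temporal involvement (all MCI at year 2), 2 high-total
# with a spared temporal region (never ill). Every single-feature split
# leaves healthy subjects inside the cases' range, so the tree must use
# total volume first and temporal share second.
tiny_cohort <- function() {
  lows <- rbind(
    tiny_baseline_row("L01", 68.5, 0.30, 0.10, 0.00, 0.010),
    tiny_baseline_row("L02", 69.0, 0.40, 0.15, 0.00, 0.010),
    tiny_baseline_row("L03", 69.5, 0.50, 0.10, 0.02, 0.010),
    tiny_baseline_row("L04", 70.0, 0.50, 0.15, 0.05, 0.010),
    tiny_baseline_row("L05", 70.5, 0.60, 0.15, 0.06, 0.012),
    tiny_baseline_row("L06", 71.0, 0.70, 0.17, 0.07, 0.020))
  hi_temp <- do.call(rbind, lapply(1:4, function(i) {
    tiny_baseline_row(sprintf("T%02d", i), 72 + i / 2,
                      frontal = 2 + 0.2 * i, parietal = 0.7,
                      temporal = 0.2 + 0.02 * i, occipital = 0.05)
  }))
  # spared temporal region but otherwise inside the cases' share ranges,
  # with the displaced share parked occipitally (priority breaks the
  # temporal/occipital tie in favour of temporal)
  hi_flat <- rbind(
    tiny_baseline_row("F01", 70.5, 2.343, 0.660, 0, 0.297),
    tiny_baseline_row("F02", 71.0, 2.520, 0.665, 0, 0.315))
  baseline <- rbind(lows, hi_temp, hi_flat)
  visits <- do.call(rbind, lapply(seq_len(nrow(baseline)), function(i) {
    id <- baseline$subject_id[i]
    if (grepl("^T", id)) {
      tiny_visits(id, c(0, 2, 4, 7), c("normal", "mci", "mci", "mci"))
    } else {
      tiny_visits(id, c(0, 2, 4, 7), rep("normal", 4))
    }
  }))
  wml_cohort(baseline, visits)
}
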
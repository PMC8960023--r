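# Harmonisation of raw captures into analysis categories, molecular
# subtyping, and the eligibility/deduplication flow.

#' Harmonise a hormone-receptor capture to positive/negative
#'
#' Allred fractions `x/8` are positive at `x >= allred_cutoff` (default 3,
#' the conventional threshold); percentages are positive at
#' `>= percent_cutoff` (default 1%); pre-categorised labels pass through.
#' A fraction with a denominator other than 8 is flagged ambiguous (`NA`
#' with attribute), as is an out-of-range category.
#'
#' @param value Captured number (Allred numerator, percent, or bare number
#'   treated as percent), or `NA`.
#' @param denominator Fraction denominator or `NA`.
#' @param category Captured category or `NA`.
#' @param allred_cutoff,percent_cutoff Positivity cutoffs.
#' @return `"positive"`, `"negative"` or `NA`.
#' @export
harmonize_receptor <- function(value = NA, denominator = NA, category = NA,
                               allred_cutoff = 3, percent_cutoff = 1) {
  if (!is.na(value)) {
    if (!is.na(denominator)) {
      if (denominator != 8) return(flagged_na("ambiguous_denominator"))
      return(if (value >= allred_cutoff) "positive" else "negative")
    }
    return(if (value >= percent_cutoff) "positive" else "negative")
  }
  if (!is.na(category)) {
    if (category %in% c("positive", "negative")) return(category)
    if (category == "equivocal") return(NA_character_)
    return(flagged_na("ambiguous_category"))
  }
  NA_character_
}

flagged_na <- function(reason) {
  structure(NA_character_, flag = reason)
}

#' Harmonise a HER2 capture to positive/negative
#'
#' IHC scores 0 and 1 are negative, 3 positive; the equivocal 2+ maps to
#' missing (HER2 is treated as strictly binary, with no reflex FISH
#' information available). Categorical labels pass through; scores outside
#' 0-3 are flagged ambiguous.
#'
#' @param value IHC score 0-3 or `NA`.
#' @param category Captured category or `NA`.
#' @return `"positive"`, `"negative"` or `NA`.
#' @export
harmonize_her2 <- function(value = NA, category = NA) {
  if (!is.na(value)) {
    if (value %in% c(0, 1)) return("negative")
    if (value == 3) return("positive")
    if (value == 2) return(NA_character_)
    return(flagged_na("her2_score_out_of_range"))
  }
  if (!is.na(category)) {
    if (category %in% c("positive", "negative")) return(category)
    if (category == "equivocal") return(NA_character_)
    return(flagged_na("ambiguous_category"))
  }
  NA_character_
}

#' Harmonise a grade capture to Nottingham bands I/II/III
#'
#' A Nottingham sum `x/9` maps 3-5 to I, 6-7 to II, 8-9 to III; literal
#' Roman numerals or arabic 1/2/3 pass through; sums outside 3-9 are
#' flagged ambiguous.
#'
#' @param value Nottingham sum (with `denominator` 9) or arabic band 1-3.
#' @param denominator Fraction denominator or `NA`.
#' @param category `"I"`, `"II"` or `"III"`, or `NA`.
#' @return `"I"`, `"II"`, `"III"` or `NA`.
#' @export
harmonize_grade <- function(value = NA, denominator = NA, category = NA) {
  if (!is.na(value)) {
    if (!is.na(denominator) && denominator == 9) {
      if (value < 3 || value > 9) return(flagged_na("grade_sum_out_of_range"))
      return(c("I", "I", "I", "II", "II", "III", "III")[value - 2])
    }
    if (value %in% 1:3) return(c("I", "II", "III")[value])
    return(flagged_na("grade_value_out_of_range"))
  }
  if (!is.na(category)) {
    if (category %in% c("I", "II", "III")) return(category)
    return(flagged_na("ambiguous_category"))
  }
  NA_character_
}

#' Dichotomise the Ki67 proliferation index at 14%
#'
#' Percentages below 14 are low (`"<14"`), 14 and above high (`">=14"`).
#' Pre-categorised labels map low/negative to `"<14"` and high/positive to
#' `">=14"`.
#'
#' @param value Percentage or `NA`.
#' @param category Captured category or `NA`.
#' @param cutoff Cutpoint, default 14.
#' @return `"<14"`, `">=14"` or `NA`.
#' @export
dichotomize_ki67 <- function(value = NA, category = NA, cutoff = 14) {
  if (!is.na(value)) {
    return(if (value < cutoff) "<14" else ">=14")
  }
  if (!is.na(category)) {
    if (category %in% c("low", "negative")) return("<14")
    if (category %in% c("high", "positive")) return(">=14")
    return(flagged_na("ambiguous_category"))
  }
  NA_character_
}

#' Derive the molecular subtype from receptor statuses
#'
#' ER+/HER2- is Luminal A and ER+/HER2+ Luminal B, regardless of PR;
#' ER-/PR-/HER2+ is HER2-overexpressing and ER-/PR-/HER2- triple negative.
#' Any missing input yields missing. The ER-/PR+ combination falls outside
#' the classification and is flagged unclassifiable (missing with attribute
#' `flag = "unclassifiable"`), never forced into a class.
#'
#' @param er,pr,her2 `"positive"`, `"negative"` or `NA`.
#' @return `"LuminalA"`, `"LuminalB"`, `"HER2-OE"`, `"TNBC"` or `NA`.
#' @export
derive_subtype <- function(er, pr, her2) {
  if (is.na(er) || is.na(pr) || is.na(her2)) return(NA_character_)
  if (er == "positive") {
    return(if (her2 == "negative") "LuminalA" else "LuminalB")
  }
  if (pr == "positive") return(flagged_na("unclassifiable"))
  if (her2 == "positive") "HER2-OE" else "TNBC"
}

#' Assign the analysis age band
#'
#' Bands `<40`, `40-49`, `50-59`, `60-69`, `70-104`.
#'
#' @param age Age in years.
#' @return Band label or `NA`.
#' @export
age_band <- function(age) {
  vapply(age, function(a) {
    if (is.na(a)) return(NA_character_)
    if (a < 40) "<40"
    else if (a < 50) "40-49"
    else if (a < 60) "50-59"
    else if (a < 70) "60-69"
    else "70-104"
  }, character(1))
}

#' Harmonise an extraction table into patient records
#'
#' Maps the raw per-parameter captures from [extract_corpus()] into
#' analysis categories (receptor statuses, grade bands, Ki67 index, age
#' band) and derives the molecular subtype, carrying along sex, episode
#' number and an empty-report flag from the corpus.
#'
#' @param extraction Data frame from [extract_corpus()].
#' @param reports The corpus the extraction came from.
#' @return Data frame of patient records, one row per report.
#' @export
harmonize_records <- function(extraction, reports) {
  stopifnot(nrow(extraction) == nrow(reports),
            all(extraction$report_id == reports$report_id))
  n <- nrow(extraction)
  g <- function(col) extraction[[col]]
  er <- character(n); pr <- character(n); her2 <- character(n)
  grade <- character(n); ki <- character(n); subtype <- character(n)
  for (i in seq_len(n)) {
    er[i] <- harmonize_receptor(g("ER_num")[i],
                                if (isTRUE(g("ER_pct")[i])) NA else g("ER_den")[i],
                                g("ER_cat")[i])
    pr[i] <- harmonize_receptor(g("PR_num")[i],
                                if (isTRUE(g("PR_pct")[i])) NA else g("PR_den")[i],
                                g("PR_cat")[i])
    her2[i] <- harmonize_her2(g("HER2_num")[i], g("HER2_cat")[i])
    grade[i] <- harmonize_grade(g("grade_num")[i], g("grade_den")[i], g("grade_cat")[i])
    ki[i] <- dichotomize_ki67(g("Ki67_num")[i], g("Ki67_cat")[i])
    subtype[i] <- derive_subtype(er[i], pr[i], her2[i])
  }
  age <- g("age_num")
  data.frame(
    report_id = extraction$report_id,
    patient_id = reports$patient_id %||% extraction$report_id,
    episode_number = reports$episode_number,
    sex = reports$sex,
    empty_report = is.na(reports$free_text) | !nzchar(reports$free_text),
    age_years = age,
    age_band = age_band(age),
    race = g("race_cat"),
    laterality = g("laterality_cat"),
    histologic_type = g("histologic_type_cat"),
    grade = grade,
    er_status = er,
    pr_status = pr,
    her2_status = her2,
    ki67_index = ki,
    subtype = subtype,
    stringsAsFactors = FALSE
  )
}

#' Apply eligibility criteria and deduplicate episodes
#'
#' Exclusion order: empty report, male case, duplicate episode, missing
#' molecular subtype. Within a duplicate-episode group the copy with the
#' most non-missing parameters is kept (ties favour the earlier report),
#' after field-wise merging that prefers non-missing values -- disparate
#' duplicate pairs thereby repair each other's gaps. Records are conserved:
#' every exclusion is logged with a reason and
#' `nrow(cohort) + nrow(exclusions) == nrow(records)`.
#'
#' @param records Data frame from [harmonize_records()].
#' @return List with `cohort` and `exclusions` (`report_id`, `reason`).
#' @export
apply_eligibility <- function(records) {
  excl <- list()
  note <- function(ids, reason) {
    if (length(ids)) {
      excl[[length(excl) + 1L]] <<- data.frame(report_id = ids, reason = reason,
                                               stringsAsFactors = FALSE)
    }
  }
  cur <- records

  drop <- cur$empty_report
  note(cur$report_id[drop], "empty_report")
  cur <- cur[!drop, , drop = FALSE]

  drop <- !is.na(cur$sex) & cur$sex == "male"
  note(cur$report_id[drop], "male")
  cur <- cur[!drop, , drop = FALSE]

  # dedup by episode within patient; merge fields preferring non-missing
  params <- c("age_years", "race", "laterality", "histologic_type", "grade",
              "er_status", "pr_status", "her2_status", "ki67_index")
  key <- paste(cur$patient_id, cur$episode_number, sep = "\r")
  if (anyDuplicated(key)) {
    keep_rows <- !duplicated(key)
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      grp <- cur[idx, , drop = FALSE]
      merged <- grp[1, , drop = FALSE]
      for (p in params) {
        vals <- grp[[p]]
        if (is.na(merged[[p]]) && any(!is.na(vals))) {
          merged[[p]] <- vals[which(!is.na(vals))[1]]
        }
      }
      richness <- rowSums(!is.na(grp[, params, drop = FALSE]))
      best <- idx[which.max(richness)]   # ties: earlier report wins
      merged$report_id <- cur$report_id[best]
      merged$subtype <- derive_subtype(merged$er_status, merged$pr_status,
                                       merged$her2_status)
      merged$ki67_index <- merged$ki67_index
      cur[idx[1], ] <- merged
      note(cur$report_id[setdiff(idx, idx[1])], "duplicate")
    }
    cur <- cur[keep_rows, , drop = FALSE]
  }

  drop <- is.na(cur$subtype)
  note(cur$report_id[drop], "no_subtype")
  cur <- cur[!drop, , drop = FALSE]

  exclusions <- if (length(excl)) do.call(rbind, excl) else {
    data.frame(report_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  list(cohort = cur, exclusions = exclusions)
}

#' Harmonised ground truth for a synthetic cohort
#'
#' Applies the same analysis categorisation to the generator's ground-truth
#' fields (Allred scores, IHC scores, Nottingham sums, Ki67 percentages) so
#' machine output can be scored against truth at the level the analysis
#' uses.
#'
#' @param truth Ground-truth data frame from [generate_corpus()].
#' @return Data frame with harmonised truth columns per report.
#' @export
harmonized_truth <- function(truth) {
  n <- nrow(truth)
  er <- ifelse(truth$er_allred >= 3, "positive", "negative")
  pr <- ifelse(truth$pr_allred >= 3, "positive", "negative")
  her2 <- ifelse(truth$her2_ihc == 3, "positive",
                 ifelse(truth$her2_ihc == 2, NA_character_, "negative"))
  grade <- ifelse(is.na(truth$grade_score), NA_character_,
                  c("I", "I", "I", "II", "II", "III", "III")[truth$grade_score - 2L])
  ki <- ifelse(is.na(truth$ki67_percent), NA_character_,
               ifelse(truth$ki67_percent < 14, "<14", ">=14"))
  subtype <- vapply(seq_len(n), function(i) {
    as.character(derive_subtype(er[i], pr[i], her2[i]))
  }, character(1))
  data.frame(
    report_id = truth$report_id,
    patient_id = truth$patient_id,
    age_years = truth$age,
    age_band = age_band(truth$age),
    race = truth$race,
    laterality = truth$laterality,
    histologic_type = truth$histologic_type,
    grade = grade,
    er_status = er,
    pr_status = pr,
    her2_status = her2,
    ki67_index = ki,
    subtype = subtype,
    stringsAsFactors = FALSE
  )
}

#' Per-parameter exact-match recovery accuracy
#'
#' Compares machine patient records to harmonised ground truth on the
#' analysis fields, scoring only reports where the truth is non-missing.
#'
#' @param machine Data frame from [harmonize_records()].
#' @param truth_h Data frame from [harmonized_truth()].
#' @return Named numeric vector of accuracies in `[0, 1]`.
#' @export
recovery_accuracy <- function(machine, truth_h) {
  stopifnot(all(machine$report_id %in% truth_h$report_id))
  truth_h <- truth_h[match(machine$report_id, truth_h$report_id), , drop = FALSE]
  fields <- c("age_years", "race", "laterality", "histologic_type", "grade",
              "er_status", "pr_status", "her2_status", "ki67_index")
  out <- vapply(fields, function(f) {
    obs <- !is.na(truth_h[[f]])
    if (!any(obs)) return(NA_real_)
    mean(!is.na(machine[[f]][obs]) & machine[[f]][obs] == truth_h[[f]][obs])
  }, numeric(1))
  out
}
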
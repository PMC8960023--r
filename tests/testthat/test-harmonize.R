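test_that("receptor harmonisation follows Allred and percent conventions", {
  expect_equal(harmonize_receptor(8, 8), "positive")
  expect_equal(harmonize_receptor(3, 8), "positive")
  expect_equal(harmonize_receptor(2, 8), "negative")
  expect_equal(harmonize_receptor(0, 8), "negative")
  expect_equal(harmonize_receptor(95), "positive")   # percent
  expect_equal(harmonize_receptor(0), "negative")
  expect_equal(harmonize_receptor(1), "positive")    # 1% boundary
  expect_equal(harmonize_receptor(category = "negative"), "negative")
  amb <- harmonize_receptor(5, 10)
  expect_true(is.na(amb))
  expect_equal(attr(amb, "flag"), "ambiguous_denominator")
  expect_true(is.na(harmonize_receptor()))
})

test_that("HER2 harmonisation treats 2+ as equivocal missing", {
  expect_equal(harmonize_her2(0), "negative")
  expect_equal(harmonize_her2(1), "negative")
  expect_equal(harmonize_her2(3), "positive")
  expect_true(is.na(harmonize_her2(2)))
  expect_equal(harmonize_her2(category = "positive"), "positive")
  out <- harmonize_her2(7)
  expect_true(is.na(out))
  expect_equal(attr(out, "flag"), "her2_score_out_of_range")
})

test_that("Nottingham sums map exhaustively onto grade bands", {
  expect_equal(harmonize_grade(5, 9), "I")
  expect_equal(harmonize_grade(9, 9), "III")
  expect_equal(vapply(3:9, function(s) harmonize_grade(s, 9), character(1)),
               c("I", "I", "I", "II", "II", "III", "III"))
  expect_equal(harmonize_grade(category = "II"), "II")
  expect_equal(harmonize_grade(2), "II")   # arabic band
  bad <- harmonize_grade(11, 9)
  expect_true(is.na(bad))
})

test_that("Ki67 dichotomises at 14 percent", {
  expect_equal(dichotomize_ki67(25), ">=14")
  expect_equal(dichotomize_ki67(13), "<14")
  expect_equal(dichotomize_ki67(14), ">=14")
  expect_equal(dichotomize_ki67(category = "high"), ">=14")
  expect_equal(dichotomize_ki67(category = "low"), "<14")
  expect_equal(dichotomize_ki67(category = "negative"), "<14")
  expect_true(is.na(dichotomize_ki67()))
})

test_that("subtype derivation matches the hand-written truth table over all 27 combinations", {
  states <- c("positive", "negative", NA_character_)
  # independent truth table, written out by hand
  oracle <- function(er, pr, her2) {
    if (is.na(er) || is.na(pr) || is.na(her2)) return(NA_character_)
    if (er == "positive" && her2 == "negative") return("LuminalA")
    if (er == "positive" && her2 == "positive") return("LuminalB")
    if (er == "negative" && pr == "negative" && her2 == "positive") return("HER2-OE")
    if (er == "negative" && pr == "negative" && her2 == "negative") return("TNBC")
    NA_character_  # ER-/PR+ unclassifiable
  }
  for (er in states) for (pr in states) for (her2 in states) {
    got <- derive_subtype(er, pr, her2)
    expect_identical(as.character(got), oracle(er, pr, her2),
                     info = sprintf("er=%s pr=%s her2=%s", er, pr, her2))
  }
  # the ER-/PR+ combination is flagged, not silently missing
  flagged <- derive_subtype("negative", "positive", "positive")
  expect_equal(attr(flagged, "flag"), "unclassifiable")
})

test_that("harmonisation is idempotent on already-normalised categories", {
  for (v in c("positive", "negative")) {
    expect_equal(harmonize_receptor(category = harmonize_receptor(category = v)), v)
    expect_equal(harmonize_her2(category = harmonize_her2(category = v)), v)
  }
  for (g in c("I", "II", "III")) {
    expect_equal(harmonize_grade(category = harmonize_grade(category = g)), g)
  }
})

test_that("age bands replicate the analysis bands", {
  expect_equal(age_band(c(18, 39, 40, 49, 50, 59, 60, 69, 70, 104, NA)),
               c("<40", "<40", "40-49", "40-49", "50-59", "50-59",
                 "60-69", "60-69", "70-104", "70-104", NA))
})

test_that("eligibility excludes empties, males and missing subtypes with conserved counts", {
  cor <- generate_corpus(60, noise = noise_free(), seed = 41)
  rec <- harmonize_records(extract_corpus(cor$reports), cor$reports)
  # plant one exclusion of each kind
  rec$empty_report[1] <- TRUE
  rec$sex[2] <- "male"
  rec$er_status[3] <- NA
  rec$subtype[3] <- NA
  out <- apply_eligibility(rec)
  expect_equal(nrow(out$cohort) + nrow(out$exclusions), nrow(rec))
  got <- out$exclusions$reason[match(rec$report_id[1:3], out$exclusions$report_id)]
  expect_equal(got, c("empty_report", "male", "no_subtype"))
  expect_false(any(out$cohort$report_id %in% rec$report_id[1:3]))
})

test_that("exact duplicate episodes collapse to one kept record", {
  cor <- generate_corpus(30, noise = noise_config(duplicate_rate = 0.5,
                                                  conflicting_duplicate_rate = 0),
                         seed = 19)
  rec <- harmonize_records(extract_corpus(cor$reports), cor$reports)
  out <- apply_eligibility(rec)
  expect_equal(anyDuplicated(paste(out$cohort$patient_id, out$cohort$episode_number)), 0L)
  n_dup_excl <- sum(out$exclusions$reason == "duplicate")
  expect_equal(n_dup_excl, sum(duplicated(cor$truth$episode_number)))
  expect_equal(nrow(out$cohort) + nrow(out$exclusions), nrow(rec))
})

test_that("conflicting duplicates repair each other's missing fields", {
  base <- data.frame(
    report_id = c("R1", "R2"), patient_id = c("P1", "P1"),
    episode_number = c("E1", "E1"), sex = c("female", "female"),
    empty_report = c(FALSE, FALSE),
    age_years = c(55, 55), age_band = c("50-59", "50-59"),
    race = c(NA, "Black"), laterality = c("left", "left"),
    histologic_type = c("IDC", "IDC"), grade = c("II", NA),
    er_status = c("positive", "positive"), pr_status = c("positive", "positive"),
    her2_status = c("negative", "negative"),
    ki67_index = c(">=14", ">=14"),
    subtype = c("LuminalA", "LuminalA"),
    stringsAsFactors = FALSE)
  out <- apply_eligibility(base)
  expect_equal(nrow(out$cohort), 1L)
  expect_equal(out$cohort$race, "Black")   # repaired from the second copy
  expect_equal(out$cohort$grade, "II")     # kept from the first copy
  expect_equal(out$exclusions$reason, "duplicate")
})

test_that("dedup never merges distinct patients sharing nothing", {
  cor <- generate_corpus(40, noise = noise_free(), seed = 53)
  rec <- harmonize_records(extract_corpus(cor$reports), cor$reports)
  out <- apply_eligibility(rec)
  expect_equal(length(unique(out$cohort$patient_id)), nrow(out$cohort))
})
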
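# Synthetic pathology-report corpus with known ground truth.
#
# The generator emulates narrative breast-pathology reporting as seen in a
# national laboratory information system: hormone receptors as Allred
# fractions, percentages or pre-categorised labels; HER2 under a dozen
# spelling variants with IHC scores; Ki67 percentages or low/high labels;
# Nottingham grade as x/9 sums or Roman numerals; plus benign boilerplate
# clutter, spelling errors in parameter names, duplicate episodes, empty
# reports and male cases -- the record types a real pipeline must survive.

#' Default per-parameter marginal distributions
#'
#' Presets shaped like a South African national-laboratory breast-cancer
#' case mix: molecular-subtype weights around 52/16/9/22 percent (Luminal
#' A/B, HER2-overexpressing, triple negative), a high-Ki67 fraction of 0.74
#' among non-missing values, grade and age-band frequencies to match, and
#' realistic missingness (race is the worst-reported field at ~42%).
#' ER/PR/HER2 are drawn jointly through the subtype so receptor
#' combinations stay biologically consistent. All weights are configurable;
#' each categorical `weights` vector must sum to 1.
#'
#' @return Nested list of marginal specifications.
#' @export
default_marginals <- function() {
  list(
    subtype = list(levels = c("LuminalA", "LuminalB", "HER2-OE", "TNBC"),
                   weights = c(0.5234, 0.1620, 0.0913, 0.2233)),
    pr_positive_given_luminal = 0.77,
    her2_equivocal_given_negative = 0.08,
    ki67 = list(missing = 0.23, p_high = 0.74),
    grade = list(missing = 0.30,
                 levels = c("I", "II", "III"),
                 weights = c(0.094, 0.493, 0.413)),
    age = list(missing = 0.015,
               bands = list(c(18, 39), c(40, 49), c(50, 59), c(60, 69), c(70, 104)),
               weights = c(0.144, 0.233, 0.232, 0.216, 0.175)),
    race = list(missing = 0.42,
                levels = c("Asian", "Black", "Coloured", "White"),
                weights = c(0.0735, 0.7432, 0.0724, 0.1109)),
    laterality = list(missing = 0.09,
                      levels = c("left", "right"),
                      weights = c(0.510, 0.490)),
    histologic_type = list(levels = c("IDC", "other"), weights = c(0.8823, 0.1177)),
    snomed_behaviour = list(levels = c(0L, 1L, 2L, 3L, 6L),
                            weights = c(0.04, 0.03, 0.04, 0.86, 0.03))
  )
}

#' Noise configuration for corpus generation
#'
#' @param drop_prob Named numeric vector or single value: probability that a
#'   non-missing parameter's sentence is silently dropped from the text.
#' @param typo_prob Probability that a rendered parameter-name token gets a
#'   single-character edit (substitution, deletion or transposition);
#'   spelling errors hit parameter names, not values.
#' @param duplicate_rate Probability a patient's episode is emitted twice
#'   (exact copy), as registries typically hold.
#' @param empty_report_rate Probability a report's free text is empty.
#' @param male_rate Probability a case is male.
#' @param conflicting_duplicate_rate Probability a duplicated episode pair
#'   carries disparate information (one optional field missing in the first
#'   copy, present in the second).
#' @return A list of validated rates.
#' @export
noise_config <- function(drop_prob = 0, typo_prob = 0, duplicate_rate = 0,
                         empty_report_rate = 0, male_rate = 0,
                         conflicting_duplicate_rate = 0.002) {
  rates <- c(typo_prob = typo_prob, duplicate_rate = duplicate_rate,
             empty_report_rate = empty_report_rate, male_rate = male_rate,
             conflicting_duplicate_rate = conflicting_duplicate_rate, drop_prob)
  if (any(rates < 0 | rates > 1)) stop("all noise rates must lie in [0, 1]")
  list(drop_prob = drop_prob, typo_prob = typo_prob,
       duplicate_rate = duplicate_rate, empty_report_rate = empty_report_rate,
       male_rate = male_rate,
       conflicting_duplicate_rate = conflicting_duplicate_rate)
}

check_weights <- function(marg, name) {
  w <- marg$weights
  if (is.null(w) || abs(sum(w) - 1) > 1e-8 || any(w < 0)) {
    stop(sprintf("marginal weights for '%s' must be non-negative and sum to 1", name))
  }
}

draw_level <- function(n, levels, weights) {
  levels[sample.int(length(levels), n, replace = TRUE, prob = weights)]
}

#' Generate a cohort of ground-truth records
#'
#' Draws `n` patients i.i.d. from the marginals, then injects the
#' configured noise record types: male cases, missing fields, and duplicate
#' episodes appended after the base records (conflicting duplicates have
#' one optional field blanked in the first copy and intact in the second).
#' Identical `(marginals, noise, seed)` give an identical cohort.
#'
#' @param n Number of patients, >= 1.
#' @param marginals See [default_marginals()].
#' @param noise See [noise_config()].
#' @param seed Integer RNG seed.
#' @return Data frame of ground-truth records, one row per episode, with
#'   attribute `n_patients = n`.
#' @export
generate_cohort <- function(n, marginals = default_marginals(),
                            noise = noise_config(), seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("n must be a positive integer")
  n <- as.integer(n)
  for (nm in c("subtype", "grade", "age", "race", "laterality",
               "histologic_type", "snomed_behaviour")) {
    check_weights(marginals[[nm]], nm)
  }
  set.seed(seed)

  subtype <- draw_level(n, marginals$subtype$levels, marginals$subtype$weights)
  er_pos <- subtype %in% c("LuminalA", "LuminalB")
  her2_pos <- subtype %in% c("LuminalB", "HER2-OE")
  pr_pos <- er_pos & (stats::runif(n) < marginals$pr_positive_given_luminal)

  sample_allred <- function(pos) {
    ifelse(pos,
           draw_level(length(pos), 3:8, c(.05, .10, .15, .20, .25, .25)),
           draw_level(length(pos), 0:2, c(.70, .20, .10)))
  }
  er_allred <- sample_allred(er_pos)
  pr_allred <- sample_allred(pr_pos)
  her2_ihc <- integer(n)
  her2_ihc[her2_pos] <- 3L
  neg <- which(!her2_pos)
  eq <- stats::runif(length(neg)) < marginals$her2_equivocal_given_negative
  her2_ihc[neg] <- ifelse(eq, 2L, draw_level(length(neg), 0:1, c(.65, .35)))

  ki67 <- rep(NA_integer_, n)
  ki_obs <- stats::runif(n) >= marginals$ki67$missing
  hi <- stats::runif(n) < marginals$ki67$p_high
  ki67[ki_obs & hi] <- sample(14:95, sum(ki_obs & hi), replace = TRUE)
  ki67[ki_obs & !hi] <- sample(0:13, sum(ki_obs & !hi), replace = TRUE)

  grade_score <- rep(NA_integer_, n)
  g_obs <- stats::runif(n) >= marginals$grade$missing
  band <- draw_level(n, marginals$grade$levels, marginals$grade$weights)
  lo <- c(I = 3L, II = 6L, III = 8L)[band]
  hi_g <- c(I = 5L, II = 7L, III = 9L)[band]
  gs <- lo + floor(stats::runif(n) * (hi_g - lo + 1))
  grade_score[g_obs] <- as.integer(gs[g_obs])

  age <- rep(NA_integer_, n)
  a_obs <- stats::runif(n) >= marginals$age$missing
  bidx <- sample.int(length(marginals$age$bands), n, replace = TRUE,
                     prob = marginals$age$weights)
  av <- vapply(bidx, function(b) {
    rng <- marginals$age$bands[[b]]
    as.integer(rng[1] + floor(stats::runif(1) * (rng[2] - rng[1] + 1)))
  }, integer(1))
  age[a_obs] <- av[a_obs]

  race <- rep(NA_character_, n)
  r_obs <- stats::runif(n) >= marginals$race$missing
  rv <- draw_level(n, marginals$race$levels, marginals$race$weights)
  race[r_obs] <- rv[r_obs]

  lat <- rep(NA_character_, n)
  l_obs <- stats::runif(n) >= marginals$laterality$missing
  lv <- draw_level(n, marginals$laterality$levels, marginals$laterality$weights)
  lat[l_obs] <- lv[l_obs]

  histo <- draw_level(n, marginals$histologic_type$levels,
                      marginals$histologic_type$weights)
  behaviour <- draw_level(n, marginals$snomed_behaviour$levels,
                          marginals$snomed_behaviour$weights)
  sex <- ifelse(stats::runif(n) < noise$male_rate, "male", "female")

  cohort <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    episode_number = sprintf("E%08d", seq_len(n)),
    sex = sex,
    age = age,
    race = race,
    laterality = lat,
    histologic_type = histo,
    grade_score = grade_score,
    er_allred = as.integer(er_allred),
    pr_allred = as.integer(pr_allred),
    her2_ihc = her2_ihc,
    ki67_percent = ki67,
    snomed_behaviour = as.integer(behaviour),
    stringsAsFactors = FALSE
  )

  # duplicate episodes: exact second copies; a conflicting duplicate keeps
  # the full field set while the first copy loses one optional field
  dup <- stats::runif(n) < noise$duplicate_rate
  conflict <- stats::runif(n) < noise$conflicting_duplicate_rate
  dup <- dup | conflict
  if (any(dup)) {
    dup_rows <- cohort[dup, , drop = FALSE]   # snapshot before blanking
    optional <- c("race", "laterality", "grade_score", "ki67_percent")
    for (i in which(conflict)) {
      present <- optional[!vapply(optional, function(f) is.na(cohort[[f]][i]), logical(1))]
      if (length(present) == 0L) next
      fld <- if (length(present) == 1L) present else sample(present, 1L)
      cohort[[fld]][i] <- NA
    }
    cohort <- rbind(cohort, dup_rows)
  }
  attr(cohort, "n_patients") <- n
  cohort
}

#' Default rendering style profile
#'
#' Phrase templates and value-rendering modes per parameter: Allred
#' fractions ("8/8"), percentages, bare IHC digits, pre-categorised labels,
#' Nottingham x/9 sums and Roman numerals -- together with a clutter pool of
#' benign pathology boilerplate (digit-free and free of capture tokens) that
#' exercises false-positive rejection. Every template renders exactly one
#' mention of its target parameter.
#'
#' @return A list with `modes` (per-parameter mode weights) and `clutter`.
#' @export
style_profile_default <- function() {
  list(
    modes = list(
      ER = c(allred = 0.6, percent = 0.2, categorized = 0.2),
      PR = c(allred = 0.6, percent = 0.2, categorized = 0.2),
      HER2 = c(score = 0.7, categorized = 0.3),
      Ki67 = c(percent = 0.75, categorized = 0.25),
      grade = c(fraction = 0.8, roman = 0.2)
    ),
    er_variants = c("ER", "Oestrogen receptor", "Estrogen receptor"),
    pr_variants = c("PR", "PgR", "Progesterone receptor"),
    her2_variants = c("HER2NUE", "HER2-NUE", "HER2/NUE", "HERNUE", "HER2",
                      "HER", "CERB", "CERB-B2", "CERBB2", "CERBB", "C-erb2/HER2"),
    ki67_variants = c("Ki67", "Ki-67", "MIB-1"),
    grade_variants = c("Nottingham grade", "Histological grade", "Tumour grade"),
    clutter = c(
      "The specimen was received in formalin and processed routinely.",
      "Sections show tumour with surrounding desmoplastic stroma.",
      "Margins appear clear of tumour on gross examination.",
      "Immunohistochemical stains were reviewed by the reporting pathologist.",
      "No evidence of lymphovascular invasion is seen.",
      "The surrounding breast tissue shows fibrocystic change.",
      "Representative blocks were submitted for processing.",
      "Clinical correlation is advised where indicated."
    )
  )
}

# map an Allred score to a rendering percentage that preserves status
allred_to_percent <- function(a) {
  c(`0` = 0, `1` = 0, `2` = 0, `3` = 5, `4` = 10, `5` = 30,
    `6` = 60, `7` = 80, `8` = 95)[as.character(a)]
}

inject_typo <- function(token) {
  i <- sample.int(nchar(token), 1L)
  kind <- sample(c("sub", "del", "trans"), 1L)
  chars <- strsplit(token, "")[[1]]
  if (kind == "sub") {
    chars[i] <- sample(letters, 1L)
  } else if (kind == "del") {
    chars <- chars[-i]
  } else if (nchar(token) > 1L) {
    j <- if (i == length(chars)) i - 1L else i
    chars[c(j, j + 1L)] <- chars[c(j + 1L, j)]
  }
  paste(chars, collapse = "")
}

pick_mode <- function(weights) {
  names(weights)[sample.int(length(weights), 1L, prob = weights)]
}

maybe_typo <- function(kw, noise) {
  if (noise$typo_prob > 0 && stats::runif(1) < noise$typo_prob) inject_typo(kw) else kw
}

drop_p <- function(noise, param) {
  dp <- noise$drop_prob
  if (length(dp) == 1L && is.null(names(dp))) return(as.numeric(dp))
  as.numeric(dp[param] %||% 0)
}

render_sentences <- function(record, style, noise) {
  sent <- list()
  add <- function(param, s) {
    if (stats::runif(1) < drop_p(noise, param)) return()
    sent[[length(sent) + 1L]] <<- list(param = param, text = s)
  }
  receptor_sentence <- function(param, variants, allred) {
    kw <- maybe_typo(sample(variants, 1L), noise)
    mode <- pick_mode(style$modes[[param]])
    lab <- if (allred >= 3) "positive" else "negative"
    if (mode == "allred") {
      sprintf("%s: %d/8 %s.", kw, allred, lab)
    } else if (mode == "percent") {
      sprintf("%s %d%% of tumour nuclei.", kw, allred_to_percent(allred))
    } else {
      sprintf("%s is %s.", kw, lab)
    }
  }
  if (!is.na(record$age)) {
    add("age", sprintf("Age: %d years.", record$age))
  }
  if (!is.na(record$laterality)) {
    add("laterality", sprintf("Laterality: %s breast.", record$laterality))
  }
  if (!is.na(record$histologic_type)) {
    phrase <- if (record$histologic_type == "IDC") {
      sample(c("infiltrating ductal carcinoma", "invasive ductal carcinoma"), 1L)
    } else {
      sample(c("invasive lobular carcinoma", "mucinous carcinoma",
               "metaplastic carcinoma"), 1L)
    }
    add("histologic_type", sprintf("Histological type: %s.", phrase))
  }
  if (!is.na(record$grade_score)) {
    kw <- maybe_typo(sample(style$grade_variants, 1L), noise)
    mode <- pick_mode(style$modes$grade)
    if (mode == "fraction") {
      add("grade", sprintf("%s: %d/9.", kw, record$grade_score))
    } else {
      roman <- c("I", "I", "I", "II", "II", "III", "III")[record$grade_score - 2L]
      add("grade", sprintf("%s %s.", kw, roman))
    }
  }
  add("ER", receptor_sentence("ER", style$er_variants, record$er_allred))
  add("PR", receptor_sentence("PR", style$pr_variants, record$pr_allred))
  {
    kw <- maybe_typo(sample(style$her2_variants, 1L), noise)
    mode <- pick_mode(style$modes$HER2)
    s <- if (mode == "score") {
      sprintf("%s score %d.", kw, record$her2_ihc)
    } else {
      lab <- c("negative", "negative", "equivocal", "positive")[record$her2_ihc + 1L]
      sprintf("%s %s.", kw, lab)
    }
    add("HER2", s)
  }
  if (!is.na(record$ki67_percent)) {
    kw <- maybe_typo(sample(style$ki67_variants, 1L), noise)
    mode <- pick_mode(style$modes$Ki67)
    s <- if (mode == "percent") {
      sprintf("%s of about %d%% in tumour cells.", kw, record$ki67_percent)
    } else {
      sprintf("%s is %s.", kw, if (record$ki67_percent >= 14) "high" else "low")
    }
    add("Ki67", s)
  }
  if (!is.na(record$race)) {
    add("race", sprintf("Race: %s.", record$race))
  }
  sent
}

render_text <- function(record, style, noise) {
  sent <- render_sentences(record, style, noise)
  pieces <- character(0)
  pieces <- c(pieces, sample(style$clutter, 1L))
  for (s in sent) {
    pieces <- c(pieces, s$text, sample(style$clutter, 1L))
  }
  paste(pieces, collapse = " ")
}

#' Render one ground-truth record as a free-text report
#'
#' Every non-missing parameter is rendered as exactly one mention --
#' a parameter-name variant followed by its value in one of the style's
#' rendering modes -- interleaved with clutter boilerplate. Noise may drop
#' mentions, inject single-character typos into parameter names, or empty
#' the report entirely.
#'
#' @param record One-row data frame from [generate_cohort()].
#' @param style See [style_profile_default()].
#' @param noise See [noise_config()].
#' @param seed Integer seed making this single render reproducible.
#' @return One-row data frame: `report_id`, `patient_id`,
#'   `episode_number`, `snomed_code`, `sex`, `free_text`,
#'   `structured_age`, `structured_race`, `year`.
#' @export
render_report <- function(record, style = style_profile_default(),
                          noise = noise_config(), seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  render_report_impl(record, style, noise, record$patient_id)
}

render_report_impl <- function(record, style, noise, report_id) {
  empty <- stats::runif(1) < noise$empty_report_rate
  text <- if (empty) "" else render_text(record, style, noise)
  morph <- if (record$histologic_type == "IDC") "8500" else "8480"
  data.frame(
    report_id = report_id,
    patient_id = record$patient_id,
    episode_number = record$episode_number,
    snomed_code = sprintf("M-%s%d", morph, record$snomed_behaviour),
    sex = record$sex,
    free_text = text,
    structured_age = record$age,
    structured_race = record$race,
    year = 2011L + sample.int(9L, 1L) - 1L,
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic corpus with ground truth
#'
#' Draws a cohort with [generate_cohort()] and renders each episode with
#' the style profile, returning the free-text reports alongside the
#' ground-truth table for evaluation. Identical arguments give a
#' byte-identical corpus.
#'
#' @inheritParams generate_cohort
#' @param style See [style_profile_default()].
#' @return List with `reports` (corpus data frame) and `truth`
#'   (ground-truth data frame keyed by `report_id`).
#' @export
generate_corpus <- function(n, marginals = default_marginals(),
                            style = style_profile_default(),
                            noise = noise_config(), seed = 1L) {
  cohort <- generate_cohort(n, marginals, noise, seed)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    render_report_impl(cohort[i, , drop = FALSE], style, noise,
                       sprintf("R%06d", i))
  })
  reports <- do.call(rbind, rows)
  truth <- cbind(report_id = reports$report_id, cohort,
                 stringsAsFactors = FALSE)
  list(reports = reports, truth = truth)
}
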
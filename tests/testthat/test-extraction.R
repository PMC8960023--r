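rules <- default_rulesets()

test_that("summarize finds keyword variants with longest-match precedence", {
  m <- summarize(clean_text("tumour is CERB-B2 positive"), rules$HER2)
  expect_equal(nrow(m), 1L)
  expect_equal(m$matched_variant, "CERB-B2")

  expect_equal(nrow(summarize("no relevant keyword here", rules$HER2)), 0L)

  # keyword inside a longer word never fires
  expect_equal(nrow(summarize("the receptor was moderate", rules$ER)), 0L)

  # nested variants produce a single mention
  m2 <- summarize("Nottingham grade 5/9.", rules$grade)
  expect_equal(nrow(m2), 1L)
  expect_equal(tolower(m2$matched_variant), "nottingham grade")
})

test_that("summarize reports exact spans for planted keyword hits", {
  pre <- "some preamble text here. "
  mid <- " more words in between and then "
  text <- paste0(pre, "HER2 negative.", mid, "HER2NUE score 3.", mid, "CERB 0.")
  m <- summarize(text, rules$HER2)
  expect_equal(nrow(m), 3L)
  starts <- c(nchar(pre),
              nchar(pre) + nchar("HER2 negative.") + nchar(mid),
              nchar(pre) + nchar("HER2 negative.") + nchar(mid) +
                nchar("HER2NUE score 3.") + nchar(mid))
  expect_equal(m$kw_start, starts)
  expect_equal(m$matched_variant, c("HER2", "HER2NUE", "CERB"))
  # window_text always equals the spanned slice
  for (i in seq_len(nrow(m))) {
    expect_identical(m$window_text[i],
                     substring(text, m$win_start[i] + 1L, m$win_end[i]))
  }
})

test_that("narrow keeps the stated width after the keyword and clips at text end", {
  text <- "Ki67 of about 25% in tumour cells"
  m <- narrow(summarize(text, rules$Ki67), text, 17L)
  expect_equal(m$window_text, " of about 25% in ")
  expect_equal(nchar(m$window_text), 17L)
  expect_equal(m$pass_number, 2L)

  short <- "Ki67 25%"
  m2 <- narrow(summarize(short, rules$Ki67), short, 17L)
  expect_equal(m2$window_text, " 25%")   # clipped, no padding
})

test_that("values planted within the narrow width survive narrowing", {
  set.seed(5)
  for (i in 1:25) {
    val <- sample(0:99, 1)
    pad <- paste(rep(" ", sample(0:10, 1)), collapse = "")
    text <- sprintf("preamble text. Ki67%s%d%% and then a long trailing clause", pad, val)
    m <- narrow(summarize(text, rules$Ki67), text, 17L)
    expect_true(grepl(as.character(val), m$window_text, fixed = TRUE))
  }
})

test_that("numeric capture follows the digit-run rules", {
  spec <- list(max_digits = 4L, allow_pct = TRUE, allow_fraction = TRUE)
  expect_equal(capture_numeric(" of about 25% in t", spec)$value, 25)
  expect_true(capture_numeric(" of about 25% in t", spec)$pct)
  frac <- capture_numeric("8/8", spec)
  expect_equal(c(frac$value, frac$denominator), c(8, 8))
  expect_true(is.na(capture_numeric("no figure quoted", spec)$value))
  # runs longer than 4 digits are skipped as non-values
  expect_equal(capture_numeric("accession 1234567 then 42", spec)$value, 42)
  expect_true(is.na(capture_numeric("accession 1234567 only", spec)$value))
  # fraction disabled: numerator alone
  spec2 <- list(max_digits = 4L, allow_pct = TRUE, allow_fraction = FALSE)
  expect_equal(capture_numeric("5/9", spec2)$value, 5)
  expect_true(is.na(capture_numeric("5/9", spec2)$denominator))
})

test_that("categorical capture is earliest-token, boundary-aware and negation-aware", {
  lex <- c(positive = "positive", negative = "negative", low = "low", high = "high")
  expect_equal(capture_categorical(" is high", lex), "high")
  expect_equal(capture_categorical("staining not positive", lex), "negative")
  expect_equal(capture_categorical("low then high", lex), "low")
  expect_equal(capture_categorical("high then low", lex), "high")
  expect_true(is.na(capture_categorical("nothing relevant", lex)))
  # token inside a longer word does not fire ("lower" is not "low")
  expect_true(is.na(capture_categorical("slightly lowered uptake", lex)))
  # negation only within three tokens
  expect_equal(capture_categorical("not in any way shape or form positive", lex),
               "positive")
})

test_that("synthesize applies precedence, tie-breaks and conflict detection", {
  mk <- function(kw_start, num = NA_real_, den = NA_real_, pct = FALSE,
                 cat = NA_character_) {
    data.frame(parameter = "Ki67", matched_variant = "Ki67", kw_start = kw_start,
               kw_end = kw_start + 4L, win_start = kw_start + 4L,
               win_end = kw_start + 21L, window_text = "w", pass_number = 2L,
               num_value = num, num_den = den, num_pct = pct, cat_value = cat,
               stringsAsFactors = FALSE)
  }
  r <- rules$Ki67

  # numeric beats categorical
  res <- synthesize(rbind(mk(10, num = 25), mk(50, cat = "high")), r)
  expect_equal(res$status, "found")
  expect_equal(res$numeric_value, 25)
  expect_equal(res$capture_kind, "numeric")

  # earliest numeric wins among several
  res2 <- synthesize(rbind(mk(90, num = 40), mk(10, num = 25)), r)
  expect_equal(res2$numeric_value, 25)
  expect_equal(res2$n_candidates, 2L)

  # no mentions
  expect_equal(synthesize(mk(1)[0, ], r)$status, "not_reported")

  # conflicting categorical captures are ambiguous
  res3 <- synthesize(rbind(mk(10, cat = "positive"), mk(50, cat = "negative")), r)
  expect_equal(res3$status, "ambiguous")

  # concordant categorical captures are fine
  res4 <- synthesize(rbind(mk(10, cat = "high"), mk(50, cat = "high")), r)
  expect_equal(res4$status, "found")
  expect_equal(res4$category_value, "high")
})

test_that("a worked narrative report is captured field for field", {
  report <- list(report_id = "fig2",
                 free_text = paste(
                   "A 67 year old female. Age: 67 years.",
                   "Laterality: left breast.",
                   "Histological type: infiltrating ductal carcinoma.",
                   "Tumour grade: 5/9.",
                   "ER: 8/8 positive. PR: 8/8 positive.",
                   "HER2 score 0. Ki67 is high."))
  x <- extract_all(report, rules)
  expect_equal(x$age_num, 67)
  expect_equal(x$laterality_cat, "left")
  expect_equal(x$histologic_type_cat, "IDC")
  expect_equal(c(x$grade_num, x$grade_den), c(5, 9))
  expect_equal(c(x$ER_num, x$ER_den), c(8, 8))
  expect_equal(c(x$PR_num, x$PR_den), c(8, 8))
  expect_equal(x$HER2_num, 0)
  expect_equal(x$Ki67_cat, "high")
})

test_that("empty reports yield not_reported everywhere", {
  x <- extract_all(list(report_id = "empty", free_text = ""), rules)
  for (p in names(rules)) {
    expect_equal(x[[paste0(p, "_status")]], "not_reported")
  }
})

test_that("extraction is deterministic and recovers a noise-free corpus exactly", {
  cor <- generate_corpus(150, noise = noise_free(), seed = 17)
  e1 <- extract_corpus(cor$reports)
  e2 <- extract_corpus(cor$reports)
  expect_identical(e1, e2)
  rec <- harmonize_records(e1, cor$reports)
  acc <- recovery_accuracy(rec, harmonized_truth(cor$truth))
  expect_true(all(acc == 1))
})

test_that("accuracy degrades monotonically with typo rate", {
  accs <- vapply(c(0, 0.1, 0.3), function(tp) {
    cor <- generate_corpus(200, noise = noise_config(typo_prob = tp,
                                                     conflicting_duplicate_rate = 0),
                           seed = 11)
    rec <- harmonize_records(extract_corpus(cor$reports), cor$reports)
    mean(recovery_accuracy(rec, harmonized_truth(cor$truth)), na.rm = TRUE)
  }, numeric(1))
  expect_true(accs[1] >= accs[2])
  expect_true(accs[2] >= accs[3])
})

test_that("rule sets round-trip through YAML", {
  tmp <- tempfile(fileext = ".yaml")
  write_rulesets(rules, tmp)
  back <- read_rulesets(tmp)
  expect_equal(names(back), names(rules))
  for (p in names(rules)) {
    expect_equal(back[[p]]$keyword_variants, rules[[p]]$keyword_variants)
    expect_equal(back[[p]]$narrow_width, rules[[p]]$narrow_width)
    expect_equal(back[[p]]$category_lexicon, rules[[p]]$category_lexicon)
    expect_equal(back[[p]]$precedence, rules[[p]]$precedence)
  }
  # extraction behaves identically under the round-tripped rules
  text <- clean_text("ER: 6/8 positive. Ki67 22%.")
  expect_identical(extract_all(list(report_id = "x", free_text = text), back),
                   extract_all(list(report_id = "x", free_text = text), rules))
})

test_that("mention windows always equal their text slice on generated reports", {
  cor <- generate_corpus(40, noise = noise_free(), seed = 23)
  for (i in seq_len(40)) {
    text <- clean_text(cor$reports$free_text[i])
    for (p in names(rules)) {
      m <- summarize(text, rules[[p]])
      m <- narrow(m, text, rules[[p]]$narrow_width)
      for (j in seq_len(nrow(m))) {
        expect_identical(m$window_text[j],
                         substring(text, m$win_start[j] + 1L, m$win_end[j]))
      }
    }
  }
})
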
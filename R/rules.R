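#' Construct a per-parameter extraction rule set
#'
#' A rule set drives the multi-pass cascade for one parameter: which literal
#' keyword variants mark a mention, how wide the pass-1 summarisation window
#' is, how many characters after the keyword the pass-2 narrowed window
#' keeps, what numeric shapes (digit runs, percentages, `x/y` fractions) may
#' be captured, which pre-categorised tokens map to which normalised
#' categories, and whether numeric or categorical capture takes precedence.
#'
#' @param parameter One of `"age"`, `"laterality"`, `"histologic_type"`,
#'   `"grade"`, `"ER"`, `"PR"`, `"HER2"`, `"Ki67"`, `"race"`.
#' @param keyword_variants Non-empty character vector of literal spellings,
#'   matched case-insensitively with word boundaries; at a shared start
#'   offset the longest variant wins.
#' @param window_radius Pass-1 window, characters each side of the hit.
#' @param narrow_width Pass-2 window, characters after the keyword end.
#' @param numeric_pattern List: `max_digits` (runs longer than this are
#'   rejected as non-values, e.g. lab accession numbers), `allow_pct`,
#'   `allow_fraction`. `NULL` disables numeric capture.
#' @param category_lexicon Named character vector mapping literal tokens to
#'   normalised categories, or `NULL` to disable categorical capture.
#' @param precedence Character vector ordering `"numeric"`/`"categorical"`.
#' @param max_passes Number of cascade passes (informational).
#' @return An object of class `pathrex_rules`.
#' @export
parameter_rules <- function(parameter,
                            keyword_variants,
                            window_radius = 60L,
                            narrow_width = 20L,
                            numeric_pattern = list(max_digits = 4L, allow_pct = TRUE,
                                                   allow_fraction = TRUE),
                            category_lexicon = NULL,
                            precedence = c("numeric", "categorical"),
                            max_passes = 4L) {
  stopifnot(length(parameter) == 1L, is.character(keyword_variants),
            length(keyword_variants) > 0L, all(nzchar(keyword_variants)))
  window_radius <- as.integer(window_radius)
  narrow_width <- as.integer(narrow_width)
  if (narrow_width < 1L || window_radius < narrow_width) {
    stop("require window_radius >= narrow_width >= 1")
  }
  kinds <- c(if (!is.null(numeric_pattern)) "numeric",
             if (!is.null(category_lexicon)) "categorical")
  precedence <- intersect(precedence, kinds)
  if (!setequal(precedence, kinds)) {
    stop("precedence must be a permutation of the available capture kinds")
  }
  structure(list(parameter = parameter,
                 keyword_variants = keyword_variants,
                 window_radius = window_radius,
                 narrow_width = narrow_width,
                 numeric_pattern = numeric_pattern,
                 category_lexicon = category_lexicon,
                 precedence = precedence,
                 max_passes = as.integer(max_passes)),
            class = "pathrex_rules")
}

#' @export
print.pathrex_rules <- function(x, ...) {
  cat(sprintf("<pathrex_rules: %s>\n", x$parameter))
  cat("  variants:", paste(x$keyword_variants, collapse = ", "), "\n")
  cat(sprintf("  window %d, narrow %d, precedence %s\n",
              x$window_radius, x$narrow_width, paste(x$precedence, collapse = " > ")))
  invisible(x)
}

# shared receptor-status lexicon; negation of "positive" handled in capture
.status_lexicon <- c(positive = "positive", pos = "positive",
                     negative = "negative", neg = "negative",
                     equivocal = "equivocal")

#' Default rule sets for the nine study parameters
#'
#' Ships literal variant lists observed in narrative breast-pathology
#' reporting, including the full set of twelve HER2 spellings ("HER2NUE",
#' "HER2-NUE", "HER2/NUE", "HER2(NUE)", "HERNUE", "HER2", "HER", "CERB",
#' "CERB-B2", "CERBB2", "CERBB", "C-erb2/HER2"). The Ki67 narrowed window is
#' 17 characters, the width at which the value and unit survive while
#' surrounding prose is discarded. Note parenthesised variants match after
#' [clean_text()] has stripped the parentheses.
#'
#' @return Named list of [parameter_rules()] objects.
#' @export
default_rulesets <- function() {
  list(
    age = parameter_rules(
      "age",
      keyword_variants = c("age", "aged"),
      narrow_width = 17L,
      numeric_pattern = list(max_digits = 3L, allow_pct = FALSE, allow_fraction = FALSE),
      precedence = "numeric"
    ),
    laterality = parameter_rules(
      "laterality",
      keyword_variants = c("laterality", "specimen site", "side"),
      narrow_width = 20L,
      numeric_pattern = NULL,
      category_lexicon = c(left = "left", right = "right"),
      precedence = "categorical"
    ),
    histologic_type = parameter_rules(
      "histologic_type",
      keyword_variants = c("histological type", "histologic type", "tumour type", "tumor type"),
      narrow_width = 45L,
      numeric_pattern = NULL,
      category_lexicon = c(ductal = "IDC", lobular = "other", mucinous = "other",
                           metaplastic = "other", papillary = "other", other = "other"),
      precedence = "categorical"
    ),
    grade = parameter_rules(
      "grade",
      keyword_variants = c("nottingham grade", "histological grade", "tumour grade",
                           "tumor grade", "grade"),
      narrow_width = 17L,
      numeric_pattern = list(max_digits = 1L, allow_pct = FALSE, allow_fraction = TRUE),
      category_lexicon = c(iii = "III", ii = "II", i = "I"),
      precedence = c("numeric", "categorical")
    ),
    ER = parameter_rules(
      "ER",
      keyword_variants = c("ER", "oestrogen receptor", "estrogen receptor"),
      narrow_width = 20L,
      numeric_pattern = list(max_digits = 3L, allow_pct = TRUE, allow_fraction = TRUE),
      category_lexicon = .status_lexicon,
      precedence = c("numeric", "categorical")
    ),
    PR = parameter_rules(
      "PR",
      keyword_variants = c("PR", "PgR", "progesterone receptor"),
      narrow_width = 20L,
      numeric_pattern = list(max_digits = 3L, allow_pct = TRUE, allow_fraction = TRUE),
      category_lexicon = .status_lexicon,
      precedence = c("numeric", "categorical")
    ),
    HER2 = parameter_rules(
      "HER2",
      keyword_variants = c("HER2NUE", "HER2-NUE", "HER2/NUE", "HER2(NUE)", "HERNUE",
                           "HER2", "HER", "CERB", "CERB-B2", "CERBB2", "CERBB",
                           "C-erb2/HER2"),
      narrow_width = 17L,
      numeric_pattern = list(max_digits = 1L, allow_pct = FALSE, allow_fraction = FALSE),
      category_lexicon = .status_lexicon,
      precedence = c("numeric", "categorical")
    ),
    Ki67 = parameter_rules(
      "Ki67",
      keyword_variants = c("Ki67", "Ki-67", "KI 67", "MIB-1", "MIB1"),
      narrow_width = 17L,
      numeric_pattern = list(max_digits = 3L, allow_pct = TRUE, allow_fraction = FALSE),
      category_lexicon = c(positive = "positive", negative = "negative",
                           low = "low", high = "high"),
      precedence = c("numeric", "categorical")
    ),
    race = parameter_rules(
      "race",
      keyword_variants = c("race", "ethnicity", "population group"),
      narrow_width = 20L,
      numeric_pattern = NULL,
      category_lexicon = c(asian = "Asian", black = "Black", coloured = "Coloured",
                           colored = "Coloured", white = "White"),
      precedence = "categorical"
    )
  )
}

#' Read and write rule sets as YAML
#'
#' Rule sets round-trip through a YAML file, one document section per
#' parameter, so site-specific variant lists (extra spellings, local
#' phrasing) can be maintained outside the code.
#'
#' @param rulesets Named list of [parameter_rules()] objects.
#' @param path YAML file path.
#' @return `read_rulesets` returns a named list of rule sets;
#'   `write_rulesets` returns `path` invisibly.
#' @export
write_rulesets <- function(rulesets, path) {
  plain <- lapply(rulesets, function(r) {
    r <- unclass(r)
    if (!is.null(r$category_lexicon)) {
      r$category_lexicon <- as.list(r$category_lexicon)
    }
    r
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_rulesets
#' @export
read_rulesets <- function(path) {
  plain <- yaml::read_yaml(path)
  out <- lapply(plain, function(r) {
    lex <- r$category_lexicon
    if (!is.null(lex)) lex <- unlist(lex)
    np <- r$numeric_pattern
    parameter_rules(r$parameter, unlist(r$keyword_variants),
                    window_radius = r$window_radius,
                    narrow_width = r$narrow_width,
                    numeric_pattern = np,
                    category_lexicon = lex,
                    precedence = unlist(r$precedence),
                    max_passes = r$max_passes)
  })
  names(out) <- vapply(out, function(r) r$parameter, character(1))
  out
}
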
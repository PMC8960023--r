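#' Clean pathology report text
#'
#' Collapses runs of whitespace to a single space and removes asterisks,
#' colons and parentheses, the clutter characters that narrative reports
#' accumulate around scores ("ER  **(8/8)**: positive"). Value-bearing
#' characters -- digits, `%`, `/`, `-`, `+`, `.` -- are always preserved, and
#' case is left untouched so reports stay readable in error listings.
#' The function is idempotent.
#'
#' @param text Character vector; `NA` is passed through.
#' @return Character vector of the same length.
#' @examples
#' clean_text("ER  **(8/8)**:  positive")
#' @export
clean_text <- function(text) {
  if (length(text) == 0L) return(character(0))
  out <- gsub("[*:()]", "", text)
  out <- gsub("[[:space:]]+", " ", out)
  out <- trimws(out)
  out[is.na(text)] <- NA_character_
  out
}

#' Parse a SNOMED morphology/behaviour code
#'
#' Tumour-registry SNOMED morphology codes take the form `"M-85203"`: after
#' the `M-` prefix, the first four digits are the morphology and the final
#' digit is the behaviour (0 benign, 1 uncertain, 2 in situ, 3 malignant
#' primary, 6 metastatic, 9 unknown). Codes with more than five digits are
#' tolerated with a warning: the first four digits are taken as morphology
#' and the last digit as behaviour.
#'
#' @param code A single code string, e.g. `"M-85203"`.
#' @return A list with elements `morphology` (4-character string) and
#'   `behaviour` (integer).
#' @examples
#' parse_snomed("M-85203")
#' @export
parse_snomed <- function(code) {
  if (length(code) != 1L || is.na(code) || !nzchar(code)) {
    stop_parse("SNOMED code is missing or empty")
  }
  m <- regmatches(code, regexec("^M-?([0-9]{5,})$", code))[[1]]
  if (length(m) < 2L) {
    stop_parse(sprintf("malformed SNOMED code: '%s'", code))
  }
  digits <- m[2]
  if (nchar(digits) > 5L) {
    warning(sprintf("SNOMED code '%s' has %d digits; using first 4 as morphology, last as behaviour",
                    code, nchar(digits)), call. = FALSE)
  }
  behaviour <- as.integer(substr(digits, nchar(digits), nchar(digits)))
  if (!behaviour %in% c(0L, 1L, 2L, 3L, 6L, 9L)) {
    stop_parse(sprintf("SNOMED code '%s' has invalid behaviour digit %d", code, behaviour))
  }
  list(morphology = substr(digits, 1L, 4L), behaviour = behaviour)
}

stop_parse <- function(msg) {
  stop(structure(class = c("pathrex_parse_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Is a parsed SNOMED code malignant?
#'
#' Behaviour digits 2 (in situ), 3 (malignant primary) and 6 (metastatic)
#' define the malignancy class used for case retrieval.
#'
#' @param x A list from [parse_snomed()] or an integer vector of behaviour
#'   digits.
#' @return Logical.
#' @export
is_malignant <- function(x) {
  behaviour <- if (is.list(x)) x$behaviour else x
  behaviour %in% c(2L, 3L, 6L)
}

#' Retrieve malignant cases from a report corpus
#'
#' Parses each report's SNOMED code and keeps those in the malignancy class
#' (behaviour 2, 3 or 6). Nothing is silently dropped: every excluded report
#' carries a machine-readable reason (`no_code`, `bad_code`,
#' `not_malignant`), and the kept and excluded sets partition the corpus.
#'
#' @param reports Data frame with at least `report_id` and `snomed_code`
#'   columns (as produced by [generate_corpus()] or [read_corpus()]).
#' @return A list with `kept` (data frame of retained reports) and
#'   `excluded` (data frame `report_id`, `reason`).
#' @export
retrieve_malignant <- function(reports) {
  stopifnot(is.data.frame(reports), all(c("report_id", "snomed_code") %in% names(reports)))
  n <- nrow(reports)
  keep <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    code <- reports$snomed_code[i]
    if (is.na(code) || !nzchar(code)) {
      reason[i] <- "no_code"
      next
    }
    parsed <- tryCatch(suppressWarnings(parse_snomed(code)),
                       pathrex_parse_error = function(e) NULL)
    if (is.null(parsed)) {
      reason[i] <- "bad_code"
    } else if (is_malignant(parsed)) {
      keep[i] <- TRUE
    } else {
      reason[i] <- "not_malignant"
    }
  }
  list(
    kept = reports[keep, , drop = FALSE],
    excluded = data.frame(report_id = reports$report_id[!keep],
                          reason = reason[!keep],
                          stringsAsFactors = FALSE)
  )
}

#' Write an exclusion log
#'
#' @param log Data frame with `report_id` and `reason`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
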
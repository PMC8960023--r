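# Multi-pass extraction cascade.
#
# Pass 1 (summarize): locate keyword variants and keep a wide window around
# each hit -- the report shrinks to the phrases that mention the parameter.
# Pass 2 (narrow): keep only narrow_width characters after the keyword end,
# where the value sits in narrative reporting ("Ki67 of about 25% ...").
# Pass 3 (capture_numeric): first 1-4 digit run, optionally %, optionally an
# x/y fraction (Allred 8/8, Nottingham 5/9).
# Pass 4 (capture_categorical): pre-categorised tokens ("positive",
# "negative", "low", "high", ...) when the pathologist skipped the number.
# synthesize() then combines the per-mention captures into one value.

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Summarise a report around keyword hits
#'
#' Finds every occurrence of a rule set's keyword variants in cleaned text
#' (case-insensitive; matches flanked by alphanumerics are rejected, so
#' "ER" never fires inside "receptor"). At a shared start offset the longest
#' variant wins, and a match wholly contained in a longer match is dropped.
#' Each hit yields a mention whose window is `window_radius` characters
#' each side of the keyword, clipped at the text bounds.
#'
#' @param text A single cleaned report text (see [clean_text()]).
#' @param rules A [parameter_rules()] object.
#' @return Data frame of mentions: `parameter`, `matched_variant`,
#'   `kw_start`, `kw_end`, `win_start`, `win_end` (0-based half-open spans
#'   into `text`), `window_text`, `pass_number`.
#' @export
summarize <- function(text, rules) {
  stopifnot(length(text) == 1L)
  empty <- data.frame(parameter = character(0), matched_variant = character(0),
                      kw_start = integer(0), kw_end = integer(0),
                      win_start = integer(0), win_end = integer(0),
                      window_text = character(0), pass_number = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  variants <- rules$keyword_variants[order(-nchar(rules$keyword_variants))]
  pat <- paste0("(?i)(?<![A-Za-z0-9])(?:",
                paste(escape_regex(variants), collapse = "|"),
                ")(?![A-Za-z0-9])")
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m) - 1L                      # 0-based
  lens <- attr(m, "match.length")
  ends <- starts + lens                             # half-open
  # drop matches contained in another (handles "grade" inside "nottingham grade")
  keep <- rep(TRUE, length(starts))
  for (i in seq_along(starts)) {
    for (j in seq_along(starts)) {
      if (i != j && keep[j] && starts[j] <= starts[i] && ends[i] <= ends[j] &&
          (lens[j] > lens[i])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  starts <- starts[keep]; ends <- ends[keep]
  n <- nchar(text)
  win_start <- pmax(0L, starts - rules$window_radius)
  win_end <- pmin(n, ends + rules$window_radius)
  data.frame(parameter = rules$parameter,
             matched_variant = substring(text, starts + 1L, ends),
             kw_start = starts, kw_end = ends,
             win_start = win_start, win_end = win_end,
             window_text = substring(text, win_start + 1L, win_end),
             pass_number = 1L,
             stringsAsFactors = FALSE)
}

#' Narrow mention windows to the value region
#'
#' Truncates each mention's window to `width` characters following the end
#' of the matched keyword (clipped at the text end, never padded) and
#' increments the pass number. Values follow parameter names in narrative
#' reporting, so the trailing window is where capture happens.
#'
#' @param mentions Mention data frame from [summarize()].
#' @param text The same cleaned text the mentions index into.
#' @param width Window width in characters, >= 1.
#' @return The mention data frame with updated windows.
#' @export
narrow <- function(mentions, text, width) {
  stopifnot(width >= 1L)
  if (nrow(mentions) == 0L) return(mentions)
  n <- nchar(text)
  mentions$win_start <- mentions$kw_end
  mentions$win_end <- pmin(n, mentions$kw_end + as.integer(width))
  mentions$window_text <- substring(text, mentions$win_start + 1L, mentions$win_end)
  mentions$pass_number <- mentions$pass_number + 1L
  mentions
}

#' Capture a numeric value from a narrowed window
#'
#' Scans for the first digit run of length 1 to `max_digits` (longer runs,
#' e.g. accession numbers, are skipped as non-values). A run followed by
#' `%` is tagged as a percentage; a run followed by `/` and a second run is
#' returned as a fraction (numerator, denominator), the shape of Allred
#' ("8/8") and Nottingham ("5/9") scores.
#'
#' @param window Window text.
#' @param spec Numeric pattern spec from [parameter_rules()].
#' @return List `value`, `denominator`, `pct` (`value = NA` when nothing
#'   matches).
#' @export
capture_numeric <- function(window, spec) {
  miss <- list(value = NA_real_, denominator = NA_real_, pct = FALSE)
  if (is.null(spec) || is.na(window) || !nzchar(window)) return(miss)
  maxd <- spec$max_digits %||% 4L
  runs <- gregexpr("[0-9]+", window)[[1]]
  if (runs[1] == -1L) return(miss)
  lens <- attr(runs, "match.length")
  for (k in seq_along(runs)) {
    if (lens[k] > maxd) next
    start <- as.integer(runs[k])
    val <- as.numeric(substr(window, start, start + lens[k] - 1L))
    rest <- substr(window, start + lens[k], nchar(window))
    if (isTRUE(spec$allow_fraction)) {
      fm <- regmatches(rest, regexec("^\\s*/\\s*([0-9]{1,4})(?![0-9])", rest, perl = TRUE))[[1]]
      if (length(fm) == 2L) {
        return(list(value = val, denominator = as.numeric(fm[2]), pct = FALSE))
      }
    }
    pct <- isTRUE(spec$allow_pct) && grepl("^\\s*%", rest)
    return(list(value = val, denominator = NA_real_, pct = pct))
  }
  miss
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Capture a pre-categorised value from a narrowed window
#'
#' Finds the earliest lexicon token in the window (case-insensitive,
#' word-boundary match; at a shared position the longest token wins) and
#' maps it to its normalised category. A "positive" hit preceded within
#' three tokens by "not" or "no" is returned as negative.
#'
#' @param window Window text.
#' @param lexicon Named character vector, token -> normalised category.
#' @return Normalised category string, or `NA` when no token occurs.
#' @export
capture_categorical <- function(window, lexicon) {
  if (is.null(lexicon) || is.na(window) || !nzchar(window)) return(NA_character_)
  best_pos <- Inf; best_len <- -1L; best_cat <- NA_character_; best_token <- NA_character_
  for (token in names(lexicon)) {
    pat <- paste0("(?i)(?<![A-Za-z0-9])", escape_regex(token), "(?![A-Za-z0-9])")
    m <- regexpr(pat, window, perl = TRUE)
    if (m[1] == -1L) next
    pos <- as.integer(m); len <- attr(m, "match.length")
    if (pos < best_pos || (pos == best_pos && len > best_len)) {
      best_pos <- pos; best_len <- len
      best_cat <- unname(lexicon[[token]]); best_token <- token
    }
  }
  if (!is.finite(best_pos)) return(NA_character_)
  if (identical(best_cat, "positive")) {
    before <- substr(window, 1L, best_pos - 1L)
    toks <- strsplit(trimws(before), "[^A-Za-z0-9]+")[[1]]
    toks <- toks[nzchar(toks)]
    recent <- utils::tail(toks, 3L)
    if (any(tolower(recent) %in% c("not", "no"))) best_cat <- "negative"
  }
  best_cat
}

#' Synthesise per-mention captures into one extraction result
#'
#' Applies the rule set's precedence (numeric before categorical by
#' default). Among several numeric candidates the one nearest the start of
#' the report wins -- the first clinical statement -- with the rest kept in
#' provenance. With no numeric candidate, a single distinct category is
#' returned; distinct conflicting categories yield status `"ambiguous"`;
#' no mention at all yields `"not_reported"`.
#'
#' @param mentions Mention data frame augmented with capture columns
#'   `num_value`, `num_den`, `num_pct`, `cat_value` (see [extract_all()]).
#' @param rules The parameter's [parameter_rules()].
#' @return List: `status`, `numeric_value`, `denominator`, `pct`,
#'   `category_value`, `raw_value`, `variant`, `pass_number`,
#'   `capture_kind`, `n_candidates`.
#' @export
synthesize <- function(mentions, rules) {
  res <- list(status = "not_reported", numeric_value = NA_real_,
              denominator = NA_real_, pct = FALSE, category_value = NA_character_,
              raw_value = NA_character_, variant = NA_character_,
              pass_number = NA_integer_, capture_kind = NA_character_,
              n_candidates = 0L)
  if (nrow(mentions) == 0L) return(res)
  for (kind in rules$precedence) {
    if (kind == "numeric") {
      cand <- mentions[!is.na(mentions$num_value), , drop = FALSE]
      if (nrow(cand) > 0L) {
        cand <- cand[order(cand$kw_start), , drop = FALSE]
        res$status <- "found"
        res$numeric_value <- cand$num_value[1]
        res$denominator <- cand$num_den[1]
        res$pct <- cand$num_pct[1]
        res$raw_value <- cand$window_text[1]
        res$variant <- cand$matched_variant[1]
        res$pass_number <- cand$pass_number[1]
        res$capture_kind <- "numeric"
        res$n_candidates <- nrow(cand)
        return(res)
      }
    } else if (kind == "categorical") {
      cand <- mentions[!is.na(mentions$cat_value), , drop = FALSE]
      if (nrow(cand) > 0L) {
        cand <- cand[order(cand$kw_start), , drop = FALSE]
        cats <- unique(cand$cat_value)
        if (length(cats) > 1L) {
          res$status <- "ambiguous"
          res$n_candidates <- nrow(cand)
          return(res)
        }
        res$status <- "found"
        res$category_value <- cats
        res$raw_value <- cand$window_text[1]
        res$variant <- cand$matched_variant[1]
        res$pass_number <- cand$pass_number[1]
        res$capture_kind <- "categorical"
        res$n_candidates <- nrow(cand)
        return(res)
      }
    }
  }
  res
}

run_cascade <- function(text, rules) {
  mentions <- summarize(text, rules)
  mentions <- narrow(mentions, text, rules$narrow_width)
  n <- nrow(mentions)
  mentions$num_value <- rep(NA_real_, n)
  mentions$num_den <- rep(NA_real_, n)
  mentions$num_pct <- rep(FALSE, n)
  mentions$cat_value <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cap <- capture_numeric(mentions$window_text[i], rules$numeric_pattern)
    mentions$num_value[i] <- cap$value
    mentions$num_den[i] <- cap$denominator
    mentions$num_pct[i] <- cap$pct
    mentions$cat_value[i] <- capture_categorical(mentions$window_text[i],
                                                 rules$category_lexicon)
  }
  synthesize(mentions, rules)
}

#' Extract all parameters from one report
#'
#' Cleans the report text and runs the four-pass cascade for every rule
#' set. Age and race prefer the structured sidecar fields when present,
#' falling back to text capture; extraction is deterministic.
#'
#' @param report A one-row data frame or list with `report_id`, `free_text`
#'   and optionally `structured_age`, `structured_race`.
#' @param rulesets Named list from [default_rulesets()] or
#'   [read_rulesets()].
#' @return One-row data frame with, per parameter `p`, columns `p_status`,
#'   `p_num`, `p_den`, `p_pct`, `p_cat`, `p_variant`, `p_kind`.
#' @export
extract_all <- function(report, rulesets = default_rulesets()) {
  text <- clean_text(report$free_text %||% "")
  if (is.na(text)) text <- ""
  out <- list(report_id = report$report_id %||% NA_character_)
  for (p in names(rulesets)) {
    res <- run_cascade(text, rulesets[[p]])
    if (p == "age" && !is.null(report$structured_age) && !is.na(report$structured_age)) {
      res$status <- "found"; res$numeric_value <- as.numeric(report$structured_age)
      res$denominator <- NA_real_; res$pct <- FALSE
      res$capture_kind <- "structured"; res$variant <- "structured_age"
    }
    if (p == "race" && !is.null(report$structured_race) && !is.na(report$structured_race)) {
      res$status <- "found"; res$category_value <- as.character(report$structured_race)
      res$capture_kind <- "structured"; res$variant <- "structured_race"
    }
    out[[paste0(p, "_status")]] <- res$status
    out[[paste0(p, "_num")]] <- res$numeric_value
    out[[paste0(p, "_den")]] <- res$denominator
    out[[paste0(p, "_pct")]] <- res$pct
    out[[paste0(p, "_cat")]] <- res$category_value
    out[[paste0(p, "_variant")]] <- res$variant
    out[[paste0(p, "_kind")]] <- res$capture_kind
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Extract all parameters from a corpus
#'
#' @param reports Corpus data frame (see [generate_corpus()]).
#' @param rulesets Named list of rule sets.
#' @return Data frame, one row per report, as in [extract_all()].
#' @export
extract_corpus <- function(reports, rulesets = default_rulesets()) {
  rows <- lapply(seq_len(nrow(reports)), function(i) {
    extract_all(reports[i, , drop = FALSE], rulesets)
  })
  do.call(rbind, rows)
}
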
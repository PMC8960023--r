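#' Write and read a report corpus as JSON Lines
#'
#' One report per line with fields `report_id`, `episode_number`,
#' `snomed_code`, `sex`, `free_text` and any structured sidecar columns.
#' Round-trips exactly, including empty texts and non-ASCII characters; an
#' empty corpus yields an empty file. A malformed line raises a parse error
#' naming the line number rather than being skipped.
#'
#' @param reports Corpus data frame.
#' @param path File path.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` returns
#'   the corpus data frame.
#' @export
write_corpus <- function(reports, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(reports))) {
    row <- as.list(reports[i, , drop = FALSE])
    line <- jsonlite::toJSON(row, auto_unbox = TRUE, na = "null", digits = NA)
    writeLines(line, con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(report_id = character(0), episode_number = character(0),
                      snomed_code = character(0), sex = character(0),
                      free_text = character(0), stringsAsFactors = FALSE))
  }
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parsed <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) e)
    if (inherits(parsed, "error")) {
      stop_parse(sprintf("malformed corpus record at line %d: %s", i,
                         conditionMessage(parsed)))
    }
    if (is.null(parsed$report_id)) {
      stop_parse(sprintf("corpus record at line %d lacks report_id", i))
    }
    rows[[i]] <- as.data.frame(lapply(parsed, function(x) if (is.null(x)) NA else x),
                               stringsAsFactors = FALSE)
  }
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (c in setdiff(cols, names(r))) r[[c]] <- NA
    r[, cols, drop = FALSE]
  })
  do.call(rbind, rows)
}

#' Write and read a ground-truth table as CSV
#'
#' @param truth Ground-truth data frame keyed by `report_id`.
#' @param path File path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the table.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Read and write a corpus-generation configuration
#'
#' YAML with sections `marginals`, `noise` and `seed`; omitted entries fall
#' back to [default_marginals()] / [noise_config()] defaults.
#'
#' @param path YAML file path.
#' @param config List with any of `marginals`, `noise`, `seed`.
#' @return `read_corpus_config` returns a list with fully populated
#'   `marginals`, `noise` and `seed`.
#' @export
read_corpus_config <- function(path) {
  raw <- yaml::read_yaml(path)
  marg <- utils::modifyList(default_marginals(), raw$marginals %||% list())
  if (!is.null(marg$age$bands)) marg$age$bands <- lapply(marg$age$bands, unlist)
  noise <- do.call(noise_config, raw$noise %||% list())
  list(marginals = marg, noise = noise, seed = raw$seed %||% 1L)
}

#' @rdname read_corpus_config
#' @export
write_corpus_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
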
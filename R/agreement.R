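# Agreement between machine extraction and gold annotation: confusion
# matrices, one-vs-rest precision/recall/F1, Cohen's kappa, the two-way
# mixed average-score ICC for continuous parameters, and error listings
# for manual review.

#' Build a confusion matrix
#'
#' Rows are gold labels, columns machine labels, in the supplied category
#' order.
#'
#' @param gold,machine Equal-length label vectors.
#' @param categories Category order; defaults to the sorted union.
#' @return Object of class `pathrex_confusion`: list with `categories`,
#'   `counts` (square matrix), `n`.
#' @export
confusion <- function(gold, machine, categories = NULL) {
  if (length(gold) != length(machine)) stop("gold and machine must have equal length")
  if (length(gold) == 0L) stop("empty input: no labels to compare")
  if (is.null(categories)) categories <- sort(unique(c(gold, machine)))
  if (!all(c(gold, machine) %in% categories)) {
    stop("labels outside the supplied categories")
  }
  counts <- table(factor(gold, levels = categories),
                  factor(machine, levels = categories))
  counts <- matrix(as.integer(counts), nrow = length(categories),
                   dimnames = list(gold = categories, machine = categories))
  structure(list(categories = categories, counts = counts, n = length(gold)),
            class = "pathrex_confusion")
}

#' @export
print.pathrex_confusion <- function(x, ...) {
  cat(sprintf("<confusion matrix, n = %d>\n", x$n))
  print(x$counts)
  invisible(x)
}

wilson_ci <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' One-vs-rest precision, recall and F1 for one category
#'
#' TP/FP/FN are read off the confusion matrix one-vs-rest; precision is
#' TP/(TP+FP), recall TP/(TP+FN) and F1 the harmonic mean 2PR/(P+R) (0 when
#' P+R = 0). A zero denominator yields value 0 with `degenerate = TRUE`.
#' Precision and recall get Wilson score intervals; F1 a seeded bootstrap
#' percentile interval over label pairs when `boot > 0`.
#'
#' @param m A [confusion()] object.
#' @param category Category to score.
#' @param boot Bootstrap resamples for the F1 interval (0 disables).
#' @param seed Seed for the bootstrap.
#' @param level Confidence level.
#' @return List: `precision`, `recall`, `f1`, intervals `precision_ci`,
#'   `recall_ci`, `f1_ci`, and `degenerate`.
#' @export
precision_recall_f1 <- function(m, category, boot = 0L, seed = 1L, level = 0.95) {
  stopifnot(inherits(m, "pathrex_confusion"))
  if (!category %in% m$categories) stop("category not present in the matrix")
  i <- match(category, m$categories)
  tp <- m$counts[i, i]
  fp <- sum(m$counts[-i, i])
  fn <- sum(m$counts[i, -i])
  degenerate <- (tp + fp == 0) || (tp + fn == 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  f1_ci <- c(NA_real_, NA_real_)
  if (boot > 0L) {
    labs <- expand_labels(m)
    set.seed(seed)
    stat <- replicate(boot, {
      idx <- sample.int(m$n, m$n, replace = TRUE)
      mb <- confusion(labs$gold[idx], labs$machine[idx], m$categories)
      j <- match(category, m$categories)
      tpb <- mb$counts[j, j]; fpb <- sum(mb$counts[-j, j]); fnb <- sum(mb$counts[j, -j])
      pb <- if (tpb + fpb > 0) tpb / (tpb + fpb) else 0
      rb <- if (tpb + fnb > 0) tpb / (tpb + fnb) else 0
      if (pb + rb > 0) 2 * pb * rb / (pb + rb) else 0
    })
    f1_ci <- unname(stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  list(precision = p, recall = r, f1 = f1,
       precision_ci = wilson_ci(tp, tp + fp, level),
       recall_ci = wilson_ci(tp, tp + fn, level),
       f1_ci = f1_ci, degenerate = degenerate)
}

expand_labels <- function(m) {
  gold <- character(0); machine <- character(0)
  for (i in seq_along(m$categories)) {
    for (j in seq_along(m$categories)) {
      k <- m$counts[i, j]
      if (k > 0) {
        gold <- c(gold, rep(m$categories[i], k))
        machine <- c(machine, rep(m$categories[j], k))
      }
    }
  }
  list(gold = gold, machine = machine)
}

#' Cohen's kappa from a confusion matrix
#'
#' Observed agreement P0 is the diagonal fraction; chance agreement Pe the
#' sum over categories of (row total x column total)/n^2; kappa is
#' (P0 - Pe)/(1 - Pe). When Pe = 1 kappa is undefined and flagged rather
#' than propagating NaN. The interval is a seeded bootstrap percentile
#' interval when `boot > 0`.
#'
#' @param m A [confusion()] object.
#' @param boot Bootstrap resamples (0 disables the interval).
#' @param seed Seed for the bootstrap.
#' @param level Confidence level.
#' @return List: `kappa`, `p0`, `pe`, `kappa_ci`, `undefined`.
#' @export
cohen_kappa <- function(m, boot = 0L, seed = 1L, level = 0.95) {
  stopifnot(inherits(m, "pathrex_confusion"), m$n >= 1)
  p0 <- sum(diag(m$counts)) / m$n
  pe <- sum(rowSums(m$counts) * colSums(m$counts)) / m$n^2
  if (1 - pe < .Machine$double.eps) {
    return(list(kappa = NA_real_, p0 = p0, pe = pe,
                kappa_ci = c(NA_real_, NA_real_), undefined = TRUE))
  }
  k <- (p0 - pe) / (1 - pe)
  ci <- c(NA_real_, NA_real_)
  if (boot > 0L) {
    labs <- expand_labels(m)
    set.seed(seed)
    stat <- replicate(boot, {
      idx <- sample.int(m$n, m$n, replace = TRUE)
      mb <- confusion(labs$gold[idx], labs$machine[idx], m$categories)
      p0b <- sum(diag(mb$counts)) / mb$n
      peb <- sum(rowSums(mb$counts) * colSums(mb$counts)) / mb$n^2
      if (1 - peb < .Machine$double.eps) NA_real_ else (p0b - peb) / (1 - peb)
    })
    stat <- stat[!is.na(stat)]
    if (length(stat)) {
      ci <- unname(stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2)))
    }
  }
  list(kappa = k, p0 = p0, pe = pe, kappa_ci = ci, undefined = FALSE)
}

#' Two-way mixed, absolute-agreement, average-measures ICC
#'
#' ICC(A,k) for an n x k grid of ratings (subjects by raters):
#' `(MSB - MSE) / (MSB + (MSR - MSE)/n)`, where MSB, MSR and MSE are the
#' between-subject, between-rater and residual mean squares of the two-way
#' ANOVA decomposition. The absolute-agreement definition penalises a
#' constant shift between raters. The confidence interval uses the
#' single-measures agreement F-bounds converted to average measures by the
#' Spearman-Brown relation. Zero total variance is flagged degenerate.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, raters in
#'   columns, no missing cells, n >= 2 subjects and >= 2 raters.
#' @param level Confidence level.
#' @return List: `icc`, `ci`, `msb`, `msr`, `mse`, `n`, `k`, `degenerate`.
#' @export
icc_two_way_mixed_avg <- function(ratings, level = 0.95) {
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("ratings grid must have no missing cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssb <- k * sum((row_m - grand)^2)
  ssr <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssb - ssr
  msb <- ssb / (n - 1)
  msr <- ssr / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst < .Machine$double.eps) {
    return(list(icc = NA_real_, ci = c(NA_real_, NA_real_), msb = msb,
                msr = msr, mse = mse, n = n, k = k, degenerate = TRUE))
  }
  icc <- (msb - mse) / (msb + (msr - mse) / n)
  # single-measures agreement bounds (F approximation), then Spearman-Brown
  alpha <- 1 - level
  r1 <- (msb - mse) / (msb + (k - 1) * mse + (k / n) * (msr - mse))
  a <- (k * r1) / (n * (1 - r1))
  b <- 1 + (k * r1 * (n - 1)) / (n * (1 - r1))
  v <- (a * msr + b * mse)^2 /
    ((a * msr)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msb - fl * mse) /
    (fl * (k * msr + (k * n - k - n) * mse) + n * msb)
  up1 <- n * (fu * msb - mse) /
    (k * msr + (k * n - k - n) * mse + n * fu * msb)
  sb <- function(r) k * r / (1 + (k - 1) * r)
  list(icc = icc, ci = c(sb(lo1), sb(up1)), msb = msb, msr = msr, mse = mse,
       n = n, k = k, degenerate = FALSE)
}

#' List disagreements between gold and machine annotations
#'
#' Returns up to `k` disagreeing reports with a text snippet centred on the
#' relevant mention (located by searching the report for the gold or
#' machine value), for manual error review.
#'
#' @param gold,machine Aligned label vectors.
#' @param texts Aligned report texts.
#' @param k Maximum number of disagreements to list.
#' @param width Snippet width in characters.
#' @return Data frame: `index`, `gold`, `machine`, `snippet`.
#' @export
error_listing <- function(gold, machine, texts, k = 10L, width = 80L) {
  stopifnot(length(gold) == length(machine), length(gold) == length(texts))
  mism <- which(is.na(gold) != is.na(machine) |
                  (!is.na(gold) & !is.na(machine) & gold != machine))
  mism <- utils::head(mism, k)
  snippet <- vapply(mism, function(i) {
    txt <- texts[i]
    if (is.na(txt) || !nzchar(txt)) return("")
    target <- c(gold[i], machine[i])
    target <- target[!is.na(target)]
    pos <- NA_integer_
    for (t in target) {
      p <- regexpr(t, txt, fixed = TRUE)
      if (p[1] != -1L) { pos <- as.integer(p); break }
    }
    if (is.na(pos)) pos <- 1L
    start <- max(1L, pos - width %/% 2L)
    substr(txt, start, min(nchar(txt), start + width))
  }, character(1))
  data.frame(index = mism, gold = gold[mism], machine = machine[mism],
             snippet = snippet, stringsAsFactors = FALSE)
}

#' Full agreement report for a validation sample
#'
#' For each categorical parameter: per-category precision/recall/F1 plus a
#' single multi-category kappa; for age: the two-way mixed
#' absolute-agreement average-measures ICC.
#'
#' @param gold,machine Data frames keyed by `report_id` sharing the
#'   parameter columns.
#' @param categorical Character vector of categorical parameter columns.
#' @param continuous Character vector of continuous parameter columns.
#' @param boot Bootstrap resamples for F1/kappa intervals.
#' @param seed Bootstrap seed.
#' @return List with `categorical` (data frame shaped like a validation
#'   table: parameter, category, precision, recall, f1, kappa) and
#'   `continuous` (data frame: parameter, icc, ci bounds).
#' @export
agreement_report <- function(gold, machine,
                             categorical = c("er_status", "pr_status", "her2_status",
                                             "ki67_index", "grade", "histologic_type",
                                             "laterality"),
                             continuous = "age_years",
                             boot = 0L, seed = 1L) {
  machine <- machine[match(gold$report_id, machine$report_id), , drop = FALSE]
  cat_rows <- list()
  for (p in categorical) {
    ok <- !is.na(gold[[p]]) & !is.na(machine[[p]])
    if (!any(ok)) next
    m <- confusion(gold[[p]][ok], machine[[p]][ok])
    kap <- cohen_kappa(m, boot = boot, seed = seed)
    for (cat in m$categories) {
      prf <- precision_recall_f1(m, cat, boot = 0L)
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        parameter = p, category = cat,
        precision = prf$precision, recall = prf$recall, f1 = prf$f1,
        kappa = kap$kappa, n = m$n, stringsAsFactors = FALSE)
    }
  }
  cont_rows <- list()
  for (p in continuous) {
    ok <- !is.na(gold[[p]]) & !is.na(machine[[p]])
    if (sum(ok) < 2L) next
    res <- icc_two_way_mixed_avg(cbind(gold[[p]][ok], machine[[p]][ok]))
    cont_rows[[length(cont_rows) + 1L]] <- data.frame(
      parameter = p, icc = res$icc, ci_low = res$ci[1], ci_high = res$ci[2],
      n = res$n, stringsAsFactors = FALSE)
  }
  list(categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else NULL,
       continuous = if (length(cont_rows)) do.call(rbind, cont_rows) else NULL)
}
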
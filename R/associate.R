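# Univariable association analysis: binary logistic and multinomial
# (reference-outcome contrast) models fitted by IRLS, Wald intervals, and
# stratified trend tables. For a single categorical covariate the fitted
# odds ratios coincide with the contingency cross-product ratios; that
# identity is the internal oracle the tests lean on.

irls_logit <- function(X, y, w, tol = 1e-8, max_iter = 100L) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wt <- w * mu * (1 - mu)
    score <- drop(crossprod(X, w * (y - mu)))
    info <- crossprod(X, X * wt)
    delta <- solve(info, score)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X, X * (w * mu * (1 - mu)))
  se <- sqrt(diag(solve(info)))
  list(beta = beta, se = se, iterations = it)
}

#' Build a contingency table from patient records
#'
#' @param records Data frame.
#' @param covariate,outcome Column names (categorical).
#' @param covariate_levels,outcome_levels Optional level orders; the first
#'   level of each is the reference.
#' @return Integer matrix, covariate levels in rows, outcome levels in
#'   columns.
#' @export
contingency <- function(records, covariate, outcome,
                        covariate_levels = NULL, outcome_levels = NULL) {
  x <- records[[covariate]]; y <- records[[outcome]]
  ok <- !is.na(x) & !is.na(y)
  x <- factor(x[ok], levels = covariate_levels %||% sort(unique(x[ok])))
  y <- factor(y[ok], levels = outcome_levels %||% sort(unique(y[ok])))
  tab <- table(x, y)
  matrix(as.integer(tab), nrow = nlevels(x),
         dimnames = list(levels(x), levels(y)))
}

#' Odds ratio and Wald interval from a 2x2 table
#'
#' For counts `a` (reference level, reference outcome), `b` (reference
#' level, index outcome), `c` (index level, reference outcome), `d` (index
#' level, index outcome): OR = ad/bc... more precisely the cross-product
#' `(d * a) / (b * c)`, with Wald CI
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param a,b,c,d Cell counts.
#' @param level Confidence level.
#' @return List `or`, `ci_low`, `ci_high`, `se_log`, `p_value`,
#'   `estimable`.
#' @export
or_from_counts <- function(a, b, c, d, level = 0.95) {
  if (min(a, b, c, d) == 0) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                se_log = NA_real_, p_value = NA_real_, estimable = FALSE))
  }
  or <- (d * a) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  zstat <- log(or) / se
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       se_log = se, p_value = 2 * stats::pnorm(-abs(zstat)), estimable = TRUE)
}

fit_binary_contrast <- function(tab, ref_col, idx_col, level = 0.95) {
  # tab: covariate levels x outcomes; dummy-coded IRLS fit of idx vs ref.
  # Levels with a zero cell are separated and excluded from the fit, then
  # reported as non-estimable -- never as infinite odds ratios.
  lev <- rownames(tab)
  counts_ref <- tab[, ref_col]
  counts_idx <- tab[, idx_col]
  estimable <- counts_ref > 0 & counts_idx > 0 & counts_ref[1] > 0 & counts_idx[1] > 0
  estimable[1] <- counts_ref[1] > 0 && counts_idx[1] > 0
  fit_lev <- lev[estimable]
  beta <- stats::setNames(rep(NA_real_, length(lev)), lev)
  se <- beta
  if (estimable[1] && length(fit_lev) > 1L) {
    L <- length(fit_lev)
    X <- cbind(1, diag(L)[, -1, drop = FALSE])
    Xw <- X[rep(seq_len(L), 2L), , drop = FALSE]
    yw <- rep(c(0, 1), each = L)
    w <- c(counts_ref[estimable], counts_idx[estimable])
    fit <- irls_logit(Xw, yw, w)
    beta[fit_lev[-1]] <- fit$beta[-1]
    se[fit_lev[-1]] <- fit$se[-1]
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(seq_along(lev)[-1], function(j) {
    est <- estimable[1] && estimable[j]
    b <- beta[[lev[j]]]; s <- se[[lev[j]]]
    data.frame(level = lev[j],
               beta = if (est) b else NA_real_,
               se = if (est) s else NA_real_,
               odds_ratio = if (est) exp(b) else NA_real_,
               ci_low = if (est) exp(b - z * s) else NA_real_,
               ci_high = if (est) exp(b + z * s) else NA_real_,
               p_value = if (est) 2 * stats::pnorm(-abs(b / s)) else NA_real_,
               estimable = est,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Univariable multinomial logistic regression by reference contrasts
#'
#' The multinomial model with outcome reference category j0 factorises, for
#' a single categorical covariate, into separate binary logistic fits of
#' each outcome category against the reference; each contrast's odds
#' ratios equal the corresponding contingency cross-product ratios. Fits
#' use IRLS (tolerance 1e-8, at most 100 iterations) with Wald 95%
#' intervals `exp(beta +/- z * SE)`. Contrasts with a zero cell are flagged
#' non-estimable rather than reported as infinite.
#'
#' @param records Data frame, or an already-built contingency matrix
#'   (covariate levels x outcome levels).
#' @param covariate Covariate column name (ignored when `records` is a
#'   matrix).
#' @param outcome Outcome column name, default `"subtype"`.
#' @param reference_outcome Outcome reference category, default Luminal A.
#' @param reference_level Covariate reference level (default: first row).
#' @param outcome_levels,covariate_levels Optional level orders.
#' @param level Confidence level.
#' @return Data frame of association results: `covariate`, `level`,
#'   `contrast`, `beta`, `se`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `estimable`.
#' @export
univariable_multinomial <- function(records, covariate = NULL, outcome = "subtype",
                                    reference_outcome = "LuminalA",
                                    reference_level = NULL,
                                    outcome_levels = NULL, covariate_levels = NULL,
                                    level = 0.95) {
  tab <- if (is.matrix(records)) records else {
    contingency(records, covariate, outcome, covariate_levels, outcome_levels)
  }
  if (!reference_outcome %in% colnames(tab)) {
    stop(sprintf("reference outcome '%s' not among outcome levels", reference_outcome))
  }
  if (!is.null(reference_level)) {
    ord <- c(reference_level, setdiff(rownames(tab), reference_level))
    tab <- tab[ord, , drop = FALSE]
  }
  if (ncol(tab) < 2L) stop("outcome must have at least 2 levels")
  out <- list()
  for (j in setdiff(colnames(tab), reference_outcome)) {
    res <- fit_binary_contrast(tab, reference_outcome, j, level)
    res$contrast <- sprintf("%s vs %s", j, reference_outcome)
    res$covariate <- covariate %||% "covariate"
    out[[length(out) + 1L]] <- res
  }
  res <- do.call(rbind, out)
  res[, c("covariate", "level", "contrast", "beta", "se", "odds_ratio",
          "ci_low", "ci_high", "p_value", "estimable")]
}

#' Univariable binary logistic regression
#'
#' The two-outcome special case: odds of the second outcome level versus
#' the first across covariate levels, fitted by IRLS with Wald intervals.
#'
#' @inheritParams univariable_multinomial
#' @param outcome Binary outcome column, default `"ki67_index"`.
#' @return Data frame as in [univariable_multinomial()].
#' @export
univariable_logistic <- function(records, covariate = NULL, outcome = "ki67_index",
                                 reference_level = NULL, outcome_levels = NULL,
                                 covariate_levels = NULL, level = 0.95) {
  tab <- if (is.matrix(records)) records else {
    contingency(records, covariate, outcome, covariate_levels, outcome_levels)
  }
  if (ncol(tab) != 2L) stop("binary model requires exactly 2 outcome levels")
  univariable_multinomial(tab, covariate = covariate,
                          reference_outcome = colnames(tab)[1],
                          reference_level = reference_level, level = level)
}

#' Stratified proportion trend table
#'
#' Cross-tabulates two categorical parameters and normalises within
#' stratum, the shape used to chart subtype or Ki67 proportions across
#' years, age bands and racial groups. Empty strata are flagged (`NaN`
#' proportions retained), not dropped.
#'
#' @param records Data frame.
#' @param row,col Column names; proportions are computed within each `col`
#'   stratum by default.
#' @param margin `2` to normalise within columns (default), `1` within
#'   rows.
#' @return Matrix of proportions with a `counts` attribute.
#' @export
trend_table <- function(records, row, col, margin = 2L) {
  tab <- contingency(records, row, col)
  tot <- apply(tab, margin, sum)
  prop <- if (margin == 2L) sweep(tab, 2L, tot, "/") else sweep(tab, 1L, tot, "/")
  attr(prop, "counts") <- tab
  prop
}
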
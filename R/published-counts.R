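# Published contingency counts from a South African national-laboratory
# breast-cancer cohort (N = 9669), bundled as example inputs so the
# univariable association layer can be exercised against reported odds
# ratios without access to the protected source data.

#' Published subtype-association contingency counts
#'
#' Cross-tabulations of molecular subtype (Luminal A the reference
#' outcome) against age band, laterality and racial group, as reported for
#' a South African national-laboratory breast-cancer cohort. Rows are
#' covariate levels (first = reference), columns are subtypes.
#'
#' @return Named list of integer matrices.
#' @export
subtype_assoc_counts <- function() {
  list(
    age = matrix(
      c(647, 283, 125, 311,
        1169, 419, 206, 569,
        1132, 367, 237, 478,
        1129, 287, 192, 448,
        985, 209, 123, 353),
      nrow = 5, byrow = TRUE,
      dimnames = list(c("<40", "40-49", "50-59", "60-69", "70-104"),
                      c("LuminalA", "LuminalB", "HER2-OE", "TNBC"))),
    laterality = matrix(
      c(2552, 765, 476, 1117,
        2510, 800, 407, 1042),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("left", "right"),
                      c("LuminalA", "LuminalB", "HER2-OE", "TNBC"))),
    race = matrix(
      c(3017, 959, 553, 1549,
        608, 112, 49, 77,
        769, 310, 185, 341,
        668, 184, 96, 192),
      nrow = 4, byrow = TRUE,
      dimnames = list(c("Black", "Asian", "Coloured", "White"),
                      c("LuminalA", "LuminalB", "HER2-OE", "TNBC")))
  )
}

#' Published Ki67-association contingency counts
#'
#' Cross-tabulations of the dichotomised Ki67 proliferation index (low
#' `<14` the reference outcome) against age band, receptor statuses, grade,
#' laterality, race, histologic type and molecular subtype, as reported
#' for the same cohort.
#'
#' @return Named list of integer matrices, columns `<14`, `>=14`.
#' @export
ki67_assoc_counts <- function() {
  two <- function(x, rn) {
    matrix(x, ncol = 2, byrow = TRUE, dimnames = list(rn, c("<14", ">=14")))
  }
  list(
    age = two(c(234, 816, 415, 1405, 404, 1297, 456, 1136, 409, 845),
              c("<40", "40-49", "50-59", "60-69", "70-104")),
    er = two(c(262, 1868, 1656, 3631), c("negative", "positive")),
    pr = two(c(614, 2592, 1304, 2907), c("negative", "positive")),
    her2 = two(c(1629, 3903, 289, 1596), c("negative", "positive")),
    grade = two(c(539, 363, 1154, 2298, 225, 2838), c("I", "II", "III")),
    laterality = two(c(943, 2777, 975, 2722), c("left", "right")),
    race = two(c(1140, 3696, 284, 387, 207, 785, 287, 631),
               c("Black", "Asian", "Coloured", "White")),
    histologic_type = two(c(1659, 4947, 259, 552), c("IDC", "other")),
    subtype = two(c(1474, 2744, 212, 1054, 77, 542, 155, 1159),
                  c("LuminalA", "LuminalB", "HER2-OE", "TNBC"))
  )
}
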
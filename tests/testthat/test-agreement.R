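test_that("confusion matrices count gold-by-machine cells", {
  m <- confusion(c("P", "P", "N", "N"), c("P", "N", "N", "N"), c("P", "N"))
  expect_equal(m$counts, matrix(c(1L, 0L, 1L, 2L), nrow = 2,
                                dimnames = list(gold = c("P", "N"),
                                                machine = c("P", "N"))))
  expect_equal(m$n, 4L)

  g <- sample(c("A", "B", "C"), 30, replace = TRUE)
  expect_true(all(diag(confusion(g, g)$counts) == table(factor(g))))

  expect_error(confusion(character(0), character(0)), "empty")
  expect_error(confusion(c("A"), c("A", "B")), "equal length")
  expect_error(confusion("A", "Z", categories = c("A", "B")), "outside")
})

test_that("precision, recall and F1 follow the one-vs-rest identities", {
  m <- confusion(c("P", "P", "N", "N"), c("P", "N", "N", "N"), c("P", "N"))
  r <- precision_recall_f1(m, "P")
  expect_equal(r$precision, 1.0)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, 2 / 3)

  diag_m <- confusion(c("A", "B", "A"), c("A", "B", "A"))
  perfect <- precision_recall_f1(diag_m, "A")
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))

  # category absent from gold: recall degenerate
  m2 <- confusion(c("A", "A"), c("A", "B"), c("A", "B"))
  r2 <- precision_recall_f1(m2, "B")
  expect_true(r2$degenerate)
  expect_equal(r2$recall, 0)
})

test_that("F1 is the harmonic mean of precision and recall on random matrices", {
  for (s in 1:30) {
    labs <- random_labels(60, sample(2:4, 1), seed = s)
    m <- confusion(labs$gold, labs$machine)
    for (cat in m$categories) {
      r <- precision_recall_f1(m, cat)
      hm <- if (r$precision + r$recall > 0) {
        2 * r$precision * r$recall / (r$precision + r$recall)
      } else 0
      expect_equal(r$f1, hm, tolerance = 1e-12)
      expect_true(r$f1 >= min(r$precision, r$recall) - 1e-12)
      expect_true(r$f1 <= max(r$precision, r$recall) + 1e-12)
    }
  }
})

test_that("Cohen's kappa matches the hand-computed example and bounds", {
  gold <- c(rep("P", 50), rep("N", 50))
  machine <- c(rep("P", 45), rep("N", 5), rep("P", 15), rep("N", 35))
  k <- cohen_kappa(confusion(gold, machine, c("P", "N")))
  expect_equal(k$p0, 0.8)
  expect_equal(k$pe, 0.5)
  expect_equal(k$kappa, 0.6)

  g <- c("A", "B", "A", "B")
  perfect <- cohen_kappa(confusion(g, g))
  expect_equal(perfect$kappa, 1)

  # constant labels: Pe = 1 flagged, not NaN
  const <- cohen_kappa(confusion(rep("A", 5), rep("A", 5), c("A", "B")))
  expect_true(const$undefined)
  expect_true(is.na(const$kappa))
})

test_that("kappa of independent labels concentrates near zero", {
  set.seed(2024)
  n <- 10000
  gold <- sample(c("A", "B"), n, replace = TRUE)
  machine <- sample(c("A", "B"), n, replace = TRUE)
  k <- cohen_kappa(confusion(gold, machine))
  # kappa of independent labels has s.e. ~ 1/sqrt(n)
  expect_lt(abs(k$kappa), 3 / sqrt(n))
})

test_that("kappa and P/R/F1 agree exactly with brute-force implementations", {
  for (s in 1:100) {
    labs <- random_labels(40 + s, sample(2:4, 1), seed = 1000 + s)
    m <- confusion(labs$gold, labs$machine)
    k <- cohen_kappa(m)
    if (!k$undefined) {
      expect_equal(k$kappa, kappa_brute(labs$gold, labs$machine), tolerance = 1e-12)
      expect_true(k$kappa <= k$p0 + 1e-12)
    }
    for (cat in m$categories) {
      r <- precision_recall_f1(m, cat)
      o <- prf_brute(labs$gold, labs$machine, cat)
      expect_equal(unname(c(r$precision, r$recall, r$f1)), unname(o), tolerance = 1e-12)
    }
  }
})

test_that("ICC(A,k) behaves on constructed grids and matches the ANOVA oracle", {
  expect_equal(icc_two_way_mixed_avg(cbind(1:10, 1:10))$icc, 1)

  # a constant shift is penalised by absolute agreement
  shifted <- icc_two_way_mixed_avg(cbind(1:50, 1:50 + 10))
  expect_lt(shifted$icc, 1)
  expect_gt(shifted$icc, 0)

  # subject reordering leaves ICC unchanged
  set.seed(8)
  x <- cbind(rnorm(30), rnorm(30))
  perm <- sample(30)
  expect_equal(icc_two_way_mixed_avg(x)$icc, icc_two_way_mixed_avg(x[perm, ])$icc,
               tolerance = 1e-12)

  # agreement with stats::aov mean squares on random grids
  for (s in 1:100) {
    set.seed(3000 + s)
    n <- sample(5:40, 1)
    subj <- rnorm(n, sd = 2)
    g <- cbind(subj + rnorm(n, sd = 0.5), subj + rnorm(n, sd = 0.5))
    expect_equal(icc_two_way_mixed_avg(g)$icc, icc_aov(g), tolerance = 1e-10)
  }

  expect_error(icc_two_way_mixed_avg(cbind(c(1, NA), c(1, 2))), "missing")
  deg <- icc_two_way_mixed_avg(matrix(5, 4, 2))
  expect_true(deg$degenerate)
})

test_that("simulated raters recover the theoretical ICC", {
  set.seed(99)
  n <- 4000
  sd_s <- 2; sd_e <- 1
  subj <- rnorm(n, sd = sd_s)
  g <- cbind(subj + rnorm(n, sd = sd_e), subj + rnorm(n, sd = sd_e))
  # ICC(A,k) with no rater effect: k*var_s / (k*var_s + var_e), k = 2
  theo <- 2 * sd_s^2 / (2 * sd_s^2 + sd_e^2)
  got <- icc_two_way_mixed_avg(g)$icc
  expect_lt(abs(got - theo), 3 * (1 - theo^2) / sqrt(n))
})

test_that("error listings surface exactly the disagreements", {
  gold <- c("left", "right", "left")
  machine <- c("left", "right", "left")
  texts <- c("Laterality left breast", "Laterality right breast", "Laterality left breast")
  expect_equal(nrow(error_listing(gold, machine, texts)), 0L)

  machine[2] <- "left"
  lst <- error_listing(gold, machine, texts, k = 10)
  expect_equal(lst$index, 2L)
  expect_equal(lst$gold, "right")
  expect_true(grepl("right", lst$snippet))

  # k larger than the number of disagreements: all listed, no padding
  machine[1] <- "right"
  expect_equal(nrow(error_listing(gold, machine, texts, k = 99)), 2L)
})

test_that("the agreement report covers categorical and continuous parameters", {
  cor <- generate_corpus(100, noise = noise_free(), seed = 67)
  rec <- harmonize_records(extract_corpus(cor$reports), cor$reports)
  gold <- harmonized_truth(cor$truth)
  rep_out <- agreement_report(gold, rec)
  expect_true(all(rep_out$categorical$precision == 1))
  expect_true(all(rep_out$categorical$kappa == 1))
  expect_equal(rep_out$continuous$icc[rep_out$continuous$parameter == "age_years"], 1)
})
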
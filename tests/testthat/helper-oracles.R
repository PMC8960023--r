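# Shared fixtures and independent brute-force oracles for the test suite.

noise_free <- function() noise_config(conflicting_duplicate_rate = 0)

# direct-counting kappa, independent of the package implementation
kappa_brute <- function(gold, machine) {
  n <- length(gold)
  agree <- 0
  for (i in seq_len(n)) if (gold[i] == machine[i]) agree <- agree + 1
  p0 <- agree / n
  cats <- unique(c(gold, machine))
  pe <- 0
  for (cat in cats) {
    pg <- sum(gold == cat) / n
    pm <- sum(machine == cat) / n
    pe <- pe + pg * pm
  }
  (p0 - pe) / (1 - pe)
}

prf_brute <- function(gold, machine, category) {
  tp <- sum(gold == category & machine == category)
  fp <- sum(gold != category & machine == category)
  fn <- sum(gold == category & machine != category)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(p = p, r = r, f1 = f1)
}

# ICC(A,k) through stats::aov mean squares -- an independent ANOVA path
icc_aov <- function(ratings) {
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(y = as.vector(x),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  msb <- ms[1]; msr <- ms[2]; mse <- ms[3]
  (msb - mse) / (msb + (msr - mse) / n)
}

random_labels <- function(n, n_cat, seed) {
  set.seed(seed)
  cats <- LETTERS[seq_len(n_cat)]
  list(gold = sample(cats, n, replace = TRUE),
       machine = sample(cats, n, replace = TRUE))
}
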
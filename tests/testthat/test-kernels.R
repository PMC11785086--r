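test_that("AUC equals brute-force pairwise counting", {
  # worked example: 3 wins and 1 loss over the 4 case/non-case pairs
  r <- auc_mann_whitney(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$n_pos, 2); expect_equal(r$n_neg, 2)

  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))          # both classes present
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(auc_mann_whitney(scores, labels)$auc,
                 auc_bruteforce(scores, labels))
  }
})

test_that("AUC honours the degenerate conventions and symmetry", {
  lab <- c(0, 0, 1, 1, 1)
  expect_equal(auc_mann_whitney(lab, lab)$auc, 1)        # perfect separation
  allsame <- auc_mann_whitney(rep(2, 5), lab)
  expect_equal(allsame$auc, 0.5)                          # all-tie convention
  expect_equal(allsame$variance, 0)
  set.seed(2)
  s <- rnorm(40); l <- rbinom(40, 1, 0.5); l[1:2] <- c(0, 1)
  expect_equal(auc_mann_whitney(s, l)$auc +
                 auc_mann_whitney(-s, l)$auc, 1)
  r <- auc_mann_whitney(s, l)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_error(auc_mann_whitney(s, rep(1, 40)), "both classes")
})

test_that("the paired DeLong test agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:10) {
    n <- 120
    l <- c(0, 1, rbinom(n - 2, 1, 0.3))
    base <- rnorm(n) + l
    a <- base + rnorm(n)
    b <- 0.4 * base + rnorm(n)
    got <- delong_test(a, b, l)
    ref <- pROC::roc.test(
      pROC::roc(l, a, quiet = TRUE, levels = c(0, 1), direction = "<"),
      pROC::roc(l, b, quiet = TRUE, levels = c(0, 1), direction = "<"),
      method = "delong", paired = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-8)
    expect_equal(abs(got$z), abs(unname(ref$statistic)), tolerance = 1e-8)
  }
})

test_that("DeLong test is antisymmetric and null on identical curves", {
  set.seed(22)
  l <- rbinom(200, 1, 0.3); l[1:2] <- c(0, 1)
  a <- rnorm(200); b <- rnorm(200)
  expect_equal(delong_test(a, a, l)$p, 1)
  ab <- delong_test(a, b, l); ba <- delong_test(b, a, l)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_error(delong_test(a, b[-1], l), "equal length")
})

test_that("DeLong p agrees with a stratified-bootstrap oracle", {
  set.seed(23)
  n <- 2000
  l <- rbinom(n, 1, 0.2)
  informative <- rnorm(n) + 1.2 * l
  noise <- rnorm(n)
  got <- delong_test(informative, noise, l)$p

  boot_diff <- replicate(400, {
    i1 <- sample(which(l == 1), replace = TRUE)
    i0 <- sample(which(l == 0), replace = TRUE)
    i <- c(i1, i0); ll <- l[i]
    auc_mann_whitney(informative[i], ll)$auc -
      auc_mann_whitney(noise[i], ll)$auc
  })
  obs <- auc_mann_whitney(informative, l)$auc -
    auc_mann_whitney(noise, l)$auc
  boot_p <- 2 * pnorm(-abs(obs / sd(boot_diff)))
  expect_true((got < 0.01 && boot_p < 0.01) ||
                (got > 0.10 && boot_p > 0.10))
})

test_that("NEF counts effective tests from the eigen spectrum", {
  # uncorrelated columns: principal-component scores have an identity
  # sample correlation, so every eigenvalue is 1 and NEF = plain Bonferroni
  set.seed(31)
  z <- prcomp(matrix(rnorm(400 * 10), 400, 10))$x
  p10 <- runif(10)
  r <- nef_adjust(z, p10)
  expect_equal(r$n_effective, 10)
  expect_equal(r$eigenvalues, rep(1, 10), tolerance = 1e-8)
  expect_equal(r$adjusted_p, pmin(1, p10 * 10))
  expect_equal(sum(r$eigenvalues), 10, tolerance = 1e-8)

  # five copies of one column: rank-1 correlation, no adjustment
  x <- rnorm(50)
  r1 <- nef_adjust(cbind(x, x, x, x, x), rep(0.03, 5))
  expect_equal(r1$n_effective, 1)
  expect_equal(r1$adjusted_p, rep(0.03, 5))
  expect_equal(r1$eigenvalues, c(5, 0, 0, 0, 0), tolerance = 1e-8)
})

test_that("NEF matches an independently coded eigen solver", {
  set.seed(32)
  for (i in 1:5) {
    n <- 200
    blocks <- matrix(rnorm(n * 5), n, 5)[, sample(5, 50, TRUE)]
    mat <- 0.7 * blocks + 0.5 * matrix(rnorm(n * 50), n, 50)
    r <- nef_adjust(mat, runif(50))
    expect_equal(r$n_effective, nef_bruteforce(mat))
  }
})

test_that("NEF handles missing cells pairwise and rejects degenerate input", {
  set.seed(33)
  mat <- matrix(rnorm(300 * 6), 300, 6)
  mat[sample(length(mat), 150)] <- NA
  r <- nef_adjust(mat, runif(6))
  expect_true(r$n_effective >= 1 && r$n_effective <= 6)
  expect_true(all(r$adjusted_p >= r$raw_p))
  expect_true(all(diff(r$eigenvalues) <= 1e-12))
  bad <- mat; bad[, 2] <- 1
  expect_error(nef_adjust(bad, runif(6)), "zero-variance")
})

test_that("NEF is monotone in exchangeable correlation strength", {
  set.seed(34)
  n <- 2000; p <- 20
  neff <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    shared <- rnorm(n)
    mat <- sqrt(rho) * shared + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
    nef_adjust(mat, runif(p))$n_effective
  }, numeric(1))
  expect_true(all(diff(neff) <= 0))
})

test_that("odds ratios match the closed-form Wald formulas", {
  expect_equal(odds_ratio_2x2(10, 20, 20, 10)$or_value, 0.25)

  r <- odds_ratio_2x2(5, 5, 7, 7)
  expect_equal(r$or_value, 1)
  expect_true(r$ci_low < 1 && r$ci_high > 1)

  # independent evaluation of the Wald formulas
  r2 <- odds_ratio_2x2(50, 950, 100, 900)
  lor <- log((50 * 900) / (950 * 100))
  se <- sqrt(1 / 50 + 1 / 950 + 1 / 100 + 1 / 900)
  expect_equal(r2$or_value, exp(lor))
  expect_equal(r2$or_value, 0.4737, tolerance = 1e-4)
  expect_equal(r2$ci_low, exp(lor - qnorm(0.975) * se))
  expect_equal(r2$ci_high, exp(lor + qnorm(0.975) * se))
  expect_equal(r2$ci_low, 0.333, tolerance = 1e-3)
  expect_equal(r2$ci_high, 0.673, tolerance = 1e-3)
  expect_equal(r2$p, 2 * pnorm(-abs(lor / se)))
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  r <- odds_ratio_2x2(0, 10, 5, 5)
  expect_true(r$corrected)
  expect_equal(r$or_value, (0.5 * 5.5) / (10.5 * 5.5))
  expect_false(odds_ratio_2x2(1, 10, 5, 5)$corrected)
  expect_error(odds_ratio_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("two odds ratios are compared by a 1-df chi-square on log-ORs", {
  a <- odds_ratio_2x2(30, 70, 50, 50)
  expect_equal(compare_odds_ratios(a, a)$p, 1)
  b <- odds_ratio_2x2(80, 20, 50, 50)
  cmp <- compare_odds_ratios(a, b)
  x2 <- (a$log_or - b$log_or)^2 / (a$se_log_or^2 + b$se_log_or^2)
  expect_equal(cmp$chisq, x2)
  expect_equal(cmp$p, pchisq(x2, 1, lower.tail = FALSE))
})

test_that("Welch t matches the textbook formulas and is antisymmetric", {
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  got <- welch_t(x, y)
  # independent textbook evaluation
  se2 <- var(x) / 4 + var(y) / 4
  t_ref <- (mean(x) - mean(y)) / sqrt(se2)
  df_ref <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  expect_equal(got$t, t_ref)
  expect_equal(got$df, df_ref)
  expect_equal(got$p, 2 * pt(-abs(t_ref), df_ref))

  expect_equal(welch_t(x, x)$t, 0)
  expect_equal(welch_t(x, x)$p, 1)
  swapped <- welch_t(y, x)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)
  expect_error(welch_t(c(1, 1), y), "positive variance")
})

test_that("column-wise Welch agrees with the scalar kernel", {
  set.seed(41)
  mat <- matrix(rnorm(80 * 6), 80, 6)
  mat[sample(length(mat), 40)] <- NA
  grp <- rbinom(80, 1, 0.5)
  res <- metaboprs:::welch_t_cols(mat, grp == 1)
  for (j in 1:6) {
    ref <- welch_t(mat[grp == 1, j], mat[grp == 0, j])
    expect_equal(res$t[j], ref$t)
    expect_equal(res$df[j], ref$df)
    expect_equal(res$p[j], ref$p)
  }
})
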
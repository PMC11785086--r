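test_that("MRS betas recover a planted single-metabolite effect", {
  set.seed(71)
  n <- 50000; p <- 8
  z <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("met_%03d", 1:p)))
  status <- rbinom(n, 1, plogis(-3.2 + 0.5 * z[, 3]))
  m <- fit_mrs(z, status, seed = 1)
  betas <- m$betas[-1]
  expect_lt(abs(betas[["met_003"]] - 0.5), 0.1)
  expect_true(all(abs(betas[setdiff(names(betas), "met_003")]) < 0.1))
  # oracle: full-data maximum-likelihood fit agrees with the fold mean
  full <- glm.fit(cbind(1, z), status, family = binomial())
  expect_lt(max(abs(m$betas - full$coefficients)), 0.1)
  expect_length(m$ridge_folds, 0)
})

test_that("MRS betas are stable across fold seeds", {
  set.seed(72)
  n <- 20000; p <- 6
  z <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("m%02d", 1:p)))
  status <- rbinom(n, 1, plogis(-3 + 0.3 * z[, 1]))
  m1 <- fit_mrs(z, status, seed = 1)
  m2 <- fit_mrs(z, status, seed = 2)
  expect_lt(max(abs(m1$betas - m2$betas)), 0.05)
})

test_that("MRS scoring is a plain weighted sum", {
  set.seed(73)
  z <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  status <- rbinom(200, 1, 0.3)
  m <- fit_mrs(z, status, seed = 1)

  zero <- m; zero$betas[] <- 0
  expect_equal(as.numeric(score_mrs(zero, z)), rep(0, 200))

  onehot <- m; onehot$betas[] <- 0; onehot$betas["m2"] <- 1
  expect_equal(as.numeric(score_mrs(onehot, z)), unname(z[, "m2"]))

  # brute-force dot products
  sc <- score_mrs(m, z, mode = "full_fit")
  ref <- apply(z, 1, function(r) sum(r * m$betas[colnames(z)]))
  expect_equal(as.numeric(sc), unname(ref), tolerance = 1e-12)

  # out-of-fold scoring uses the held-out fold's betas
  oof <- score_mrs(m, z, mode = "out_of_fold")
  i <- which(m$foldid == 2)[1]
  expect_equal(as.numeric(oof)[i],
               sum(z[i, ] * m$fold_betas[colnames(z), 2]))
  expect_error(score_mrs(m, z[, 1:3]), "match")
})

test_that("the resilience sum is the plain probit-score sum", {
  set.seed(74)
  pm <- matrix(rnorm(50 * 4), 50, 4,
               dimnames = list(NULL, c("Lactate", "Pyruvate", "Citrate",
                                       "Alanine")))
  s <- resilience_sum(pm)
  expect_equal(as.numeric(s), unname(rowSums(pm[, 1:3])))
  expect_equal(as.numeric(resilience_sum(pm, "Lactate")),
               unname(pm[, "Lactate"]))
  mirrored <- cbind(a = pm[, 1], b = -pm[, 1])
  expect_equal(as.numeric(resilience_sum(mirrored, c("a", "b"))),
               rep(0, 50))
  expect_error(resilience_sum(pm, c("Lactate", "Unknown")), "Unknown")
})

test_that("interaction_test matches the glm formula interface", {
  cfg <- small_config(n = 8000, seed = 75, gamma_interaction = -0.3)
  co <- impute_cohort(generate_cohort(cfg))
  pm <- probit_matrix(co)
  rs <- resilience_sum(pm)
  got <- interaction_test(co, rs)

  df <- data.frame(status = co$status, prs = co$prs, score = as.numeric(rs),
                   age = co$age, age_sq = co$age^2, sex = co$sex,
                   ethnicity = co$ethnicity, season = co$season,
                   ct = co$collection_time,
                   fasting_cat = cut(co$fasting_hours, c(-Inf, 4, 8, Inf)),
                   smoking = co$smoking, alcohol = co$alcohol,
                   caffeine = co$caffeine, activity = co$activity,
                   bmi = co$bmi, sbp = co$sbp, diabetes = co$diabetes,
                   hba1c = co$hba1c, cad = co$cad, bb = co$beta_blocker,
                   os = co$oral_steroid, sph_eq = co$sph_eq)
  ref <- glm(status ~ . - prs - score + prs * score, family = binomial(),
             data = df)
  sm <- summary(ref)$coefficients["prs:score", ]
  expect_equal(got$coefficient, unname(sm["Estimate"]), tolerance = 1e-6)
  expect_equal(got$wald_p, unname(sm["Pr(>|z|)"]), tolerance = 1e-6)
})

test_that("a planted negative interaction is detected with the right sign", {
  signs <- vapply(1:5, function(s) {
    cfg <- small_config(n = 20000, seed = 700 + s,
                        gamma_interaction = -0.3)
    co <- impute_cohort(generate_cohort(cfg))
    rs <- resilience_sum(probit_matrix(co))
    interaction_test(co, rs)$coefficient
  }, numeric(1))
  expect_true(all(signs < 0))
})

test_that("degenerate scores are rejected", {
  co <- impute_cohort(generate_cohort(small_config(n = 1000, seed = 76)))
  expect_error(interaction_test(co, rep(0, nrow(co))), "zero variance")
})

test_that("the OR grid reproduces closed-form values on fixed counts", {
  # hand-built cohort: status depends deterministically on cell counts
  lv <- c("Q1", "Q2", "Q3", "Q4")
  cells <- expand.grid(p = 1:4, s = 1:4)
  cases <- matrix(c(10, 12, 14, 16,
                    20, 18, 16, 14,
                    30, 24, 18, 12,
                    40, 30, 20, 10), 4, 4, byrow = TRUE)
  total <- 100
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    i <- cells$p[k]; j <- cells$s[k]
    data.frame(prs = i + (seq_len(total) - 1) / (4 * total),
               score = j + (seq_len(total) - 1) / (4 * total),
               status = rep(c(1L, 0L), c(cases[i, j], total - cases[i, j])))
  }))
  co <- generate_cohort(small_config(n = nrow(rows), seed = 77,
                                     missing_rate = 0))
  co$prs <- rows$prs; co$status <- rows$status
  co <- impute_cohort(co)

  tab <- build_interaction_table(co, rows$score, "within_prs_quartile")
  g <- tab$grid
  expect_equal(sum(g$total), nrow(rows))
  expect_true(all(g$or[g$reference] == 1))
  for (i in 1:4) for (j in 2:4) {
    got <- g$or[g$prs_q == lv[i] & g$score_q == lv[j]]
    ref <- (cases[i, j] * (total - cases[i, 1])) /
      ((total - cases[i, j]) * cases[i, 1])
    expect_equal(got, ref, tolerance = 1e-12)
  }

  tabg <- build_interaction_table(co, rows$score, "global_q1q1")
  gg <- tabg$grid
  expect_equal(sum(gg$reference), 1)
  got <- gg$or[gg$prs_q == "Q4" & gg$score_q == "Q4"]
  ref <- (cases[4, 4] * (total - cases[1, 1])) /
    ((total - cases[4, 4]) * cases[1, 1])
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("null scores give ORs whose intervals usually cover 1", {
  cfg <- null_config(n = 20000, seed = 78, beta_prs = 1.02)
  co <- impute_cohort(generate_cohort(cfg))
  set.seed(1)
  noise <- rnorm(nrow(co))
  tab <- build_interaction_table(co, noise, "within_prs_quartile")
  g <- tab$grid[!tab$grid$reference, ]
  expect_true(mean(g$ci_low <= 1 & g$ci_high >= 1) >= 10 / 12)
  expect_gt(tab$interaction_p, 0.001)
})

test_that("three-way age interaction behaves and validates", {
  cfg <- small_config(n = 30000, seed = 79, gamma_interaction = -0.2)
  co <- impute_cohort(generate_cohort(cfg))
  pm <- probit_matrix(co)
  st <- stratify_by_prs(co)
  rs <- resilience_sum(pm)
  got <- three_way_age_interaction(co, rs, st$top10)
  expect_true(got$wald_p >= 0 && got$wald_p <= 1)
  expect_equal(got$age_cut, median(co$age[st$top10]))
  # age split at the median balances the strata
  ages <- co$age[st$top10]
  expect_lte(abs(sum(ages >= got$age_cut) - sum(ages < got$age_cut)),
             ceiling(0.1 * length(ages)))
  co2 <- co; co2$age <- 50
  expect_error(three_way_age_interaction(co2, rs, st$top10), "degenerate")
})
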
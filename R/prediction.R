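#' Fit one nested penalized prediction model
#'
#' Fits an L1-penalized logistic regression for one covariate tier and
#' metabolite set: the cohort is split 80/20 stratified by case status with
#' a seeded shuffle, the penalty weight is selected on the training split by
#' 5-fold cross-validated binomial deviance over a log-spaced grid, the
#' model is refit at the selected weight on the full training split, and the
#' held-out 20% provides the reported ROC/AUC. L1 penalization zeroes
#' redundant coefficients, handling the strong collinearity of the
#' metabolite panel. The held-out rows never influence the penalty
#' selection or the coefficients.
#'
#' @param table a cohort data.frame (imputed internally if needed).
#' @param tier covariate tier 1..4 (see [build_design()]).
#' @param metabolite_set `"none"`, `"certified27"` or `"full168"`.
#' @param seed integer controlling the split and fold assignment.
#' @param train_fraction fraction used for training (default 0.8).
#' @param folds cross-validation folds inside the training split.
#' @param nlambda size of the log-spaced penalty grid (>= 50).
#' @param standardize passed to glmnet; FALSE keeps covariates on their
#'   native scales (metabolites are already probit-scored).
#' @return List of class `prediction_model` with coefficients, selected
#'   `penalty_weight`, held-out indices/scores and `heldout_auc`.
#' @export
fit_prediction_model <- function(table, tier, metabolite_set, seed = 1L,
                                 train_fraction = 0.8, folds = 5L,
                                 nlambda = 100L, standardize = FALSE) {
  stopifnot(nlambda >= 50, train_fraction > 0, train_fraction < 1)
  table <- impute_cohort(table)
  x <- build_design(table, tier, metabolite_set)
  y <- table$status
  n <- length(y)

  set.seed(seed)
  train <- stratified_split(y, train_fraction)
  if (length(unique(y[train])) < 2 || length(unique(y[-train])) < 2)
    stop("a class is absent from the train or test split")

  foldid <- NULL
  for (attempt in seq_len(10L)) {
    foldid <- stratified_folds(y[train], folds)
    ok <- all(vapply(seq_len(folds), function(k)
      length(unique(y[train][foldid != k])) == 2L, logical(1)))
    if (ok) break
    if (attempt == 10L) stop("could not form folds with both classes")
  }

  cv <- glmnet::cv.glmnet(x[train, , drop = FALSE], y[train],
                          family = "binomial", alpha = 1,
                          foldid = foldid, nlambda = nlambda,
                          type.measure = "deviance",
                          standardize = standardize,
                          thresh = 1e-8)
  lam <- cv$lambda.min
  beta <- as.matrix(stats::coef(cv, s = lam))[, 1]
  scores <- as.numeric(stats::predict(cv, newx = x[-train, , drop = FALSE],
                                      s = lam, type = "link"))
  structure(list(
    tier = as.integer(tier), metabolite_set = metabolite_set,
    coefficients = beta, penalty_weight = lam,
    train_fraction = train_fraction, folds = as.integer(folds),
    seed = as.integer(seed), n = n,
    train_idx = train, test_idx = setdiff(seq_len(n), train),
    heldout_scores = scores, heldout_labels = y[-train],
    heldout_auc = auc_mann_whitney(scores, y[-train])),
    class = "prediction_model")
}

# Seeded stratified index sample: the same fraction of each class.
stratified_split <- function(y, fraction) {
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  sort(c(sample(idx1, round(length(idx1) * fraction)),
         sample(idx0, round(length(idx0) * fraction))))
}

stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    foldid[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  foldid
}

#' @exportS3Method base::print
print.prediction_model <- function(x, ...) {
  nz <- sum(x$coefficients[-1] != 0)
  cat(sprintf("<prediction_model> tier %d / %s: %d of %d coefficients kept, lambda %.4g\n",
              x$tier, x$metabolite_set, nz, length(x$coefficients) - 1,
              x$penalty_weight))
  print(x$heldout_auc)
  invisible(x)
}

#' Compare two prediction models by the paired DeLong test
#'
#' Both models must have been evaluated on the identical held-out rows
#' (same cohort, same split seed).
#'
#' @param a,b `prediction_model` objects.
#' @return List of class `model_comparison`: `auc_a`, `auc_b`, `delong_z`,
#'   `delong_p`.
#' @export
compare_models <- function(a, b) {
  stopifnot(inherits(a, "prediction_model"), inherits(b, "prediction_model"))
  if (!identical(a$test_idx, b$test_idx) ||
      !identical(a$heldout_labels, b$heldout_labels))
    stop("models were evaluated on different held-out sets")
  d <- delong_test(a$heldout_scores, b$heldout_scores, a$heldout_labels)
  structure(list(auc_a = d$auc_a, auc_b = d$auc_b,
                 delong_z = d$z, delong_p = d$p),
            class = "model_comparison")
}

#' Stratified held-out AUC with and without metabolites
#'
#' Fits the chosen tier twice under the same seeded split -- once with the
#' metabolite panel, once without -- and compares their held-out AUCs within
#' demographic strata: each ethnicity level, age below vs at-or-above 55
#' years, and sex. Strata whose held-out subset lacks a class are flagged
#' and skipped.
#'
#' @param table a cohort data.frame.
#' @param tier covariate tier (default 3: full covariates, no PRS).
#' @param metabolite_set panel used for the with-metabolites model.
#' @param seed split seed shared by both fits.
#' @return data.frame with one row per stratum: sizes, the two AUCs, the
#'   DeLong p, and a `skipped` flag.
#' @export
stratified_auc <- function(table, tier = 3L, metabolite_set = "full168",
                           seed = 1L) {
  table <- impute_cohort(table)
  with_m <- fit_prediction_model(table, tier, metabolite_set, seed = seed)
  without <- fit_prediction_model(table, tier, "none", seed = seed)
  stopifnot(identical(with_m$test_idx, without$test_idx))

  test <- with_m$test_idx
  labels <- with_m$heldout_labels
  strata <- c(
    stats::setNames(lapply(levels(table$ethnicity), function(l)
      table$ethnicity[test] == l), paste0("ethnicity:", levels(table$ethnicity))),
    list("age:<55" = table$age[test] < 55,
         "age:>=55" = table$age[test] >= 55,
         "sex:male" = table$sex[test] == "male",
         "sex:female" = table$sex[test] == "female"))

  rows <- lapply(names(strata), function(nm) {
    sel <- which(strata[[nm]])
    out <- data.frame(stratum = nm, n = length(sel),
                      cases = sum(labels[sel] == 1),
                      auc_without = NA_real_, auc_with = NA_real_,
                      delong_p = NA_real_, skipped = TRUE)
    if (length(sel) >= 2 && length(unique(labels[sel])) == 2) {
      d <- delong_test(with_m$heldout_scores[sel],
                       without$heldout_scores[sel], labels[sel])
      out$auc_with <- d$auc_a; out$auc_without <- d$auc_b
      out$delong_p <- d$p; out$skipped <- FALSE
    }
    out
  })
  do.call(rbind, rows)
}
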
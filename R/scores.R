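#' Fit the metabolite risk score (MRS) model
#'
#' Fits an unpenalized maximum-likelihood logistic regression of case
#' status on all panel probit scores within each of `folds` seeded
#' stratified folds' training portions. The exported betas are the
#' element-wise mean of the fold-wise coefficient vectors; the fold-wise
#' betas and fold assignment are retained so participants can be scored
#' out-of-fold (each scored with the betas of the fold that held them
#' out). On separation or non-convergence a fold falls back to an almost
#' unpenalized ridge fit (penalty 1e-6) and is flagged.
#'
#' @param probit a complete [probit_matrix()].
#' @param status binary case vector.
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return List of class `mrs_model`: `betas` (named, incl. intercept),
#'   `fold_betas`, `foldid`, `folds`, `seed`, `ridge_folds`.
#' @export
fit_mrs <- function(probit, status, folds = 5L, seed = 1L) {
  if (anyNA(probit)) stop("probit matrix has missing cells; impute first")
  n <- nrow(probit)
  stopifnot(length(status) == n, all(status %in% 0:1))
  set.seed(seed)
  foldid <- stratified_folds(status, folds)
  x <- cbind(`(Intercept)` = 1, probit)
  fold_betas <- matrix(NA_real_, ncol(x), folds,
                       dimnames = list(colnames(x), NULL))
  ridge_folds <- integer(0)
  for (k in seq_len(folds)) {
    tr <- foldid != k
    if (length(unique(status[tr])) < 2)
      stop("a class is absent from a training fold")
    fit <- suppressWarnings(
      stats::glm.fit(x[tr, , drop = FALSE], status[tr],
                     family = stats::binomial(),
                     control = list(epsilon = 1e-8, maxit = 100)))
    if (!fit$converged || any(!is.finite(fit$coefficients))) {
      rf <- glmnet::glmnet(x[tr, -1, drop = FALSE], status[tr],
                           family = "binomial", alpha = 0,
                           lambda = 1e-6, standardize = FALSE)
      fold_betas[, k] <- as.matrix(stats::coef(rf))[, 1]
      ridge_folds <- c(ridge_folds, k)
    } else {
      fold_betas[, k] <- fit$coefficients
    }
  }
  structure(list(betas = rowMeans(fold_betas), fold_betas = fold_betas,
                 foldid = foldid, folds = as.integer(folds),
                 seed = as.integer(seed), ridge_folds = ridge_folds),
            class = "mrs_model")
}

#' Score participants with an MRS model
#'
#' The MRS of participant i is the weighted sum over metabolites of beta_j
#' times the probit score (the intercept is excluded). `full_fit` uses the
#' exported mean betas for everyone; `out_of_fold` scores each participant
#' with the betas of the fold in which they were held out, which is the
#' unbiased choice for downstream inference on the same cohort.
#'
#' @param model an [fit_mrs()] result.
#' @param probit probit matrix with the model's metabolite columns.
#' @param mode `"full_fit"` or `"out_of_fold"`.
#' @return Numeric score vector of class `score_vector` with attributes
#'   `kind` and `provenance`.
#' @export
score_mrs <- function(model, probit, mode = c("full_fit", "out_of_fold")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "mrs_model"))
  mets <- setdiff(names(model$betas), "(Intercept)")
  if (!all(mets %in% colnames(probit)))
    stop("probit matrix does not match the model's metabolite panel")
  xm <- probit[, mets, drop = FALSE]
  if (mode == "full_fit") {
    v <- drop(xm %*% model$betas[mets])
  } else {
    if (nrow(xm) != length(model$foldid))
      stop("out_of_fold scoring requires the fitting cohort")
    v <- numeric(nrow(xm))
    for (k in seq_len(model$folds)) {
      i <- model$foldid == k
      v[i] <- drop(xm[i, , drop = FALSE] %*% model$fold_betas[mets, k])
    }
  }
  structure(v, kind = "mrs", provenance = mode, class = "score_vector")
}

#' Resilience-metabolite probit sum
#'
#' Per-participant sum of the probit scores of the configured resilience
#' metabolites (by default the glycolysis/TCA trio: lactate, pyruvate,
#' citrate).
#'
#' @param probit a probit matrix.
#' @param members metabolite names to sum.
#' @return Numeric vector of class `score_vector`.
#' @export
resilience_sum <- function(probit,
                           members = c("Lactate", "Pyruvate", "Citrate")) {
  miss <- setdiff(members, colnames(probit))
  if (length(miss)) stop("unknown panel member(s): ",
                         paste(miss, collapse = ", "))
  structure(rowSums(probit[, members, drop = FALSE]),
            kind = "resilience_sum", provenance = "full_fit",
            class = "score_vector")
}

#' Test the PRS x score interaction
#'
#' Maximum-likelihood logistic fit of
#' `status ~ PRS * score + covariates` (the product term in addition to
#' both main effects); returns the Wald two-sided p-value and estimate of
#' the product term.
#'
#' @param table an imputed cohort data.frame.
#' @param score a per-participant score vector.
#' @param covariate_design optional covariate matrix with intercept
#'   (default [residual_design()] of the table).
#' @return List: `wald_p`, `coefficient`, `se`, `z`.
#' @export
interaction_test <- function(table, score, covariate_design = NULL) {
  if (is.null(covariate_design)) covariate_design <- residual_design(table)
  score <- as.numeric(score)
  if (stats::sd(score) == 0) stop("degenerate score: zero variance")
  x <- cbind(covariate_design, prs = table$prs, score = score,
             `prs:score` = table$prs * score)
  fit <- stats::glm.fit(x, table$status, family = stats::binomial(),
                        control = list(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("interaction model did not converge (deviance ",
                           round(fit$deviance, 2), ")")
  k <- ncol(x)
  if (is.na(fit$coefficients[k])) stop("interaction term is collinear")
  # Wald SE from the unscaled covariance of the IRLS working fit
  cov_u <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                              drop = FALSE])
  ord <- fit$qr$pivot[seq_len(fit$rank)]
  pos <- match(k, ord)
  if (is.na(pos)) stop("interaction term was dropped as collinear")
  se <- sqrt(cov_u[pos, pos])
  est <- unname(fit$coefficients[k])
  z <- est / se
  list(wald_p = 2 * stats::pnorm(-abs(z)), coefficient = est,
       se = se, z = z)
}

#' Quartile cross-classified odds-ratio grid
#'
#' Bins PRS and the score independently into quartiles and computes, for
#' each of the 16 cells, the glaucoma odds ratio against the declared
#' reference: the same-PRS-quartile score-Q1 cell
#' (`within_prs_quartile`), or the global (PRS Q1, score Q1) cell
#' (`global_q1q1`). Reference cells carry OR exactly 1 and no CI. The
#' continuous interaction p-value from [interaction_test()] is attached.
#'
#' @param table an imputed cohort data.frame.
#' @param score a per-participant score vector.
#' @param reference_mode `"within_prs_quartile"` or `"global_q1q1"`.
#' @param covariate_design optional covariate matrix for the interaction
#'   test.
#' @return List of class `interaction_table`: `grid` (data.frame of 16
#'   rows: quartiles, counts, OR, CI, p, reference flag), `cutpoints`,
#'   `interaction_p`, `reference_mode`.
#' @export
build_interaction_table <- function(table, score,
                                    reference_mode = c("within_prs_quartile",
                                                       "global_q1q1"),
                                    covariate_design = NULL) {
  reference_mode <- match.arg(reference_mode)
  qp <- quartile_bin(table$prs, "prs")
  qs <- quartile_bin(as.numeric(score), "score")
  lv <- c("Q1", "Q2", "Q3", "Q4")

  cases <- table(qp$labels, qs$labels, table$status)[, , "1"]
  totals <- table(qp$labels, qs$labels)
  noncases <- totals - cases

  grid <- expand.grid(prs_q = lv, score_q = lv, stringsAsFactors = FALSE)
  grid$cases <- mapply(function(i, j) cases[i, j], grid$prs_q, grid$score_q)
  grid$total <- mapply(function(i, j) totals[i, j], grid$prs_q, grid$score_q)
  grid$or <- NA_real_; grid$ci_low <- NA_real_; grid$ci_high <- NA_real_
  grid$p <- NA_real_; grid$reference <- FALSE; grid$corrected <- FALSE

  for (r in seq_len(nrow(grid))) {
    i <- grid$prs_q[r]; j <- grid$score_q[r]
    ref <- if (reference_mode == "within_prs_quartile") c(i, "Q1")
           else c("Q1", "Q1")
    if (identical(c(i, j), ref)) {
      grid$or[r] <- 1; grid$reference[r] <- TRUE
      next
    }
    cell <- odds_ratio_2x2(cases[i, j], noncases[i, j],
                           cases[ref[1], ref[2]], noncases[ref[1], ref[2]])
    grid$or[r] <- cell$or_value
    grid$ci_low[r] <- cell$ci_low; grid$ci_high[r] <- cell$ci_high
    grid$p[r] <- cell$p; grid$corrected[r] <- cell$corrected
  }
  it <- interaction_test(table, score, covariate_design)
  structure(list(grid = grid,
                 cutpoints = list(prs = qp$cutpoints, score = qs$cutpoints),
                 interaction_p = it$wald_p,
                 interaction_coefficient = it$coefficient,
                 reference_mode = reference_mode),
            class = "interaction_table")
}

#' @exportS3Method base::print
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table> reference: %s, interaction p = %.3g\n",
              x$reference_mode, x$interaction_p))
  print(x$grid, digits = 3)
  invisible(x)
}

#' Three-way age x score x PRS interaction in the top PRS decile
#'
#' Within the supplied high-PRS stratum, fits a logistic model with binary
#' age (at or above the cut, default the stratum median), the score, the
#' PRS, all two-way products, the three-way product and the covariates,
#' and returns the Wald p of the three-way term.
#'
#' @param table an imputed cohort data.frame.
#' @param score a per-participant score vector (full cohort length).
#' @param stratum_rows row indices of the high-PRS stratum.
#' @param age_cut dichotomization age (default stratum median).
#' @param covariate_design optional covariate matrix with intercept.
#' @return List: `wald_p`, `coefficient`, `age_cut`.
#' @export
three_way_age_interaction <- function(table, score, stratum_rows,
                                      age_cut = NULL,
                                      covariate_design = NULL) {
  tab <- table[stratum_rows, , drop = FALSE]
  sc <- as.numeric(score)[stratum_rows]
  if (is.null(age_cut)) age_cut <- stats::median(tab$age)
  agehi <- as.numeric(tab$age >= age_cut)
  if (stats::sd(agehi) == 0) stop("degenerate age split: one stratum empty")
  for (g in c(0, 1))
    if (length(unique(tab$status[agehi == g])) < 2)
      stop("an age stratum lacks cases or non-cases")
  if (is.null(covariate_design)) {
    cd <- residual_design(tab)
    # age enters as the binary split here; drop the continuous terms
    cd <- cd[, setdiff(colnames(cd), c("age", "age_sq")), drop = FALSE]
  } else cd <- covariate_design[stratum_rows, , drop = FALSE]
  x <- cbind(cd, age_hi = agehi, score = sc, prs = tab$prs,
             `age:score` = agehi * sc, `age:prs` = agehi * tab$prs,
             `score:prs` = sc * tab$prs,
             `age:score:prs` = agehi * sc * tab$prs)
  fit <- stats::glm.fit(x, tab$status, family = stats::binomial(),
                        control = list(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("three-way interaction model did not converge")
  k <- ncol(x)
  cov_u <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                              drop = FALSE])
  ord <- fit$qr$pivot[seq_len(fit$rank)]
  pos <- match(k, ord)
  if (is.na(pos)) stop("three-way term was dropped as collinear")
  se <- sqrt(cov_u[pos, pos])
  z <- fit$coefficients[k] / se
  list(wald_p = 2 * stats::pnorm(-abs(z)),
       coefficient = unname(fit$coefficients[k]), age_cut = age_cut)
}
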
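#' Rank-based probit transform
#'
#' Maps the non-missing entries of a vector onto standard-normal quantiles
#' through their ranks: entry with rank \eqn{r} among \eqn{m} non-missing
#' values (ties averaged) becomes \eqn{\Phi^{-1}((r - 0.5)/m)}. The result
#' has mean ~0 and SD ~1 whatever the input distribution, removing skew
#' while preserving order. Missing entries stay missing.
#'
#' @param x numeric vector, possibly with NA.
#' @return Numeric vector of probit scores, NA where `x` is NA.
#' @export
probit_transform <- function(x) {
  obs <- !is.na(x)
  v <- x[obs]
  if (length(unique(v)) < 2)
    stop("probit transform undefined for a constant column")
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[obs] <- stats::qnorm((r - 0.5) / length(v))
  out
}

#' Probit-score matrix of a cohort's metabolites
#'
#' Applies [probit_transform()] column-wise to the metabolite panel of a
#' cohort.
#'
#' @param table a cohort data.frame.
#' @return Numeric matrix of probit scores with the panel attached as the
#'   `panel` attribute and per-column non-missing counts as `n_nonmissing`.
#' @export
probit_matrix <- function(table) {
  m <- metabolite_matrix(table)
  out <- apply(m, 2, probit_transform)
  dimnames(out) <- dimnames(m)
  attr(out, "panel") <- cohort_panel(table)
  attr(out, "n_nonmissing") <- colSums(!is.na(m))
  out
}

col_mode <- function(x) {
  tab <- table(x)                       # table() follows level order,
  names(tab)[which.max(tab)]            # so ties break on the first level
}

#' Median/mode imputation
#'
#' Replaces missing numeric cells by the column median of the observed
#' values and missing factor cells by the most frequent level (ties broken
#' by schema level order). Status and PRS are required complete on input.
#'
#' @param table a cohort data.frame.
#' @return The imputed cohort; no cell remains missing.
#' @export
impute_cohort <- function(table) {
  for (cl in setdiff(names(table), c("participant_id", "status", "prs"))) {
    x <- table[[cl]]
    if (!anyNA(x)) next
    if (all(is.na(x))) stop("column '", cl, "' is fully missing")
    if (is.factor(x)) {
      x[is.na(x)] <- col_mode(x)
    } else {
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    }
    table[[cl]] <- x
  }
  table
}

#' Quartile binning
#'
#' Assigns Q1..Q4 by the empirical 25/50/75th percentiles (linear
#' interpolation): Q1 if `v <= c1`, Q2 if `c1 < v <= c2`, Q3 if
#' `c2 < v <= c3`, else Q4.
#'
#' @param values numeric vector (>= 4 non-missing values).
#' @param source label recorded for provenance.
#' @return List with `labels` (factor Q1..Q4, NA where the input is NA),
#'   `cutpoints` (length 3) and `source`.
#' @export
quartile_bin <- function(values, source = deparse(substitute(values))) {
  obs <- values[!is.na(values)]
  if (length(obs) < 4) stop("need at least 4 non-missing values")
  if (length(unique(obs)) == 1) stop("quartiles undefined for constant values")
  cp <- stats::quantile(obs, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  lab <- cut(values, breaks = c(-Inf, cp, Inf),
             labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  list(labels = lab, cutpoints = cp, source = source)
}

# Dummy-coded covariate columns for a tier (reference level dropped).
tier_covariates <- function(tier) {
  t2 <- c("age", "sex", "ethnicity", "season", "collection_time",
          "fasting_hours")
  t3 <- c("smoking", "alcohol", "caffeine", "activity", "bmi", "sbp",
          "diabetes", "hba1c", "cad", "beta_blocker", "oral_steroid",
          "sph_eq")
  switch(tier, character(0), t2, c(t2, t3), c(t2, t3))
}

#' Design matrix for the nested prediction models
#'
#' Builds the model matrix for one of the four nested tiers: tier 1 holds
#' metabolite probit scores only; tier 2 adds demographic covariates (age,
#' sex, ethnicity, season, collection time, fasting hours); tier 3 adds the
#' clinical covariates (smoking, alcohol, caffeine, physical activity, BMI,
#' systolic BP, diabetes, HbA1c, coronary artery disease, beta-blocker use,
#' oral steroid use, spherical equivalent); tier 4 adds the PRS. Factors
#' are dummy-coded against their first schema level.
#'
#' @param table an imputed cohort data.frame.
#' @param tier integer 1..4.
#' @param metabolite_set `"none"`, `"certified27"` or `"full168"`.
#' @param probit optional precomputed [probit_matrix()] (recomputed
#'   otherwise).
#' @return Numeric model matrix without an intercept column (the fitters
#'   add their own); metabolite columns come first.
#' @export
build_design <- function(table, tier,
                         metabolite_set = c("none", "certified27", "full168"),
                         probit = NULL) {
  metabolite_set <- match.arg(metabolite_set)
  tier <- as.integer(tier)
  stopifnot(tier %in% 1:4)
  if (tier == 1 && metabolite_set == "none")
    stop("tier 1 with no metabolites gives an empty design")

  blocks <- list()
  if (metabolite_set != "none") {
    if (is.null(probit)) probit <- probit_matrix(table)
    if (anyNA(probit)) stop("probit matrix has missing cells; impute first")
    panel <- cohort_panel(table)
    keep <- if (metabolite_set == "certified27") panel$name[panel$certified]
            else panel$name
    blocks$mets <- probit[, keep, drop = FALSE]
  }
  covs <- tier_covariates(tier)
  if (length(covs)) {
    cd <- table[, covs, drop = FALSE]
    if (anyNA(cd)) stop("covariates contain missing values; impute first")
    mm <- stats::model.matrix(~ ., data = cd)
    blocks$covs <- mm[, -1, drop = FALSE]    # drop intercept
  }
  if (tier == 4) blocks$prs <- matrix(table$prs, ncol = 1,
                                      dimnames = list(NULL, "prs"))
  do.call(cbind, blocks)
}

#' Residualization design matrix
#'
#' Covariate set used when adjusting probit metabolites for their
#' determinants: age, age squared, fasting category (<=4, 5-8, 9+ hours),
#' sex, ethnicity, season, collection time, smoking, alcohol, caffeine,
#' physical activity, BMI, systolic BP, diabetes, HbA1c, coronary artery
#' disease, beta-blocker use, oral steroid use and spherical equivalent.
#' Includes an intercept column.
#'
#' @param table an imputed cohort data.frame.
#' @return Numeric model matrix with intercept.
#' @export
residual_design <- function(table) {
  cd <- table[, c("age", "fasting_hours", "sex", "ethnicity", "season",
                  "collection_time", "smoking", "alcohol", "caffeine",
                  "activity", "bmi", "sbp", "diabetes", "hba1c", "cad",
                  "beta_blocker", "oral_steroid", "sph_eq"), drop = FALSE]
  if (anyNA(cd)) stop("covariates contain missing values; impute first")
  cd$age_sq <- cd$age^2
  cd$fasting_cat <- cut(cd$fasting_hours, breaks = c(-Inf, 4, 8, Inf),
                        labels = c("le4", "5to8", "9plus"))
  cd$fasting_hours <- NULL
  stats::model.matrix(~ ., data = cd)
}
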
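#' Residualize probit metabolites on their covariate determinants
#'
#' Regresses each probit-scored metabolite column by ordinary least squares
#' on the residualization covariate set ([residual_design()]) and returns
#' the residual matrix. Collinear design columns are dropped (with a
#' warning) via the pivoted QR. Residuals are orthogonal to every retained
#' design column.
#'
#' @param probit a complete [probit_matrix()] (impute the cohort first).
#' @param table the imputed cohort supplying the covariates.
#' @return List of class `residual_matrix`: `residuals` (n x p),
#'   `covariate_list`, `r_squared` per metabolite.
#' @export
residualize <- function(probit, table) {
  if (anyNA(probit)) stop("probit matrix has missing cells; impute first")
  x <- residual_design(table)
  stopifnot(nrow(x) == nrow(probit))
  fit <- stats::lm.fit(x, probit)
  if (fit$rank < ncol(x))
    warning("dropped ", ncol(x) - fit$rank,
            " collinear residualization column(s)")
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(probit)
  tss <- colSums(scale(probit, scale = FALSE)^2)
  structure(list(residuals = res,
                 covariate_list = colnames(x)[seq_len(fit$rank)],
                 r_squared = 1 - colSums(res^2) / tss),
            class = "residual_matrix")
}

#' Stratify a cohort by polygenic risk
#'
#' Returns the row indices of the top decile (PRS at or above the 90th
#' empirical percentile) and the bottom half (PRS at or below the median),
#' the two strata in which resilience metabolites are screened. Ties are
#' kept on the high side for the top decile and the low side for the bottom
#' half, so the strata can overlap only under extreme ties (an error).
#'
#' @param table a cohort data.frame with complete PRS.
#' @return List: `top10` and `bottom50` integer index vectors.
#' @export
stratify_by_prs <- function(table) {
  prs <- table$prs
  if (anyNA(prs)) stop("PRS must be complete")
  if (length(prs) < 20) stop("need at least 20 participants to stratify")
  q90 <- stats::quantile(prs, 0.9, names = FALSE, type = 7)
  q50 <- stats::quantile(prs, 0.5, names = FALSE, type = 7)
  top10 <- which(prs >= q90)
  bottom50 <- which(prs <= q50)
  if (length(intersect(top10, bottom50)))
    stop("degenerate PRS distribution: strata overlap")
  list(top10 = top10, bottom50 = bottom50)
}

#' Screen for resilience metabolites within a PRS stratum
#'
#' For each metabolite, compares covariate-adjusted residuals between cases
#' and non-cases inside the stratum by the Welch t-test, then corrects the
#' p-values for the panel's covariance by the effective-number-of-tests
#' rule computed on the stratum's residual matrix (components explaining
#' more than `variance_threshold` of total variance). A metabolite is
#' called `significant` at NEF-adjusted p < 0.05, `suggestive` at < 0.2,
#' otherwise `null`. A resilience metabolite shows a higher mean residual
#' in non-cases than in cases.
#'
#' @param resid a [residualize()] result.
#' @param status binary case vector for the full cohort.
#' @param stratum_rows integer row indices of the stratum.
#' @param stratum_name label stored with the result.
#' @param variance_threshold eigen component threshold (default 0.01).
#' @return data.frame of class `resilience_result` with one row per
#'   metabolite (means, t, raw and NEF-adjusted p, call), the NEF spectrum
#'   attached as attribute `nef`.
#' @export
discover_resilience <- function(resid, status, stratum_rows,
                                stratum_name = "stratum",
                                variance_threshold = 0.01) {
  stopifnot(inherits(resid, "residual_matrix"))
  r <- resid$residuals[stratum_rows, , drop = FALSE]
  s <- status[stratum_rows]
  if (sum(s == 1) < 10 || sum(s == 0) < 10)
    stop("stratum needs >= 10 cases and >= 10 non-cases")
  tt <- welch_t_cols(r, s == 1)
  nef <- nef_adjust(r, tt$p, variance_threshold)
  call <- ifelse(nef$adjusted_p < 0.05, "significant",
                 ifelse(nef$adjusted_p < 0.2, "suggestive", "null"))
  out <- data.frame(metabolite = colnames(r),
                    mean_residual_cases = tt$mean_1,
                    mean_residual_noncases = tt$mean_0,
                    t = tt$t, raw_p = tt$p,
                    adjusted_p_nef = nef$adjusted_p,
                    call = call, stratum = stratum_name,
                    row.names = NULL)
  attr(out, "nef") <- nef
  class(out) <- c("resilience_result", "data.frame")
  out
}
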
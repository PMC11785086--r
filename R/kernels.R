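#' @title Statistical kernels
#' @description Self-contained primitives used throughout the analysis:
#'   Mann-Whitney AUC with DeLong variance, the paired DeLong test for
#'   correlated ROC curves, the effective-number-of-tests (eigenvalue)
#'   multiple-testing correction, two-by-two odds ratios with Wald CIs, the
#'   Welch t-test, and a chi-square comparison of two odds ratios.
#' @name kernels
NULL

# DeLong structural components via midranks: O((m+n) log(m+n)).
delong_components <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels may not be NA")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  x <- scores[labels == 1L]; y <- scores[labels == 0L]
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) stop("both classes must be present")
  tz <- rank(c(x, y), ties.method = "average")
  tx <- rank(x, ties.method = "average")
  ty <- rank(y, ties.method = "average")
  auc <- (sum(tz[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc,
       v10 = (tz[seq_len(m)] - tx) / n,
       v01 = 1 - (tz[m + seq_len(n)] - ty) / m,
       m = m, n = n)
}

var0 <- function(x) if (length(x) > 1) stats::var(x) else 0
cov0 <- function(x, y) if (length(x) > 1) stats::cov(x, y) else 0

#' Mann-Whitney AUC with DeLong confidence interval
#'
#' Computes the area under the ROC curve as the scaled Mann-Whitney U
#' statistic (ties counted 1/2) and its variance from DeLong's structural
#' components, with a 95% Wald CI clipped to \[0, 1\].
#'
#' @param scores numeric predictions (higher = more case-like).
#' @param labels binary 0/1 vector; both classes must be present.
#' @return List of class `auc_result`: `auc`, `ci_low`, `ci_high`,
#'   `variance`, `n_pos`, `n_neg`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  d <- delong_components(scores, labels)
  v <- var0(d$v10) / d$m + var0(d$v01) / d$n
  z <- stats::qnorm(0.975)
  structure(list(auc = d$auc,
                 ci_low = max(0, d$auc - z * sqrt(v)),
                 ci_high = min(1, d$auc + z * sqrt(v)),
                 variance = v, n_pos = d$m, n_neg = d$n),
            class = "auc_result")
}

#' @exportS3Method base::print
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d cases / %d non-cases\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong test for two correlated ROC curves
#'
#' Tests the AUC difference of two score vectors evaluated on the same
#' participants. The variance of the difference accounts for the covariance
#' of the structural components, so the curves may be arbitrarily
#' correlated. Antisymmetric in its two score arguments.
#'
#' @param scores_a,scores_b numeric predictions on identical participants.
#' @param labels binary 0/1 vector.
#' @return List: `auc_a`, `auc_b`, `z`, `p` (two-sided), `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must have equal length")
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  vd <- (var0(da$v10) + var0(db$v10) - 2 * cov0(da$v10, db$v10)) / da$m +
        (var0(da$v01) + var0(db$v01) - 2 * cov0(da$v01, db$v01)) / da$n
  diff <- da$auc - db$auc
  if (vd <= 0) {
    z <- if (abs(diff) < .Machine$double.eps^0.5) 0 else sign(diff) * Inf
  } else z <- diff / sqrt(vd)
  list(auc_a = da$auc, auc_b = db$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), var_diff = max(vd, 0))
}

#' Effective-number-of-tests (NEF) correction
#'
#' Replaces the raw test count in a Bonferroni adjustment by the number of
#' eigen components of the biomarker correlation matrix that each explain
#' more than `variance_threshold` of the total variance. The correlation
#' matrix is computed over pairwise-complete observations; negative
#' eigenvalues (possible for pairwise-complete matrices) are clipped at 0
#' before counting, and the total variance is taken as p (the trace of a
#' correlation matrix).
#'
#' @param data_matrix n x p numeric matrix (NA allowed pairwise-complete).
#' @param raw_p numeric vector of p raw p-values.
#' @param variance_threshold fraction of total variance a component must
#'   exceed to count (default 0.01).
#' @return List of class `nef_result`: `eigenvalues` (nonincreasing),
#'   `n_effective`, `variance_captured`, `raw_p`, `adjusted_p`.
#' @export
nef_adjust <- function(data_matrix, raw_p, variance_threshold = 0.01) {
  p <- ncol(data_matrix)
  stopifnot(p >= 2, length(raw_p) == p)
  sds <- apply(data_matrix, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds)) || any(sds == 0))
    stop("zero-variance or empty column in data matrix")
  cm <- stats::cor(data_matrix, use = "pairwise.complete.obs")
  if (any(!is.finite(cm))) stop("non-finite correlation (too few complete pairs)")
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  keep <- ev / p > variance_threshold
  n_eff <- max(1L, sum(keep))
  structure(list(eigenvalues = ev, n_effective = n_eff,
                 variance_captured = if (any(keep)) sum(ev[keep]) / p
                                     else max(ev) / p,
                 raw_p = raw_p,
                 adjusted_p = pmin(1, raw_p * n_eff)),
            class = "nef_result")
}

#' Odds ratio of a 2x2 table with Wald confidence interval
#'
#' `a` counts exposed cases, `b` exposed non-cases, `c` reference cases,
#' `d` reference non-cases; OR = (a d)/(b c). If any cell is zero, the
#' Haldane-Anscombe correction adds 0.5 to every cell (flagged in the
#' result). 95% CI and two-sided p come from the Wald normal approximation
#' on the log odds ratio.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return List of class `or_cell`: `or_value`, `ci_low`, `ci_high`, `p`,
#'   `log_or`, `se_log_or`, `corrected`, `counts`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("counts must be non-negative")
  corrected <- any(counts == 0)
  w <- if (corrected) counts + 0.5 else counts
  lor <- log(w["a"]) + log(w["d"]) - log(w["b"]) - log(w["c"])
  se <- sqrt(sum(1 / w))
  z975 <- stats::qnorm(0.975)
  structure(list(or_value = unname(exp(lor)),
                 ci_low = unname(exp(lor - z975 * se)),
                 ci_high = unname(exp(lor + z975 * se)),
                 p = unname(2 * stats::pnorm(-abs(lor / se))),
                 log_or = unname(lor), se_log_or = unname(se),
                 corrected = corrected, counts = counts),
            class = "or_cell")
}

#' Chi-square comparison of two odds ratios
#'
#' 1-df Wald chi-square on the difference of two log odds ratios from
#' independent strata.
#'
#' @param cell_a,cell_b [odds_ratio_2x2()] results.
#' @return List: `chisq`, `p`.
#' @export
compare_odds_ratios <- function(cell_a, cell_b) {
  stopifnot(inherits(cell_a, "or_cell"), inherits(cell_b, "or_cell"))
  x2 <- (cell_a$log_or - cell_b$log_or)^2 /
    (cell_a$se_log_or^2 + cell_b$se_log_or^2)
  list(chisq = x2, p = stats::pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value. Thin wrapper over [stats::t.test()] returning the
#' bare triple.
#'
#' @param x,y numeric vectors, each with >= 2 values and positive variance.
#' @return List: `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2 ||
      stats::var(x) == 0 || stats::var(y) == 0)
    stop("each group needs >= 2 values with positive variance")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

# Column-wise Welch t of a matrix split by a binary group; vectorized for
# the per-metabolite loops. Agrees with welch_t() column by column.
welch_t_cols <- function(mat, grp) {
  grp <- as.logical(grp)
  m1 <- mat[grp, , drop = FALSE]; m0 <- mat[!grp, , drop = FALSE]
  n1 <- colSums(!is.na(m1)); n0 <- colSums(!is.na(m0))
  mu1 <- colMeans(m1, na.rm = TRUE); mu0 <- colMeans(m0, na.rm = TRUE)
  v1 <- apply(m1, 2, stats::var, na.rm = TRUE)
  v0 <- apply(m0, 2, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v0 / n0
  t <- (mu1 - mu0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  data.frame(mean_1 = mu1, mean_0 = mu0, t = t, df = df,
             p = 2 * stats::pt(-abs(t), df))
}
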
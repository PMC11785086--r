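round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Prevalence as a printed percentage
#'
#' 100 * cases / (cases + non-cases), rounded half-up to one decimal, the
#' convention used in the cohort characteristic tables.
#'
#' @param n_cases,n_noncases non-negative counts, not both zero.
#' @return Prevalence in percent with one decimal.
#' @export
prevalence <- function(n_cases, n_noncases) {
  if (n_cases < 0 || n_noncases < 0) stop("counts must be non-negative")
  total <- n_cases + n_noncases
  if (total == 0) stop("empty stratum")
  round_half_up(100 * n_cases / total, 1)
}

#' Case/non-case characteristic summary
#'
#' Table-1-style description of a cohort: numeric covariates as mean (SD)
#' and median \[IQR\], factors as level counts with column percentages
#' within each group. Values are summarized as observed (missing cells are
#' counted, not imputed); group-difference tests are intentionally not
#' reported.
#'
#' @param table a cohort data.frame.
#' @return data.frame with columns `variable`, `level`, `statistic`,
#'   `no_glaucoma`, `glaucoma`.
#' @export
summarize_characteristics <- function(table) {
  grp <- list(no_glaucoma = table$status == 0, glaucoma = table$status == 1)
  rows <- list()
  add <- function(variable, level, statistic, v0, v1)
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, level = level, statistic = statistic,
      no_glaucoma = v0, glaucoma = v1, stringsAsFactors = FALSE)

  add("sample_size", "", "n (%)",
      sprintf("%d (%.1f)", sum(grp$no_glaucoma),
              prevalence(sum(grp$no_glaucoma), sum(grp$glaucoma))),
      sprintf("%d (%.1f)", sum(grp$glaucoma),
              prevalence(sum(grp$glaucoma), sum(grp$no_glaucoma))))

  for (cl in intersect(covariate_names(), names(table))) {
    x <- table[[cl]]
    if (is.factor(x)) {
      for (lv in levels(x)) {
        cnt <- vapply(grp, function(g) sum(x[g] == lv, na.rm = TRUE),
                      numeric(1))
        tot <- vapply(grp, function(g) sum(!is.na(x[g])), numeric(1))
        add(cl, lv, "n (%)",
            sprintf("%d (%.1f)", cnt[1], 100 * cnt[1] / tot[1]),
            sprintf("%d (%.1f)", cnt[2], 100 * cnt[2] / tot[2]))
      }
      nmiss <- vapply(grp, function(g) sum(is.na(x[g])), numeric(1))
      if (any(nmiss > 0))
        add(cl, "<missing>", "n", as.character(nmiss[1]),
            as.character(nmiss[2]))
    } else {
      f0 <- x[grp$no_glaucoma]; f1 <- x[grp$glaucoma]
      add(cl, "", "mean (SD)",
          sprintf("%.2f (%.2f)", mean(f0, na.rm = TRUE),
                  stats::sd(f0, na.rm = TRUE)),
          sprintf("%.2f (%.2f)", mean(f1, na.rm = TRUE),
                  stats::sd(f1, na.rm = TRUE)))
      q0 <- stats::quantile(f0, c(0.25, 0.5, 0.75), na.rm = TRUE)
      q1 <- stats::quantile(f1, c(0.25, 0.5, 0.75), na.rm = TRUE)
      add(cl, "", "median [IQR]",
          sprintf("%.2f [%.2f, %.2f]", q0[2], q0[1], q0[3]),
          sprintf("%.2f [%.2f, %.2f]", q1[2], q1[1], q1[3]))
    }
  }
  do.call(rbind, rows)
}

#' Per-stratum prevalence bookkeeping
#'
#' Prevalence of cases in the full cohort and in the two PRS screening
#' strata (top decile, bottom half).
#'
#' @param table a cohort data.frame.
#' @return data.frame: stratum, n_cases, n_noncases, prevalence_pct.
#' @export
stratum_prevalences <- function(table) {
  st <- stratify_by_prs(table)
  one <- function(name, rows) {
    s <- table$status[rows]
    data.frame(stratum = name, n_cases = sum(s == 1),
               n_noncases = sum(s == 0),
               prevalence_pct = prevalence(sum(s == 1), sum(s == 0)))
  }
  rbind(one("all", seq_len(nrow(table))),
        one("top10_prs", st$top10),
        one("bottom50_prs", st$bottom50))
}
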
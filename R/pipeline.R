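#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end on one cohort: simulate (or read),
#' preprocess, fit the nested prediction models, screen for resilience
#' metabolites in the PRS strata, run the score/interaction analyses, and
#' write descriptive reports. Every artifact is a plain TSV or JSON file
#' under `out_dir`, plus a `manifest.json` recording the configuration and
#' seeds; identical configuration yields identical artifacts.
#'
#' @param config nested list (parseable from JSON/YAML) with elements:
#'   `simulate` (arguments to [sim_config()]) or `cohort` (path to a
#'   cohort file); optional `seed` (default 1), `tiers` (default 1:4),
#'   `metabolite_sets` (default none/certified27/full168),
#'   `resilience_members` (default lactate/pyruvate/citrate),
#'   `reference_mode`, `stages` (subset of simulate, predict, resilience,
#'   interact, report).
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list of the stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stages_all <- c("simulate", "predict", "resilience", "interact", "report")
  stages <- config$stages %||% stages_all
  if (!all(stages %in% stages_all)) stop("unknown stage in config")
  seed <- config$seed %||% 1L
  if (is.null(config$simulate) && is.null(config$cohort))
    stop("config needs either a 'simulate' block or a 'cohort' path",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  if (!is.null(config$simulate)) {
    sc <- do.call(sim_config, c(config$simulate, list(seed = seed)))
    cohort <- generate_cohort(sc)
    if ("simulate" %in% stages)
      write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
  } else {
    cohort <- read_cohort(config$cohort)
  }

  imputed <- impute_cohort(cohort)
  probit <- probit_matrix(imputed)

  if ("predict" %in% stages) {
    tiers <- config$tiers %||% 1:4
    sets <- config$metabolite_sets %||% c("none", "certified27", "full168")
    fits <- list()
    rows <- list()
    for (tier in tiers) for (ms in sets) {
      if (tier == 1 && ms == "none") next
      fit <- fit_prediction_model(imputed, tier, ms, seed = seed)
      fits[[paste0("tier", tier, "_", ms)]] <- fit
      rows[[length(rows) + 1]] <- data.frame(
        tier = tier, metabolite_set = ms,
        auc = fit$heldout_auc$auc, ci_low = fit$heldout_auc$ci_low,
        ci_high = fit$heldout_auc$ci_high,
        penalty_weight = fit$penalty_weight,
        nonzero_coefs = sum(fit$coefficients[-1] != 0))
    }
    auc_tab <- do.call(rbind, rows)
    data.table::fwrite(auc_tab, file.path(out_dir, "prediction_auc.tsv"),
                       sep = "\t")
    results$prediction <- list(fits = fits, auc_table = auc_tab)
  }

  if ("resilience" %in% stages) {
    strata <- stratify_by_prs(imputed)
    res <- residualize(probit, imputed)
    out <- list()
    for (nm in names(strata)) {
      d <- discover_resilience(res, imputed$status, strata[[nm]],
                               stratum_name = nm)
      d <- d[order(d$adjusted_p_nef), ]
      data.table::fwrite(d, file.path(out_dir,
                                      paste0("resilience_", nm, ".tsv")),
                         sep = "\t")
      out[[nm]] <- d
    }
    results$resilience <- out
  }

  if ("interact" %in% stages) {
    members <- config$resilience_members %||%
      c("Lactate", "Pyruvate", "Citrate")
    refmode <- config$reference_mode %||% "within_prs_quartile"
    rsum <- resilience_sum(probit, members)
    tab_sum <- build_interaction_table(imputed, rsum, refmode)
    mrs <- fit_mrs(probit, imputed$status, seed = seed)
    mrs_oof <- score_mrs(mrs, probit, mode = "out_of_fold")
    tab_mrs <- build_interaction_table(imputed, mrs_oof, refmode)
    strata <- stratify_by_prs(imputed)
    three <- three_way_age_interaction(imputed, rsum, strata$top10)
    for (nm in c("resilience_sum", "mrs")) {
      tb <- if (nm == "mrs") tab_mrs else tab_sum
      data.table::fwrite(tb$grid,
                         file.path(out_dir, paste0("or_grid_", nm, ".tsv")),
                         sep = "\t")
    }
    jsonlite::write_json(
      list(interaction_p_resilience_sum = tab_sum$interaction_p,
           interaction_p_mrs = tab_mrs$interaction_p,
           three_way_age_p = three$wald_p,
           reference_mode = refmode),
      file.path(out_dir, "interaction_stats.json"),
      auto_unbox = TRUE, digits = NA)
    results$interaction <- list(resilience_sum = tab_sum, mrs = tab_mrs,
                                three_way_age = three)
  }

  if ("report" %in% stages) {
    data.table::fwrite(summarize_characteristics(cohort),
                       file.path(out_dir, "characteristics.tsv"), sep = "\t")
    data.table::fwrite(stratum_prevalences(imputed),
                       file.path(out_dir, "prevalence.tsv"), sep = "\t")
  }

  manifest <- list(package_version = as.character(
                     utils::packageVersion("metaboprs")),
                   seed = seed, stages = stages,
                   config = config[setdiff(names(config), "stages")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
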
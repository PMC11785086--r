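#!/usr/bin/env Rscript
# Generate the study cohort at the default conditions (100,000 participants,
# 168 metabolites in 12 correlation blocks, ~4% glaucoma prevalence, PRS
# log-odds 1.02, protective PRS x glycolysis-trio interaction -0.15) and
# summarize its structure. Downstream drivers regenerate the same cohort
# from the same seed instead of reading a bulky intermediate file.

suppressMessages(library(metaboprs))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_participants = 100000L, seed = 1L)
cohort <- generate_cohort(cfg)
print(cohort)

prev <- stratum_prevalences(cohort)
print(prev)
cat(sprintf(
  "Overall prevalence %.1f%%; top PRS decile %.1f%%, bottom half %.1f%% -- the\n",
  prev$prevalence_pct[1], prev$prevalence_pct[2], prev$prevalence_pct[3]),
  "high-risk decile carries roughly a tenfold enrichment of cases.\n")

chars <- summarize_characteristics(cohort)
data.table::fwrite(chars, "results/characteristics.tsv", sep = "\t")
data.table::fwrite(prev, "results/prevalence.tsv", sep = "\t")
cat("wrote results/characteristics.tsv and results/prevalence.tsv\n")
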
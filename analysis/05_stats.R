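#!/usr/bin/env Rscript
# Stage 5 - the statistical plan.
# Verifies every number derivable from the published summary tables, then
# reproduces the result-table structure on the synthetic cohort:
# patient-vs-control comparisons with pooled-SD effect sizes, the
# ROC/Youden-derived high/low BrainAGE split, three-group comparisons with
# age-adjusted NfL, univariate risk factors, and the screened multivariate
# logistic model.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

say("-- Published-table verification --")
ver <- verify_printed_values()
print(ver, digits = 3)
stopifnot(all(ver$pass))
write.csv(ver, file.path(RESULTS, "printed_verification.csv"),
          row.names = FALSE)

man <- read_manifest(file.path(COHORT_DIR, "manifest.csv"))
scores <- read.csv(file.path(RESULTS, "scores.csv"))
volum <- read.csv(file.path(RESULTS, "volumetry.csv"))
covar_cols <- c("id", "role", "offset_delta", "log_nfl",
                cognitive_domains())
study <- Reduce(function(a, b) merge(a, b, by = "id"),
                list(man[man$role != "training", covar_cols], scores,
                     volum))
pat <- study[study$group == "patient", ]
ctl <- study[study$group == "control", ]

say("-- Patient vs control (n = %d vs %d) --", nrow(pat), nrow(ctl))
t2 <- brainager:::table2_analog(pat, ctl)
print(t2, digits = 3)
write.csv(t2, file.path(RESULTS, "table2_analog.csv"), row.names = FALSE)

say("-- ROC / Youden stratification on low reaction-time performance --")
outcome <- study$reaction_time < 80
roc <- roc_youden(study$z_score, outcome)
print(roc)
write.csv(roc$curve, file.path(RESULTS, "roc_curve.csv"), row.names = FALSE)
pat$stratum <- ifelse(pat$z_score > roc$threshold, "high", "low")
say("High/low BrainAGE split at z = %.2f: %d high, %d low",
    roc$threshold, sum(pat$stratum == "high"), sum(pat$stratum == "low"))

if (min(table(pat$stratum)) >= 2) {
  t3 <- brainager:::table3_analog(pat, ctl)
  print(t3, digits = 3)
  write.csv(t3, file.path(RESULTS, "table3_analog.csv"), row.names = FALSE)

  t4 <- brainager:::table4_analog(pat)
  print(t4, digits = 3)
  write.csv(t4, file.path(RESULTS, "table4_analog.csv"), row.names = FALSE)

  say("-- Screened multivariate logistic model (high vs low BrainAGE) --")
  covars <- pat[, c("chronological_age", "log_nfl", cognitive_domains())]
  rep5 <- screen_and_fit_logistic(covars, pat$stratum == "high")
  print(rep5)
  if (!is.null(rep5$model))
    write.csv(rep5$model, file.path(RESULTS, "table5_analog.csv"),
              row.names = FALSE)
} else {
  say("Stratum too small for three-group tables this run")
}
say("Wrote tables to %s/", RESULTS)
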
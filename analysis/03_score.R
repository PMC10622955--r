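#!/usr/bin/env Rscript
# Stage 3 - BrainAGE scoring of the study sample.
# Predicts brain age for controls and patients, fits the age-bias model on
# the controls (gap ~ chronological age), residualizes, and converts to
# control-referenced z-scores.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

man <- read_manifest(file.path(COHORT_DIR, "manifest.csv"))
study <- man[man$role != "training", ]
say("Scoring %d study subjects", nrow(study))
X <- vapply(study$volume_path,
            function(p) preprocess_volume(read_labeled_volume(p)),
            array(0, PHANTOM$grid_shape))
dim(X) <- c(prod(PHANTOM$grid_shape), nrow(study))

model <- load_age_model(file.path(RESULTS, "model.json"))
pred <- predict_age(model, X)
sc <- score_cohort(pred, study$chronological_age, study$role)

say("Age-bias model (controls): intercept %.2f, alpha %.3f",
    sc$bias$intercept, sc$bias$alpha)
pat_z <- sc$scores$z_score[study$role == "patient"]
ctl_z <- sc$scores$z_score[study$role == "control"]
say("BrainAGE z: patients %.2f (SD %.2f) vs controls %.2f (SD %.2f)",
    mean(pat_z), sd(pat_z), mean(ctl_z), sd(ctl_z))
gap_diff <- mean(sc$scores$corrected_gap[study$role == "patient"]) -
  mean(sc$scores$corrected_gap[study$role == "control"])
say("Corrected-gap difference %.2f y (injected offset averaged %.2f y)",
    gap_diff, mean(study$offset_delta[study$role == "patient"]))

write_scores(sc$scores, file.path(RESULTS, "scores.csv"), ids = study$id)
save_bias_model(sc$bias, file.path(RESULTS, "bias_model.json"))
say("Wrote scores.csv, bias_model.json to %s/", RESULTS)
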
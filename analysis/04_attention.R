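#!/usr/bin/env Rscript
# Stage 4 - occlusion-sensitivity attention maps.
# Probes the trained regressor with the sliding 8^3 mask for every study
# subject, averages the per-subject maps into the population map, and
# quantifies how strongly the attention concentrates on the aging
# morphology (ventricles + gray-matter ribbon) versus the background shell.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

man <- read_manifest(file.path(COHORT_DIR, "manifest.csv"))
study <- man[man$role != "training", ]
model <- load_age_model(file.path(RESULTS, "model.json"))

say("Computing occlusion maps for %d subjects (mask %s, stride %s)",
    nrow(study), paste(OCCLUSION$mask_size, collapse = "x"),
    paste(OCCLUSION$stride, collapse = "x"))
maps <- lapply(seq_len(nrow(study)), function(i) {
  vol <- read_labeled_volume(study$volume_path[i])
  occlusion_map(model, preprocess_volume(vol), OCCLUSION,
                subject_id = study$id[i])
})
pop <- average_maps(maps)
write_attention_map(pop, file.path(RESULTS, "attention_population.nii.gz"),
                    PHANTOM$voxel_size)

ref_spec <- PHANTOM; ref_spec$noise_sd <- 0; ref_spec$wmh_rate <- 0
ref <- generate_subject_volume(mean(study$effective_age), ref_spec,
                               seed = ROOT_SEED)
rr <- attention_region_ratio(pop, ref$labels)
say("Population attention: signal-region mean %.4f, background %.4f, ratio %.2f",
    rr$signal_mean, rr$background_mean, rr$ratio)
writeLines(jsonlite::toJSON(rr, auto_unbox = TRUE, digits = NA),
           file.path(RESULTS, "attention_summary.json"))
say("Wrote attention_population.nii.gz, attention_summary.json to %s/",
    RESULTS)
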
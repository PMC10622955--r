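# Shared fixtures. Heavy multi-seed pipeline runs are computed once per
# session and cached, because several acceptance properties (offset recovery,
# model sanity, attention localization) read the same trained pipelines.

# A fast phantom/training setup for unit tests that exercise mechanics, not
# statistical power.
tiny_phantom <- function() phantom_spec(grid_shape = c(16L, 16L, 16L),
                                        brain_semiaxes = c(6.5, 7.2, 6.5),
                                        ventricle_base_volume = 26,
                                        ventricle_growth = 0.7,
                                        gm_ribbon_base = 700,
                                        gm_thinning = 1.2,
                                        wm_outer_volume = 520)

tiny_arch <- function() architecture_spec(
  conv_blocks = data.frame(filters = c(4L, 8L), kernel = 3L, stride = 2L),
  input_shape = c(16L, 16L, 16L))

tiny_config <- function(iterations = 20L, seed = 1L, ...) {
  args <- list(iterations = iterations, seed = seed, ...)
  if (is.null(args$max_translation)) args$max_translation <- 1
  if (is.null(args$max_rotation)) args$max_rotation <- 5
  do.call(training_config, args)
}

# Preprocessed volume matrix + ages for a small healthy cohort.
tiny_training_set <- function(n = 24, seed = 7, spec = tiny_phantom()) {
  coh <- generate_cohort(cohort_spec(n_training = n, n_controls = 0,
                                     n_patients = 0, seed = seed), spec)
  X <- vapply(coh$volumes, preprocess_volume, array(0, spec$grid_shape))
  dim(X) <- c(prod(spec$grid_shape), n)
  list(X = X, ages = coh$manifest$effective_age, manifest = coh$manifest)
}

# ---- cached full-scale pipeline runs (study conditions) -------------------

.run_cache <- new.env(parent = emptyenv())

# Compact summary of one full pipeline run; volumes and maps are dropped.
.pipeline_summary <- function(report) {
  pat <- report$scores[report$scores$role == "patient", ]
  ctl <- report$scores[report$scores$role == "control", ]
  tt <- two_sample_t(pat$corrected_gap, ctl$corrected_gap)
  one_sided_p <- if (tt$statistic > 0) tt$p_value / 2 else 1 - tt$p_value / 2
  list(validation = report$validation,
       gap_diff = mean(pat$corrected_gap) - mean(ctl$corrected_gap),
       gap_one_sided_p = one_sided_p,
       z_pat_mean = mean(pat$z_score), z_ctl_mean = mean(ctl$z_score),
       z_two_sided_p = two_sample_t(pat$z_score, ctl$z_score)$p_value,
       attention_ratio = report$attention_summary$ratio,
       z_cutoff = report$z_cutoff)
}

# Study-scale runs: 200 training phantoms at 32^3, 24 controls, 70 patients
# with offset ~ N(4, 2) (signal) or exactly 0 (null). Attention is averaged
# over 16 study subjects for signal runs (the localization ratio is stable
# well below the full 94) and skipped down to 2 for null runs, which only
# feed the group-difference calibration check.
pipeline_runs <- function(kind = c("signal", "null"), seeds = 1:10) {
  kind <- match.arg(kind)
  key <- paste0(kind, "_", paste(range(seeds), collapse = "_"))
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  offs <- if (kind == "signal") c(4, 2) else c(0, 0)
  out <- lapply(seeds, function(s) {
    cfg <- run_config(
      cohort = cohort_spec(n_training = 200L, n_controls = 24L,
                           n_patients = 70L, offset_mean_sd = offs),
      n_attention = if (kind == "signal") 16 else 2, root_seed = s)
    .pipeline_summary(run_full_pipeline(cfg))
  })
  .run_cache[[key]] <- out
  out
}
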
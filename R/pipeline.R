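# End-to-end orchestration: simulate -> preprocess -> train -> predict ->
# score -> attention -> statistics, all seeded from one root seed, emitting a
# report whose tables mirror the reference study's result structure on
# synthetic data.

#' Full-run configuration
#'
#' Bundles the per-module configurations and a root seed that is propagated
#' to every module's substream.
#'
#' @param cohort A [cohort_spec()]; its `seed` is overridden by `root_seed`.
#' @param phantom A [phantom_spec()].
#' @param training A [training_config()]; its `seed` is overridden.
#' @param occlusion An [occlusion_config()].
#' @param outcome_score,outcome_cutoff Stratification outcome: the cognitive
#'   score (default reaction time) and the impairment cutoff (standardized
#'   score < 80) whose ROC/Youden analysis defines the high/low BrainAGE
#'   threshold for this run.
#' @param validation_fraction Held-out fraction of the training set used for
#'   the validation MAE.
#' @param n_attention Number of study subjects entering the population
#'   attention map (`Inf` = all).
#' @param run_cv Also run the k-fold cross-validation of the training
#'   protocol (slower).
#' @param output_dir Directory for persisted artifacts (`NULL` = in-memory
#'   only).
#' @param root_seed Integer; the only seed of the run.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), phantom = phantom_spec(),
                       training = training_config(),
                       occlusion = occlusion_config(),
                       outcome_score = "reaction_time", outcome_cutoff = 80,
                       validation_fraction = 0.2, n_attention = Inf,
                       run_cv = FALSE, output_dir = NULL, root_seed = 1L) {
  stopifnot(outcome_score %in% cognitive_domains(),
            validation_fraction > 0, validation_fraction < 1)
  cohort$seed <- as.integer(root_seed)
  training$seed <- as.integer(root_seed)
  structure(list(cohort = cohort, phantom = phantom, training = training,
                 occlusion = occlusion, outcome_score = outcome_score,
                 outcome_cutoff = outcome_cutoff,
                 validation_fraction = validation_fraction,
                 n_attention = n_attention, run_cv = isTRUE(run_cv),
                 output_dir = output_dir, root_seed = as.integer(root_seed)),
            class = "run_config")
}

#' Run the full BrainAGE pipeline
#'
#' Executes every stage in order on a synthetic cohort and returns a
#' `run_report`. The high/low BrainAGE split is re-derived per run from the
#' ROC/Youden analysis of the impaired-outcome indicator (low reaction-time
#' score), exactly as the stratification plan prescribes, rather than
#' hard-coding a cutoff. With `output_dir` set, volumes, manifests, scores,
#' the model checkpoint and the report JSON are persisted.
#'
#' @param config A [run_config()].
#' @param verbose Print per-stage progress.
#' @return Object of class `run_report`; see the elements `table2_analog`,
#'   `table3_analog`, `table4_analog`, `table5_analog`, `bias`, `roc`,
#'   `validation`, `attention_summary`, `provenance`.
#' @export
run_full_pipeline <- function(config, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()
  dir <- config$output_dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  ## stage 1: simulate
  say("[simulate] cohort (root seed %d)", config$root_seed)
  coh <- generate_cohort(config$cohort, config$phantom, dir = dir)
  man <- coh$manifest

  ## stage 2: preprocess (min-max normalization over the brain mask)
  say("[preprocess] %d volumes", nrow(man))
  nvox <- prod(config$phantom$grid_shape)
  X <- vapply(coh$volumes, preprocess_volume,
              array(0, config$phantom$grid_shape))
  dim(X) <- c(nvox, nrow(man))

  is_train <- man$role == "training"
  is_study <- !is_train
  is_ctrl <- man$role == "control"
  is_pat <- man$role == "patient"

  ## stage 3: train (with an internal held-out validation split)
  n_tr <- sum(is_train)
  idx_tr <- which(is_train)
  n_val <- max(1L, round(config$validation_fraction * n_tr))
  val_idx <- with_seed(substream_seed(config$root_seed, "folds"),
                       sample(idx_tr, n_val))
  fit_idx <- setdiff(idx_tr, val_idx)
  say("[train] %d fit / %d validation subjects", length(fit_idx), n_val)
  model <- init_age_model(architecture_spec(
    input_shape = config$phantom$grid_shape), seed = config$root_seed)
  model <- train_age_model(model, X[, fit_idx, drop = FALSE],
                           man$effective_age[fit_idx], config$training)
  val_pred <- predict_age(model, X[, val_idx, drop = FALSE])
  validation <- list(
    mae = mean(abs(val_pred - man$effective_age[val_idx])),
    r = cor(val_pred, man$effective_age[val_idx]),
    baseline_mae = mean(abs(mean(man$effective_age[fit_idx]) -
                            man$effective_age[val_idx])),
    sd_ages = sd(man$effective_age[val_idx]), n = n_val)

  cv <- NULL
  if (config$run_cv) {
    say("[crossvalidate] %d folds", config$training$folds)
    cv <- crossvalidate_age_model(X[, idx_tr, drop = FALSE],
                                  man$effective_age[idx_tr],
                                  config$training)
  }

  ## stage 4: predict + score the study sample
  say("[score] %d study subjects", sum(is_study))
  pred <- predict_age(model, X[, is_study, drop = FALSE])
  study <- man[is_study, ]
  sc <- score_cohort(pred, study$chronological_age, study$role)
  study <- cbind(study, sc$scores[, c("predicted_age", "raw_gap",
                                      "corrected_gap", "z_score")])

  ## stage 5: attention maps
  n_att <- min(config$n_attention, sum(is_study))
  att_idx <- which(is_study)[seq_len(n_att)]
  say("[attention] %d subjects", n_att)
  maps <- lapply(att_idx, function(i)
    occlusion_map(model, array(X[, i], config$phantom$grid_shape),
                  config$occlusion, subject_id = man$id[i]))
  pop_map <- average_maps(maps)
  # reference anatomy for region scoring: a mid-age control phantom, no noise
  ref_spec <- config$phantom; ref_spec$noise_sd <- 0; ref_spec$wmh_rate <- 0
  ref_vol <- generate_subject_volume(mean(study$effective_age), ref_spec,
                                     seed = config$root_seed)
  att_ratio <- attention_region_ratio(pop_map, ref_vol$labels)

  ## stage 6: statistics
  say("[stats] group comparisons + stratification")
  volum <- volumetry_table(coh$volumes[man$id[is_study]])
  study <- merge(study, volum, by = "id", sort = FALSE)
  pat <- study[study$role == "patient", ]
  ctl <- study[study$role == "control", ]

  table2 <- table2_analog(pat, ctl)

  outcome <- study[[config$outcome_score]] < config$outcome_cutoff
  roc <- if (length(unique(outcome[study$role == "patient"])) > 1)
    roc_youden(study$z_score, outcome) else NULL
  z_cut <- if (!is.null(roc)) roc$threshold else NA_real_
  pat$stratum <- ifelse(pat$z_score > z_cut, "high", "low")

  table3 <- table4 <- table5 <- NULL
  if (!is.null(roc) && length(unique(pat$stratum)) == 2 &&
      min(table(pat$stratum)) >= 2) {
    table3 <- table3_analog(pat, ctl)
    table4 <- table4_analog(pat)
    covars <- pat[, c("chronological_age", "log_nfl", cognitive_domains())]
    table5 <- screen_and_fit_logistic(covars, pat$stratum == "high")
  }

  report <- structure(list(
    manifest = man, scores = study, model = model, bias = sc$bias,
    reference = sc$reference, validation = validation, cv = cv,
    roc = roc, z_cutoff = z_cut,
    table2_analog = table2, table3_analog = table3,
    table4_analog = table4, table5_analog = table5,
    attention = pop_map, attention_summary = att_ratio,
    provenance = list(
      root_seed = config$root_seed,
      config_hash = rlang::hash(config),
      n_training = n_tr, n_controls = sum(is_ctrl),
      n_patients = sum(is_pat),
      package_version = as.character(utils::packageVersion("brainager")),
      elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  ), class = "run_report")

  if (!is.null(dir)) {
    say("[persist] %s", dir)
    write_scores(study, file.path(dir, "scores.csv"), ids = study$id)
    save_age_model(model, file.path(dir, "model.json"))
    save_bias_model(sc$bias, file.path(dir, "bias_model.json"))
    write_attention_map(pop_map, file.path(dir, "attention_population.nii.gz"),
                        config$phantom$voxel_size)
    jsonlite::write_json(report_summary(report),
                         file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

# Patient-vs-control comparison per MRI metric (z-score via t; volumetry via
# t; WMH via Mann-Whitney), with pooled-SD Cohen's d - the Table 2 shape.
table2_analog <- function(pat, ctl) {
  metrics <- c(brainage_z = "z_score", gm_pct_icv = "gm_pct",
               wm_pct_icv = "wm_pct", csf_pct_icv = "csf_pct",
               wmh_ml = "wmh_ml")
  rows <- lapply(names(metrics), function(m) {
    xp <- pat[[metrics[[m]]]]; xc <- ctl[[metrics[[m]]]]
    tst <- if (m == "wmh_ml") mann_whitney(xp, xc)
           else two_sample_t(xp, xc)
    data.frame(metric = m, n_pat = length(xp), mean_pat = mean(xp),
               sd_pat = sd(xp), n_ctl = length(xc), mean_ctl = mean(xc),
               sd_ctl = sd(xc),
               cohens_d = tryCatch(cohens_d_pooled(xp, xc),
                                   error = function(e) NA_real_),
               p_value = tst$p_value, test = tst$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# High/low/control three-group comparisons: ANOVA (or Kruskal-Wallis for
# WMH), age-adjusted ANCOVA for log-NfL - the Table 3 shape.
table3_analog <- function(pat, ctl) {
  groups3 <- function(v_pat, v_ctl) {
    list(high = v_pat[pat$stratum == "high"],
         low = v_pat[pat$stratum == "low"], control = v_ctl)
  }
  vars <- c("z_score", "gm_pct", "wm_pct", "csf_pct", "wmh_ml",
            cognitive_domains())
  rows <- lapply(vars, function(v) {
    g <- groups3(pat[[v]], ctl[[v]])
    variant <- if (v == "wmh_ml") "kruskal" else "anova"
    tst <- anova_oneway(g, variant)
    data.frame(variable = v,
               mean_high = mean(g$high), mean_low = mean(g$low),
               mean_control = mean(g$control), p_value = tst$p_value,
               test = tst$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # age-adjusted log-NfL across the three groups
  values <- c(pat$log_nfl, ctl$log_nfl)
  labels <- c(paste0("sle_", pat$stratum), rep("control", nrow(ctl)))
  ages <- c(pat$chronological_age, ctl$chronological_age)
  anc <- ancova_age_adjusted(values, labels, ages)
  out <- rbind(out, data.frame(
    variable = "log_nfl_age_adjusted",
    mean_high = anc$adjusted_means[["sle_high"]],
    mean_low = anc$adjusted_means[["sle_low"]],
    mean_control = anc$adjusted_means[["control"]],
    p_value = anc$test$p_value, test = "ancova_f",
    stringsAsFactors = FALSE))
  out
}

# High-vs-low univariate risk-factor comparisons - the Table 4 shape.
table4_analog <- function(pat) {
  vars <- c("chronological_age", "log_nfl", cognitive_domains())
  hi <- pat$stratum == "high"
  rows <- lapply(vars, function(v) {
    tst <- two_sample_t(pat[[v]][hi], pat[[v]][!hi])
    data.frame(variable = v, mean_high = mean(pat[[v]][hi]),
               mean_low = mean(pat[[v]][!hi]), p_value = tst$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Flat numeric summary for JSON export / report hashing.
report_summary <- function(report) {
  list(provenance = report$provenance,
       validation = report$validation,
       bias = unclass(report$bias),
       z_cutoff = report$z_cutoff,
       attention_summary = report$attention_summary,
       table2 = report$table2_analog,
       table3 = report$table3_analog,
       table4 = report$table4_analog,
       table5 = if (!is.null(report$table5_analog))
         report$table5_analog$model)
}

#' @export
print.run_report <- function(x, ...) {
  t2 <- x$table2_analog
  bz <- t2[t2$metric == "brainage_z", ]
  cat("<run_report> root seed", x$provenance$root_seed, "\n",
      sprintf(" validation: MAE %.2f y (baseline %.2f), r = %.3f\n",
              x$validation$mae, x$validation$baseline_mae, x$validation$r),
      sprintf(" BrainAGE z: patients %.2f (SD %.2f) vs controls %.2f (SD %.2f), d = %.2f, p = %.3g\n",
              bz$mean_pat, bz$sd_pat, bz$mean_ctl, bz$sd_ctl, bz$cohens_d,
              bz$p_value),
      sprintf(" z cutoff (Youden): %.3g; attention signal/background ratio %.2f\n",
              x$z_cutoff, x$attention_summary$ratio))
  invisible(x)
}
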
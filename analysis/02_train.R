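#!/usr/bin/env Rscript
# Stage 2 - train the 3D convolutional age regressor.
# Loads the training phantoms from stage 1, holds out 20% for validation,
# runs the published SGD/MAE protocol (lr 0.001, momentum 0.1, decay 5e-5,
# batch 8, 150 epochs, translate/rotate augmentation) plus the 5-fold
# cross-validation, and writes the model checkpoint and training log.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

man <- read_manifest(file.path(COHORT_DIR, "manifest.csv"))
tr_man <- man[man$role == "training", ]
say("Loading %d training volumes", nrow(tr_man))
X <- vapply(tr_man$volume_path,
            function(p) preprocess_volume(read_labeled_volume(p)),
            array(0, PHANTOM$grid_shape))
dim(X) <- c(prod(PHANTOM$grid_shape), nrow(tr_man))
ages <- tr_man$effective_age

n_val <- round(0.2 * length(ages))
set.seed(substream_seed(ROOT_SEED, "folds"))
val <- sample(length(ages), n_val)
model <- init_age_model(architecture_spec(input_shape = PHANTOM$grid_shape),
                        seed = ROOT_SEED)
say("Training on %d phantoms (%d held out)", length(ages) - n_val, n_val)
model <- train_age_model(model, X[, -val], ages[-val], TRAINING)

pred <- predict_age(model, X[, val])
say("Held-out: MAE %.2f y (constant-predictor baseline %.2f), r = %.3f",
    mean(abs(pred - ages[val])),
    mean(abs(mean(ages[-val]) - ages[val])), cor(pred, ages[val]))

say("5-fold cross-validation of the protocol...")
cv <- crossvalidate_age_model(X, ages, TRAINING)
say("CV MAE %.2f (SD %.2f) y across folds [%s]",
    cv$mean, cv$sd, paste(round(cv$fold_mae, 2), collapse = ", "))

save_age_model(model, file.path(RESULTS, "model.json"))
write.csv(model$training_history, file.path(RESULTS, "training_log.csv"),
          row.names = FALSE)
write.csv(data.frame(fold = seq_along(cv$fold_mae), mae = cv$fold_mae),
          file.path(RESULTS, "cv_mae.csv"), row.names = FALSE)
say("Wrote model.json, training_log.csv, cv_mae.csv to %s/", RESULTS)
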
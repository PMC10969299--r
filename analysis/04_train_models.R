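#!/usr/bin/env Rscript
# Train the five classifiers on the oxygen-metabolism feature category:
# ReliefF top-25% shortlist, wrapper selection (best-first, 10-fold CV,
# threshold 0.01), SMOTE balancing, seeded shuffle, then MLP / ABoost / RF
# plus the 1D-CNN and LSTM on the full 428-feature vector (deep models use
# the full vector; their layer layout consumes all 107 features per map).
# Deep-model epochs are reduced to desk scale here; the architecture is the
# paper-shaped one regardless.
suppressPackageStartupMessages(library(physiomap))

fx <- read_feature_table("scratch/features/oxymet.csv")
seed <- 42L

rows <- list()
models <- list()
for (kind in c("MLP", "ABoost", "RF")) {
  m <- train_pipeline(fx$features, fx$labels, model_spec(kind, seed = seed),
                      seed = seed)
  models[[kind]] <- m
  rows[[kind]] <- data.frame(model = kind,
                             n_selected = length(m$features),
                             cv_accuracy = m$cv_accuracy)
  cat(sprintf("%-7s selected %2d features, 10-fold CV accuracy %.3f\n",
              kind, length(m$features), m$cv_accuracy))
}
for (kind in c("CNN1D", "LSTM")) {
  spec <- model_spec(kind, seed = seed, epochs = 30L)
  m <- train_pipeline(fx$features, fx$labels, spec, seed = seed)
  models[[kind]] <- m
  rows[[kind]] <- data.frame(model = kind, n_selected = ncol(fx$features),
                             cv_accuracy = m$cv_accuracy)
  cat(sprintf("%-7s validation accuracy %.3f (best epoch %s)\n",
              kind, m$cv_accuracy,
              m$history$epoch[which.max(m$history$val_accuracy)]))
}

dir.create("scratch/models", showWarnings = FALSE, recursive = TRUE)
saveRDS(models, "scratch/models/oxymet_models.rds")
write.csv(do.call(rbind, rows), "results/training_summary.csv",
          row.names = FALSE)
cat("models in scratch/models/, summary in results/training_summary.csv\n")
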
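#!/usr/bin/env Rscript
# Stage 4 -- train the virtual-screening models.
#
# Random-forest scorers over ECFP4-style 1024-bit features following the
# resampled-training-set protocol (here 5 sets instead of 30, 100 trees
# instead of 2000 -- desk scale), plus the fingerprint neural network
# (two ReLU layers over ECFP6-style 2048-bit features) with
# top-100-actives checkpoint selection.

library(delscreen)

dir_ <- file.path("results", "screen")
read_smi <- function(f) {
  x <- strsplit(readLines(f), " ")
  unique(vapply(x, `[`, character(1), 1))
}
pos <- read_smi(file.path(dir_, "ptes.smi"))
neg <- read_smi(file.path(dir_, "nonhits.smi"))
message(length(pos), " positives, ", length(neg), " negatives")

sets <- build_training_sets(pos, neg, n_models = 5L,
                            n_negatives = min(1000L, length(neg)), seed = 41L)
scorers <- lapply(seq_along(sets), function(i)
  train_forest(sets[[i]], n_trees = 100L, seed = 400L + i))
accs <- vapply(scorers, function(s) s$accuracy, numeric(1))
message("forest holdout accuracies: ", paste(round(accs, 3), collapse = ", "))
best <- select_best_forest(scorers)

# fingerprint DNN on a held-out tuning split
n_tune_pos <- max(2L, round(0.2 * length(pos)))
n_tune_neg <- max(10L, round(0.05 * length(neg)))
dnn <- train_dnn(setdiff(pos, pos[1:n_tune_pos]),
                 setdiff(neg, neg[1:n_tune_neg]),
                 pos[1:n_tune_pos], neg[1:n_tune_neg],
                 layers = c(256L, 32L), steps = 2000L, batch = 64L,
                 lr = 0.05, checkpoint_every = 250L, seed = 42L)
message("DNN checkpoint at step ", dnn$meta$checkpoint_step,
        " (tuning top-100-actives = ", dnn$meta$tuning_metric, ")")

jsonlite::write_json(
  list(forest_accuracies = accs,
       selected_forest = best$meta$selected_index,
       dnn_checkpoint_step = dnn$meta$checkpoint_step,
       dnn_tuning_metric = dnn$meta$tuning_metric),
  file.path(dir_, "models.json"), auto_unbox = TRUE, digits = NA)
message("wrote ", file.path(dir_, "models.json"))
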
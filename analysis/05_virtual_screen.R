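#!/usr/bin/env Rscript
# Stage 5 -- score a synthetic commercial catalog, build the purchase
# list, and demonstrate hit expansion.
#
# The 5-forest ensemble (median of member scores) ranks a 5000-compound
# catalog seeded with 100 analogs of the PTEs; the two-model filter
# (primary ensemble + fingerprint DNN) halves the top slice before
# property filtering and DISE diversity selection (0.2 Tanimoto-distance
# radius). Finally the top purchase-list compound is expanded against
# the catalog at the 0.35 ECFP6 similarity cutoff.

library(delscreen)

dir_ <- file.path("results", "screen")
read_smi <- function(f) {
  x <- strsplit(readLines(f), " ")
  unique(vapply(x, `[`, character(1), 1))
}
pos <- read_smi(file.path(dir_, "ptes.smi"))
neg <- read_smi(file.path(dir_, "nonhits.smi"))

sets <- build_training_sets(pos, neg, n_models = 5L,
                            n_negatives = min(1000L, length(neg)), seed = 41L)
scorers <- lapply(seq_along(sets), function(i)
  train_forest(sets[[i]], n_trees = 100L, seed = 400L + i))

catalog <- generate_catalog(5000L, seed = 51L, analogs_of = pos,
                            n_analogs = 100L)
rp <- ensemble_score(scorers, catalog)
rp$is_planted_analog <- catalog$is_planted_analog[match(rp$id, catalog$id)]
n_top <- sum(rp$is_planted_analog[1:100])
message("planted analogs in ensemble top 100: ", n_top,
        " (random expectation ", 100 * 100 / 5000, ")")
data.table::fwrite(rp, file.path(dir_, "predictions.csv"))

# two-model filter: drop the half of the top slice the DNN likes least
n_tune_pos <- max(2L, round(0.2 * length(pos)))
n_tune_neg <- max(10L, round(0.05 * length(neg)))
dnn <- train_dnn(setdiff(pos, pos[1:n_tune_pos]),
                 setdiff(neg, neg[1:n_tune_neg]),
                 pos[1:n_tune_pos], neg[1:n_tune_neg],
                 layers = c(256L, 32L), steps = 2000L, batch = 64L,
                 lr = 0.05, checkpoint_every = 250L, seed = 42L)
filtered <- v21_filter(rp, dnn, top_k = 1000L, keep_fraction = 0.5)
message("two-model filter: ", nrow(rp), " -> ", nrow(filtered), " candidates")

# property rules adapted to the synthetic chemistry (smaller assemblies
# than a commercial deck), then diversity selection
rules <- list(mw = c(150, 550), heavy_atoms = c(10L, 40L),
              elements = c("C", "N", "O", "S", "F", "Cl", "Br", "H"))
surv <- property_filter(as.data.frame(filtered), rules = rules)
message("property filter kept ", nrow(surv), " (rejections: ",
        paste(names(attr(surv, "rejections")), attr(surv, "rejections"),
              sep = "=", collapse = ", "), ")")
purchase <- dise_select(surv, radius = 0.2, max_n = 50L)
purchase$rank <- seq_len(nrow(purchase))
data.table::fwrite(purchase[, c("rank", "id", "smiles", "score",
                                "nearest_kept_distance")],
                   file.path(dir_, "purchase_list.csv"))
message("purchase list: ", nrow(purchase), " diverse compounds; ",
        sum(purchase$is_planted_analog), " are planted analogs")

# hit expansion around the top pick
hit <- purchase$smiles[1]
best <- suppressMessages(select_best_forest(scorers))
analogs <- hit_expand(hit, catalog, sim_threshold = 0.35, scorer = best,
                      radius = 0.2, max_n = 20L)
message("hit expansion of rank-1 compound: ", nrow(analogs),
        " diverse analogs above 0.35 similarity")
data.table::fwrite(analogs, file.path(dir_, "hit_expansion.csv"))

# novelty profile of the purchase list against the PTEs
prof <- pte_similarity_profile(purchase$smiles, pos)
data.table::fwrite(prof, file.path(dir_, "pte_similarity.csv"))
message(sprintf("purchase-list novelty: median max-similarity to PTEs %.2f, median top-10 mean %.2f",
                stats::median(prof$max_sim), stats::median(prof$mean_top_k)))
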
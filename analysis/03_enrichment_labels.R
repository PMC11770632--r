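#!/usr/bin/env Rscript
# Stage 3 -- disynthon enrichment, five-class labels, PTE export.
#
# Aggregates counts into disynthons, computes pseudocounted
# two-proportion z statistics per condition, assigns each disynthon one
# class (competitive_hit / noncompetitive_hit / promiscuous_binder /
# matrix_binder / non_hit), and exports the competitive-hit members as
# positive training examples. Compares the calls against the planted
# truth in library.csv.

library(delscreen)

dir_ <- file.path("results", "screen")
counts <- read_count_table(file.path(dir_, "counts.tsv"))
members <- data.table::fread(file.path(dir_, "library.csv"))

dis <- aggregate_disynthons(counts)
labels <- assign_classes(dis, n_disynthons = nrow(members))
message("classes: ", paste(names(table(labels$class)), table(labels$class),
                           sep = "=", collapse = ", "))

# truth vs call, at the member level (2-cycle: member == disynthon)
cls <- labels$class[match(paste0(members$block1, "|", members$block2),
                          paste0(labels$block_a, "|", labels$block_b))]
cls[is.na(cls)] <- "non_hit"
truth_comp <- !is.na(members$target_affinity) & members$competitive
truth_mat <- members$is_matrix_binder
truth_null <- is.na(members$target_affinity) & !truth_mat & !members$is_promiscuous
message(sprintf("competitive sensitivity %.3f | matrix sensitivity %.3f | non-hit specificity %.4f",
                mean(cls[truth_comp] == "competitive_hit"),
                mean(cls[truth_mat] == "matrix_binder"),
                mean(cls[truth_null] == "non_hit")))

data.table::fwrite(labels, file.path(dir_, "enrichment.tsv"), sep = "\t")

# PTEs: competitive hits expanded to member SMILES
lib <- generate_library(c(50L, 50L), seed = 1L, validate = FALSE)
lib <- plant_binders(lib, n_competitive = 5, n_noncompetitive = 3,
                     n_matrix = 25, affinity_range = c(1e-6, 1e-6),
                     motif_mode = TRUE, seed = 2L)
stopifnot(identical(lib$members$member_id, members$member_id))
ptes <- select_ptes(labels, lib, competitor_present = TRUE)
writeLines(paste(ptes$smiles, ptes$member_id), file.path(dir_, "ptes.smi"))
nonhit <- select_members(labels, lib, labels$key[labels$class == "non_hit"])
writeLines(paste(nonhit$smiles, nonhit$member_id),
           file.path(dir_, "nonhits.smi"))
message(nrow(ptes), " PTE members, ", nrow(nonhit), " non-hit members exported")
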
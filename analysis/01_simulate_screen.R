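#!/usr/bin/env Rscript
# Stage 1 -- simulate the synthetic DEL selection screen.
#
# Builds a 2-cycle 50x50 encoded library with planted ground truth
# (5 competitive motifs, 3 noncompetitive motifs, 25 matrix binders),
# runs the three parallel selection conditions (no target / target /
# target + competitor) for two selection cycles at 1e5 reads each, and
# writes FASTQ + schema + library table under results/screen/.

library(delscreen)

seed <- 1L
out <- file.path("results", "screen")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lib <- generate_library(c(50L, 50L), seed = seed, tag_length = 8L)
lib <- plant_binders(lib, n_competitive = 5, n_noncompetitive = 3,
                     n_matrix = 25, affinity_range = c(1e-6, 1e-6),
                     motif_mode = TRUE, seed = seed + 1L)

conds <- list(
  no_target = selection_condition("no_target"),
  target = selection_condition("target", target_concentration = 1e-6),
  target_plus_competitor = selection_condition(
    "target_plus_competitor", target_concentration = 1e-6,
    competitor_concentration = 1e-4))

for (i in seq_along(conds)) {
  rs <- simulate_selection(lib, conds[[i]], depth = 1e5, pcr_dup_rate = 0.1,
                           seq_error_rate = 0.001, seed = seed + 10L + i)
  write_fastq(rs, file.path(out, paste0(names(conds)[i], ".fastq")))
  message(sprintf("%-22s %d reads, %d pre-PCR molecules",
                  names(conds)[i], length(rs$reads), sum(rs$ledger$molecules)))
}

write_tag_schema(tag_schema(lib), file.path(out, "schema.json"))
data.table::fwrite(lib$members, file.path(out, "library.csv"))

message("library: ", nrow(lib$members), " members; planted truth: ",
        sum(!is.na(lib$members$target_affinity)), " binders, ",
        sum(lib$members$is_matrix_binder), " matrix binders")
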
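#!/usr/bin/env Rscript
# Stage 2 -- decode the selection FASTQ back to building-block counts.
#
# Strict decoding (error-containing reads are disregarded), UMI
# deduplication, and reads-per-million normalization within each
# (library, condition). Writes results/screen/counts.tsv.

library(delscreen)

dir_ <- file.path("results", "screen")
schema <- read_tag_schema(file.path(dir_, "schema.json"))
conds <- c("no_target", "target", "target_plus_competitor")

decoded <- lapply(conds, function(nm) {
  reads <- read_fastq(file.path(dir_, paste0(nm, ".fastq")))
  dec <- decode_reads(reads, schema, condition = nm)
  rej <- attr(dec, "rejections")
  dd <- dedupe(dec)
  message(sprintf("%-22s %6d reads: %6d decoded, %d rejected (%s), %6d unique molecules",
                  nm, length(reads), nrow(dec), sum(rej),
                  paste(names(rej), rej, sep = "=", collapse = ", "),
                  nrow(dd)))
  dd
})

counts <- build_count_table(data.table::rbindlist(decoded), schema)
write_count_table(counts, file.path(dir_, "counts.tsv"))
message("count table: ", nrow(counts), " member x condition rows")
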
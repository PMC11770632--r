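# Decoding DEL selection reads back into building-block combinations.
#
# Reads have the fixed layout [UMI][cycle tags][constant region]. Strict
# decoding keeps only reads whose every tag and constant region match the
# schema exactly (error-containing sequences are disregarded, not
# corrected); an optional 1-mismatch rescue mode exists for schemas with
# sufficient inter-tag Hamming distance.

#' Build a tag schema from an encoded library
#'
#' @param lib an `encoded_library`.
#' @param umi_length UMI length (nt) used during simulation.
#' @param constant_region constant-region sequence.
#' @return a `tag_schema`: per-cycle tag-to-block maps plus the span
#'   layout (`umi`, per-cycle tag, `constant`) tiling the read.
#' @export
tag_schema <- function(lib, umi_length = 12L, constant_region = "ACGTACGTAC") {
  stopifnot(inherits(lib, "encoded_library"))
  maps <- lapply(seq_len(lib$n_cycles), function(cy) {
    b <- lib$blocks[lib$blocks$cycle == cy, ]
    stats::setNames(b$block_id, b$tag)
  })
  tl <- lib$tag_length
  starts <- umi_length + (seq_len(lib$n_cycles) - 1L) * tl + 1L
  structure(list(library_id = lib$library_id,
                 n_cycles = lib$n_cycles,
                 umi_span = c(1L, as.integer(umi_length)),
                 tag_spans = lapply(seq_len(lib$n_cycles), function(cy)
                   c(starts[cy], starts[cy] + tl - 1L)),
                 constant_span = c(umi_length + lib$n_cycles * tl + 1L,
                                   umi_length + lib$n_cycles * tl +
                                     nchar(constant_region)),
                 constant_region = constant_region,
                 tag_maps = maps),
            class = "tag_schema")
}

#' Serialize / load a tag schema as JSON
#' @param schema a `tag_schema`.
#' @param path JSON file path.
#' @return `path` invisibly (write) or a `tag_schema` (read).
#' @export
write_tag_schema <- function(schema, path) {
  stopifnot(inherits(schema, "tag_schema"))
  x <- unclass(schema)
  x$tag_maps <- lapply(x$tag_maps, function(m)
    list(tags = names(m), blocks = unname(m)))
  jsonlite::write_json(x, path, pretty = TRUE, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_tag_schema
#' @export
read_tag_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list(
    library_id = x$library_id[[1]],
    n_cycles = as.integer(x$n_cycles[[1]]),
    umi_span = as.integer(unlist(x$umi_span)),
    tag_spans = lapply(x$tag_spans, function(sp) as.integer(unlist(sp))),
    constant_span = as.integer(unlist(x$constant_span)),
    constant_region = x$constant_region[[1]],
    tag_maps = lapply(x$tag_maps, function(m)
      stats::setNames(unlist(m$blocks), unlist(m$tags))))
  structure(out, class = "tag_schema")
}

.hamming1_match <- function(queries, tags) {
  # index of the unique tag within Hamming distance 1, else NA
  out <- rep(NA_integer_, length(queries))
  tl <- nchar(tags[1])
  tag_mat <- do.call(rbind, strsplit(tags, ""))
  uq <- unique(queries)
  q_mat <- do.call(rbind, strsplit(uq, ""))
  best <- rep(NA_integer_, length(uq))
  for (i in seq_along(uq)) {
    d <- colSums(t(tag_mat) != q_mat[i, ])
    hit <- which(d <= 1L)
    if (length(hit) == 1L) best[i] <- hit
  }
  out <- best[match(queries, uq)]
  out
}

#' Decode selection reads against a tag schema
#'
#' @param reads a `del_readset`, or a character vector of read sequences.
#' @param schema a `tag_schema`.
#' @param mode `"strict"` (exact match of every span; the default) or
#'   `"rescue"` (tags additionally matched at Hamming distance 1, allowed
#'   only when the minimum inter-tag distance within each cycle is >= 3).
#' @param condition condition label attached to decoded records; defaults
#'   to the read set's condition.
#' @return a `decoded_reads` object: data.table with `umi`, per-cycle
#'   block columns, `member_id` and `condition`; attribute `rejections`
#'   tallies discarded reads by reason (`length`, `bad_constant`,
#'   `unknown_tag`).
#' @export
decode_reads <- function(reads, schema, mode = c("strict", "rescue"),
                         condition = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(schema, "tag_schema"))
  if (inherits(reads, "del_readset")) {
    if (is.null(condition)) condition <- reads$condition
    reads <- reads$reads
  }
  if (is.null(condition)) condition <- "unknown"
  stopifnot(is.character(reads))

  if (mode == "rescue") {
    for (m in schema$tag_maps) {
      tags <- names(m)
      if (length(tags) > 1L) {
        tm <- do.call(rbind, strsplit(tags, ""))
        dmin <- min(vapply(seq_len(nrow(tm) - 1L), function(i)
          min(rowSums(tm[-seq_len(i), , drop = FALSE] !=
                        matrix(tm[i, ], nrow(tm) - i, ncol(tm), byrow = TRUE))),
          numeric(1)))
        if (dmin < 3L)
          stop("rescue mode requires minimum inter-tag Hamming distance >= 3 ",
               "(observed ", dmin, ")")
      }
    }
  }

  rej <- c(length = 0L, bad_constant = 0L, unknown_tag = 0L)
  expect_len <- schema$constant_span[2]
  empty <- function() {
    cols <- c(list(umi = character(0)),
              stats::setNames(rep(list(character(0)), schema$n_cycles),
                              paste0("block", seq_len(schema$n_cycles))),
              list(member_id = character(0), condition = character(0)))
    structure(data.table::as.data.table(cols), rejections = rej,
              class = c("decoded_reads", "data.table", "data.frame"))
  }
  if (!length(reads)) return(empty())

  ok_len <- nchar(reads) == expect_len
  rej["length"] <- sum(!ok_len)
  reads <- reads[ok_len]
  if (!length(reads)) return(empty())

  const <- substr(reads, schema$constant_span[1], schema$constant_span[2])
  ok_const <- const == schema$constant_region
  rej["bad_constant"] <- sum(!ok_const)
  reads <- reads[ok_const]
  if (!length(reads)) return(empty())

  umi <- substr(reads, schema$umi_span[1], schema$umi_span[2])
  block_idx <- vector("list", schema$n_cycles)
  ok <- rep(TRUE, length(reads))
  for (cy in seq_len(schema$n_cycles)) {
    sp <- schema$tag_spans[[cy]]
    tg <- substr(reads, sp[1], sp[2])
    m <- match(tg, names(schema$tag_maps[[cy]]))
    if (mode == "rescue") {
      miss <- which(is.na(m))
      if (length(miss))
        m[miss] <- .hamming1_match(tg[miss], names(schema$tag_maps[[cy]]))
    }
    block_idx[[cy]] <- m
    ok <- ok & !is.na(m)
  }
  rej["unknown_tag"] <- sum(!ok)

  keep <- which(ok)
  cols <- c(list(umi = umi[keep]),
            stats::setNames(lapply(seq_len(schema$n_cycles), function(cy)
              unname(schema$tag_maps[[cy]][block_idx[[cy]][keep]])),
              paste0("block", seq_len(schema$n_cycles))))
  dt <- data.table::as.data.table(cols)
  dt$member_id <- do.call(paste, c(dt[, paste0("block", seq_len(schema$n_cycles)),
                                      with = FALSE], list(sep = ".")))
  dt$condition <- condition
  structure(dt, rejections = rej,
            class = c("decoded_reads", "data.table", "data.frame"))
}

#' Collapse PCR duplicates of decoded reads
#'
#' One record is kept per distinct `(UMI, member, condition)`; the number
#' of collapsed duplicate reads is reported in the `collapsed` attribute.
#' The operation is idempotent and order-independent.
#'
#' @param decoded a `decoded_reads` table.
#' @return deduplicated `decoded_reads` with a `raw_reads` column giving
#'   the number of reads supporting each unique molecule.
#' @export
dedupe <- function(decoded) {
  stopifnot(inherits(decoded, "data.frame"))
  dt <- data.table::as.data.table(decoded)
  if (!nrow(dt)) {
    out <- dt
    out$raw_reads <- integer(0)
  } else {
    keycols <- setdiff(names(dt), "raw_reads")
    if ("raw_reads" %in% names(dt)) {
      out <- dt[, list(raw_reads = sum(raw_reads)), by = keycols]
    } else {
      out <- dt[, list(raw_reads = .N), by = keycols]
    }
    data.table::setkeyv(out, c("condition", "member_id", "umi"))
  }
  structure(out, collapsed = sum(out$raw_reads) - nrow(out),
            rejections = attr(decoded, "rejections"),
            class = c("decoded_reads", "data.table", "data.frame"))
}

#' Build a normalized count table from deduplicated molecules
#'
#' @param unique_stream deduplicated `decoded_reads` (one or several
#'   conditions row-bound together).
#' @param schema a `tag_schema` (supplies the library id).
#' @return a `count_table` data.table keyed by (library_id, member_id,
#'   condition) with `unique_count`, `raw_count`, per-(library, condition)
#'   `total_unique`, and `rpm` (reads-per-million within library and
#'   condition). Conditions with zero reads are flagged in the
#'   `zero_conditions` attribute and carry `NA` rpm.
#' @export
build_count_table <- function(unique_stream, schema) {
  stopifnot(inherits(schema, "tag_schema"))
  dt <- data.table::as.data.table(unique_stream)
  block_cols <- grep("^block[0-9]+$", names(dt), value = TRUE)
  if (!nrow(dt)) {
    out <- data.table::data.table(library_id = character(0),
                                  member_id = character(0),
                                  condition = character(0),
                                  unique_count = integer(0),
                                  raw_count = integer(0),
                                  total_unique = integer(0),
                                  rpm = numeric(0))
    return(structure(out, zero_conditions = character(0),
                     class = c("count_table", "data.table", "data.frame")))
  }
  if (!"raw_reads" %in% names(dt)) dt$raw_reads <- 1L
  counts <- dt[, list(unique_count = .N, raw_count = sum(raw_reads)),
               by = c("member_id", block_cols, "condition")]
  counts$library_id <- schema$library_id
  counts[, `:=`(total_unique = sum(unique_count)), by = c("library_id", "condition")]
  counts$rpm <- ifelse(counts$total_unique > 0,
                       counts$unique_count / counts$total_unique * 1e6, NA_real_)
  zero <- unique(counts$condition[counts$total_unique == 0])
  data.table::setcolorder(counts, c("library_id", "member_id", block_cols,
                                    "condition", "unique_count", "raw_count",
                                    "total_unique", "rpm"))
  data.table::setkeyv(counts, c("library_id", "condition", "member_id"))
  structure(counts, zero_conditions = zero,
            class = c("count_table", "data.table", "data.frame"))
}

#' Decode, deduplicate and count a set of selection read sets
#'
#' Convenience wrapper running [decode_reads()], [dedupe()] and
#' [build_count_table()] over one read set per condition.
#'
#' @param readsets named list of `del_readset` objects (names are ignored;
#'   each read set carries its condition).
#' @param schema a `tag_schema`.
#' @param mode decoding strictness, see [decode_reads()].
#' @return a `count_table`; per-condition rejection tallies are kept in
#'   the `rejections` attribute.
#' @export
count_selections <- function(readsets, schema, mode = "strict") {
  decoded <- lapply(readsets, function(rs) dedupe(decode_reads(rs, schema, mode = mode)))
  rej <- lapply(decoded, attr, "rejections")
  names(rej) <- vapply(readsets, function(rs)
    if (inherits(rs, "del_readset")) rs$condition else "unknown", character(1))
  all <- data.table::rbindlist(decoded)
  structure(build_count_table(all, schema), rejections = rej,
            class = c("count_table", "data.table", "data.frame"))
}

#' Write / read a count table as TSV
#' @param counts a `count_table`.
#' @param path TSV file.
#' @return `path` invisibly (write) or a `count_table` (read).
#' @export
write_count_table <- function(counts, path) {
  data.table::fwrite(data.table::as.data.table(counts), path, sep = "\t")
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  out <- data.table::fread(path, sep = "\t")
  structure(out, class = c("count_table", "data.table", "data.frame"))
}
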
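# Synthetic DNA-encoded library (DEL) generator.
#
# Emulates the statistical structure of split-and-pool DEL affinity
# selections: combinatorial libraries with per-cycle DNA tags, planted
# ground-truth binders (competitive / noncompetitive / matrix /
# promiscuous), two-cycle affinity capture with an occupancy model,
# PCR duplication, per-base sequencing error, and per-molecule UMIs.

.DNA <- c("A", "C", "G", "T")

# evaluate expr under a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(.DNA, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# n distinct random DNA strings
.unique_dna <- function(n, len) {
  out <- unique(.random_dna(n, len))
  guard <- 0L
  while (length(out) < n) {
    out <- unique(c(out, .random_dna(n - length(out) + 16L, len)))
    guard <- guard + 1L
    if (guard > 1000L) stop("cannot generate ", n, " distinct tags of length ", len)
  }
  out[seq_len(n)]
}

#' Substituent fragment pool for synthetic libraries
#'
#' A fixed pool of >100 simple substituent SMILES. Each fragment carries a
#' single attachment point, marked with a leading `*`; the atom following
#' the marker is bonded into the assembly template.
#'
#' @return character vector of fragment SMILES, each starting with `*`.
#' @export
fragment_pool <- function() {
  subs <- c("F", "Cl", "Br", "C", "O", "OC", "N", "N(C)C", "C#N",
            "C(F)(F)F", "OC(F)(F)F", "C(C)C", "CC", "OCC", "S(C)(=O)=O")
  frags <- c(
    paste0("c1ccc(", subs, ")cc1"),
    paste0("c1cccc(", subs, ")c1"),
    paste0("c1ccccc1", subs),
    paste0("Cc1ccc(", subs[1:10], ")cc1"),
    paste0("CCc1ccc(", subs[1:8], ")cc1"),
    "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1",
    "c1ccncc1", "c1cccnc1", "Cc1ccncc1", "Cc1cccnc1",
    "c1ccco1", "c1cccs1", "Cc1ccco1", "Cc1cccs1", "c1cc[nH]c1",
    "C", "CC", "CCC", "CCCC", "CCCCC", "C(C)C", "C(C)(C)C", "CC(C)C",
    "CC(C)(C)C", "CCO", "CCCO", "CCN", "CCCN", "CCOC", "CCCOC",
    "CC(F)(F)F", "CC#N", "CCC#N", "CC(C)O", "CCS(C)(=O)=O", "CC(=O)N",
    "CCC(=O)N", "CC(=O)OC", "CCF", "CCCF", "CCCl",
    "C1CCCCC1", "C1CCCC1", "C1CCC1", "CC1CCCCC1", "CC1CCCC1",
    "C1CCNCC1", "C1CCOCC1", "C1CCN(C)CC1", "CC1CCNCC1", "CC1CCOCC1",
    "C1CNCCN1C", "C1COCCN1C"
  )
  paste0("*", unique(frags))
}

# assembly templates: fragments are bonded at their attachment atom onto
# an amide (2-cycle) / peptoid-like (3-cycle) backbone
.assemble_smiles <- function(frags_by_cycle) {
  f <- lapply(frags_by_cycle, function(x) sub("^\\*", "", x))
  if (length(f) == 2L) {
    sprintf("N(%s)C(=O)%s", f[[1]], f[[2]])
  } else {
    sprintf("N(%s)C(=O)C(%s)NC(=O)%s", f[[1]], f[[2]], f[[3]])
  }
}

#' Generate a synthetic encoded library
#'
#' Builds an `n_cycles`-cycle combinatorial library by sampling building
#' blocks (fragment + per-cycle DNA tag) from [fragment_pool()] and
#' assembling every cycle-wise combination onto an amide/peptoid backbone
#' template. Ground-truth binding fields are initialized to "no binding";
#' use [plant_binders()] to install them.
#'
#' @param n_blocks_per_cycle integer vector (length `n_cycles`) of block
#'   counts, each at least 2 and at most the pool size.
#' @param n_cycles 2 or 3; defaults to `length(n_blocks_per_cycle)`.
#' @param seed integer seed; the whole library is deterministic in it.
#' @param library_id identifier stamped on members.
#' @param tag_length DNA tag length per cycle (nt).
#' @param validate if `TRUE`, assembled member SMILES are checked for
#'   parseability with the chemistry backend.
#' @return an `encoded_library`: list with `library_id`, `n_cycles`,
#'   `blocks` (data.table: cycle, block_id, fragment, tag) and `members`
#'   (data.table: member_id, per-cycle block ids, smiles, tag, truth
#'   columns `target_affinity` (molar KD or NA), `is_matrix_binder`,
#'   `is_promiscuous`, `competitive`).
#' @export
generate_library <- function(n_blocks_per_cycle, n_cycles = length(n_blocks_per_cycle),
                             seed = 1L, library_id = "LIB1", tag_length = 8L,
                             validate = TRUE) {
  n_blocks_per_cycle <- as.integer(n_blocks_per_cycle)
  if (!n_cycles %in% c(2L, 3L)) stop("n_cycles must be 2 or 3")
  if (length(n_blocks_per_cycle) != n_cycles)
    stop("n_blocks_per_cycle must have length n_cycles")
  if (any(n_blocks_per_cycle < 2L)) stop("each cycle needs at least 2 blocks")
  pool <- fragment_pool()
  if (any(n_blocks_per_cycle > length(pool)))
    stop("block count exceeds fragment pool size (", length(pool), ")")

  with_seed(seed, {
    blocks <- data.table::rbindlist(lapply(seq_len(n_cycles), function(cy) {
      nb <- n_blocks_per_cycle[cy]
      data.table::data.table(
        cycle = cy,
        block_id = sprintf("C%dB%03d", cy, seq_len(nb)),
        fragment = sample(pool, nb),
        tag = .unique_dna(nb, tag_length))
    }))

    idx <- do.call(data.table::CJ, c(lapply(rev(n_blocks_per_cycle), seq_len),
                                     list(sorted = FALSE)))
    data.table::setcolorder(idx, rev(seq_len(n_cycles)))
    data.table::setnames(idx, paste0("i", seq_len(n_cycles)))
    per_cycle <- lapply(seq_len(n_cycles), function(cy) {
      b <- blocks[blocks$cycle == cy, ]
      list(id = b$block_id, frag = b$fragment, tag = b$tag)
    })
    members <- data.table::data.table(
      member_id = do.call(paste, c(lapply(seq_len(n_cycles), function(cy)
        per_cycle[[cy]]$id[idx[[cy]]]), list(sep = "."))))
    for (cy in seq_len(n_cycles))
      members[[paste0("block", cy)]] <- per_cycle[[cy]]$id[idx[[cy]]]
    members$smiles <- .assemble_smiles(
      lapply(seq_len(n_cycles), function(cy) per_cycle[[cy]]$frag[idx[[cy]]]))
    members$tag <- do.call(paste0, lapply(seq_len(n_cycles), function(cy)
      per_cycle[[cy]]$tag[idx[[cy]]]))
    members$target_affinity <- NA_real_
    members$is_matrix_binder <- FALSE
    members$is_promiscuous <- FALSE
    members$competitive <- FALSE

    if (validate) {
      ok <- validate_smiles(members$smiles)
      if (!all(ok))
        stop("assembled member SMILES failed to parse: ",
             paste(utils::head(members$smiles[!ok], 5), collapse = ", "))
    }
    if (anyDuplicated(members$tag))
      stop("internal error: member tag collision")

    structure(list(library_id = library_id, n_cycles = n_cycles,
                   tag_length = as.integer(tag_length),
                   blocks = blocks, members = members, seed = as.integer(seed)),
              class = "encoded_library")
  })
}

#' @export
print.encoded_library <- function(x, ...) {
  cat(sprintf("encoded_library %s: %d cycles (%s blocks), %d members\n",
              x$library_id, x$n_cycles,
              paste(table(x$blocks$cycle), collapse = "x"),
              nrow(x$members)))
  planted <- sum(!is.na(x$members$target_affinity)) +
    sum(x$members$is_matrix_binder) + sum(x$members$is_promiscuous)
  cat(sprintf("  truth: %d members with planted roles\n", planted))
  invisible(x)
}

#' Plant ground-truth binders into a library
#'
#' Installs synthetic binding truth used by [simulate_selection()].
#' With `motif_mode = TRUE`, competitive and noncompetitive binders are
#' planted as shared building-block motifs (all blocks fixed except the
#' final cycle), so every member carrying the motif receives the same
#' affinity and the signal aggregates at the disynthon level. Matrix and
#' promiscuous binders are always planted on individual members. When
#' roles collide, precedence is matrix > promiscuous > competitive >
#' noncompetitive.
#'
#' @param lib an `encoded_library`.
#' @param n_competitive,n_noncompetitive number of motifs (in motif mode)
#'   or members to plant per role.
#' @param n_matrix,n_promiscuous number of members to plant per role.
#' @param affinity_range KD range (molar); affinities are drawn
#'   log-uniformly within it.
#' @param motif_mode plant target binders as building-block motifs.
#' @param seed integer seed.
#' @return the library with truth columns populated and a `planted`
#'   attribute recording the planted motifs/members per role.
#' @export
plant_binders <- function(lib, n_competitive = 0L, n_noncompetitive = 0L,
                          n_matrix = 0L, n_promiscuous = 0L,
                          affinity_range = c(1e-8, 1e-6),
                          motif_mode = FALSE, seed = 1L) {
  stopifnot(inherits(lib, "encoded_library"))
  mem <- data.table::copy(lib$members)
  n_mem <- nrow(mem)
  draw_kd <- function(n) exp(stats::runif(n, log(affinity_range[1]), log(affinity_range[2])))

  with_seed(seed, {
    planted <- list()
    fixed_cols <- paste0("block", seq_len(lib$n_cycles - 1L))

    plant_motifs <- function(n_comp, n_noncomp) {
      n <- n_comp + n_noncomp
      if (n == 0L) return(list(competitive = NULL, noncompetitive = NULL))
      combos <- unique(mem[, fixed_cols, with = FALSE])
      if (n > nrow(combos)) stop("more motifs requested than available block combinations")
      pick <- combos[sample(nrow(combos), n), ]
      pick$kd <- draw_kd(n)
      pick$competitive <- rep(c(TRUE, FALSE), c(n_comp, n_noncomp))
      for (r in seq_len(n)) {
        sel <- rep(TRUE, n_mem)
        for (cc in fixed_cols) sel <- sel & mem[[cc]] == pick[[cc]][r]
        mem$target_affinity[sel] <<- pick$kd[r]
        mem$competitive[sel] <<- pick$competitive[r]
      }
      list(competitive = pick[pick$competitive],
           noncompetitive = pick[!pick$competitive])
    }

    plant_members <- function(n, role) {
      if (n == 0L) return(NULL)
      # matrix and promiscuous roles may land on members that already
      # carry an affinity; the precedence pass below resolves overlaps
      free <- switch(role,
        matrix = which(!mem$is_matrix_binder),
        promiscuous = which(!mem$is_matrix_binder & !mem$is_promiscuous),
        which(is.na(mem$target_affinity)))
      if (n > length(free)) stop("not enough unassigned members for role ", role)
      pick <- sample(free, n)
      if (role == "matrix") {
        mem$is_matrix_binder[pick] <<- TRUE
      } else if (role == "promiscuous") {
        mem$is_promiscuous[pick] <<- TRUE
        mem$target_affinity[pick] <<- draw_kd(n)
      } else {
        mem$target_affinity[pick] <<- draw_kd(n)
        mem$competitive[pick] <<- role == "competitive"
      }
      mem$member_id[pick]
    }

    if (motif_mode) {
      motifs <- plant_motifs(n_competitive, n_noncompetitive)
      planted$competitive_motifs <- motifs$competitive
      planted$noncompetitive_motifs <- motifs$noncompetitive
    } else {
      planted$competitive_members <- plant_members(n_competitive, "competitive")
      planted$noncompetitive_members <- plant_members(n_noncompetitive, "noncompetitive")
    }
    # matrix/promiscuous planted last but with highest precedence on overlap
    planted$promiscuous_members <- plant_members(n_promiscuous, "promiscuous")
    planted$matrix_members <- plant_members(n_matrix, "matrix")

    # precedence: matrix > promiscuous > competitive > noncompetitive
    ovl <- mem$is_matrix_binder & (mem$is_promiscuous | !is.na(mem$target_affinity))
    if (any(ovl)) {
      message(sum(ovl), " member(s) resolved to matrix_binder by precedence")
      mem$is_promiscuous[ovl] <- FALSE
      mem$target_affinity[ovl] <- NA_real_
      mem$competitive[ovl] <- FALSE
    }
    ovl2 <- mem$is_promiscuous & mem$competitive
    if (any(ovl2)) {
      message(sum(ovl2), " member(s) resolved to promiscuous by precedence")
      mem$competitive[ovl2] <- FALSE
    }

    out <- lib
    out$members <- mem
    attr(out, "planted") <- planted
    out
  })
}

#' Construct a selection condition
#'
#' @param kind one of `"no_target"`, `"target"`, `"target_plus_competitor"`.
#' @param target_concentration free target concentration (molar); forced
#'   to 0 for `no_target`.
#' @param competitor_concentration competitor concentration (molar).
#' @param matrix_capture_prob per-cycle probability that any library
#'   member is retained by the capture matrix regardless of affinity.
#' @param n_cycles_of_selection number of selection/recovery rounds.
#' @return a `selection_condition` list.
#' @export
selection_condition <- function(kind = c("no_target", "target", "target_plus_competitor"),
                                target_concentration = 1e-6,
                                competitor_concentration = 0,
                                matrix_capture_prob = 0.01,
                                n_cycles_of_selection = 2L) {
  kind <- match.arg(kind)
  if (kind == "no_target") target_concentration <- 0
  if (kind == "target_plus_competitor" && competitor_concentration <= 0)
    competitor_concentration <- 1e-4
  stopifnot(matrix_capture_prob >= 0, matrix_capture_prob <= 1,
            target_concentration >= 0, competitor_concentration >= 0)
  structure(list(kind = kind,
                 target_concentration = target_concentration,
                 competitor_concentration = competitor_concentration,
                 matrix_capture_prob = matrix_capture_prob,
                 n_cycles_of_selection = as.integer(n_cycles_of_selection)),
            class = "selection_condition")
}

# per-member, per-cycle capture probability under a condition
.capture_prob <- function(lib, cond, matrix_binder_capture = 0.5, kd_comp = 1e-6) {
  mem <- lib$members
  theta <- rep(0, nrow(mem))
  tt <- cond$target_concentration
  if (tt > 0) {
    kd <- mem$target_affinity
    has <- !is.na(kd)
    kd_eff <- kd
    if (cond$kind == "target_plus_competitor" && cond$competitor_concentration > 0) {
      # competitive binders are displaced; noncompetitive and promiscuous
      # binders keep their site
      disp <- has & mem$competitive & !mem$is_promiscuous
      kd_eff[disp] <- kd[disp] * (1 + cond$competitor_concentration / kd_comp)
    }
    theta[has] <- tt / (tt + kd_eff[has])
  }
  base <- ifelse(mem$is_matrix_binder, matrix_binder_capture, cond$matrix_capture_prob)
  pmin(theta + base, 1)
}

#' Simulate an affinity selection and its sequencing reads
#'
#' Survival follows an occupancy model: per selection cycle, a member is
#' retained with probability `theta + matrix_capture`, clamped to 1, where
#' `theta = [T] / ([T] + KD_eff)`; `KD_eff = KD * (1 + [C]/kd_comp)` for
#' competitive binders in the competitor condition and `KD_eff = KD`
#' otherwise. Non-binders survive only through matrix capture. Cycles are
#' independent, so the sampling weight is `capture ^ n_cycles`. Pre-PCR
#' molecules are drawn multinomially over members at those weights, each
#' molecule receives a distinct UMI, PCR emits `1 + Geometric(pcr_dup_rate)`
#' reads per molecule (truncated so the total equals `depth`), and every
#' emitted base is substituted independently at `seq_error_rate`.
#'
#' @param lib an `encoded_library` (typically after [plant_binders()]).
#' @param cond a [selection_condition()].
#' @param depth number of sequencing reads to emit.
#' @param pcr_dup_rate geometric PCR duplication parameter in `[0, 1)`.
#' @param seq_error_rate per-base substitution probability in `[0, 1)`.
#' @param seed integer seed.
#' @param matrix_binder_capture per-cycle capture probability of planted
#'   matrix binders.
#' @param kd_comp competitor dissociation constant (molar) used in the
#'   competitive-inhibition correction.
#' @param umi_length UMI length (nt).
#' @param constant_region 3' constant-region sequence appended to every read.
#' @return a `del_readset`: list with `reads` (character vector,
#'   `[UMI][tags][constant]`), `condition`, `schema` description, and
#'   `ledger` (data.table member_id / molecules: the pre-PCR molecule
#'   multiset actually drawn).
#' @export
simulate_selection <- function(lib, cond, depth, pcr_dup_rate = 0,
                               seq_error_rate = 0, seed = 1L,
                               matrix_binder_capture = 0.5, kd_comp = 1e-6,
                               umi_length = 12L, constant_region = "ACGTACGTAC") {
  stopifnot(inherits(lib, "encoded_library"), inherits(cond, "selection_condition"))
  if (pcr_dup_rate < 0 || pcr_dup_rate >= 1) stop("pcr_dup_rate must be in [0, 1)")
  if (seq_error_rate < 0 || seq_error_rate >= 1) stop("seq_error_rate must be in [0, 1)")
  depth <- as.integer(depth)

  schema_info <- list(umi_length = as.integer(umi_length),
                      tag_length = lib$tag_length,
                      n_cycles = lib$n_cycles,
                      constant_region = constant_region)
  empty <- function() {
    warning("depth of 0 requested: empty read set")
    structure(list(reads = character(0), condition = cond$kind,
                   schema = schema_info,
                   ledger = data.table::data.table(member_id = character(0),
                                                   molecules = integer(0)),
                   seed = as.integer(seed)),
              class = "del_readset")
  }
  if (depth < 1L) return(empty())

  with_seed(seed, {
    capture <- .capture_prob(lib, cond, matrix_binder_capture, kd_comp)
    w <- capture ^ cond$n_cycles_of_selection
    if (sum(w) <= 0) stop("no member has positive survival probability")
    prob <- w / sum(w)

    # pre-PCR molecules, each expanded to 1 + Geom(p) reads, totalling depth
    if (pcr_dup_rate == 0) {
      dup <- rep(1L, depth)
    } else {
      n_guess <- ceiling(depth * (1 - pcr_dup_rate)) + 10L
      dup <- integer(0)
      while (sum(dup) < depth)
        dup <- c(dup, 1L + stats::rgeom(n_guess, prob = 1 - pcr_dup_rate))
      n_mol <- which(cumsum(dup) >= depth)[1]
      dup <- dup[seq_len(n_mol)]
      dup[n_mol] <- dup[n_mol] - (sum(dup) - depth)
    }
    n_mol <- length(dup)
    mol_member <- sample.int(nrow(lib$members), n_mol, replace = TRUE, prob = prob)

    umis <- .random_dna(n_mol, umi_length)
    guard <- 0L
    while (anyDuplicated(umis)) {
      d <- which(duplicated(umis))
      umis[d] <- .random_dna(length(d), umi_length)
      guard <- guard + 1L
      if (guard > 100L) stop("cannot allocate distinct UMIs; increase umi_length")
    }

    templ <- paste0(umis, lib$members$tag[mol_member], constant_region)
    reads <- rep(templ, times = dup)

    if (seq_error_rate > 0 && length(reads)) {
      L <- nchar(reads[1])
      n_err <- stats::rbinom(length(reads), L, seq_error_rate)
      hit <- which(n_err > 0)
      if (length(hit)) {
        split_reads <- strsplit(reads[hit], "")
        for (k in seq_along(hit)) {
          pos <- sample.int(L, n_err[hit[k]])
          cur <- split_reads[[k]][pos]
          split_reads[[k]][pos] <- vapply(cur, function(b)
            sample(setdiff(.DNA, b), 1), character(1))
        }
        reads[hit] <- vapply(split_reads, paste, character(1), collapse = "")
      }
    }

    tab <- tabulate(mol_member, nbins = nrow(lib$members))
    ledger <- data.table::data.table(member_id = lib$members$member_id,
                                     molecules = tab)[tab > 0L]
    structure(list(reads = reads, condition = cond$kind, schema = schema_info,
                   ledger = ledger, seed = as.integer(seed)),
              class = "del_readset")
  })
}

#' @export
print.del_readset <- function(x, ...) {
  cat(sprintf("del_readset (%s): %d reads, %d pre-PCR molecules\n",
              x$condition, length(x$reads), sum(x$ledger$molecules)))
  invisible(x)
}

#' Write a read set as FASTQ
#'
#' Four-line records with dummy qualities, via Biostrings.
#'
#' @param rs a `del_readset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "del_readset"))
  x <- Biostrings::DNAStringSet(rs$reads)
  if (length(x))
    names(x) <- sprintf("read%07d_%s", seq_along(x), rs$condition)
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Read sequences from a FASTQ file
#'
#' @param path FASTQ file.
#' @return character vector of read sequences.
#' @export
read_fastq <- function(path) {
  unname(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
}
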
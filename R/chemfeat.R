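# Fingerprint featurization and Tanimoto similarity.
#
# Circular (Morgan/ECFP) fingerprints are computed with OpenBabel's ECFP
# implementation (radius r == ECFP{2r}) and folded to a fixed bit width.
# Bit positions are backend-specific; all downstream logic relies only on
# invariance properties (canonical-molecule identity, determinism), never
# on particular bit indices.

.obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("obabel executable not found on PATH")
  p
}

#' Compute Morgan/ECFP fingerprints for a set of SMILES
#'
#' Each molecule is featurized as a circular substructure fingerprint of
#' the given radius (environment diameter `2 * radius` bonds), folded to
#' `nbits` bits. Fingerprints are deterministic and invariant to the atom
#' ordering of the input SMILES (the backend canonicalizes internally).
#'
#' @param smiles character vector of SMILES strings.
#' @param radius circular environment radius in bonds (2 for ECFP4-style,
#'   3 for ECFP6-style features).
#' @param nbits folded width in bits (power of two).
#' @param ids optional identifiers, defaults to the SMILES themselves.
#' @return A `del_fp` object: a list with `bits` (per-molecule sorted
#'   integer vectors of set 1-based bit positions), `nbits`, `radius`,
#'   `ids` and `smiles`.
#' @export
fingerprint <- function(smiles, radius = 2L, nbits = 1024L, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  radius <- as.integer(radius)
  nbits <- as.integer(nbits)
  if (radius < 0L || radius > 5L) stop("radius must be in 0..5")
  if (nbits < 32L || bitwAnd(nbits, nbits - 1L) != 0L)
    stop("nbits must be a power of two >= 32")
  bad <- is.na(smiles) | !nzchar(smiles)
  if (any(bad)) stop("unparseable SMILES: ", paste(smiles[bad], collapse = ", "))

  tmp_in <- tempfile(fileext = ".smi")
  tmp_out <- tempfile(fileext = ".fpt")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  # internal sequential titles let us map records back and spot failures
  writeLines(paste(smiles, sprintf("dfp%08d", seq_along(smiles))), tmp_in)
  fpname <- paste0("ECFP", 2L * radius)
  status <- system2(.obabel_path(),
                    c(tmp_in, "-ofpt", paste0("-xf", fpname),
                      paste0("-xN", nbits), "-xh", "-O", tmp_out),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(tmp_out))
    stop("fingerprint backend failed (obabel exit status ", status, ")")

  lines <- readLines(tmp_out)
  rec_title <- character(0)
  rec_hex <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      ttl <- sub("^>\\s*(\\S+).*$", "\\1", ln)
      rec_title <- c(rec_title, ttl)
      cur <- length(rec_title)
      rec_hex[[cur]] <- character(0)
    } else if (!is.null(cur) && grepl("^[0-9a-f]{8}( |$)", ln)) {
      rec_hex[[cur]] <- c(rec_hex[[cur]], regmatches(ln, gregexpr("[0-9a-f]{8}", ln))[[1]])
    }
  }
  idx <- match(sprintf("dfp%08d", seq_along(smiles)), rec_title)
  if (anyNA(idx)) {
    offenders <- smiles[is.na(idx)]
    stop("unparseable SMILES: ", paste(unique(offenders), collapse = ", "))
  }

  ok_width <- vapply(rec_hex[idx], length, integer(1)) * 32L == nbits
  if (!all(ok_width))
    stop("fingerprint width mismatch for SMILES ",
         paste(utils::head(smiles[!ok_width], 3), collapse = ", "))
  # vectorized hex -> bit positions over the whole batch; nibble j
  # (1-based from the left, after word reversal) covers bits
  # (nn - j)*4 + 1..4 -- the absolute placement is arbitrary but fixed
  n <- length(smiles)
  nn <- nbits %/% 4L
  hexcat <- vapply(rec_hex[idx], function(w) paste(rev(w), collapse = ""),
                   character(1))
  vals <- strtoi(unlist(strsplit(hexcat, ""), use.names = FALSE), 16L)
  rec_of <- rep(seq_len(n), each = nn)
  base <- rep((nn - seq_len(nn)) * 4L, n)
  recs <- integer(0); poss <- integer(0)
  for (b in 1:4) {
    sel <- bitwAnd(vals, bitwShiftL(1L, b - 1L)) > 0L
    recs <- c(recs, rec_of[sel])
    poss <- c(poss, base[sel] + b)
  }
  bits <- rep(list(integer(0)), n)
  if (length(recs)) {
    byrec <- split(poss, factor(recs, levels = seq_len(n)))
    bits <- lapply(byrec, sort)
    names(bits) <- NULL
  }
  structure(list(bits = bits, nbits = nbits, radius = radius,
                 ids = if (is.null(ids)) smiles else as.character(ids),
                 smiles = smiles),
            class = "del_fp")
}

#' @export
length.del_fp <- function(x) length(x$bits)

#' @export
`[.del_fp` <- function(x, i) {
  structure(list(bits = x$bits[i], nbits = x$nbits, radius = x$radius,
                 ids = x$ids[i], smiles = x$smiles[i]),
            class = "del_fp")
}

#' @export
print.del_fp <- function(x, ...) {
  cat(sprintf("del_fp set: %d molecule(s), radius %d, %d bits\n",
              length(x), x$radius, x$nbits))
  invisible(x)
}

#' Number of set bits per fingerprint
#' @param fp a `del_fp` object.
#' @return integer vector of popcounts.
#' @export
fp_popcount <- function(fp) {
  stopifnot(inherits(fp, "del_fp"))
  vapply(fp$bits, length, integer(1))
}

#' Dense 0/1 feature matrix from a fingerprint set
#'
#' @param fp a `del_fp` object.
#' @param rows optional indices of molecules to materialize.
#' @return integer matrix (molecules x nbits).
#' @export
fp_dense <- function(fp, rows = NULL) {
  stopifnot(inherits(fp, "del_fp"))
  if (is.null(rows)) rows <- seq_len(length(fp))
  m <- matrix(0L, nrow = length(rows), ncol = fp$nbits)
  bl <- fp$bits[rows]
  lens <- lengths(bl)
  if (sum(lens))
    m[cbind(rep(seq_along(rows), lens), unlist(bl, use.names = FALSE))] <- 1L
  colnames(m) <- paste0("b", seq_len(fp$nbits))
  m
}

.check_compatible <- function(a, b) {
  if (!inherits(a, "del_fp") || !inherits(b, "del_fp"))
    stop("tanimoto expects del_fp objects")
  if (a$nbits != b$nbits || a$radius != b$radius)
    stop("fingerprint parameters differ: ",
         sprintf("(radius %d, %d bits) vs (radius %d, %d bits)",
                 a$radius, a$nbits, b$radius, b$nbits))
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|`. Two empty fingerprints have undefined
#' similarity; it is returned as 0 with a warning.
#'
#' @param a,b single-molecule `del_fp` objects with matching radius/width.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  .check_compatible(a, b)
  if (length(a) != 1L || length(b) != 1L)
    stop("tanimoto compares exactly one fingerprint to one fingerprint; see tanimoto_matrix")
  ba <- a$bits[[1]]; bb <- b$bits[[1]]
  if (length(ba) == 0L && length(bb) == 0L) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  inter <- length(intersect(ba, bb))
  inter / (length(ba) + length(bb) - inter)
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param a,b `del_fp` sets with matching parameters.
#' @return numeric matrix `length(a)` x `length(b)`.
#' @export
tanimoto_matrix <- function(a, b) {
  .check_compatible(a, b)
  da <- fp_dense(a)
  db <- fp_dense(b)
  inter <- da %*% t(db)
  pa <- rowSums(da)
  pb <- rowSums(db)
  uni <- outer(pa, pb, "+") - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  dimnames(out) <- list(a$ids, b$ids)
  out
}

#' Similarity profile of predictions against positive training examples
#'
#' For each prediction, reports the Tanimoto similarity to its most
#' similar PTE and the mean similarity over the `k` most similar PTEs
#' (ECFP6-style features at 1024 bits by default, the convention used for
#' prediction-to-training-set novelty profiling).
#'
#' @param predictions character vector of SMILES.
#' @param ptes character vector of PTE SMILES (non-empty).
#' @param k number of top PTE similarities averaged (capped at the PTE count).
#' @param radius,nbits fingerprint parameters.
#' @return data.frame with `id`, `max_sim`, `mean_top_k`.
#' @export
pte_similarity_profile <- function(predictions, ptes, k = 10L,
                                   radius = 3L, nbits = 1024L) {
  if (length(ptes) < 1L) stop("at least one PTE is required")
  k <- min(as.integer(k), length(ptes))
  fp_pred <- fingerprint(predictions, radius = radius, nbits = nbits)
  fp_pte <- fingerprint(ptes, radius = radius, nbits = nbits)
  sims <- tanimoto_matrix(fp_pred, fp_pte)
  max_sim <- apply(sims, 1, max)
  mean_top_k <- apply(sims, 1, function(s) mean(sort(s, decreasing = TRUE)[seq_len(k)]))
  data.frame(id = fp_pred$ids, max_sim = as.numeric(max_sim),
             mean_top_k = as.numeric(mean_top_k), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Validate SMILES strings with the chemistry backend
#'
#' @param smiles character vector.
#' @return logical vector, `TRUE` where the SMILES parses.
#' @export
validate_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (!length(smiles)) return(logical(0))
  tmp_in <- tempfile(fileext = ".smi")
  tmp_out <- tempfile(fileext = ".txt")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  writeLines(paste(smiles, sprintf("v%08d", seq_along(smiles))), tmp_in)
  system2(.obabel_path(), c(tmp_in, "-otxt", "-O", tmp_out),
          stdout = FALSE, stderr = FALSE)
  ok_titles <- if (file.exists(tmp_out)) readLines(tmp_out) else character(0)
  sprintf("v%08d", seq_along(smiles)) %in% ok_titles
}

#' Molecular weight, formula and heavy-atom composition
#'
#' @param smiles character vector of parseable SMILES.
#' @return data.frame with `smiles`, `mw` (Da), `formula`, `heavy_atoms`,
#'   and `elements` (list column of element symbols present, including H).
#' @export
mol_properties <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  tmp_in <- tempfile(fileext = ".smi")
  tmp_out <- tempfile(fileext = ".txt")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  writeLines(paste(smiles, sprintf("p%08d", seq_along(smiles))), tmp_in)
  system2(.obabel_path(), c(tmp_in, "-otxt", "--append", "MW formula",
                            "-O", tmp_out),
          stdout = FALSE, stderr = FALSE)
  lines <- if (file.exists(tmp_out)) readLines(tmp_out) else character(0)
  parts <- strsplit(lines, "\\s+")
  titles <- vapply(parts, `[`, character(1), 1)
  idx <- match(sprintf("p%08d", seq_along(smiles)), titles)
  if (anyNA(idx))
    stop("unparseable SMILES: ",
         paste(unique(smiles[is.na(idx)]), collapse = ", "))
  mw <- as.numeric(vapply(parts[idx], `[`, character(1), 2))
  formula <- vapply(parts[idx], `[`, character(1), 3)
  comp <- lapply(formula, .parse_formula)
  heavy <- vapply(comp, function(cc) sum(cc[names(cc) != "H"]), numeric(1))
  data.frame(smiles = smiles, mw = mw, formula = formula,
             heavy_atoms = as.integer(heavy),
             elements = I(lapply(comp, names)),
             stringsAsFactors = FALSE)
}

# "C10H13NO2" -> named integer vector of element counts
.parse_formula <- function(f) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, list(m))[[1]]
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Z][a-z]?", "", toks))
  n[is.na(n)] <- 1L
  counts <- tapply(n, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
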
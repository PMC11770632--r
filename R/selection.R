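# Purchase-list selection: drug-likeness property filtering, directed
# sphere exclusion (DISE) diversity selection, and model-guided hit
# expansion.
#
# "Radius" throughout is a Tanimoto DISTANCE cutoff (1 - similarity),
# the usual sphere-exclusion convention: a candidate is kept only if it
# lies strictly outside the exclusion sphere of every already-kept
# compound.

#' Default drug-likeness property rules
#'
#' Conventional windows (molecular weight 250-550 Da, 17-40 heavy atoms,
#' organic element set); fully configurable.
#'
#' @return list with `mw`, `heavy_atoms`, `elements`.
#' @export
default_property_rules <- function() {
  list(mw = c(250, 550),
       heavy_atoms = c(17L, 40L),
       elements = c("C", "N", "O", "S", "F", "Cl", "Br", "H"))
}

#' Filter compounds by physicochemical property rules
#'
#' A compound survives iff it passes every rule; per-rule rejection
#' counts are tallied (a compound failing several rules counts once in
#' each tally).
#'
#' @param compounds character vector of SMILES, or a data.frame with a
#'   `smiles` column.
#' @param rules list with any of `mw = c(lo, hi)`, `heavy_atoms = c(lo,
#'   hi)`, `elements = <allowed element symbols>`; an empty list is the
#'   identity filter.
#' @return the surviving rows (data.frame with `smiles`, `mw`,
#'   `heavy_atoms`), with attribute `rejections` (named integer vector
#'   per rule).
#' @export
property_filter <- function(compounds, rules = default_property_rules()) {
  df <- if (is.data.frame(compounds)) compounds else
    data.frame(smiles = compounds, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    return(structure(df, rejections = integer(0)))
  }
  if (!length(rules)) {
    return(structure(df, rejections = stats::setNames(integer(0), character(0))))
  }
  props <- mol_properties(df$smiles)
  ok <- rep(TRUE, nrow(df))
  rej <- integer(0)
  if (!is.null(rules$mw)) {
    pass <- props$mw >= rules$mw[1] & props$mw <= rules$mw[2]
    rej["mw"] <- sum(!pass)
    ok <- ok & pass
  }
  if (!is.null(rules$heavy_atoms)) {
    pass <- props$heavy_atoms >= rules$heavy_atoms[1] &
      props$heavy_atoms <= rules$heavy_atoms[2]
    rej["heavy_atoms"] <- sum(!pass)
    ok <- ok & pass
  }
  if (!is.null(rules$elements)) {
    pass <- vapply(props$elements, function(el)
      all(el %in% rules$elements), logical(1))
    rej["elements"] <- sum(!pass)
    ok <- ok & pass
  }
  out <- df[ok, , drop = FALSE]
  out$mw <- props$mw[ok]
  out$heavy_atoms <- props$heavy_atoms[ok]
  rownames(out) <- NULL
  structure(out, rejections = rej)
}

#' Directed sphere exclusion diversity selection
#'
#' Scans candidates in descending score order (the "direction") and
#' keeps a candidate iff its Tanimoto distance to every already-kept
#' compound exceeds `radius`. The kept set is therefore pairwise
#' separated by more than `radius` by construction. Ties in score are
#' broken by input order.
#'
#' @param candidates a `ranked_predictions` table or any data.frame with
#'   `smiles` and `score` columns.
#' @param radius Tanimoto distance cutoff in `[0, 1]`.
#' @param max_n optional cap on the number kept.
#' @param fp optional precomputed `del_fp` aligned with `candidates`.
#' @param fp_radius,nbits fingerprint parameters when `fp` is not given
#'   (ECFP6-style 1024-bit by default).
#' @return the kept rows, in selection order, with a
#'   `nearest_kept_distance` column (distance to the closest previously
#'   kept compound; `NA` for the first).
#' @export
dise_select <- function(candidates, radius = 0.2, max_n = NULL, fp = NULL,
                        fp_radius = 3L, nbits = 1024L) {
  stopifnot(radius >= 0, radius <= 1)
  df <- data.table::as.data.table(candidates)
  if (!nrow(df)) return(df)
  ord <- order(-df$score)
  df <- df[ord]
  if (is.null(fp)) {
    fp <- fingerprint(df$smiles, radius = fp_radius, nbits = nbits)
  } else {
    fp <- fp[ord]
  }
  pops <- fp_popcount(fp)
  nb <- fp$nbits
  kept <- integer(0)
  kept_mat <- NULL   # rows = kept fingerprints
  kept_pops <- numeric(0)
  nearest <- numeric(0)
  if (is.null(max_n)) max_n <- nrow(df)
  for (i in seq_len(nrow(df))) {
    b <- fp$bits[[i]]
    if (length(kept) == 0L) {
      dmin <- NA_real_
      keep <- TRUE
    } else {
      inter <- if (length(b)) rowSums(kept_mat[, b, drop = FALSE]) else
        numeric(length(kept))
      sim <- ifelse(kept_pops + pops[i] - inter == 0, 0,
                    inter / (kept_pops + pops[i] - inter))
      dmin <- min(1 - sim)
      keep <- dmin > radius
    }
    if (keep) {
      kept <- c(kept, i)
      row <- numeric(nb); row[b] <- 1
      kept_mat <- rbind(kept_mat, row)
      kept_pops <- c(kept_pops, length(b))
      nearest <- c(nearest, dmin)
      if (length(kept) >= max_n) break
    }
  }
  out <- df[kept]
  out$nearest_kept_distance <- nearest
  out
}

#' Model-guided hit expansion
#'
#' Retrieves catalog analogs of a confirmed hit (ECFP6 Tanimoto
#' similarity above `sim_threshold`), ranks them with the scorer, and
#' diversifies the ranked list with [dise_select()].
#'
#' @param hit SMILES of the hit compound.
#' @param catalog character vector of catalog SMILES, or a data.frame
#'   with `id` and `smiles`.
#' @param sim_threshold similarity cutoff in `(0, 1]` (the conventional
#'   analog-retrieval default is 0.35).
#' @param scorer a `del_scorer` used to rank the analogs.
#' @param radius DISE Tanimoto distance cutoff.
#' @param max_n optional cap on returned analogs.
#' @param fp_radius,nbits fingerprint parameters for the similarity
#'   filter and DISE.
#' @return ranked, diversity-selected analogs with a `similarity_to_hit`
#'   column; zero rows with a warning when nothing passes the filter.
#' @export
hit_expand <- function(hit, catalog, sim_threshold = 0.35, scorer,
                       radius = 0.2, max_n = NULL, fp_radius = 3L,
                       nbits = 1024L) {
  stopifnot(sim_threshold > 0, sim_threshold <= 1)
  df <- if (is.data.frame(catalog)) data.table::as.data.table(catalog) else
    data.table::data.table(id = catalog, smiles = catalog)
  fp_cat <- fingerprint(df$smiles, radius = fp_radius, nbits = nbits)
  fp_hit <- fingerprint(hit, radius = fp_radius, nbits = nbits)
  sims <- as.numeric(tanimoto_matrix(fp_cat, fp_hit))
  pass <- sims >= sim_threshold
  if (!any(pass)) {
    warning("no catalog compound reaches similarity ", sim_threshold,
            " to the hit")
    out <- df[0]
    out$similarity_to_hit <- numeric(0)
    out$score <- numeric(0)
    return(out)
  }
  sub <- df[pass]
  sub$similarity_to_hit <- sims[pass]
  sub$score <- predict(scorer, sub$smiles)
  dise_select(sub, radius = radius, max_n = max_n,
              fp = fp_cat[which(pass)], fp_radius = fp_radius, nbits = nbits)
}
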
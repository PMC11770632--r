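# Disynthon aggregation, enrichment statistics and five-class labeling.
#
# Members are aggregated into disynthons (pairs of building blocks from
# two synthesis cycles; for 2-cycle libraries the member itself), a
# pseudocounted two-proportion z statistic is computed per condition
# against the appropriate reference, and each disynthon is assigned one
# of five classes: competitive_hit, noncompetitive_hit,
# promiscuous_binder, matrix_binder, non_hit (or target_hit replacing
# both hit classes when no competitor condition was run).

#' Aggregate a member-level count table into disynthons
#'
#' A 3-cycle member contributes its unique count to each of its three
#' cycle-pair disynthons; for a 2-cycle library the aggregation is the
#' identity (every member is its own disynthon).
#'
#' @param counts a `count_table` from [build_count_table()].
#' @return data.table with `library_id`, `cycle_pair` (e.g. `"1-2"`),
#'   `block_a`, `block_b`, `key`, `condition`, `k` (summed unique counts)
#'   and `N` (total unique molecules in that library and condition).
#' @export
aggregate_disynthons <- function(counts) {
  dt <- data.table::as.data.table(counts)
  block_cols <- sort(grep("^block[0-9]+$", names(dt), value = TRUE))
  n_cycles <- length(block_cols)
  if (!n_cycles %in% c(2L, 3L)) stop("expected 2 or 3 block columns")
  pairs <- utils::combn(seq_len(n_cycles), 2L, simplify = FALSE)
  views <- lapply(pairs, function(pr) {
    a <- block_cols[pr[1]]; b <- block_cols[pr[2]]
    v <- dt[, list(k = sum(unique_count)),
            by = c("library_id", "condition", a, b)]
    data.table::setnames(v, c(a, b), c("block_a", "block_b"))
    v$cycle_pair <- paste(pr, collapse = "-")
    v
  })
  out <- data.table::rbindlist(views, use.names = TRUE)
  totals <- dt[, list(N = sum(unique_count)), by = c("library_id", "condition")]
  out <- merge(out, totals, by = c("library_id", "condition"), sort = FALSE)
  out$key <- paste(out$library_id, out$cycle_pair, out$block_a, out$block_b,
                   sep = "|")
  data.table::setcolorder(out, c("library_id", "cycle_pair", "block_a",
                                 "block_b", "key", "condition", "k", "N"))
  out[]
}

#' Two-proportion enrichment z statistic with pseudocounts
#'
#' `p_i = (k_i + c) / (N_i + c)`, pooled
#' `p = (k_sel + k_ref + 2c) / (N_sel + N_ref + 2c)`, and
#' `z = (p_sel - p_ref) / sqrt(p (1 - p) (1/N_sel + 1/N_ref))`.
#' The statistic is antisymmetric: swapping the selected and reference
#' roles negates it. All arguments recycle.
#'
#' @param k_sel,N_sel unique count and total in the selected condition.
#' @param k_ref,N_ref unique count and total in the reference condition.
#' @param pseudocount additive regularizer keeping z finite at zero counts.
#' @return numeric z score(s).
#' @export
enrichment_statistic <- function(k_sel, N_sel, k_ref, N_ref, pseudocount = 0.5) {
  if (any(N_sel <= 0) || any(N_ref <= 0)) stop("totals must be positive")
  c0 <- pseudocount
  p_sel <- (k_sel + c0) / (N_sel + c0)
  p_ref <- (k_ref + c0) / (N_ref + c0)
  p_bar <- (k_sel + k_ref + 2 * c0) / (N_sel + N_ref + 2 * c0)
  (p_sel - p_ref) / sqrt(p_bar * (1 - p_bar) * (1 / N_sel + 1 / N_ref))
}

.dcast_counts <- function(dis) {
  wide <- data.table::dcast(dis, library_id + cycle_pair + block_a + block_b + key ~
                              condition, value.var = c("k", "N"), fill = 0)
  # a disynthon absent from a condition has k = 0 but the condition total
  # is still that condition's N
  for (cond in unique(dis$condition)) {
    ncol_ <- paste0("N_", cond)
    tot <- unique(dis[dis$condition == cond, c("library_id", "N")])
    wide[[ncol_]] <- tot$N[match(wide$library_id, tot$library_id)]
  }
  wide
}

#' Assign five-class labels to disynthons
#'
#' Enrichment is computed per disynthon as
#' `z_target` (target vs no_target), `z_comp` (target_plus_competitor vs
#' no_target, when present) and `z_matrix` (no_target vs input pool;
#' a uniform input pool is assumed when no `input_pool` condition is in
#' the table). A disynthon counts as *enriched* in a comparison when its
#' z reaches `z_star` and its selected-side count reaches `k_min`.
#' Classes are assigned with top-down precedence:
#' \enumerate{
#'   \item `matrix_binder` if enriched in no_target vs input pool;
#'   \item `promiscuous_binder` if enriched against > 50% of a panel of
#'     at least 3 targets (requires `panel`);
#'   \item `competitive_hit` if enriched in target and
#'     `z_comp < z_star * comp_factor`;
#'   \item `noncompetitive_hit` if enriched in target and
#'     `z_comp >= z_star * comp_factor`;
#'   \item `non_hit` otherwise.
#' }
#' Without a competitor condition both hit classes merge into
#' `target_hit`.
#'
#' @param dis disynthon table from [aggregate_disynthons()]; must contain
#'   `no_target` and `target` conditions.
#' @param z_star enrichment threshold on z.
#' @param k_min minimum selected-side unique count to call enrichment.
#' @param comp_factor competition criterion: "not enriched with
#'   competitor" means `z_comp < z_star * comp_factor`.
#' @param n_disynthons number of disynthons per cycle-pair view used for
#'   the uniform input-pool expectation; defaults to the number of
#'   distinct keys observed in the view.
#' @param panel optional data.frame (`key`, `target`, `enriched`) of
#'   enrichment calls for the same disynthons against other targets.
#' @return data.table with per-condition counts, `z_target`, `z_comp`,
#'   `z_matrix`, and `class`.
#' @export
assign_classes <- function(dis, z_star = 6, k_min = 5L, comp_factor = 0.5,
                           n_disynthons = NULL, panel = NULL) {
  dis <- data.table::as.data.table(dis)
  conds <- unique(dis$condition)
  if (!"no_target" %in% conds) stop("no_target condition is required")
  if (!"target" %in% conds) stop("target condition is required")
  has_comp <- "target_plus_competitor" %in% conds
  has_pool <- "input_pool" %in% conds

  wide <- .dcast_counts(dis)
  wide[is.na(wide)] <- 0

  wide$z_target <- enrichment_statistic(wide$k_target, wide$N_target,
                                        wide$k_no_target, wide$N_no_target)
  if (has_comp) {
    wide$z_comp <- enrichment_statistic(wide$k_target_plus_competitor,
                                        wide$N_target_plus_competitor,
                                        wide$k_no_target, wide$N_no_target)
  } else {
    wide$z_comp <- NA_real_
  }
  if (has_pool) {
    wide$z_matrix <- enrichment_statistic(wide$k_no_target, wide$N_no_target,
                                          wide$k_input_pool, wide$N_input_pool)
  } else {
    # uniform input pool: expected share 1/n_disynthons of the same total
    nd <- wide[, list(nd = .N), by = c("library_id", "cycle_pair")]
    wide <- merge(wide, nd, by = c("library_id", "cycle_pair"), sort = FALSE)
    if (!is.null(n_disynthons)) wide$nd <- n_disynthons
    wide$z_matrix <- enrichment_statistic(wide$k_no_target, wide$N_no_target,
                                          wide$N_no_target / wide$nd,
                                          wide$N_no_target)
    wide$nd <- NULL
  }

  enriched_target <- wide$z_target >= z_star & wide$k_target >= k_min
  enriched_matrix <- wide$z_matrix >= z_star & wide$k_no_target >= k_min

  promiscuous <- rep(FALSE, nrow(wide))
  if (!is.null(panel)) {
    pan <- data.table::as.data.table(panel)
    ntarg <- length(unique(pan$target))
    if (ntarg >= 3L) {
      frac <- pan[, list(frac = mean(enriched)), by = "key"]
      promiscuous <- frac$frac[match(wide$key, frac$key)] > 0.5
      promiscuous[is.na(promiscuous)] <- FALSE
    }
  }

  cls <- rep("non_hit", nrow(wide))
  if (has_comp) {
    not_comp_enriched <- wide$z_comp < z_star * comp_factor
    cls[enriched_target & !not_comp_enriched] <- "noncompetitive_hit"
    cls[enriched_target & not_comp_enriched] <- "competitive_hit"
  } else {
    cls[enriched_target] <- "target_hit"
  }
  cls[promiscuous] <- "promiscuous_binder"
  cls[enriched_matrix] <- "matrix_binder"
  wide$class <- cls
  wide$enriched_target <- enriched_target
  wide[]
}

#' Select positive training examples (PTEs)
#'
#' The PTE class is `competitive_hit` when a competitor condition was run
#' and `target_hit` otherwise. Each PTE disynthon is expanded to the
#' SMILES of all library members that carry it.
#'
#' @param labels output of [assign_classes()].
#' @param lib the `encoded_library` the counts came from.
#' @param competitor_present whether the screen included a competitor
#'   condition.
#' @return data.table with `key`, `member_id`, `smiles` (one row per PTE
#'   member); zero rows with a warning when no disynthon qualifies. The
#'   label table with an `is_PTE` flag is attached as attribute `labels`.
#' @export
select_ptes <- function(labels, lib, competitor_present = TRUE) {
  stopifnot(inherits(lib, "encoded_library"))
  labels <- data.table::as.data.table(labels)
  pte_class <- if (competitor_present) "competitive_hit" else "target_hit"
  labels$is_PTE <- labels$class == pte_class
  pte <- labels[labels$is_PTE]
  if (!nrow(pte)) {
    warning("no positive training examples: PTE class '", pte_class,
            "' is empty; model training is blocked")
    out <- data.table::data.table(member_id = character(0),
                                  smiles = character(0))
    out$key <- character(0)
    data.table::setcolorder(out, c("key", "member_id", "smiles"))
    return(structure(out, labels = labels))
  }
  mem <- lib$members
  rows <- lapply(seq_len(nrow(pte)), function(r) {
    cyc <- as.integer(strsplit(pte$cycle_pair[r], "-")[[1]])
    sel <- mem[[paste0("block", cyc[1])]] == pte$block_a[r] &
      mem[[paste0("block", cyc[2])]] == pte$block_b[r]
    dt <- data.table::data.table(member_id = mem$member_id[sel],
                                 smiles = mem$smiles[sel])
    dt$key <- pte$key[r]
    data.table::setcolorder(dt, c("key", "member_id", "smiles"))
    dt
  })
  out <- unique(data.table::rbindlist(rows))
  structure(out, labels = labels)
}
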
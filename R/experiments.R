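# Validation experiments over the synthetic screen: the study-condition
# defaults live here so the analysis scripts, the test suite and the
# acceptance script all run the identical computation.

#' Simulate a planted screen and return labels plus truth
#'
#' Runs the canonical three-condition screen (no target / target /
#' target + competitor, two selection cycles) on a freshly generated
#' library with planted ground truth, decodes and counts the reads, and
#' assigns disynthon classes. Planted binders have KD equal to the
#' target concentration (occupancy 0.5 per cycle), giving them a ~50x
#' per-cycle capture advantage over the 0.01 background matrix capture.
#'
#' @param n_blocks per-cycle block counts.
#' @param depth reads per condition.
#' @param n_competitive,n_noncompetitive,n_matrix planted role counts
#'   (motif mode for the target binders).
#' @param seed integer seed for the whole screen.
#' @return list with `lib`, `counts`, `labels`, and per-member `truth` /
#'   assigned `class` vectors aligned with `lib$members`.
#' @export
run_planted_screen <- function(n_blocks = c(50L, 50L), depth = 1e5,
                               n_competitive = 5L, n_noncompetitive = 3L,
                               n_matrix = 25L, seed = 1L) {
  lib <- generate_library(n_blocks, seed = seed, validate = FALSE)
  lib <- plant_binders(lib, n_competitive = n_competitive,
                       n_noncompetitive = n_noncompetitive,
                       n_matrix = n_matrix,
                       affinity_range = c(1e-6, 1e-6),
                       motif_mode = TRUE, seed = .derive_seed(seed, 1L))
  conds <- list(
    no_target = selection_condition("no_target"),
    target = selection_condition("target", target_concentration = 1e-6),
    target_plus_competitor = selection_condition(
      "target_plus_competitor", target_concentration = 1e-6,
      competitor_concentration = 1e-4))
  readsets <- lapply(seq_along(conds), function(i)
    simulate_selection(lib, conds[[i]], depth = depth,
                       seed = .derive_seed(seed, 10L + i)))
  counts <- count_selections(readsets, tag_schema(lib))
  labels <- assign_classes(aggregate_disynthons(counts),
                           n_disynthons = nrow(lib$members))
  mem <- lib$members
  cls <- labels$class[match(paste0(mem$block1, "|", mem$block2),
                            paste0(labels$block_a, "|", labels$block_b))]
  truth <- rep("null", nrow(mem))
  truth[!is.na(mem$target_affinity) & !mem$competitive] <- "noncompetitive"
  truth[!is.na(mem$target_affinity) & mem$competitive] <- "competitive"
  truth[mem$is_promiscuous] <- "promiscuous"
  truth[mem$is_matrix_binder] <- "matrix"
  list(lib = lib, counts = counts, labels = labels, truth = truth,
       class = cls)
}

#' Label-recovery study over replicate screens
#'
#' Repeats [run_planted_screen()] over seeds and pools per-member
#' confusion counts: the sensitivity of competitive-hit and
#' matrix-binder calls against the planted truth and the specificity of
#' non-hit calls (members absent from the count table are counted as
#' non-hits).
#'
#' @param seeds integer vector of screen seeds.
#' @param ... forwarded to [run_planted_screen()].
#' @return list with `sensitivity_competitive`, `sensitivity_matrix`,
#'   `specificity_nonhit` and the pooled `counts` table.
#' @export
label_recovery_study <- function(seeds = 1:10, ...) {
  tallies <- lapply(seeds, function(s) {
    scr <- run_planted_screen(seed = s, ...)
    cls <- scr$class
    cls[is.na(cls)] <- "non_hit"
    c(comp_n = sum(scr$truth == "competitive"),
      comp_ok = sum(cls[scr$truth == "competitive"] == "competitive_hit"),
      mat_n = sum(scr$truth == "matrix"),
      mat_ok = sum(cls[scr$truth == "matrix"] == "matrix_binder"),
      null_n = sum(scr$truth == "null"),
      null_ok = sum(cls[scr$truth == "null"] == "non_hit"))
  })
  m <- do.call(rbind, tallies)
  tot <- colSums(m)
  list(sensitivity_competitive = unname(tot["comp_ok"] / tot["comp_n"]),
       sensitivity_matrix = unname(tot["mat_ok"] / tot["mat_n"]),
       specificity_nonhit = unname(tot["null_ok"] / tot["null_n"]),
       counts = m)
}

#' Planted-analog enrichment study for the forest ensemble
#'
#' One scaled screen supplies positives (competitive-hit members) and
#' negatives (non-hit members). For each model seed, a forest ensemble
#' (`n_models` x `n_trees` trees, `n_negatives` negatives per model) is
#' trained, a fresh synthetic catalog of `catalog_size` compounds with
#' `n_analogs` planted analogs of the positives is scored, and the
#' number of planted analogs within the top 100 ensemble predictions is
#' counted. The random expectation is `100 * n_analogs / catalog_size`.
#'
#' @param model_seeds seeds for the training/catalog replicates.
#' @param screen_seed seed of the shared screen.
#' @param n_blocks,depth screen scale.
#' @param n_models,n_trees,n_negatives forest ensemble scale.
#' @param catalog_size,n_analogs catalog composition.
#' @return list with `top100_analogs` (per seed), `expectation`,
#'   `enrichment_factors`, and the trained models' holdout accuracies.
#' @export
analog_enrichment_study <- function(model_seeds = 1:5, screen_seed = 8001L,
                                    n_blocks = c(105L, 105L), depth = 3e5,
                                    n_models = 5L, n_trees = 100L,
                                    n_negatives = 1e4L,
                                    catalog_size = 5e4L, n_analogs = 100L) {
  scr <- run_planted_screen(n_blocks = n_blocks, depth = depth,
                            seed = screen_seed)
  ptes <- select_ptes(scr$labels, scr$lib, competitor_present = TRUE)
  nonhit <- select_members(scr$labels, scr$lib,
                           scr$labels$key[scr$labels$class == "non_hit"])
  pos <- unique(ptes$smiles)
  neg <- unique(nonhit$smiles)
  fp_pool <- fingerprint(unique(c(pos, neg)), radius = 2L, nbits = 1024L)

  accs <- list()
  top100 <- vapply(model_seeds, function(s) {
    sets <- build_training_sets(pos, neg, n_models = n_models,
                                n_negatives = n_negatives,
                                seed = .derive_seed(s, 900L))
    scorers <- lapply(seq_len(n_models), function(i)
      train_forest(sets[[i]], n_trees = n_trees,
                   seed = .derive_seed(s, 910L + i), fp = fp_pool))
    accs[[as.character(s)]] <<- vapply(scorers, function(x) x$accuracy,
                                       numeric(1))
    catalog <- generate_catalog(catalog_size, seed = .derive_seed(s, 950L),
                                analogs_of = pos, n_analogs = n_analogs)
    rp <- ensemble_score(scorers, catalog)
    sum(catalog$is_planted_analog[match(rp$id[seq_len(100)], catalog$id)])
  }, numeric(1))

  expectation <- 100 * n_analogs / catalog_size
  list(top100_analogs = top100, expectation = expectation,
       enrichment_factors = top100 / expectation,
       holdout_accuracies = accs)
}

#' Parameter-recovery study for the binding-model fits
#'
#' Simulate-then-fit round trips at the stated noise levels: steady
#' state (2% CV, 8-point 3-fold series), kinetics (2% CV), and thermal
#' melt (1% CV, 1 degree C sampling).
#'
#' @param n_seeds replicates per assay.
#' @return list of median relative errors (`kd_steady`, `ka_kinetic`,
#'   `kd_kinetic`) and the median absolute `tm` error (degrees C), plus
#'   the maximal noiseless relative residual across all four fit kinds
#'   (`noiseless_residual`).
#' @export
bindfit_recovery_study <- function(n_seeds = 100L) {
  kd_true <- 18e-6
  kd_err <- vapply(seq_len(n_seeds), function(s) {
    ts <- simulate_assay("spr_steady", list(KD = kd_true, Rmax = 50),
                         list(top = 90e-6, dilution = 3, n_points = 8),
                         cv = 0.02, seed = s)
    abs(fit_steady_state(ts)$parameters[["KD"]] - kd_true) / kd_true
  }, numeric(1))

  des <- list(time = seq(0, 600, by = 4),
              concentrations = c(2e-6, 6e-6, 18e-6, 54e-6), t_assoc = 300)
  kin_err <- vapply(seq_len(n_seeds), function(s) {
    sg <- simulate_assay("spr_kinetic", list(ka = 1e5, kd = 1e-2, Rmax = 80),
                         des, cv = 0.02, seed = s)
    f <- fit_kinetic_1to1(sg)
    c(abs(f$parameters[["ka"]] - 1e5) / 1e5,
      abs(f$parameters[["kd"]] - 1e-2) / 1e-2)
  }, numeric(2))

  tm_err <- vapply(seq_len(n_seeds), function(s) {
    d <- simulate_assay("dsf", list(Tm = 52, slope = 2, Fmin = 100,
                                    Fmax = 1000),
                        list(temperatures = seq(25, 85)), cv = 0.01, seed = s)
    abs(fit_boltzmann_tm(d$temperature, d$fluorescence)$parameters[["Tm"]] - 52)
  }, numeric(1))

  # noiseless residuals across the four fit kinds, relative to the
  # response scale
  r1 <- fit_steady_state(simulate_assay("spr_steady",
                                        list(KD = kd_true, Rmax = 50),
                                        list(top = 90e-6, dilution = 3,
                                             n_points = 8), cv = 0, seed = 1))
  r2 <- fit_kinetic_1to1(simulate_assay("spr_kinetic",
                                        list(ka = 1e5, kd = 1e-2, Rmax = 80),
                                        des, cv = 0, seed = 1))
  r3 <- fit_boltzmann_tm_wrap()
  r4 <- fit_fp_displacement(simulate_assay("fp",
                                           list(Kdisp = 1e-6, hill = 1,
                                                top = 200, bottom = 50),
                                           list(concentrations = 1e-4 / 3^(11:0)),
                                           cv = 0, seed = 1))
  noiseless <- max(r1$residual_norm / 50, r2$residual_norm / 80,
                   r3$residual_norm / 900, r4$residual_norm / 200)

  list(kd_steady = stats::median(kd_err),
       ka_kinetic = stats::median(kin_err[1, ]),
       kd_kinetic = stats::median(kin_err[2, ]),
       tm = stats::median(tm_err),
       noiseless_residual = noiseless)
}

# noiseless melt fit used by the recovery study
fit_boltzmann_tm_wrap <- function() {
  d <- simulate_assay("dsf", list(Tm = 52, slope = 2, Fmin = 100, Fmax = 1000),
                      list(temperatures = seq(25, 85)), cv = 0, seed = 1)
  fit_boltzmann_tm(d$temperature, d$fluorescence)
}
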
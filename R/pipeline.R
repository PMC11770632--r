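# End-to-end orchestration: simulate -> decode -> enrich -> train ->
# predict -> select, with per-stage derived seeds, a JSON manifest and
# reproducible on-disk artifacts.

.PIPELINE_STAGES <- c("simulate", "decode", "enrich", "train", "predict", "select")

#' Derive the seed of a pipeline stage from the root seed
#'
#' @param root_seed integer root seed.
#' @param stage stage name.
#' @return integer seed, stable in (root_seed, stage).
#' @export
stage_seed <- function(root_seed, stage) {
  i <- match(stage, .PIPELINE_STAGES)
  if (is.na(i)) stop("unknown stage: ", stage)
  .derive_seed(root_seed, 100L + i)
}

#' Build a pipeline run configuration
#'
#' Bundles every stage's parameters with a root seed. The `toy` profile
#' is a minutes-scale smoke screen; `desk` matches the scaled study
#' conditions used by the package's validation suite (2-cycle 50x50
#' library, 1e5 reads per condition, ~50x occupancy advantage for
#' planted binders).
#'
#' @param profile `"toy"` or `"desk"`.
#' @param seed root seed; all stage seeds derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(profile = c("toy", "desk"), seed = 1L) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile,
    seed = as.integer(seed),
    library = list(n_blocks = c(10L, 10L), tag_length = 8L),
    planted = list(n_competitive = 2L, n_noncompetitive = 1L,
                   n_matrix = 5L, n_promiscuous = 0L,
                   affinity_range = c(1e-6, 1e-6), motif_mode = TRUE),
    selection = list(depth = 10000L, pcr_dup_rate = 0.1,
                     seq_error_rate = 0.001,
                     target_concentration = 1e-6,
                     competitor_concentration = 1e-4,
                     matrix_capture_prob = 0.01,
                     matrix_binder_capture = 0.5,
                     kd_comp = 1e-6),
    thresholds = list(z_star = 6, k_min = 5L, comp_factor = 0.5),
    models = list(n_models = 3L, n_trees = 50L, min_split = 5L,
                  n_negatives = 60L, pos_fraction = 0.9, holdout = 0.1),
    catalog = list(size = 400L, n_analogs = 20L),
    purchase = list(rules = list(mw = c(150, 550), heavy_atoms = c(10L, 40L),
                                 elements = c("C", "N", "O", "S", "F",
                                              "Cl", "Br", "H")),
                    dise_radius = 0.2, max_n = 50L)
  )
  if (profile == "desk") {
    base$library$n_blocks <- c(50L, 50L)
    base$planted$n_competitive <- 5L
    base$planted$n_noncompetitive <- 3L
    base$planted$n_matrix <- 25L
    base$selection$depth <- 100000L
    base$models$n_models <- 5L
    base$models$n_trees <- 100L
    base$models$n_negatives <- 1000L
    base$catalog$size <- 5000L
    base$catalog$n_analogs <- 100L
  }
  structure(base, class = "run_config")
}

#' Generate a synthetic commercial catalog
#'
#' Random 2-cycle assemblies from the fragment pool, optionally seeded
#' with structural analogs of given active compounds (an analog is an
#' active member decorated with a small N-substituent, so it shares most
#' of its circular-fingerprint environments with the active).
#'
#' @param n catalog size.
#' @param seed integer seed.
#' @param analogs_of optional character vector of active SMILES to plant
#'   analogs of.
#' @param n_analogs number of planted analogs (included in `n`).
#' @return data.table with `id`, `smiles`, `is_planted_analog`.
#' @export
generate_catalog <- function(n, seed = 1L, analogs_of = NULL, n_analogs = 0L) {
  n <- as.integer(n)
  if (n_analogs > 0 && is.null(analogs_of))
    stop("analogs_of is required when n_analogs > 0")
  pool <- sub("^\\*", "", fragment_pool())
  with_seed(seed, {
    decorations <- c("C", "CC", "CCC", "CCCC", "CC(C)", "CCO", "CCN",
                     "CCOC", "CCCO", "C1CCCCC1", "C1CCCC1", "CCCC(C)",
                     "CCF", "CCCN", "CC#N", "CCCl", "CCBr", "CCCOC",
                     "CC(C)C", "CCCCC")
    analogs <- character(0)
    if (n_analogs > 0) {
      combos <- data.table::CJ(a = seq_along(analogs_of),
                               d = seq_along(decorations))
      combos <- combos[sample(nrow(combos), min(n_analogs, nrow(combos)))]
      if (nrow(combos) < n_analogs)
        stop("cannot plant ", n_analogs, " distinct analogs from ",
             length(analogs_of), " actives")
      # append at the tail, distal to the shared scaffold, so an analog
      # keeps most of its parent's circular environments
      analogs <- paste0(analogs_of[combos$a], decorations[combos$d])
    }
    n_bg <- n - length(analogs)
    bg <- character(0)
    while (length(bg) < n_bg) {
      f1 <- sample(pool, n_bg, replace = TRUE)
      f2 <- sample(pool, n_bg, replace = TRUE)
      deco <- sample(c("", decorations), n_bg, replace = TRUE)
      bg <- unique(c(bg, sprintf("N(%s%s)C(=O)%s",
                                 ifelse(deco == "", "", paste0(deco, "")),
                                 f1, f2)))
      bg <- setdiff(bg, analogs)
    }
    bg <- bg[seq_len(n_bg)]
    smiles <- c(analogs, bg)
    out <- data.table::data.table(
      id = sprintf("CAT%06d", seq_len(n)),
      smiles = smiles,
      is_planted_analog = c(rep(TRUE, length(analogs)), rep(FALSE, n_bg)))
    out[sample(n)]  # shuffle so analogs are not clustered at the top
  })
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full hit-finding pipeline
#'
#' Executes simulate -> decode -> enrich -> train -> predict -> select
#' under a single configuration, writing every stage artifact plus a
#' JSON manifest (stage seeds, row counts, file digests) into `out_dir`.
#' Rerunning with the same configuration reproduces the artifacts.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("delscreen")),
                   profile = config$profile, root_seed = config$seed,
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(seed = stage_seed(config$seed, stage)), list(...))
  }

  # -- simulate ------------------------------------------------------
  sim <- .stage("simulate", {
    s <- stage_seed(config$seed, "simulate")
    lib <- generate_library(config$library$n_blocks, seed = s,
                            tag_length = config$library$tag_length)
    lib <- do.call(plant_binders, c(list(lib = lib, seed = .derive_seed(s, 2L)),
                                    config$planted))
    sel <- config$selection
    conds <- list(
      no_target = selection_condition("no_target",
                                      matrix_capture_prob = sel$matrix_capture_prob),
      target = selection_condition("target",
                                   target_concentration = sel$target_concentration,
                                   matrix_capture_prob = sel$matrix_capture_prob),
      target_plus_competitor = selection_condition(
        "target_plus_competitor",
        target_concentration = sel$target_concentration,
        competitor_concentration = sel$competitor_concentration,
        matrix_capture_prob = sel$matrix_capture_prob))
    readsets <- lapply(seq_along(conds), function(i)
      simulate_selection(lib, conds[[i]], depth = sel$depth,
                         pcr_dup_rate = sel$pcr_dup_rate,
                         seq_error_rate = sel$seq_error_rate,
                         seed = .derive_seed(s, 10L + i),
                         matrix_binder_capture = sel$matrix_binder_capture,
                         kd_comp = sel$kd_comp))
    names(readsets) <- names(conds)
    schema <- tag_schema(lib)
    for (nm in names(readsets))
      write_fastq(readsets[[nm]], file.path(out_dir, paste0(nm, ".fastq")))
    write_tag_schema(schema, file.path(out_dir, "schema.json"))
    data.table::fwrite(lib$members, file.path(out_dir, "library.csv"))
    list(lib = lib, schema = schema, readsets = readsets)
  })
  note("simulate", n_members = nrow(sim$lib$members),
       reads_per_condition = vapply(sim$readsets, function(r) length(r$reads),
                                    integer(1)))

  # -- decode --------------------------------------------------------
  counts <- .stage("decode", {
    schema <- read_tag_schema(file.path(out_dir, "schema.json"))
    rs <- lapply(names(sim$readsets), function(nm) {
      reads <- read_fastq(file.path(out_dir, paste0(nm, ".fastq")))
      dedupe(decode_reads(reads, schema, condition = nm))
    })
    ct <- build_count_table(data.table::rbindlist(rs), schema)
    write_count_table(ct, file.path(out_dir, "counts.tsv"))
    ct
  })
  note("decode", n_rows = nrow(counts),
       unique_molecules = sum(counts$unique_count))

  # -- enrich --------------------------------------------------------
  enr <- .stage("enrich", {
    dis <- aggregate_disynthons(counts)
    th <- config$thresholds
    labels <- assign_classes(dis, z_star = th$z_star, k_min = th$k_min,
                             comp_factor = th$comp_factor,
                             n_disynthons = nrow(sim$lib$members))
    ptes <- select_ptes(labels, sim$lib, competitor_present = TRUE)
    data.table::fwrite(attr(ptes, "labels"), file.path(out_dir, "enrichment.tsv"),
                       sep = "\t")
    writeLines(paste(ptes$smiles, ptes$member_id),
               file.path(out_dir, "ptes.smi"))
    list(labels = attr(ptes, "labels"), ptes = ptes)
  })
  note("enrich", n_disynthons = nrow(enr$labels),
       class_counts = as.list(table(enr$labels$class)),
       n_pte_members = nrow(enr$ptes))

  # -- train ---------------------------------------------------------
  trained <- .stage("train", {
    s <- stage_seed(config$seed, "train")
    mc <- config$models
    nonhit_keys <- enr$labels$key[enr$labels$class == "non_hit"]
    nonhit <- select_members(enr$labels, sim$lib, nonhit_keys)
    if (!nrow(enr$ptes)) stop("no positive training examples")
    sets <- build_training_sets(unique(enr$ptes$smiles), unique(nonhit$smiles),
                                n_models = mc$n_models,
                                n_negatives = min(mc$n_negatives,
                                                  length(unique(nonhit$smiles))),
                                pos_fraction = mc$pos_fraction,
                                holdout = mc$holdout, seed = s)
    scorers <- lapply(seq_along(sets), function(i)
      train_forest(sets[[i]], n_trees = mc$n_trees, min_split = mc$min_split,
                   seed = .derive_seed(s, 50L + i)))
    best <- select_best_forest(scorers)
    jsonlite::write_json(
      list(n_models = length(scorers),
           accuracies = vapply(scorers, function(x) x$accuracy, numeric(1)),
           selected = best$meta$selected_index),
      file.path(out_dir, "models.json"), auto_unbox = TRUE, digits = NA)
    list(scorers = scorers, best = best)
  })
  note("train", n_models = length(trained$scorers),
       best_accuracy = trained$best$accuracy)

  # -- predict -------------------------------------------------------
  preds <- .stage("predict", {
    s <- stage_seed(config$seed, "predict")
    cat_ <- generate_catalog(config$catalog$size, seed = s,
                             analogs_of = unique(enr$ptes$smiles),
                             n_analogs = config$catalog$n_analogs)
    rp <- ensemble_score(trained$scorers, cat_)
    rp$is_planted_analog <- cat_$is_planted_analog[match(rp$id, cat_$id)]
    data.table::fwrite(rp, file.path(out_dir, "predictions.csv"))
    rp
  })
  note("predict", n_compounds = nrow(preds),
       analogs_in_top100 = sum(preds$is_planted_analog[seq_len(min(100, nrow(preds)))]))

  # -- select --------------------------------------------------------
  purchase <- .stage("select", {
    pc <- config$purchase
    surv <- property_filter(as.data.frame(preds), rules = pc$rules)
    picked <- dise_select(surv, radius = pc$dise_radius, max_n = pc$max_n)
    picked$rank <- seq_len(nrow(picked))
    data.table::fwrite(picked[, c("rank", "id", "smiles", "score",
                                  "nearest_kept_distance")],
                       file.path(out_dir, "purchase_list.csv"))
    list(picked = picked, n_surv = nrow(surv))
  })
  note("select", n_after_property_filter = purchase$n_surv,
       n_purchase = nrow(purchase$picked))

  manifest$files <- as.list(tools::md5sum(
    sort(list.files(out_dir, full.names = TRUE,
                    pattern = "\\.(csv|tsv|json|smi|fastq)$"))))
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Expand disynthon keys to member SMILES
#'
#' @param labels a label table from [assign_classes()].
#' @param lib the `encoded_library`.
#' @param keys disynthon keys to expand.
#' @return data.table with `key`, `member_id`, `smiles`.
#' @export
select_members <- function(labels, lib, keys) {
  labels <- data.table::as.data.table(labels)
  sel <- labels[labels$key %in% keys]
  mem <- lib$members
  rows <- lapply(seq_len(nrow(sel)), function(r) {
    cyc <- as.integer(strsplit(sel$cycle_pair[r], "-")[[1]])
    hit <- mem[[paste0("block", cyc[1])]] == sel$block_a[r] &
      mem[[paste0("block", cyc[2])]] == sel$block_b[r]
    dt <- data.table::data.table(member_id = mem$member_id[hit],
                                 smiles = mem$smiles[hit])
    dt$key <- sel$key[r]
    data.table::setcolorder(dt, c("key", "member_id", "smiles"))
    dt
  })
  unique(data.table::rbindlist(rows))
}

#' Materialize the canonical test fixture screen
#'
#' Runs the pipeline for the requested profile into a directory.
#'
#' @param profile `"toy"` or `"desk"`.
#' @param seed root seed.
#' @param out_dir target directory; a temporary one by default.
#' @return path to the fixture directory.
#' @export
make_fixtures <- function(profile = "toy", seed = 1L,
                          out_dir = tempfile("delscreen_fixtures_")) {
  config <- run_config(profile, seed = seed)
  run_pipeline(config, out_dir)
  out_dir
}
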
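# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a small planted screen: [20,20] library, 2 competitive + 1 noncompetitive
# motifs, 8 matrix binders, 3 parallel conditions at depth 3e4
small_screen <- function() {
  memo("small_screen", function() {
    lib <- generate_library(c(20L, 20L), seed = 101, validate = FALSE)
    lib <- plant_binders(lib, n_competitive = 2, n_noncompetitive = 1,
                         n_matrix = 8, affinity_range = c(1e-6, 1e-6),
                         motif_mode = TRUE, seed = 102)
    conds <- list(
      no_target = selection_condition("no_target"),
      target = selection_condition("target", target_concentration = 1e-6),
      target_plus_competitor = selection_condition(
        "target_plus_competitor", target_concentration = 1e-6,
        competitor_concentration = 1e-4))
    readsets <- lapply(seq_along(conds), function(i)
      simulate_selection(lib, conds[[i]], depth = 3e4, pcr_dup_rate = 0.1,
                         seq_error_rate = 0.001, seed = 110 + i))
    names(readsets) <- names(conds)
    schema <- tag_schema(lib)
    counts <- count_selections(readsets, schema)
    list(lib = lib, conds = conds, readsets = readsets, schema = schema,
         counts = counts)
  })
}

# separable two-class SMILES fixture: positives share a para-fluorophenyl
# amide scaffold, negatives a piperidine amide scaffold
separable_classes <- function() {
  tails_pos <- c("CCO", "CCN", "CCC", "CCOC", "CCCO", "CCCN", "CC(C)C",
                 "CCCC", "CC#N", "CCF", "CCCl", "CC(C)O", "C1CCCCC1",
                 "C1CCCC1", "CCCCC", "CC(=O)N", "CCC(=O)N", "CCCOC",
                 "CC(F)(F)F", "CCS(C)(=O)=O")
  tails_neg <- c("c1ccccc1", "c1ccncc1", "c1cccnc1", "c1ccco1", "c1cccs1",
                 "Cc1ccccc1", "c1ccc(Cl)cc1", "c1ccc(Br)cc1", "c1cccc(F)c1",
                 "c1ccc(OC)cc1", "c1ccc(N)cc1", "c1ccc(C)cc1", "Cc1ccncc1",
                 "Cc1ccco1", "c1cc[nH]c1", "CCc1ccccc1", "c1ccc(O)cc1",
                 "c1cccc(Cl)c1", "c1cccc(C)c1", "c1ccccc1C")
  list(pos = paste0("N(c1ccc(F)cc1)C(=O)", tails_pos),
       neg = paste0("N(C1CCNCC1)C(=O)", tails_neg))
}

# hand-constructed fingerprint set from explicit bit positions
fp_from_bits <- function(bits, nbits = 16L, radius = 2L) {
  structure(list(bits = lapply(bits, function(b) sort(as.integer(b))),
                 nbits = as.integer(nbits), radius = as.integer(radius),
                 ids = paste0("m", seq_along(bits)),
                 smiles = rep(NA_character_, length(bits))),
            class = "del_fp")
}

# random sparse fingerprint set
random_fps <- function(n, nbits = 1024L, density = 0.04, radius = 3L, seed = 1L) {
  withr::with_seed(seed, {
    fp_from_bits(lapply(seq_len(n), function(i)
      which(stats::runif(nbits) < density)), nbits = nbits, radius = radius)
  })
}
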
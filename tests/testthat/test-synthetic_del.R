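# Synthetic library generation, binder planting and selection simulation.

test_that("library combinatorics and determinism", {
  lib <- generate_library(c(3, 3), seed = 1)
  expect_equal(nrow(lib$members), 9L)
  expect_equal(length(unique(lib$members$tag)), 9L)
  expect_true(all(validate_smiles(lib$members$smiles)))

  lib2 <- generate_library(c(3, 3), seed = 1)
  expect_identical(lib, lib2)
  lib3 <- generate_library(c(3, 3), seed = 2)
  expect_false(identical(lib$members$smiles, lib3$members$smiles))

  big <- generate_library(c(10, 10, 10), n_cycles = 3, seed = 7, validate = FALSE)
  expect_equal(nrow(big$members), 1000L)
  expect_equal(anyDuplicated(big$members$tag), 0L)
})

test_that("library preconditions are enforced", {
  expect_error(generate_library(c(3, 3, 3, 3), n_cycles = 4), "2 or 3")
  expect_error(generate_library(c(1, 5), seed = 1), "at least 2")
  expect_error(generate_library(c(5000, 5), seed = 1), "fragment pool")
})

test_that("tags decode uniquely back to block tuples", {
  lib <- generate_library(c(5, 4), seed = 3)
  schema <- tag_schema(lib)
  for (r in sample(nrow(lib$members), 5)) {
    m <- lib$members[r, ]
    t1 <- substr(m$tag, 1, 8); t2 <- substr(m$tag, 9, 16)
    expect_equal(unname(schema$tag_maps[[1]][t1]), m$block1)
    expect_equal(unname(schema$tag_maps[[2]][t2]), m$block2)
  }
})

test_that("motif planting marks one block-combination worth of members", {
  lib <- generate_library(c(10, 10), seed = 5, validate = FALSE)
  pl <- plant_binders(lib, n_competitive = 1, motif_mode = TRUE, seed = 6)
  hits <- pl$members[!is.na(pl$members$target_affinity), ]
  expect_equal(nrow(hits), 10L)                      # one fixed cycle-1 block
  expect_equal(length(unique(hits$block1)), 1L)
  expect_equal(length(unique(hits$target_affinity)), 1L)
  expect_true(all(hits$competitive))

  none <- plant_binders(lib, seed = 6)
  expect_true(all(is.na(none$members$target_affinity)))
  expect_false(any(none$members$is_matrix_binder))

  again <- plant_binders(lib, n_competitive = 1, motif_mode = TRUE, seed = 6)
  expect_identical(pl$members, again$members)
})

test_that("role precedence resolves overlaps toward matrix binders", {
  lib <- generate_library(c(4, 4), seed = 9, validate = FALSE)
  # every member competitive, then all matrix: matrix must win everywhere
  pl <- suppressMessages(plant_binders(lib, n_competitive = 16, n_matrix = 16,
                                       motif_mode = FALSE, seed = 10))
  expect_true(all(pl$members$is_matrix_binder))
  expect_true(all(is.na(pl$members$target_affinity)))
  expect_false(any(pl$members$competitive))
})

test_that("null-truth selection sampling is multinomial around uniform", {
  lib <- generate_library(c(10, 10), seed = 21, validate = FALSE)
  cond <- selection_condition("no_target")
  rs <- simulate_selection(lib, cond, depth = 1e5, seed = 22)
  counts <- rep(0L, 100)
  counts[match(rs$ledger$member_id, lib$members$member_id)] <- rs$ledger$molecules
  p <- 1 / 100
  expected <- 1e5 * p
  sigma <- sqrt(1e5 * p * (1 - p))
  expect_lt(max(abs(counts - expected)), 4 * sigma)
  expect_equal(sum(counts), 1e5)
})

test_that("saturating competitor suppresses competitive binders ~ analytically", {
  lib <- generate_library(c(10, 10), seed = 31, validate = FALSE)
  lib <- plant_binders(lib, n_competitive = 1, motif_mode = TRUE,
                       affinity_range = c(1e-6, 1e-6), seed = 32)
  target <- selection_condition("target", target_concentration = 1e-6)
  comp <- selection_condition("target_plus_competitor",
                              target_concentration = 1e-6,
                              competitor_concentration = 1e-4)
  # analytic occupancy ratio before simulating: theta_comp^2 / theta_t^2
  kd <- 1e-6; kd_comp <- 1e-6; pm <- 0.01
  th_t <- 1e-6 / (1e-6 + kd) + pm
  th_c <- 1e-6 / (1e-6 + kd * (1 + 1e-4 / kd_comp)) + pm
  expect_lt((th_c / th_t)^2, 0.1)

  rs_t <- simulate_selection(lib, target, depth = 5e4, seed = 33)
  rs_c <- simulate_selection(lib, comp, depth = 5e4, seed = 34)
  binder_ids <- lib$members$member_id[!is.na(lib$members$target_affinity)]
  # depth renormalizes shares, so compare counts per binder relative to
  # counts per background member: that ratio tracks the occupancy weight
  rel_enrich <- function(rs) {
    k_b <- sum(rs$ledger$molecules[rs$ledger$member_id %in% binder_ids]) /
      length(binder_ids)
    k_bg <- sum(rs$ledger$molecules[!rs$ledger$member_id %in% binder_ids]) /
      (nrow(lib$members) - length(binder_ids))
    k_b / k_bg
  }
  expect_lt(rel_enrich(rs_c) / rel_enrich(rs_t), 0.1)
})

test_that("selection read sets conserve molecules and honor depth", {
  lib <- generate_library(c(5, 5), seed = 41, validate = FALSE)
  cond <- selection_condition("no_target")
  rs <- simulate_selection(lib, cond, depth = 5000, pcr_dup_rate = 0.3,
                           seq_error_rate = 0, seed = 42)
  expect_equal(length(rs$reads), 5000L)
  umis <- substr(rs$reads, 1, 12)
  expect_equal(length(unique(umis)), sum(rs$ledger$molecules))

  rs2 <- simulate_selection(lib, cond, depth = 5000, pcr_dup_rate = 0.3,
                            seq_error_rate = 0, seed = 42)
  expect_identical(rs$reads, rs2$reads)

  expect_warning(empty <- simulate_selection(lib, cond, depth = 0, seed = 1),
                 "empty")
  expect_equal(length(empty$reads), 0L)
  expect_error(simulate_selection(lib, cond, depth = 10, pcr_dup_rate = 1),
               "pcr_dup_rate")
})

test_that("expected counts are monotone in affinity", {
  lib <- generate_library(c(10, 10), seed = 51, validate = FALSE)
  # plant two individual binders with very different KD by hand
  lib$members$target_affinity[1] <- 1e-8   # tight
  lib$members$target_affinity[2] <- 1e-5   # weak
  cond <- selection_condition("target", target_concentration = 1e-6)
  rs <- simulate_selection(lib, cond, depth = 1e5, seed = 52)
  k <- function(id) {
    i <- match(id, rs$ledger$member_id)
    if (is.na(i)) 0L else rs$ledger$molecules[i]
  }
  expect_gt(k(lib$members$member_id[1]), k(lib$members$member_id[2]))
})

test_that("vanishing target concentration converges to the no-target null", {
  lib <- generate_library(c(8, 8), seed = 61, validate = FALSE)
  lib$members$target_affinity[1:5] <- 1e-6
  cond0 <- selection_condition("no_target")
  pvals <- vapply(1:20, function(s) {
    condt <- selection_condition("target", target_concentration = 1e-15)
    rs0 <- simulate_selection(lib, cond0, depth = 2000, seed = 1000 + s)
    rst <- simulate_selection(lib, condt, depth = 2000, seed = 2000 + s)
    c0 <- rep(0, 64); c0[match(rs0$ledger$member_id, lib$members$member_id)] <- rs0$ledger$molecules
    ct <- rep(0, 64); ct[match(rst$ledger$member_id, lib$members$member_id)] <- rst$ledger$molecules
    suppressWarnings(stats::ks.test(c0, ct)$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.01))
})

test_that("FASTQ round-trip preserves reads", {
  lib <- generate_library(c(3, 3), seed = 71, validate = FALSE)
  rs <- simulate_selection(lib, selection_condition("no_target"),
                           depth = 200, seed = 72)
  f <- tempfile(fileext = ".fastq")
  write_fastq(rs, f)
  back <- read_fastq(f)
  expect_identical(back, rs$reads)
})
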
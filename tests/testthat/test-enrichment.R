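# Disynthon aggregation, enrichment z statistic and class assignment.

make_counts <- function(df) {
  # helper: member-level count table from a plain data.frame
  dt <- data.table::as.data.table(df)
  dt[, `:=`(total_unique = sum(unique_count)), by = c("library_id", "condition")]
  dt$raw_count <- dt$unique_count
  dt$rpm <- dt$unique_count / dt$total_unique * 1e6
  structure(dt, class = c("count_table", "data.table", "data.frame"))
}

test_that("2-cycle aggregation is the identity on member counts", {
  ct <- make_counts(data.frame(
    library_id = "L", member_id = c("a.x", "a.y", "b.x"),
    block1 = c("a", "a", "b"), block2 = c("x", "y", "x"),
    condition = "target", unique_count = c(5L, 7L, 2L)))
  dis <- aggregate_disynthons(ct)
  expect_equal(nrow(dis), 3L)
  expect_equal(sort(dis$k), c(2L, 5L, 7L))
  expect_true(all(dis$N == 14L))
  expect_equal(unique(dis$cycle_pair), "1-2")
})

test_that("a 3-cycle member feeds all three of its disynthons", {
  ct <- make_counts(data.frame(
    library_id = "L", member_id = "a.x.p",
    block1 = "a", block2 = "x", block3 = "p",
    condition = "target", unique_count = 5L))
  dis <- aggregate_disynthons(ct)
  expect_equal(nrow(dis), 3L)
  expect_setequal(dis$cycle_pair, c("1-2", "1-3", "2-3"))
  expect_true(all(dis$k == 5L))
})

test_that("disynthon sums equal an independent group-by oracle", {
  set.seed(33)
  n <- 200
  df <- data.frame(
    library_id = "L",
    block1 = sample(paste0("a", 1:6), n, TRUE),
    block2 = sample(paste0("b", 1:6), n, TRUE),
    block3 = sample(paste0("c", 1:6), n, TRUE),
    condition = sample(c("target", "no_target"), n, TRUE),
    unique_count = sample(1:20, n, TRUE))
  df$member_id <- paste(df$block1, df$block2, df$block3, sep = ".")
  df <- stats::aggregate(unique_count ~ ., data = df, FUN = sum)
  dis <- aggregate_disynthons(make_counts(df))

  oracle <- stats::aggregate(unique_count ~ block1 + block2 + condition,
                             data = df, FUN = sum)
  v12 <- dis[dis$cycle_pair == "1-2"]
  merged <- merge(as.data.frame(v12), oracle,
                  by.x = c("block_a", "block_b", "condition"),
                  by.y = c("block1", "block2", "condition"))
  expect_equal(nrow(merged), nrow(oracle))
  expect_equal(merged$k, merged$unique_count)
})

test_that("enrichment z matches direct formula evaluation and its symmetries", {
  # independent evaluation of the pseudocounted two-proportion z for
  # (100, 1e4) vs (10, 1e4) at c = 0.5, frozen from a hand computation
  p1 <- 100.5 / 10000.5; p2 <- 10.5 / 10000.5
  pbar <- 111 / 20001
  z_oracle <- (p1 - p2) / sqrt(pbar * (1 - pbar) * 2e-4)
  expect_equal(z_oracle, 8.566, tolerance = 1e-3)
  expect_equal(enrichment_statistic(100, 1e4, 10, 1e4), z_oracle)

  expect_equal(enrichment_statistic(37, 1000, 37, 1000), 0)
  expect_lt(enrichment_statistic(0, 1e4, 10, 1e4), 0)
  expect_equal(enrichment_statistic(25, 1e3, 70, 2e3),
               -enrichment_statistic(70, 2e3, 25, 1e3))
  expect_error(enrichment_statistic(1, 0, 1, 10), "positive")

  # monotone in the selected count
  ks <- seq(0, 200, by = 10)
  zs <- enrichment_statistic(ks, 1e4, 10, 1e4)
  expect_true(all(diff(zs) > 0))
})

rule_table_dis <- function(k_target, k_comp, k_no_target,
                           N = 1e4, nd = 100) {
  # two disynthons: the one under test plus a filler absorbing the rest
  data.table::rbindlist(lapply(
    list(c("target", k_target), c("target_plus_competitor", k_comp),
         c("no_target", k_no_target)),
    function(x) {
      dt <- data.table::data.table(
        library_id = "L", cycle_pair = "1-2",
        block_a = c("a", "zz"), block_b = c("x", "zz"),
        condition = x[1],
        k = c(as.numeric(x[2]), N - as.numeric(x[2])), N = N)
      dt$key <- c("L|1-2|a|x", "L|1-2|zz|zz")
      dt
    }))
}

test_that("class assignment follows the precedence rule table", {
  # strong target enrichment, quiet competitor -> competitive hit
  lab <- assign_classes(rule_table_dis(500, 100, 100), n_disynthons = 100)
  row <- lab[lab$key == "L|1-2|a|x"]
  expect_gt(row$z_target, 6)
  expect_lt(row$z_comp, 3)
  expect_equal(row$class, "competitive_hit")

  # enriched in target AND competitor -> noncompetitive
  lab2 <- assign_classes(rule_table_dis(500, 500, 100), n_disynthons = 100)
  expect_equal(lab2[lab2$key == "L|1-2|a|x"]$class, "noncompetitive_hit")

  # uniform counts everywhere -> non-hit
  lab3 <- assign_classes(rule_table_dis(100, 100, 100), n_disynthons = 100)
  expect_equal(lab3[lab3$key == "L|1-2|a|x"]$class, "non_hit")

  # huge no-target excess beats everything else (precedence)
  lab4 <- assign_classes(rule_table_dis(500, 100, 3000), n_disynthons = 100)
  expect_equal(lab4[lab4$key == "L|1-2|a|x"]$class, "matrix_binder")

  expect_error(assign_classes(rule_table_dis(1, 1, 1)[condition != "no_target"]),
               "no_target")
})

test_that("hit classes merge to target_hit without a competitor condition", {
  dis <- rule_table_dis(500, 100, 100)
  dis <- dis[dis$condition != "target_plus_competitor"]
  lab <- assign_classes(dis, n_disynthons = 100)
  expect_equal(lab[lab$key == "L|1-2|a|x"]$class, "target_hit")
})

test_that("promiscuity requires a panel of at least three targets", {
  dis <- rule_table_dis(500, 100, 100)
  pan2 <- data.frame(key = "L|1-2|a|x", target = c("t1", "t2"),
                     enriched = TRUE)
  lab <- assign_classes(dis, n_disynthons = 100, panel = pan2)
  expect_equal(lab[lab$key == "L|1-2|a|x"]$class, "competitive_hit")

  pan3 <- data.frame(key = "L|1-2|a|x", target = c("t1", "t2", "t3"),
                     enriched = TRUE)
  lab2 <- assign_classes(dis, n_disynthons = 100, panel = pan3)
  expect_equal(lab2[lab2$key == "L|1-2|a|x"]$class, "promiscuous_binder")
})

test_that("every disynthon receives exactly one class", {
  scr <- small_screen()
  dis <- aggregate_disynthons(scr$counts)
  lab <- assign_classes(dis, n_disynthons = nrow(scr$lib$members))
  expect_equal(nrow(lab), length(unique(dis$key)))
  expect_true(all(lab$class %in% c("competitive_hit", "noncompetitive_hit",
                                   "promiscuous_binder", "matrix_binder",
                                   "non_hit")))
})

test_that("PTE selection honors the competitor flag and expands members", {
  scr <- small_screen()
  dis <- aggregate_disynthons(scr$counts)
  lab <- assign_classes(dis, n_disynthons = nrow(scr$lib$members))

  ptes <- select_ptes(lab, scr$lib, competitor_present = TRUE)
  comp_keys <- lab$key[lab$class == "competitive_hit"]
  expect_setequal(unique(ptes$key), comp_keys)

  # without the competitor reading, both hit classes fold into target_hit
  dis_nc <- dis[dis$condition != "target_plus_competitor"]
  lab_nc <- assign_classes(dis_nc, n_disynthons = nrow(scr$lib$members))
  ptes_nc <- select_ptes(lab_nc, scr$lib, competitor_present = FALSE)
  expect_gt(nrow(ptes_nc), nrow(ptes))

  empty_lab <- lab[lab$class == "non_hit"]
  expect_warning(select_ptes(empty_lab, scr$lib, TRUE), "no positive")
})

test_that("planted truth is recovered from the simulated screen", {
  scr <- small_screen()
  dis <- aggregate_disynthons(scr$counts)
  lab <- assign_classes(dis, n_disynthons = nrow(scr$lib$members))
  mem <- scr$lib$members
  truth <- mem$member_id
  lab_mem <- lab$class[match(paste0(mem$block1, "|", mem$block2),
                             paste0(lab$block_a, "|", lab$block_b))]

  is_comp <- !is.na(mem$target_affinity) & mem$competitive
  is_noncomp <- !is.na(mem$target_affinity) & !mem$competitive & !mem$is_promiscuous
  is_matrix <- mem$is_matrix_binder
  is_null <- !is_comp & !is_noncomp & !is_matrix

  expect_gte(mean(lab_mem[is_comp] == "competitive_hit"), 0.9)
  expect_gte(mean(lab_mem[is_matrix] == "matrix_binder"), 0.9)
  expect_gte(mean(lab_mem[is_null] == "non_hit", na.rm = TRUE), 0.99)
})
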
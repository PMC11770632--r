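# Training-set assembly, forest/DNN scorers, metric and ensembling.

test_that("training sets follow the resampling arithmetic", {
  # 100 distinct positives / negatives: two scaffolds with graded chains
  chains <- c(strrep("C", 1:50), paste0(strrep("C", 1:50), "O"))
  pos <- paste0("N(c1ccc(F)cc1)C(=O)", chains)
  neg <- paste0("N(C1CCNCC1)C(=O)", chains)
  sets <- build_training_sets(pos, neg, n_models = 4, n_negatives = 50,
                              pos_fraction = 0.9, holdout = 0.1,
                              oversample_pos = 2, seed = 7)
  expect_length(sets, 4L)
  s1 <- sets[[1]]
  expect_length(s1$pos_train, 180L)                     # 90 sampled, twice
  expect_length(unique(s1$pos_train), 90L)
  expect_length(s1$pos_test, 10L)
  expect_length(s1$neg_train, 45L)
  expect_length(s1$neg_test, 5L)
  expect_length(intersect(s1$pos_train, s1$pos_test), 0L)
  expect_length(intersect(s1$neg_train, s1$neg_test), 0L)

  # per-set seeds recorded and sets distinct but reproducible
  expect_length(unique(vapply(sets, function(s) s$seed, integer(1))), 4L)
  expect_false(identical(sets[[1]]$neg_train, sets[[2]]$neg_train))
  again <- build_training_sets(pos, neg, n_models = 4, n_negatives = 50, seed = 7)
  expect_identical(sets[[2]]$pos_train, again[[2]]$pos_train)
})

test_that("training-set preconditions", {
  cls <- separable_classes()
  expect_error(build_training_sets(character(0), cls$neg), "positive")
  expect_error(build_training_sets(cls$pos, cls$neg[1:5]), "10 negative")
  expect_error(build_training_sets(cls$pos[1], cls$neg, n_models = 1),
               "stratified")
  expect_message(build_training_sets(cls$pos, c(cls$neg, cls$pos[1]),
                                     n_models = 1, seed = 1), "both classes")
})

test_that("forests separate a separable fixture and are reproducible", {
  cls <- separable_classes()
  sets <- build_training_sets(cls$pos, cls$neg, n_models = 1,
                              n_negatives = 20, seed = 3)
  sc <- train_forest(sets[[1]], n_trees = 60, seed = 11)
  expect_equal(sc$accuracy, 1.0)
  p <- predict(sc, c(cls$pos[1], cls$neg[1]))
  expect_gt(p[1], 0.8)
  expect_lt(p[2], 0.2)

  sc2 <- train_forest(sets[[1]], n_trees = 60, seed = 11)
  expect_identical(predict(sc2, cls$pos[1:5]), predict(sc, cls$pos[1:5]))
})

test_that("label-shuffled training yields chance-level holdout accuracy", {
  cls <- separable_classes()
  # shuffle labels by constructing a training set whose classes mix both
  # scaffolds equally: no signal remains
  mixed <- sample(c(cls$pos, cls$neg))
  ts <- structure(list(pos_train = mixed[1:16], pos_test = mixed[17:20],
                       neg_train = mixed[21:36], neg_test = mixed[37:40],
                       radius = 2L, nbits = 1024L, seed = 1L),
                  class = "training_set")
  sc <- train_forest(ts, n_trees = 60, seed = 5)
  # holdout is 4 + 4 balanced; binomial 3-sigma band around 0.5
  expect_gte(sc$accuracy, 0.5 - 3 * sqrt(0.25 / 8))
  expect_lte(sc$accuracy, 0.5 + 3 * sqrt(0.25 / 8))
})

test_that("degenerate single-class sets are refused", {
  cls <- separable_classes()
  ts <- structure(list(pos_train = character(0), pos_test = cls$pos[1],
                       neg_train = cls$neg[1:10], neg_test = cls$neg[11:12],
                       radius = 2L, nbits = 1024L, seed = 1L),
                  class = "training_set")
  expect_error(train_forest(ts, n_trees = 10), "single-class")
})

test_that("best-forest selection maximizes accuracy with stable ties", {
  mk <- function(acc) structure(list(kind = "plugin", model = identity,
                                     radius = 2L, nbits = 1024L,
                                     accuracy = acc, meta = list()),
                                class = "del_scorer")
  out <- suppressMessages(select_best_forest(list(mk(0.7), mk(0.9), mk(0.8))))
  expect_equal(out$meta$selected_index, 2L)
  tie <- suppressMessages(select_best_forest(list(mk(0.8), mk(0.8), mk(0.8))))
  expect_equal(tie$meta$selected_index, 1L)
  single <- suppressMessages(select_best_forest(list(mk(0.5))))
  expect_equal(single$meta$selected_index, 1L)
  expect_error(select_best_forest(list()), "no scorers")
})

test_that("top_100_actives matches a brute-force sort-and-count oracle", {
  oracle <- function(scores, labels, n) {
    n <- min(n, length(scores))
    # explicit stable selection: scan scores from the largest down,
    # resolving ties by input position
    taken <- integer(0)
    remaining <- seq_along(scores)
    while (length(taken) < n) {
      best <- remaining[which.max(scores[remaining])]
      taken <- c(taken, best)
      remaining <- setdiff(remaining, best)
    }
    sum(labels[taken])
  }
  set.seed(42)
  for (i in 1:200) {
    m <- sample(5:60, 1)
    scores <- round(stats::runif(m), sample(c(1, 2, 6), 1))  # force ties
    labels <- stats::rbinom(m, 1, 0.3)
    n <- sample(c(3, 10, 100), 1)
    if (m < n) {
      expect_warning(got <- top_100_actives(scores, labels, n))
    } else {
      got <- top_100_actives(scores, labels, n)
    }
    expect_identical(got, oracle(scores, labels, n))
  }
})

test_that("top-slice composition behaves under extremes and permutation", {
  # all actives scored above all inactives
  scores <- c(stats::runif(150, 0.6, 1), stats::runif(100, 0, 0.4))
  labels <- rep(c(1, 0), c(150, 100))
  expect_equal(top_100_actives(scores, labels, 100), 100L)

  # random scores: expectation n * P / N over shuffles
  set.seed(9)
  N <- 200; P <- 60; n <- 50
  labels <- rep(c(1, 0), c(P, N - P))
  counts <- vapply(1:1000, function(i)
    top_100_actives(stats::runif(N), labels, n), integer(1))
  expected <- n * P / N
  sigma <- sqrt(n * (P / N) * (1 - P / N))  # binomial upper bound on sd
  expect_lt(abs(mean(counts) - expected), 3 * sigma / sqrt(1000))
})

test_that("the fingerprint network learns the separable fixture", {
  cls <- separable_classes()
  dn <- train_dnn(cls$pos[1:14], cls$neg[1:14], cls$pos[15:20], cls$neg[15:20],
                  layers = c(32, 8), steps = 400, batch = 8, lr = 0.05,
                  checkpoint_every = 100, seed = 21)
  # tuning metric capped by tuning size: all 6 positives in the top slice
  expect_equal(dn$meta$tuning_metric, 6L)
  p <- predict(dn, c(cls$pos[15], cls$neg[15]))
  expect_gt(p[1], p[2])

  dn2 <- train_dnn(cls$pos[1:14], cls$neg[1:14], cls$pos[15:20], cls$neg[15:20],
                   layers = c(32, 8), steps = 400, batch = 8, lr = 0.05,
                   checkpoint_every = 100, seed = 21)
  expect_identical(dn$model, dn2$model)
  expect_error(train_dnn(cls$pos[1:10], cls$neg[1:10], cls$pos[1:2],
                         cls$neg[11:12]), "disjoint")
})

test_that("zero training steps return the initialized network", {
  cls <- separable_classes()
  expect_warning(
    dn <- train_dnn(cls$pos[1:10], cls$neg[1:10], cls$pos[11:14],
                    cls$neg[11:14], layers = c(16, 4), steps = 0,
                    checkpoint_every = 10, seed = 3),
    "initialization")
  expect_equal(dn$meta$checkpoint_step, 0L)
})

const_scorer <- function(v, radius = 2L, nbits = 64L) {
  plugin_scorer(function(x) rep(v, nrow(x)), radius = radius, nbits = nbits)
}

test_that("ensembling is a median of replica medians", {
  fps <- fp_from_bits(list(c(1, 5), c(2, 6), c(3, 7)), nbits = 64)

  # one run, replicas {0.1, 0.2, 0.9} -> 0.2
  rp <- ensemble_score(list(const_scorer(0.1), const_scorer(0.2),
                            const_scorer(0.9)), fps)
  expect_true(all(rp$score == 0.2))

  # permuting replicas changes nothing
  rp2 <- ensemble_score(list(const_scorer(0.9), const_scorer(0.1),
                             const_scorer(0.2)), fps)
  expect_equal(rp2$score, rp$score)

  # two runs of medians, then the median over runs
  runs <- list(list(const_scorer(0.2), const_scorer(0.3), const_scorer(0.4)),
               list(const_scorer(0.8), const_scorer(0.7), const_scorer(0.6)))
  rp3 <- ensemble_score(runs, fps)
  expect_true(all(rp3$score == stats::median(c(0.3, 0.7))))

  # identical members reduce to the single model; bounded by member range
  rp4 <- ensemble_score(list(const_scorer(0.42), const_scorer(0.42)), fps)
  expect_true(all(rp4$score == 0.42))
  expect_error(ensemble_score(list(), fps), "empty")
  expect_error(ensemble_score(list(const_scorer(0.1, nbits = 64),
                                   const_scorer(0.1, nbits = 128)), fps),
               "feature spec")
})

test_that("ensemble output is sorted and within member score bounds", {
  cls <- separable_classes()
  sets <- build_training_sets(cls$pos, cls$neg, n_models = 3,
                              n_negatives = 20, seed = 5)
  scorers <- lapply(1:3, function(i) train_forest(sets[[i]], n_trees = 30, seed = i))
  compounds <- c(cls$pos[1:5], cls$neg[1:5])
  rp <- ensemble_score(scorers, compounds)
  expect_false(is.unsorted(rev(rp$score)))
  per <- vapply(scorers, function(s) predict(s, compounds), numeric(10))
  lo <- apply(per, 1, min); hi <- apply(per, 1, max)
  m <- match(compounds, rp$id)
  expect_true(all(rp$score[m] >= lo - 1e-12 & rp$score[m] <= hi + 1e-12))
})

test_that("the two-model filter keeps the secondary-score survivors", {
  prim <- structure(data.table::data.table(
    id = paste0("c", 1:4), smiles = paste0("c", 1:4),
    score = c(0.9, 0.8, 0.7, 0.6), rank = 1:4),
    class = c("ranked_predictions", "data.table", "data.frame"))

  # hand case: secondary scores by id; items 1 and 3 survive
  sec <- c(0.9, 0.1, 0.8, 0.2)
  out <- v21_filter(prim, sec, top_k = 4, keep_fraction = 0.5)
  expect_equal(out$id, c("c1", "c3"))
  expect_equal(out$rank, 1:2)

  # secondary == primary: survivors are the top k/2 by primary
  out2 <- v21_filter(prim, prim$score, top_k = 4, keep_fraction = 0.5)
  expect_equal(out2$id, c("c1", "c2"))

  # keep_fraction 1 is the identity on the slice
  out3 <- v21_filter(prim, sec, top_k = 4, keep_fraction = 1)
  expect_equal(out3$id, prim$id)

  expect_warning(v21_filter(prim, sec, top_k = 10, keep_fraction = 0.5),
                 "capping")
})
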
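# Model training and ensembling for fingerprint-based virtual screening.
#
# Two scorer families are provided behind one interface: random forests
# (probability forests over ECFP4-style 1024-bit features) and a small
# fully connected neural network over ECFP6-style 2048-bit features.
# The message-passing graph network used at production scale in this
# problem domain is deliberately NOT re-implemented here; any score
# source can be wrapped as a scorer, and the fingerprint network plays
# that role throughout the package.

.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)
}

#' Assemble resampled training sets
#'
#' Each of `n_models` sets independently samples `pos_fraction` of the
#' positives into its training partition (the remainder is the positive
#' holdout) and `n_negatives` negatives, of which `holdout` are held out.
#' Training positives are oversampled `oversample_pos` times; holdout
#' partitions are never oversampled.
#'
#' @param positives,negatives character vectors of SMILES (disjoint).
#' @param n_models number of independently resampled sets.
#' @param n_negatives negatives sampled per set (at most the pool size).
#' @param pos_fraction fraction of positives placed in training.
#' @param holdout fraction of sampled negatives held out for testing.
#' @param oversample_pos multiplicity of positives in the training
#'   partition.
#' @param radius,nbits fingerprint feature specification.
#' @param seed root seed; per-set seeds are derived from it and recorded.
#' @return list of `training_set` objects with elements `pos_train`,
#'   `pos_test`, `neg_train`, `neg_test`, `radius`, `nbits`, `seed`.
#' @export
build_training_sets <- function(positives, negatives, n_models = 30L,
                                n_negatives = length(negatives),
                                pos_fraction = 0.9, holdout = 0.1,
                                oversample_pos = 2L, radius = 2L,
                                nbits = 1024L, seed = 1L) {
  positives <- unique(positives)
  negatives <- unique(negatives)
  overlap <- intersect(positives, negatives)
  if (length(overlap)) {
    message("removing ", length(overlap), " structure(s) present in both classes from the negatives")
    negatives <- setdiff(negatives, overlap)
  }
  if (length(positives) < 1L) stop("at least one positive example is required")
  if (length(negatives) < 10L) stop("at least 10 negative examples are required")
  if (n_negatives > length(negatives))
    stop("n_negatives (", n_negatives, ") exceeds the negative pool (",
         length(negatives), ")")
  n_pos_train <- round(pos_fraction * length(positives))
  if (n_pos_train < 1L || n_pos_train >= length(positives) + (pos_fraction >= 1))
    stop("positive count too small for a stratified holdout at pos_fraction = ",
         pos_fraction)

  lapply(seq_len(n_models), function(m) {
    sm <- .derive_seed(seed, m)
    with_seed(sm, {
      ip <- sample(length(positives), n_pos_train)
      pos_train <- positives[ip]
      pos_test <- positives[-ip]
      neg <- sample(negatives, n_negatives)
      n_neg_test <- max(1L, round(holdout * n_negatives))
      neg_test <- neg[seq_len(n_neg_test)]
      neg_train <- neg[-seq_len(n_neg_test)]
      structure(list(pos_train = rep(pos_train, oversample_pos),
                     pos_test = pos_test,
                     neg_train = neg_train, neg_test = neg_test,
                     radius = as.integer(radius), nbits = as.integer(nbits),
                     seed = sm),
                class = "training_set")
    })
  })
}

.scorer <- function(kind, model, radius, nbits, accuracy = NA_real_,
                    meta = list()) {
  structure(list(kind = kind, model = model, radius = as.integer(radius),
                 nbits = as.integer(nbits), accuracy = accuracy, meta = meta),
            class = "del_scorer")
}

#' @export
print.del_scorer <- function(x, ...) {
  cat(sprintf("del_scorer (%s), features radius %d / %d bits", x$kind,
              x$radius, x$nbits))
  if (!is.na(x$accuracy)) cat(sprintf(", holdout accuracy %.3f", x$accuracy))
  cat("\n")
  invisible(x)
}

.coerce_features <- function(newdata, radius, nbits) {
  if (is.matrix(newdata)) return(newdata)
  if (inherits(newdata, "del_fp")) {
    if (newdata$radius != radius || newdata$nbits != nbits)
      stop("fingerprint parameters do not match the scorer's feature spec")
    return(fp_dense(newdata))
  }
  if (is.character(newdata))
    return(fp_dense(fingerprint(newdata, radius = radius, nbits = nbits)))
  stop("newdata must be SMILES, a del_fp set, or a dense feature matrix")
}

#' Score compounds with a trained scorer
#'
#' @param object a `del_scorer`.
#' @param newdata SMILES character vector, `del_fp` set matching the
#'   scorer's feature spec, or a dense 0/1 matrix.
#' @param ... unused.
#' @return numeric scores in `[0, 1]`.
#' @export
predict.del_scorer <- function(object, newdata, ...) {
  x <- .coerce_features(newdata, object$radius, object$nbits)
  if (object$kind == "forest") {
    pr <- stats::predict(object$model, data = x,
                         num.threads = 1)$predictions
    as.numeric(pr[, "1"])
  } else if (object$kind == "dnn") {
    as.numeric(.mlp_forward(object$model, x)$p)
  } else if (object$kind == "plugin") {
    as.numeric(object$model(x))
  } else stop("unknown scorer kind: ", object$kind)
}

#' Wrap an arbitrary scoring function as a scorer
#'
#' @param fn function taking a dense 0/1 feature matrix and returning
#'   scores in `[0, 1]`.
#' @param radius,nbits feature spec the function expects.
#' @return a `del_scorer` of kind `"plugin"`.
#' @export
plugin_scorer <- function(fn, radius = 2L, nbits = 1024L) {
  stopifnot(is.function(fn))
  .scorer("plugin", fn, radius, nbits)
}

#' Train a random-forest scorer on a training set
#'
#' A probability forest over fingerprint features; the score of a
#' compound is the fraction of trees voting for the positive class.
#' Holdout accuracy (at a 0.5 threshold) is computed on the set's test
#' partition.
#'
#' @param ts a `training_set`.
#' @param n_trees number of trees.
#' @param min_split minimum node size eligible for splitting.
#' @param seed integer seed.
#' @param fp optional precomputed `del_fp` covering every SMILES in the
#'   set (training and holdout), to avoid re-featurizing shared pools.
#' @return a `del_scorer` of kind `"forest"` with `accuracy` filled in.
#' @export
train_forest <- function(ts, n_trees = 2000L, min_split = 5L, seed = 1L,
                         fp = NULL) {
  stopifnot(inherits(ts, "training_set"))
  tr_smiles <- c(ts$pos_train, ts$neg_train)
  y <- factor(rep(c(1L, 0L), c(length(ts$pos_train), length(ts$neg_train))),
              levels = c(0L, 1L))
  if (length(unique(y)) < 2L) stop("degenerate single-class training set")
  if (is.null(fp)) {
    all_smiles <- unique(c(tr_smiles, ts$pos_test, ts$neg_test))
    fp <- fingerprint(all_smiles, radius = ts$radius, nbits = ts$nbits)
  } else if (fp$radius != ts$radius || fp$nbits != ts$nbits) {
    stop("fp cache does not match the training set's feature spec")
  }
  ix <- match(tr_smiles, fp$ids)
  if (anyNA(ix)) stop("fp cache is missing training SMILES")
  x <- fp_dense(fp, ix)
  fit <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                        min.node.size = min_split, probability = TRUE,
                        seed = seed, num.threads = 1)
  sc <- .scorer("forest", fit, ts$radius, ts$nbits, meta = list(seed = seed))
  te_smiles <- c(ts$pos_test, ts$neg_test)
  y_te <- rep(c(1L, 0L), c(length(ts$pos_test), length(ts$neg_test)))
  p <- predict(sc, fp_dense(fp, match(te_smiles, fp$ids)))
  sc$accuracy <- mean((p >= 0.5) == (y_te == 1L))
  sc
}

#' Pick the forest with the highest holdout accuracy
#'
#' Ties are broken by the lowest model index.
#'
#' @param scorers list of `del_scorer` objects with accuracies.
#' @return the selected scorer, with `meta$selected_index` recording the
#'   choice.
#' @export
select_best_forest <- function(scorers) {
  if (!length(scorers)) stop("no scorers supplied")
  acc <- vapply(scorers, function(s) s$accuracy, numeric(1))
  i <- which.max(acc)  # first maximum: lowest index on ties
  message("selected model ", i, " (holdout accuracy ", signif(acc[i], 4), ")")
  out <- scorers[[i]]
  out$meta$selected_index <- i
  out
}

#' Count actives among the top-ranked predictions
#'
#' The model-selection metric: the number of true actives within the `n`
#' highest scores. Boundary ties are resolved by stable input order.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1/TRUE = active), same length.
#' @param n size of the top slice.
#' @return integer count.
#' @export
top_100_actives <- function(scores, labels, n = 100L) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(as.logical(labels))
  if (length(scores) < n) {
    warning("fewer than ", n, " predictions; evaluating over all ",
            length(scores))
    n <- length(scores)
  }
  ord <- order(-scores)  # stable: ties keep input order
  sum(labels[ord[seq_len(n)]])
}

# ---- minimal two-hidden-layer MLP (ReLU, logistic output) ----

.mlp_init <- function(nbits, layers, seed) {
  with_seed(seed, {
    dims <- c(nbits, layers, 1L)
    W <- list(); b <- list()
    for (l in seq_len(length(dims) - 1L)) {
      W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                       dims[l], dims[l + 1L])
      b[[l]] <- rep(0, dims[l + 1L])
    }
    list(W = W, b = b)
  })
}

.mlp_forward <- function(par, x) {
  a <- list(x)
  nl <- length(par$W)
  for (l in seq_len(nl)) {
    z <- sweep(a[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    a[[l + 1L]] <- if (l < nl) pmax(z, 0) else z
  }
  p <- 1 / (1 + exp(-a[[nl + 1L]]))
  list(a = a, p = p)
}

.mlp_step <- function(par, x, y, lr) {
  nl <- length(par$W)
  fw <- .mlp_forward(par, x)
  n <- nrow(x)
  delta <- (fw$p - y) / n            # dL/dz at the logistic output
  for (l in rev(seq_len(nl))) {
    gW <- t(fw$a[[l]]) %*% delta
    gb <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(par$W[[l]])) * (fw$a[[l]] > 0)
    }
    par$W[[l]] <- par$W[[l]] - lr * gW
    par$b[[l]] <- par$b[[l]] - lr * gb
  }
  par
}

#' Train the fingerprint neural-network scorer
#'
#' A fully connected network (two hidden ReLU layers, logistic output,
#' log-loss, minibatch SGD) over folded circular-fingerprint features.
#' Checkpoints are taken every `checkpoint_every` steps and the
#' checkpoint with the highest [top_100_actives()] on the tuning set is
#' returned; if no checkpoint improves on the initialized network, the
#' last checkpoint is returned with a warning.
#'
#' @param positives,negatives training SMILES.
#' @param tune_positives,tune_negatives tuning set (disjoint from
#'   training) used for checkpoint selection.
#' @param layers hidden layer sizes.
#' @param steps total SGD steps.
#' @param batch minibatch size.
#' @param lr learning rate.
#' @param checkpoint_every checkpoint cadence in steps.
#' @param radius,nbits fingerprint feature spec.
#' @param top_n slice size for the checkpoint-selection metric.
#' @param seed integer seed (initialization and batch sampling).
#' @return a `del_scorer` of kind `"dnn"`; `meta` records the selected
#'   checkpoint step and its metric value.
#' @export
train_dnn <- function(positives, negatives, tune_positives, tune_negatives,
                      layers = c(2000L, 100L), steps = 10000L, batch = 128L,
                      lr = 0.01, checkpoint_every = 1000L,
                      radius = 3L, nbits = 2048L, top_n = 100L, seed = 1L) {
  if (length(intersect(c(positives, negatives),
                       c(tune_positives, tune_negatives))))
    stop("tuning set must be disjoint from training")
  smi_tr <- c(positives, negatives)
  y_tr <- rep(c(1, 0), c(length(positives), length(negatives)))
  fp_tr <- fingerprint(unique(smi_tr), radius = radius, nbits = nbits)
  x_tr <- fp_dense(fp_tr)[match(smi_tr, fp_tr$ids), , drop = FALSE]
  smi_tu <- c(tune_positives, tune_negatives)
  y_tu <- rep(c(1, 0), c(length(tune_positives), length(tune_negatives)))
  x_tu <- fp_dense(fingerprint(smi_tu, radius = radius, nbits = nbits))

  par <- .mlp_init(nbits, layers, seed)
  metric <- function(p) top_100_actives(p, y_tu, n = min(top_n, length(y_tu)))
  init_metric <- suppressWarnings(metric(.mlp_forward(par, x_tu)$p))
  best <- list(par = par, metric = init_metric, step = 0L)
  improved <- FALSE

  with_seed(.derive_seed(seed, 17L), {
    step <- 0L
    while (step < steps) {
      idx <- sample.int(nrow(x_tr), min(batch, nrow(x_tr)))
      par <- .mlp_step(par, x_tr[idx, , drop = FALSE], y_tr[idx], lr)
      step <- step + 1L
      if (step %% checkpoint_every == 0L || step == steps) {
        m <- suppressWarnings(metric(.mlp_forward(par, x_tu)$p))
        if (m > best$metric) {
          best <- list(par = par, metric = m, step = step)
          improved <- TRUE
        }
      }
    }
    if (!improved) {
      max_attainable <- min(top_n, length(y_tu), sum(y_tu))
      if (step == 0L || best$metric < max_attainable)
        warning("no checkpoint improved on initialization; returning the last checkpoint")
      # a metric saturated at its maximum cannot improve; keep the most
      # trained weights either way
      best <- list(par = par, metric = suppressWarnings(metric(.mlp_forward(par, x_tu)$p)),
                    step = step)
    }
  })
  .scorer("dnn", best$par, radius, nbits,
          meta = list(checkpoint_step = best$step, tuning_metric = best$metric,
                      layers = layers, seed = seed))
}

#' Ensemble scores as median-of-medians
#'
#' Scorers are grouped as runs of replicas; each compound's score is the
#' median over replicas within each run, then the median over runs.
#' Output is sorted by descending score (stable on ties).
#'
#' @param scorers either a flat list of `del_scorer`s (one run) or a list
#'   of lists (runs of replicas). All must share the feature spec.
#' @param compounds SMILES character vector, `del_fp` set, or data.frame
#'   with `id` and `smiles` columns.
#' @return a `ranked_predictions` data.table: `id`, `smiles`, `score`,
#'   `rank`.
#' @export
ensemble_score <- function(scorers, compounds) {
  if (!length(scorers)) stop("empty scorer set")
  runs <- if (inherits(scorers[[1]], "del_scorer")) list(scorers) else scorers
  flat <- unlist(runs, recursive = FALSE)
  spec <- vapply(flat, function(s) paste(s$radius, s$nbits), character(1))
  if (length(unique(spec)) != 1L)
    stop("all scorers in an ensemble must share the feature spec")

  if (is.data.frame(compounds)) {
    ids <- compounds$id
    smiles <- compounds$smiles
  } else if (inherits(compounds, "del_fp")) {
    ids <- compounds$ids
    smiles <- compounds$smiles
  } else {
    ids <- smiles <- compounds
  }
  fp <- if (inherits(compounds, "del_fp")) compounds else
    fingerprint(smiles, radius = flat[[1]]$radius, nbits = flat[[1]]$nbits,
                ids = ids)

  x <- fp_dense(fp)
  run_scores <- vapply(runs, function(replicas) {
    rep_scores <- vapply(replicas, function(s) predict(s, x), numeric(nrow(x)))
    apply(matrix(rep_scores, nrow = nrow(x)), 1, stats::median)
  }, numeric(nrow(x)))
  score <- apply(matrix(run_scores, nrow = nrow(x)), 1, stats::median)

  out <- data.table::data.table(id = ids, smiles = smiles, score = score)
  out <- out[order(-score)]
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("ranked_predictions", "data.table", "data.frame"))
}

#' Two-model filter over a ranked prediction list
#'
#' Takes the `top_k` compounds by primary score, drops the
#' `1 - keep_fraction` of them with the lowest secondary scores, and
#' re-ranks the survivors by primary score.
#'
#' @param primary a `ranked_predictions` table (sorted by primary score).
#' @param secondary_scorer a `del_scorer`, or a numeric vector of
#'   secondary scores aligned with `primary`.
#' @param top_k primary slice size (capped at the table size).
#' @param keep_fraction fraction of the slice retained.
#' @return filtered `ranked_predictions`, re-ranked by primary score.
#' @export
v21_filter <- function(primary, secondary_scorer, top_k = 100000L,
                       keep_fraction = 0.5) {
  primary <- data.table::as.data.table(primary)
  if (top_k > nrow(primary)) {
    warning("top_k exceeds the candidate list (", nrow(primary), "); capping")
    top_k <- nrow(primary)
  }
  slice <- primary[order(-primary$score)][seq_len(top_k)]
  sec <- if (is.numeric(secondary_scorer)) {
    stopifnot(length(secondary_scorer) == nrow(primary))
    secondary_scorer[match(slice$id, primary$id)]
  } else {
    predict(secondary_scorer, slice$smiles)
  }
  n_keep <- round(keep_fraction * top_k)
  keep <- order(-sec)[seq_len(n_keep)]
  out <- slice[sort(keep)]             # preserve primary (score) order
  out <- out[order(-out$score)]
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("ranked_predictions", "data.table", "data.frame"))
}
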
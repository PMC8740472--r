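#' Known regulation direction of the anchor transcription factors
#'
#' Expected regulation per context for the two anchor TFs: IRF8 suppresses
#' osteoclastogenesis, so it is expected down (-1) in OCU comparisons and up
#' (+1) in OCD; NFATc1, the master activator of osteoclast differentiation,
#' is the reverse.
#'
#' @return Named list of per-context direction vectors (+1 / -1), one per TF.
#' @export
ctap_tf_directions <- function() {
  list(IRF8 = c(OCU = -1, OCD = 1),
       NFATc1 = c(OCU = 1, OCD = -1))
}

#' Build the labelled training set
#'
#' One training sample per (functional-group gene entry, comparison pair)
#' plus one per (anchor TF, comparison pair). Genes appearing in several
#' groups contribute one sample per entry. Each sample carries the
#' five-value feature vector and the class label: the group's expected
#' regulation in the CP's context (+1 up, -1 down), or the TF's known
#' direction. Gene entries missing from a CP's study carry the zero-imputed
#' features of the big-matrix rule.
#'
#' @param cohort A [build_cohort()] result.
#' @param fg_registry An `fg_registry` (see [read_fg_registry()]).
#' @param tf_directions Named list of per-context direction vectors for the
#'   anchor TFs (default [ctap_tf_directions()]); use `list()` to train on
#'   functional groups alone.
#' @return Data frame with columns `gene`, `group`, `cp_id`, `context`, the
#'   five feature columns, and `label`.
#' @export
build_training_set <- function(cohort, fg_registry,
                               tf_directions = ctap_tf_directions()) {
  stopifnot(inherits(cohort, "ctap_cohort"))
  if (length(fg_registry) < 1L) stop_ctap("empty functional-group registry")
  names(fg_registry) <- vapply(fg_registry, `[[`, "", "name")
  entries <- do.call(rbind, lapply(fg_registry, function(g)
    data.frame(gene = g$genes, group = g$name, stringsAsFactors = FALSE)))
  tf_genes <- toupper(names(tf_directions))
  all_entries <- rbind(entries,
                       if (length(tf_genes))
                         data.frame(gene = tf_genes, group = "TF"))
  feats <- feature_table(cohort, all_entries$gene)
  n_cp <- length(cohort$cps)
  idx <- rep(seq_len(nrow(all_entries)), times = n_cp)
  out <- cbind(all_entries[idx, , drop = FALSE], feats[, -1L])
  rownames(out) <- NULL
  out$label <- ifelse(
    out$group == "TF",
    vapply(seq_len(nrow(out)), function(i)
      if (out$group[i] == "TF")
        tf_directions[[match(out$gene[i], tf_genes)]][[out$context[i]]]
      else NA_real_, 0),
    vapply(seq_len(nrow(out)), function(i)
      if (out$group[i] != "TF")
        expected_label(fg_registry[[out$group[i]]], out$context[i])
      else NA_real_, 0))
  out
}

# -- model fitting ----------------------------------------------------------

default_grids <- function() {
  list(svm = list(cost = c(0.01, 0.1, 1, 10)),
       lr = list(lambda = c(1e-4, 1e-3, 1e-2, 1e-1)),
       gnb = list(),
       nn = list())
}

# fit one classifier family on a feature matrix; y in {+1, -1}.
# Returns list(fit, score(newX) -> numeric favouring class +1).
fit_family <- function(X, y, family, hyper = list()) {
  X <- as.matrix(X)
  yf <- factor(y, levels = c(-1, 1))
  switch(family,
    svm = {
      fit <- e1071::svm(X, yf, kernel = "linear",
                        cost = hyper$cost %||% 1, scale = TRUE)
      list(fit = fit, hyper = hyper, score = function(newX) {
        dv <- attr(predict(fit, as.matrix(newX), decision.values = TRUE),
                   "decision.values")
        # orient so positive decision value favours class "+1"
        if (grepl("^1/", colnames(dv)[1L])) dv[, 1L] else -dv[, 1L]
      })
    },
    lr = {
      lam <- hyper$lambda %||% 1e-2
      fit <- glmnet::glmnet(X, yf, family = "binomial", alpha = 1,
                            lambda = lam)
      list(fit = fit, hyper = hyper, score = function(newX)
        as.vector(predict(fit, as.matrix(newX), s = lam, type = "link")))
    },
    gnb = {
      fit <- e1071::naiveBayes(X, yf)
      list(fit = fit, hyper = hyper, score = function(newX) {
        p <- predict(fit, as.matrix(newX), type = "raw")
        p[, "1"] - p[, "-1"]
      })
    },
    nn = {
      fit <- mlp_fit(X, as.numeric(yf == "1"),
                     hidden = hyper$hidden %||% c(5L, 3L))
      list(fit = fit, hyper = hyper, score = function(newX)
        mlp_prob(fit, as.matrix(newX)) - 0.5)
    },
    stop_ctap("unknown model family '", family, "'"))
}

# stratified (by label) split of row indices; returns list(train, test)
stratified_split <- function(labels, split_fraction) {
  idx <- seq_along(labels)
  train <- unlist(lapply(split(idx, labels), function(i)
    sample(i, size = round(length(i) * split_fraction))))
  list(train = sort(train), test = sort(setdiff(idx, train)))
}

#' Train a regulation-state classifier
#'
#' Splits the training samples 70/30 (stratified by label, seeded), fits one
#' of four classifier families on the training portion -- linear-kernel SVM,
#' L1-penalised logistic regression, Gaussian naive Bayes, or a small neural
#' network with two hidden layers of 5 and 3 rectified-linear units trained
#' with the adaptive-moment optimiser -- and evaluates on the held-out
#' portion. For SVM and LR a small hyperparameter grid is scanned and the
#' value with the highest held-out AUC kept.
#'
#' @param samples Training-sample data frame from [build_training_set()].
#' @param family `"svm"`, `"lr"`, `"gnb"` or `"nn"`.
#' @param split_fraction Fraction of samples used for fitting (default 0.7).
#' @param seed Integer seed controlling the split and any stochastic fitting.
#' @param grid Optional named list overriding the family's default
#'   hyperparameter grid.
#' @return An object of class `ctap_model`: the fitted classifier, the
#'   chosen hyperparameters, and `metrics` (a `ctap_eval` on the held-out
#'   30\%).
#' @export
ctap_train <- function(samples, family = c("svm", "lr", "gnb", "nn"),
                       split_fraction = 0.7, seed = 1, grid = NULL) {
  family <- match.arg(family)
  if (split_fraction <= 0 || split_fraction >= 1)
    stop_ctap("split_fraction must lie in (0, 1)")
  X <- as.matrix(samples[, feature_columns])
  y <- samples$label
  if (!all(y %in% c(-1, 1))) stop_ctap("labels must be +1 / -1")
  with_seed(seed, {
    sp <- stratified_split(y, split_fraction)
    if (length(unique(y[sp$train])) < 2L || length(unique(y[sp$test])) < 2L)
      stop_ctap("single-class train or test split; reseed or rebalance")
    grid <- grid %||% default_grids()[[family]]
    combos <- if (length(grid)) do.call(expand.grid, c(grid, KEEP.OUT.ATTRS = FALSE))
              else data.frame(row.names = 1L)
    best <- NULL
    for (ci in seq_len(max(nrow(combos), 1L))) {
      hyper <- if (ncol(combos)) as.list(combos[ci, , drop = FALSE]) else list()
      fitted <- fit_family(X[sp$train, , drop = FALSE], y[sp$train],
                           family, hyper)
      auc <- auc_score(y[sp$test], fitted$score(X[sp$test, , drop = FALSE]))
      if (is.null(best) || auc > best$auc)
        best <- list(fitted = fitted, auc = auc, hyper = hyper)
    }
    metrics <- evaluate(
      predicted = ifelse(best$fitted$score(X[sp$test, , drop = FALSE]) > 0, 1, -1),
      truth = y[sp$test],
      scores = best$fitted$score(X[sp$test, , drop = FALSE]))
    structure(
      list(family = family, fitted = best$fitted, hyper = best$hyper,
           metrics = metrics, split_fraction = split_fraction, seed = seed,
           n_train = length(sp$train), n_test = length(sp$test)),
      class = "ctap_model")
  })
}

#' @export
print.ctap_model <- function(x, ...) {
  cat(sprintf("<ctap_model> %s (train %d / test %d, seed %d)\n",
              toupper(x$family), x$n_train, x$n_test, x$seed))
  print(x$metrics)
  invisible(x)
}

#' Predict regulation state for new feature vectors
#'
#' @param object A `ctap_model`.
#' @param newdata Data frame containing the five feature columns (or a
#'   numeric matrix in that column order).
#' @param type `"class"` for +1/-1 calls, `"score"` for the raw decision
#'   score (positive favours up-regulation).
#' @param ... Unused.
#' @return Numeric vector of calls or scores.
#' @export
predict.ctap_model <- function(object, newdata,
                               type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- if (is.data.frame(newdata)) as.matrix(newdata[, feature_columns])
       else as.matrix(newdata)
  s <- object$fitted$score(X)
  if (type == "score") s else ifelse(s > 0, 1, -1)
}

# -- evaluation -------------------------------------------------------------

auc_score <- function(truth, scores) {
  as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = as.vector(scores),
    levels = c(-1, 1), direction = "<", quiet = TRUE)))
}

#' Confusion counts and derived metrics
#'
#' Up-regulation (+1) is the positive class. Reports TP/TN/FP/FN, accuracy,
#' Matthews correlation coefficient, sensitivity, specificity, and (when
#' decision scores are supplied) the area under the ROC curve. Values are
#' kept at full precision; rounding to two decimals (half away from zero)
#' happens only in the print method.
#'
#' @param predicted,truth Vectors of +1/-1 labels.
#' @param scores Optional decision scores for the AUC.
#' @return An object of class `ctap_eval`.
#' @export
evaluate <- function(predicted, truth, scores = NULL) {
  if (length(predicted) != length(truth) || length(truth) == 0L)
    stop_ctap("evaluate: predicted and truth must be equal-length, non-empty")
  if (!all(c(predicted, truth) %in% c(-1, 1)))
    stop_ctap("evaluate: labels must be +1 / -1")
  tp <- sum(predicted == 1 & truth == 1)
  tn <- sum(predicted == -1 & truth == -1)
  fp <- sum(predicted == 1 & truth == -1)
  fn <- sum(predicted == -1 & truth == 1)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  structure(
    list(tp = tp, tn = tn, fp = fp, fn = fn,
         acc = (tp + tn) / (tp + tn + fp + fn),
         mcc = if (denom > 0) (tp * tn - fp * fn) / denom else 0,
         sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         auc = if (!is.null(scores)) auc_score(truth, scores) else NA_real_),
    class = "ctap_eval")
}

#' @export
print.ctap_eval <- function(x, ...) {
  fmt <- function(v) formatC(round_half_up(v, 2), format = "f", digits = 2)
  cat(sprintf("  ACC %s  MCC %s  Sn %s  Sp %s%s   (TP %d TN %d FP %d FN %d)\n",
              fmt(x$acc), fmt(x$mcc), fmt(x$sn), fmt(x$sp),
              if (is.finite(x$auc)) paste0("  AUC ", fmt(x$auc)) else "",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Random-gene baseline
#'
#' Re-trains the classifier after replacing every functional-group (and TF)
#' gene slot by a randomly drawn non-FG cohort gene that inherits the slot's
#' label. Because the random genes carry no context-consistent signal, the
#' held-out AUC should hover around 0.5 -- the null against which the FG-gene
#' models are judged.
#'
#' @inheritParams build_training_set
#' @param family Classifier family (see [ctap_train()]).
#' @param n_repeats Number of seeded repeats (0 returns an empty summary).
#' @param seed Integer seed; repeat r uses `seed + r` internally.
#' @param split_fraction Train fraction per repeat.
#' @return List with `per_repeat` (data frame of metrics per repeat) and
#'   `mean` (named numeric vector of column means).
#' @export
random_gene_baseline <- function(cohort, fg_registry,
                                 tf_directions = ctap_tf_directions(),
                                 family = "svm", n_repeats = 10, seed = 1,
                                 split_fraction = 0.7) {
  template <- build_training_set(cohort, fg_registry, tf_directions)
  slots <- unique(template[, c("gene", "group")])
  pool <- setdiff(rownames(cohort$m$values), unique(template$gene))
  if (length(pool) < nrow(slots))
    stop_ctap("not enough non-FG genes (", length(pool), ") to fill ",
              nrow(slots), " slots")
  if (n_repeats == 0L)
    return(list(per_repeat = data.frame(), mean = numeric(0)))
  rows <- lapply(seq_len(n_repeats), function(r) {
    with_seed(seed + r, {
      repl <- sample(pool, nrow(slots))
      samples <- template
      map <- setNames(repl, paste(slots$gene, slots$group))
      key <- paste(template$gene, template$group)
      samples$gene <- unname(map[key])
      feats <- feature_table(cohort, samples$gene[seq_len(nrow(slots))])
      # feature_table returns entries x cp blocks in the same order
      samples[, feature_columns] <- feats[, feature_columns]
      model <- ctap_train(samples, family, split_fraction, seed = seed + r,
                          grid = list())
      m <- model$metrics
      data.frame(repeat_ = r, acc = m$acc, mcc = m$mcc, sn = m$sn,
                 sp = m$sp, auc = m$auc)
    })
  })
  per_repeat <- do.call(rbind, rows)
  list(per_repeat = per_repeat,
       mean = colMeans(per_repeat[, -1L, drop = FALSE]))
}

#' Leave-one-functional-group-out TFGS evaluation
#'
#' For each functional group in turn: hold its member genes out, train on
#' the remaining groups (plus the anchor TFs), predict +1/-1 for every
#' held-out member gene in every CP, score the held-out group per CP by
#' substituting the predictions for the member log2 ratios in the group
#' score, and count the (CP, group) cells whose predicted score follows the
#' expected state. The same folds are also scored from the observed log2
#' ratios alone, giving the fold-change-only reference.
#'
#' @inheritParams build_training_set
#' @param families Classifier families to evaluate: a character vector, or a
#'   named list mixing family names with custom trainers -- functions
#'   `function(X, y)` returning `list(score = function(newX) ...)` with
#'   positive scores favouring up-regulation (useful for oracle bounds).
#' @param seed Integer seed (per-fold fitting).
#' @return List with one `tfgs_result` per family plus `log2fc_only`, and
#'   `max` (the attainable ceiling, #groups x #CPs).
#' @export
loo_fg_tfgs <- function(cohort, fg_registry,
                        tf_directions = ctap_tf_directions(),
                        families = c("svm", "lr", "gnb", "nn"), seed = 1) {
  if (length(fg_registry) < 2L) stop_ctap("need at least 2 functional groups")
  if (is.character(families)) families <- setNames(as.list(families), families)
  if (is.null(names(families)) || any(!nzchar(names(families))))
    stop_ctap("'families' entries must be named")
  n_fg <- length(fg_registry)
  cps <- cohort$cps
  follows <- lapply(families, function(f)
    matrix(NA, length(cps), n_fg,
           dimnames = list(vapply(cps, `[[`, 1L, "cp_id"),
                           vapply(fg_registry, `[[`, "", "name"))))
  follows_fc <- follows[[1L]]
  for (j in seq_len(n_fg)) {
    held <- fg_registry[[j]]
    rest <- structure(fg_registry[-j], class = "fg_registry")
    samples <- build_training_set(cohort, rest, tf_directions)
    feats <- feature_table(cohort, held$genes)
    for (f in names(families)) {
      fam <- families[[f]]
      X <- as.matrix(samples[, feature_columns])
      fit <- with_seed(seed + j,
        if (is.function(fam)) fam(X, samples$label)
        else fit_family(X, samples$label, fam))
      pred <- ifelse(fit$score(as.matrix(feats[, feature_columns])) > 0, 1, -1)
      for (ci in seq_along(cps)) {
        p <- pred[feats$cp_id == cps[[ci]]$cp_id]
        follows[[f]][ci, j] <- fg_state(fg_score(p),
                                        held$expected_state[[cps[[ci]]$context]])
      }
    }
    for (ci in seq_along(cps)) {
      fc <- vapply(held$genes, function(g)
        if (g %in% names(cps[[ci]]$log2fc)) cps[[ci]]$log2fc[[g]] else 0, 0)
      follows_fc[ci, j] <- fg_state(fg_score(fc),
                                    held$expected_state[[cps[[ci]]$context]])
    }
  }
  out <- lapply(follows, tfgs)
  out$log2fc_only <- tfgs(follows_fc)
  out$max <- n_fg * length(cps)
  out
}
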
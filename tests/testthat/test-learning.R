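test_that("training samples pair every gene entry with every CP", {
  cohort <- shared_cohort()
  fg1 <- structure(list(list(name = "G1", genes = c("CTSK", "ACP5", "MMP9"),
                             expected_state = c(OCU = "Activation",
                                                OCD = "Inhibition"))),
                   class = "fg_registry")
  ts <- build_training_set(cohort, fg1, tf_directions = list())
  expect_equal(nrow(ts), 3L * 16L)
  expect_setequal(unique(ts$label[ts$context == "OCU"]), 1)
  expect_setequal(unique(ts$label[ts$context == "OCD"]), -1)

  # anchor TFs carry their known directions as labels
  ts2 <- build_training_set(cohort, fg1)
  irf8 <- ts2[ts2$gene == "IRF8", ]
  expect_true(all(irf8$label[irf8$context == "OCU"] == -1))
  expect_true(all(irf8$label[irf8$context == "OCD"] == 1))
  expect_true(all(ts2$label[ts2$gene == "NFATC1" & ts2$context == "OCU"] == 1))
  expect_error(build_training_set(cohort, structure(list(), class = "fg_registry")),
               "empty")
})

test_that("confusion metrics match a brute-force recount", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    truth <- sample(c(-1, 1), n, replace = TRUE)
    pred <- sample(c(-1, 1), n, replace = TRUE)
    ev <- evaluate(pred, truth)
    tab <- table(factor(pred, c(-1, 1)), factor(truth, c(-1, 1)))
    expect_equal(ev$tp, tab["1", "1"], ignore_attr = TRUE)
    expect_equal(ev$tn, tab["-1", "-1"], ignore_attr = TRUE)
    expect_equal(ev$fp, tab["1", "-1"], ignore_attr = TRUE)
    expect_equal(ev$fn, tab["-1", "1"], ignore_attr = TRUE)
    expect_equal(ev$acc, mean(pred == truth))
    expect_equal(ev$sn, mean(pred[truth == 1] == 1))
    expect_equal(ev$sp, mean(pred[truth == -1] == -1))
  }
  perfect <- evaluate(c(1, -1, 1, -1), c(1, -1, 1, -1))
  expect_equal(c(perfect$acc, perfect$mcc, perfect$sn, perfect$sp),
               c(1, 1, 1, 1))
  expect_error(evaluate(numeric(0), numeric(0)), "non-empty")
  expect_error(evaluate(c(1, 2), c(1, -1)), "\\+1 / -1")
})

separable_samples <- function(n = 120, seed = 2) {
  set.seed(seed)
  label <- rep(c(1, -1), n / 2)
  data.frame(gene = sprintf("g%03d", seq_len(n)), group = "G", cp_id = 1,
             context = "OCU",
             log2fc = label * 2 + rnorm(n, sd = 0.1),
             z_col_control = rnorm(n), z_col_test = rnorm(n),
             z_row_control = rnorm(n), z_row_test = label + rnorm(n, sd = 0.1),
             label = label)
}

test_that("all four families learn a separable problem perfectly", {
  samples <- separable_samples()
  for (fam in c("svm", "lr", "gnb", "nn")) {
    m <- ctap_train(samples, fam, seed = 1)
    expect_equal(m$metrics$acc, 1, info = fam)
    expect_equal(m$metrics$mcc, 1, info = fam)
  }
})

test_that("training is deterministic and stratified given a seed", {
  samples <- shared_training()
  m1 <- ctap_train(samples, "svm", seed = 3, grid = list())
  m2 <- ctap_train(samples, "svm", seed = 3, grid = list())
  expect_identical(m1$metrics, m2$metrics)
  # stratification: held-out class balance mirrors the full set
  expect_equal(m1$n_test, round(0.3 * nrow(samples)), tolerance = 0.01)
  expect_error(ctap_train(samples, "svm", split_fraction = 1.5), "0, 1")
  one_class <- samples[samples$label == 1, ]
  expect_error(ctap_train(one_class, "svm", seed = 1), "single-class")
})

test_that("class predictions are the sign of the decision score", {
  m <- shared_model("svm")
  samples <- shared_training()[1:50, ]
  s <- predict(m, samples, type = "score")
  cl <- predict(m, samples, type = "class")
  expect_identical(cl, ifelse(s > 0, 1, -1))
  expect_true(all(cl %in% c(-1, 1)))
})

test_that("shuffled labels give chance-level AUC", {
  samples <- shared_training()
  set.seed(99)
  aucs <- replicate(20, {
    shuffled <- samples
    shuffled$label <- sample(shuffled$label)
    tryCatch(ctap_train(shuffled, "lr", seed = sample.int(1e6, 1),
                        grid = list())$metrics$auc,
             error = function(e) NA_real_)
  })
  expect_true(mean(aucs, na.rm = TRUE) > 0.4 && mean(aucs, na.rm = TRUE) < 0.6)
})

test_that("FG-gene models dominate random-gene models across seeds", {
  cohort <- shared_cohort()
  fg <- ctap_fg_osteoclast()
  wins <- vapply(1:10, function(s) {
    auc_fg <- ctap_train(shared_training(), "svm", seed = s,
                         grid = list())$metrics$auc
    auc_rand <- random_gene_baseline(cohort, fg, family = "svm",
                                     n_repeats = 1, seed = 100 + s)$mean[["auc"]]
    auc_fg > auc_rand
  }, logical(1))
  # sign test at n = 10: >= 9 wins rejects equality at p < 0.05
  expect_gte(sum(wins), 9L)
})

test_that("the random-gene baseline is seeded and validates its pool", {
  cohort <- shared_cohort()
  fg <- ctap_fg_osteoclast()
  empty <- random_gene_baseline(cohort, fg, n_repeats = 0)
  expect_equal(nrow(empty$per_repeat), 0L)
  r1 <- random_gene_baseline(cohort, fg, family = "lr", n_repeats = 2, seed = 4)
  r2 <- random_gene_baseline(cohort, fg, family = "lr", n_repeats = 2, seed = 4)
  expect_identical(r1$per_repeat, r2$per_repeat)
  # a cohort with (almost) no spare genes cannot host the baseline
  small <- simulate_cohort(ctap_sim_config(n_background_genes = 30,
                                           n_decoys = 0, seed = 1))
  small_cohort <- build_cohort(small$studies, small$cp_specs)
  expect_error(random_gene_baseline(small_cohort, fg), "not enough")
})

test_that("leave-one-group-out TFGS hits its oracle bounds", {
  cohort <- noiseless_cohort()
  fg <- ctap_fg_osteoclast()
  # in the noiseless limit the fold-change sign equals the expected direction,
  # so scoring by the first feature is an expected-label oracle
  oracle <- function(X, y) list(score = function(newX) newX[, 1])
  anti <- function(X, y) list(score = function(newX) -newX[, 1])
  const_up <- function(X, y) list(score = function(newX) rep(1, nrow(newX)))
  res <- loo_fg_tfgs(cohort, fg,
                     families = list(oracle = oracle, anti = anti,
                                     const_up = const_up))
  expect_equal(res$max, 14L * 16L)
  expect_equal(res$oracle$count, 224L)
  expect_equal(res$anti$count, 0L)
  # a constant up-call follows exactly the Activation-expected contexts:
  # every group expects Activation in 8 of the 16 CPs
  expect_equal(res$const_up$count, 112L)
  expect_equal(res$log2fc_only$count, 224L)
  expect_error(loo_fg_tfgs(cohort, fg[1], families = list(o = oracle)),
               "at least 2")
})
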